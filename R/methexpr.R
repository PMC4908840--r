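psi_fun <- function(psi, tuning) {
  switch(psi,
    huber = list(
      w = function(u) ifelse(abs(u) <= tuning, 1, tuning / abs(u)),
      psi = function(u) pmin(pmax(u, -tuning), tuning),
      dpsi = function(u) as.numeric(abs(u) <= tuning)),
    bisquare = list(
      w = function(u) ifelse(abs(u) <= tuning, (1 - (u / tuning)^2)^2, 0),
      psi = function(u) ifelse(abs(u) <= tuning,
                               u * (1 - (u / tuning)^2)^2, 0),
      dpsi = function(u) ifelse(abs(u) <= tuning,
                                (1 - (u / tuning)^2) *
                                  (1 - 5 * (u / tuning)^2), 0)))
}

irls_fit <- function(X, y, psi, tuning, scale, max_iter, tol, start) {
  fns <- psi_fun(psi, tuning)
  beta <- start
  iter <- 0L
  rel <- Inf
  repeat {
    iter <- iter + 1L
    r <- y - X %*% beta
    w <- fns$w(as.numeric(r) / scale)
    if (all(w == 0)) w[] <- 1e-8  # pathological: every point rejected
    wX <- X * w
    beta_new <- solve(crossprod(wX, X), crossprod(wX, y))
    rel <- max(abs(beta_new - beta)) / max(1e-12, max(abs(beta)))
    beta <- beta_new
    if (rel < tol || iter >= max_iter) break
  }
  list(beta = as.numeric(beta), iterations = iter, rel_change = rel,
       converged = rel < tol, fns = fns)
}

#' Robust regression of promoter methylation on expression
#'
#' Intra-individual association model of the expression-correlation stage:
#' the response is the gene's per-sample M-value, the predictors are the
#' gene's expression level and fibrosis stage, optionally with an
#' expression-by-fibrosis interaction. Fitting is a redescending
#' M-estimator: iteratively reweighted least squares with a Huber start
#' (k = 1.345) and Tukey bisquare weights (c = 4.685), scale fixed at the
#' MAD of the Huber residuals; this resists the gross outliers that arise
#' in small clinical expression cohorts. P-values use the classical
#' M-estimation variance (Huber 1973) with a t reference on n - p degrees
#' of freedom. `psi = "ols"` gives the plain least-squares fit (the
#' constant-weight limit).
#'
#' @param m numeric vector of per-sample M-values (response).
#' @param expr numeric vector of per-sample expression (predictor of
#'   interest).
#' @param fibrosis optional numeric ordinal fibrosis stage, added as a
#'   covariate.
#' @param interaction add an `expr x fibrosis` term; the reported
#'   `coefficient`/`p` stay those of the expression main effect, the
#'   interaction term is returned alongside.
#' @param psi `"bisquare"` (default, Huber start), `"huber"`, or `"ols"`.
#' @param tuning bisquare tuning constant (default 4.685, 95 % Gaussian
#'   efficiency).
#' @param max_iter,tol IRLS iteration cap and relative-change tolerance.
#' @return list with `coefficient` and `p` for the expression term, all
#'   `coefficients`, `se`, `n_used`, `iterations`, `converged`, `scale`,
#'   and (when `interaction`) `interaction_coefficient`, `interaction_p`.
#' @export
robust_regression <- function(m, expr, fibrosis = NULL, interaction = FALSE,
                              psi = c("bisquare", "huber", "ols"),
                              tuning = 4.685, max_iter = 200, tol = 1e-9) {
  psi <- match.arg(psi)
  stopifnot(length(m) == length(expr))
  if (!is.null(fibrosis)) stopifnot(length(fibrosis) == length(m))
  keep <- stats::complete.cases(m, expr,
                                if (is.null(fibrosis)) rep(0, length(m))
                                else fibrosis)
  m <- m[keep]; expr <- expr[keep]
  if (!is.null(fibrosis)) fibrosis <- fibrosis[keep]
  n <- length(m)
  if (stats::sd(expr) == 0) {
    stop_input("expression has no variation; cannot fit association model")
  }
  X <- cbind(`(Intercept)` = 1, expr = expr)
  if (!is.null(fibrosis)) X <- cbind(X, fibrosis = fibrosis)
  if (interaction) {
    if (is.null(fibrosis)) {
      stop_input("interaction model requires a fibrosis vector")
    }
    X <- cbind(X, `expr:fibrosis` = expr * fibrosis)
  }
  p <- ncol(X)
  if (n < p + 3) {
    stop_input("need at least ", p + 3, " complete samples for ", p,
               " model terms; have ", n)
  }
  if (qr(X)$rank < p) stop_input("singular design in robust regression")

  ols_beta <- qr.solve(X, m)
  res_ols <- m - X %*% ols_beta

  if (psi == "ols") {
    rdf <- n - p
    sigma2 <- sum(res_ols^2) / rdf
    se <- sqrt(diag(solve(crossprod(X))) * sigma2)
    tv <- ols_beta / se
    pv <- 2 * stats::pt(-abs(tv), rdf)
    out <- list(coefficient = unname(ols_beta["expr"]),
                p = unname(pv["expr"]),
                coefficients = stats::setNames(as.numeric(ols_beta),
                                               colnames(X)),
                se = stats::setNames(as.numeric(se), colnames(X)),
                n_used = n, iterations = 0L, converged = TRUE,
                scale = sqrt(sigma2), psi = psi)
    if (interaction) {
      out$interaction_coefficient <- unname(ols_beta["expr:fibrosis"])
      out$interaction_p <- unname(pv["expr:fibrosis"])
    }
    return(out)
  }

  s0 <- stats::mad(as.numeric(res_ols))
  if (s0 < 1e-10) {
    # (near-)exact linear data: the OLS solution is the robust solution
    coefs <- stats::setNames(as.numeric(ols_beta), colnames(X))
    out <- list(coefficient = unname(coefs["expr"]), p = 0,
                coefficients = coefs,
                se = stats::setNames(rep(0, p), colnames(X)),
                n_used = n, iterations = 0L, converged = TRUE, scale = 0,
                psi = psi)
    if (interaction) {
      out$interaction_coefficient <- unname(coefs["expr:fibrosis"])
      out$interaction_p <- 0
    }
    return(out)
  }

  hub <- irls_fit(X, m, "huber", 1.345, s0, max_iter, tol,
                  start = as.numeric(ols_beta))
  s1 <- stats::mad(as.numeric(m - X %*% hub$beta))
  if (s1 < 1e-10) s1 <- s0
  fit <- if (psi == "bisquare") {
    irls_fit(X, m, "bisquare", tuning, s1, max_iter, tol, start = hub$beta)
  } else hub
  if (!fit$converged) {
    stop("robust regression did not converge after ", fit$iterations,
         " iterations (last relative change ",
         format(fit$rel_change, digits = 3), ")", call. = FALSE)
  }
  scale_used <- if (psi == "bisquare") s1 else s0
  u <- as.numeric(m - X %*% fit$beta) / scale_used
  fns <- fit$fns
  num <- sum(fns$psi(u)^2) / (n - p)
  den <- (mean(fns$dpsi(u)))^2
  tau2 <- scale_used^2 * num / den
  se <- sqrt(diag(solve(crossprod(X))) * tau2)
  tv <- fit$beta / se
  pv <- 2 * stats::pt(-abs(tv), n - p)
  names(pv) <- names(se) <- colnames(X)
  out <- list(coefficient = unname(fit$beta[match("expr", colnames(X))]),
              p = unname(pv["expr"]),
              coefficients = stats::setNames(fit$beta, colnames(X)),
              se = se, n_used = n, iterations = fit$iterations +
                hub$iterations, converged = TRUE, scale = scale_used,
              psi = psi)
  if (interaction) {
    out$interaction_coefficient <-
      unname(fit$beta[match("expr:fibrosis", colnames(X))])
    out$interaction_p <- unname(pv["expr:fibrosis"])
  }
  out
}

#' Pearson correlation of methylation and expression in a subgroup
#'
#' Uncorrected sample Pearson correlation with a two-sided t-test
#' (df = n - 2), applied within a diagnosis subgroup (NAFLD cases or
#' controls) of the matched cohort.
#'
#' @param m per-sample M-values.
#' @param expr per-sample expression.
#' @param subgroup optional logical mask selecting the subgroup (default:
#'   all samples).
#' @return list with `r`, `p`, `n_used`.
#' @export
pearson_subgroup <- function(m, expr, subgroup = NULL) {
  stopifnot(length(m) == length(expr))
  if (is.null(subgroup)) subgroup <- rep(TRUE, length(m))
  stopifnot(length(subgroup) == length(m))
  m <- m[subgroup]; expr <- expr[subgroup]
  keep <- stats::complete.cases(m, expr)
  m <- m[keep]; expr <- expr[keep]
  if (length(m) < 3) stop_input("subgroup has fewer than 3 complete samples")
  if (stats::sd(m) == 0 || stats::sd(expr) == 0) {
    stop_input("zero variance in methylation or expression; ",
               "correlation undefined")
  }
  ct <- stats::cor.test(m, expr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = length(m))
}

# collapse duplicate expression rows (multiple transcript ids per gene) by
# mean, reporting the per-gene id count
collapse_expression <- function(expression) {
  genes <- toupper(rownames(expression))
  if (!anyDuplicated(genes)) {
    rownames(expression) <- genes
    return(expression)
  }
  counts <- table(genes)
  multi <- counts[counts > 1]
  message("collapse_expression: averaging ", length(multi),
          " gene(s) with multiple transcript identifiers (",
          paste(utils::head(sprintf("%s x%d", names(multi), multi), 5),
                collapse = ", "), ")")
  out <- rowsum(expression, group = genes) / as.vector(counts[sort(unique(genes))])
  out[order(rownames(out)), , drop = FALSE]
}

assoc_empty <- function() {
  out <- data.frame(gene = character(), direction = character(),
                    model = character(), coefficient = numeric(),
                    p = numeric(), n_used = integer(),
                    neighbor_of = character(), stringsAsFactors = FALSE)
  class(out) <- c("meth_expr_assoc", "data.frame")
  out
}

#' Methylation-expression association for validated genes
#'
#' For every gene x direction methylation profile, fits four models in the
#' matched (EC) cohort: a robust regression of the M-value on expression
#' adjusting for fibrosis; the same with an expression-by-fibrosis
#' interaction; and uncorrected Pearson correlations within the NAFLD
#' (SS/NASH) and control subgroups. Genes absent from the expression matrix
#' are skipped with a message.
#'
#' @param profiles `gene_meth_profile` data frame from
#'   [gene_methylation_profiles()].
#' @param expression genes x samples matrix of log-scale intensities;
#'   duplicate gene rows are collapsed by mean.
#' @param samples sample table for the matched cohort (needs `sample_id`,
#'   `diagnosis`, `fibrosis_stage`).
#' @param psi robust weight function passed to [robust_regression()].
#' @param orientation `"m_on_expr"` (default: M-value is the response,
#'   expression the predictor) or `"expr_on_m"` (reversed; the robust slope
#'   is then expression change per M-value unit, the scale on which a
#'   planted coupling slope is defined). The choice is recorded in the
#'   `orientation` attribute of the result.
#' @return data frame of class `meth_expr_assoc`: one row per
#'   gene x direction x model (`robust_adjusted`, `robust_interaction`,
#'   `pearson_cases`, `pearson_controls`) with `coefficient` (robust slope
#'   or Pearson r), `p`, `n_used`.
#' @export
associate_genes <- function(profiles, expression, samples,
                            psi = "bisquare",
                            orientation = c("m_on_expr", "expr_on_m")) {
  orientation <- match.arg(orientation)
  expression <- collapse_expression(as.matrix(expression))
  rows <- list()
  combos <- unique(profiles[, c("gene", "direction")])
  for (k in seq_len(nrow(combos))) {
    g <- combos$gene[k]; dir <- combos$direction[k]
    if (!g %in% rownames(expression)) {
      message("associate_genes: no expression row for gene '", g,
              "'; skipped")
      next
    }
    prof <- profiles[profiles$gene == g & profiles$direction == dir, ,
                     drop = FALSE]
    ids <- intersect(prof$sample_id, colnames(expression))
    ids <- intersect(ids, samples$sample_id)
    prof <- prof[match(ids, prof$sample_id), , drop = FALSE]
    ex <- expression[g, ids]
    meta <- samples[match(ids, samples$sample_id), , drop = FALSE]
    fib <- as.numeric(meta$fibrosis_stage)
    fib[is.na(fib)] <- 0
    is_case <- meta$diagnosis %in% c("SS", "NASH", "unknown")

    resp <- if (orientation == "m_on_expr") prof$m_value else ex
    pred <- if (orientation == "m_on_expr") ex else prof$m_value
    ra <- robust_regression(resp, pred, fib, interaction = FALSE, psi = psi)
    ri <- robust_regression(resp, pred, fib, interaction = TRUE, psi = psi)
    pc <- tryCatch(pearson_subgroup(prof$m_value, ex, is_case),
                   error = function(e) NULL)
    pn <- tryCatch(pearson_subgroup(prof$m_value, ex, !is_case),
                   error = function(e) NULL)
    add <- function(model, coefficient, p, n_used) {
      data.frame(gene = g, direction = dir, model = model,
                 coefficient = coefficient, p = p, n_used = n_used,
                 neighbor_of = NA_character_, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(
      add("robust_adjusted", ra$coefficient, ra$p, ra$n_used),
      add("robust_interaction", ri$coefficient, ri$p, ri$n_used),
      if (!is.null(pc)) add("pearson_cases", pc$r, pc$p, pc$n_used),
      if (!is.null(pn)) add("pearson_controls", pn$r, pn$p, pn$n_used))
  }
  out <- if (length(rows)) do.call(rbind, rows) else assoc_empty()
  rownames(out) <- NULL
  attr(out, "orientation") <- orientation
  class(out) <- c("meth_expr_assoc", "data.frame")
  out
}

#' Neighboring-gene expression scan
#'
#' Asks whether a validated gene's promoter methylation also tracks the
#' expression of its genomic neighbors: for each gene x direction profile,
#' the robust fibrosis-adjusted model is refit against the expression of up
#' to `k` genes upstream and `k` downstream of the source gene's TSS. Rows
#' carry `gene` = the expression (neighbor) gene and `neighbor_of` = the
#' methylation source gene. Neighbors without expression data are skipped
#' with a message.
#'
#' @param profiles `gene_meth_profile` data frame.
#' @param expression genes x samples expression matrix.
#' @param gene_coords gene coordinate table (see [neighbor_genes()]).
#' @param samples matched-cohort sample table.
#' @param k neighbors per side (default 5).
#' @param psi robust weight function.
#' @return `meth_expr_assoc` data frame of `robust_adjusted` rows with
#'   `neighbor_of` set.
#' @export
neighbor_expression_scan <- function(profiles, expression, gene_coords,
                                     samples, k = 5, psi = "bisquare") {
  if (k == 0) return(assoc_empty())
  expression <- collapse_expression(as.matrix(expression))
  rows <- list()
  combos <- unique(profiles[, c("gene", "direction")])
  for (i in seq_len(nrow(combos))) {
    g <- combos$gene[i]; dir <- combos$direction[i]
    nbrs <- tryCatch(neighbor_genes(gene_coords, g, k),
                     error = function(e) character())
    prof <- profiles[profiles$gene == g & profiles$direction == dir, ,
                     drop = FALSE]
    for (nb in nbrs) {
      if (!nb %in% rownames(expression)) {
        message("neighbor_expression_scan: no expression for neighbor '",
                nb, "' of '", g, "'; skipped")
        next
      }
      ids <- intersect(prof$sample_id, colnames(expression))
      ids <- intersect(ids, samples$sample_id)
      pr <- prof[match(ids, prof$sample_id), , drop = FALSE]
      ex <- expression[nb, ids]
      meta <- samples[match(ids, samples$sample_id), , drop = FALSE]
      fib <- as.numeric(meta$fibrosis_stage)
      fib[is.na(fib)] <- 0
      fit <- tryCatch(
        robust_regression(pr$m_value, ex, fib, interaction = FALSE,
                          psi = psi),
        error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = nb, direction = dir, model = "robust_adjusted",
        coefficient = fit$coefficient, p = fit$p, n_used = fit$n_used,
        neighbor_of = g, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else assoc_empty()
  rownames(out) <- NULL
  class(out) <- c("meth_expr_assoc", "data.frame")
  out
}
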