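#' Fit one covariate-adjusted linear model
#'
#' Ordinary least squares of a response (typically one probe's beta values)
#' on a predictor of interest plus covariates, returning the predictor's
#' coefficient and its two-sided t-test p-value. Rows with missing values
#' are dropped listwise.
#'
#' @param y numeric response vector.
#' @param design data frame of predictors; the first column (or the one
#'   named by `predictor`) is the predictor of interest, the rest are
#'   covariates.
#' @param predictor name of the column of interest (default: first column).
#' @return list with `coefficient`, `raw_p`, `n_used`, `df_residual`.
#' @examples
#' fit_linear_model(c(1, 2, 3, 4), data.frame(x = c(0, 1, 2, 3)))
#' @export
fit_linear_model <- function(y, design, predictor = names(design)[1]) {
  stopifnot(is.data.frame(design), length(y) == nrow(design))
  if (!predictor %in% names(design)) {
    stop_input("predictor '", predictor, "' not found in design")
  }
  keep <- stats::complete.cases(y, design)
  y <- y[keep]
  design <- design[keep, , drop = FALSE]
  X <- stats::model.matrix(~ ., data = design)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    stop_input("insufficient data: ", n, " complete observations for ",
               p, " model terms")
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop_input("singular design; collinear column(s): ",
               paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  rdf <- n - p
  if (rdf < 1) stop_input("zero residual degrees of freedom")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / rdf
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  # the model-matrix column for the predictor (numeric predictors keep their
  # name; a two-level factor gets a level suffix)
  col <- if (predictor %in% colnames(X)) predictor else {
    hit <- grep(paste0("^", predictor), colnames(X), value = TRUE)
    if (length(hit) != 1L) {
      stop_input("predictor '", predictor,
                 "' maps to ", length(hit), " design columns")
    }
    hit
  }
  coefficient <- unname(fit$coefficients[col])
  tval <- coefficient / se[[col]]
  raw_p <- 2 * stats::pt(-abs(tval), df = rdf)
  list(coefficient = coefficient, raw_p = raw_p, n_used = n,
       df_residual = rdf)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: ordered p-values are scaled by
#' m/rank and made monotone from the largest down, capped at 1. Ties share
#' the min-over-tail value.
#'
#' @param raw_p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return vector of adjusted p-values, same order and length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(raw_p) {
  ok <- !is.na(raw_p)
  if (any(raw_p[ok] < 0 | raw_p[ok] > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(raw_p, method = "BH")
}

# shared per-probe scan engine: regress each probe's beta on a predictor
# plus covariates; one row per probe-gene pair, p adjusted on unique probes
scan_probes <- function(beta, probe_sets, design, predictor, covariate_names,
                        cohort, adjust = TRUE) {
  pairs <- data.frame(
    gene = rep(names(probe_sets), lengths(probe_sets)),
    probe_id = unlist(probe_sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[pairs$probe_id %in% rownames(beta), , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop_input("no probes from the probe sets are present in the beta matrix")
  }
  uprobe <- unique(pairs$probe_id)
  fits <- lapply(uprobe, function(pid) {
    fit_linear_model(beta[pid, ], design, predictor = predictor)
  })
  coefv <- vapply(fits, `[[`, numeric(1), "coefficient")
  rawp <- vapply(fits, `[[`, numeric(1), "raw_p")
  nused <- vapply(fits, `[[`, numeric(1), "n_used")
  adjp <- if (adjust) bh_adjust(rawp) else rep(NA_real_, length(rawp))
  i <- match(pairs$probe_id, uprobe)
  res <- data.frame(
    probe_id = pairs$probe_id,
    gene = pairs$gene,
    predictor = predictor,
    cohort = cohort,
    n_used = nused[i],
    coefficient = coefv[i],
    raw_p = rawp[i],
    adjusted_p = adjp[i],
    direction = ifelse(coefv[i] >= 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )
  res$significant <- if (adjust) res$adjusted_p < 0.05 else res$raw_p < 0.05
  res <- res[order(res$gene, res$probe_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "covariates") <- covariate_names
  class(res) <- c("cpg_scan", "data.frame")
  res
}

covariate_design <- function(samples, covariates) {
  avail <- character()
  design <- list()
  for (cv in covariates) {
    if (cv %in% names(samples) && any(!is.na(samples[[cv]]))) {
      v <- samples[[cv]]
      if (cv == "sex") v <- as.numeric(v == "female")
      design[[cv]] <- v
      avail <- c(avail, cv)
    }
  }
  list(design = design, used = avail)
}

#' Discovery scan: per-CpG disease regression
#'
#' Regresses each TSS1500 probe's beta values on NAFLD status (control = 0,
#' SS or NASH = 1), adjusting for age, sex and BMI, across the discovery
#' cohort. P-values are Benjamini-Hochberg adjusted across the scan family
#' (all unique probes passed in, i.e. one gene cluster per call by default);
#' significance means adjusted p < 0.05.
#'
#' @param beta probe-by-sample matrix of beta values.
#' @param samples sample table with `diagnosis` (`control`/`SS`/`NASH`) and
#'   covariate columns; row order must match `colnames(beta)` by
#'   `sample_id`.
#' @param probe_sets named list (gene -> probe ids), e.g. from
#'   [tss1500_probe_sets()].
#' @param covariates covariate columns to adjust for when present.
#' @param fdr_threshold significance threshold on adjusted p.
#' @return a `cpg_scan` data frame: one row per probe-gene pair with
#'   `coefficient` (beta change, control to NAFLD), `raw_p`, `adjusted_p`,
#'   `direction` (`hyper`/`hypo`), `significant`.
#' @export
discovery_scan <- function(beta, samples, probe_sets,
                           covariates = c("age", "sex", "bmi"),
                           fdr_threshold = 0.05) {
  samples <- align_samples(beta, samples)
  if (!all(c("control") %in% samples$diagnosis) ||
      !any(samples$diagnosis %in% c("SS", "NASH"))) {
    stop_input("discovery cohort must contain both control and NAFLD ",
               "(SS/NASH) samples")
  }
  disease <- as.numeric(samples$diagnosis %in% c("SS", "NASH"))
  cd <- covariate_design(samples, covariates)
  design <- data.frame(disease = disease, cd$design,
                       stringsAsFactors = FALSE)
  res <- scan_probes(beta, probe_sets, design, "disease", cd$used,
                     cohort = "discovery", adjust = TRUE)
  res$significant <- res$adjusted_p < fdr_threshold
  res
}

#' Validation scan: per-CpG disease-progression regression
#'
#' In the NAFLD-only validation cohort, regresses each probe's beta values
#' on an ordinal stage variable (fibrosis stage 0-2 or steatosis grade 0-3),
#' adjusting for whichever of the requested covariates are present (the used
#' set is recorded in the `covariates` attribute). This is a targeted
#' confirmation of discovery hits, so raw p < 0.05 counts as significant
#' and no FDR adjustment is applied.
#'
#' @param beta probe-by-sample beta matrix.
#' @param samples sample table with `fibrosis_stage` / `steatosis_grade`.
#' @param probe_sets named list (gene -> probe ids).
#' @param stage_variable `"fibrosis"` or `"steatosis"`.
#' @param covariates covariates to adjust for when available.
#' @param p_threshold raw-p significance threshold.
#' @return a `cpg_scan` data frame (`adjusted_p` is NA here).
#' @export
validation_scan <- function(beta, samples, probe_sets,
                            stage_variable = c("fibrosis", "steatosis"),
                            covariates = c("age", "sex", "bmi"),
                            p_threshold = 0.05) {
  stage_variable <- match.arg(stage_variable)
  samples <- align_samples(beta, samples)
  col <- if (stage_variable == "fibrosis") "fibrosis_stage" else
    "steatosis_grade"
  if (!col %in% names(samples)) {
    stop_input("sample table lacks column '", col, "'")
  }
  stage <- as.numeric(samples[[col]])
  if (length(unique(stage[!is.na(stage)])) < 2) {
    stop_input("stage variable '", stage_variable,
               "' has no variation in this cohort")
  }
  cd <- covariate_design(samples, covariates)
  design <- data.frame(stage = stage, cd$design, stringsAsFactors = FALSE)
  names(design)[1] <- stage_variable
  res <- scan_probes(beta, probe_sets, design, stage_variable, cd$used,
                     cohort = "validation", adjust = FALSE)
  res$significant <- res$raw_p < p_threshold
  res
}

align_samples <- function(beta, samples) {
  if (!"sample_id" %in% names(samples)) {
    stop_input("sample table must have a 'sample_id' column")
  }
  idx <- match(colnames(beta), samples$sample_id)
  if (anyNA(idx)) {
    stop_input("beta matrix columns missing from the sample table: ",
               paste(utils::head(colnames(beta)[is.na(idx)], 5),
                     collapse = ", "))
  }
  samples[idx, , drop = FALSE]
}

#' Direction-consistent validated CpG sites
#'
#' A probe-gene pair is carried forward iff it is significant in the
#' discovery scan (FDR-adjusted p below threshold), significant in the
#' validation scan (raw p below threshold, fibrosis by default), and the
#' coefficient signs agree in the two cohorts. The agreed direction is
#' recorded as `hyper` (methylation rises with disease/stage) or `hypo`.
#'
#' @param discovery a `cpg_scan` from [discovery_scan()].
#' @param validation a `cpg_scan` from [validation_scan()].
#' @return data frame with columns `probe_id`, `gene`, `direction`,
#'   `coefficient_discovery`, `coefficient_validation`, `adjusted_p`,
#'   `raw_p_validation`, `validated` (all rows shared by both scans; the
#'   validated subset is the analysis set downstream).
#' @export
consistent_validated_sites <- function(discovery, validation) {
  key <- c("probe_id", "gene")
  merged <- merge(discovery, validation, by = key,
                  suffixes = c("_disc", "_val"))
  if (nrow(merged) == 0L) {
    stop_input("discovery and validation scans share no probe-gene pairs")
  }
  same_sign <- sign(merged$coefficient_disc) == sign(merged$coefficient_val)
  validated <- merged$significant_disc & merged$significant_val & same_sign
  out <- data.frame(
    probe_id = merged$probe_id,
    gene = merged$gene,
    direction = ifelse(merged$coefficient_disc >= 0, "hyper", "hypo"),
    coefficient_discovery = merged$coefficient_disc,
    coefficient_validation = merged$coefficient_val,
    adjusted_p = merged$adjusted_p_disc,
    raw_p_validation = merged$raw_p_val,
    validated = validated,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
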