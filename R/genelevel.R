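#' Binomial overrepresentation test for a gene's significant CpG sites
#'
#' Upper-tail probability that at least `n_sig` of a gene's `n_total`
#' TSS1500 CpG sites would be called significant if each site were
#' independently significant at the null rate `p0`: P(X >= n_sig) for
#' X ~ Binomial(n_total, p0). Small tails (down to ~1e-20) are computed
#' stably via the complementary binomial CDF.
#'
#' @param n_sig number of validated significant sites (one direction).
#' @param n_total total TSS1500 sites of the gene.
#' @param p0 per-site null significance rate (default 0.05).
#' @return upper-tail probability in (0, 1].
#' @examples
#' binomial_overrepresentation(6, 7)   # 1.05e-07
#' binomial_overrepresentation(8, 8)   # 0.05^8
#' @export
binomial_overrepresentation <- function(n_sig, n_total, p0 = 0.05) {
  if (any(n_total < 1)) stop_input("n_total must be >= 1")
  if (any(n_sig < 0) || any(n_sig > n_total)) {
    stop_input("n_sig must lie in [0, n_total]")
  }
  if (p0 <= 0 || p0 >= 1) stop_input("p0 must lie in (0, 1)")
  stats::pbinom(n_sig - 1, size = n_total, prob = p0, lower.tail = FALSE)
}

#' Percentage of differentially methylated sites
#'
#' Integer percentage `100 * n_sig / n_total`, rounded half away from zero
#' (the printed-table convention, so 85.7 -> 86 and 12.5 -> 13).
#'
#' @param n_sig significant site count.
#' @param n_total total site count (>= 1).
#' @return integer percent.
#' @examples
#' percent_significant(6, 7)   # 86
#' percent_significant(9, 13)  # 69
#' @export
percent_significant <- function(n_sig, n_total) {
  if (any(n_total < 1)) stop_input("n_total must be >= 1")
  as.integer(round_half_away(100 * n_sig / n_total))
}

#' Categorize the strength of a gene's methylation change
#'
#' Three-tier scheme combining CpG density and the fraction of changed
#' sites:
#' \itemize{
#'   \item category 1 (strong): >= 7 TSS1500 sites with >= 50 % changed;
#'   \item category 2 (medium): 3-6 sites with >= 50 % changed, or >= 7
#'     sites with 30-50 % changed (30 % inclusive, 50 % exclusive there);
#'   \item category 3 (weak): fewer than 3 sites, or < 30 % changed, or
#'     3-6 sites with < 50 % changed.
#' }
#' `n_sig` here is the combined count of changed sites (both directions).
#'
#' @param n_total total TSS1500 sites (>= 0).
#' @param n_sig changed sites, `0 <= n_sig <= n_total`.
#' @return integer category 1, 2 or 3 (vectorized).
#' @examples
#' categorize_gene(7, 6)   # 1
#' categorize_gene(3, 2)   # 2
#' categorize_gene(21, 2)  # 3
#' @export
categorize_gene <- function(n_total, n_sig) {
  if (any(n_total < 0) || any(n_sig < 0) || any(n_sig > n_total)) {
    stop_input("need 0 <= n_sig <= n_total")
  }
  frac <- ifelse(n_total > 0, n_sig / n_total, 0)
  out <- rep(3L, length(frac))
  out[n_total >= 7 & frac >= 0.5] <- 1L
  out[(n_total >= 3 & n_total <= 6 & frac >= 0.5) |
        (n_total >= 7 & frac >= 0.3 & frac < 0.5)] <- 2L
  out
}

#' Split validated sites by methylation direction
#'
#' Partitions a validated-site table into per-gene hyper- and hypomethylated
#' site sets. A gene may contribute to both directions (a predominantly
#' hypermethylated promoter can still carry an isolated hypomethylated
#' site).
#'
#' @param sites data frame with columns `gene`, `probe_id`, `direction`
#'   (`hyper`/`hypo`), e.g. the validated subset from
#'   [consistent_validated_sites()].
#' @return list with elements `hyper` and `hypo`, each a named list
#'   (gene -> probe ids).
#' @export
split_by_direction <- function(sites) {
  stopifnot(all(c("gene", "probe_id", "direction") %in% names(sites)))
  if (nrow(sites) && !all(sites$direction %in% c("hyper", "hypo"))) {
    stop_input("direction must be 'hyper' or 'hypo'")
  }
  one <- function(d) {
    sub <- sites[sites$direction == d, , drop = FALSE]
    if (!nrow(sub)) return(stats::setNames(list(), character(0)))
    lapply(split(sub$probe_id, sub$gene), unique)
  }
  list(hyper = one("hyper"), hypo = one("hypo"))
}

#' Per-sample mean beta over a site set
#'
#' @param beta probe-by-sample beta matrix.
#' @param site_set character vector of probe ids (nonempty, present in
#'   `beta`).
#' @return named numeric vector, one mean per sample.
#' @export
average_beta <- function(beta, site_set) {
  if (length(site_set) == 0L) {
    stop_input("cannot average over an empty site set")
  }
  missing <- setdiff(site_set, rownames(beta))
  if (length(missing)) {
    stop_input("site(s) absent from beta matrix: ",
               paste(utils::head(missing, 5), collapse = ", "))
  }
  colMeans(beta[site_set, , drop = FALSE], na.rm = TRUE)
}

#' Beta to M-value transformation
#'
#' `M = log2(beta / (1 - beta))`, the log2 ratio of methylated to
#' unmethylated intensity. Variance-stabilizes the methylation fraction for
#' correlation with expression. Inputs at 0 or 1 are clamped to
#' `[eps, 1 - eps]` before the transform.
#'
#' @param beta numeric vector/matrix in `[0, 1]`.
#' @param eps clamp width (default 1e-6).
#' @return M-values, same shape as the input.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  vals <- beta[!is.na(beta)]
  if (length(vals) && (any(vals < 0) || any(vals > 1))) {
    stop_input("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' M-value to beta transformation (inverse of [beta_to_m()])
#'
#' @param m numeric M-values.
#' @return beta fractions in (0, 1).
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Gene-level summaries of validated methylation changes
#'
#' Collapses validated CpG sites to one row per gene and direction:
#' total TSS1500 sites, validated sites in that direction, the percent of
#' changed sites, the binomial overrepresentation p-value (per direction),
#' and the change-strength category (computed from the combined count of
#' changed sites in both directions).
#'
#' @param validated_sites validated-site data frame (`gene`, `probe_id`,
#'   `direction`), e.g. `subset(consistent_validated_sites(...), validated)`.
#' @param probe_sets named list (gene -> all TSS1500 probe ids); defines
#'   `n_total` per gene.
#' @param p0 per-site null rate for the binomial test.
#' @param cluster optional cluster label recorded in the output.
#' @return data frame of class `gene_meth_summary` with columns `gene`,
#'   `direction`, `n_total`, `n_sig`, `n_sig_combined`, `pct_sig`,
#'   `p_binomial`, `category`, `cluster`.
#' @export
summarize_gene_methylation <- function(validated_sites, probe_sets,
                                       p0 = 0.05, cluster = NA_character_) {
  split_sets <- split_by_direction(validated_sites)
  rows <- list()
  for (dir in c("hyper", "hypo")) {
    sets <- split_sets[[dir]]
    for (g in names(sets)) {
      if (!g %in% names(probe_sets)) {
        stop_input("gene '", g, "' has validated sites but no probe set")
      }
      n_total <- length(probe_sets[[g]])
      n_sig <- length(sets[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, direction = dir, n_total = n_total, n_sig = n_sig,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(gene = character(), direction = character(),
                      n_total = integer(), n_sig = integer(),
                      n_sig_combined = integer(), pct_sig = integer(),
                      p_binomial = numeric(), category = integer(),
                      cluster = character(), stringsAsFactors = FALSE)
    class(out) <- c("gene_meth_summary", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  combined <- tapply(out$n_sig, out$gene, sum)
  out$n_sig_combined <- as.integer(combined[out$gene])
  out$pct_sig <- percent_significant(out$n_sig, out$n_total)
  out$p_binomial <- binomial_overrepresentation(out$n_sig, out$n_total, p0)
  out$category <- categorize_gene(out$n_total, out$n_sig_combined)
  out$cluster <- cluster
  out <- out[order(out$direction, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_meth_summary", "data.frame")
  out
}

#' Per-sample methylation profiles for validated genes
#'
#' For each gene and direction, averages the beta values of the validated
#' sites of that direction across samples and transforms the mean to an
#' M-value. These per-sample profiles are the methylation side of the
#' methylation-expression association stage.
#'
#' @param beta probe-by-sample beta matrix (typically the EC cohort).
#' @param validated_sites validated-site data frame (`gene`, `probe_id`,
#'   `direction`).
#' @param all_sites optional named list (gene -> probe ids); when supplied,
#'   averaging uses all TSS1500 sites of the gene instead of only the
#'   validated ones (all-sites mode).
#' @return data frame of class `gene_meth_profile`: one row per
#'   gene x direction x sample with `mean_beta` and `m_value`.
#' @export
gene_methylation_profiles <- function(beta, validated_sites,
                                      all_sites = NULL) {
  split_sets <- split_by_direction(validated_sites)
  rows <- list()
  for (dir in c("hyper", "hypo")) {
    sets <- split_sets[[dir]]
    for (g in names(sets)) {
      ids <- if (is.null(all_sites)) sets[[g]] else all_sites[[g]]
      ids <- intersect(ids, rownames(beta))
      if (!length(ids)) next
      mb <- average_beta(beta, ids)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, direction = dir, sample_id = names(mb),
        n_sites = length(ids), mean_beta = unname(mb),
        m_value = unname(beta_to_m(mb)), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), direction = character(),
               sample_id = character(), n_sites = integer(),
               mean_beta = numeric(), m_value = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_meth_profile", "data.frame")
  out
}
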