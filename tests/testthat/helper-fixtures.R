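# in-code fixtures shared across test files

toy_annotation <- function() {
  data.frame(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05", "cg06"),
    chrom = "chr1",
    pos = c(900, 1500, 2500, 4000, 1200, 1800),
    gene = c("GENEA", "GENEA", "GENEA", "GENEA", "GENEB", "GENEB"),
    tss_distance = c(-100, 1500, -1501, 3000, 0, 600),
    snp_overlap = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

write_annotation_csv <- function(df, path = tempfile(fileext = ".csv"),
                                 names_map = NULL) {
  if (!is.null(names_map)) names(df)[match(names(names_map), names(df))] <-
    unlist(names_map)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# evenly spaced synthetic gene coordinates on one chromosome
toy_gene_coords <- function(n = 11, spacing = 1000) {
  data.frame(gene = sprintf("G%02d", seq_len(n)), chrom = "chr1",
             tss_pos = seq_len(n) * spacing, strand = "+",
             stringsAsFactors = FALSE)
}

# minimal sample table for scan tests
toy_samples <- function(n_control = 37, n_case = 37, seed = 1) {
  set.seed(seed)
  n <- n_control + n_case
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    diagnosis = rep(c("control", "SS"), c(n_control, n_case)),
    age = rnorm(n, 50, 10),
    sex = sample(c("male", "female"), n, replace = TRUE),
    bmi = rnorm(n, 35, 8),
    fibrosis_stage = NA_integer_,
    steatosis_grade = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# brute-force step-up FDR oracle: adjusted p_i = min over all j whose sorted
# rank is >= rank(i) of p_(j) * m / j, capped at 1 (computed by definition,
# independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- match(seq_along(p), ord)  # rank of each element after sorting
  sapply(seq_along(p), function(i) {
    js <- which(seq_len(m) >= ranks[i])
    min(1, min(p[ord[js]] * m / js))
  })
}

# normal-equations OLS oracle returning coefficient and p for one column
ols_oracle <- function(y, X, col) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  rdf <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / rdf
  se <- sqrt(diag(solve(XtX)) * s2)
  tv <- unname(b[col, 1] / se[col])
  list(coefficient = unname(b[col, 1]), p = 2 * pt(-abs(tv), rdf))
}

# exact binomial upper tail by direct summation of the pmf
binom_tail_oracle <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
             numeric(1)))
}
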