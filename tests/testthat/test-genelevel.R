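# (total, significant) counts and binomial tails as printed in the published
# gene summaries (3 significant figures)
published_binomials <- data.frame(
  gene = c("ABCB11", "ABCC2", "ABCG5", "CYP7B1", "CYP8B1", "EPHX1",
           "HNF1A", "NR2A1", "SLC51A"),
  n_total = c(3, 5, 12, 12, 6, 13, 8, 18, 7),
  n_sig = c(2, 3, 11, 4, 5, 9, 8, 15, 6),
  p = c(7.25e-3, 1.16e-3, 5.59e-14, 2.24e-3, 1.80e-6, 1.16e-9,
        3.91e-11, 2.16e-17, 1.05e-7),
  stringsAsFactors = FALSE
)

test_that("binomial overrepresentation reproduces the published tails", {
  got <- binomial_overrepresentation(published_binomials$n_sig,
                                     published_binomials$n_total)
  expect_equal(signif(got, 3), published_binomials$p)
  # analytic anchor: all sites significant is p0^n
  expect_equal(binomial_overrepresentation(8, 8), 0.05^8, tolerance = 1e-15)
  expect_equal(binomial_overrepresentation(0, 10), 1)
  expect_error(binomial_overrepresentation(4, 3), "n_sig")
  expect_error(binomial_overrepresentation(1, 0), "n_total")
  expect_error(binomial_overrepresentation(1, 2, p0 = 0), "p0")
})

test_that("binomial tail matches direct summation and decreases in k", {
  for (n in 1:25) {
    ks <- 0:n
    got <- binomial_overrepresentation(ks, rep(n, n + 1))
    want <- vapply(ks, binom_tail_oracle, numeric(1), n = n, p0 = 0.05)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(diff(got) < 0))  # strictly decreasing in n_sig
  }
  # numerically stable deep into the tail
  expect_gt(binomial_overrepresentation(20, 20), 0)
  expect_equal(log(binomial_overrepresentation(20, 20)), 20 * log(0.05),
               tolerance = 1e-10)
})

test_that("percent of changed sites uses half-away-from-zero rounding", {
  expect_identical(percent_significant(6, 7), 86L)
  expect_identical(percent_significant(9, 13), 69L)
  expect_identical(percent_significant(5, 13), 38L)
  expect_identical(percent_significant(0, 5), 0L)
  expect_identical(percent_significant(1, 8), 13L)  # 12.5 rounds up
  expect_identical(percent_significant(1, 1), 100L)
  expect_error(percent_significant(0, 0), "n_total")
})

test_that("category assignment covers the whole small domain", {
  # published anchor cases
  expect_identical(categorize_gene(7, 6), 1L)    # dense, mostly changed
  expect_identical(categorize_gene(13, 9), 1L)
  expect_identical(categorize_gene(3, 2), 2L)    # sparse, half changed
  expect_identical(categorize_gene(21, 2), 3L)   # dense, little changed
  expect_identical(categorize_gene(0, 0), 3L)
  # boundary policy: exactly 50 % at >=7 sites is category 1; exactly 30 %
  # at >=7 sites is category 2
  expect_identical(categorize_gene(8, 4), 1L)
  expect_identical(categorize_gene(10, 3), 2L)
  expect_identical(categorize_gene(13, 5), 2L)   # 38 % with >= 7 sites

  # exhaustive check against an independently written rule
  rule <- function(n, k) {
    if (n < 3) return(3L)
    f <- k / n
    if (n >= 7) {
      if (f >= 0.5) return(1L)
      if (f >= 0.3) return(2L)
      return(3L)
    }
    if (f >= 0.5) return(2L) else return(3L)
  }
  for (n in 0:12) for (k in 0:n) {
    expect_identical(categorize_gene(n, k), rule(n, k),
                     label = sprintf("categorize_gene(%d, %d)", n, k))
  }
  expect_error(categorize_gene(3, 4), "n_sig")
})

test_that("direction split partitions validated sites per gene", {
  sites <- data.frame(
    gene = c(rep("SLCO2B1", 7), "ABCB11", "ABCB11"),
    probe_id = paste0("cg", 1:9),
    direction = c(rep("hyper", 6), "hypo", "hyper", "hyper"),
    stringsAsFactors = FALSE)
  sp <- split_by_direction(sites)
  expect_equal(lengths(sp$hyper), c(ABCB11 = 2L, SLCO2B1 = 6L))
  expect_equal(lengths(sp$hypo), c(SLCO2B1 = 1L))
  expect_length(intersect(sp$hyper$SLCO2B1, sp$hypo$SLCO2B1), 0)

  all_hyper <- sites[sites$direction == "hyper", ]
  expect_length(split_by_direction(all_hyper)$hypo, 0)
  expect_length(split_by_direction(sites[0, ])$hyper, 0)
  bad <- sites
  bad$direction[1] <- "sideways"
  expect_error(split_by_direction(bad), "direction")
})

test_that("beta averaging and the M transform behave as stated", {
  beta <- rbind(cg1 = c(0.2, 0.5), cg2 = c(0.4, 0.7))
  colnames(beta) <- c("s1", "s2")
  expect_equal(average_beta(beta, "cg1"), c(s1 = 0.2, s2 = 0.5))
  expect_equal(average_beta(beta, c("cg1", "cg2")), c(s1 = 0.3, s2 = 0.6))
  expect_equal(average_beta(beta, c("cg2", "cg1")),
               average_beta(beta, c("cg1", "cg2")))
  expect_error(average_beta(beta, character(0)), "empty site set")
  expect_error(average_beta(beta, "cgX"), "absent")

  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  # clamped at the edges, still finite
  expect_true(is.finite(beta_to_m(0)) && is.finite(beta_to_m(1)))

  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)   # inverse
  expect_equal(beta_to_m(b), -beta_to_m(1 - b), tolerance = 1e-9)  # antisym
  expect_true(all(diff(beta_to_m(b)) > 0))  # strictly increasing
})

test_that("gene summaries combine counts, binomial p and category", {
  probe_sets <- list(SLCO2B1 = paste0("cg", 1:9), ABCB11 = paste0("cg", 10:12))
  sites <- data.frame(
    gene = c(rep("SLCO2B1", 6), "ABCB11", "ABCB11"),
    probe_id = c(paste0("cg", 1:6), "cg10", "cg11"),
    direction = c(rep("hyper", 5), "hypo", "hyper", "hyper"),
    stringsAsFactors = FALSE)
  gs <- summarize_gene_methylation(sites, probe_sets, cluster = "bile_acid")
  row <- function(g, d) gs[gs$gene == g & gs$direction == d, ]

  sl_h <- row("SLCO2B1", "hyper")
  expect_equal(sl_h$n_total, 9)
  expect_equal(sl_h$n_sig, 5)
  expect_equal(sl_h$p_binomial, binomial_overrepresentation(5, 9))
  expect_equal(sl_h$n_sig_combined, 6)
  expect_equal(sl_h$category, 1L)      # 6 of 9 changed, dense promoter
  sl_l <- row("SLCO2B1", "hypo")
  expect_equal(sl_l$n_sig, 1)
  expect_equal(sl_l$category, 1L)      # category reflects the combined count
  ab <- row("ABCB11", "hyper")
  expect_equal(ab$pct_sig, 67L)
  expect_equal(ab$category, 2L)

  empty <- summarize_gene_methylation(sites[0, ], probe_sets)
  expect_equal(nrow(empty), 0)

  # per-sample profiles: averaged beta then M, per direction
  set.seed(30)
  beta <- matrix(runif(12 * 4, 0.2, 0.8), 12, 4,
                 dimnames = list(paste0("cg", 1:12), paste0("s", 1:4)))
  prof <- gene_methylation_profiles(beta, sites)
  pr <- prof[prof$gene == "SLCO2B1" & prof$direction == "hyper", ]
  expect_equal(pr$mean_beta,
               unname(colMeans(beta[paste0("cg", 1:5), ])))
  expect_equal(pr$m_value, unname(beta_to_m(colMeans(beta[paste0("cg", 1:5), ]))))
})
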