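gen_clean <- function(n = 50, slope = -0.5, noise = 0.2, seed = 1,
                      fib_coef = 0.1) {
  set.seed(seed)
  expr <- rnorm(n, 8, 1)
  fib <- sample(0:2, n, replace = TRUE)
  m <- slope * expr + fib_coef * fib + rnorm(n, 0, noise)
  list(m = m, expr = expr, fib = fib)
}

test_that("robust regression is exact on noise-free linear data", {
  set.seed(2)
  expr <- rnorm(30, 8, 1)
  fib <- sample(0:2, 30, replace = TRUE)
  m <- -0.5 * expr + 0.1 * fib
  for (psi in c("bisquare", "huber", "ols")) {
    fit <- robust_regression(m, expr, fib, psi = psi)
    expect_equal(fit$coefficient, -0.5, tolerance = 1e-6)
    expect_lt(fit$p, 1e-10)
  }
})

test_that("robust slope tracks OLS on clean data across replicates", {
  for (seed in 1:20) {
    d <- gen_clean(seed = seed)
    rob <- robust_regression(d$m, d$expr, d$fib)
    ols <- robust_regression(d$m, d$expr, d$fib, psi = "ols")
    expect_lt(abs(rob$coefficient - ols$coefficient), 0.05)
  }
})

test_that("a gross outlier moves OLS but not the bisquare fit", {
  moved_rob <- moved_ols <- logical(10)
  for (seed in 1:10) {
    d <- gen_clean(n = 50, slope = -0.5, noise = 0.5, seed = 100 + seed)
    clean_ols <- robust_regression(d$m, d$expr, d$fib, psi = "ols")
    # shift the response of the highest-leverage point by 10 residual sd
    i <- which.max(abs(d$expr - mean(d$expr)))
    m2 <- d$m
    m2[i] <- m2[i] + 10 * 0.5
    rob <- robust_regression(m2, d$expr, d$fib)
    ols <- robust_regression(m2, d$expr, d$fib, psi = "ols")
    moved_rob[seed] <- abs(rob$coefficient - clean_ols$coefficient) <= 0.1
    moved_ols[seed] <- abs(ols$coefficient - clean_ols$coefficient) > 0.1
  }
  expect_gte(sum(moved_rob), 9)  # robust fit stays on the clean solution
  expect_gte(sum(moved_ols), 9)  # plain OLS is dragged away
})

test_that("constant weights reduce the fit to ordinary least squares", {
  d <- gen_clean(seed = 33)
  fit <- robust_regression(d$m, d$expr, d$fib, psi = "ols")
  ref <- lm(d$m ~ d$expr + d$fib)
  expect_equal(unname(fit$coefficients),
               unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$p, summary(ref)$coefficients["d$expr", 4],
               tolerance = 1e-8)
})

test_that("bisquare fit agrees with an independent MM estimator", {
  skip_if_not_installed("MASS")
  for (seed in 1:5) {
    d <- gen_clean(n = 60, noise = 0.3, seed = 200 + seed)
    m2 <- d$m
    m2[1:3] <- m2[1:3] + c(3, -4, 5)  # contaminate
    rob <- robust_regression(m2, d$expr, d$fib)
    ref <- MASS::rlm(m2 ~ d$expr + d$fib, method = "MM", maxit = 100)
    expect_lt(abs(rob$coefficient - coef(ref)[["d$expr"]]), 0.05)
  }
})

test_that("interaction variant reports the expression main effect", {
  d <- gen_clean(seed = 55)
  fit <- robust_regression(d$m, d$expr, d$fib, interaction = TRUE)
  expect_true(is.finite(fit$interaction_coefficient))
  expect_true(fit$interaction_p >= 0 && fit$interaction_p <= 1)
  expect_named(fit$coefficients,
               c("(Intercept)", "expr", "fibrosis", "expr:fibrosis"))
  expect_error(robust_regression(d$m, d$expr, interaction = TRUE),
               "requires a fibrosis")
})

test_that("degenerate association inputs are rejected", {
  expect_error(robust_regression(rnorm(20), rep(1, 20)), "no variation")
  expect_error(robust_regression(rnorm(4), rnorm(4), sample(0:2, 4, TRUE)),
               "at least")
})

test_that("Pearson subgroup correlation matches its definition", {
  set.seed(9)
  m <- rnorm(30)
  r1 <- pearson_subgroup(m, 2 * m)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-12)
  expect_equal(pearson_subgroup(m, -m)$r, -1, tolerance = 1e-12)

  # affine invariance (positive scale) and sign flip (negative scale)
  e <- rnorm(30)
  base <- pearson_subgroup(m, e)
  expect_equal(pearson_subgroup(m, 3 * e + 7)$r, base$r, tolerance = 1e-12)
  expect_equal(pearson_subgroup(m, -2 * e + 1)$r, -base$r, tolerance = 1e-12)

  mask <- rep(c(TRUE, FALSE), 15)
  sub <- pearson_subgroup(m, e, mask)
  expect_equal(sub$n_used, 15)
  expect_equal(sub$r, cor(m[mask], e[mask]), tolerance = 1e-12)

  expect_error(pearson_subgroup(m, e, c(TRUE, TRUE, rep(FALSE, 28))),
               "fewer than 3")
  expect_error(pearson_subgroup(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("Pearson p-values are calibrated under independence", {
  set.seed(77)
  p <- replicate(1000, pearson_subgroup(rnorm(30), rnorm(30))$p)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

ec_fixture <- function(gamma, seed, genes = paste0("E", 1:4)) {
  cfg <- sim_config(genes = genes, n_probes_per_gene = 6,
                    disease_effect = 0.5, fraction_affected = 0.6,
                    prob_flip = 0, gamma = gamma, seed = seed)
  st <- simulate_study(cfg, seed = seed)
  pr <- st$truth$probes
  aff <- pr[pr$affected & pr$decoy == "none", ]
  validated <- data.frame(gene = aff$gene, probe_id = aff$probe_id,
                          direction = ifelse(aff$direction > 0, "hyper",
                                             "hypo"),
                          stringsAsFactors = FALSE)
  profiles <- gene_methylation_profiles(st$ec$beta, validated)
  list(study = st, profiles = profiles)
}

test_that("association stage recovers a planted coupling", {
  hits <- 0L
  total <- 0L
  for (seed in 1:5) {
    fx <- ec_fixture(gamma = -0.6, seed = 300 + seed)
    assoc <- associate_genes(fx$profiles, fx$study$ec$expression,
                             fx$study$ec$samples)
    rob <- assoc[assoc$model == "robust_adjusted", ]
    total <- total + nrow(rob)
    hits <- hits + sum(rob$p < 0.05 & rob$coefficient < 0)
  }
  expect_gte(hits / total, 0.9)

  # null coupling: mostly quiet
  fx0 <- ec_fixture(gamma = 0, seed = 401)
  a0 <- associate_genes(fx0$profiles, fx0$study$ec$expression,
                        fx0$study$ec$samples)
  expect_gte(mean(a0$p >= 0.05), 0.75)

  # four model rows per gene x direction
  expect_setequal(unique(a0$model),
                  c("robust_adjusted", "robust_interaction",
                    "pearson_cases", "pearson_controls"))
})

test_that("genes without expression are skipped with a log entry", {
  fx <- ec_fixture(gamma = -0.6, seed = 501)
  expr <- fx$study$ec$expression
  keep <- setdiff(rownames(expr), "E2")
  expect_message(
    a <- associate_genes(fx$profiles, expr[keep, ], fx$study$ec$samples),
    "no expression row for gene 'E2'")
  expect_false("E2" %in% a$gene)

  # duplicate transcript rows collapse by mean
  dup <- rbind(expr, expr["E1", , drop = FALSE])
  expect_message(
    a2 <- associate_genes(fx$profiles, dup, fx$study$ec$samples),
    "multiple transcript identifiers")
  a1 <- suppressMessages(
    associate_genes(fx$profiles, expr, fx$study$ec$samples))
  expect_equal(a2[a2$gene == "E1", ], a1[a1$gene == "E1", ])
})

test_that("reversed orientation estimates the coupling slope itself", {
  est <- numeric(0)
  for (seed in 1:5) {
    fx <- ec_fixture(gamma = -0.6, seed = 600 + seed)
    a <- associate_genes(fx$profiles, fx$study$ec$expression,
                         fx$study$ec$samples, orientation = "expr_on_m")
    est <- c(est, a$coefficient[a$model == "robust_adjusted"])
  }
  expect_lt(abs(median(est) - (-0.6)), 0.1)
  expect_identical(attr(suppressMessages(
    associate_genes(fx$profiles, fx$study$ec$expression,
                    fx$study$ec$samples, orientation = "expr_on_m")),
    "orientation"), "expr_on_m")
})

test_that("neighbor scan finds a planted cross-gene coupling", {
  genes <- paste0("N", 1:6)
  cfg <- sim_config(genes = genes, n_probes_per_gene = 6,
                    disease_effect = 0.5, fraction_affected = 0.6,
                    prob_flip = 0, gamma = 0,
                    neighbor_coupling = list(source = "N3", target = "N4",
                                             gamma = -0.8),
                    seed = 700)
  st <- simulate_study(cfg, seed = 700)
  pr <- st$truth$probes
  aff <- pr[pr$affected & pr$decoy == "none" & pr$gene == "N3", ]
  validated <- data.frame(gene = aff$gene, probe_id = aff$probe_id,
                          direction = ifelse(aff$direction > 0, "hyper",
                                             "hypo"),
                          stringsAsFactors = FALSE)
  profiles <- gene_methylation_profiles(st$ec$beta, validated)
  nb <- neighbor_expression_scan(profiles, st$ec$expression, st$gene_coords,
                                 st$ec$samples, k = 2)
  expect_true(all(nb$neighbor_of == "N3"))
  expect_setequal(unique(nb$gene), c("N1", "N2", "N4", "N5"))
  hit <- nb[nb$gene == "N4", ]
  expect_true(all(hit$p < 0.05))
  expect_true(all(hit$coefficient < 0))
  expect_gte(mean(nb$p[nb$gene != "N4"] >= 0.05), 0.7)

  expect_identical(nrow(neighbor_expression_scan(
    profiles, st$ec$expression, st$gene_coords, st$ec$samples, k = 0)), 0L)

  # neighbor missing from the expression matrix is skipped with a message
  expr2 <- st$ec$expression[setdiff(genes, "N2"), ]
  expect_message(
    nb2 <- neighbor_expression_scan(profiles, expr2, st$gene_coords,
                                    st$ec$samples, k = 2),
    "no expression for neighbor 'N2'")
  expect_false("N2" %in% nb2$gene)
})
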