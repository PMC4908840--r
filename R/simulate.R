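#' Simulation configuration
#'
#' Describes the synthetic study the generator emits: three liver cohorts
#' mirroring the structure of the real discovery (controls + NAFLD, n = 74),
#' validation (staged NAFLD only, n = 54) and expression-correlation
#' (matched methylation + expression, n = 50) data sets.
#'
#' The generative model is logit-normal: for probe j of gene g and sample i,
#' `logit(beta_ij) = a_j + b_j * disease_i + f_j * fibrosis_i +
#'  c_age * age_z + c_sex * sex + c_bmi * bmi_z + u_gi + eps_ij`,
#' with `u ~ N(0, gene_sample_sd^2)` a shared regional (promoter-level)
#' effect and `eps ~ N(0, noise_sd^2)` independent probe noise. Affected probes of a gene carry
#' `b_j = dir_j * disease_effect` and `f_j = dir_j * disease_effect *
#' fibrosis_effect_scale` (per stage); null probes have `b_j = f_j = 0`.
#' Betas are the inverse logit, clamped to `[1e-6, 1 - 1e-6]`. The default
#' disease effect of 0.25 logits shifts beta by roughly 3-6 percentage
#' points at typical promoter methylation levels, the range reported for
#' NAFLD-dependent promoter CpGs; the per-stage fibrosis shift defaults to
#' the same magnitude, matching the observed parity of discovery and
#' validation coefficients.
#'
#' @param genes character vector of gene symbols to simulate (default: the
#'   union of the two built-in clusters).
#' @param n_probes_per_gene TSS1500 probes per gene.
#' @param n_decoy_outside per gene, probes placed outside the TSS1500 window
#'   (annotation-filter exercise).
#' @param n_decoy_snp per gene, SNP-flagged probes inside the window.
#' @param n_discovery_control,n_discovery_ss,n_discovery_nash discovery
#'   cohort composition (defaults 45/14/15).
#' @param n_validation validation cohort size (default 54, NAFLD only).
#' @param n_ec_control,n_ec_ss,n_ec_nash expression-correlation cohort
#'   composition (defaults 30/13/7).
#' @param baseline_logit_mean,baseline_logit_sd distribution of per-probe
#'   baseline logits `a_j`.
#' @param disease_effect logit shift magnitude for affected probes.
#' @param fibrosis_effect_scale per-stage fibrosis shift as a multiple of
#'   `disease_effect`.
#' @param steatosis_effect_scale analogous multiplier for steatosis grade
#'   (default 0: steatosis hardly moves promoter methylation).
#' @param fraction_affected probability that a TSS1500 probe of a gene
#'   carries the planted effect.
#' @param prop_hyper probability that a gene's planted direction is
#'   hypermethylation.
#' @param prob_flip probability that an individual affected probe takes the
#'   direction opposite to its gene (isolated discordant sites).
#' @param age_effect,sex_effect,bmi_effect logit shifts per SD of age, for
#'   female sex, and per SD of BMI.
#' @param noise_sd per-probe residual SD on the logit scale.
#' @param gene_sample_sd SD of a per-gene, per-sample regional random effect
#'   on the logit scale (default 0.3): CpGs of one promoter are
#'   co-methylated within an individual, so the gene-level methylation
#'   summary varies between individuals beyond what independent probe noise
#'   would allow.
#' @param age_mean,age_sd,bmi_mean,bmi_sd demographic distributions.
#' @param female_prop probability a sample is female.
#' @param gamma expression-coupling slope for genes with planted methylation
#'   effects: `x_gi = mu_g + gamma * Mbar_gi + delta * fibrosis_i + eta`,
#'   where `Mbar` is the sample mean M-value over the gene's affected
#'   probes. Genes without affected probes get slope 0.
#' @param expr_mu_mean,expr_mu_sd baseline expression intensity distribution
#'   (log scale).
#' @param expr_fibrosis_effect the `delta` above.
#' @param expr_noise_sd SD of the expression noise `eta`.
#' @param neighbor_coupling optional `list(source=, target=, gamma=)`
#'   coupling one gene's methylation into another gene's expression.
#' @param missing_rate fraction of beta entries set missing (default 0).
#' @param gene_spacing bp between consecutive synthetic TSSs on the
#'   synthetic chromosome.
#' @param truth_seed optional separate seed for the ground truth so sample
#'   draws can vary while the planted effects stay fixed.
#' @param seed default seed used by [simulate_study()] when none is given.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genes = NULL,
                       n_probes_per_gene = 8,
                       n_decoy_outside = 2,
                       n_decoy_snp = 1,
                       n_discovery_control = 45,
                       n_discovery_ss = 14,
                       n_discovery_nash = 15,
                       n_validation = 54,
                       n_ec_control = 30,
                       n_ec_ss = 13,
                       n_ec_nash = 7,
                       baseline_logit_mean = -1.4,
                       baseline_logit_sd = 0.8,
                       disease_effect = 0.25,
                       fibrosis_effect_scale = 1,
                       steatosis_effect_scale = 0,
                       fraction_affected = 0.5,
                       prop_hyper = 0.75,
                       prob_flip = 0.1,
                       age_effect = 0.05,
                       sex_effect = 0.05,
                       bmi_effect = 0.05,
                       noise_sd = 0.35,
                       gene_sample_sd = 0.3,
                       age_mean = 50, age_sd = 12,
                       bmi_mean = 40, bmi_sd = 10,
                       female_prop = 0.7,
                       gamma = -0.5,
                       expr_mu_mean = 8, expr_mu_sd = 1,
                       expr_fibrosis_effect = 0.2,
                       expr_noise_sd = 0.5,
                       neighbor_coupling = NULL,
                       missing_rate = 0,
                       gene_spacing = 1e5,
                       truth_seed = NULL,
                       seed = 1) {
  if (is.null(genes)) {
    genes <- unique(builtin_gene_clusters()$gene)
  }
  cfg <- as.list(environment())
  cfg$genes <- toupper(genes)
  counts <- c(n_probes_per_gene, n_discovery_control, n_discovery_ss,
              n_discovery_nash, n_validation, n_ec_control, n_ec_ss, n_ec_nash)
  if (any(counts <= 0 & c(TRUE, rep(FALSE, 7))) || n_probes_per_gene < 1) {
    stop_input("n_probes_per_gene must be a positive count")
  }
  if (n_discovery_control + n_discovery_ss + n_discovery_nash < 2 ||
      n_validation < 2 || n_ec_control + n_ec_ss + n_ec_nash < 2) {
    stop_input("cohort sizes must be positive")
  }
  sds <- c(baseline_logit_sd, noise_sd, gene_sample_sd, expr_noise_sd,
           age_sd, bmi_sd, expr_mu_sd)
  if (any(sds < 0)) stop_input("standard deviations must be >= 0")
  fr <- c(fraction_affected, prop_hyper, prob_flip, missing_rate, female_prop)
  if (any(fr < 0 | fr > 1)) stop_input("fractions must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# synthetic genome layout + probe annotation with decoys; truth drawn here
build_ground_truth <- function(config, truth_seed) {
  set.seed(truth_seed)
  genes <- config$genes
  gene_coords <- data.frame(
    gene = genes,
    chrom = "chrS1",
    tss_pos = 1e6 + seq_along(genes) * config$gene_spacing,
    strand = rep(c("+", "-"), length.out = length(genes)),
    stringsAsFactors = FALSE
  )
  per_gene <- config$n_probes_per_gene + config$n_decoy_outside +
    config$n_decoy_snp
  ann <- vector("list", length(genes))
  counter <- 0L
  for (gi in seq_along(genes)) {
    d_in <- sample(-1500:1500, config$n_probes_per_gene, replace = TRUE)
    d_out <- if (config$n_decoy_outside > 0) {
      sample(c(-1, 1), config$n_decoy_outside, replace = TRUE) *
        sample(1501:5000, config$n_decoy_outside, replace = TRUE)
    } else integer()
    d_snp <- if (config$n_decoy_snp > 0) {
      sample(-1500:1500, config$n_decoy_snp, replace = TRUE)
    } else integer()
    dist <- c(d_in, d_out, d_snp)
    decoy <- c(rep("none", config$n_probes_per_gene),
               rep("outside", config$n_decoy_outside),
               rep("snp", config$n_decoy_snp))
    ids <- sprintf("cg%07d", counter + seq_along(dist))
    counter <- counter + length(dist)
    ann[[gi]] <- data.frame(
      probe_id = ids,
      chrom = "chrS1",
      pos = gene_coords$tss_pos[gi] + dist,
      gene = genes[gi],
      tss_distance = dist,
      snp_overlap = decoy == "snp",
      decoy = decoy,
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, ann)

  gene_dir <- ifelse(stats::runif(length(genes)) < config$prop_hyper, 1, -1)
  names(gene_dir) <- genes
  eligible <- ann$decoy == "none"
  affected <- eligible & stats::runif(nrow(ann)) < config$fraction_affected
  dir <- integer(nrow(ann))
  flip <- stats::runif(nrow(ann)) < config$prob_flip
  dir[affected] <- ifelse(flip[affected], -1, 1) * gene_dir[ann$gene[affected]]
  probes <- data.frame(
    probe_id = ann$probe_id,
    gene = ann$gene,
    decoy = ann$decoy,
    affected = affected,
    direction = dir,
    logit_effect_disease = dir * config$disease_effect,
    logit_effect_fibrosis = dir * config$disease_effect *
      config$fibrosis_effect_scale,
    logit_effect_steatosis = dir * config$disease_effect *
      config$steatosis_effect_scale,
    baseline_logit = stats::rnorm(nrow(ann), config$baseline_logit_mean,
                                  config$baseline_logit_sd),
    stringsAsFactors = FALSE
  )
  has_effect <- tapply(probes$affected & probes$decoy == "none",
                       probes$gene, any)[genes]
  gene_truth <- data.frame(
    gene = genes,
    direction = gene_dir,
    gamma = ifelse(has_effect, config$gamma, 0),
    fraction_affected_realized = tapply(
      probes$affected[eligible], probes$gene[eligible], mean)[genes],
    stringsAsFactors = FALSE
  )
  rownames(gene_truth) <- NULL
  list(probes = probes, genes = gene_truth,
       annotation = ann[, names(ann) != "decoy"],
       gene_coords = gene_coords, truth_seed = truth_seed)
}

draw_samples <- function(config, cohort_role, n_offset = 0) {
  role <- cohort_role
  if (role == "discovery") {
    diagnosis <- rep(c("control", "SS", "NASH"),
                     c(config$n_discovery_control, config$n_discovery_ss,
                       config$n_discovery_nash))
    fib_report <- FALSE
  } else if (role == "validation") {
    diagnosis <- rep("unknown", config$n_validation)
    fib_report <- TRUE
  } else {
    diagnosis <- rep(c("control", "SS", "NASH"),
                     c(config$n_ec_control, config$n_ec_ss, config$n_ec_nash))
    fib_report <- TRUE
  }
  n <- length(diagnosis)
  # latent fibrosis/steatosis: controls unfibrotic; NAFLD spread over stages
  fib <- integer(n)
  ste <- integer(n)
  for (i in seq_len(n)) {
    fib[i] <- switch(diagnosis[i],
      control = 0L,
      SS = sample(0:1, 1, prob = c(0.75, 0.25)),
      NASH = sample(0:2, 1, prob = c(0.45, 0.35, 0.2)),
      unknown = sample(1:2, 1, prob = c(0.593, 0.407)))
    ste[i] <- switch(diagnosis[i],
      control = sample(0:1, 1, prob = c(0.8, 0.2)),
      SS = sample(1:3, 1, prob = c(0.2, 0.4, 0.4)),
      NASH = sample(1:3, 1, prob = c(0.1, 0.2, 0.7)),
      unknown = sample(0:3, 1, prob = c(0.074, 0.426, 0.296, 0.204)))
  }
  data.frame(
    sample_id = sprintf("%s_%03d", substr(role, 1, 3), n_offset + seq_len(n)),
    cohort = role,
    diagnosis = diagnosis,
    age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
    sex = ifelse(stats::runif(n) < config$female_prop, "female", "male"),
    bmi = round(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 1),
    fibrosis_stage = if (role == "discovery") NA_integer_ else fib,
    steatosis_grade = if (role == "discovery") NA_integer_ else ste,
    stringsAsFactors = FALSE,
    check.names = FALSE
  ) -> samples
  attr(samples, "latent_fibrosis") <- fib
  attr(samples, "latent_steatosis") <- ste
  samples
}

#' Simulate one methylation cohort
#'
#' Draws a sample table and a probe-by-sample beta matrix from the
#' logit-normal model described in [sim_config()]. Deterministic given
#' `(config, seed)`; the planted effects come from `truth` (built once per
#' study so all cohorts share the same affected probes and directions).
#'
#' @param config a [sim_config()] object.
#' @param cohort_role `"discovery"`, `"validation"` or `"ec"`.
#' @param seed integer seed for the sample draws.
#' @param truth optional ground truth from a previous call / shared study;
#'   built from `config$truth_seed` (falling back to `seed`) when absent.
#' @return an object of class `sim_cohort`: a list with elements `beta`
#'   (matrix, probes x samples), `samples`, `annotation`, `gene_coords`,
#'   `truth`, `config`, `seed`, `cohort_role`, and `expression` (NULL until
#'   [simulate_expression()] is applied).
#' @export
simulate_methylation_cohort <- function(config, cohort_role = c("discovery",
                                                                "validation",
                                                                "ec"),
                                        seed = config$seed, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohort_role <- match.arg(cohort_role)
  if (is.null(truth)) {
    ts <- if (is.null(config$truth_seed)) seed else config$truth_seed
    truth <- build_ground_truth(config, ts)
  }
  set.seed(seed)
  samples <- draw_samples(config, cohort_role)
  n <- nrow(samples)
  fib <- attr(samples, "latent_fibrosis")
  ste <- attr(samples, "latent_steatosis")
  disease <- as.numeric(samples$diagnosis %in% c("SS", "NASH", "unknown"))
  age_z <- (samples$age - config$age_mean) / max(config$age_sd, 1e-9)
  bmi_z <- (samples$bmi - config$bmi_mean) / max(config$bmi_sd, 1e-9)
  sexf <- as.numeric(samples$sex == "female")
  pr <- truth$probes
  m <- nrow(pr)
  lin <- matrix(pr$baseline_logit, m, n) +
    outer(pr$logit_effect_disease, disease) +
    outer(pr$logit_effect_fibrosis, fib) +
    outer(pr$logit_effect_steatosis, ste) +
    matrix(config$age_effect * age_z + config$sex_effect * sexf +
             config$bmi_effect * bmi_z, m, n, byrow = TRUE) +
    matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)
  if (config$gene_sample_sd > 0) {
    genes <- config$genes
    u <- matrix(stats::rnorm(length(genes) * n, 0, config$gene_sample_sd),
                length(genes), n, dimnames = list(genes, NULL))
    lin <- lin + u[pr$gene, , drop = FALSE]
  }
  beta <- clamp_beta(inv_logit(lin))
  dimnames(beta) <- list(pr$probe_id, samples$sample_id)
  if (config$missing_rate > 0) {
    beta[stats::runif(length(beta)) < config$missing_rate] <- NA
  }
  structure(list(beta = beta, expression = NULL, samples = samples,
                 annotation = truth$annotation, gene_coords = truth$gene_coords,
                 truth = truth, config = config, seed = seed,
                 cohort_role = cohort_role),
            class = "sim_cohort")
}

#' Add a matched expression matrix to a simulated cohort
#'
#' Expression of gene g in sample i is
#' `x_gi = mu_g + gamma_g * Mbar_gi + delta * fibrosis_i + eta_gi`, with
#' `Mbar_gi` the M-value of the sample's mean beta over the gene's affected
#' probes (all TSS1500 probes when none are affected, where `gamma_g = 0`
#' anyway) and
#' `eta ~ N(0, expr_noise_sd^2)`. An optional `neighbor_coupling` in the
#' config adds `gamma * Mbar_source` to the target gene's expression,
#' planting a methylation-expression link across gene boundaries for the
#' neighbor scan.
#'
#' @param cohort a `sim_cohort`.
#' @param seed seed for the expression noise (default derived from the
#'   cohort seed).
#' @return the cohort with `expression` set (genes x samples matrix).
#' @export
simulate_expression <- function(cohort, seed = cohort$seed + 1000L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(cohort$beta)) stop_input("cohort has no beta matrix")
  config <- cohort$config
  set.seed(seed)
  genes <- config$genes
  fib <- attr(cohort$samples, "latent_fibrosis")
  if (is.null(fib)) fib <- ifelse(is.na(cohort$samples$fibrosis_stage), 0,
                                  cohort$samples$fibrosis_stage)
  n <- nrow(cohort$samples)
  # the gene's methylation summary on the analysis scale: M-value of the
  # per-sample mean beta over the affected (planted) probes
  mbar <- sapply(genes, function(g) {
    pr <- cohort$truth$probes
    ids <- pr$probe_id[pr$gene == g & pr$affected & pr$decoy == "none"]
    if (!length(ids)) ids <- pr$probe_id[pr$gene == g & pr$decoy == "none"]
    beta_to_m(colMeans(cohort$beta[ids, , drop = FALSE], na.rm = TRUE))
  })                                     # samples x genes
  gamma_g <- cohort$truth$genes$gamma[match(genes, cohort$truth$genes$gene)]
  mu_g <- stats::rnorm(length(genes), config$expr_mu_mean, config$expr_mu_sd)
  expr <- t(mbar) * gamma_g + mu_g +
    matrix(config$expr_fibrosis_effect * fib, length(genes), n, byrow = TRUE) +
    matrix(stats::rnorm(length(genes) * n, 0, config$expr_noise_sd),
           length(genes), n)
  nc <- config$neighbor_coupling
  if (!is.null(nc)) {
    src <- toupper(nc$source); tgt <- toupper(nc$target)
    if (!src %in% genes || !tgt %in% genes) {
      stop_input("neighbor_coupling genes must be in the simulated gene list")
    }
    expr[match(tgt, genes), ] <- expr[match(tgt, genes), ] +
      nc$gamma * mbar[, match(src, genes)]
  }
  dimnames(expr) <- list(genes, cohort$samples$sample_id)
  cohort$expression <- expr
  cohort$expression_seed <- seed
  cohort
}

#' Simulate a full three-cohort study
#'
#' Builds one shared ground truth (planted probe effects and gene coupling
#' slopes) and draws three independent cohorts from it: a discovery cohort
#' of controls and NAFLD patients, a validation cohort of staged NAFLD
#' patients, and an expression-correlation (EC) cohort with matched
#' expression. Defaults reproduce the real cohort sizes 74 / 54 / 50.
#'
#' @param config a [sim_config()].
#' @param seed master seed; cohort seeds are derived as small offsets. The
#'   ground truth uses `config$truth_seed` when set, else this seed, so two
#'   studies with different seeds but the same `truth_seed` share planted
#'   effects.
#' @return an object of class `sim_study`: list with `discovery`,
#'   `validation`, `ec` (`sim_cohort`s, the latter with expression),
#'   `truth`, `annotation`, `gene_coords`, `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ts <- if (is.null(config$truth_seed)) seed else config$truth_seed
  truth <- build_ground_truth(config, ts)
  disc <- simulate_methylation_cohort(config, "discovery",
                                      seed = seed + 1L, truth = truth)
  vali <- simulate_methylation_cohort(config, "validation",
                                      seed = seed + 2L, truth = truth)
  ec <- simulate_methylation_cohort(config, "ec",
                                    seed = seed + 3L, truth = truth)
  ec <- simulate_expression(ec, seed = seed + 4L)
  structure(list(discovery = disc, validation = vali, ec = ec,
                 truth = truth, annotation = truth$annotation,
                 gene_coords = truth$gene_coords, config = config,
                 seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic methylation study (seed ", x$seed, ")\n", sep = "")
  cat("  genes: ", length(x$config$genes),
      "; probes: ", nrow(x$annotation), " (incl. decoys)\n", sep = "")
  cat("  discovery n = ", nrow(x$discovery$samples),
      "; validation n = ", nrow(x$validation$samples),
      "; EC n = ", nrow(x$ec$samples), "\n", sep = "")
  aff <- x$truth$probes
  cat("  affected probes: ", sum(aff$affected), " of ",
      sum(aff$decoy == "none"), " eligible\n", sep = "")
  invisible(x)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort '", x$cohort_role, "': ", nrow(x$beta), " probes x ",
      ncol(x$beta), " samples", sep = "")
  if (!is.null(x$expression)) {
    cat("; expression ", nrow(x$expression), " genes", sep = "")
  }
  cat(" (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the same plain-text formats the pipeline consumes: `beta.tsv`
#' (probes x samples), `samples.tsv`, `annotation.tsv`, `gene_coords.tsv`,
#' `ground_truth_probes.tsv`, `ground_truth_genes.tsv`, `expression.tsv`
#' when present, and a JSON run manifest recording config and seed.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta_df <- data.frame(probe_id = rownames(cohort$beta), cohort$beta,
                        check.names = FALSE)
  write_tsv(beta_df, file.path(dir, "beta.tsv"))
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(cohort$gene_coords, file.path(dir, "gene_coords.tsv"))
  write_tsv(cohort$truth$probes, file.path(dir, "ground_truth_probes.tsv"))
  write_tsv(cohort$truth$genes, file.path(dir, "ground_truth_genes.tsv"))
  if (!is.null(cohort$expression)) {
    expr_df <- data.frame(gene = rownames(cohort$expression),
                          cohort$expression, check.names = FALSE)
    write_tsv(expr_df, file.path(dir, "expression.tsv"))
  }
  manifest <- list(package = "tssmeth",
                   version = as.character(utils::packageVersion("tssmeth")),
                   cohort_role = cohort$cohort_role,
                   seed = cohort$seed,
                   truth_seed = cohort$truth$truth_seed,
                   config = unclass(cohort$config))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    dput(manifest, file.path(dir, "manifest.R"))
  }
  invisible(dir)
}
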