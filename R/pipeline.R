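#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input source (a
#' simulation config or file paths), cluster selection, significance
#' thresholds, the TSS window, covariates, and robust-fit options.
#'
#' @param simulation a [sim_config()] to generate the study in memory, or
#'   NULL when `paths` are given.
#' @param paths named list of input files when not simulating:
#'   `annotation`, `gene_coords`, `beta_discovery`, `samples_discovery`,
#'   `beta_validation`, `samples_validation`, `beta_ec`, `samples_ec`,
#'   `expression_ec`.
#' @param clusters which built-in clusters to analyze.
#' @param include_optional include optional cluster members (e.g. NAT2).
#' @param genes optional explicit gene list overriding `clusters`.
#' @param discovery_fdr FDR threshold for the discovery scan (default 0.05).
#' @param validation_p raw-p threshold for the validation scan.
#' @param association_p significance threshold for association rows.
#' @param p0 per-site null rate of the binomial overrepresentation test.
#' @param tss_window TSS interval half-width in bp (default 1500).
#' @param covariates adjustment covariates for the scans.
#' @param fdr_family `"cluster"` (adjust within each cluster scan, default)
#'   or `"global"` (one family across all clusters).
#' @param validation_requires `"fibrosis"` (default) or `"either"`: which
#'   validation predictor must be significant for a site to validate.
#' @param psi robust weight function for the association stage.
#' @param orientation association model orientation (see
#'   [associate_genes()]).
#' @param neighbor_k neighbors per side in the neighbor expression scan.
#' @param average_all_sites use all TSS1500 sites (not only validated ones)
#'   when averaging beta for the association stage.
#' @param seed seed for the simulated study.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            clusters = c("bile_acid", "drug_metabolism"),
                            include_optional = FALSE, genes = NULL,
                            discovery_fdr = 0.05, validation_p = 0.05,
                            association_p = 0.05, p0 = 0.05,
                            tss_window = 1500,
                            covariates = c("age", "sex", "bmi"),
                            fdr_family = c("cluster", "global"),
                            validation_requires = c("fibrosis", "either"),
                            psi = "bisquare",
                            orientation = c("m_on_expr", "expr_on_m"),
                            neighbor_k = 5,
                            average_all_sites = FALSE, seed = 1) {
  fdr_family <- match.arg(fdr_family)
  validation_requires <- match.arg(validation_requires)
  orientation <- match.arg(orientation)
  if (is.null(simulation) && is.null(paths)) {
    stop_input("provide either a simulation config or input paths")
  }
  thr <- c(discovery_fdr, validation_p, association_p, p0)
  if (any(thr <= 0 | thr >= 1)) stop_input("thresholds must lie in (0, 1)")
  if (tss_window <= 0) stop_input("tss_window must be positive")
  clusters <- match.arg(clusters, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

read_matrix_tsv <- function(path, id_col) {
  tab <- read_table_auto(path)
  if (!id_col %in% names(tab)) {
    stop_input("matrix file '", path, "' lacks id column '", id_col, "'")
  }
  ids <- as.character(tab[[id_col]])
  m <- as.matrix(tab[, setdiff(names(tab), id_col), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

load_sample_table <- function(path) {
  tab <- read_table_auto(path)
  if (!"sample_id" %in% names(tab)) {
    stop_input("sample table '", path, "' lacks a sample_id column")
  }
  if ("fibrosis_stage" %in% names(tab)) {
    tab$fibrosis_stage <- map_fibrosis_stage(tab$fibrosis_stage)
  }
  if ("steatosis_grade" %in% names(tab)) {
    tab$steatosis_grade <- map_steatosis_grade(tab$steatosis_grade)
  }
  tab
}

load_study_from_paths <- function(paths) {
  need <- c("annotation", "beta_discovery", "samples_discovery",
            "beta_validation", "samples_validation", "beta_ec",
            "samples_ec", "expression_ec")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop_input("paths are missing entries: ", paste(missing, collapse = ", "))
  }
  list(
    annotation = load_probe_annotation(paths$annotation),
    gene_coords = if (!is.null(paths$gene_coords))
      load_gene_coords(paths$gene_coords) else NULL,
    discovery = list(beta = read_matrix_tsv(paths$beta_discovery, "probe_id"),
                     samples = load_sample_table(paths$samples_discovery)),
    validation = list(beta = read_matrix_tsv(paths$beta_validation,
                                             "probe_id"),
                      samples = load_sample_table(paths$samples_validation)),
    ec = list(beta = read_matrix_tsv(paths$beta_ec, "probe_id"),
              samples = load_sample_table(paths$samples_ec),
              expression = read_matrix_tsv(paths$expression_ec, "gene"))
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full targeted methylation-expression pipeline
#'
#' Executes, per gene cluster: TSS1500 probe selection, the discovery
#' disease scan with FDR control, the validation fibrosis and steatosis
#' scans, direction-consistent site validation, gene-level summaries
#' (binomial overrepresentation, percent, category), per-sample methylation
#' profiles, robust methylation-expression association, and the
#' neighboring-gene expression scan. Deterministic given the config and
#' seed.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `meth_pipeline` bundling all stage tables
#'   (`discovery`, `validation_fibrosis`, `validation_steatosis`,
#'   `validated_sites`, `gene_summaries`, `associations`,
#'   `neighbor_associations`, `summary`) plus a `manifest` of per-stage
#'   record counts, the config and the seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- if (!is.null(config$simulation)) {
    run_stage("simulate",
              simulate_study(config$simulation, seed = config$seed))
  } else {
    run_stage("load", load_study_from_paths(config$paths))
  }
  annotation <- study$annotation
  gene_coords <- study$gene_coords

  cluster_tab <- builtin_gene_clusters(config$include_optional)
  cluster_sets <- lapply(config$clusters, function(cl) {
    genes <- if (is.null(config$genes)) {
      cluster_tab$gene[cluster_tab$cluster == cl]
    } else toupper(config$genes)
    ps <- run_stage("annotation", {
      s <- tss1500_probe_sets(annotation, genes, config$tss_window)
      s[lengths(s) > 0]
    })
    if (!length(ps)) {
      stop_input("cluster '", cl, "': no genes with TSS1500 probes")
    }
    ps
  })
  names(cluster_sets) <- config$clusters
  disc_global <- if (config$fdr_family == "global") {
    all_sets <- do.call(c, unname(cluster_sets))
    all_sets <- all_sets[!duplicated(names(all_sets))]
    run_stage("discovery", discovery_scan(
      study$discovery$beta, study$discovery$samples, all_sets,
      covariates = config$covariates, fdr_threshold = config$discovery_fdr))
  } else NULL
  per_cluster <- lapply(config$clusters, function(cl) {
    probe_sets <- cluster_sets[[cl]]
    disc <- if (is.null(disc_global)) {
      run_stage("discovery", discovery_scan(
        study$discovery$beta, study$discovery$samples, probe_sets,
        covariates = config$covariates,
        fdr_threshold = config$discovery_fdr))
    } else {
      disc_global[disc_global$gene %in% names(probe_sets), , drop = FALSE]
    }
    val_fib <- run_stage("validation", validation_scan(
      study$validation$beta, study$validation$samples, probe_sets,
      stage_variable = "fibrosis", covariates = config$covariates,
      p_threshold = config$validation_p))
    val_ste <- run_stage("validation", validation_scan(
      study$validation$beta, study$validation$samples, probe_sets,
      stage_variable = "steatosis", covariates = config$covariates,
      p_threshold = config$validation_p))
    cons_fib <- run_stage("consistency",
                          consistent_validated_sites(disc, val_fib))
    if (config$validation_requires == "either") {
      cons_ste <- consistent_validated_sites(disc, val_ste)
      key <- paste(cons_fib$probe_id, cons_fib$gene)
      key_ok <- paste(cons_ste$probe_id, cons_ste$gene)[cons_ste$validated]
      cons_fib$validated <- cons_fib$validated | key %in% key_ok
    }
    validated <- cons_fib[cons_fib$validated, , drop = FALSE]
    summaries <- run_stage("gene_level", summarize_gene_methylation(
      validated, probe_sets, p0 = config$p0, cluster = cl))
    profiles <- run_stage("gene_level", gene_methylation_profiles(
      study$ec$beta, validated,
      all_sites = if (config$average_all_sites) probe_sets else NULL))
    assoc <- run_stage("association", associate_genes(
      profiles, study$ec$expression, study$ec$samples, psi = config$psi,
      orientation = config$orientation))
    nbr <- if (!is.null(gene_coords)) {
      run_stage("neighbor_scan", neighbor_expression_scan(
        profiles, study$ec$expression, gene_coords, study$ec$samples,
        k = config$neighbor_k, psi = config$psi))
    } else assoc_empty()
    for (nm in c("disc", "val_fib", "val_ste", "validated", "assoc", "nbr")) {
      obj <- get(nm)
      obj$cluster <- cl
      assign(nm, obj)
    }
    list(discovery = disc, validation_fibrosis = val_fib,
         validation_steatosis = val_ste, validated_sites = validated,
         gene_summaries = summaries, associations = assoc,
         neighbor_associations = nbr)
  })
  bind <- function(field) {
    do.call(rbind, lapply(per_cluster, `[[`, field))
  }
  bundle <- list(
    discovery = bind("discovery"),
    validation_fibrosis = bind("validation_fibrosis"),
    validation_steatosis = bind("validation_steatosis"),
    validated_sites = bind("validated_sites"),
    gene_summaries = bind("gene_summaries"),
    associations = bind("associations"),
    neighbor_associations = bind("neighbor_associations"),
    truth = study$truth,
    config = config,
    seed = config$seed
  )
  bundle$summary <- render_summary(bundle,
                                   association_p = config$association_p)
  bundle$manifest <- list(
    package = "tssmeth",
    version = as.character(utils::packageVersion("tssmeth")),
    seed = config$seed,
    clusters = config$clusters,
    counts = lapply(bundle[c("discovery", "validation_fibrosis",
                             "validation_steatosis", "validated_sites",
                             "gene_summaries", "associations",
                             "neighbor_associations", "summary")], nrow)
  )
  class(bundle) <- "meth_pipeline"
  bundle
}

#' Render the per-gene summary table
#'
#' One row per gene x direction (x cluster) with at least one validated
#' site: the change-strength category (1-3), the methylation direction
#' (`hyper`/`hypo`), and the association status from the robust
#' fibrosis-adjusted model: `inverse` when methylation and expression are
#' significantly negatively associated, `parallel` when positively, `none`
#' when not significant (the text equivalent of the figure color scheme).
#'
#' @param bundle a `meth_pipeline` (or a list with `gene_summaries` and
#'   `associations`).
#' @param association_p significance threshold for the association rows.
#' @return data frame with columns `cluster`, `gene`, `direction`,
#'   `category`, `n_total`, `n_sig`, `pct_sig`, `p_binomial`,
#'   `association`, `assoc_coefficient`, `assoc_p`.
#' @export
render_summary <- function(bundle, association_p = 0.05) {
  gs <- bundle$gene_summaries
  as_tab <- bundle$associations
  if (is.null(gs) || nrow(gs) == 0L) {
    return(data.frame(cluster = character(), gene = character(),
                      direction = character(), category = integer(),
                      n_total = integer(), n_sig = integer(),
                      pct_sig = integer(), p_binomial = numeric(),
                      association = character(),
                      assoc_coefficient = numeric(), assoc_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(gs$cluster)) gs$cluster <- NA_character_
  rob <- as_tab[as_tab$model == "robust_adjusted", , drop = FALSE]
  keyg <- paste(gs$cluster, gs$gene, gs$direction)
  keyr <- paste(rob$cluster, rob$gene, rob$direction)
  i <- match(keyg, keyr)
  coefv <- rob$coefficient[i]
  pv <- rob$p[i]
  status <- rep("none", nrow(gs))
  sig <- !is.na(pv) & pv < association_p
  status[sig & coefv < 0] <- "inverse"
  status[sig & coefv > 0] <- "parallel"
  out <- data.frame(
    cluster = gs$cluster, gene = gs$gene, direction = gs$direction,
    category = gs$category, n_total = gs$n_total, n_sig = gs$n_sig,
    pct_sig = gs$pct_sig, p_binomial = gs$p_binomial,
    association = status, assoc_coefficient = coefv, assoc_p = pv,
    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$category, out$gene, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.meth_pipeline <- function(x, ...) {
  cat("Targeted TSS1500 methylation-expression pipeline (seed ", x$seed,
      ")\n", sep = "")
  cnt <- x$manifest$counts
  cat("  probes scanned (probe-gene pairs): ", cnt$discovery, "\n", sep = "")
  cat("  validated sites: ", cnt$validated_sites,
      "; gene x direction summaries: ", cnt$gene_summaries, "\n", sep = "")
  cat("  association rows: ", cnt$associations,
      "; neighbor rows: ", cnt$neighbor_associations, "\n", sep = "")
  cat("  summary rows: ", cnt$summary, "\n", sep = "")
  invisible(x)
}

#' @export
summary.meth_pipeline <- function(object, ...) {
  object$summary
}

#' Write all pipeline tables to a directory
#'
#' Emits one TSV per stage (discovery, validation fibrosis/steatosis,
#' validated sites, gene summaries, associations, neighbor associations,
#' summary) plus a JSON run manifest.
#'
#' @param bundle a `meth_pipeline`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "meth_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("discovery", "validation_fibrosis", "validation_steatosis",
            "validated_sites", "gene_summaries", "associations",
            "neighbor_associations", "summary")
  for (tb in tabs) {
    write_tsv(as.data.frame(bundle[[tb]]), file.path(dir, paste0(tb, ".tsv")))
  }
  manifest <- bundle$manifest
  manifest$config <- unclass(bundle$config)
  manifest$config$simulation <- if (!is.null(bundle$config$simulation))
    unclass(bundle$config$simulation) else NULL
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(dir)
}
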