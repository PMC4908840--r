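#' Load a 450K-style probe annotation table
#'
#' Reads a manifest-style annotation (CSV or TSV, sniffed from the header)
#' into a probe-record data frame with one row per probe-gene pair. Column
#' names are resolved through a `dialect` map so that tables exported from
#' different annotation sources can be consumed without editing.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect named character vector mapping the canonical field names
#'   (`probe_id`, `chrom`, `pos`, `gene`, `tss_distance`, `snp_overlap`) to
#'   the column names used in the file. Fields absent from the map are
#'   assumed to use the canonical name.
#' @return a data frame with columns `probe_id`, `chrom`, `pos` (1-based),
#'   `gene` (upper-cased symbol), `tss_distance` (signed bp, negative =
#'   upstream), `snp_overlap` (logical). Rows with unparseable positions or
#'   distances are dropped with a message reporting the count.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("probe_id,chrom,pos,gene,tss_distance,snp_overlap",
#'              "cg0001,chr1,1000,GENE1,-200,FALSE"), tf)
#' load_probe_annotation(tf)
#' @export
load_probe_annotation <- function(path, dialect = character()) {
  tab <- read_table_auto(path)
  fields <- c("probe_id", "chrom", "pos", "gene", "tss_distance", "snp_overlap")
  cols <- stats::setNames(fields, fields)
  cols[names(dialect)] <- dialect
  missing <- cols[!cols %in% names(tab)]
  if (length(missing)) {
    stop_input("annotation is missing required column(s): ",
               paste0("'", missing, "'", collapse = ", "),
               " (canonical field(s): ",
               paste(names(missing), collapse = ", "), ")")
  }
  if (nrow(tab) == 0L) stop_input("annotation file has no rows: '", path, "'")
  out <- data.frame(
    probe_id = as.character(tab[[cols["probe_id"]]]),
    chrom = as.character(tab[[cols["chrom"]]]),
    pos = suppressWarnings(as.numeric(tab[[cols["pos"]]])),
    gene = toupper(as.character(tab[[cols["gene"]]])),
    tss_distance = suppressWarnings(as.numeric(tab[[cols["tss_distance"]]])),
    snp_overlap = parse_flag(tab[[cols["snp_overlap"]]]),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$pos) | !is.finite(out$tss_distance)
  if (any(bad)) {
    message("load_probe_annotation: dropped ", sum(bad),
            " row(s) with unparseable position or TSS distance")
    out <- out[!bad, , drop = FALSE]
  }
  dup <- duplicated(out[, c("probe_id", "gene")])
  if (any(dup)) out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  toupper(trimws(as.character(x))) %in% c("TRUE", "T", "YES", "Y", "1")
}

#' Select a gene's TSS1500 probes
#'
#' Returns the CpG probes lying within 1500 bp of the gene's transcription
#' start site (boundary inclusive, |distance| <= window) and not overlapping
#' a known SNP. These are the sites the scan stages operate on; SNP-flagged
#' probes are excluded because a polymorphism under the probe confounds the
#' methylation signal.
#'
#' @param probes probe annotation data frame from [load_probe_annotation()].
#' @param gene gene symbol (case-insensitive).
#' @param window half-width of the TSS interval in bp (default 1500).
#' @return character vector of probe ids (possibly empty), sorted.
#' @export
select_tss1500_probes <- function(probes, gene, window = 1500) {
  stopifnot(is.data.frame(probes), length(gene) == 1L, window > 0)
  keep <- probes$gene == toupper(gene) &
    abs(probes$tss_distance) <= window &
    !probes$snp_overlap
  sort(unique(probes$probe_id[keep]))
}

#' TSS1500 probe sets for a list of genes
#'
#' @param probes probe annotation data frame.
#' @param genes character vector of gene symbols.
#' @param window half-width in bp.
#' @return named list of probe-id vectors; genes with no eligible probe map
#'   to an empty vector.
#' @export
tss1500_probe_sets <- function(probes, genes, window = 1500) {
  stats::setNames(
    lapply(genes, function(g) select_tss1500_probes(probes, g, window)),
    toupper(genes)
  )
}

#' Built-in bile-acid and drug-metabolism gene clusters
#'
#' The two curated gene networks the targeted analysis interrogates:
#' cluster 1, 43 genes governing bile-acid synthesis, transport, conjugation
#' and signaling; cluster 2, 40 genes covering phase I/II drug metabolism,
#' drug transport and their transcriptional regulators. Several genes act in
#' both networks (e.g. NR1I2, SLCO2B1) and appear in both clusters. NAT2 is
#' shipped as an optional extra cluster-2 member (flagged `optional`), off by
#' default.
#'
#' @param include_optional include members flagged optional (default FALSE).
#' @return a data frame with columns `gene`, `cluster` (`bile_acid` or
#'   `drug_metabolism`), `functional_category`, `alias`, `optional`.
#' @export
builtin_gene_clusters <- function(include_optional = FALSE) {
  path <- system.file("extdata", "gene_clusters.tsv", package = "tssmeth",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, na.strings = NULL)
  tab$alias[is.na(tab$alias)] <- ""
  if (!include_optional) tab <- tab[!tab$optional, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Genes belonging to one cluster
#'
#' @param cluster `"bile_acid"` or `"drug_metabolism"`.
#' @param include_optional include optional members.
#' @return character vector of gene symbols in table order.
#' @export
cluster_genes <- function(cluster = c("bile_acid", "drug_metabolism"),
                          include_optional = FALSE) {
  cluster <- match.arg(cluster)
  tab <- builtin_gene_clusters(include_optional = include_optional)
  tab$gene[tab$cluster == cluster]
}

#' Load gene TSS coordinates
#'
#' BED-like TSV with columns `chrom`, `tss_pos` (1-based), `strand`, `gene`.
#'
#' @param path file path.
#' @return data frame with one row per gene symbol.
#' @export
load_gene_coords <- function(path) {
  tab <- read_table_auto(path)
  need <- c("chrom", "tss_pos", "strand", "gene")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_input("gene coordinate table is missing column(s): ",
               paste(missing, collapse = ", "))
  }
  out <- data.frame(gene = toupper(as.character(tab$gene)),
                    chrom = as.character(tab$chrom),
                    tss_pos = as.numeric(tab$tss_pos),
                    strand = as.character(tab$strand),
                    stringsAsFactors = FALSE)
  out[!duplicated(out$gene), , drop = FALSE]
}

#' Nearest neighboring genes by TSS position
#'
#' Finds up to `k` genes upstream and `k` genes downstream of the query
#' gene's TSS on the same chromosome, ordered by increasing distance. Used by
#' the neighboring-gene expression scan, which asks whether a target's
#' promoter methylation also tracks the expression of flanking genes.
#'
#' @param gene_coords data frame from [load_gene_coords()] (or the synthetic
#'   generator), columns `gene`, `chrom`, `tss_pos`.
#' @param gene query gene symbol.
#' @param k neighbors per side (default 5).
#' @return character vector of neighbor gene symbols sorted by distance
#'   (closest first); fewer than `2k` if the chromosome runs out.
#' @export
neighbor_genes <- function(gene_coords, gene, k = 5) {
  stopifnot(k >= 0)
  gene <- toupper(gene)
  idx <- match(gene, gene_coords$gene)
  if (is.na(idx)) stop_input("no coordinates for gene '", gene, "'")
  if (k == 0) return(character())
  same <- gene_coords[gene_coords$chrom == gene_coords$chrom[idx] &
                        gene_coords$gene != gene, , drop = FALSE]
  pos0 <- gene_coords$tss_pos[idx]
  up <- same[same$tss_pos < pos0, , drop = FALSE]
  dn <- same[same$tss_pos >= pos0, , drop = FALSE]
  up <- up[order(pos0 - up$tss_pos), , drop = FALSE]
  dn <- dn[order(dn$tss_pos - pos0), , drop = FALSE]
  sel <- rbind(utils::head(up, k), utils::head(dn, k))
  sel$gene[order(abs(sel$tss_pos - pos0))]
}

#' Map fibrosis labels to the ordinal stage scale
#'
#' Harmonizes the two encodings used across cohorts: numeric stages
#' 0/0.5/1/2 and the labels insignificant/mild/advanced. "Insignificant"
#' covers stages 0 and 0.5.
#'
#' @param x vector of labels or numeric codes (NA passed through).
#' @return integer vector with values in {0, 1, 2}.
#' @examples
#' map_fibrosis_stage(c(0.5, "Advanced", 1))
#' @export
map_fibrosis_stage <- function(x) {
  map_one <- function(v) {
    if (is.na(v)) return(NA_integer_)
    key <- tolower(trimws(as.character(v)))
    switch(key,
           "0" = 0L, "0.5" = 0L, "insignificant" = 0L,
           "1" = 1L, "mild" = 1L,
           "2" = 2L, "advanced" = 2L,
           stop_input("unknown fibrosis stage label: '", v, "'"))
  }
  vapply(x, map_one, integer(1), USE.NAMES = FALSE)
}

#' Map steatosis labels to the ordinal grade scale
#'
#' Grades 0-3 correspond to the histological fat-fraction bands
#' <5 %, 5-33 %, 34-66 % and >66 %.
#'
#' @param x vector of labels or numeric codes (NA passed through).
#' @return integer vector with values in {0, 1, 2, 3}.
#' @examples
#' map_steatosis_grade(c("<5 %", ">66 %", 2))
#' @export
map_steatosis_grade <- function(x) {
  map_one <- function(v) {
    if (is.na(v)) return(NA_integer_)
    key <- gsub("[[:space:]]", "", tolower(as.character(v)))
    switch(key,
           "0" = 0L, "<5%" = 0L,
           "1" = 1L, "5-33%" = 1L, "5–33%" = 1L,
           "2" = 2L, "34-66%" = 2L, "34–66%" = 2L,
           "3" = 3L, ">66%" = 3L,
           stop_input("unknown steatosis grade label: '", v, "'"))
  }
  vapply(x, map_one, integer(1), USE.NAMES = FALSE)
}
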