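#' Logit and inverse-logit
#'
#' Natural-log odds transform used on the generator side; the analysis-side
#' M-value uses base-2 logs (see [beta_to_m()]).
#'
#' @param p numeric vector in (0, 1).
#' @param x numeric vector.
#' @return numeric vector.
#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

# round half away from zero (printed-table convention); base round() is
# half-to-even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# clamp beta fractions to the open unit interval
clamp_beta <- function(b, eps = 1e-6) pmin(pmax(b, eps), 1 - eps)

stop_input <- function(...) stop(..., call. = FALSE)

# read a delimited table, sniffing tab vs comma from the header line
read_table_auto <- function(path) {
  if (!file.exists(path)) {
    stop_input("input file does not exist: '", path, "'")
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_input("input file is empty: '", path, "'")
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
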