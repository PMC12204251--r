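#' Read a tab-delimited site table
#'
#' Expected header: gene_id, chrom, pos, ref, alt, mu, qual, consequence,
#' lof_hc, missense_score.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_site_table <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         na.strings = c("NA", ""))
  req <- c("gene_id", "chrom", "pos", "ref", "alt", "mu", "qual",
           "consequence")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Read a BED-like gene CDS table
#'
#' Tab-delimited chrom, start, end, gene_id (half-open 0-based intervals,
#' multiple rows per gene allowed); a header is optional.
#'
#' @param path file path.
#' @return data.frame with the four named columns.
#' @export
read_gene_bed <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("chrom", "start", "end", "gene_id") %in% names(x))) {
    if (ncol(x) < 4) stop("gene BED needs 4 columns")
    names(x)[1:4] <- c("chrom", "start", "end", "gene_id")
  }
  validate_gene_table(x[, c("chrom", "start", "end", "gene_id")])
  x
}

#' Read a de novo variant list
#'
#' Tab-delimited with header chrom, pos, ref, alt and optionally subcohort.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_denovo_table <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("de novo table missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Read a population allele-count table
#'
#' Tab-delimited with header gene_id, mu, k, n (per-site rows).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_allele_table <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  miss <- setdiff(c("gene_id", "mu", "k", "n"), names(x))
  if (length(miss)) stop("allele-count table missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
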