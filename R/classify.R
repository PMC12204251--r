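#' Classify variants into functional categories
#'
#' Assigns each candidate SNV to one of three classes used throughout the
#' pipeline, or rejects it:
#' \itemize{
#'   \item \code{LoF}: high-confidence LoF flag set AND a consequence of
#'     \code{stop_gained}, \code{splice_donor_variant} or
#'     \code{splice_acceptor_variant};
#'   \item \code{synonymous}: consequence labels are synonymous only, with no
#'     splice involvement;
#'   \item \code{missense}: annotated missense with pathogenicity score
#'     strictly greater than \code{missense_cutoff}.
#' }
#' Sites whose rate-model quality tier is neither \code{"high"} nor
#' \code{"TFBS"} are rejected outright. A missense site lacking a score is
#' rejected and counted in the diagnostics tally.
#'
#' @param sites data.frame with columns `mu` (> 0), `qual`, `consequence`
#'   (one or more labels separated by `&` or `,`), `lof_hc` (logical),
#'   `missense_score` (numeric in \[0,1\], `NA` allowed).
#' @param missense_cutoff strict lower cutoff on the missense score
#'   (default 0.1).
#' @return factor of classes (`LoF`, `synonymous`, `missense`, `rejected`)
#'   with a `diagnostics` attribute tallying rejection reasons.
#' @export
classify_variants <- function(sites, missense_cutoff = 0.1) {
  stopifnot(all(c("mu", "qual", "consequence") %in% names(sites)))
  if (any(sites$mu <= 0)) stop("all baseline rates mu must be > 0")
  if (all(c("ref", "alt") %in% names(sites)) &&
      any(sites$ref == sites$alt)) stop("ref and alt must differ")
  n <- nrow(sites)
  lof_hc <- if ("lof_hc" %in% names(sites)) {
    as.logical(sites$lof_hc)
  } else rep(FALSE, n)
  score <- if ("missense_score" %in% names(sites)) {
    as.numeric(sites$missense_score)
  } else rep(NA_real_, n)

  labs <- strsplit(as.character(sites$consequence), "[&,]")
  labs <- lapply(labs, trimws)
  admissible <- sites$qual %in% c("high", "TFBS")
  has <- function(ll, pat) vapply(ll, function(x) any(grepl(pat, x)), logical(1))
  lof_csq <- vapply(
    labs,
    function(x) any(x %in% c("stop_gained", "splice_donor_variant",
                             "splice_acceptor_variant")),
    logical(1)
  )
  splicey <- has(labs, "splice")
  syn_only <- vapply(
    labs,
    function(x) length(x) > 0 && all(grepl("synonymous", x)),
    logical(1)
  )
  missense <- has(labs, "missense")

  cls <- rep("rejected", n)
  is_lof <- admissible & lof_hc & lof_csq
  is_syn <- admissible & !is_lof & syn_only & !splicey
  is_mis <- admissible & !is_lof & !is_syn & missense &
    !is.na(score) & score > missense_cutoff
  cls[is_lof] <- "LoF"
  cls[is_syn] <- "synonymous"
  cls[is_mis] <- "missense"
  out <- factor(cls, levels = c("LoF", "synonymous", "missense", "rejected"))
  attr(out, "diagnostics") <- c(
    inadmissible_quality = sum(!admissible),
    missense_missing_score = sum(admissible & missense & !is_lof & !is_syn &
                                   is.na(score)),
    rejected_total = sum(cls == "rejected")
  )
  out
}

#' Synonymous-normalised mutational expectations
#'
#' Scales per-site baseline mutation rates into expected de novo counts for a
#' given cohort by anchoring on the observed number of synonymous de novo
#' mutations: lambda_v = NS * mu_v / sum over admissible synonymous sites of
#' mu. The normalisation absorbs cohort-level factors (parental age,
#' coverage) and makes expectations comparable across variant classes.
#' Gene-by-class expectations are sums of site expectations.
#'
#' @param sites data.frame of admissible sites with columns `gene_id`, `mu`
#'   and `class` (values among `LoF`, `synonymous`, `missense`; other rows
#'   are ignored).
#' @param ns_count observed synonymous de novo count NS (>= 0).
#' @return object of class `ces_expectation`: list with `ns_count`, `sites`
#'   (input plus `lambda` column) and `genes` (gene_id, class, lambda_g,
#'   n_sites).
#' @export
compute_expectations <- function(sites, ns_count) {
  stopifnot(all(c("gene_id", "mu", "class") %in% names(sites)))
  if (length(ns_count) != 1L || is.na(ns_count) || ns_count < 0) {
    stop("ns_count must be a single nonnegative number")
  }
  keep <- sites$class %in% c("LoF", "synonymous", "missense")
  sites <- sites[keep, , drop = FALSE]
  syn_mu <- sum(sites$mu[sites$class == "synonymous"])
  if (!(syn_mu > 0)) {
    stop("no admissible synonymous sites: expectation undefined")
  }
  sites$lambda <- ns_count * sites$mu / syn_mu
  ag <- stats::aggregate(
    cbind(lambda_g = sites$lambda, n_sites = 1),
    by = list(gene_id = sites$gene_id, class = sites$class),
    FUN = sum
  )
  ag <- ag[order(ag$gene_id, ag$class), , drop = FALSE]
  rownames(ag) <- NULL
  structure(
    list(ns_count = ns_count, sites = sites, genes = ag),
    class = "ces_expectation"
  )
}

#' @export
print.ces_expectation <- function(x, ...) {
  cat("Synonymous-normalised expectations: NS =", x$ns_count, "over",
      nrow(x$sites), "sites,", nrow(x$genes), "gene-class groups\n")
  invisible(x)
}

#' Count observed de novo mutations per site
#'
#' Matches a de novo variant list against a site table by (chrom, pos, ref,
#' alt) and returns the per-site recurrence count.
#'
#' @param sites site table with `chrom`, `pos`, `ref`, `alt`.
#' @param denovo de novo list with the same four columns (one row per event).
#' @return integer vector of counts, aligned with `sites` rows; unmatched
#'   de novo events are tallied in `attr(, "unmatched")`.
#' @export
count_denovo <- function(sites, denovo) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  tab <- table(key(denovo))
  out <- as.integer(tab[key(sites)])
  out[is.na(out)] <- 0L
  attr(out, "unmatched") <- nrow(denovo) - sum(out)
  out
}
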