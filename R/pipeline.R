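#' Default analysis thresholds
#'
#' The constants used across the pipeline stages: prevalence lower bound
#' (inverse = ascertainment bound), per-site overdispersion factor,
#' gene-level and variant-level FDR thresholds, the constraint-score cutoff
#' for the LoF-2 selection, and the site/rate filters of the
#' mutation-selection-drift analysis.
#'
#' @return named list of defaults.
#' @export
ces_thresholds <- function() {
  list(prevalence_lower_bound = 0.01,
       gamma = 0.004,
       fdr_gene = 0.1,
       fdr_variant = 0.2,
       loeuf_threshold = 0.5,
       nei_min_sites = 10,
       nei_min_mu = 1.0,
       # null mean of the variant-level test: "cohort" = synonymous-scaled
       # expectation lambda_v (keeps variant- and gene-level tests on one
       # scale); "raw" = the unscaled baseline rate mu_v
       gof_expectation = "cohort")
}

run_stage <- function(report, name, deps, fun) {
  for (d in deps) {
    if (!identical(report$stages[[d]]$status, "ok")) {
      report$stages[[name]] <- list(status = "skipped",
                                    reason = paste("dependency failed:", d))
      return(report)
    }
  }
  res <- tryCatch(list(status = "ok", value = fun()),
                  error = function(e) list(status = "failed",
                                           reason = conditionMessage(e)))
  report$stages[[name]] <- res
  report
}

#' Run the full CES discovery pipeline
#'
#' Orchestrates expectation -> dispersion control -> subcohort homogeneity
#' -> variant-level (GoF) and gene-level (LoF-1, LoF-2) candidate tests ->
#' population-genetic mutation-selection-drift decomposition -> SFS-based
#' shet estimation -> trio-vs-sperm comparison. Stage failures are recorded
#' and dependent stages skipped; independent stages still run.
#'
#' @param inputs list with elements:
#'   `sites` (site table with class column or raw annotations),
#'   `genes` (CDS interval table),
#'   `denovo` (de novo list with subcohort column),
#'   `subcohort_weights` (named synonymous counts per subcohort),
#'   `loeuf` (named per-gene scores),
#'   `allele_counts` (optional population table with `n` column),
#'   `sperm` (optional data.frame gene_id, m_sperm, lambda_sperm),
#'   `mu_scale` (optional, for the popgen stage).
#' @param thresholds overrides of [ces_thresholds()].
#' @param seed integer seed recorded in the report (the analysis itself is
#'   deterministic given inputs).
#' @return object of class `ces_report`: `thresholds`, `seed`, `stages`
#'   (each `status` plus stage value), `version`.
#' @export
run_ces_pipeline <- function(inputs, thresholds = list(), seed = 1L) {
  thr <- utils::modifyList(ces_thresholds(), thresholds)
  report <- list(
    version = as.character(utils::packageVersion("cesscan")),
    seed = seed,
    thresholds = thr,
    stages = list()
  )
  ascert <- ascertainment_model(thr$prevalence_lower_bound)

  report <- run_stage(report, "expectation", character(0), function() {
    sites <- inputs$sites
    genes <- select_nonoverlapping_genes(inputs$genes)
    retained <- attr(genes, "retained")
    sites <- sites[sites$gene_id %in% retained, , drop = FALSE]
    if (!"class" %in% names(sites)) {
      sites$class <- as.character(classify_variants(sites))
    }
    ns <- sum(count_denovo(sites[sites$class == "synonymous", , drop = FALSE],
                           inputs$denovo))
    exp <- compute_expectations(sites, ns)
    list(expectation = exp, retained_genes = retained,
         dropped_genes = attr(genes, "dropped"))
  })

  report <- run_stage(report, "dispersion", "expectation", function() {
    exp <- report$stages$expectation$value$expectation
    syn <- exp$sites[exp$sites$class == "synonymous", , drop = FALSE]
    nv <- count_denovo(syn, inputs$denovo)
    site_fit <- fit_gamma(nv, syn$lambda)
    ge <- stats::aggregate(cbind(ng = nv), by = list(gene_id = syn$gene_id),
                          FUN = sum)
    lg <- stats::aggregate(cbind(lambda_g = syn$lambda),
                           by = list(gene_id = syn$gene_id), FUN = sum)
    chi <- gene_level_chi2(ge$ng, lg$lambda_g)
    list(site_fit = site_fit, gene_chi2 = chi)
  })

  report <- run_stage(report, "homogeneity", "expectation", function() {
    exp <- report$stages$expectation$value$expectation
    lofs <- exp$sites[exp$sites$class == "LoF", , drop = FALSE]
    dn <- inputs$denovo
    if (!"subcohort" %in% names(dn)) stop("de novo table lacks subcohort")
    key <- paste(lofs$chrom, lofs$pos, lofs$ref, lofs$alt, sep = ":")
    dn$site_key <- paste(dn$chrom, dn$pos, dn$ref, dn$alt, sep = ":")
    dn <- dn[dn$site_key %in% key, , drop = FALSE]
    dn$gene_id <- lofs$gene_id[match(dn$site_key, key)]
    cohorts <- names(inputs$subcohort_weights)
    counts <- table(factor(dn$gene_id),
                    factor(dn$subcohort, levels = cohorts))
    compare_homogeneity(unclass(counts), inputs$subcohort_weights)
  })

  report <- run_stage(report, "gof", "expectation", function() {
    exp <- report$stages$expectation$value$expectation
    mis <- exp$sites[exp$sites$class == "missense", , drop = FALSE]
    nv <- count_denovo(mis, inputs$denovo)
    expd <- if (identical(thr$gof_expectation, "raw")) mis$mu else mis$lambda
    gof_variant_test(nv, expd, ascert, gamma = thr$gamma,
                     unit = paste(mis$chrom, mis$pos, mis$ref, mis$alt,
                                  sep = ":"))
  })

  report <- run_stage(report, "lof1", "expectation", function() {
    exp <- report$stages$expectation$value$expectation
    lofs <- exp$sites[exp$sites$class == "LoF", , drop = FALSE]
    nv <- count_denovo(lofs, inputs$denovo)
    ng <- tapply(nv, lofs$gene_id, sum)
    lg <- tapply(lofs$lambda, lofs$gene_id, sum)
    lof1_gene_test(as.integer(ng), as.numeric(lg), ascert,
                   unit = names(ng))
  })

  report <- run_stage(report, "lof2", "expectation", function() {
    exp <- report$stages$expectation$value$expectation
    lofs <- exp$sites[exp$sites$class == "LoF", , drop = FALSE]
    nv <- count_denovo(lofs, inputs$denovo)
    ng <- tapply(nv, lofs$gene_id, sum)
    lg <- tapply(lofs$lambda, lofs$gene_id, sum)
    loeuf <- inputs$loeuf[names(ng)]
    lof2_select(as.integer(ng), as.numeric(lg), as.numeric(loeuf),
                fdr = thr$fdr_gene, loeuf_threshold = thr$loeuf_threshold,
                unit = names(ng))
  })

  report <- run_stage(report, "nei", character(0), function() {
    if (is.null(inputs$allele_counts)) stop("no allele-count input")
    tab <- filter_nei_genes(inputs$allele_counts,
                            min_mu = thr$nei_min_mu,
                            min_sites = thr$nei_min_sites)
    if (nrow(tab) == 0L) stop("no genes pass the popgen filters")
    n <- unique(inputs$allele_counts$n)
    est <- nei_decompose_genes(tab, n = n,
                               mu_scale = if (!is.null(inputs$mu_scale))
                                 inputs$mu_scale else 1)
    resid <- tryCatch(ces_residuals(est), error = function(e) NULL)
    list(estimates = est, residuals = resid)
  })

  report <- run_stage(report, "compare", c("expectation", "lof1"),
                      function() {
    if (is.null(inputs$sperm)) stop("no sperm-sequencing input")
    lof1 <- report$stages$lof1$value
    sp <- inputs$sperm
    idx <- match(lof1$unit, sp$gene_id)
    ok <- !is.na(idx)
    compare_cohorts(lof1$observed[ok], sp$m_sperm[idx[ok]],
                    lof1$expected[ok], sp$lambda_sperm[idx[ok]],
                    unit = lof1$unit[ok])
  })

  class(report) <- "ces_report"
  report
}

#' @export
print.ces_report <- function(x, ...) {
  cat("CES pipeline report (version", x$version, ", seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")") else ""))
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serialises stage statuses, thresholds and the main result tables; model
#' objects are reduced to their numeric summaries.
#'
#' @param report a `ces_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ces_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  slim <- lapply(report$stages, function(st) {
    out <- list(status = st$status)
    if (!is.null(st$reason)) out$reason <- st$reason
    if (identical(st$status, "ok")) out$value <- unclass_deep(st$value)
    out
  })
  jsonlite::write_json(
    list(version = report$version, seed = report$seed,
         thresholds = report$thresholds, stages = slim),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.data.frame(x)) {
    as.data.frame(unclass(x))
  } else {
    x
  }
}
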