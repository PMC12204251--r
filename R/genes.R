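#' Validate a gene CDS interval table
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `gene_id`;
#'   one row per CDS interval (half-open, 0-based), multiple rows per gene.
#' @return the table, with intervals sorted within gene, invisibly on success.
#' @details Errors if any interval has `end <= start`, or if two intervals of
#'   the *same* gene overlap (a gene's CDS footprint must be a disjoint union).
#' @export
validate_gene_table <- function(genes) {
  req <- c("chrom", "start", "end", "gene_id")
  if (!all(req %in% names(genes))) {
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(genes) == 0L) return(invisible(genes))
  bad <- which(!(genes$end > genes$start))
  if (length(bad)) {
    stop("malformed CDS interval (end <= start) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  genes <- genes[order(genes$gene_id, genes$chrom, genes$start), , drop = FALSE]
  for (g in split(genes, genes$gene_id)) {
    if (nrow(g) > 1L) {
      o <- order(g$chrom, g$start)
      same <- g$chrom[o][-nrow(g)] == g$chrom[o][-1]
      if (any(same & g$end[o][-nrow(g)] > g$start[o][-1])) {
        stop("overlapping CDS intervals within gene ", g$gene_id[1])
      }
    }
  }
  invisible(genes)
}

#' Total CDS length per gene
#'
#' @inheritParams validate_gene_table
#' @return named numeric vector of summed interval lengths (bases).
#' @export
gene_cds_length <- function(genes) {
  validate_gene_table(genes)
  if (nrow(genes) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply(genes$end - genes$start, genes$gene_id, sum)
}

# Pairs of genes whose CDS footprints share at least one base.
# Sweep per chromosome over interval endpoints.
gene_overlap_pairs <- function(genes) {
  pairs <- list()
  for (g in split(genes, genes$chrom)) {
    o <- order(g$start, g$end)
    g <- g[o, , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && g$start[j] < g$end[i]) {
        if (g$gene_id[i] != g$gene_id[j]) {
          pairs[[length(pairs) + 1L]] <-
            sort(c(g$gene_id[i], g$gene_id[j]))
        }
        j <- j + 1L
      }
    }
  }
  if (!length(pairs)) {
    return(data.frame(a = character(0), b = character(0)))
  }
  m <- unique(do.call(rbind, pairs))
  data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
}

# TRUE if sorted id vector a precedes b lexicographically
# (element-wise; a strict prefix precedes the longer vector).
ids_precede <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- min(length(a), length(b))
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
  }
  length(a) < length(b)
}

# Exact maximum-weight independent set on one connected component,
# branch-and-bound on adjacency lists. ids: character; w: weights;
# adj: list of integer neighbour indices. Ties resolved toward the
# lexicographically smallest sorted id set.
mwis_component <- function(ids, w, adj) {
  n <- length(ids)
  best_w <- -Inf
  best_set <- integer(0)
  consider <- function(set) {
    tw <- sum(w[set])
    if (tw > best_w + 1e-9 ||
        (abs(tw - best_w) <= 1e-9 && ids_precede(ids[set], ids[best_set]))) {
      best_w <<- tw
      best_set <<- set
    }
  }
  recurse <- function(active, set) {
    if (!length(active)) { consider(set); return() }
    # bound: current + everything still active (keep equal-weight branches
    # alive so the lexicographic tie-break sees them)
    if (sum(w[set]) + sum(w[active]) < best_w - 1e-9) return()
    v <- active[order(-w[active], ids[active])][1]
    recurse(setdiff(active, c(v, adj[[v]])), c(set, v))
    recurse(setdiff(active, v), set)
  }
  recurse(seq_len(n), integer(0))
  best_set
}

#' Select a maximal non-overlapping gene subset
#'
#' Given genes with possibly overlapping CDS footprints, returns the subset of
#' pairwise non-overlapping genes maximising total CDS length (maximum-weight
#' independent set on the interval-overlap graph). For a single overlapping
#' pair this retains the longer gene. Ties are broken toward the
#' lexicographically smallest set of gene ids, so the result is deterministic.
#'
#' @inheritParams validate_gene_table
#' @return the input table restricted to retained genes; the retained ids are
#'   in `attr(, "retained")` and dropped ids in `attr(, "dropped")`.
#' @export
select_nonoverlapping_genes <- function(genes) {
  validate_gene_table(genes)
  if (nrow(genes) == 0L) {
    out <- genes
    attr(out, "retained") <- character(0)
    attr(out, "dropped") <- character(0)
    return(out)
  }
  w_all <- gene_cds_length(genes)
  ids_all <- names(w_all)
  ed <- gene_overlap_pairs(genes)
  adj <- stats::setNames(vector("list", length(ids_all)), ids_all)
  for (i in seq_len(nrow(ed))) {
    adj[[ed$a[i]]] <- c(adj[[ed$a[i]]], ed$b[i])
    adj[[ed$b[i]]] <- c(adj[[ed$b[i]]], ed$a[i])
  }
  # connected components
  comp <- stats::setNames(rep(NA_integer_, length(ids_all)), ids_all)
  cid <- 0L
  for (v in ids_all) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, adj[[u]])
    }
  }
  retained <- character(0)
  for (k in unique(comp)) {
    ids <- ids_all[comp == k]
    if (length(ids) == 1L) { retained <- c(retained, ids); next }
    adj_i <- lapply(ids, function(u) match(intersect(adj[[u]], ids), ids))
    sel <- mwis_component(ids, unname(w_all[ids]), adj_i)
    retained <- c(retained, ids[sel])
  }
  retained <- sort(retained)
  out <- genes[genes$gene_id %in% retained, , drop = FALSE]
  attr(out, "retained") <- retained
  attr(out, "dropped") <- sort(setdiff(ids_all, retained))
  out
}
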