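# shared fixture builders and independent oracles

make_gene <- function(id, start, end, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(id)), start = start, end = end,
             gene_id = id, stringsAsFactors = FALSE)
}

# random gene instance with chained overlaps for the subset-selection oracle
random_gene_instance <- function(n_genes, span = 2000L) {
  starts <- sample.int(span, n_genes, replace = TRUE)
  lens <- sample(50:400, n_genes, replace = TRUE)
  do.call(rbind, lapply(seq_len(n_genes), function(i) {
    make_gene(sprintf("g%02d", i), starts[i], starts[i] + lens[i])
  }))
}

# brute-force maximum-weight independent set over all subsets (<= 15 genes);
# independent of the package implementation. Returns the winning id set
# (ties: lexicographically smallest sorted id vector).
brute_force_selection <- function(genes) {
  ids <- sort(unique(genes$gene_id))
  n <- length(ids)
  w <- sapply(ids, function(g) {
    gg <- genes[genes$gene_id == g, ]
    sum(gg$end - gg$start)
  })
  # conflict bitmask per gene
  conflict <- integer(n)
  for (i in seq_len(n - 1)) {
    ga <- genes[genes$gene_id == ids[i], ]
    for (j in (i + 1):n) {
      gb <- genes[genes$gene_id == ids[j], ]
      hit <- FALSE
      for (a in seq_len(nrow(ga))) {
        if (any(ga$chrom[a] == gb$chrom & ga$start[a] < gb$end &
                  gb$start < ga$end[a])) { hit <- TRUE; break }
      }
      if (hit) {
        conflict[i] <- bitwOr(conflict[i], bitwShiftL(1L, j - 1L))
        conflict[j] <- bitwOr(conflict[j], bitwShiftL(1L, i - 1L))
      }
    }
  }
  # vectorised sweep over all subsets
  masks <- 0:(2^n - 1)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  feasible <- rep(TRUE, length(masks))
  weight <- numeric(length(masks))
  for (i in seq_len(n)) {
    sel_i <- bitwAnd(masks, bits[i]) > 0
    feasible <- feasible & !(sel_i & bitwAnd(masks, conflict[i]) > 0)
    weight <- weight + w[i] * sel_i
  }
  weight[!feasible] <- -1
  best_w <- max(weight)
  cand <- masks[weight == best_w]
  sets <- lapply(cand, function(m) ids[bitwAnd(m, bits) > 0])
  keys <- vapply(sets, paste, "", collapse = "|")
  sets[[order(keys)[1]]]
}

make_site <- function(gene_id = "G1", mu = 1, qual = "high",
                      consequence = "synonymous_variant", lof_hc = FALSE,
                      missense_score = NA_real_, pos = 100, ref = "A",
                      alt = "G", chrom = "chr1") {
  data.frame(gene_id = gene_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, mu = mu, qual = qual, consequence = consequence,
             lof_hc = lof_hc, missense_score = missense_score,
             stringsAsFactors = FALSE)
}

# small site table across classes and genes
site_fixture <- function(n = 1000, seed = 42) {
  set.seed(seed)
  cls <- sample(c("LoF", "synonymous", "missense"), n, replace = TRUE,
                prob = c(0.2, 0.4, 0.4))
  data.frame(
    gene_id = sample(sprintf("G%03d", 1:20), n, replace = TRUE),
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    mu = rlnorm(n, 0, 1),
    class = cls,
    stringsAsFactors = FALSE
  )
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
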