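# Small in-code fixtures shared across test files.

# genes x (3 genotypes x n_rep) matrix from per-genotype mean values, with
# optional replicate-level log2 noise
toy_matrix <- function(means_wt, means_a, means_b, n_rep = 2,
                       noise_sd = 0, gene_ids = NULL) {
  n <- length(means_wt)
  gene_ids <- gene_ids %||% sprintf("g%03d", seq_len(n))
  genotype <- rep(c("WT", "A-KO", "B-KO"), each = n_rep)
  base <- cbind(means_wt, means_a, means_b)
  vals <- matrix(0, n, length(genotype), dimnames = list(gene_ids, NULL))
  for (j in seq_along(genotype)) {
    g <- match(genotype[j], c("WT", "A-KO", "B-KO"))
    eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    vals[, j] <- base[, g] * 2^eps
  }
  expression_matrix(vals, genotype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built DE row set for classifier tests: one row per gene given
# log2fc and p per contrast
toy_de <- function(gene_id, log2fc, pvalue, fc = 1.5, p_cutoff = 0.05) {
  abs_fc <- 2^abs(log2fc)
  structure(
    data.frame(gene_id = gene_id,
               mean_g1 = 2^log2fc, mean_g2 = 1,
               log2fc = log2fc, abs_fc = abs_fc, pvalue = pvalue,
               regulated = abs_fc > fc & pvalue < p_cutoff,
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
}

# quadratic brute-force maximum bipartite matching on the interval overlap
# graph (Kuhn's augmenting-path algorithm); independent oracle for
# overlap_peaks()
oracle_max_matching <- function(set_x, set_y) {
  nx <- nrow(set_x); ny <- nrow(set_y)
  adj <- vector("list", nx)
  for (i in seq_len(nx)) {
    hits <- which(set_y$chrom == set_x$chrom[i] &
                    set_y$start < set_x$end[i] &
                    set_x$start[i] < set_y$end)
    adj[[i]] <- hits
  }
  match_y <- rep(0L, ny)
  seen <- logical(ny)
  augment <- function(i) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <<- TRUE
      if (match_y[j] == 0L || augment(match_y[j])) {
        match_y[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  n_matched <- 0L
  for (i in seq_len(nx)) {
    seen <- logical(ny)
    if (augment(i)) n_matched <- n_matched + 1L
  }
  n_matched
}

# linear-scan nearest-TSS oracle with the package's tie rule (smaller
# position, then lexicographically first gene id)
oracle_nearest_tss <- function(peaks, tss) {
  mid <- (peaks$start + peaks$end) %/% 2L
  vapply(seq_len(nrow(peaks)), function(i) {
    rows <- which(tss$chrom == peaks$chrom[i])
    if (length(rows) == 0) return(NA_character_)
    d <- abs(tss$tss[rows] - mid[i])
    best <- rows[d == min(d)]
    best <- best[order(tss$tss[best], tss$gene_id[best])]
    tss$gene_id[best[1]]
  }, character(1))
}

random_peak_set <- function(n, chroms = c("chr1", "chr2"), span = 50000,
                            width_max = 800) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(width_max, n, replace = TRUE)
  peak_set(chrom = sample(chroms, n, replace = TRUE),
           start = start, end = start + width,
           height = runif(n, 1, 50),
           fold_enrichment = runif(n, 4, 30),
           pvalue = 10^-runif(n, 6, 12))
}
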