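#' Simulation settings for synthetic paralog-dose data
#'
#' Defines the generative model used by [generate_expression()],
#' [generate_peaks()] and [generate_mfi()]: a transcriptome of `n_genes`
#' genes with lognormal baseline RPKM, a planted mixture of unaffected
#' ("null"), pan-regulated and paralog-specific genes, and replicate-level
#' multiplicative noise on the log2 scale.
#'
#' Pan genes are perturbed in both knockout contrasts with a fixed dominance
#' asymmetry: when the B-knockout and A-knockout effects share a sign, the
#' planted log2 fold change in the B contrast is `log2(asymmetry_r)` larger
#' in magnitude than in the A contrast, so the linear fold change is
#' `asymmetry_r` times larger. Paralog-specific genes are perturbed in
#' exactly one contrast. Effect magnitudes are `effect_log2fc_mean` plus a
#' half-normal excess with scale `effect_log2fc_sd`, so `effect_log2fc_mean`
#' is a guaranteed minimum planted |log2FC|.
#'
#' Baselines of genes carrying a planted effect are truncated below at
#' `expressed_floor` RPKM (regulated transcripts are by definition
#' detectable); null-gene baselines are left untruncated so the
#' low-expression filter path is exercised.
#'
#' @param n_genes number of genes.
#' @param frac_null,frac_pan,frac_a_specific,frac_b_specific category
#'   proportions; must sum to 1.
#' @param asymmetry_r linear fold-change multiplier applied to pan-gene
#'   effects in the B-knockout contrast relative to the A-knockout contrast
#'   (> 1 means loss of B hits harder).
#' @param effect_log2fc_mean minimum planted effect magnitude (log2 scale).
#' @param effect_log2fc_sd half-normal scale of the magnitude excess.
#' @param baseline_log_mean,baseline_log_sd lognormal baseline RPKM
#'   parameters (natural-log scale).
#' @param noise_sd per-replicate log2 noise standard deviation.
#' @param n_replicates replicates per genotype (>= 2).
#' @param effect_direction `"random"` (sign drawn per gene), `"down"` or
#'   `"up"`.
#' @param expressed_floor baseline truncation floor (RPKM) for genes with a
#'   planted effect.
#' @param seed integer RNG seed.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000,
                              frac_null = 0.70,
                              frac_pan = 0.25,
                              frac_a_specific = 0.02,
                              frac_b_specific = 0.03,
                              asymmetry_r = 2,
                              effect_log2fc_mean = 1.0,
                              effect_log2fc_sd = 0.5,
                              baseline_log_mean = -2.4,
                              baseline_log_sd = 1.8,
                              noise_sd = 0.25,
                              n_replicates = 3,
                              effect_direction = c("random", "down", "up"),
                              expressed_floor = 1,
                              seed = 1L) {
  fr <- c(frac_null, frac_pan, frac_a_specific, frac_b_specific)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
    stop_config("category proportions must lie in [0,1] and sum to 1")
  if (n_genes < 1) stop_config("n_genes must be positive")
  if (n_replicates < 2) stop_config("n_replicates must be >= 2")
  if (asymmetry_r <= 0) stop_config("asymmetry_r must be > 0")
  if (noise_sd < 0) stop_config("noise_sd must be nonnegative")
  if (effect_log2fc_mean < 0 || effect_log2fc_sd < 0)
    stop_config("effect magnitude parameters must be nonnegative")
  structure(
    list(n_genes = as.integer(n_genes),
         frac_null = frac_null, frac_pan = frac_pan,
         frac_a_specific = frac_a_specific,
         frac_b_specific = frac_b_specific,
         asymmetry_r = asymmetry_r,
         effect_log2fc_mean = effect_log2fc_mean,
         effect_log2fc_sd = effect_log2fc_sd,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates),
         effect_direction = match.arg(effect_direction),
         expressed_floor = expressed_floor,
         seed = as.integer(seed)),
    class = "simulation_config")
}

# Integer category counts that sum exactly to n_genes (remainder -> null).
category_counts <- function(config) {
  n <- config$n_genes
  k <- c(pan = round(config$frac_pan * n),
         a_specific = round(config$frac_a_specific * n),
         b_specific = round(config$frac_b_specific * n))
  if (sum(k) > n) stop_config("category proportions round above n_genes")
  c(null = n - sum(k), k)
}

#' Generate a synthetic expression matrix with planted ground truth
#'
#' Draws a genes-by-samples RPKM matrix for three genotypes (`WT`, `A-KO`,
#' `B-KO`) with `n_replicates` columns each. Replicate values are
#' `baseline * 2^(log2fc_genotype + N(0, noise_sd))`, with the WT log2 fold
#' change fixed at 0. Identical configs (including seed) give identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data frame: `gene_id`, `category`, `log2fc_a`, `log2fc_b`,
#'   `baseline`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    k <- category_counts(config)
    category <- sample(rep(names(k), k))
    gene_id <- sprintf("gene%05d", seq_len(n))

    baseline <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    affected <- category != "null"
    if (config$baseline_log_sd > 0 && any(affected)) {
      # truncated lognormal above the expressed floor via inverse CDF
      p0 <- stats::plnorm(config$expressed_floor,
                          config$baseline_log_mean, config$baseline_log_sd)
      u <- runif(sum(affected), p0, 1)
      baseline[affected] <- stats::qlnorm(u, config$baseline_log_mean,
                                          config$baseline_log_sd)
    }

    sgn <- switch(config$effect_direction,
                  random = sample(c(-1, 1), n, replace = TRUE),
                  down = rep(-1, n),
                  up = rep(1, n))
    mag <- config$effect_log2fc_mean +
      abs(rnorm(n, 0, config$effect_log2fc_sd))

    log2fc_a <- numeric(n)
    log2fc_b <- numeric(n)
    pan <- category == "pan"
    log2fc_a[pan] <- sgn[pan] * mag[pan]
    log2fc_b[pan] <- sgn[pan] * (mag[pan] + log2(config$asymmetry_r))
    asp <- category == "a_specific"
    log2fc_a[asp] <- sgn[asp] * mag[asp]
    bsp <- category == "b_specific"
    log2fc_b[bsp] <- sgn[bsp] * mag[bsp]

    genotype <- rep(c("WT", "A-KO", "B-KO"), each = config$n_replicates)
    fc <- cbind(0, log2fc_a, log2fc_b)  # per-genotype planted log2FC
    vals <- matrix(0, n, length(genotype),
                   dimnames = list(gene_id, NULL))
    for (j in seq_along(genotype)) {
      g <- match(genotype[j], c("WT", "A-KO", "B-KO"))
      eps <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
      vals[, j] <- baseline * 2^(fc[, g] + eps)
    }

    list(matrix = expression_matrix(vals, genotype),
         truth = data.frame(gene_id = gene_id, category = category,
                            log2fc_a = log2fc_a, log2fc_b = log2fc_b,
                            baseline = baseline,
                            stringsAsFactors = FALSE))
  })
}

#' Generate synthetic ChIP-seq peak sets across an allele-dosage series
#'
#' Draws one candidate binding site per gene near a synthetic TSS, with a
#' lognormal peak height. Retention across genotypes is a deterministic
#' height threshold: a peak is present in a genotype exactly when its height
#' reaches that genotype's cutoff. With cutoffs ordered
#' `WT <= het <= A-KO <= B-KO` this reproduces the loss hierarchy in which
#' only the tallest (highest-affinity) sites survive progressive loss of
#' the dominant paralog.
#'
#' @param config a [simulation_config()] (supplies gene count and seed).
#' @param thresholds named numeric height cutoffs for `WT`, `het`, `A-KO`,
#'   `B-KO`, in nondecreasing order. Default: height quantiles chosen so
#'   retained-peak counts fall off steeply from WT to B-KO.
#' @param height_log_mean,height_log_sd lognormal height parameters.
#' @param heights optional vector of `n_genes` peak heights overriding the
#'   lognormal draw (useful for constructing exactly reproducible cases).
#' @return A list with `peaks` (named list of [peak_set()] data frames, one
#'   per genotype), `tss` (TSS annotation data frame), `truth` (per-peak
#'   height, linked gene and per-genotype retention flags) and `thresholds`.
#' @export
generate_peaks <- function(config, thresholds = NULL,
                           height_log_mean = log(20),
                           height_log_sd = 0.8, heights = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_genes
    gene_id <- sprintf("gene%05d", seq_len(n))
    chrom <- paste0("chr", ((seq_len(n) - 1) %% 19) + 1)
    tss_pos <- 100000 + 200000 * ((seq_len(n) - 1) %/% 19)
    strand <- rep(c("+", "-"), length.out = n)
    tss <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tss = tss_pos, stringsAsFactors = FALSE)

    height <- heights %||% rlnorm(n, height_log_mean, height_log_sd)
    if (length(height) != n)
      stop_config("heights must have one value per gene")
    if (is.null(thresholds)) {
      q <- quantile(height, c(0, 0.48, 0.52, 0.92), names = FALSE)
      thresholds <- c(WT = 0, het = q[2], `A-KO` = q[3], `B-KO` = q[4])
    }
    gts <- c("WT", "het", "A-KO", "B-KO")
    if (!all(gts %in% names(thresholds)))
      stop_config("thresholds must be named WT, het, A-KO, B-KO")
    thresholds <- thresholds[gts]
    if (is.unsorted(thresholds))
      stop_config("thresholds must be nondecreasing WT <= het <= A-KO <= B-KO")

    mid <- tss_pos + round(runif(n, -8000, 8000))
    width <- round(runif(n, 200, 600))
    start <- mid - width %/% 2
    end <- start + width

    retained <- vapply(gts, function(g) height >= thresholds[[g]], logical(n))
    truth <- data.frame(peak_id = sprintf("peak%05d", seq_len(n)),
                        gene_id = gene_id, height = height,
                        in_wt = retained[, "WT"], in_het = retained[, "het"],
                        in_ako = retained[, "A-KO"],
                        in_bko = retained[, "B-KO"],
                        stringsAsFactors = FALSE)
    peaks <- lapply(gts, function(g) {
      keep <- retained[, g]
      peak_set(chrom = chrom[keep], start = start[keep], end = end[keep],
               height = height[keep],
               # synthetic peaks model already-called peaks: enrichment and
               # p-value are tied to height so all pass the calling filter
               fold_enrichment = 3 + height[keep] / 4,
               pvalue = 10^(-5 - height[keep] / 10),
               name = truth$peak_id[keep], genotype = g)
    })
    names(peaks) <- gts
    list(peaks = peaks, tss = tss, truth = truth, thresholds = thresholds)
  })
}

#' Generate a synthetic MFI table across the Stat5 allele series
#'
#' Models total-STAT5 flow cytometry mean fluorescence intensity as
#' proportional to the summed per-allele protein contributions:
#' `MFI = baseline_mfi * (a_alleles * unit_a + b_alleles * unit_b)` for the
#' five informative genotypes (WT 2A+2B, three-allele A- and B-deficient,
#' one-allele A- and B-deficient).
#'
#' @param config a [simulation_config()] (unused randomness; kept for a
#'   uniform generator interface).
#' @param unit_a,unit_b nonnegative per-allele MFI contributions of the A
#'   and B paralog.
#' @param baseline_mfi positive scale factor.
#' @return A data frame with columns `genotype`, `a_alleles`, `b_alleles`,
#'   `mfi`.
#' @export
generate_mfi <- function(config, unit_a = 1, unit_b = 2, baseline_mfi = 100) {
  if (unit_a < 0 || unit_b < 0)
    stop_config("per-allele unit contributions must be nonnegative")
  if (baseline_mfi <= 0)
    stop_config("baseline_mfi must be positive")
  g <- data.frame(
    genotype = c("WT", "A-def-3allele", "B-def-3allele",
                 "A-def-1allele", "B-def-1allele"),
    a_alleles = c(2, 1, 2, 0, 1),
    b_alleles = c(2, 2, 1, 1, 0),
    stringsAsFactors = FALSE)
  g$mfi <- baseline_mfi * (g$a_alleles * unit_a + g$b_alleles * unit_b)
  if (any(g$mfi <= 0))
    stop_config("unit contributions yield nonpositive MFI for some genotype")
  g
}

#' Write synthetic ground truth as JSON
#'
#' @param truth a truth data frame from [generate_expression()] or
#'   [generate_peaks()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
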