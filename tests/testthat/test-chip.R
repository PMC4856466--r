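test_that("peak calling filter applies strict thresholds", {
  # fe = 3.0 exactly fails the strict > 3 rule even with a tiny p
  p1 <- peak_set("chr1", 0, 100, height = 5, fold_enrichment = 3.0,
                 pvalue = 1e-6)
  expect_equal(nrow(filter_called_peaks(p1)), 0L)
  p2 <- peak_set("chr1", 0, 100, height = 5, fold_enrichment = 10,
                 pvalue = 4e-5)
  expect_equal(nrow(filter_called_peaks(p2)), 1L)

  # 6 peaks: 2 fail enrichment, 2 fail p, with 1 failing both -> 3 survive
  p6 <- peak_set("chr1", (0:5) * 1000, (0:5) * 1000 + 100,
                 height = rep(5, 6),
                 fold_enrichment = c(2, 2.5, 10, 10, 8, 9),
                 pvalue = c(1e-6, 1e-4, 1e-4, 1e-6, 1e-6, 1e-6))
  expect_equal(nrow(filter_called_peaks(p6)), 3L)

  p6$fold_enrichment[1] <- NA
  expect_error(filter_called_peaks(p6), class = "paralogdose_data_error")
})

test_that("peak overlap respects half-open boundaries", {
  x <- peak_set("chr1", 100, 200, height = 1)
  y <- peak_set("chr1", 150, 250, height = 1)
  expect_equal(overlap_peaks(x, y)$shared, 1L)
  z <- peak_set("chr1", 200, 300, height = 1)   # abuts, no shared base
  expect_equal(overlap_peaks(x, z)$shared, 0L)
  w <- peak_set("chr2", 100, 200, height = 1)   # different chromosome
  expect_equal(overlap_peaks(x, w)$shared, 0L)
})

test_that("greedy matching equals brute-force maximum matching", {
  set.seed(101)
  for (i in 1:40) {
    a <- random_peak_set(sample(5:120, 1))
    b <- random_peak_set(sample(5:120, 1))
    res <- overlap_peaks(a, b)
    expect_equal(res$shared, oracle_max_matching(a, b))
    # symmetry of the shared count
    expect_equal(overlap_peaks(b, a)$shared, res$shared)
    # one-to-one: no peak used twice
    expect_false(anyDuplicated(res$pairs$x) > 0)
    expect_false(anyDuplicated(res$pairs$y) > 0)
  }
})

tss_fixture <- function() {
  data.frame(gene_id = c("gA", "gB", "gC"),
             chrom = c("chr1", "chr1", "chr2"),
             strand = c("+", "-", "+"),
             tss = c(10000, 60000, 5000),
             stringsAsFactors = FALSE)
}

test_that("TSS localization bins signed strand-aware distances", {
  tss <- tss_fixture()
  # midpoint exactly at gA's TSS -> distance 0 -> bin [0, 10kb)
  at_tss <- peak_set("chr1", 9900, 10100, height = 1)
  loc <- tss_localization(at_tss, tss)
  expect_equal(loc$distances$distance, 0)
  expect_equal(loc$histogram$bin_left, 0)
  expect_equal(loc$histogram$pct, 100)

  # midpoint 25 kb downstream of gC (the only TSS there) -> [20kb, 30kb)
  far <- peak_set("chr2", 29900, 30100, height = 1)
  lf <- tss_localization(far, tss)
  expect_equal(lf$distances$distance, 25000)
  expect_equal(lf$histogram$bin_left, 20000)

  # minus-strand gene: a peak 3 kb right of gB's TSS is 3 kb upstream
  minus <- peak_set("chr1", 62900, 63100, height = 1)
  lm <- tss_localization(minus, tss)
  expect_equal(lm$distances$gene_id, "gB")
  expect_equal(lm$distances$distance, -3000)

  expect_error(tss_localization(at_tss, tss[0, ]),
               class = "paralogdose_data_error")
})

test_that("nearest-TSS assignment matches the linear-scan oracle", {
  set.seed(202)
  for (i in 1:25) {
    n_tss <- sample(3:40, 1)
    tss <- data.frame(gene_id = sprintf("g%03d", seq_len(n_tss)),
                      chrom = sample(c("chr1", "chr2"), n_tss,
                                     replace = TRUE),
                      strand = sample(c("+", "-"), n_tss, replace = TRUE),
                      tss = sample.int(100000, n_tss),
                      stringsAsFactors = FALSE)
    peaks <- random_peak_set(sample(5:60, 1), span = 100000)
    loc <- tss_localization(peaks, tss)
    expect_equal(loc$distances$gene_id,
                 oracle_nearest_tss(peaks, tss))
    expect_equal(sum(loc$histogram$pct), 100, tolerance = 1e-9)
  }
})

test_that("peak-to-gene assignment uses a closed +/- window", {
  tss <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    strand = "+", tss = c(50000, 80000))
  # midpoint 40000: exactly 10 kb from g1 -> assigned (closed boundary)
  pk <- peak_set("chr1", 39950, 40050, height = 2)
  asn <- assign_peaks_to_genes(pk, tss, window = 10000)
  expect_equal(asn$gene_id, "g1")
  # one bp beyond the window -> not assigned
  pk2 <- peak_set("chr1", 39949, 40049, height = 2)
  expect_equal(nrow(assign_peaks_to_genes(pk2, tss, window = 10000)), 0L)
  # a peak between two close genes serves both
  tss2 <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     strand = "+", tss = c(50000, 55000))
  mid <- peak_set("chr1", 52450, 52550, height = 2)
  expect_setequal(assign_peaks_to_genes(mid, tss2)$gene_id, c("g1", "g2"))
  expect_error(assign_peaks_to_genes(pk, tss, window = -1),
               class = "paralogdose_config_error")
})

test_that("synthetic peak-to-gene links match the generator's truth", {
  cfg <- simulation_config(n_genes = 200, seed = 55)
  pk <- generate_peaks(cfg, thresholds = c(WT = 0, het = 0, `A-KO` = 0,
                                           `B-KO` = 0))
  asn <- assign_peaks_to_genes(pk$peaks$WT, pk$tss)
  linked <- setNames(asn$gene_id, asn$name)
  expect_equal(unname(linked[pk$truth$peak_id]), pk$truth$gene_id)
})

test_that("occupancy hierarchy nests genotype retention correctly", {
  tss <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                    strand = "+",
                    tss = c(10000, 50000, 90000, 130000, 170000))
  mk <- function(genes) {
    pos <- tss$tss[match(genes, tss$gene_id)]
    peak_set("chr1", pos - 100, pos + 100, height = 5,
             fold_enrichment = 10, pvalue = 1e-6)
  }
  hier <- occupancy_hierarchy(
    wt = mk(c("g1", "g2", "g3", "g4")),
    het = mk(c("g2", "g3", "g4")),
    ako = mk(c("g3", "g4", "g5")),    # g5 bound in KO but not WT
    bko = mk("g4"),
    tss = tss)
  grp <- setNames(hier$group, hier$gene_id)
  expect_equal(grp[["g1"]], 1L)   # WT only
  expect_equal(grp[["g2"]], 2L)   # WT + het
  expect_equal(grp[["g3"]], 3L)   # WT + het + A-KO
  expect_equal(grp[["g4"]], 4L)   # all four genotypes
  expect_equal(attr(hier, "non_wt_genes"), "g5")
  # groups partition the WT-bound genes
  expect_equal(sort(hier$gene_id), sprintf("g%d", 1:4))
})

test_that("occupancy-vs-expression aggregates height and variance", {
  tss <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                    tss = c(10000, 50000))
  wt <- peak_set("chr1", c(9900, 49900), c(10100, 50100),
                 height = c(10, 30), fold_enrichment = 10, pvalue = 1e-6)
  hier <- structure(
    data.frame(gene_id = c("g1", "g2"), group = c(2L, 2L), in_wt = TRUE,
               in_het = TRUE, in_ako = FALSE, in_bko = FALSE),
    class = c("occupancy_hierarchy", "data.frame"))
  de <- toy_de(c("g1", "g2"), log2fc = c(1, 1), pvalue = c(0.1, 0.001))
  occ <- occupancy_vs_expression(hier, wt, tss, de)
  row2 <- occ[occ$group == 2, ]
  expect_equal(row2$n, 2L)
  expect_equal(row2$mean_wt_height, 20)
  expect_equal(row2$mean_neglog10_p, 2)  # mean of 1 and 3
  # single-gene group sanity: height 30, p 0.001 -> -log10 p = 3
  hier1 <- hier[2, , drop = FALSE]
  occ1 <- occupancy_vs_expression(hier1, wt, tss, de)
  expect_equal(occ1$mean_wt_height[occ1$group == 2], 30)
  expect_equal(occ1$mean_neglog10_p[occ1$group == 2], 3)
  # empty groups are flagged with NA means, not silent zeros
  expect_true(all(is.na(occ$mean_wt_height[occ$n == 0])))
  # genes without a p-value are dropped and counted
  de_partial <- de[1, ]
  occ2 <- suppressMessages(
    occupancy_vs_expression(hier, wt, tss, de_partial))
  expect_equal(attr(occ2, "dropped"), 1L)
  expect_equal(sum(occ2$n), 1L)
})

test_that("height-thresholded synthetic peaks order the genotype counts", {
  cfg <- simulation_config(n_genes = 500, seed = 91)
  pk <- generate_peaks(cfg)
  counts <- vapply(pk$peaks, nrow, integer(1))
  expect_true(all(diff(counts) <= 0))  # WT >= het >= A-KO >= B-KO
  # genes' hierarchy groups equal the threshold bracket of their peak
  hier <- occupancy_hierarchy(pk$peaks$WT, pk$peaks$het, pk$peaks$`A-KO`,
                              pk$peaks$`B-KO`, pk$tss)
  tr <- pk$truth
  bracket <- 1L + (tr$height >= pk$thresholds[["het"]]) +
    (tr$height >= pk$thresholds[["A-KO"]]) +
    (tr$height >= pk$thresholds[["B-KO"]])
  expect_equal(setNames(hier$group, hier$gene_id)[tr$gene_id],
               setNames(bracket, tr$gene_id))
})
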