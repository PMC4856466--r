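#' Construct a ChIP-seq peak set
#'
#' Peaks are BED-style 0-based half-open intervals carrying a height (tag
#' count), a fold enrichment over background and a calling p-value. The
#' peak's position, where a single coordinate is needed, is the interval
#' midpoint `floor((start + end) / 2)`.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param height positive peak heights (tag counts).
#' @param fold_enrichment fold enrichment over background.
#' @param pvalue peak-calling p-values.
#' @param name optional peak identifiers.
#' @param genotype optional genotype label, stored as an attribute.
#' @return A `peak_set` data frame.
#' @export
peak_set <- function(chrom, start, end, height, fold_enrichment = NA_real_,
                     pvalue = NA_real_, name = NULL, genotype = NA_character_) {
  n <- length(start)
  if (any(start >= end)) stop_data("peak intervals require start < end")
  if (any(height <= 0)) stop_data("peak heights must be positive")
  structure(
    data.frame(chrom = rep_len(as.character(chrom), n),
               start = as.integer(start), end = as.integer(end),
               name = name %||% sprintf("peak%05d", seq_len(n)),
               height = rep_len(height, n),
               fold_enrichment = rep_len(fold_enrichment, n),
               pvalue = rep_len(pvalue, n),
               row.names = NULL, stringsAsFactors = FALSE),
    genotype = genotype,
    class = c("peak_set", "data.frame"))
}

peak_midpoint <- function(peaks) (peaks$start + peaks$end) %/% 2L

# 0-based half-open -> 1-based closed GRanges
peaks_to_granges <- function(peaks) {
  if (any(peaks$start >= peaks$end)) stop_data("malformed peak intervals")
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Apply the peak-calling retention thresholds
#'
#' Keeps peaks with fold enrichment strictly above `min_fold` and p-value
#' strictly below `max_p` (defaults: > 3-fold over background, p < 5e-5).
#'
#' @param peaks a [peak_set()] with `fold_enrichment` and `pvalue` set.
#' @param min_fold,max_p retention thresholds.
#' @return The filtered `peak_set`.
#' @export
filter_called_peaks <- function(peaks, min_fold = 3, max_p = 5e-5) {
  if (!all(c("fold_enrichment", "pvalue") %in% names(peaks)))
    stop_data("peaks must carry fold_enrichment and pvalue columns")
  if (anyNA(peaks$fold_enrichment) || anyNA(peaks$pvalue))
    stop_data("fold_enrichment / pvalue contain missing values")
  keep <- peaks$fold_enrichment > min_fold & peaks$pvalue < max_p
  peaks[keep, , drop = FALSE]
}

#' Match overlapping peaks between two sets
#'
#' Two peaks overlap when they share a chromosome and intersect in at
#' least 1 bp under half-open coordinates. Each peak is matched at most
#' once; chained overlaps are resolved greedily by position (peaks are
#' processed in order of their right end and matched to the unmatched
#' overlapping partner ending first), which yields a maximum one-to-one
#' matching for interval overlap graphs. The shared count is therefore
#' symmetric in the two arguments.
#'
#' @param set_x,set_y [peak_set()]s.
#' @return A list with `pairs` (data frame of matched row indices `x`,
#'   `y`) and `shared` (the matched-pair count).
#' @export
overlap_peaks <- function(set_x, set_y) {
  # disjoint chromosome sets are a legitimate no-overlap case, not a
  # seqlevel mismatch worth warning about
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(peaks_to_granges(set_x),
                                peaks_to_granges(set_y)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh) == 0)
    return(list(pairs = data.frame(x = integer(), y = integer()),
                shared = 0L))
  adj <- split(sh, qh)
  x_order <- order(set_x$end[as.integer(names(adj))])
  y_end <- set_y$end
  matched_y <- logical(nrow(set_y))
  px <- integer(0); py <- integer(0)
  for (i in x_order) {
    cand <- adj[[i]][!matched_y[adj[[i]]]]
    if (length(cand) == 0) next
    pick <- cand[which.min(y_end[cand])]
    matched_y[pick] <- TRUE
    px <- c(px, as.integer(names(adj))[i])
    py <- c(py, pick)
  }
  ord <- order(px)
  list(pairs = data.frame(x = px[ord], y = py[ord]),
       shared = length(px))
}

#' Pairwise shared-peak table across genotypes
#'
#' Circos-ready long table of shared-peak counts between every ordered
#' pair of peak sets (or, with `wt_only = TRUE`, only pairs involving the
#' first set, conventionally WT).
#'
#' @param sets named list of [peak_set()]s.
#' @param wt_only restrict to pairs involving the first set.
#' @return Data frame with `group_x`, `group_y`, `shared`.
#' @export
peak_overlap_table <- function(sets, wt_only = FALSE) {
  nm <- names(sets)
  combos <- utils::combn(nm, 2, simplify = FALSE)
  if (wt_only)
    combos <- Filter(function(p) nm[1] %in% p, combos)
  do.call(rbind, lapply(combos, function(p) {
    data.frame(group_x = p[1], group_y = p[2],
               shared = overlap_peaks(sets[[p[1]]], sets[[p[2]]])$shared,
               stringsAsFactors = FALSE)
  }))
}

# Nearest TSS (by absolute midpoint distance) for each peak; ties go to the
# smaller genomic position, then the first gene id at that position.
# Deterministic by construction; peaks on chromosomes absent from the
# annotation are flagged with NA.
nearest_tss <- function(peaks, tss) {
  if (nrow(tss) == 0) stop_data("empty TSS annotation")
  mid <- peak_midpoint(peaks)
  idx <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    rows <- which(tss$chrom == ch)
    if (length(rows) == 0) next
    rows <- rows[order(tss$tss[rows], tss$gene_id[rows])]
    pos <- tss$tss[rows]
    pk <- which(peaks$chrom == ch)
    lo <- findInterval(mid[pk], pos)
    lo_i <- pmax(lo, 1L)
    hi_i <- pmin(lo + 1L, length(pos))
    d_lo <- abs(mid[pk] - pos[lo_i])
    d_hi <- abs(mid[pk] - pos[hi_i])
    use_lo <- lo >= 1 & (lo >= length(pos) | d_lo <= d_hi)
    idx[pk] <- rows[ifelse(use_lo, lo_i, hi_i)]
  }
  idx
}

#' Peak localization relative to transcription start sites
#'
#' For each peak, the signed distance from the peak midpoint to the
#' nearest TSS: positive downstream and negative upstream of the gene
#' (i.e. the sign follows gene strand). Distances are binned into 10 kb
#' intervals and reported as percentages of peaks per bin (summing
#' to 100).
#'
#' @param peaks a [peak_set()].
#' @param tss annotation data frame: `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based position).
#' @param binwidth bin width in bp (default 10000).
#' @return A `tss_localization` list: `distances` (per-peak data frame
#'   with nearest gene and signed distance), `histogram` (`bin_left`,
#'   `bin_right`, `count`, `pct`), `n` and `dropped` (peaks on
#'   chromosomes absent from the annotation).
#' @export
tss_localization <- function(peaks, tss, binwidth = 10000) {
  if (nrow(tss) == 0) stop_data("empty TSS annotation")
  idx <- nearest_tss(peaks, tss)
  dropped <- sum(is.na(idx))
  if (dropped)
    warning(sprintf("%d peak(s) on chromosomes absent from annotation",
                    dropped))
  keep <- !is.na(idx)
  if (!any(keep)) stop_data("no peak lies on an annotated chromosome")
  mid <- peak_midpoint(peaks)[keep]
  g <- tss[idx[keep], ]
  dist <- (mid - g$tss) * ifelse(g$strand == "+", 1L, -1L)
  bin <- floor(dist / binwidth)
  tab <- table(bin)
  lefts <- as.integer(names(tab))
  structure(
    list(distances = data.frame(name = peaks$name[keep],
                                gene_id = g$gene_id, distance = dist,
                                stringsAsFactors = FALSE),
         histogram = data.frame(bin_left = lefts * binwidth,
                                bin_right = (lefts + 1) * binwidth,
                                count = as.integer(tab),
                                pct = 100 * as.integer(tab) / sum(tab)),
         n = sum(keep), dropped = dropped),
    class = "tss_localization")
}

#' Assign peaks to genes within a TSS window
#'
#' A peak is assigned to every gene whose TSS lies within `window` bp of
#' the peak midpoint, boundary included. A peak may serve several genes
#' and a gene may collect several peaks.
#'
#' @param peaks a [peak_set()].
#' @param tss annotation data frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param window half-width of the assignment window in bp (default
#'   10000, i.e. +/- 10 kb).
#' @return Data frame with one row per (gene, peak) link: `gene_id`,
#'   `peak` (row index into `peaks`), `name`, `height`, `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, tss, window = 10000) {
  if (window <= 0) stop_config("window must be positive")
  if (nrow(peaks) == 0)
    return(data.frame(gene_id = character(), peak = integer(),
                      name = character(), height = numeric(),
                      distance = integer(), stringsAsFactors = FALSE))
  mid <- peak_midpoint(peaks)
  win <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(mid - window + 1L, mid + window + 1L))
  pts <- GenomicRanges::GRanges(tss$chrom,
                                IRanges::IRanges(tss$tss + 1L, tss$tss + 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win, pts))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(gene_id = tss$gene_id[si], peak = qi,
                    name = peaks$name[qi], height = peaks$height[qi],
                    distance = mid[qi] - tss$tss[si],
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$peak), , drop = FALSE]
}

#' Gene-level occupancy hierarchy across the genotype series
#'
#' Labels every WT-bound gene (a gene with at least one assigned WT peak)
#' by the deepest nested genotype group in which it retains binding:
#' group 1 = WT only, group 2 = WT + het, group 3 = WT + het + A-KO,
#' group 4 = all four genotypes. Nesting is strict: a gene bound in A-KO
#' but not in het stays in group 1. Genes bound in a knockout but not in
#' WT are reported in the `non_wt_genes` attribute, not grouped.
#'
#' @param wt,het,ako,bko [peak_set()]s for the four genotypes (already
#'   filtered).
#' @param tss annotation data frame.
#' @param window TSS assignment half-width in bp.
#' @return An `occupancy_hierarchy` data frame: `gene_id`, `group`
#'   (1–4), and logical `in_wt`, `in_het`, `in_ako`, `in_bko`.
#' @export
occupancy_hierarchy <- function(wt, het, ako, bko, tss, window = 10000) {
  genes_of <- function(p) unique(assign_peaks_to_genes(p, tss, window)$gene_id)
  g_wt <- genes_of(wt); g_het <- genes_of(het)
  g_ako <- genes_of(ako); g_bko <- genes_of(bko)
  in_het <- g_wt %in% g_het
  in_ako <- g_wt %in% g_ako
  in_bko <- g_wt %in% g_bko
  group <- 1L + (in_het) + (in_het & in_ako) + (in_het & in_ako & in_bko)
  structure(
    data.frame(gene_id = g_wt, group = as.integer(group),
               in_wt = TRUE, in_het = in_het, in_ako = in_ako,
               in_bko = in_bko, stringsAsFactors = FALSE),
    non_wt_genes = setdiff(unique(c(g_het, g_ako, g_bko)), g_wt),
    class = c("occupancy_hierarchy", "data.frame"))
}

#' Relate binding-site occupancy groups to expression change
#'
#' For each occupancy group: the number of member genes, the mean WT peak
#' height (each gene first summarized as the mean height of its assigned
#' WT peaks, then averaged over genes) and the mean expression variance
#' (-log10 p from the supplied DE contrast). Genes without a p-value are
#' dropped and their count reported; empty groups keep `n = 0` with `NA`
#' means.
#'
#' @param hierarchy an [occupancy_hierarchy()] result.
#' @param wt_peaks the WT [peak_set()].
#' @param tss annotation data frame.
#' @param de a `de_table` providing p-values per gene.
#' @param window TSS assignment half-width in bp.
#' @return An `occupancy_summary` data frame: `group`, `n`,
#'   `mean_wt_height`, `mean_neglog10_p`; attribute `dropped` counts
#'   grouped genes lacking a p-value.
#' @export
occupancy_vs_expression <- function(hierarchy, wt_peaks, tss, de,
                                    window = 10000) {
  asn <- assign_peaks_to_genes(wt_peaks, tss, window)
  gene_height <- tapply(asn$height, asn$gene_id, mean)
  h <- hierarchy
  h$height <- as.numeric(gene_height[h$gene_id])
  h$pvalue <- de$pvalue[match(h$gene_id, de$gene_id)]
  dropped <- sum(is.na(h$pvalue))
  if (dropped)
    message(dropped, " grouped gene(s) lack a DE p-value and were dropped")
  h <- h[!is.na(h$pvalue), , drop = FALSE]
  out <- do.call(rbind, lapply(1:4, function(g) {
    rows <- h[h$group == g, , drop = FALSE]
    data.frame(group = g, n = nrow(rows),
               mean_wt_height = if (nrow(rows)) mean(rows$height) else NA_real_,
               mean_neglog10_p = if (nrow(rows)) mean(-log10(rows$pvalue))
                                 else NA_real_)
  }))
  structure(out, dropped = dropped,
            class = c("occupancy_summary", "data.frame"))
}

#' Read / write peak sets as extended BED
#'
#' Nine tab-separated columns without header: chrom, start, end, name,
#' score, strand, height, fold_enrichment, pvalue (coordinates 0-based
#' half-open).
#'
#' @param peaks a [peak_set()].
#' @param path file path.
#' @param genotype genotype label to attach on read.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   0L, ".", peaks$height, peaks$fold_enrichment,
                   peaks$pvalue)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path, genotype = NA_character_) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 9)
    stop_data("extended BED needs 9 columns (6 BED + height, fold, p)")
  peak_set(chrom = df[[1]], start = df[[2]], end = df[[3]], name = df[[4]],
           height = df[[7]], fold_enrichment = df[[8]], pvalue = df[[9]],
           genotype = genotype)
}

#' Write a TSS annotation table as TSV
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tss` (0-based).
#'
#' @param tss annotation data frame.
#' @param path file path.
#' @export
write_tss_tsv <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_tsv
#' @export
read_tss_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data(paste0("TSS TSV missing columns: ",
                     paste(miss, collapse = ", ")))
  df
}
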