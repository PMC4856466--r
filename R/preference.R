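#' Paralog score for one knockout-vs-WT contrast
#'
#' The absolute fold change multiplied by the higher of the two group-mean
#' RPKMs (WT or KO). Taking the absolute fold change drops the up/down
#' distinction; the RPKM multiplier up-weights abundant transcripts.
#'
#' @param abs_fc absolute (linear) fold change, >= 1.
#' @param rpkm_wt,rpkm_ko positive offset-added group-mean RPKMs.
#' @return `abs_fc * pmax(rpkm_wt, rpkm_ko)` (vectorized).
#' @export
paralog_score <- function(abs_fc, rpkm_wt, rpkm_ko) {
  if (any(abs_fc < 1))
    stop_data("absolute fold change must be >= 1")
  if (any(rpkm_wt <= 0) || any(rpkm_ko <= 0))
    stop_data("RPKM values must be positive (offset-added)")
  abs_fc * pmax(rpkm_wt, rpkm_ko)
}

#' Log2 paralog preference from a pair of paralog scores
#'
#' `log2(score_b / score_a)`: positive values mark transcripts more
#' impacted by loss of the B paralog, negative values by loss of A.
#'
#' @param score_b,score_a positive paralog scores from the B-KO and A-KO
#'   contrasts.
#' @return Numeric preference value(s).
#' @export
preference_score <- function(score_b, score_a) {
  if (any(score_b <= 0) || any(score_a <= 0))
    stop_data("paralog scores must be positive")
  log2(score_b / score_a)
}

#' Per-gene preference records from two knockout contrasts
#'
#' Builds paralog scores for both contrasts for every pooled gene —
#' regardless of which contrast triggered inclusion — and the log2
#' preference. Both DE tables must be oriented KO over WT (`mean_g1` = KO,
#' `mean_g2` = WT).
#'
#' @param de_a,de_b `de_table`s for the A-KO-vs-WT and B-KO-vs-WT
#'   contrasts, same gene universe.
#' @param genes genes to score; defaults to [pool_regulated()] of the two
#'   tables.
#' @return A `preference_table` data frame: `gene_id`, `score_a`,
#'   `score_b`, `preference`.
#' @export
preference_table <- function(de_a, de_b,
                             genes = pool_regulated(de_a, de_b)) {
  if (!setequal(de_a$gene_id, de_b$gene_id))
    stop_data("DE tables have mismatched gene universes")
  if (length(genes) == 0) stop_data("no genes to score")
  missing <- setdiff(genes, de_a$gene_id)
  if (length(missing))
    stop_data(paste0("genes absent from DE tables: ",
                     paste(head(missing, 5), collapse = ", ")))
  ia <- match(genes, de_a$gene_id)
  ib <- match(genes, de_b$gene_id)
  score_a <- paralog_score(de_a$abs_fc[ia], de_a$mean_g2[ia],
                           de_a$mean_g1[ia])
  score_b <- paralog_score(de_b$abs_fc[ib], de_b$mean_g2[ib],
                           de_b$mean_g1[ib])
  structure(
    data.frame(gene_id = genes, score_a = score_a, score_b = score_b,
               preference = preference_score(score_b, score_a),
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("preference_table", "data.frame"))
}

preference_values <- function(x) {
  if (inherits(x, "preference_table") || is.data.frame(x)) x$preference
  else as.numeric(x)
}

#' Bin preference values into the 12-bin histogram
#'
#' Bin 1 collects values below -5; bins 2–11 are the left-closed unit
#' intervals \[-5,-4), ..., \[4,5); bin 12 collects values of 5 and above.
#' The median is computed on the raw (unbinned) preferences with the usual
#' midpoint convention for even n.
#'
#' @param x a `preference_table` or numeric vector of preference values.
#' @return A `preference_histogram`: list with `counts` (length 12),
#'   `edges` (length 13, infinite outer edges), `median` and `n`.
#' @export
bin_preferences <- function(x) {
  p <- preference_values(x)
  if (length(p) == 0) stop_data("no preference values to bin")
  if (any(!is.finite(p))) stop_data("preference values must be finite")
  counts <- tabulate(findInterval(p, seq(-5, 5)) + 1L, nbins = 12L)
  structure(list(counts = counts, edges = c(-Inf, seq(-5, 5), Inf),
                 median = median(p), n = length(p)),
            class = "preference_histogram")
}

#' @export
print.preference_histogram <- function(x, ...) {
  cat("Paralog preference histogram (", x$n, " genes)\n", sep = "")
  lab <- c("(-Inf,-5)", paste0("[", seq(-5, 4), ",", seq(-4, 5), ")"),
           "[5,Inf)")
  for (i in seq_len(12))
    cat(sprintf("  bin %2d %-10s %d\n", i, lab[i], x$counts[i]))
  cat(sprintf("  median preference: %.3f\n", x$median))
  invisible(x)
}

#' Project a gene set onto the preference scale
#'
#' Restricts the preference histogram and median to a gene subset (e.g.
#' transcripts mobilized by ectopic expression of one paralog). Genes not
#' present among the records are reported by warning, never silently
#' dropped.
#'
#' @param records a `preference_table`.
#' @param gene_list character vector of gene ids.
#' @return A `preference_histogram` over the intersection.
#' @export
project_gene_set <- function(records, gene_list) {
  found <- intersect(gene_list, records$gene_id)
  if (length(found) == 0)
    stop_data("gene list has no overlap with preference records")
  missing <- setdiff(gene_list, records$gene_id)
  if (length(missing))
    warning(sprintf("%d gene(s) not in preference records: %s",
                    length(missing),
                    paste(head(missing, 5), collapse = ", ")))
  bin_preferences(records[records$gene_id %in% found, ])
}

#' Write preference records and histograms
#'
#' @param records a `preference_table`.
#' @param hist a `preference_histogram`.
#' @param path file path.
#' @export
write_preference_tsv <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_preference_tsv
#' @export
write_histogram_json <- function(hist, path) {
  jsonlite::write_json(unclass(hist), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
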