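#' Classify regulated genes as pan or paralog-specific
#'
#' Applies the fold-change rule chain to three contrasts (A-KO vs WT,
#' B-KO vs WT, A-KO vs B-KO) over the pooled regulated gene list:
#'
#' 1. genes regulated in both KO-vs-WT contrasts with opposite log2
#'    fold-change signs are excluded (`excluded_opposite`);
#' 2. a candidate must differ between the two knockouts directly
#'    (absolute FC > `fc`, p < `p_cutoff` in the KO-vs-KO contrast);
#' 3. a candidate is `a_specific` when regulated in A-KO vs WT
#'    (absFC > `fc`, p < `p_cutoff`) but essentially unchanged in B-KO vs
#'    WT (absFC < `fc_ceiling`, no p condition), and symmetrically for
#'    `b_specific`;
#' 4. genes regulated in both KO-vs-WT contrasts (same direction) are
#'    `pan`;
#' 5. everything else is `unclassified`.
#'
#' The exclusion and specific rules cannot both fire (a specific call
#' requires the other contrast below `fc_ceiling`; exclusion requires it
#' above `fc`), so every gene receives exactly one label.
#'
#' @param de_a_wt,de_b_wt,de_a_b `de_table`s over the same gene universe:
#'   the two KO-vs-WT contrasts and the direct KO-vs-KO contrast.
#' @param genes genes to classify; defaults to
#'   `pool_regulated(de_a_wt, de_b_wt)`.
#' @param fc regulation fold-change threshold (default 1.5).
#' @param fc_ceiling "unchanged in the other knockout" ceiling
#'   (default 1.2).
#' @param p_cutoff significance threshold (default 0.05).
#' @return A `specificity_calls` data frame: `gene_id`, `label` (factor
#'   over pan / a_specific / b_specific / excluded_opposite /
#'   unclassified) and the supporting fold changes and p-values.
#' @export
classify_specificity <- function(de_a_wt, de_b_wt, de_a_b,
                                 genes = pool_regulated(de_a_wt, de_b_wt),
                                 fc = 1.5, fc_ceiling = 1.2,
                                 p_cutoff = 0.05) {
  if (!setequal(de_a_wt$gene_id, de_b_wt$gene_id) ||
      !setequal(de_a_wt$gene_id, de_a_b$gene_id))
    stop_data("DE tables have mismatched gene universes")
  missing <- setdiff(genes, de_a_wt$gene_id)
  if (length(missing))
    stop_data(paste0("genes absent from DE tables: ",
                     paste(head(missing, 5), collapse = ", ")))
  ia <- match(genes, de_a_wt$gene_id)
  ib <- match(genes, de_b_wt$gene_id)
  iab <- match(genes, de_a_b$gene_id)

  afc_a <- de_a_wt$abs_fc[ia]; p_a <- de_a_wt$pvalue[ia]
  l2_a <- de_a_wt$log2fc[ia]
  afc_b <- de_b_wt$abs_fc[ib]; p_b <- de_b_wt$pvalue[ib]
  l2_b <- de_b_wt$log2fc[ib]
  afc_ab <- de_a_b$abs_fc[iab]; p_ab <- de_a_b$pvalue[iab]

  reg_a <- afc_a > fc & p_a < p_cutoff
  reg_b <- afc_b > fc & p_b < p_cutoff
  candidate <- afc_ab > fc & p_ab < p_cutoff
  opposite <- reg_a & reg_b & (sign(l2_a) * sign(l2_b) < 0)
  a_spec <- candidate & reg_a & afc_b < fc_ceiling
  b_spec <- candidate & reg_b & afc_a < fc_ceiling

  label <- rep("unclassified", length(genes))
  label[reg_a & reg_b] <- "pan"
  label[a_spec] <- "a_specific"
  label[b_spec] <- "b_specific"
  label[opposite] <- "excluded_opposite"  # exclusion takes precedence

  structure(
    data.frame(gene_id = genes,
               label = factor(label, levels = specificity_levels()),
               absfc_a_wt = afc_a, p_a_wt = p_a,
               absfc_b_wt = afc_b, p_b_wt = p_b,
               absfc_a_b = afc_ab, p_a_b = p_ab,
               log2fc_a_wt = l2_a, log2fc_b_wt = l2_b,
               row.names = NULL, stringsAsFactors = FALSE),
    thresholds = c(fc = fc, fc_ceiling = fc_ceiling, p = p_cutoff),
    class = c("specificity_calls", "data.frame"))
}

specificity_levels <- function() {
  c("pan", "a_specific", "b_specific", "excluded_opposite", "unclassified")
}

#' Summarize specificity calls
#'
#' @param calls a `specificity_calls` data frame.
#' @return A `specificity_summary`: list with per-label `counts` and
#'   `fractions`, `n` and `fraction_specific`
#'   (`(a_specific + b_specific) / n`).
#' @export
summarize_specificity <- function(calls) {
  if (nrow(calls) == 0) stop_data("no specificity calls to summarize")
  counts <- table(calls$label)
  n <- nrow(calls)
  structure(
    list(counts = setNames(as.integer(counts), names(counts)),
         fractions = setNames(as.numeric(counts) / n, names(counts)),
         n = n,
         fraction_specific =
           sum(counts[c("a_specific", "b_specific")]) / n),
    class = "specificity_summary")
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat("Specificity calls over", x$n, "regulated genes\n")
  for (l in names(x$counts))
    cat(sprintf("  %-18s %5d  (%.1f%%)\n", l, x$counts[[l]],
                100 * x$fractions[[l]]))
  cat(sprintf("  paralog-specific fraction: %.1f%%\n",
              100 * x$fraction_specific))
  invisible(x)
}

#' Write specificity calls as TSV
#'
#' @param calls a `specificity_calls` data frame.
#' @param path file path.
#' @export
write_specificity_tsv <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
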