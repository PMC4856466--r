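#' Compute the small-offset normalization constant
#'
#' Fold changes of low-abundance transcripts are unstable, so a small
#' constant is added to every RPKM value before fold changes are taken. The
#' constant is the second quartile (median) of all entries in the dataset;
#' for transcriptome-scale RPKM matrices this typically lands around
#' 0.2–0.3, and a warning is raised when it falls outside that range.
#'
#' @param x an [expression_matrix()], not yet offset.
#' @return The offset (a positive scalar unless the matrix median is 0).
#' @export
compute_offset <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(x$offset))
    stop_config("matrix already has an offset applied")
  if (length(x$values) == 0) stop_data("empty expression matrix")
  off <- median(x$values)
  if (off < 0.2 || off > 0.3)
    warning(sprintf(
      "offset %.4g outside the 0.2-0.3 range typical of RPKM datasets", off))
  off
}

#' Add the offset to every RPKM value
#'
#' @param x an [expression_matrix()].
#' @param offset positive offset, by default from [compute_offset()].
#' @return The offset-added `expr_matrix` (with `offset` recorded).
#' @export
apply_offset <- function(x, offset = compute_offset(x)) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(x$offset))
    stop_config("offset already applied; refusing to apply twice")
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0)
    stop_config("offset must be a single positive number")
  x$values <- x$values + offset
  x$offset <- offset
  x
}

#' Collapse multiple fragments per gene to the most abundant one
#'
#' When quantification reports several fragments (isoform-level rows) for a
#' gene, only the most abundant — highest mean RPKM averaged across the
#' per-genotype means — is kept, under the gene's identifier. Ties are
#' broken by the lexicographically smallest fragment id.
#'
#' @param x an [expression_matrix()] whose rows are fragments.
#' @param map data frame with columns `fragment_id`, `gene_id` covering all
#'   fragments in `x`.
#' @return An `expr_matrix` with one row per gene.
#' @export
collapse_fragments <- function(x, map) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!all(c("fragment_id", "gene_id") %in% names(map)))
    stop_data("map must have fragment_id and gene_id columns")
  frags <- rownames(x$values)
  unmapped <- setdiff(frags, map$fragment_id)
  if (length(unmapped))
    stop_data(paste0("unmapped fragments: ",
                     paste(unmapped, collapse = ", ")))
  gm <- genotype_means(x)
  score <- rowMeans(gm)  # unweighted mean of the per-genotype means
  gene <- map$gene_id[match(frags, map$fragment_id)]
  ord <- order(gene, -score, frags)  # ties -> lexicographically smaller id
  keep <- ord[!duplicated(gene[ord])]
  keep <- sort(keep)  # preserve original row order
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  rownames(out$values) <- gene[keep]
  out
}

#' Drop transcripts below 1 RPKM in every genotype
#'
#' A gene is retained if at least one genotype's mean RPKM is >= 1. The
#' filter operates on raw (pre-offset) values so the threshold keeps its
#' meaning across datasets with different offsets.
#'
#' @param x an [expression_matrix()], not yet offset.
#' @param min_rpkm retention threshold on the genotype mean (default 1).
#' @return The filtered `expr_matrix`.
#' @export
filter_low_expression <- function(x, min_rpkm = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(x$offset))
    stop_config("low-expression filter must run on pre-offset values")
  keep <- apply(genotype_means(x) >= min_rpkm, 1, any)
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' Differential expression between two genotypes
#'
#' Per gene: the log2 fold change of offset-added group-mean RPKM
#' (`log2(mean_g1 / mean_g2)`), the linear absolute fold change
#' (`max/min >= 1`), and a p-value from a pooled-variance two-sample t test
#' on log2 values with a variance floor `s0` added to the pooled variance.
#' The floor guards the n = 2–3 replicate designs typical of these
#' experiments against near-zero variance estimates. A gene is flagged
#' `regulated` when absolute fold change > `fc` and p < `p_cutoff`.
#'
#' @param x an offset-added [expression_matrix()].
#' @param group1,group2 genotype labels; the fold change is group1 over
#'   group2 (conventionally KO over WT).
#' @param fc,p_cutoff regulation thresholds (defaults 1.5 and 0.05).
#' @param s0 variance floor on the log2 scale.
#' @return A `de_table` data frame: `gene_id`, `mean_g1`, `mean_g2`,
#'   `log2fc`, `abs_fc`, `pvalue`, `regulated`; attribute `contrast`.
#' @export
compute_de <- function(x, group1, group2, fc = 1.5, p_cutoff = 0.05,
                       s0 = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  i1 <- which(x$genotype == group1)
  i2 <- which(x$genotype == group2)
  if (length(i1) < 2 || length(i2) < 2)
    stop_data("each group needs at least 2 replicates")
  if (any(x$values[, c(i1, i2)] <= 0))
    stop_data("expression values must be positive (apply the offset first)")
  v1 <- x$values[, i1, drop = FALSE]
  v2 <- x$values[, i2, drop = FALSE]
  m1 <- rowMeans(v1)
  m2 <- rowMeans(v2)
  log2fc <- log2(m1 / m2)
  abs_fc <- 2^abs(log2fc)

  l1 <- log2(v1)
  l2 <- log2(v2)
  n1 <- length(i1); n2 <- length(i2)
  s2p <- ((n1 - 1) * apply(l1, 1, var) + (n2 - 1) * apply(l2, 1, var)) /
    (n1 + n2 - 2)
  tstat <- (rowMeans(l1) - rowMeans(l2)) /
    sqrt((s2p + s0) * (1 / n1 + 1 / n2))
  pvalue <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)

  out <- data.frame(gene_id = rownames(x$values),
                    mean_g1 = m1, mean_g2 = m2,
                    log2fc = log2fc, abs_fc = abs_fc, pvalue = pvalue,
                    regulated = abs_fc > fc & pvalue < p_cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, contrast = c(group1, group2),
            thresholds = c(fc = fc, p = p_cutoff),
            class = c("de_table", "data.frame"))
}

#' Pool genes regulated in either knockout contrast
#'
#' The union of regulated genes from the two knockout-vs-WT tables forms
#' the regulated gene list used by the preference scale. Order follows the
#' first table's gene order.
#'
#' @param de_a,de_b `de_table`s over the same gene universe.
#' @return Character vector of regulated gene ids.
#' @export
pool_regulated <- function(de_a, de_b) {
  if (!setequal(de_a$gene_id, de_b$gene_id) ||
      nrow(de_a) != nrow(de_b))
    stop_data("DE tables have mismatched gene universes")
  reg <- de_a$gene_id[de_a$regulated]
  reg_b <- de_b$gene_id[de_b$regulated]
  de_a$gene_id[de_a$gene_id %in% union(reg, reg_b)]
}

#' Read / write differential expression tables as TSV
#'
#' Columns: `gene_id`, `mean_g1`, `mean_g2`, `log2fc`, `abs_fc`, `pvalue`,
#' `regulated` (0/1). `read_de_tsv` also accepts precomputed tables from
#' external DE tools, provided the columns are present.
#'
#' @param de a `de_table`.
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  out <- as.data.frame(de)
  out$regulated <- as.integer(out$regulated)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "mean_g1", "mean_g2", "log2fc", "abs_fc",
            "pvalue", "regulated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data(paste0("DE TSV missing columns: ", paste(miss, collapse = ", ")))
  df$regulated <- as.logical(df$regulated)
  structure(df, class = c("de_table", "data.frame"))
}
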