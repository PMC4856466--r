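#' Construct an expression matrix with genotype metadata
#'
#' Container for a genes-by-samples RPKM matrix with a genotype label and a
#' replicate index per sample, plus a record of whether (and by how much) the
#' small-offset normalization has been applied.
#'
#' @param values numeric matrix of nonnegative RPKM values; rownames are gene
#'   (or fragment) identifiers, one column per sample.
#' @param genotype character vector of genotype labels, one per column,
#'   e.g. `"WT"`, `"A-KO"`, `"B-KO"`, `"het"`.
#' @param replicate optional integer replicate index per column; defaults to
#'   a running index within each genotype.
#' @param offset numeric offset already added to `values`, or `NULL` if none.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `genotype`, `replicate` and `offset`.
#' @export
expression_matrix <- function(values, genotype, replicate = NULL,
                              offset = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop_data("`values` must have gene identifiers as rownames")
  if (anyDuplicated(rownames(values)))
    stop_data("duplicate gene identifiers in expression matrix")
  if (length(genotype) != ncol(values))
    stop_data("`genotype` must have one label per sample column")
  if (any(values < 0))
    stop_data("RPKM values must be nonnegative")
  genotype <- as.character(genotype)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(genotype), genotype, FUN = seq_along)
  }
  if (is.null(colnames(values)))
    colnames(values) <- paste0(genotype, "_rep", replicate)
  structure(
    list(values = values, genotype = genotype,
         replicate = as.integer(replicate), offset = offset),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  tab <- table(x$genotype)
  cat("Genotypes:", paste(names(tab), "(n=", tab, ")", sep = "",
                          collapse = ", "), "\n")
  cat(if (is.null(x$offset)) "Offset: not applied\n"
      else sprintf("Offset: %.4g applied\n", x$offset))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Per-genotype mean expression
#'
#' Arithmetic mean of replicate RPKM values within each genotype.
#'
#' @param x an [expression_matrix()].
#' @return numeric matrix, genes by genotypes.
#' @export
genotype_means <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  gts <- unique(x$genotype)
  out <- vapply(gts, function(g) {
    rowMeans(x$values[, x$genotype == g, drop = FALSE])
  }, numeric(nrow(x$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(x$values), gts))
  out
}

#' Read / write expression matrices as TSV
#'
#' The on-disk format is one `gene_id` column followed by one column per
#' sample, with headers of the form `<genotype>_rep<k>` (e.g. `WT_rep1`,
#' `A-KO_rep2`).
#'
#' @param x an [expression_matrix()].
#' @param path file path.
#' @return `read_expression_tsv` returns an `expr_matrix`;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop_data("expression TSV must have a gene_id column")
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  samples <- colnames(m)
  if (!all(grepl("_rep[0-9]+$", samples)))
    stop_data("sample columns must be named <genotype>_rep<k>")
  expression_matrix(
    m,
    genotype  = sub("_rep[0-9]+$", "", samples),
    replicate = as.integer(sub("^.*_rep", "", samples)))
}
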