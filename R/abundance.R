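#' Relative paralog abundance from mRNA expression
#'
#' Normalized expression of the two paralogs is converted to the share of
#' the combined pool contributed by each: `pct_b = 100 * b / (a + b)`.
#'
#' @param expr_a,expr_b nonnegative normalized expression values
#'   (e.g. FPKM or microarray intensity) for the A and B paralog.
#' @return An `abundance_result`: list with `pct_a`, `pct_b`, `source`
#'   and the echoed `inputs`.
#' @export
mrna_paralog_percentages <- function(expr_a, expr_b) {
  if (length(expr_a) != 1 || length(expr_b) != 1)
    stop_data("expr_a and expr_b must be scalars")
  if (expr_a < 0 || expr_b < 0)
    stop_data("expression values must be nonnegative")
  if (expr_a + expr_b <= 0)
    stop_data("at least one paralog must have nonzero expression")
  pct_b <- 100 * expr_b / (expr_a + expr_b)
  abundance_result(100 - pct_b, pct_b, "mrna",
                   list(expr_a = expr_a, expr_b = expr_b))
}

#' Relative paralog abundance from total-protein MFI across allele dosages
#'
#' Each genotype's mean fluorescence intensity is first divided by the WT
#' baseline to give a fold change; fold changes are then compared between
#' A- and B-deficient genotypes carrying the same total allele number. The
#' numerator of each ratio is the genotype retaining relatively more B
#' alleles, so a ratio above 1 reads as B dominance:
#' `r1 = fold(0A+1B) / fold(1A+0B)`, `r3 = fold(1A+2B) / fold(2A+1B)`.
#' The two ratios are averaged (`r = (r1 + r3) / 2`) and converted to a
#' percentage, `pct_b = 100 * r / (1 + r)`.
#'
#' The WT division cancels from the ratios but is performed as part of the
#' procedure so intermediate fold changes are available for audit.
#'
#' @param mfi data frame with columns `genotype`, `a_alleles`, `b_alleles`,
#'   `mfi` (all MFIs positive) containing WT (2A+2B) and the four
#'   A/B-deficient genotypes; an optional `replicate` column allows
#'   repeated measures.
#' @param mode with replicates, `"pooled"` averages MFIs per genotype
#'   before forming ratios; `"replicate"` forms ratios within each
#'   replicate and averages the per-replicate `r` values.
#' @return An `abundance_result` with `pct_a`, `pct_b`, the intermediate
#'   ratios and fold changes in `inputs`.
#' @export
protein_paralog_percentages <- function(mfi, mode = c("pooled", "replicate")) {
  mode <- match.arg(mode)
  need <- c("genotype", "a_alleles", "b_alleles", "mfi")
  if (!all(need %in% names(mfi)))
    stop_data("MFI table must have genotype, a_alleles, b_alleles, mfi")
  if (any(mfi$mfi <= 0)) stop_data("all MFI values must be positive")

  pick <- function(tab, a, b) {
    v <- tab$mfi[tab$a_alleles == a & tab$b_alleles == b]
    if (length(v) == 0)
      stop_data(sprintf("MFI table lacks the %dA+%dB genotype", a, b))
    v
  }
  ratio_from <- function(tab) {
    wt <- mean(pick(tab, 2, 2))
    fold <- c(b1 = mean(pick(tab, 0, 1)) / wt,   # one-allele, A-deficient
              a1 = mean(pick(tab, 1, 0)) / wt,   # one-allele, B-deficient
              b3 = mean(pick(tab, 1, 2)) / wt,   # three-allele, A-deficient
              a3 = mean(pick(tab, 2, 1)) / wt)   # three-allele, B-deficient
    c(r1 = fold[["b1"]] / fold[["a1"]], r3 = fold[["b3"]] / fold[["a3"]],
      fold)
  }

  if (mode == "replicate" && !is.null(mfi$replicate)) {
    reps <- lapply(split(mfi, mfi$replicate), ratio_from)
    rmat <- do.call(rbind, reps)
    r1 <- mean(rmat[, "r1"]); r3 <- mean(rmat[, "r3"])
  } else {
    rr <- ratio_from(mfi)
    r1 <- rr[["r1"]]; r3 <- rr[["r3"]]
  }
  r <- (r1 + r3) / 2
  pct_b <- 100 * r / (1 + r)
  abundance_result(100 - pct_b, pct_b, "protein",
                   list(r1 = r1, r3 = r3, r = r))
}

abundance_result <- function(pct_a, pct_b, source, inputs) {
  stopifnot(abs(pct_a + pct_b - 100) < 1e-9)
  structure(list(pct_a = pct_a, pct_b = pct_b, source = source,
                 inputs = inputs),
            class = "abundance_result")
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(sprintf("Relative paralog abundance (%s): A %.1f%% / B %.1f%%\n",
              x$source, x$pct_a, x$pct_b))
  invisible(x)
}

#' Read an MFI table from TSV
#'
#' Expected columns: `genotype`, `a_alleles`, `b_alleles`, `mfi`, and
#' optionally `replicate`.
#'
#' @param path file path.
#' @return A data frame suitable for [protein_paralog_percentages()].
#' @export
read_mfi_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype", "a_alleles", "b_alleles", "mfi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data(paste0("MFI TSV missing columns: ",
                     paste(miss, collapse = ", ")))
  df
}
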