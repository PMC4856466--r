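#' Pipeline configuration
#'
#' Bundles input paths (or the synthetic-data switch), analysis thresholds
#' and the seed for a full [run_pipeline()] pass. All thresholds default to
#' the method's canonical values: 1.5-fold regulation with p < 0.05, a
#' 1.2-fold "unchanged" ceiling for specificity calls, peak retention at
#' > 3-fold enrichment with p < 5e-5, and a +/- 10 kb TSS window.
#'
#' @param simulate generate inputs with the synthetic module instead of
#'   reading files.
#' @param sim a [simulation_config()] used when `simulate = TRUE`.
#' @param matrix_path expression TSV path (required when
#'   `simulate = FALSE`).
#' @param fragment_map optional data frame (`fragment_id`, `gene_id`) for
#'   fragment collapsing.
#' @param peak_paths optional named list/vector of extended-BED paths for
#'   genotypes `WT`, `het`, `A-KO`, `B-KO`.
#' @param tss_path optional TSS TSV path.
#' @param mfi_path optional MFI TSV path.
#' @param fc,fc_ceiling,p_cutoff,peak_fe,peak_p,tss_window analysis
#'   thresholds.
#' @param seed integer seed governing all randomness in the run.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, sim = simulation_config(),
                       matrix_path = NULL, fragment_map = NULL,
                       peak_paths = NULL, tss_path = NULL, mfi_path = NULL,
                       fc = 1.5, fc_ceiling = 1.2, p_cutoff = 0.05,
                       peak_fe = 3, peak_p = 5e-5, tss_window = 10000,
                       seed = 1L) {
  if (any(c(fc, fc_ceiling, p_cutoff, peak_fe, peak_p, tss_window) <= 0))
    stop_config("all thresholds must be positive")
  if (!simulate && is.null(matrix_path))
    stop_config("matrix_path is required when simulate = FALSE")
  structure(list(simulate = simulate, sim = sim, matrix_path = matrix_path,
                 fragment_map = fragment_map, peak_paths = peak_paths,
                 tss_path = tss_path, mfi_path = mfi_path,
                 fc = fc, fc_ceiling = fc_ceiling, p_cutoff = p_cutoff,
                 peak_fe = peak_fe, peak_p = peak_p,
                 tss_window = tss_window, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full paralog-dose pipeline
#'
#' Executes offset computation, optional fragment collapsing,
#' low-expression filtering, the three DE contrasts, regulated-gene
#' pooling, the preference histogram, the specificity classification,
#' ChIP-seq occupancy integration (when peaks are available) and relative
#' protein abundance (when an MFI table is available), and collects every
#' intermediate summary into a machine-readable report.
#'
#' @param config a [run_config()].
#' @return A `paralog_report` list; see [write_report()] for the JSON
#'   serialization. Gene counts satisfy
#'   `n_input >= n_after_collapse >= n_after_filter >= n_pooled >=` each
#'   label count, asserted on every run.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  warnings_seen <- character(0)
  note <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  peaks <- NULL; tss <- NULL; mfi <- NULL; peak_truth <- NULL
  if (config$simulate) {
    sim <- config$sim
    sim$seed <- config$seed
    gen <- generate_expression(sim)
    x <- gen$matrix
    pk <- generate_peaks(sim)
    peaks <- pk$peaks; tss <- pk$tss; peak_truth <- pk$truth
    mfi <- generate_mfi(sim)
  } else {
    x <- read_expression_tsv(config$matrix_path)
    if (!is.null(config$peak_paths)) {
      peaks <- lapply(config$peak_paths, read_peaks_bed)
      tss <- read_tss_tsv(config$tss_path %||%
                            stop_config("tss_path required with peaks"))
    }
    if (!is.null(config$mfi_path)) mfi <- read_mfi_tsv(config$mfi_path)
  }

  n_input <- nrow(x$values)
  offset <- note(compute_offset(x))
  if (!is.null(config$fragment_map))
    x <- collapse_fragments(x, config$fragment_map)
  n_after_collapse <- nrow(x$values)
  x <- filter_low_expression(x)
  n_after_filter <- nrow(x$values)
  if (n_after_filter == 0) stop_data("no gene passes the expression filter")
  x <- apply_offset(x, offset)

  de_a <- compute_de(x, "A-KO", "WT", fc = config$fc,
                     p_cutoff = config$p_cutoff)
  de_b <- compute_de(x, "B-KO", "WT", fc = config$fc,
                     p_cutoff = config$p_cutoff)
  de_ab <- compute_de(x, "A-KO", "B-KO", fc = config$fc,
                      p_cutoff = config$p_cutoff)
  pooled <- pool_regulated(de_a, de_b)

  pref <- NULL; hist <- NULL; spec_summary <- NULL; calls <- NULL
  if (length(pooled) > 0) {
    pref <- preference_table(de_a, de_b, pooled)
    hist <- bin_preferences(pref)
    calls <- classify_specificity(de_a, de_b, de_ab, pooled,
                                  fc = config$fc,
                                  fc_ceiling = config$fc_ceiling,
                                  p_cutoff = config$p_cutoff)
    spec_summary <- summarize_specificity(calls)
    stopifnot(n_input >= n_after_collapse,
              n_after_collapse >= n_after_filter,
              n_after_filter >= length(pooled),
              all(spec_summary$counts <= length(pooled)))
  }

  chip <- NULL
  if (!is.null(peaks)) {
    called <- lapply(peaks, filter_called_peaks,
                     min_fold = config$peak_fe, max_p = config$peak_p)
    hier <- occupancy_hierarchy(called$WT, called$het, called$`A-KO`,
                                called$`B-KO`, tss,
                                window = config$tss_window)
    occ <- suppressMessages(
      occupancy_vs_expression(hier, called$WT, tss, de_b,
                              window = config$tss_window))
    loc <- tss_localization(called$WT, tss)
    chip <- list(
      peak_counts = vapply(called, nrow, integer(1)),
      overlap_with_wt = peak_overlap_table(called, wt_only = TRUE),
      group_summary = as.data.frame(occ),
      genes_dropped_no_p = attr(occ, "dropped"),
      localization = loc$histogram)
  }

  abundance <- if (!is.null(mfi)) protein_paralog_percentages(mfi)

  structure(
    list(seed = config$seed,
         offset = offset,
         counts = list(n_input = n_input,
                       n_after_collapse = n_after_collapse,
                       n_after_filter = n_after_filter,
                       n_pooled = length(pooled)),
         de = list(n_regulated_a = sum(de_a$regulated),
                   n_regulated_b = sum(de_b$regulated),
                   n_regulated_ab = sum(de_ab$regulated)),
         preference = if (!is.null(hist))
           list(counts = hist$counts, median = hist$median, n = hist$n),
         specificity = if (!is.null(spec_summary))
           list(counts = as.list(spec_summary$counts),
                fraction_specific = spec_summary$fraction_specific),
         chip = chip,
         abundance = if (!is.null(abundance))
           list(pct_a = abundance$pct_a, pct_b = abundance$pct_b,
                source = abundance$source),
         config = list(fc = config$fc, fc_ceiling = config$fc_ceiling,
                       p_cutoff = config$p_cutoff,
                       peak_fe = config$peak_fe, peak_p = config$peak_p,
                       tss_window = config$tss_window,
                       simulate = config$simulate,
                       sim = if (config$simulate) unclass(config$sim)),
         warnings = warnings_seen),
    tables = list(de_a = de_a, de_b = de_b, de_ab = de_ab,
                  preference = pref, calls = calls,
                  peak_truth = peak_truth),
    class = "paralog_report")
}

#' @export
print.paralog_report <- function(x, ...) {
  cat("Paralog-dose pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  offset: %.4g\n", x$offset))
  cat(sprintf("  genes: %d input -> %d after collapse -> %d after filter -> %d pooled\n",
              x$counts$n_input, x$counts$n_after_collapse,
              x$counts$n_after_filter, x$counts$n_pooled))
  if (!is.null(x$preference))
    cat(sprintf("  median paralog preference: %.3f (n = %d)\n",
                x$preference$median, x$preference$n))
  if (!is.null(x$specificity))
    cat(sprintf("  paralog-specific fraction: %.1f%%\n",
                100 * x$specificity$fraction_specific))
  if (!is.null(x$chip))
    cat("  peak counts:", paste(names(x$chip$peak_counts),
                                x$chip$peak_counts, collapse = ", "), "\n")
  if (!is.null(x$abundance))
    cat(sprintf("  protein abundance: A %.1f%% / B %.1f%%\n",
                x$abundance$pct_a, x$abundance$pct_b))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' The serialization is deterministic: identical configs (including the
#' seed) produce byte-identical files.
#'
#' @param report a `paralog_report` from [run_pipeline()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns",
                       null = "null")
  invisible(path)
}
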