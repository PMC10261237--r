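TABLE4_BIN_LABELS <- c("<0.001", "0.001-0.1", "0.1-1", "1-10", ">10")
DURATION_LEVELS <- c("naive", "1-3 months", "3-6 months", "6-12 months", ">1 year")

#' Summarize a cohort in the style of the study's demographic tables
#'
#' Produces the %IS-bin distribution (five molecular-response strata with
#' edges 0.001, 0.1, 1, 10 %IS), the treatment-duration distribution and the
#' sex split, each with counts and percentages rounded half-up to one
#' decimal.  Bin membership follows the analysis convention — a value
#' strictly greater than an edge belongs to the upper bin — so summaries and
#' the cutoff sweep can never disagree at a boundary.  (Published versions of
#' such tables sometimes label adjacent bins 0.001--0.1 and 0.11--1, leaving
#' the sliver (0.1, 0.11) unassigned; this summary uses contiguous half-open
#' bins instead.)
#'
#' @param records data.frame with column `percent_is` (or `qrt_percent_is`)
#'   and optional columns `duration` (character, matching
#'   `"naive", "1-3 months", "3-6 months", "6-12 months", ">1 year"`)
#'   and `sex` (`"M"`/`"F"`).
#' @return Object of class `cohort_summary`: list with `n_total`,
#'   `is_bins` (data.frame label/count/percent), optionally
#'   `duration` (same shape), `n_male`, `n_female`, `sex_ratio`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_domain("`records` must be a non-empty data.frame")
  }
  is_val <- records$percent_is %||% records$qrt_percent_is
  if (is.null(is_val)) stopf("`records` must contain a `percent_is` or `qrt_percent_is` column")
  if (any(!is.finite(is_val)) || any(is_val < 0)) stopf("%%IS values must be finite and >= 0")
  n <- length(is_val)
  edges <- c(0.001, 0.1, 1, 10)
  # bin index: number of edges strictly below the value, +1
  bin <- vapply(is_val, function(v) sum(v > edges), integer(1)) + 1L
  counts <- tabulate(bin, nbins = 5L)
  out <- list(
    n_total = n,
    is_bins = data.frame(
      label = TABLE4_BIN_LABELS,
      count = counts,
      percent = round_half_up(100 * counts / n, 1),
      stringsAsFactors = FALSE
    )
  )
  if (!is.null(records$duration)) {
    d <- factor(records$duration, levels = DURATION_LEVELS)
    if (any(is.na(d))) {
      stopf("unrecognized treatment-duration value(s): %s",
            paste(unique(records$duration[is.na(d)]), collapse = ", "))
    }
    dc <- as.integer(table(d))
    out$duration <- data.frame(
      label = DURATION_LEVELS, count = dc,
      percent = round_half_up(100 * dc / n, 1), stringsAsFactors = FALSE
    )
  }
  if (!is.null(records$sex)) {
    sx <- toupper(trimws(as.character(records$sex)))
    if (!all(sx %in% c("M", "F"))) stopf("`sex` must be coded M/F")
    out$n_male <- sum(sx == "M")
    out$n_female <- sum(sx == "F")
    out$sex_ratio <- if (out$n_female > 0) sex_ratio(out$n_male, out$n_female) else NA_real_
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", x$n_total))
  cat("  %IS bin distribution:\n")
  for (i in seq_len(nrow(x$is_bins))) {
    cat(sprintf("    %-10s %4d (%.1f%%)\n", x$is_bins$label[i],
                x$is_bins$count[i], x$is_bins$percent[i]))
  }
  if (!is.null(x$duration)) {
    cat("  treatment duration:\n")
    for (i in seq_len(nrow(x$duration))) {
      cat(sprintf("    %-12s %4d (%.1f%%)\n", x$duration$label[i],
                  x$duration$count[i], x$duration$percent[i]))
    }
  }
  if (!is.null(x$n_male)) {
    cat(sprintf("  sex: %d M / %d F (ratio %.1f:1)\n", x$n_male, x$n_female, x$sex_ratio))
  }
  invisible(x)
}

#' Male-to-female ratio
#'
#' @param n_male,n_female non-negative counts; `n_female` must be > 0.
#' @return the ratio rounded half-up to one decimal.
#' @examples
#' sex_ratio(139, 80)  # 1.7
#' @export
sex_ratio <- function(n_male, n_female) {
  assert_scalar_number(n_male, "n_male", lower = 0)
  if (!is.numeric(n_female) || length(n_female) != 1L || !is.finite(n_female) ||
      n_female <= 0) {
    stop_domain("undefined ratio: `n_female` must be > 0")
  }
  round_half_up(n_male / n_female, 1)
}

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[mpxcutoff] ", fmt), ...))
}

#' Run the full simulate/evaluate/report pipeline
#'
#' Executes the configured stages and writes the report bundle to `out_dir`:
#'
#' * `cohort.csv` — the simulated (or copied) paired-assay table;
#' * `sweep.csv` — the cutoff performance profile over the evaluation grid;
#' * `roc.csv` — the full ROC point set;
#' * `auc.json` — DeLong AUC, SE and CI (both Wald and logit), and the
#'   optimal cutoff with its operating characteristics;
#' * `summary.json` — the %IS-bin cohort summary;
#' * `manifest.json` — inputs, seed, package version and row counts.
#'
#' Outputs are a pure function of (inputs, config, seed): re-running with the
#' same configuration yields byte-identical files.  Progress is logged to
#' standard error.
#'
#' @param config either a [cohort_config()] (simulate mode) or a path to an
#'   existing paired-assay CSV (evaluate mode).
#' @param out_dir output directory, created if needed.
#' @param cutoffs evaluation grid, default `seq(0.1, 1, by = 0.1)`.
#' @param level confidence level for the AUC interval.
#' @return (invisibly) a list with `sweep`, `roc`, `auc`, `optimal`,
#'   `summary`, `paths`.
#' @export
run_full_pipeline <- function(config, out_dir,
                              cutoffs = seq(0.1, 1, by = 0.1), level = 0.95) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(config, "cohort_config")) {
    log_stage("simulate: n = %d, seed = %d", config$n_patients, config$seed)
    cohort <- sample_cohort(config)
    df <- cohort$samples
    cohort_src <- sprintf("simulated(seed=%d)", config$seed)
  } else if (is.character(config) && length(config) == 1L) {
    log_stage("load cohort: %s", config)
    df <- read_cohort_csv(config)
    if (!"true_percent_is" %in% names(df)) df$true_percent_is <- df$qrt_percent_is
    cohort_src <- config
  } else {
    stopf("`config` must be a cohort_config or a cohort CSV path")
  }
  pairs <- paired_samples(df$qrt_percent_is, df$mpx_result, df$sample_id)
  log_stage("evaluate: %d samples, %d index-positive", nrow(pairs), sum(pairs$index_result))

  sweep <- sweep_cutoffs(pairs, cutoffs)
  roc <- roc_points(pairs)
  auc_w <- delong_auc(pairs, level = level, ci = "wald")
  auc_l <- delong_auc(pairs, level = level, ci = "logit")
  opt <- optimal_cutoff(sweep)
  summ <- summarize_cohort(data.frame(percent_is = pairs$reference_value))
  log_stage("AUC %.3f (%.0f%% CI %.3f-%.3f); optimal cutoff %.2f %%IS",
            auc_w$auc, 100 * level, auc_w$ci_low, auc_w$ci_high, opt$cutoff)

  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    sweep = file.path(out_dir, "sweep.csv"),
    roc = file.path(out_dir, "roc.csv"),
    auc = file.path(out_dir, "auc.json"),
    summary = file.path(out_dir, "summary.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  if (!"true_percent_is" %in% names(df)) df$true_percent_is <- NA_real_
  write_cohort_csv(df, paths$cohort)
  utils::write.csv(format_numeric_df(sweep), paths$sweep, row.names = FALSE, quote = FALSE)
  utils::write.csv(format_numeric_df(roc), paths$roc, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    auc = round(auc_w$auc, 3), se = auc_w$se,
    ci_wald = c(auc_w$ci_low, auc_w$ci_high),
    ci_logit = c(auc_l$ci_low, auc_l$ci_high),
    level = level, n_pos = auc_w$n_pos, n_neg = auc_w$n_neg,
    optimal_cutoff = opt$cutoff,
    optimal_performance = as.list(opt$performance)
  ), paths$auc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(
    n_total = summ$n_total,
    is_bins = summ$is_bins
  ), paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(
    package = "mpxcutoff",
    version = as.character(utils::packageVersion("mpxcutoff")),
    cohort_source = cohort_src,
    n_samples = nrow(pairs),
    n_index_positive = sum(pairs$index_result),
    cutoff_grid = cutoffs,
    confidence_level = level
  ), paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("report bundle written to %s", out_dir)
  invisible(list(sweep = sweep, roc = roc, auc = auc_w, optimal = opt,
                 summary = summ, paths = paths))
}

# Stable decimal formatting so pipeline outputs are byte-identical across runs.
format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
  }
  df
}
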