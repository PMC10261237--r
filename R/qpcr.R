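#' Fit a qPCR calibration curve from plasmid reference standards
#'
#' Least-squares regression of cycle threshold (Ct) on log10 copy-number
#' concentration over the individual standard wells, the standard-curve
#' construction used with certified plasmid reference materials run in
#' triplicate across the 10 to 1e6 copies/uL range.  The fit uses individual
#' wells rather than replicate means to preserve degrees of freedom in the
#' goodness-of-fit statistic.
#'
#' Amplification efficiency derives from the slope as
#' \eqn{E = 10^{-1/\mathrm{slope}} - 1}; a perfect doubling per cycle gives a
#' slope of \eqn{-1/\log_{10} 2 \approx -3.3219} and \eqn{E = 1} (100%).
#' A warning is raised (the fit is still returned) when the efficiency falls
#' outside the conventional 90--110% acceptance window.
#'
#' @param standards data.frame with numeric columns `copies_per_ul` (> 0) and
#'   `ct` (finite cycle thresholds), one row per well.
#' @return Object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n_points`.
#' @examples
#' std <- data.frame(copies_per_ul = 10^(1:6),
#'                   ct = 40 - 3.3219 * (1:6))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("copies_per_ul", "ct") %in% names(standards))) {
    stopf("`standards` must be a data.frame with columns `copies_per_ul` and `ct`")
  }
  x <- as.numeric(standards$copies_per_ul)
  y <- as.numeric(standards$ct)
  if (any(!is.finite(x)) || any(x <= 0)) stopf("`copies_per_ul` must be finite and > 0")
  if (any(!is.finite(y))) stopf("all standard `ct` values must be finite")
  if (length(unique(x)) < 3L) {
    stopf("insufficient calibration data: need >= 3 distinct concentration levels, got %d",
          length(unique(x)))
  }
  fit <- stats::lm(y ~ I(log10(x)))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0) {
    stopf("calibration failure: fitted slope is %s (must be negative: Ct falls as input rises)",
          format(slope))
  }
  # manual R^2: summary.lm() warns on numerically perfect standard lines
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  eff <- 10^(-1 / slope) - 1
  curve <- structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = eff, n_points = length(y)),
    class = "calibration_curve"
  )
  if (eff < 0.9 || eff > 1.1) {
    warning(sprintf("amplification efficiency %.1f%% outside the 90-110%% QC window",
                    100 * eff), call. = FALSE)
  }
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  Ct = %.4f * log10(copies) + %.4f   (n = %d wells)\n",
              x$slope, x$intercept, x$n_points))
  cat(sprintf("  R^2 = %.6f, efficiency = %.1f%%\n", x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Extrapolate copy number from a Ct value
#'
#' Inverts the calibration line: \eqn{c = 10^{(Ct - b)/a}} with slope \eqn{a}
#' and intercept \eqn{b}.  An undetermined Ct (`NA`) maps to 0 copies — the
#' convention for a well in which the target never crossed threshold.
#'
#' @param curve a [fit_calibration()] result.
#' @param ct numeric vector of cycle thresholds; `NA` = undetermined well.
#' @return copy numbers (same length as `ct`).
#' @export
ct_to_copies <- function(curve, ct) {
  if (!inherits(curve, "calibration_curve")) stopf("`curve` must be a `calibration_curve`")
  if (curve$slope >= 0) stopf("invalid calibration curve: slope must be negative")
  out <- 10^((ct - curve$intercept) / curve$slope)
  out[is.na(ct)] <- 0
  out
}

#' BCR::ABL1 percent international scale
#'
#' The normalized percent international scale value:
#' \deqn{\%IS = \frac{\mathrm{BCR::ABL1\ copies}}{\mathrm{ABL1\ copies}}
#'   \times 100 \times CF}
#' where \eqn{CF} is the laboratory-specific conversion factor obtained by
#' harmonization against a reference laboratory.  The default is 0.542; note
#' that some published descriptions of this assay print the factor rounded to
#' 0.5 in the displayed formula while stating 0.542 in the text — the factor
#' is therefore an explicit argument, never hard-wired.
#'
#' @param bcr_abl1_copies summed BCR::ABL1 copy number (>= 0).
#' @param abl1_copies summed ABL1 (control gene) copy number; must be > 0 —
#'   a zero denominator means the control gene failed and the sample is
#'   invalid, not zero disease burden.
#' @param conversion_factor positive laboratory-specific scalar (default 0.542).
#' @return %IS value(s), >= 0.
#' @examples
#' percent_is(542, 1e5)            # 0.293764
#' percent_is(100, 100, 0.5)       # 50
#' @export
percent_is <- function(bcr_abl1_copies, abl1_copies, conversion_factor = 0.542) {
  if (any(!is.finite(bcr_abl1_copies)) || any(bcr_abl1_copies < 0)) {
    stopf("`bcr_abl1_copies` must be finite and >= 0")
  }
  if (any(!is.finite(abl1_copies)) || any(abl1_copies <= 0)) {
    stopf("invalid sample: ABL1 control-gene copy number must be > 0")
  }
  assert_scalar_number(conversion_factor, "conversion_factor", lower = .Machine$double.xmin)
  (bcr_abl1_copies / abl1_copies) * 100 * conversion_factor
}

#' Quantify one sample from duplicate Ct measurements
#'
#' Converts each well's Ct to copies through its target's calibration curve,
#' sums the duplicates per target (the summed numerator and denominator of the
#' %IS formula), and applies [percent_is()].  An undetermined BCR::ABL1 well
#' contributes 0 copies (non-detection); undetermined ABL1 wells are dropped
#' from the control sum, and a sample in which *both* ABL1 wells are
#' undetermined is an error (no denominator).  The `valid` flag is `FALSE`
#' when the summed ABL1 copies fall below `abl1_floor`, the usual QC gate for
#' adequate RNA input (default 10,000 summed copies; configurable, not a
#' published constant).
#'
#' @param bcr_ct numeric vector (typically length 2) of BCR::ABL1 Ct values;
#'   `NA` = undetermined.
#' @param abl_ct numeric vector (typically length 2) of ABL1 Ct values;
#'   `NA` = undetermined.
#' @param bcr_curve,abl_curve [fit_calibration()] curves for each target.
#' @param conversion_factor see [percent_is()].
#' @param abl1_floor minimum summed ABL1 copies for a valid sample.
#' @return Object of class `sample_quant`: list with `bcr_abl1_copies`,
#'   `abl1_copies`, `percent_is`, `conversion_factor`, `valid`.
#' @export
quantify_sample <- function(bcr_ct, abl_ct, bcr_curve, abl_curve,
                            conversion_factor = 0.542, abl1_floor = 1e4) {
  if (length(abl_ct) == 0 || all(is.na(abl_ct))) {
    stopf("invalid sample: all ABL1 control wells undetermined (no denominator)")
  }
  bcr_copies <- sum(ct_to_copies(bcr_curve, bcr_ct))
  abl_copies <- sum(ct_to_copies(abl_curve, abl_ct))
  structure(
    list(
      bcr_abl1_copies = bcr_copies,
      abl1_copies = abl_copies,
      percent_is = percent_is(bcr_copies, abl_copies, conversion_factor),
      conversion_factor = conversion_factor,
      valid = abl_copies >= abl1_floor
    ),
    class = "sample_quant"
  )
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("<sample_quant> %%IS = %.6g (BCR::ABL1 %.4g / ABL1 %.4g, CF %.3f)%s\n",
              x$percent_is, x$bcr_abl1_copies, x$abl1_copies, x$conversion_factor,
              if (x$valid) "" else "  [INVALID: low control copies]"))
  invisible(x)
}

#' Read calibration wells from CSV and fit per-target curves
#'
#' Input schema: `target, copies_per_ul, ct`, one row per well.  Returns a
#' named list of [fit_calibration()] curves, one per target.
#'
#' @param path CSV file.
#' @return named list of `calibration_curve` objects.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stopf("calibration file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "copies_per_ul", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("%s: missing required column(s): %s", path, paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stopf("%s: calibration file contains no wells", path)
  lapply(split(df, df$target), fit_calibration)
}

#' Quantify a cohort of samples from a per-well Ct table
#'
#' Input schema: `sample_id, target, replicate, ct` with `target` in
#' `{BCR_ABL1, ABL1}` (case-insensitive; `::`, `-` and `_` are equivalent)
#' and empty/`NA`/`Undetermined` Ct for wells that never crossed threshold.
#' Samples whose ABL1 wells are all undetermined are marked invalid with
#' `percent_is = NA` rather than aborting the batch.
#'
#' @param samples data.frame or CSV path with the schema above.
#' @param curves named list of calibration curves with entries `BCR_ABL1` and
#'   `ABL1` (as from [read_calibration_csv()]).
#' @param conversion_factor,abl1_floor see [quantify_sample()].
#' @return data.frame: `sample_id, bcr_abl1_copies, abl1_copies, percent_is,
#'   valid`.
#' @export
quantify_cohort <- function(samples, curves, conversion_factor = 0.542,
                            abl1_floor = 1e4) {
  if (is.character(samples)) {
    path <- samples
    if (!file.exists(path)) stopf("sample Ct file not found: %s", path)
    samples <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(c("sample_id", "target", "ct"), names(samples))
    if (length(missing) > 0) {
      stopf("%s: missing required column(s): %s", path, paste(missing, collapse = ", "))
    }
  }
  norm_target <- function(x) {
    x <- toupper(gsub("[^A-Za-z0-9]+", "_", x))
    x <- sub("_+$", "", x)
    ifelse(x %in% c("BCR_ABL1", "BCR_ABL", "BCRABL1"), "BCR_ABL1",
           ifelse(x %in% c("ABL1", "ABL"), "ABL1", x))
  }
  cn <- norm_target(names(curves))
  if (!all(c("BCR_ABL1", "ABL1") %in% cn)) {
    stopf("`curves` must contain calibration curves for BCR_ABL1 and ABL1")
  }
  bcr_curve <- curves[[which(cn == "BCR_ABL1")[1L]]]
  abl_curve <- curves[[which(cn == "ABL1")[1L]]]
  samples$target <- norm_target(samples$target)
  ct <- suppressWarnings(as.numeric(ifelse(
    samples$ct %in% c("", "Undetermined", "undetermined", "NA"), NA, samples$ct)))
  rows <- lapply(split(seq_len(nrow(samples)), samples$sample_id), function(i) {
    bcr_ct <- ct[i][samples$target[i] == "BCR_ABL1"]
    abl_ct <- ct[i][samples$target[i] == "ABL1"]
    sid <- samples$sample_id[i[1L]]
    if (length(abl_ct) == 0 || all(is.na(abl_ct))) {
      return(data.frame(sample_id = sid, bcr_abl1_copies = NA_real_,
                        abl1_copies = 0, percent_is = NA_real_, valid = FALSE))
    }
    q <- quantify_sample(bcr_ct, abl_ct, bcr_curve, abl_curve,
                         conversion_factor, abl1_floor)
    data.frame(sample_id = sid, bcr_abl1_copies = q$bcr_abl1_copies,
               abl1_copies = q$abl1_copies, percent_is = q$percent_is,
               valid = q$valid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
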