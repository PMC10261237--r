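#' Generative configuration for a synthetic CML monitoring cohort
#'
#' A `cohort_config` describes the joint distribution of a paired-sample
#' cohort: a latent BCR::ABL1 transcript burden on the percent international
#' scale (%IS) drawn from a binned marginal distribution, and a qualitative
#' multiplex PCR (mpx-PCR) readout generated from the latent burden through a
#' logistic limit-of-detection model (see [detection_probability()]).
#'
#' The default bin layout follows the standard molecular-response strata used
#' for CML monitoring: edges at 0.001, 0.1, 1 and 10 %IS delimit five bins
#' (below 0.001; 0.001--0.1; 0.1--1; 1--10; above 10).  Bins are half-open:
#' a value strictly greater than an edge belongs to the upper bin, the same
#' convention the cutoff analysis uses, so summaries and sweeps never disagree
#' at a boundary.
#'
#' @param n_patients number of patients to simulate; must be positive.
#' @param bin_edges strictly increasing positive %IS boundaries separating the
#'   burden bins (default `c(0.001, 0.1, 1, 10)`, giving five bins).
#' @param bin_probs probability of membership in each bin; length
#'   `length(bin_edges) + 1`, non-negative, summing to 1 within `1e-12`.
#' @param p_zero_in_lowest_bin probability that a lowest-bin patient carries
#'   truly zero transcript (transcript-free) rather than a detectable burden
#'   below the lowest edge; in `[0, 1]`.
#' @param detection_mid %IS at which the mpx-PCR detection probability is 50%;
#'   must be positive.  Default 0.3 %IS, a modelling choice placing the
#'   analytical limit of detection near the 1e-3 transcript-frequency region.
#' @param detection_slope logistic scale parameter on the log10(%IS) axis;
#'   `0` is allowed and means a perfect step detector at `detection_mid`.
#' @param false_positive_rate probability of a positive mpx-PCR call on a
#'   transcript-free sample (contamination); in `[0, 1]`, default 0.
#' @param lower_cap smallest non-zero %IS drawn for lowest-bin patients
#'   (default `1e-5`).
#' @param upper_cap largest %IS drawn for the open top bin (default 100).
#' @param measurement_cv coefficient of variation of optional log-normal
#'   measurement noise applied to the reported qRT-PCR value; default 0
#'   (reported value equals the latent value, keeping oracle checks exact).
#' @param seed integer seed controlling all randomness in [sample_cohort()].
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [default_table4_config()], [sample_cohort()],
#'   [detection_probability()]
#' @examples
#' cfg <- cohort_config(n_patients = 50, seed = 1)
#' cfg$bin_probs
#' @export
cohort_config <- function(n_patients,
                          bin_edges = c(0.001, 0.1, 1, 10),
                          bin_probs = c(9, 35, 25, 24, 126) / 219,
                          p_zero_in_lowest_bin = 0.5,
                          detection_mid = 0.3,
                          detection_slope = 0.25,
                          false_positive_rate = 0,
                          lower_cap = 1e-5,
                          upper_cap = 100,
                          measurement_cv = 0,
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      !is.finite(n_patients) || n_patients <= 0 || n_patients != floor(n_patients)) {
    stopf("`n_patients` must be a positive integer, got %s", format(n_patients))
  }
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      bin_edges = as.numeric(bin_edges),
      bin_probs = as.numeric(bin_probs),
      p_zero_in_lowest_bin = as.numeric(p_zero_in_lowest_bin),
      detection_mid = as.numeric(detection_mid),
      detection_slope = as.numeric(detection_slope),
      false_positive_rate = as.numeric(false_positive_rate),
      lower_cap = as.numeric(lower_cap),
      upper_cap = as.numeric(upper_cap),
      measurement_cv = as.numeric(measurement_cv),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of a [cohort_config()]: bin probabilities
#' non-negative and summing to 1 within `1e-12`, strictly increasing positive
#' bin edges, positive detection midpoint, probabilities inside `[0, 1]`, and
#' caps bracketing the bin range.
#'
#' @param cfg object to validate.
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_cohort_config <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stopf("not a `cohort_config` object")
  e <- cfg$bin_edges
  p <- cfg$bin_probs
  if (length(e) < 1L || any(!is.finite(e)) || any(e <= 0) || any(diff(e) <= 0)) {
    stopf("`bin_edges` must be strictly increasing and positive")
  }
  if (length(p) != length(e) + 1L) {
    stopf("`bin_probs` must have length(bin_edges) + 1 = %d entries, got %d",
          length(e) + 1L, length(p))
  }
  if (any(!is.finite(p)) || any(p < 0)) stopf("`bin_probs` must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) {
    stopf("`bin_probs` must sum to 1 within 1e-12 (sum = %.15g)", sum(p))
  }
  assert_scalar_number(cfg$p_zero_in_lowest_bin, "p_zero_in_lowest_bin", 0, 1)
  assert_scalar_number(cfg$false_positive_rate, "false_positive_rate", 0, 1)
  assert_scalar_number(cfg$measurement_cv, "measurement_cv", 0, Inf)
  if (!is.finite(cfg$detection_mid) || cfg$detection_mid <= 0) {
    stopf("`detection_mid` must be > 0")
  }
  if (!is.finite(cfg$detection_slope) || cfg$detection_slope < 0) {
    stopf("`detection_slope` must be >= 0 (0 = step detector)")
  }
  if (cfg$lower_cap <= 0 || cfg$lower_cap >= e[1L]) {
    stopf("`lower_cap` must lie in (0, first bin edge)")
  }
  if (cfg$upper_cap <= e[length(e)]) {
    stopf("`upper_cap` must exceed the last bin edge")
  }
  invisible(cfg)
}

#' Default cohort configuration mimicking the validation study population
#'
#' Returns a [cohort_config()] whose bin probabilities reproduce the %IS
#' distribution of the 219-patient validation cohort: 9, 35, 25, 24 and 126
#' patients in the bins below 0.001, 0.001--0.1, 0.1--1, 1--10 and above
#' 10 %IS respectively.  Detection parameters default to a logistic
#' limit-of-detection model with midpoint 0.3 %IS, slope 0.25 on the
#' log10 scale and no contamination; these are documented modelling
#' choices, not published assay constants.
#'
#' @param n_patients cohort size (the source study enrolled 219).
#' @param seed integer seed.
#' @param ... further arguments passed to [cohort_config()] to override
#'   defaults.
#' @return A `cohort_config`.
#' @examples
#' cfg <- default_table4_config(219, seed = 7)
#' sum(cfg$bin_probs)  # 1
#' @export
default_table4_config <- function(n_patients = 219L, seed = 1L, ...) {
  cohort_config(
    n_patients = n_patients,
    bin_probs = c(9, 35, 25, 24, 126) / 219,
    seed = seed,
    ...
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  n_patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  bin_edges : %s (%%IS)\n", paste(x$bin_edges, collapse = ", ")))
  cat(sprintf("  bin_probs : %s\n", paste(signif(x$bin_probs, 4), collapse = ", ")))
  cat(sprintf("  detection : mid %g %%IS, slope %g, fpr %g\n",
              x$detection_mid, x$detection_slope, x$false_positive_rate))
  cat(sprintf("  lowest bin: P(true zero) = %g; caps [%g, %g] %%IS\n",
              x$p_zero_in_lowest_bin, x$lower_cap, x$upper_cap))
  invisible(x)
}

#' Serialize / restore a cohort configuration
#'
#' Writes the configuration as a flat JSON object so that a simulation run is
#' reproducible from its config file alone; `read_cohort_config()` restores a
#' validated `cohort_config` from such a file.
#'
#' @param cfg a [cohort_config()].
#' @param path file path for the JSON document.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a `cohort_config`.
#' @export
write_cohort_config <- function(cfg, path) {
  validate_cohort_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_config, raw)
}
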