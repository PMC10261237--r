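#' Detection probability of the qualitative multiplex PCR
#'
#' Probability that the mpx-PCR assay calls a sample positive given its true
#' transcript burden.  The model is a logistic curve on the log10(%IS) axis
#' with a contamination floor:
#' \deqn{P(+) = r + (1 - r)\,\mathrm{logistic}\!\left(
#'   \frac{\log_{10} x - \log_{10} m}{s}\right)}
#' where \eqn{x} is the true %IS, \eqn{m} the midpoint
#' (`detection_mid`), \eqn{s} the slope (`detection_slope`) and \eqn{r} the
#' false-positive rate.  A transcript-free sample (\eqn{x = 0}) fires only
#' through contamination, so \eqn{P(+) = r}; with \eqn{r = 0} a stringent PCR
#' never fires on zero transcript.  `detection_slope = 0` denotes the step
#' limit \eqn{1\{x > m\}} (with probability 0.5 exactly at the midpoint).
#' The function is monotone non-decreasing in `true_is`.
#'
#' @param true_is true %IS value(s), each `>= 0`.
#' @param config a [cohort_config()] supplying the detection parameters.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' cfg <- default_table4_config(219)
#' detection_probability(c(0, cfg$detection_mid, 10), cfg)
#' @export
detection_probability <- function(true_is, config) {
  validate_cohort_config(config)
  if (!is.numeric(true_is) || any(!is.finite(true_is))) {
    stop_domain("`true_is` must be finite and numeric")
  }
  if (any(true_is < 0)) stop_domain("`true_is` must be >= 0")
  r <- config$false_positive_rate
  p <- rep(r, length(true_is))
  nz <- true_is > 0
  if (any(nz)) {
    z <- log10(true_is[nz]) - log10(config$detection_mid)
    base <- if (config$detection_slope == 0) {
      ifelse(z > 0, 1, ifelse(z < 0, 0, 0.5))
    } else {
      stats::plogis(z / config$detection_slope)
    }
    p[nz] <- r + (1 - r) * base
  }
  p
}

#' Simulate a paired-assay cohort
#'
#' Draws a cohort of `config$n_patients` patients.  Bin membership comes from
#' a multinomial over `bin_probs`; within a bin the latent %IS is log-uniform
#' between the bin's edges (the open top bin is capped at `upper_cap`, and
#' non-zero lowest-bin draws are bounded below by `lower_cap`).  A lowest-bin
#' patient is truly transcript-free (latent %IS exactly 0) with probability
#' `p_zero_in_lowest_bin`.  Each binary mpx-PCR result is Bernoulli with
#' [detection_probability()] evaluated at the latent burden.  The reported
#' qRT-PCR reference value equals the latent value unless `measurement_cv > 0`,
#' in which case multiplicative log-normal noise with that coefficient of
#' variation is applied to non-zero values.
#'
#' All randomness flows from `config$seed` through a locally scoped RNG:
#' identical configs give byte-identical cohorts and the caller's
#' `.Random.seed` is untouched.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `samples`
#'   (data.frame `sample_id`, `true_percent_is`, `qrt_percent_is`,
#'   `mpx_result` 0/1), `true_is_values`, `config` and `seed`.
#' @examples
#' cohort <- sample_cohort(default_table4_config(219, seed = 42))
#' table(cohort$samples$mpx_result)
#' @export
sample_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  edges <- config$bin_edges
  k <- length(config$bin_probs)
  # Half-open bins (lo, hi]; bin 1 is (0, edges[1]] plus the exact zeros.
  lo <- c(config$lower_cap, edges)
  hi <- c(edges, config$upper_cap)

  with_local_seed(config$seed, {
    bin <- sample.int(k, n, replace = TRUE, prob = config$bin_probs)
    u <- stats::runif(n)
    true_is <- 10^(log10(lo[bin]) + u * (log10(hi[bin]) - log10(lo[bin])))
    in_lowest <- bin == 1L
    if (any(in_lowest)) {
      zero <- stats::runif(sum(in_lowest)) < config$p_zero_in_lowest_bin
      true_is[in_lowest][zero] <- 0
    }
    qrt <- true_is
    if (config$measurement_cv > 0) {
      sdlog <- sqrt(log(1 + config$measurement_cv^2))
      noise <- exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
      qrt <- true_is * noise
    }
    p <- detection_probability(true_is, config)
    mpx <- as.integer(stats::runif(n) < p)
    structure(
      list(
        samples = data.frame(
          sample_id = sprintf("S%04d", seq_len(n)),
          true_percent_is = true_is,
          qrt_percent_is = qrt,
          mpx_result = mpx,
          stringsAsFactors = FALSE
        ),
        true_is_values = true_is,
        config = config,
        seed = config$seed
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<synthetic_cohort> n = %d, seed = %d\n", nrow(s), x$seed))
  cat(sprintf("  mpx positive: %d (%.1f%%); true zeros: %d\n",
              sum(s$mpx_result), 100 * mean(s$mpx_result),
              sum(s$true_percent_is == 0)))
  cat(sprintf("  %%IS range (non-zero): [%.3g, %.3g]\n",
              min(s$true_percent_is[s$true_percent_is > 0]),
              max(s$true_percent_is)))
  invisible(x)
}

#' Write / read a simulated cohort as CSV
#'
#' The on-disk schema is `sample_id, true_percent_is, qrt_percent_is,
#' mpx_result` with `mpx_result` coded 0/1.  Values round-trip at full double
#' precision (written with 17 significant digits).
#'
#' @param cohort a `synthetic_cohort` or a data.frame with the schema above.
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the samples data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "synthetic_cohort")) cohort$samples else cohort
  need <- c("sample_id", "true_percent_is", "qrt_percent_is", "mpx_result")
  if (!all(need %in% names(df))) {
    stopf("cohort is missing columns: %s", paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- df[need]
  out$true_percent_is <- formatC(out$true_percent_is, digits = 17, format = "g")
  out$qrt_percent_is <- formatC(out$qrt_percent_is, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "qrt_percent_is", "mpx_result")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("%s: missing required column(s): %s", path, paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stopf("%s: cohort file contains no samples", path)
  df
}
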