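#' Construct a paired-sample table
#'
#' The atom of the cutoff analysis: one continuous reference %IS value per
#' patient (from qRT-PCR) paired with one binary index-test result (from the
#' qualitative multiplex assay).
#'
#' @param reference_value numeric vector of %IS values, finite and `>= 0`.
#' @param index_result binary results: 0/1, logical, or `"neg"/"pos"`
#'   (also accepts `"negative"/"positive"`, case-insensitive).
#' @param sample_id optional identifiers (defaults to `S0001, ...`).
#' @return data.frame of class `paired_samples` with columns `sample_id`,
#'   `reference_value`, `index_result` (integer 0/1).
#' @export
paired_samples <- function(reference_value, index_result, sample_id = NULL) {
  reference_value <- as.numeric(reference_value)
  if (any(!is.finite(reference_value)) || any(reference_value < 0)) {
    stop_domain("reference %IS values must be finite and >= 0")
  }
  idx <- parse_binary_result(index_result)
  if (length(idx) != length(reference_value)) {
    stopf("`reference_value` and `index_result` lengths differ (%d vs %d)",
          length(reference_value), length(idx))
  }
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_along(idx))
  structure(
    data.frame(sample_id = as.character(sample_id),
               reference_value = reference_value,
               index_result = idx, stringsAsFactors = FALSE),
    class = c("paired_samples", "data.frame")
  )
}

parse_binary_result <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stopf("numeric index results must be coded 0/1")
    return(as.integer(x))
  }
  key <- tolower(trimws(as.character(x)))
  map <- c("0" = 0L, "1" = 1L, neg = 0L, pos = 1L,
           negative = 0L, positive = 1L)
  out <- map[key]
  if (any(is.na(out))) {
    stopf("unrecognized index result value(s): %s",
          paste(unique(key[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Read a paired-assay CSV
#'
#' Schema: `sample_id, qrt_percent_is, mpx_result`, where `mpx_result` may be
#' coded 0/1 or neg/pos.
#'
#' @param path CSV file.
#' @return a [paired_samples()] table.
#' @export
read_paired_csv <- function(path) {
  df <- read_cohort_csv(path)
  paired_samples(df$qrt_percent_is, df$mpx_result, df$sample_id)
}

as_paired <- function(pairs) {
  if (inherits(pairs, "synthetic_cohort")) {
    return(paired_samples(pairs$samples$qrt_percent_is,
                          pairs$samples$mpx_result,
                          pairs$samples$sample_id))
  }
  if (inherits(pairs, "paired_samples")) return(pairs)
  if (is.data.frame(pairs)) {
    ref <- pairs$reference_value %||% pairs$qrt_percent_is
    res <- pairs$index_result %||% pairs$mpx_result
    if (is.null(ref) || is.null(res)) {
      stopf("data.frame must have columns reference_value/qrt_percent_is and index_result/mpx_result")
    }
    return(paired_samples(ref, res, pairs$sample_id))
  }
  stopf("`pairs` must be a paired_samples table, compatible data.frame, or synthetic_cohort")
}

#' Dichotomize the continuous reference at a cutoff
#'
#' Condition-positive means the reference value **strictly exceeds** the
#' cutoff; a value equal to the cutoff counts as below it.  This strict
#' convention is used consistently across the sweep, the ROC construction and
#' the cohort summaries.
#'
#' @param values numeric %IS values.
#' @param cutoff scalar cutoff on the same scale.
#' @return logical vector, `TRUE` = condition positive.
#' @examples
#' binarize_reference(c(0.05, 0.6, 2.0), 0.6)  # FALSE FALSE TRUE
#' @export
binarize_reference <- function(values, cutoff) {
  if (any(!is.finite(values))) stop_domain("reference values must be finite")
  assert_scalar_number(cutoff, "cutoff")
  values > cutoff
}

#' Index-test performance at one reference cutoff
#'
#' Computes the confusion matrix of the binary index test against the
#' dichotomized reference (condition = reference > cutoff) and the inverted
#' operating characteristics: sensitivity is the proportion of index-positive
#' samples among those whose reference value exceeded the cutoff, and
#' specificity the proportion of index-negative samples among those at or
#' below it.  When a denominator class is empty the corresponding rate is
#' `NA` (undefined), never coerced to 0 — coercion would corrupt downstream
#' cutoff selection.
#'
#' @param pairs a [paired_samples()] table (or coercible object).
#' @param cutoff scalar %IS cutoff.
#' @return one-row data.frame of class `cutoff_performance`: `cutoff, tp, fp,
#'   tn, fn, sensitivity, specificity, accuracy`.
#' @examples
#' p <- paired_samples(c(2, 0.9, 0.3, 0), c(1, 1, 0, 0))
#' performance_at_cutoff(p, 0.6)
#' @export
performance_at_cutoff <- function(pairs, cutoff) {
  pairs <- as_paired(pairs)
  if (nrow(pairs) == 0) stop_domain("cannot evaluate performance on an empty cohort")
  cond <- binarize_reference(pairs$reference_value, cutoff)
  pred <- pairs$index_result == 1L
  tp <- sum(cond & pred); fn <- sum(cond & !pred)
  tn <- sum(!cond & !pred); fp <- sum(!cond & pred)
  n <- tp + fp + tn + fn
  out <- data.frame(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / n
  )
  class(out) <- c("cutoff_performance", "data.frame")
  out
}

#' Sweep the performance profile over a cutoff grid
#'
#' Evaluates [performance_at_cutoff()] at each cutoff of a grid.  The default
#' grid is the ten cutoffs 0.1, 0.2, ..., 1.0 %IS spanning the clinically
#' decisive molecular-response range.  Cutoffs are sorted ascending;
#' duplicates are removed with a warning.
#'
#' @param pairs a [paired_samples()] table (or coercible object).
#' @param cutoffs numeric vector of cutoffs; default `seq(0.1, 1, by = 0.1)`.
#' @return data.frame of class `cutoff_sweep`, one row per distinct cutoff.
#' @export
sweep_cutoffs <- function(pairs, cutoffs = seq(0.1, 1, by = 0.1)) {
  if (length(cutoffs) == 0 || any(!is.finite(cutoffs))) {
    stopf("`cutoffs` must be a non-empty finite numeric vector")
  }
  dedup <- sort(unique(cutoffs))
  if (length(dedup) < length(cutoffs)) {
    warning(sprintf("%d duplicate cutoff(s) removed from the grid",
                    length(cutoffs) - length(dedup)), call. = FALSE)
  }
  pairs <- as_paired(pairs)
  out <- do.call(rbind, lapply(dedup, function(ct) performance_at_cutoff(pairs, ct)))
  rownames(out) <- NULL
  class(out) <- c("cutoff_sweep", "data.frame")
  out
}

#' ROC curve over all possible cutoffs
#'
#' Builds the full operating-characteristic curve by taking as candidate
#' cutoffs every distinct observed reference value plus a sentinel strictly
#' below the minimum.  At the all-positive end (cutoff below every value)
#' specificity is undefined and the point is pinned to its limit (1, 1); at
#' the all-negative end (cutoff = maximum value, no strict exceeders)
#' sensitivity is undefined and the point is pinned to (0, 0).  With `d`
#' distinct reference values the curve has at most `d + 1` distinct confusion
#' matrices.
#'
#' @param pairs a [paired_samples()] table (or coercible object).
#' @return data.frame of class `roc_curve`: `cutoff, sensitivity, specificity,
#'   fpr` (= 1 - specificity), ordered by increasing cutoff.
#' @export
roc_points <- function(pairs) {
  pairs <- as_paired(pairs)
  if (nrow(pairs) == 0) stop_domain("cannot build a ROC curve from an empty cohort")
  v <- sort(unique(pairs$reference_value))
  sentinel_low <- if (v[1] > 0) v[1] / 2 else -1
  cand <- c(sentinel_low, v)
  rows <- lapply(cand, function(ct) performance_at_cutoff(pairs, ct))
  out <- do.call(rbind, rows)
  # pin degenerate endpoints to their limiting ROC corners
  all_pos <- out$tn + out$fp == 0
  out$specificity[all_pos] <- 0   # limit: (fpr, sens) = (1, 1)
  out$sensitivity[all_pos] <- 1
  all_neg <- out$tp + out$fn == 0
  out$sensitivity[all_neg] <- 0   # limit: (fpr, sens) = (0, 0)
  out$specificity[all_neg] <- 1
  out$fpr <- 1 - out$specificity
  out <- out[, c("cutoff", "sensitivity", "specificity", "fpr")]
  rownames(out) <- NULL
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' DeLong AUC with standard error and confidence interval
#'
#' The AUC point estimate is the two-sample Mann--Whitney statistic treating
#' the binary index result as the class label and the continuous reference
#' value as the score, with ties between scores counting one half (midrank
#' convention).  The variance follows DeLong's nonparametric estimator from
#' the placement values of each class:
#' \deqn{\widehat{\mathrm{Var}} = \frac{S_{10}}{m} + \frac{S_{01}}{n}}
#' where \eqn{S_{10}} and \eqn{S_{01}} are the sample variances of the
#' positive- and negative-class placements and \eqn{m, n} the class sizes.
#' The confidence interval is Wald on the AUC scale by default, clipped to
#' `[0, 1]`; `ci = "logit"` transforms to the logit scale first, which
#' respects the boundary for AUCs near 1.
#'
#' Note the orientation: this is the standard ROC conditioning (classes
#' defined by the binary test, scores by the continuous reference).  The
#' inverted sensitivity/specificity profile of [sweep_cutoffs()] conditions
#' the other way around; the two constructions are different conditional
#' probabilities and both are exposed deliberately.
#'
#' @param pairs a [paired_samples()] table (or coercible object); both index
#'   classes must be present.
#' @param level confidence level, default 0.95.
#' @param ci `"wald"` (default) or `"logit"`.
#' @return Object of class `auc_estimate`: list with `auc`, `se`, `ci_low`,
#'   `ci_high`, `level`, `ci_method`, `n_pos`, `n_neg`.
#' @examples
#' p <- paired_samples(c(1, 5, 2, 5, 9), c(0, 0, 1, 1, 1))
#' delong_auc(p)$auc  # 5.5/6
#' @export
delong_auc <- function(pairs, level = 0.95, ci = c("wald", "logit")) {
  ci <- match.arg(ci)
  assert_scalar_number(level, "level", lower = 1e-6, upper = 1 - 1e-6)
  pairs <- as_paired(pairs)
  x <- pairs$reference_value[pairs$index_result == 1L]  # index-positive scores
  y <- pairs$reference_value[pairs$index_result == 0L]  # index-negative scores
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) {
    stop_domain("degenerate classes: both positive and negative index results are required")
  }
  # Placement values via midranks: V10[i] = (#{y < x_i} + 0.5 #{y == x_i}) / n
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "wald") {
    lo <- max(0, auc - z * se)
    hi <- min(1, auc + z * se)
  } else {
    if (auc <= 0 || auc >= 1 || se == 0) {
      lo <- hi <- auc
    } else {
      lse <- se / (auc * (1 - auc))
      lo <- stats::plogis(stats::qlogis(auc) - z * lse)
      hi <- stats::plogis(stats::qlogis(auc) + z * lse)
    }
  }
  structure(
    list(auc = auc, se = se, ci_low = lo, ci_high = hi, level = level,
         ci_method = ci, n_pos = m, n_neg = n),
    class = "auc_estimate"
  )
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("<auc_estimate> AUC = %.3f (%.0f%% CI %.3f-%.3f, %s; SE %.4f; n+ %d, n- %d)\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$ci_method, x$se,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Select the optimal cutoff from a sweep
#'
#' Default criterion is Youden's J = sensitivity + specificity - 1, the usual
#' choice when neither error carries an explicit cost; `"accuracy"` and
#' `"closest_topleft"` (minimal Euclidean distance to the perfect corner
#' (0, 1) in ROC space) are available alternatives.  Only rows with both
#' sensitivity and specificity defined compete; ties break toward the lower
#' cutoff.
#'
#' @param sweep a [sweep_cutoffs()] result (or compatible data.frame).
#' @param criterion `"youden"` (default), `"accuracy"`, or
#'   `"closest_topleft"`.
#' @return list with `cutoff` and `performance` (the winning row).
#' @export
optimal_cutoff <- function(sweep, criterion = c("youden", "accuracy", "closest_topleft")) {
  criterion <- match.arg(criterion)
  if (!is.data.frame(sweep) || nrow(sweep) == 0) {
    stop_domain("`sweep` must be a non-empty cutoff sweep")
  }
  ok <- !is.na(sweep$sensitivity) & !is.na(sweep$specificity)
  if (!any(ok)) {
    stop_domain("no cutoff has both sensitivity and specificity defined")
  }
  rows <- sweep[ok, , drop = FALSE]
  score <- switch(criterion,
    youden = rows$sensitivity + rows$specificity - 1,
    accuracy = rows$accuracy,
    closest_topleft = -sqrt((1 - rows$sensitivity)^2 + (1 - rows$specificity)^2)
  )
  best <- which(score == max(score))
  pick <- best[which.min(rows$cutoff[best])]   # ties -> lower cutoff
  list(cutoff = rows$cutoff[pick], performance = rows[pick, , drop = FALSE])
}
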