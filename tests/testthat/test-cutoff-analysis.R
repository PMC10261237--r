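four_pairs <- function() {
  paired_samples(c(2.0, 0.9, 0.3, 0.0), c("pos", "pos", "neg", "neg"))
}

test_that("binarize_reference uses the strict exceed-the-cutoff convention", {
  expect_identical(binarize_reference(c(0.05, 0.6, 2.0), 0.6),
                   c(FALSE, FALSE, TRUE))
  v <- c(0.1, 0.5, 1, 3)
  expect_true(all(binarize_reference(v, 0.05)))
  expect_identical(sum(binarize_reference(v, max(v))), 0L)
  # brute-force comparison at arbitrary cutoffs
  set.seed(9)
  vals <- runif(50, 0, 5)
  for (ct in c(0, vals[1:5], 5)) {
    expect_identical(binarize_reference(vals, ct), vals > ct)
  }
})

test_that("paired_samples parses both binary codings and rejects junk", {
  a <- paired_samples(c(1, 2), c(0, 1))
  b <- paired_samples(c(1, 2), c("neg", "pos"))
  d <- paired_samples(c(1, 2), c("Negative", "POSITIVE"))
  expect_identical(a$index_result, b$index_result)
  expect_identical(a$index_result, d$index_result)
  expect_error(paired_samples(c(1, 2), c("yes", "no")), "unrecognized")
  expect_error(paired_samples(c(-1, 2), c(0, 1)), class = "mpxcutoff_domain_error")
})

test_that("performance_at_cutoff computes the inverted confusion matrix", {
  p <- four_pairs()
  at06 <- performance_at_cutoff(p, 0.6)
  expect_equal(as.numeric(at06[c("tp", "fp", "tn", "fn")]), c(2, 0, 2, 0))
  expect_equal(as.numeric(at06[c("sensitivity", "specificity", "accuracy")]),
               c(1, 1, 1))
  at15 <- performance_at_cutoff(p, 1.5)
  expect_equal(as.numeric(at15[c("tp", "fp", "tn", "fn")]), c(1, 1, 2, 0))
  expect_equal(at15$sensitivity, 1)
  expect_equal(at15$specificity, 2 / 3)
  expect_equal(at15$accuracy, 3 / 4)
  expect_error(performance_at_cutoff(paired_samples(numeric(0), integer(0)), 1),
               class = "mpxcutoff_domain_error")
})

test_that("empty denominator classes yield NA rates, not zeros", {
  all_pos <- paired_samples(c(1, 2, 3), c(1, 1, 1))
  low <- performance_at_cutoff(all_pos, 0.5)   # nobody below cutoff
  expect_equal(low$sensitivity, 1)
  expect_true(is.na(low$specificity))
  high <- performance_at_cutoff(all_pos, 3)    # nobody above cutoff (strict)
  expect_true(is.na(high$sensitivity))
})

test_that("confusion counts obey the conservation laws on random inputs", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_pairs(sample(5:80, 1), tie_grid = sample(c(NA, 0, 1), 1))
    ct <- runif(1, -1, 11)
    perf <- performance_at_cutoff(p, ct)
    expect_identical(perf$tp + perf$fn, sum(p$reference_value > ct))
    expect_identical(perf$tn + perf$fp, sum(p$reference_value <= ct))
    expect_identical(perf$tp + perf$fp + perf$tn + perf$fn, nrow(p))
    expect_equal(perf$accuracy, (perf$tp + perf$tn) / nrow(p))
  }
})

test_that("sweep_cutoffs covers the default ten-point grid and deduplicates", {
  p <- four_pairs()
  sw <- sweep_cutoffs(p)
  expect_identical(nrow(sw), 10L)
  expect_equal(sw$cutoff, seq(0.1, 1, by = 0.1))
  single <- sweep_cutoffs(p, 0.6)
  expect_equal(as.data.frame(single), as.data.frame(performance_at_cutoff(p, 0.6)))
  expect_warning(dup <- sweep_cutoffs(p, c(0.3, 0.6, 0.3)), "duplicate")
  expect_equal(dup$cutoff, c(0.3, 0.6))  # set-unique, sorted
})

test_that("roc_points spans the degenerate corners", {
  # deterministic threshold detector: perfect agreement geometry
  set.seed(55)
  ref <- runif(40, 0, 4)
  p <- paired_samples(ref, as.integer(ref > 1.7))
  roc <- roc_points(p)
  expect_true(any(roc$fpr == 0 & roc$sensitivity == 0))
  expect_true(any(roc$fpr == 0 & roc$sensitivity == 1))
  expect_true(any(roc$fpr == 1 & roc$sensitivity == 1))
  # one candidate per distinct value plus the below-minimum sentinel
  expect_identical(nrow(roc), length(unique(ref)) + 1L)
})

test_that("an uninformative index test hugs the diagonal", {
  set.seed(77)
  n <- 4000
  p <- paired_samples(runif(n, 0, 10), rbinom(n, 1, 0.5))
  est <- delong_auc(p)
  expect_lt(abs(est$auc - 0.5), 3 * est$se)
  # points with adequately filled denominator classes sit near sens = fpr;
  # extreme cutoffs have tiny denominators and are excluded from the check
  roc <- roc_points(p)
  q <- quantile(p$reference_value, c(0.05, 0.95))
  mid <- roc$cutoff > q[1] & roc$cutoff < q[2]
  expect_lt(max(abs(roc$sensitivity[mid] - roc$fpr[mid])), 0.1)
})

test_that("distinct confusion matrices are at most n_distinct + 1", {
  set.seed(13)
  for (i in 1:10) {
    p <- random_pairs(sample(5:40, 1), tie_grid = 0)
    v <- sort(unique(p$reference_value))
    cand <- c(v[1] / 2 - 1, v)
    mats <- unique(do.call(rbind, lapply(cand, function(ct) {
      performance_at_cutoff(p, ct)[, c("tp", "fp", "tn", "fn")]
    })))
    expect_lte(nrow(mats), length(v) + 1L)
  }
})

test_that("delong_auc equals exhaustive midrank pair counting", {
  # perfect separation
  sep <- paired_samples(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))
  expect_identical(delong_auc(sep)$auc, 1)
  # pure ties
  tied <- paired_samples(rep(2, 6), c(1, 1, 1, 0, 0, 0))
  expect_identical(delong_auc(tied)$auc, 0.5)
  # mixed ties: enumerate the six pairs by hand -> (1+0+1+0.5+1+1)/6
  mixed <- paired_samples(c(2, 5, 9, 1, 5), c(1, 1, 1, 0, 0))
  expect_equal(delong_auc(mixed)$auc, 4.5 / 6, tolerance = 1e-15)
  expect_equal(delong_auc(mixed)$auc, oracle_auc(c(2, 5, 9), c(1, 5)),
               tolerance = 1e-15)
  expect_error(delong_auc(paired_samples(c(1, 2), c(1, 1))),
               class = "mpxcutoff_domain_error")
})

test_that("confidence intervals bracket the estimate and respect [0, 1]", {
  set.seed(2)
  p <- make_lognormal_pairs(60, 40, 2.5)
  wald <- delong_auc(p, ci = "wald")
  logit <- delong_auc(p, ci = "logit")
  for (est in list(wald, logit)) {
    expect_lte(est$ci_low, est$auc)
    expect_gte(est$ci_high, est$auc)
    expect_gte(est$ci_low, 0)
    expect_lte(est$ci_high, 1)
  }
  expect_lt(logit$ci_high, 1)  # logit CI cannot touch the boundary
  narrow <- delong_auc(p, level = 0.5)
  expect_lt(narrow$ci_high - narrow$ci_low, wald$ci_high - wald$ci_low)
})

test_that("optimal_cutoff maximizes Youden's J with lower-cutoff ties", {
  sweep <- data.frame(
    cutoff = c(0.2, 0.4, 0.6),
    tp = 1, fp = 1, tn = 1, fn = 1,
    sensitivity = c(0.5, 0.94, 0.6),
    specificity = c(0.7, 0.94, 0.9),
    accuracy = c(0.6, 0.94, 0.75)
  )
  expect_identical(optimal_cutoff(sweep)$cutoff, 0.4)
  tie <- sweep
  tie$sensitivity <- c(0.9, 0.8, 0.9)
  tie$specificity <- c(0.8, 0.9, 0.8)
  expect_identical(optimal_cutoff(tie)$cutoff, 0.2)
  # undefined rows never compete
  nas <- sweep
  nas$specificity[2] <- NA
  expect_identical(optimal_cutoff(nas)$cutoff, 0.6)
  nas$specificity <- NA_real_
  expect_error(optimal_cutoff(nas), class = "mpxcutoff_domain_error")
  # alternative criteria
  expect_identical(optimal_cutoff(sweep, "accuracy")$cutoff, 0.4)
  expect_identical(optimal_cutoff(sweep, "closest_topleft")$cutoff, 0.4)
})

test_that("a step detector's optimal cutoff recovers the true threshold", {
  cfg <- default_table4_config(5000, seed = 321, detection_mid = 0.4,
                               detection_slope = 0)
  sw <- sweep_cutoffs(sample_cohort(cfg))
  expect_equal(optimal_cutoff(sw)$cutoff, 0.4)
})

test_that("sweep sensitivity is monotone for a deterministic threshold detector", {
  cfg <- default_table4_config(3000, seed = 654, detection_mid = 0.5,
                               detection_slope = 0)
  sw <- sweep_cutoffs(sample_cohort(cfg))
  sens <- sw$sensitivity[!is.na(sw$sensitivity)]
  expect_true(all(diff(sens) >= -1e-12))
})
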