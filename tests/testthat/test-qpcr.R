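perfect_standards <- function(slope, intercept, reps = 3) {
  conc <- rep(10^(1:6), each = reps)
  data.frame(copies_per_ul = conc, ct = slope * log10(conc) + intercept)
}

test_that("fit_calibration recovers an exact standard line", {
  slope_2fold <- -1 / log10(2)  # perfect doubling per cycle, ~ -3.3219
  cal <- fit_calibration(perfect_standards(slope_2fold, 40))
  expect_equal(cal$slope, slope_2fold, tolerance = 1e-12)
  expect_equal(cal$intercept, 40, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$efficiency, 1, tolerance = 1e-12)
  expect_identical(cal$n_points, 18L)
})

test_that("efficiency follows 10^(-1/slope) - 1 and flags the QC window", {
  expect_warning(
    cal <- fit_calibration(perfect_standards(-3.6, 38)),
    "90-110"
  )
  expect_equal(cal$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-12)
  expect_equal(cal$efficiency, 0.8957, tolerance = 1e-4)
  expect_silent(fit_calibration(perfect_standards(-3.4, 38)))  # eff ~ 96.9%
})

test_that("fit with replicate scatter matches the normal-equations oracle", {
  set.seed(42)
  for (i in 1:5) {
    std <- perfect_standards(-3.3, 39)
    std$ct <- std$ct + rnorm(nrow(std), sd = 0.3)
    cal <- fit_calibration(std)
    ora <- oracle_lsq(log10(std$copies_per_ul), std$ct)
    expect_equal(cal$slope, ora$slope, tolerance = 1e-9)
    expect_equal(cal$intercept, ora$intercept, tolerance = 1e-9)
    expect_equal(cal$r_squared, ora$r_squared, tolerance = 1e-9)
  }
})

test_that("fit_calibration rejects unusable input", {
  two_levels <- data.frame(copies_per_ul = c(10, 10, 100), ct = c(36, 36.1, 33))
  expect_error(fit_calibration(two_levels), "3 distinct concentration levels")
  rising <- data.frame(copies_per_ul = 10^(1:4), ct = c(30, 32, 34, 36))
  expect_error(fit_calibration(rising), "slope")
  bad_ct <- perfect_standards(-3.3, 39); bad_ct$ct[1] <- NA
  expect_error(fit_calibration(bad_ct), "finite")
})

test_that("ct_to_copies inverts the calibration line", {
  cal <- fit_calibration(perfect_standards(-3.3219, 40))
  expect_equal(ct_to_copies(cal, 40), 1, tolerance = 1e-9)
  expect_equal(ct_to_copies(cal, 36.6781), 10, tolerance = 1e-9)
  expect_equal(ct_to_copies(cal, 23.3905), 1e5, tolerance = 1e-4)
  expect_identical(ct_to_copies(cal, NA_real_), 0)  # undetermined well
})

test_that("round-trip ct -> copies is exact for fitted curves", {
  set.seed(7)
  for (i in 1:5) {
    std <- perfect_standards(runif(1, -3.8, -3.1), runif(1, 36, 42))
    std$ct <- std$ct + rnorm(nrow(std), sd = 0.2)
    cal <- suppressWarnings(fit_calibration(std))
    conc <- 10^runif(8, 0, 7)
    predicted_ct <- cal$slope * log10(conc) + cal$intercept
    expect_equal(ct_to_copies(cal, predicted_ct), conc, tolerance = 1e-9)
  }
})

test_that("percent_is applies the ratio x 100 x conversion factor", {
  expect_identical(percent_is(0, 1e5), 0)
  expect_equal(percent_is(100, 100, 0.5), 50)
  expect_equal(percent_is(542, 1e5, 0.542), 0.293764, tolerance = 1e-12)
  expect_error(percent_is(10, 0), "ABL1")
  # scale equivariance: common factors cancel
  expect_equal(percent_is(3 * 542, 3 * 1e5, 0.542), percent_is(542, 1e5, 0.542))
})

test_that("quantify_sample sums duplicate wells per target", {
  bcr_cal <- fit_calibration(perfect_standards(-3.35, 39.5))
  abl_cal <- fit_calibration(perfect_standards(-3.3, 38.8))

  # non-detection of the fusion target is a valid zero-burden sample
  q0 <- quantify_sample(c(NA, NA), c(24, 24.1), bcr_cal, abl_cal)
  expect_identical(q0$percent_is, 0)
  expect_true(q0$valid)

  # identical duplicates equal the single-well computation (sums cancel)
  q1 <- quantify_sample(c(30, 30), c(25, 25), bcr_cal, abl_cal)
  single <- percent_is(ct_to_copies(bcr_cal, 30), ct_to_copies(abl_cal, 25))
  expect_equal(q1$percent_is, single, tolerance = 1e-12)

  # mixed duplicates match the per-well oracle
  q2 <- quantify_sample(c(29.2, 30.4), c(24.6, 25.3), bcr_cal, abl_cal)
  ora <- percent_is(sum(10^((c(29.2, 30.4) - bcr_cal$intercept) / bcr_cal$slope)),
                    sum(10^((c(24.6, 25.3) - abl_cal$intercept) / abl_cal$slope)))
  expect_equal(q2$percent_is, ora, tolerance = 1e-12)

  # control-gene failure has no denominator
  expect_error(quantify_sample(c(30, 30), c(NA, NA), bcr_cal, abl_cal),
               "ABL1 control wells undetermined")

  # low ABL1 input trips the validity floor but still computes
  qlow <- quantify_sample(c(30, 30), c(33, 33), bcr_cal, abl_cal, abl1_floor = 1e4)
  expect_false(qlow$valid)
  expect_gt(qlow$percent_is, 0)
})

test_that("quantify_cohort processes a per-well Ct table with QC flags", {
  cal_csv <- withr::local_tempfile(fileext = ".csv")
  std <- rbind(cbind(target = "BCR_ABL1", perfect_standards(-3.35, 39.5)),
               cbind(target = "ABL1", perfect_standards(-3.3, 38.8)))
  write.csv(std, cal_csv, row.names = FALSE)
  curves <- read_calibration_csv(cal_csv)
  expect_named(curves, c("ABL1", "BCR_ABL1"))

  wells <- data.frame(
    sample_id = rep(c("P1", "P2", "P3"), each = 4),
    target = rep(c("BCR::ABL1", "BCR::ABL1", "ABL1", "ABL1"), 3),
    replicate = rep(1:2, 6),
    ct = c(30.1, 30.3, 24.0, 24.2,      # ordinary positive sample
           "Undetermined", "Undetermined", 24.5, 24.4,  # fusion non-detection
           31.0, 30.8, "Undetermined", "Undetermined")  # control failure
  )
  out <- quantify_cohort(wells, curves)
  expect_identical(out$sample_id, c("P1", "P2", "P3"))
  expect_true(out$valid[1] && out$percent_is[1] > 0)
  expect_identical(out$percent_is[2], 0)
  expect_false(out$valid[3])
  expect_true(is.na(out$percent_is[3]))
})
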