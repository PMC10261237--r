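# Diagnostic amplicon sizes (bp) of the multiplex reaction: the major
# breakpoint fusions b2a2/b3a2, the minor e1a2, the micro e19a2, two rare
# variants, and the wild-type BCR internal amplification control at 808 bp.
MPX_EXPECTED_BANDS <- c(
  b2a2 = 310, b3a2 = 385, e1a2 = 481, control = 808,
  e19a2 = 927, e6a2 = 1125, e8a2 = 1319
)

#' Classify a gel band pattern into a transcript call
#'
#' Matches each observed fragment length to the nearest expected amplicon size
#' within a fractional tolerance and derives the run-level interpretation:
#'
#' * a matched 808 bp band sets `control_present` (wild-type BCR internal
#'   control, evidence the reaction worked);
#' * any matched fusion-size band sets `variant` (when several fusion bands
#'   co-occur the largest amplicon is reported, with a warning);
#' * a lane with neither a fusion band nor the control band is an **invalid**
#'   run (total amplification failure);
#' * a lane with the control only is a valid **negative**;
#' * a lane with a fusion band is a valid **positive** — by default even
#'   without the control band, since fusion amplification itself demonstrates
#'   a working reaction; set `strict_control = TRUE` to require the control
#'   band for validity.
#'
#' The default tolerance of 3% is far below the ~22% relative gap between the
#' two closest expected sizes (310 vs 385 bp), so no band can legally match
#' two targets; a band that nonetheless falls within tolerance of two expected
#' sizes (possible only with a large tolerance) is an error.
#'
#' @param band_sizes numeric vector of observed fragment lengths in bp (may be
#'   empty for a blank lane); all entries must be positive.
#' @param tolerance fractional size tolerance in `(0, 0.1]`; default 0.03.
#' @param strict_control if `TRUE`, a fusion band without the 808 bp control
#'   is scored invalid instead of positive.
#' @param sample_id optional identifier carried into the result.
#' @return Object of class `transcript_call`: list with `sample_id`,
#'   `variant` (one of `b2a2, b3a2, e1a2, e19a2, e6a2, e8a2, none`),
#'   `control_present`, `valid`, `binary_result`
#'   (`"positive"/"negative"/"invalid"`), `matched_bands`.
#' @examples
#' classify_bands(c(385, 808))   # b3a2, valid positive
#' classify_bands(808)           # valid negative
#' classify_bands(numeric(0))    # invalid run
#' @export
classify_bands <- function(band_sizes, tolerance = 0.03,
                           strict_control = FALSE, sample_id = NA_character_) {
  assert_scalar_number(tolerance, "tolerance", lower = 1e-12, upper = 0.1)
  band_sizes <- as.numeric(band_sizes)
  if (any(!is.finite(band_sizes)) || any(band_sizes <= 0)) {
    stopf("all band sizes must be positive and finite")
  }
  expected <- MPX_EXPECTED_BANDS
  matched <- character(0)
  for (b in band_sizes) {
    within <- abs(b - expected) <= tolerance * expected
    if (sum(within) > 1L) {
      stopf("ambiguous band: %g bp lies within tolerance of %s",
            b, paste(names(expected)[within], collapse = " and "))
    }
    if (any(within)) matched <- c(matched, names(expected)[within])
  }
  matched <- unique(matched)
  control_present <- "control" %in% matched
  fusions <- setdiff(matched, "control")
  if (length(fusions) > 1L) {
    warning(sprintf("multiple fusion bands in one lane (%s); reporting the largest amplicon",
                    paste(fusions, collapse = ", ")), call. = FALSE)
  }
  variant <- if (length(fusions) == 0L) "none" else {
    fusions[which.max(expected[fusions])]
  }
  valid <- if (variant != "none") {
    !strict_control || control_present
  } else {
    control_present
  }
  binary <- if (!valid) "invalid" else if (variant != "none") "positive" else "negative"
  structure(
    list(sample_id = sample_id, variant = variant,
         control_present = control_present, valid = valid,
         binary_result = binary, matched_bands = matched),
    class = "transcript_call"
  )
}

#' @export
print.transcript_call <- function(x, ...) {
  cat(sprintf("<transcript_call> %s: %s (control %s) -> %s\n",
              ifelse(is.na(x$sample_id), "?", x$sample_id), x$variant,
              if (x$control_present) "present" else "absent", x$binary_result))
  invisible(x)
}

#' Fraction of valid assay runs in a cohort
#'
#' @param calls list of [classify_bands()] results (or any list of objects
#'   with a logical `valid` field).
#' @return fraction of valid runs in `[0, 1]`.
#' @examples
#' calls <- list(classify_bands(808), classify_bands(numeric(0)))
#' cohort_validity_rate(calls)  # 0.5
#' @export
cohort_validity_rate <- function(calls) {
  if (length(calls) == 0) stop_domain("cannot compute a validity rate for an empty cohort")
  mean(vapply(calls, function(x) isTRUE(x$valid), logical(1)))
}

#' Classify a band-pattern CSV
#'
#' Input schema: `sample_id, band_sizes` where `band_sizes` is a
#' semicolon-separated list of fragment lengths in bp (empty = blank lane).
#'
#' @param input data.frame with that schema, or a CSV path.
#' @inheritParams classify_bands
#' @return data.frame: `sample_id, variant, control_present, valid,
#'   binary_result`.
#' @export
classify_bands_table <- function(input, tolerance = 0.03, strict_control = FALSE) {
  if (is.character(input)) {
    path <- input
    if (!file.exists(path)) stopf("band file not found: %s", path)
    input <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  missing <- setdiff(c("sample_id", "band_sizes"), names(input))
  if (length(missing) > 0) {
    stopf("band table: missing required column(s): %s", paste(missing, collapse = ", "))
  }
  calls <- lapply(seq_len(nrow(input)), function(i) {
    raw <- input$band_sizes[i]
    bands <- if (is.na(raw) || !nzchar(trimws(raw))) numeric(0) else {
      as.numeric(strsplit(trimws(raw), "[;,[:space:]]+")[[1]])
    }
    classify_bands(bands, tolerance, strict_control, sample_id = input$sample_id[i])
  })
  data.frame(
    sample_id = vapply(calls, `[[`, character(1), "sample_id"),
    variant = vapply(calls, `[[`, character(1), "variant"),
    control_present = vapply(calls, `[[`, logical(1), "control_present"),
    valid = vapply(calls, `[[`, logical(1), "valid"),
    binary_result = vapply(calls, `[[`, character(1), "binary_result"),
    stringsAsFactors = FALSE
  )
}
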