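# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base \code{round()} uses banker's rounding (round half to even); cohort
#' tables in the molecular-monitoring literature use conventional half-up
#' rounding (22.35 -> 22.4), so percentages and ratios are rounded with this
#' helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(22.35, 1)  # 22.4, where round() gives 22.3 or 22.4
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Keeps the generators free of global
# side effects without adding a dependency.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("mpxcutoff_domain_error", "error")))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("`%s` must lie in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}
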