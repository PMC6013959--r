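# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("configuration error: `", name, "` must be a probability in [0, 1]",
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (if (positive) x >= 1 else x >= 0)
  if (!ok) {
    stop("configuration error: `", name, "` must be a ",
         if (positive) "positive" else "nonnegative", " integer", call. = FALSE)
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop("configuration error: `", name, "` must be a positive number",
         call. = FALSE)
  }
  invisible(x)
}

# Percentage of a count over a total, rounded for reporting.
#' Report a proportion as a percentage
#'
#' Small arithmetic helper used by [cohort_summary()] to turn raw counts into
#' the percentages reported in cohort tables (e.g. 6374 flagged of 27,334
#' admissions is 23.3%).
#'
#' @param numerator Count of events.
#' @param denominator Total count; must be positive.
#' @param digits Decimal places to round the percentage to (default 1).
#' @return A single number, `round(100 * numerator / denominator, digits)`.
#' @examples
#' rate_percent(6374, 27334) # 23.3
#' @export
rate_percent <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  round(100 * numerator / denominator, digits)
}
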