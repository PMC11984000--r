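#' @keywords internal
"_PACKAGE"

# Round half away from zero, the convention used for reported percentages.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vu_stop <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && abs(x - round(x)) < 1e-8
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Percentage share of a count
#'
#' Expresses `count / total` as a percentage, rounded half away from zero.
#' Used for reported coverage and summary shares (e.g. the fraction of a
#' corpus that carries a text description).
#'
#' @param count Numerator count (non-negative).
#' @param total Denominator count (positive).
#' @param digits Decimal places to round to (default 2).
#' @return A single number, `100 * count / total` rounded to `digits`.
#' @examples
#' share_pct(8963, 9873)  # 90.78
#' @export
share_pct <- function(count, total, digits = 2) {
  if (!is_count(count) || !is.numeric(total) || total <= 0) {
    vu_stop("share_pct() needs a nonnegative count and a positive total")
  }
  round_half_up(100 * count / total, digits)
}

# Run code with a private RNG stream, restoring the caller's stream after.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
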