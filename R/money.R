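#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to the IEEE half-to-even rule
#' used by [base::round()]. All monetary reporting in this package goes
#' through this function: staff-line costs are rounded to cents, annual cost
#' and income cells to whole dollars. A relative epsilon guards against
#' binary floating-point representation of decimal inputs (e.g. `0.1 * 3`).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(261.1476, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  v <- x * p
  floor(abs(v) + 0.5 + abs(v) * 1e-12) * sign(v) / p
}

# cents: per-line clinic costs; dollars: annual report cells
round_money <- function(x) round_half_up(x, 2)
round_dollars <- function(x) round_half_up(x, 0)

# validation condition with a path into the offending document/object
abort_validation <- function(msg, path = NULL) {
  if (!is.null(path) && nzchar(path)) msg <- sprintf("%s: %s", path, msg)
  stop(structure(
    class = c("teleroi_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

check_nonneg <- function(value, what, path = NULL) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value < 0) {
    abort_validation(sprintf("%s must be a single non-negative number, got %s",
                             what, paste(format(value), collapse = ", ")), path)
  }
  invisible(value)
}

check_proportion <- function(value, what, path = NULL) {
  check_nonneg(value, what, path)
  if (value > 1) abort_validation(sprintf("%s must lie in [0, 1], got %g", what, value), path)
  invisible(value)
}
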