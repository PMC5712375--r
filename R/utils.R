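#' Round half away from zero
#'
#' Standard commercial rounding: ties go away from zero rather than to the
#' nearest even digit (which is what [base::round()] does). Reported
#' performance indices use this convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.925, 2) # 0.93
#' round(0.925, 2)         # 0.92 under banker's rounding
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# abort with a classed condition so tests can target specific failures
stop_gaitbci <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gaitbci_error"))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_gaitbci(sprintf("%s contains non-finite values", what),
                 "gaitbci_validation_error")
  }
  invisible(x)
}

# run-length helper: lengths and values of maximal runs in a logical vector
runs_of <- function(x) {
  r <- rle(as.logical(x))
  tibble::tibble(value = r$values, length = r$lengths)
}
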