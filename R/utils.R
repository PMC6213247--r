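# internal helpers shared across modules

#' Round half away from zero
#'
#' Printed tables round 5 upward (`0.065 -> 0.07`), unlike [base::round()]'s
#' round-half-even. Used whenever a computed quantity is compared against a
#' printed cell at its printed precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# diet-group labels used throughout; "HFHS+w3" is the fish-oil supplemented arm
diet_groups <- function() c("STD", "HFHS", "HFHS+w3")

stop_if_not_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}
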