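#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed clinical tables
#' conventionally round half up. Used for all 1-decimal table reporting.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

upper_tri_pairs <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
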