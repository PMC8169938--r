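#' @keywords internal
.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)) ||
      any(x <= 0)) {
    stop("invalid input: `", name, "` must be a positive finite number",
         call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
.check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
      any(x < lo) || any(x > hi)) {
    stop("invalid input: `", name, "` must lie in [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  invisible(x)
}

#' Unit conversions used at the reporting layer
#'
#' Internal computations are strictly SI; these helpers convert to the units
#' conventional in small-scale pump work.
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
flow_m3s_to_ulps <- function(x) x * 1e9

#' @rdname units
#' @export
flow_ulps_to_mlmin <- function(x) x * 0.06

#' @rdname units
#' @export
viscosity_pas_to_cp <- function(x) x * 1e3

#' @rdname units
#' @export
viscosity_cp_to_pas <- function(x) x * 1e-3
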