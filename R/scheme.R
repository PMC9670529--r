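#' Diffusion-weighting scheme
#'
#' A b-value scheme pairs the diffusion weightings of a multi-b-value DWI
#' acquisition with the number of signal averages (NEX) acquired at each
#' weighting.  Averaging reduces the effective noise standard deviation at a
#' given b-value by `1/sqrt(averages)`.
#'
#' @param b_values numeric vector of diffusion weightings in s/mm^2;
#'   must start at 0 and be strictly increasing.
#' @param averages positive integer vector of signal-average counts, one per
#'   b-value.  Defaults to one average everywhere.
#' @return an object of class `bvalue_scheme` (a list with elements
#'   `b_values` and `averages`).
#' @examples
#' sch <- bvalue_scheme(c(0, 200, 400, 800), c(1, 1, 2, 3))
#' length(sch)
#' @export
bvalue_scheme <- function(b_values, averages = rep(1L, length(b_values))) {
  if (!is.numeric(b_values) || length(b_values) < 2L) {
    stop("`b_values` must be a numeric vector of length >= 2")
  }
  if (b_values[1L] != 0) {
    stop("the first b-value must be 0 (unweighted image)")
  }
  if (any(diff(b_values) <= 0)) {
    stop("`b_values` must be strictly increasing")
  }
  if (length(averages) != length(b_values)) {
    stop("`averages` must have the same length as `b_values`")
  }
  if (any(averages < 1) || any(averages != round(averages))) {
    stop("`averages` must be positive integers")
  }
  structure(
    list(b_values = as.numeric(b_values), averages = as.integer(averages)),
    class = "bvalue_scheme"
  )
}

#' Default ten-point knee DWI scheme
#'
#' b = 0/50/100/150/200/300/400/600/800/1000 s/mm^2 with
#' 1/1/1/1/1/1/2/2/3/3 signal averages, i.e. one average up to b = 300,
#' two at b = 400 and 600, three at b = 800 and 1000.
#'
#' @return a [bvalue_scheme()].
#' @export
default_bvalue_scheme <- function() {
  bvalue_scheme(
    b_values = c(0, 50, 100, 150, 200, 300, 400, 600, 800, 1000),
    averages = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L)
  )
}

#' @export
length.bvalue_scheme <- function(x) length(x$b_values)

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("b-value scheme (", length(x), " weightings)\n", sep = "")
  cat("  b (s/mm^2):", paste(x$b_values, collapse = "/"), "\n")
  cat("  averages:  ", paste(x$averages, collapse = "/"), "\n")
  invisible(x)
}

#' One measured signal-vs-b curve
#'
#' @param scheme a [bvalue_scheme()].
#' @param signal non-negative numeric vector of signal intensities
#'   (arbitrary units), one per b-value.
#' @return an object of class `signal_curve`.
#' @export
signal_curve <- function(scheme, signal) {
  if (!inherits(scheme, "bvalue_scheme")) stop("`scheme` must be a bvalue_scheme")
  if (length(signal) != length(scheme)) {
    stop("`signal` must have one value per b-value")
  }
  if (any(!is.finite(signal)) || any(signal < 0)) {
    stop("signal intensities must be finite and non-negative")
  }
  structure(list(scheme = scheme, signal = as.numeric(signal)),
            class = "signal_curve")
}
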