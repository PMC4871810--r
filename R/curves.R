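#' Raw and normalized denaturation curves
#'
#' A `raw_curve` carries the as-recorded CD signal (ellipticity at 222 nm,
#' arbitrary units) versus denaturant together with its baseline parameters:
#' `alpha_N`, the y-intercept of the native baseline; `alpha_D` and `beta_D`,
#' intercept and slope of the denatured baseline. [normalize_curve()] maps it
#' to a `denaturation_curve` on the normalized 0 (native) to 1 (denatured)
#' scale via
#' \deqn{y(D) = \frac{signal - \alpha_N}{\alpha_D + \beta_D D - \alpha_N},}
#' which deliberately retains any slope of the native baseline (terminal
#' fraying) in the normalized data.
#'
#' @param construct_id construct identifier.
#' @param D denaturant concentrations, M GuHCl, non-negative.
#' @param signal raw CD signal values, same length as `D`.
#' @param alpha_N native-baseline intercept.
#' @param alpha_D denatured-baseline intercept.
#' @param beta_D denatured-baseline slope (default 0; the denatured-baseline
#'   slopes of the CTPR constructs were not significant).
#' @return `raw_curve()` an object of class `raw_curve`.
#' @export
raw_curve <- function(construct_id, D, signal, alpha_N, alpha_D, beta_D = 0) {
  stopifnot(length(D) == length(signal), all(is.finite(D)), all(is.finite(signal)))
  if (any(D < 0)) stop("denaturant concentrations must be >= 0", call. = FALSE)
  ord <- order(D)
  structure(list(construct_id = construct_id, D = D[ord], signal = signal[ord],
                 alpha_N = alpha_N, alpha_D = alpha_D, beta_D = beta_D),
            class = "raw_curve")
}

#' @rdname raw_curve
#' @param x denaturant concentrations, M GuHCl.
#' @param y normalized signal values.
#' @return `denaturation_curve()` an object of class `denaturation_curve`.
#' @export
denaturation_curve <- function(construct_id, x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0)) stop("denaturant concentrations must be >= 0", call. = FALSE)
  ord <- order(x)
  structure(list(construct_id = construct_id, x = x[ord], y = y[ord]),
            class = "denaturation_curve")
}

#' @export
print.denaturation_curve <- function(x, ...) {
  cat("Denaturation curve ", x$construct_id, ": ", length(x$x),
      " points, x in [", min(x$x), ", ", max(x$x), "] M\n", sep = "")
  invisible(x)
}

#' @export
print.raw_curve <- function(x, ...) {
  cat("Raw denaturation curve ", x$construct_id, ": ", length(x$D),
      " points; baselines alpha_N = ", x$alpha_N, ", alpha_D = ", x$alpha_D,
      ", beta_D = ", x$beta_D, "\n", sep = "")
  invisible(x)
}

#' @rdname raw_curve
#' @param raw a `raw_curve`.
#' @export
#' @examples
#' r <- raw_curve("CTPR2", c(0, 2, 4), c(-20, -11, -1.6),
#'                alpha_N = -20, alpha_D = -2, beta_D = 0.1)
#' normalize_curve(r)$y
normalize_curve <- function(raw) {
  stopifnot(inherits(raw, "raw_curve"))
  denom <- raw$alpha_D + raw$beta_D * raw$D - raw$alpha_N
  if (any(abs(denom) < 1e-12))
    stop("normalization denominator vanishes within the data range",
         call. = FALSE)
  denaturation_curve(raw$construct_id, raw$D, (raw$signal - raw$alpha_N) / denom)
}
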