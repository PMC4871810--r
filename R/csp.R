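#' Combined amide chemical-shift perturbation
#'
#' Weighted combination of the proton and nitrogen chemical-shift differences
#' of an amide cross-peak between two HSQC spectra:
#' \deqn{\Delta\delta = \sqrt{(\delta_H^2 + (\alpha\,\delta_N)^2) / 2},}
#' with the nitrogen scaling factor `alpha` defaulting to 0.14. Symmetric in
#' the sign of both inputs.
#'
#' @param dH proton chemical-shift difference, ppm.
#' @param dN nitrogen chemical-shift difference, ppm.
#' @param alpha nitrogen scaling factor.
#' @return non-negative perturbation(s), ppm.
#' @export
#' @examples
#' csp(0.1, 0.5)
csp <- function(dH, dN, alpha = 0.14) {
  stopifnot(all(is.finite(dH)), all(is.finite(dN)))
  sqrt((dH^2 + (alpha * dN)^2) / 2)
}

#' Classify HSQC cross-peaks by perturbation
#'
#' Classifies each residue's amide cross-peak between a reference and a
#' perturbed spectrum as `"unchanged"` (\eqn{\Delta\delta \le} the
#' `unchanged_max` threshold, boundary inclusive), `"moved"`, or `"lost"`
#' (peak disappeared or moved into a crowded region; the lost flag dominates
#' any computable perturbation). Perturbations above `moved_max` are still
#' `"moved"`: that bound is the observed colour-scale maximum, not a rule.
#'
#' @param shifts data.frame with columns `residue_id`, `dH`, `dN` and
#'   logical `lost`.
#' @param unchanged_max upper bound of the unchanged class, ppm.
#' @param moved_max colour-scale ceiling recorded alongside the class, ppm.
#' @param alpha nitrogen scaling factor passed to [csp()].
#' @return the input data.frame with columns `delta` (combined perturbation,
#'   `NA` for lost peaks) and `class` (factor unchanged/moved/lost).
#' @export
#' @examples
#' classify_peaks(data.frame(residue_id = c("K5", "A6"),
#'                           dH = c(0.01, 0.2), dN = c(0.1, 0.3),
#'                           lost = c(FALSE, FALSE)))
classify_peaks <- function(shifts, unchanged_max = 0.04, moved_max = 0.22,
                           alpha = 0.14) {
  stopifnot(is.data.frame(shifts),
            all(c("residue_id", "dH", "dN", "lost") %in% names(shifts)),
            unchanged_max > 0, moved_max > unchanged_max)
  lost <- as.logical(shifts$lost)
  delta <- ifelse(lost, NA_real_, csp(ifelse(lost, 0, shifts$dH),
                                      ifelse(lost, 0, shifts$dN), alpha))
  cls <- ifelse(lost, "lost",
                ifelse(delta <= unchanged_max, "unchanged", "moved"))
  shifts$delta <- delta
  shifts$class <- factor(cls, levels = c("unchanged", "moved", "lost"))
  attr(shifts, "thresholds") <- c(unchanged_max = unchanged_max,
                                  moved_max = moved_max)
  shifts
}
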