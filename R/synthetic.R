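#' Recipe for a synthetic deletion-series experiment
#'
#' Bundles a ground-truth [energy_model()], a list of construct topologies,
#' the denaturant sampling, the per-point Gaussian noise level and a seed.
#' [generate_series()] then emulates a full normalized equilibrium titration
#' of the series: for every construct and replicate,
#' `y(x) = 1 - fraction_folded(x) + N(0, noise_sd)`.
#'
#' Defaults emulate a CTPR-like campaign: 40-point titrations on 0-6 M
#' GuHCl, duplicate denaturations, homoscedastic noise at 2% of the
#' normalized amplitude (the residual scale of real global fits).
#'
#' @param true_model the generating [energy_model()].
#' @param constructs list of [topology()] objects.
#' @param replicates replicate curves per construct (default 2).
#' @param x_grid denaturant sampling (default 40 points, 0-6 M).
#' @param noise_sd Gaussian noise standard deviation on the normalized
#'   signal (default 0.02).
#' @param seed integer RNG seed.
#' @return an object of class `series_recipe`.
#' @export
series_recipe <- function(true_model, constructs, replicates = 2L,
                          x_grid = seq(0, 6, length.out = 40L),
                          noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(true_model, "energy_model"),
            all(vapply(constructs, inherits, TRUE, "topology")),
            replicates >= 1L, noise_sd >= 0)
  structure(list(true_model = true_model, constructs = constructs,
                 replicates = as.integer(replicates), x_grid = x_grid,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "series_recipe")
}

#' Canonical six-construct CTPRn-like deletion series
#'
#' The full-length, dA and dS constructs of CTPR2 and CTPR3: the smallest
#' series that separates N-cap, internal and C-cap parameters.
#'
#' @param series passed to [build_topology()].
#' @return list of six [topology()] objects.
#' @export
ctpr_deletion_series <- function(series = "CTPRn") {
  specs <- expand.grid(n = 2:3, del = c("none", "dA", "dS"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(specs)), function(i)
    build_topology(specs$n[i], series,
                   n_cap = specs$del[i] != "dA",
                   c_cap = specs$del[i] != "dS"))
}

#' Generate noisy normalized curves from a recipe
#'
#' @param recipe a [series_recipe()].
#' @return list of [denaturation_curve()] objects, one per construct and
#'   replicate, reproducible from the recipe seed.
#' @export
#' @examples
#' rec <- series_recipe(ctprn_table1(), ctpr_deletion_series(),
#'                      replicates = 1, noise_sd = 0)
#' curves <- generate_series(rec)
generate_series <- function(recipe) {
  stopifnot(inherits(recipe, "series_recipe"))
  set.seed(recipe$seed)
  out <- list()
  for (top in recipe$constructs) {
    clean <- 1 - fraction_folded(top, recipe$true_model, recipe$x_grid)
    for (r in seq_len(recipe$replicates)) {
      y <- clean + rnorm(length(recipe$x_grid), sd = recipe$noise_sd)
      out[[length(out) + 1L]] <-
        denaturation_curve(top$construct_id, recipe$x_grid, y)
    }
  }
  names(out) <- make.unique(vapply(out, `[[`, "", "construct_id"))
  out
}

#' Generate raw (baseline-bearing) curves from a recipe
#'
#' Inverts the normalization mapping to synthesize raw ellipticity traces:
#' `signal = alpha_N + y * (alpha_D + beta_D * D - alpha_N)`, with `y` the
#' noisy normalized signal of [generate_series()] under the same seed, so
#' `normalize_curve(generate_raw_series(...))` round-trips exactly.
#'
#' @param recipe a [series_recipe()].
#' @param alpha_N,alpha_D,beta_D baseline parameters applied to every
#'   construct (defaults emulate CD ellipticity in millidegrees).
#' @return list of [raw_curve()] objects.
#' @export
generate_raw_series <- function(recipe, alpha_N = -20, alpha_D = -2,
                                beta_D = 0) {
  curves <- generate_series(recipe)
  lapply(curves, function(cv) {
    denom <- alpha_D + beta_D * cv$x - alpha_N
    if (any(abs(denom) < 1e-12))
      stop("baseline parameters give a vanishing normalization denominator",
           call. = FALSE)
    raw_curve(cv$construct_id, cv$x, alpha_N + cv$y * denom,
              alpha_N = alpha_N, alpha_D = alpha_D, beta_D = beta_D)
  })
}
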