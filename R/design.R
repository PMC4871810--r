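#' Simulate a normalized denaturation curve
#'
#' The model's prediction for a normalized chemical-denaturation curve is the
#' fraction unfolded, `1 - fraction_folded(x)`. The sloping pre-transition
#' baseline of constructs with frayed termini emerges from the model itself.
#'
#' @inheritParams partition_function
#' @param x_grid denaturant concentrations, M GuHCl, non-empty.
#' @return a [denaturation_curve()].
#' @export
simulate_curve <- function(top, model, x_grid = seq(0, 8, by = 0.01)) {
  if (length(x_grid) == 0L) stop("x_grid must be non-empty", call. = FALSE)
  denaturation_curve(top$construct_id, x_grid,
                     1 - fraction_folded(top, model, x_grid))
}

#' Midpoint of a (simulated or measured) denaturation curve
#'
#' Denaturant concentration at which the normalized signal crosses 0.5,
#' by linear interpolation on the curve grid.
#'
#' @param curve a [denaturation_curve()].
#' @return midpoint in M GuHCl (`NA` if the curve does not cross 0.5).
#' @export
curve_midpoint <- function(curve) {
  x <- curve$x
  y <- curve$y
  i <- which(y[-length(y)] < 0.5 & y[-1L] >= 0.5)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1L]
  x[i] + (0.5 - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
}

profile_from_popfun <- function(popfun, x_grid, construct_id) {
  pop <- popfun(x_grid)
  i <- which.max(pop)
  lo <- x_grid[max(1L, i - 1L)]
  hi <- x_grid[min(length(x_grid), i + 1L)]
  if (lo < hi) {
    opt <- optimize(popfun, c(lo, hi), maximum = TRUE, tol = 1e-6)
    beta <- opt$objective
    x_at_max <- opt$maximum
    if (pop[i] > beta) { beta <- pop[i]; x_at_max <- x_grid[i] }
  } else {
    beta <- pop[i]
    x_at_max <- x_grid[i]
  }
  alpha <- popfun(0)
  structure(list(construct_id = construct_id, x_grid = x_grid,
                 population = pop, alpha = alpha, beta = beta,
                 x_at_max = x_at_max, amplitude = beta - alpha),
            class = "intermediate_profile")
}

#' @export
print.intermediate_profile <- function(x, ...) {
  cat("Intermediate-state population profile",
      if (nzchar(x$construct_id)) paste0(" (", x$construct_id, ")"), "\n",
      sep = "")
  cat(sprintf("  alpha (population at 0 M): %.4f\n", x$alpha))
  cat(sprintf("  beta (maximum population): %.4f at %.3f M GuHCl\n",
              x$beta, x$x_at_max))
  cat(sprintf("  amplitude (beta - alpha):  %.4f\n", x$amplitude))
  invisible(x)
}

#' Population profile of the C-cap-unfolded intermediate
#'
#' The C-cap-unfolded intermediate is the exact conformation with every helix
#' folded except the C-cap S-helix. Its population typically rises from near
#' zero at 0 M denaturant to a maximum \eqn{\beta} at intermediate GuHCl and
#' falls again as the rest of the protein denatures. The profile records
#' \eqn{\alpha} (population at 0 M, the natively frayed fraction),
#' \eqn{\beta} (maximum, refined beyond the grid by golden-section search),
#' the concentration of the maximum, and the amplitude \eqn{\beta - \alpha}.
#'
#' With `min_folded_others` set, a relaxed definition is used instead: all
#' states with the C-cap unfolded and at least that many of the remaining
#' helices folded (computed by a count-resolved transfer matrix).
#'
#' @inheritParams simulate_curve
#' @param min_folded_others optional integer for the relaxed state set;
#'   `NULL` (default) keeps the exact single-state definition.
#' @return an object of class `intermediate_profile`.
#' @export
#' @examples
#' intermediate_profile(build_topology(3), ctprn_table1())
intermediate_profile <- function(top, model, x_grid = seq(0, 8, by = 0.01),
                                 min_folded_others = NULL) {
  n <- n_helices(top)
  if (top$helices[n] != "S")
    stop("topology has no C-cap S-helix", call. = FALSE)
  if (is.null(min_folded_others)) {
    folded <- c(rep(TRUE, n - 1L), FALSE)
    popfun <- function(x) state_population(top, model, x, folded)
  } else {
    popfun <- function(x)
      relaxed_ccap_population(top, model, x, min_folded_others)
  }
  profile_from_popfun(popfun, x_grid, top$construct_id)
}

# P(C-cap unfolded and >= k of the other helices folded), by a transfer
# matrix that also tracks the number of folded helices.
relaxed_ccap_population <- function(top, model, x, k) {
  n <- n_helices(top)
  sapply(x, function(xi) {
    w <- tm_weights(top, model, xi)
    kv <- w$k[, 1L]
    tv <- if (n > 1L) w$t[, 1L] else numeric(0)
    # rows: count of folded helices so far (0..n), cols: last helix folded?
    f <- numeric(n + 1L)
    u <- numeric(n + 1L)
    u[1L] <- 1
    for (i in seq_len(n)) {
      ti <- if (i == 1L) 1 else tv[i - 1L]
      unf <- f + u
      fold <- c(0, (ti * f + u)[-(n + 1L)]) * kv[i]
      if (i == n) unf_last <- unf            # states with C-cap unfolded
      f <- fold
      u <- unf
    }
    q <- sum(f + u)
    sum(unf_last[seq.int(k + 1L, n + 1L)]) / q
  })
}

#' Population profile of a single-terminal-helix-unfolded state
#'
#' As [intermediate_profile()], but for the exact state in which only the
#' chosen terminal helix (N- or C-terminal) is unfolded. Comparing the two
#' termini quantifies the thermodynamic asymmetry of the array.
#'
#' @inheritParams intermediate_profile
#' @param terminus `"C"` (last helix) or `"N"` (first helix).
#' @return an object of class `intermediate_profile`.
#' @export
terminal_state_profile <- function(top, model, x_grid = seq(0, 8, by = 0.01),
                                   terminus = c("C", "N")) {
  terminus <- match.arg(terminus)
  n <- n_helices(top)
  folded <- rep(TRUE, n)
  folded[if (terminus == "C") n else 1L] <- FALSE
  popfun <- function(x) state_population(top, model, x, folded)
  profile_from_popfun(popfun, x_grid, top$construct_id)
}

#' Free energy of adding one helix to a folded array
#'
#' \eqn{\Delta G_{0 \to 1}(x) = G_i + G_{i-1,i} + (m_1 + m_2) x} for the given
#' class, with only the variant-active m-values contributing. At `x = 0` this
#' is the water stability of docking one helix of that class onto an already
#' folded ensemble; negative values are stabilising.
#'
#' @inheritParams kappa
#' @param x denaturant concentration(s), M GuHCl (default 0).
#' @return numeric vector of free energies, kcal/mol.
#' @export
#' @examples
#' helix_addition_stability(ctprn_table1(), "A")   # -3.7 kcal/mol
helix_addition_stability <- function(model, class, x = 0) {
  stopifnot(inherits(model, "energy_model"), length(class) == 1L)
  check_class(model, class)
  model$G_intr[[class]] + model$G_int[[class]] +
    (model$m_intr[[class]] + model$m_int[[class]]) * x
}

#' Scan progressive destabilisation of the C-cap helix
#'
#' For each offset in `deltas`, raises the S-class intrinsic free energy by
#' that amount (making the C-cap helix less stable) and recomputes the
#' simulated denaturation curve and the C-cap-unfolded intermediate profile.
#'
#' @inheritParams intermediate_profile
#' @param deltas numeric vector of destabilisation offsets, kcal/mol.
#' @return a list with one element per delta: `list(delta, model, curve,
#'   profile)`.
#' @export
#' @examples
#' sw <- build_switch_chimera(ctprn_table1(), ctpran_table1(), 3)
#' scan <- destabilization_scan(sw$topology, sw$model, c(0, 0.5, 1, 2))
#' sapply(scan, function(s) s$profile$alpha)
destabilization_scan <- function(top, model, deltas,
                                 x_grid = seq(0, 8, by = 0.01)) {
  stopifnot(all(is.finite(deltas)))
  check_class(model, "S")
  lapply(deltas, function(d) {
    m <- model
    m$G_intr[["S"]] <- m$G_intr[["S"]] + d
    list(delta = d, model = m,
         curve = simulate_curve(top, m, x_grid),
         profile = intermediate_profile(top, m, x_grid))
  })
}

#' Residual unfolding of the non-C-cap helices
#'
#' `1 - theta_F` computed over all helices except the C-cap S-helix: how much
#' helical structure beyond the C-cap is lost at denaturant concentration
#' `x`. A diagnostic for how cleanly a switch construct uncouples its C-cap.
#'
#' @inheritParams partition_function
#' @return numeric vector, one value per element of `x`.
#' @export
partial_unfolding <- function(top, model, x) {
  n <- n_helices(top)
  if (n < 2L) stop("need at least two helices", call. = FALSE)
  w <- tm_weights(top, model, x)
  q <- tm_partition(w$k, w$t, rep(FALSE, n))
  idx <- seq_len(n - 1L)
  acc <- numeric(length(x))
  for (i in idx) {
    constrained <- rep(FALSE, n)
    constrained[i] <- TRUE
    acc <- acc + tm_partition(w$k, w$t, constrained)
  }
  1 - acc / (length(idx) * q)
}
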