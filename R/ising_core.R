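# Transfer-matrix engine.
#
# State weight rule: for a binary conformation (folded/unfolded per helix),
# weight = prod over folded helices of kappa_i * prod over adjacent pairs of
# folded helices of tau_{i-1,i}; the fully unfolded chain has weight 1.
# The left-to-right recursion keeps two accumulators (f, u): total weight of
# all conformations of helices 1..i in which helix i is folded/unfolded:
#   f_i = kappa_i * (tau_{i-1,i} * f_{i-1} + u_{i-1}),   u_i = f_{i-1} + u_{i-1}
# with (f_0, u_0) = (0, 1) and no tau for the first helix. Constraining a
# helix folded (the Eq.-style v = 0 indicator) zeroes its unfolded branch.

# per-helix kappa and per-interface tau at each x: matrices n x length(x)
tm_weights <- function(top, model, x) {
  rt <- rt_energy(model)
  check_class(model, unique(c(top$helices, top$interfaces)))
  k <- exp(-(outer(model$G_intr[top$helices], rep(1, length(x))) +
               outer(model$m_intr[top$helices], x)) / rt)
  t <- if (length(top$interfaces))
    exp(-(outer(model$G_int[top$interfaces], rep(1, length(x))) +
            outer(model$m_int[top$interfaces], x)) / rt)
  else matrix(0, 0, length(x))
  dimnames(k) <- NULL
  dimnames(t) <- NULL
  list(k = k, t = t)
}

tm_partition <- function(k, t, constrained) {
  nx <- ncol(k)
  f <- numeric(nx)
  u <- rep(1, nx)
  for (i in seq_len(nrow(k))) {
    ti <- if (i == 1L) 1 else t[i - 1L, ]
    fi <- k[i, ] * (ti * f + u)
    u <- if (constrained[i]) numeric(nx) else f + u
    f <- fi
  }
  f + u
}

#' Ising partition function of a construct
#'
#' Sum of Boltzmann weights over all allowed conformations, computed by a
#' left-to-right transfer-matrix product. A conformation assigns each helix
#' folded or unfolded; its weight is the product of \eqn{\kappa_i} over
#' folded helices times \eqn{\tau_{i-1,i}} over adjacent pairs of folded
#' helices. Helices flagged in `constrained` are restricted to the folded
#' state (the subpartition mechanism used by [fraction_folded()]).
#'
#' @param top a [topology()].
#' @param model an [energy_model()] covering all classes in `top`.
#' @param x denaturant concentration(s), M GuHCl.
#' @param constrained logical vector, one per helix: `TRUE` restricts that
#'   helix to its folded state. Default: none constrained.
#' @return numeric vector of strictly positive partition-function values,
#'   one per element of `x`.
#' @export
#' @examples
#' top <- build_topology(2)
#' partition_function(top, ctprn_table1(), c(0, 2, 4))
partition_function <- function(top, model, x, constrained = NULL) {
  stopifnot(inherits(top, "topology"), inherits(model, "energy_model"))
  if (n_helices(top) < 1L) stop("empty topology", call. = FALSE)
  if (any(x < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  if (is.null(constrained)) constrained <- rep(FALSE, n_helices(top))
  if (length(constrained) != n_helices(top))
    stop("constrained mask length must match the number of helices", call. = FALSE)
  w <- tm_weights(top, model, x)
  q <- tm_partition(w$k, w$t, constrained)
  if (any(!is.finite(q)))
    stop("partition function overflowed the double range", call. = FALSE)
  q
}

#' Brute-force enumeration of all conformational states
#'
#' Exhaustively lists all `2^n` folded/unfolded assignments of an `n`-helix
#' construct with their statistical weights, computed directly from the
#' product weight rule (not via the transfer matrix). Serves as an
#' independent oracle for [partition_function()] and [state_population()].
#'
#' @inheritParams partition_function
#' @param x a single denaturant concentration, M GuHCl.
#' @return a `data.frame` with one row per state: `state` (string of 0/1,
#'   1 = folded, first helix first) and `weight`. The logical state matrix is
#'   attached as attribute `"folded"`.
#' @export
#' @examples
#' enumerate_states(build_topology(1, c_cap = FALSE), ctprn_table1(), 0)
enumerate_states <- function(top, model, x) {
  stopifnot(inherits(top, "topology"), inherits(model, "energy_model"),
            length(x) == 1L, x >= 0)
  n <- n_helices(top)
  if (n > 20L) stop("enumeration limited to 20 helices (2^n states)", call. = FALSE)
  w <- tm_weights(top, model, x)
  k <- w$k[, 1L]
  t <- if (n > 1L) w$t[, 1L] else numeric(0)
  n_states <- 2L^n
  folded <- matrix(FALSE, n_states, n)
  weight <- numeric(n_states)
  for (s in seq_len(n_states) - 1L) {
    mask <- as.logical(bitwAnd(bitwShiftR(s, seq_len(n) - 1L), 1L))
    wt <- prod(k[mask])
    if (n > 1L) {
      pair <- mask[-n] & mask[-1L]
      wt <- wt * prod(t[pair])
    }
    folded[s + 1L, ] <- mask
    weight[s + 1L] <- wt
  }
  out <- data.frame(
    state = apply(folded, 1L, function(z) paste(as.integer(z), collapse = "")),
    weight = weight)
  attr(out, "folded") <- folded
  out
}

#' Average fraction of helices folded
#'
#' \eqn{\theta_F(x) = \sum_{i=1}^n q(i) / (n \, q(n))} where \eqn{q(i)} is the
#' subpartition function with helix `i` constrained folded. Identically the
#' average over helices of the probability that each helix is folded, so the
#' model's normalized unfolding curve is `1 - fraction_folded(...)`.
#'
#' @inheritParams partition_function
#' @return numeric vector in `[0, 1]`, one value per element of `x`.
#' @export
fraction_folded <- function(top, model, x) {
  stopifnot(inherits(top, "topology"), inherits(model, "energy_model"))
  if (any(x < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  n <- n_helices(top)
  w <- tm_weights(top, model, x)
  q <- tm_partition(w$k, w$t, rep(FALSE, n))
  acc <- numeric(length(x))
  for (i in seq_len(n)) {
    constrained <- rep(FALSE, n)
    constrained[i] <- TRUE
    acc <- acc + tm_partition(w$k, w$t, constrained)
  }
  theta <- acc / (n * q)
  if (any(!is.finite(theta)))
    stop("fraction folded overflowed the double range", call. = FALSE)
  theta
}

#' Population of one exact conformational state
#'
#' Weight of the single conformation given by `folded` divided by the full
#' partition function. Populations over all `2^n` states sum to one.
#'
#' @inheritParams partition_function
#' @param folded logical vector, one entry per helix: `TRUE` = folded.
#' @return numeric vector in `[0, 1]`, one value per element of `x`.
#' @export
#' @examples
#' top <- build_topology(3)
#' # all helices folded except the C-cap, at 2 M GuHCl:
#' state_population(build_topology(3), ctprn_table1(), 2,
#'                  c(rep(TRUE, 6), FALSE))
state_population <- function(top, model, x, folded) {
  stopifnot(inherits(top, "topology"), inherits(model, "energy_model"))
  n <- n_helices(top)
  folded <- as.logical(folded)
  if (length(folded) != n || anyNA(folded))
    stop("'folded' must give TRUE/FALSE for every helix", call. = FALSE)
  if (any(x < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  w <- tm_weights(top, model, x)
  wt <- rep(1, length(x))
  for (i in which(folded)) wt <- wt * w$k[i, ]
  if (n > 1L) {
    for (i in which(folded[-n] & folded[-1L])) wt <- wt * w$t[i, ]
  }
  q <- tm_partition(w$k, w$t, rep(FALSE, n))
  p <- wt / q
  if (any(!is.finite(p)))
    stop("state population overflowed the double range", call. = FALSE)
  p
}
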