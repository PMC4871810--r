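#' Two-state linear-extrapolation fit of one curve
#'
#' Baseline comparator to the Ising analysis: fits the standard two-state
#' linear-extrapolation model to a normalized curve,
#' \deqn{y(x) = \frac{e^{-(\Delta G - m x)/RT}}{1 + e^{-(\Delta G - m x)/RT}},}
#' where \eqn{\Delta G} is the water stability (kcal/mol) and `m` the
#' denaturant dependence (kcal/mol/M). The midpoint is \eqn{\Delta G / m}.
#'
#' @param curve a [denaturation_curve()] spanning both baselines.
#' @param temperature temperature, K.
#' @param gas_constant gas constant, kcal/mol/K.
#' @return an object of class `two_state_fit`: list with `dG`, `m`,
#'   `midpoint`, standard errors `se`, residual `rms` and the underlying
#'   `nls` fit.
#' @export
#' @examples
#' x <- seq(0, 6, length.out = 40)
#' rt <- 1.9872e-3 * 283.15
#' y <- plogis((2 * x - 5) / rt)
#' fit_two_state(denaturation_curve("demo", x, y))$midpoint
fit_two_state <- function(curve, temperature = 283.15,
                          gas_constant = 1.9872e-3) {
  stopifnot(inherits(curve, "denaturation_curve"))
  x <- curve$x
  y <- curve$y
  if (diff(range(y)) < 0.5)
    stop("no unfolding transition: curve does not span both baselines",
         call. = FALSE)
  rt <- gas_constant * temperature
  x_mid <- x[which.min(abs(y - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp((dG - m * x) / rt)),
                      data = list(x = x, y = y, rt = rt),
                      start = list(dG = max(2 * x_mid, 1), m = 2),
                      lower = c(0, 0.01), upper = c(50, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("two-state fit failed: ", conditionMessage(e),
                             call. = FALSE))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  structure(list(dG = unname(est[["dG"]]), m = unname(est[["m"]]),
                 midpoint = unname(est[["dG"]] / est[["m"]]),
                 se = c(dG = unname(se[1L]), m = unname(se[2L])),
                 rms = sqrt(mean(residuals(fit)^2)), fit = fit),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state fit: dG(H2O) = %.3f kcal/mol, m = %.3f kcal/mol/M, midpoint = %.3f M (rms %.4f)\n",
    x$dG, x$m, x$midpoint, x$rms))
  invisible(x)
}

# parameter vector layout for a variant over a set of class labels
par_layout <- function(classes, variant) {
  nm <- c(paste0("G_", classes), paste0("Gint_", classes))
  lower <- rep(-15, 2L * length(classes))
  upper <- rep(15, 2L * length(classes))
  m_blocks <- switch(variant,
                     interface_m = "m_",
                     intrinsic_m = "m_",
                     both_m = c("m1_", "m2_"))
  for (b in m_blocks) {
    nm <- c(nm, paste0(b, classes))
    lower <- c(lower, rep(0, length(classes)))
    upper <- c(upper, rep(5, length(classes)))
  }
  list(names = nm, lower = lower, upper = upper)
}

# unpack a parameter vector into an energy_model
par_to_model <- function(par, classes, variant, temperature, gas_constant) {
  nc <- length(classes)
  G_intr <- setNames(par[seq_len(nc)], classes)
  G_int <- setNames(par[nc + seq_len(nc)], classes)
  args <- list(G_intr = G_intr, G_int = G_int, variant = variant,
               temperature = temperature, gas_constant = gas_constant)
  if (variant == "both_m") {
    args$m_intr <- setNames(par[2L * nc + seq_len(nc)], classes)
    args$m_int <- setNames(par[3L * nc + seq_len(nc)], classes)
  } else {
    args$m <- setNames(par[2L * nc + seq_len(nc)], classes)
  }
  do.call(energy_model, args)
}

#' Global multi-start Ising fit of a denaturation-curve series
#'
#' Fits one shared [energy_model()] to every curve in the series by
#' minimising the summed squared deviation between the normalized data and
#' the model prediction `1 - fraction_folded(x)`. The objective is polished
#' from `n_starts` random initialisations (free energies uniform in
#' \[-15, 15\] kcal/mol, m-values uniform in \[0, 5\] kcal/mol/M) by bounded
#' Levenberg-Marquardt least squares, and the best minimum is retained. No
#' sign constraints are imposed on the free energies: stabilising interfaces
#' are a result of the fit, not an assumption.
#'
#' Separating the three parameter classes requires a deletion series: a
#' warning is raised unless the input contains at least one construct
#' without an N-cap and one without a C-cap.
#'
#' @param curves list of [denaturation_curve()] objects (replicates may
#'   repeat a `construct_id`; each curve contributes equally pointwise).
#' @param topologies named list of [topology()] objects keyed by
#'   `construct_id`, or `NULL` to build canonical CTPR topologies from the
#'   identifiers via [parse_construct_id()].
#' @param variant model variant, see [energy_model()].
#' @param n_starts number of random initialisations (default 256).
#' @param seed integer seed making the whole fit reproducible.
#' @param temperature,gas_constant fixed thermodynamic constants.
#' @param maxiter maximum Levenberg-Marquardt iterations per start (the retained minimum is then polished to tight convergence).
#' @return an object of class `ising_fit`: the fitted `model`, `objective`
#'   (best sum of squares), `per_curve_rms` (RMS residual of each curve as a
#'   fraction of the normalized amplitude), `start_objectives`,
#'   `convergence` codes, `n_starts`, `seed`.
#' @export
global_fit <- function(curves, topologies = NULL, variant = c(
                         "interface_m", "intrinsic_m", "both_m"),
                       n_starts = 256L, seed = 1L,
                       temperature = 283.15, gas_constant = 1.9872e-3,
                       maxiter = 50L) {
  variant <- match.arg(variant)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "denaturation_curve")))
  ids <- vapply(curves, `[[`, "", "construct_id")
  if (is.null(topologies)) {
    topologies <- lapply(unique(ids), function(id) {
      info <- parse_construct_id(id)
      if (info$switch)
        stop("cannot auto-build a topology for switch construct '", id,
             "'; supply it in 'topologies'", call. = FALSE)
      build_topology(info$n_repeats, info$series, info$n_cap, info$c_cap)
    })
    names(topologies) <- unique(ids)
  }
  missing <- setdiff(ids, names(topologies))
  if (length(missing))
    stop("no topology supplied for construct(s): ",
         paste(unique(missing), collapse = ", "), call. = FALSE)

  tops <- topologies[ids]
  comps <- unique(vapply(tops, function(t) paste(t$helices, collapse = ""), ""))
  if (length(comps) < 2L)
    warning("parameters are not identifiable from a single helix composition",
            call. = FALSE)
  has_dA <- any(vapply(tops, function(t) t$helices[1L] != "A", TRUE))
  has_dS <- any(vapply(tops, function(t) t$helices[n_helices(t)] != "S", TRUE))
  if (!(has_dA && has_dS))
    warning(paste("series lacks a dA and/or dS deletion construct;",
                  "cap parameters may not be separable"), call. = FALSE)

  classes <- sort(unique(unlist(lapply(tops, function(t)
    c(t$helices, t$interfaces)))))
  layout <- par_layout(classes, variant)
  rt <- gas_constant * temperature
  nc <- length(classes)

  # canonical internal ordering makes the fit exactly invariant to the
  # order in which curves are supplied
  key <- vapply(curves, function(cv)
    paste(format(c(cv$x, cv$y), digits = 17), collapse = ","), "")
  ord <- order(ids, key)

  # per-curve integer views into the parameter vector
  views <- lapply(ord, function(j) {
    t <- tops[[j]]
    hi <- match(t$helices, classes)
    ii <- match(t$interfaces, classes)
    list(hG = hi, iG = nc + ii,
         hm = switch(variant, intrinsic_m = 2L * nc + hi,
                     both_m = 2L * nc + hi, interface_m = integer(0)),
         im = switch(variant, interface_m = 2L * nc + ii,
                     both_m = 3L * nc + ii, intrinsic_m = integer(0)),
         x = curves[[j]]$x, y = curves[[j]]$y)
  })
  ys <- lapply(curves, `[[`, "y")
  xs <- lapply(curves, `[[`, "x")

  resid_fun <- function(par) series_residuals_cpp(par, views, rt)

  set.seed(seed)
  starts <- matrix(runif(n_starts * length(layout$names),
                         rep(layout$lower, each = n_starts),
                         rep(layout$upper, each = n_starts)),
                   nrow = n_starts)
  objectives <- rep(Inf, n_starts)
  info <- rep(NA_integer_, n_starts)
  best <- NULL
  lm_run <- function(par, iter)
    tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par, lower = layout$lower,
                           upper = layout$upper, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = iter))),
      error = function(e) NULL)
  for (s in seq_len(n_starts)) {
    res <- lm_run(starts[s, ], maxiter)
    if (is.null(res)) next
    objectives[s] <- res$deviance
    info[s] <- res$info
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  # polish the retained minimum to tight convergence
  polish <- lm_run(best$par, 400L)
  if (!is.null(polish) && polish$deviance <= best$deviance) best <- polish

  par <- setNames(best$par, layout$names)
  model <- par_to_model(par, classes, variant, temperature, gas_constant)
  per_curve <- vapply(seq_along(curves), function(j) {
    pred <- 1 - fraction_folded(tops[[j]], model, xs[[j]])
    sqrt(mean((ys[[j]] - pred)^2))
  }, 0)
  names(per_curve) <- make.unique(ids)

  structure(list(model = model, parameters = par, objective = best$deviance,
                 per_curve_rms = per_curve, n_starts = n_starts, seed = seed,
                 start_objectives = objectives, convergence = info,
                 best_start = which.min(objectives), variant = variant,
                 classes = classes),
            class = "ising_fit")
}

#' @export
print.ising_fit <- function(x, ...) {
  cat("Global heteropolymer Ising fit (", x$variant, ")\n", sep = "")
  cat("  curves:", length(x$per_curve_rms),
      "| starts:", x$n_starts, "| seed:", x$seed, "\n")
  cat(sprintf("  best objective (SSQ): %.6g\n", x$objective))
  cat(sprintf("  per-curve RMS residual: %.4f - %.4f of amplitude\n",
              min(x$per_curve_rms), max(x$per_curve_rms)))
  print(x$model)
  invisible(x)
}
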