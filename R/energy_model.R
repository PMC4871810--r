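#' Per-helix-class free-energy model
#'
#' An `energy_model` holds, for every helix class (e.g. N-cap `"A"`, internal
#' `"I"`, C-cap `"S"`), the intrinsic folding free energy `G_intr` of a helix
#' of that class, the interfacial free energy `G_int` of the interface
#' associated with that class, and linear denaturant sensitivities
#' (m-values). Three variants differ in where the denaturant acts:
#'
#' * `"intrinsic_m"`: the m-value multiplies the intrinsic term,
#'   \eqn{\kappa = \exp(-(G_i + m x)/RT)}, interfaces denaturant-independent.
#' * `"interface_m"`: the m-value multiplies the interfacial term,
#'   \eqn{\tau = \exp(-(G_{i-1,i} + m x)/RT)}, intrinsic terms
#'   denaturant-independent. This is the working model for the CTPR series.
#' * `"both_m"`: separate m-values on both terms (two per class).
#'
#' Sign conventions: positive `G_intr` means folding an isolated helix is
#' unfavourable; negative `G_int` means the interface stabilises; m-values
#' are in kcal/mol/M GuHCl and positive values destabilise with denaturant.
#'
#' @param G_intr named numeric vector of intrinsic folding free energies
#'   (kcal/mol), one per helix class; names define the class labels.
#' @param G_int named numeric vector of interfacial free energies (kcal/mol),
#'   same names as `G_intr`.
#' @param m named numeric vector of m-values (kcal/mol/M) for the single-m
#'   variants; routed to the intrinsic term for `"intrinsic_m"` and to the
#'   interfacial term for `"interface_m"`. Ignored for `"both_m"`.
#' @param variant one of `"interface_m"`, `"intrinsic_m"`, `"both_m"`.
#' @param m_intr,m_int named numeric vectors of m-values for `"both_m"`
#'   (intrinsic and interfacial respectively).
#' @param temperature temperature in Kelvin (default 283.15 K, i.e. 10 degC,
#'   the condition of the CTPR denaturation experiments).
#' @param gas_constant gas constant in kcal/mol/K.
#' @return An object of class `energy_model`.
#' @seealso [kappa()], [tau()], [ctprn_table1()], [ctpran_table1()]
#' @export
#' @examples
#' m <- energy_model(G_intr = c(A = 5.3, I = 4.8, S = 2.95),
#'                   G_int  = c(A = -9.0, I = -7.7, S = -6.3),
#'                   m      = c(A = 0.9, I = 0.6, S = 1.0))
#' kappa(m, "I", 0)
energy_model <- function(G_intr, G_int, m = NULL,
                         variant = c("interface_m", "intrinsic_m", "both_m"),
                         m_intr = NULL, m_int = NULL,
                         temperature = 283.15, gas_constant = 1.9872e-3) {
  variant <- match.arg(variant)
  classes <- names(G_intr)
  if (is.null(classes) || anyDuplicated(classes) || any(classes == ""))
    stop("G_intr must be a named vector with unique class labels", call. = FALSE)
  if (!identical(sort(names(G_int)), sort(classes)))
    stop("G_int must carry the same class labels as G_intr", call. = FALSE)
  G_int <- G_int[classes]
  zero <- setNames(numeric(length(classes)), classes)
  pick <- function(v, what) {
    if (is.null(v)) stop("variant '", variant, "' requires ", what, call. = FALSE)
    if (!identical(sort(names(v)), sort(classes)))
      stop(what, " must carry the same class labels as G_intr", call. = FALSE)
    v[classes]
  }
  if (variant == "interface_m") {
    m_int <- pick(if (is.null(m_int)) m else m_int, "m (interfacial m-values)")
    m_intr <- zero
  } else if (variant == "intrinsic_m") {
    m_intr <- pick(if (is.null(m_intr)) m else m_intr, "m (intrinsic m-values)")
    m_int <- zero
  } else {
    m_intr <- pick(m_intr, "m_intr")
    m_int <- pick(m_int, "m_int")
  }
  stopifnot(temperature > 0, gas_constant > 0)
  vals <- c(G_intr, G_int, m_intr, m_int)
  if (any(!is.finite(vals))) stop("all energies must be finite", call. = FALSE)
  structure(
    list(variant = variant, classes = classes,
         G_intr = G_intr, G_int = G_int, m_intr = m_intr, m_int = m_int,
         temperature = temperature, gas_constant = gas_constant),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Heteropolymer Ising energy model (", x$variant, ")\n", sep = "")
  cat("T =", x$temperature, "K; RT =",
      signif(rt_energy(x), 5), "kcal/mol\n")
  tab <- data.frame(G_intr = x$G_intr, G_int = x$G_int,
                    m_intr = x$m_intr, m_int = x$m_int,
                    dG_addition = x$G_intr + x$G_int,
                    row.names = x$classes)
  print(tab, ...)
  invisible(x)
}

rt_energy <- function(model) model$gas_constant * model$temperature

check_class <- function(model, class) {
  bad <- setdiff(class, model$classes)
  if (length(bad))
    stop("unknown helix class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(class)
}

#' Intrinsic-folding equilibrium constant
#'
#' \eqn{\kappa_i = \exp(-(G_i + m_1 x)/RT)}, the Boltzmann weight of folding
#' one helix of the given class in isolation at denaturant concentration `x`.
#' The intrinsic m-value \eqn{m_1} is active only for variants
#' `"intrinsic_m"` and `"both_m"`.
#'
#' @param model an [energy_model()].
#' @param class a helix-class label present in `model`.
#' @param x denaturant concentration(s), M GuHCl, non-negative.
#' @return numeric vector of strictly positive equilibrium constants,
#'   one per element of `x`.
#' @export
kappa <- function(model, class, x) {
  stopifnot(inherits(model, "energy_model"), length(class) == 1L)
  check_class(model, class)
  if (any(x < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  out <- exp(-(model$G_intr[[class]] + model$m_intr[[class]] * x) / rt_energy(model))
  if (any(!is.finite(out)))
    stop("kappa overflowed the double range", call. = FALSE)
  out
}

#' Interfacial equilibrium constant
#'
#' \eqn{\tau_{i-1,i} = \exp(-(G_{i-1,i} + m_2 x)/RT)}, the Boltzmann weight
#' gained when two adjacent helices are both folded, for the interface class
#' given. The interfacial m-value \eqn{m_2} is active only for variants
#' `"interface_m"` and `"both_m"`.
#'
#' @inheritParams kappa
#' @param class an interface-class label present in `model`.
#' @return numeric vector of strictly positive equilibrium constants.
#' @export
tau <- function(model, class, x) {
  stopifnot(inherits(model, "energy_model"), length(class) == 1L)
  check_class(model, class)
  if (any(x < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  out <- exp(-(model$G_int[[class]] + model$m_int[[class]] * x) / rt_energy(model))
  if (any(!is.finite(out)))
    stop("tau overflowed the double range", call. = FALSE)
  out
}

#' Published parameter sets for the CTPR series
#'
#' Global-fit parameter values for the two CTPR deletion series under the
#' denaturant-dependent-interface model (`variant = "interface_m"`) at
#' 283.15 K. `ctprn_table1()` is the CTPRn series (PNN repeat linker),
#' `ctpran_table1()` the CTPRan series (PRS linker, destabilised repeat
#' junctions). Units: kcal/mol and kcal/mol/M GuHCl.
#'
#' @return an [energy_model()].
#' @export
ctprn_table1 <- function() {
  energy_model(G_intr = c(A = 5.3, I = 4.8, S = 2.95),
               G_int  = c(A = -9.0, I = -7.7, S = -6.3),
               m      = c(A = 0.9, I = 0.6, S = 1.0),
               variant = "interface_m")
}

#' @rdname ctprn_table1
#' @export
ctpran_table1 <- function() {
  energy_model(G_intr = c(A = 2.6, I = 3.5, S = 6.0),
               G_int  = c(A = -6.2, I = -5.5, S = -7.7),
               m      = c(A = 1.3, I = 0.6, S = 0.8),
               variant = "interface_m")
}
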