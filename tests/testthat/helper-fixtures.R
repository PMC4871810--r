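# Shared fixtures: published parameter sets, random topologies/models for
# property-style tests, and the thermodynamic constants used throughout.

RT10 <- 1.9872e-3 * 283.15  # kcal/mol at 10 degC

# a model over arbitrary class labels with explicitly chosen kappa/tau
# values at x = 0 (G = -RT log k); unused slots zero
model_from_weights <- function(kappas, taus = NULL) {
  labels <- names(kappas)
  G_intr <- -RT10 * log(kappas)
  G_int <- setNames(numeric(length(labels)), labels)
  if (!is.null(taus)) {
    G_intr <- c(G_intr, setNames(numeric(length(taus)), names(taus)))
    G_int <- c(G_int, -RT10 * log(taus))
    labels <- c(labels, names(taus))
  }
  m <- setNames(numeric(length(labels)), labels)
  energy_model(G_intr = G_intr, G_int = G_int, m = m, variant = "interface_m")
}

# random heteropolymer topology + model with kappa, tau in (1e-4, 1e4)
random_case <- function(n) {
  hl <- paste0("h", seq_len(n))
  il <- if (n > 1) paste0("i", seq_len(n - 1)) else character(0)
  kappas <- setNames(10^runif(n, -4, 4), hl)
  taus <- if (n > 1) setNames(10^runif(n - 1, -4, 4), il)
  list(top = topology(hl, il, construct_id = paste0("rand", n)),
       model = model_from_weights(kappas, taus))
}

# slow reference: mean over helices of P(helix folded), from enumeration
enum_fraction_folded <- function(top, model, x) {
  st <- enumerate_states(top, model, x)
  folded <- attr(st, "folded")
  mean(colSums(st$weight * folded) / sum(st$weight))
}
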