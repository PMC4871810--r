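test_that("helix addition stabilities reproduce the published sums", {
  n <- ctprn_table1()
  an <- ctpran_table1()
  expect_equal(helix_addition_stability(n, "A"), -3.7, tolerance = 1e-12)
  expect_equal(helix_addition_stability(n, "I"), -2.9, tolerance = 1e-12)
  expect_equal(helix_addition_stability(an, "A"), -3.6, tolerance = 1e-12)
  expect_equal(helix_addition_stability(an, "S"), -1.7, tolerance = 1e-12)
  # denaturant dependence enters through the variant-active m-values
  expect_equal(helix_addition_stability(n, "I", 2), -2.9 + 0.6 * 2)
  # a class with G_intr = -G_int is neutral in water
  neutral <- energy_model(G_intr = c(Z = 4), G_int = c(Z = -4),
                          m = c(Z = 1), variant = "interface_m")
  expect_equal(helix_addition_stability(neutral, "Z"), 0)
})

test_that("simulated curves unfold to completion and order by stability", {
  x <- seq(0, 8, by = 0.02)
  n <- ctprn_table1()
  c3 <- simulate_curve(build_topology(3), n, x)
  expect_gt(tail(c3$y, 1), 0.999)
  expect_lt(c3$y[1], 0.01)
  sw <- build_switch_chimera(ctprn_table1(), ctpran_table1(), 3)
  csw <- simulate_curve(sw$topology, sw$model, x)
  c3dS <- simulate_curve(build_topology(3, c_cap = FALSE), n, x)
  # the switch is less stable than its parent ...
  expect_lt(curve_midpoint(csw), curve_midpoint(c3))
  # ... with a midpoint matching the C-cap deletion within 0.1 M
  expect_lt(abs(curve_midpoint(csw) - curve_midpoint(c3dS)), 0.1)
  expect_error(simulate_curve(build_topology(3), n, numeric(0)), "non-empty")
})

test_that("intermediate profile locates an interior maximum", {
  p <- intermediate_profile(build_topology(3), ctprn_table1())
  expect_gte(p$alpha, 0)
  expect_lte(p$beta, 1)
  expect_gt(p$beta, p$alpha)
  expect_equal(p$amplitude, p$beta - p$alpha)
  expect_gt(p$x_at_max, 0)
  expect_lt(p$x_at_max, 8)
  # rises from near zero and decays back at high denaturant
  expect_lt(p$population[1], 0.01)
  expect_lt(tail(p$population, 1), 0.01)
  expect_error(intermediate_profile(build_topology(3, c_cap = FALSE),
                                    ctprn_table1()), "no C-cap")
})

test_that("profiles agree with the enumeration oracle", {
  top <- build_topology(2)
  m <- ctprn_table1()
  x <- 2.2
  st <- enumerate_states(top, m, x)
  folded <- attr(st, "folded")
  target <- apply(folded, 1, function(z) all(z[1:4]) && !z[5])
  expect_equal(state_population(top, m, x, c(rep(TRUE, 4), FALSE)),
               sum(st$weight[target]) / sum(st$weight), tolerance = 1e-10)
  # the exact intermediate population can never exceed 1 - P(fully folded)
  pfull <- state_population(top, m, x, rep(TRUE, 5))
  p <- intermediate_profile(top, m, seq(0, 8, by = 0.05))
  expect_lte(p$beta, 1 - 0 + 1e-12)
  expect_lte(state_population(top, m, x, c(rep(TRUE, 4), FALSE)), 1 - pfull)
})

test_that("terminal asymmetry follows the cap stabilities", {
  top <- build_topology(3)
  n <- ctprn_table1()
  pc <- terminal_state_profile(top, n, terminus = "C")
  pn <- terminal_state_profile(top, n, terminus = "N")
  # the C-cap is the least stable cap: it frays first and more
  expect_gt(pc$beta, pn$beta)
  # a symmetric homopolymer shows no preference
  sym <- energy_model(G_intr = c(I = 3), G_int = c(I = -5),
                      m = c(I = 0.8), variant = "interface_m")
  stop5 <- topology(rep("I", 5))
  ps_c <- terminal_state_profile(stop5, sym, terminus = "C")
  ps_n <- terminal_state_profile(stop5, sym, terminus = "N")
  expect_equal(ps_c$beta, ps_n$beta, tolerance = 1e-9)
  expect_equal(ps_c$x_at_max, ps_n$x_at_max, tolerance = 1e-4)
})

test_that("repeat extension deepens the switch intermediate", {
  sw <- build_switch_chimera(ctprn_table1(), ctpran_table1(), 3)
  p3 <- intermediate_profile(sw$topology, sw$model)
  sw10_top <- extend_repeats(sw$topology, 7)
  p10 <- intermediate_profile(sw10_top, sw$model)
  expect_gt(p10$beta, p3$beta)
  # and the switch doubles the intermediate relative to its parent
  pc3 <- intermediate_profile(build_topology(3), ctprn_table1())
  expect_gt(p3$beta / pc3$beta, 1.8)
})

test_that("destabilization scan trades amplitude for native fraying", {
  sw <- build_switch_chimera(ctprn_table1(), ctpran_table1(), 3)
  scan <- destabilization_scan(sw$topology, sw$model, c(0, 0.5, 1, 2),
                               x_grid = seq(0, 8, by = 0.02))
  base <- intermediate_profile(sw$topology, sw$model, seq(0, 8, by = 0.02))
  expect_equal(scan[[1]]$profile$beta, base$beta, tolerance = 1e-12)
  expect_equal(scan[[1]]$curve$y, simulate_curve(sw$topology, sw$model,
                                                 seq(0, 8, by = 0.02))$y)
  alphas <- vapply(scan, function(s) s$profile$alpha, 0)
  expect_true(all(diff(alphas) > 0))
  betas <- vapply(scan, function(s) s$profile$beta, 0)
  expect_true(all(diff(betas) > 0))
})

test_that("relaxed intermediate definition nests the exact one", {
  top <- build_topology(3)
  m <- ctprn_table1()
  grid <- seq(0, 8, by = 0.1)
  exact <- intermediate_profile(top, m, grid)
  relaxed <- intermediate_profile(top, m, grid, min_folded_others = 4)
  expect_true(all(relaxed$population >= exact$population - 1e-12))
  # requiring all six others folded is exactly the single-state definition
  same <- intermediate_profile(top, m, grid, min_folded_others = 6)
  expect_equal(same$population, exact$population, tolerance = 1e-10)
  # oracle check at one concentration: S unfolded and >= 4 others folded
  st <- enumerate_states(top, m, 2.5)
  folded <- attr(st, "folded")
  sel <- !folded[, 7] & rowSums(folded[, 1:6]) >= 4
  expect_equal(relaxed$population[which(grid == 2.5)],
               sum(st$weight[sel]) / sum(st$weight), tolerance = 1e-10)
})

test_that("partial unfolding of the core stays within bounds", {
  sw <- build_switch_chimera(ctprn_table1(), ctpran_table1(), 3)
  v <- partial_unfolding(sw$topology, sw$model, c(0, 2.8, 8))
  expect_true(all(v >= 0 & v <= 1))
  expect_lt(v[1], 0.01)
  expect_gt(v[3], 0.99)
})
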