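---
title: "Heteropolymer Ising analysis of repeat-protein unfolding with repfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heteropolymer Ising analysis of repeat-protein unfolding with repfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repfold)
```

## The model

Consensus TPR proteins (CTPRs) are built from $n$ identical 34-residue
helix-turn-helix motifs closed by a single solvating C-cap helix, giving a
quasi one-dimensional array of $2n + 1$ helices. `repfold` treats each helix
as a two-state unit in a nearest-neighbour (1-D Ising) model. A conformation
assigns every helix folded or unfolded; its statistical weight is

$$w(\mathbf{s}) \;=\; \prod_{i\,\mathrm{folded}} \kappa_i
  \prod_{\substack{(i-1,i)\\ \text{both folded}}} \tau_{i-1,i},$$

with the fully unfolded chain as the weight-1 reference. The equilibrium
constants derive from per-class free energies: an intrinsic folding term
$G_i$ (positive: folding an isolated helix is unfavourable, dominated by the
entropic cost of helix nucleation) and an interfacial coupling term
$G_{i-1,i}$ (negative: packing two adjacent folded helices is what pays for
folding). Helices belong to classes — N-cap `A`, internal `I`, C-cap `S` —
that share parameters, so one small parameter set describes a whole deletion
series. Denaturant (GuHCl, concentration $x$) enters linearly through
m-values. Three variants differ in where $x$ acts:

* `intrinsic_m`: $\kappa_i = e^{-(G_i + m_1 x)/RT}$, $\tau$ independent of $x$;
* `interface_m`: $\tau_{i-1,i} = e^{-(G_{i-1,i} + m_2 x)/RT}$, $\kappa$
  independent of $x$ — the working model throughout, on the view that the
  interfacial term carries the solvent-exposed surface buried on docking;
* `both_m`: both, with independent m-values (see "Identifiability" below for
  why this variant is over-parameterised in practice).

Interface typing follows the caps: the interface adjacent to the N-cap is
A-typed, the one entering the C-cap is S-typed, all others I-typed. Deletion
constructs (`dA`, `dS`) simply lack the corresponding terminal helix and its
interface. This is the only typing under which the per-class helix-addition
stabilities $\Delta G_{0\to1} = G_i + G_{i-1,i}$ add up consistently across
the deletion series.

Defaults are $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and
$T = 283.15$ K (equilibrium denaturations at 10 °C); both are arguments of
`energy_model()`.

## Partition functions and observables

`partition_function()` evaluates $q$ by a left-to-right transfer-matrix
recursion over two accumulators (suffix weight with the current helix folded
or unfolded); a helix is constrained folded by zeroing its unfolded branch —
the indicator-variable mechanism that defines subpartition functions
$q(i)$. The observable fitted to CD data is the average fraction of helices
folded,

$$\theta_F(x) = \frac{\sum_{i=1}^{n} q(i)}{n\, q(n)},
\qquad \hat y(x) = 1 - \theta_F(x),$$

so the sloping pre-transition baselines of frayed constructs emerge from the
model rather than from an ad hoc baseline. `state_population()` gives the
population of one exact conformation; the *C-cap-unfolded intermediate* is
the exact state with every helix folded except the C-cap, and
`intermediate_profile()` summarises its population curve by $\alpha$ (value
at 0 M — natively frayed cap), $\beta$ (maximum) and the concentration of
the maximum.

Because the printed form of the matrix product is easy to get wrong in
transcription, correctness is anchored to `enumerate_states()`, a brute-force
$2^n$ oracle that applies the weight rule state by state ($n \le 20$). The
test suite checks transfer-matrix/oracle agreement to $10^{-10}$ relative
tolerance over hundreds of random heteropolymers.

## Numerical choices

* The user-facing R engine accumulates weights in plain doubles and raises a
  numeric-range error on overflow rather than returning `Inf`; for
  experimentally sensible energies this cannot trigger below roughly 25
  helices.
* The fitting path (`src/ising.cpp`) evaluates $\theta_F$ with a
  forward–backward pass that renormalises at every step and carries scales
  in log space, because random multi-start parameter vectors can produce
  astronomically large weights. The two paths are tested for equality at
  $10^{-12}$.
* Population profiles are scanned on a 0–8 M grid in 0.01 M steps
  (all transitions complete well below 6 M for the shipped parameter sets)
  and the maximum is refined off-grid with `optimize()` to $10^{-6}$ M.
* A degenerate one-helix topology is legal (no interfaces);
  $\theta_F = \kappa/(1+\kappa)$.

## Global fitting

`global_fit()` minimises the summed squared deviation between all normalized
curves of a series and $\hat y(x)$ under one shared parameter set
(nine parameters for the single-m variants over classes A/I/S). The
normalization of raw CD traces is
$y(D) = (\text{signal} - \alpha_N)/(\alpha_D + \beta_D D - \alpha_N)$, which
maps the native baseline intercept to 0 and the denatured baseline to 1
while retaining any native-baseline slope; denatured-baseline slopes default
to zero (they are not significant for these constructs).

The objective has many local minima, so the fit is multi-start: free
energies are drawn uniformly from $[-15, 15]$ kcal/mol and m-values from
$[0, 5]$ kcal/mol/M (brackets all plausible values with wide margin), each
start is polished by bounded Levenberg–Marquardt, and the best minimum is
kept and re-polished to tight convergence. No sign constraints are imposed:
that interfaces come out stabilising and intrinsic terms unfavourable is a
result. The default of 256 starts is a desk-scale choice — commercial
global optimizers with orders of magnitude more trajectories find the same
basin on this problem — and everything is reproducible from a single seed.
Curves are ordered canonically inside the fitter, so the result is exactly
invariant to the order in which curves are supplied. In the heavier test
runs the per-start iteration cap is set to 25 (with the final polish at
400); this was validated to reach the same optima as the default cap of 50.

`fit_two_state()` provides the standard linear-extrapolation two-state
comparator on a single normalized curve.

## Identifiability

Two structural facts about this fit deserve emphasis, and both are verified
by simulation in the test suite:

1. **The deletion series is essential.** With only full-length constructs,
   cap and internal parameters are confounded; `global_fit()` warns unless
   the series contains at least one `dA` and one `dS` construct.
2. **Only the sums are strongly determined.** Within each class, the split
   of $\Delta G_{0\to1}$ into $G_i$ and $G_{i-1,i}$ is informed almost
   entirely by conformations in which a helix is folded *without* a folded
   neighbour. Those states are rare (weight $\sim e^{-G_i/RT}$), so the
   likelihood is nearly flat in the direction $G_i + \delta$,
   $G_{i-1,i} - \delta$ for $\delta > 0$. At a realistic noise level of 2%
   of the amplitude, synthetic-data experiments show the fitted split can
   wander by many kcal/mol (sometimes with a *better* objective than the
   generating values) while the helix-addition sums and all m-values are
   recovered within 0.5 and 0.2 kcal/mol respectively. Downstream
   quantities — predicted curves, intermediate populations — depend almost
   exclusively on the identifiable combinations. Conclusions should
   therefore be drawn from $\Delta G_{0\to1}$ and the m-values, not from
   the raw split. For the same reason, fitting the `both_m` variant (six
   m-values) to data generated with a single m per class drives at least
   one fitted m to the zero bound: the data cannot support the extra
   freedom, and the leaner `interface_m` variant is preferred.

## Design simulation

The fitted model is generative. `build_switch_chimera()` composes a switch
construct from a stable CTPRn core and the less stable CTPRan C-cap (the
S-typed interface travels with the cap, because the destabilising mutation
sits in the junction into the cap). Two re-design strategies are available
for enlarging the C-cap-unfolded intermediate:

* `destabilization_scan()` raises $G_i^S$ stepwise. It does raise $\beta$,
  but mostly by making the cap natively unfolded (larger $\alpha$), eroding
  the useful amplitude $\beta - \alpha$.
* `extend_repeats()` adds whole motifs, raising total ensemble stability so
  the core stays folded while the cap melts — higher $\beta$ at small
  $\alpha$.

`terminal_state_profile()` quantifies the thermodynamic asymmetry between
the two caps, and `partial_unfolding()` reports residual unfolding of the
non-cap helices at a given denaturant concentration (a diagnostic for how
cleanly the cap uncouples; its precise experimental counterpart is
ambiguous, so it is reported but never asserted against). An intermediate
"efficiency" in terms of a third quantity $\gamma$ appears in the design
literature without a usable definition; no efficiency is computed unless
the user supplies one.

A relaxed intermediate definition (C-cap unfolded with at least $k$ of the
remaining helices folded, computed by a count-resolved transfer matrix) is
available via `intermediate_profile(..., min_folded_others = k)`; the exact
single-state definition is the default and the one used everywhere else.

## Synthetic data

`series_recipe()`/`generate_series()` emulate a titration campaign: per
construct and replicate, $y = 1 - \theta_F(x) + \varepsilon$ with
homoscedastic Gaussian $\varepsilon$, by default 40 points on 0–6 M, two
replicates and $\sigma = 0.02$ — the flat residual fraction observed in real
global fits. `generate_raw_series()` inverts the normalization to produce
baseline-bearing raw traces for end-to-end tests. The generator reproduces
what matters for testing the fitter (shared parameters across constructs,
sigmoidal transitions, fraying-induced sloping baselines, replicate noise);
it does not emulate instrument effects (wavelength dimension, HT voltage,
concentration errors, buffer shifts of midpoints), heteroscedastic noise, or
baseline-estimation uncertainty, so passing tests demonstrate correctness of
the machinery, not robustness to every artefact of real CD data.

## NMR validation arithmetic

The `csp()`/`classify_peaks()` pair implements the combined amide
chemical-shift perturbation
$\Delta\delta = \sqrt{(\delta_H^2 + (0.14\,\delta_N)^2)/2}$ and the
three-way classification used to test C-cap unfolding by HSQC:
*unchanged* ($\Delta\delta \le 0.04$, boundary inclusive), *moved*, or
*lost* (disappeared or unassignable; dominates any computable value).
Perturbations above the 0.22 colour-scale ceiling remain "moved" — that
bound is an observed maximum, not a rule.

## Problem sizes and limitations

The shipped analyses use constructs up to 21 helices, grids of up to 801
points, fits of 12 curves with 256 starts, and recovery studies of 20
seeded trials — all single-CPU scale. Known limitations: no folding
kinetics, no thermal (van't Hoff / $\Delta C_p$) dimension, no branched or
two-dimensional topologies, no residue-level energetics (sequences are
metadata), and point estimates only (no bootstrap or posterior uncertainty
on fitted parameters; residual RMS per curve is the reported fit quality).
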