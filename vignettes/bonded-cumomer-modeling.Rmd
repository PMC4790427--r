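---
title: "Bonded-cumomer modeling of neuronal-glial brain energy metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bonded-cumomer modeling of neuronal-glial brain energy metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dynamic in vivo ^13^C MRS during [1,6-^13^C~2~]glucose infusion follows
the incorporation of ^13^C into the carbon positions of brain glutamate
(Glu) and glutamine (Gln). Fitting a compartmental metabolic model to
these turnover curves yields quantitative metabolic fluxes: the neuronal
and glial TCA cycle rates, the malate-aspartate shuttle exchange V~x~,
the apparent glutamate-glutamine neurotransmission cycle V~nt~, pyruvate
carboxylase V~pc~, and dilution fluxes. At high field the ^13^C-^13^C
scalar couplings between adjacent labeled carbons resolve each resonance
into multiplets (singlet, doublets, triplet, doublet of doublets), whose
individual time courses carry information about *joint* labeling of
neighbouring carbons that is averaged away in positional (total
enrichment) data. This package implements the forward model that
predicts those multiplet time courses, and the estimation machinery that
turns measured or synthetic curves into fluxes with Monte-Carlo
uncertainties, correlations and sensitivity scans.

## Bonded cumomers

A cumomer fraction pi~M{i}~ of molecule M is the sum of all isotopomer
fractions labeled at least at the position set {i}; the set size is the
cumomer order. One-bond multiplets only depend on the joint labeling of
a carbon and its immediate neighbours, so it suffices to track cumomers
whose position sets are contiguous in the carbon chain ("bonded") up to
order 3. For a carbon c with two inequivalent couplings (such as Glu
C4), the observable intensities follow from the bonded cumomers by

* Q = pi~{c-1,c,c+1}~
* D~left~ = pi~{c-1,c}~ − pi~{c-1,c,c+1}~
* D~right~ = pi~{c,c+1}~ − pi~{c-1,c,c+1}~
* S = pi~{c}~ − pi~{c-1,c}~ − pi~{c,c+1}~ + pi~{c-1,c,c+1}~

and for equal couplings (Glu/Gln C3) the two doublets merge into D and
the both-neighbour term becomes the triplet T. The patterns always sum
to the positional enrichment pi~{c}~; both transforms are linear and
invertible, and `c4_type_transform()` / `c3_type_transform()` enforce
the containment inequalities before applying them.

Cumomer balance equations close order by order: for a cumomer S of a
pool with concentration P,

P dpi~S~/dt = sum over inflows of V times the product of the source-pool
cumomer fractions covering the mapped positions, minus the total
consumption rate times pi~S~.

Condensations multiply the cumomer fractions of the substrates that
contribute fragments; unlabeled sources contribute the natural-abundance
factor (0.011 per position); reactions passing through a symmetric
intermediate average two orientation maps with weight 1/2.

## The canonical network

The two-compartment neuronal-glial network is assembled in
`build_default_network()`: plasma glucose (driven input, C1 and C6
labeled) feeds brain glucose; glycolysis delivers each triose half to a
compartment-specific pyruvate pool; a shared lactate pool exchanges with
both pyruvate pools (LDH exchange, constant 0.5 umol/g/min) and with
unlabeled extracerebral lactate (V~in~ = V~out~), which implements the
labeling dilution by plasma lactate; each compartment runs pyruvate
dehydrogenase, citrate synthase/IDH, and the 2-oxoglutarate-to-
oxaloacetate span with fumarate scrambling; V~x~ exchanges
2-oxoglutarate with Glu and oxaloacetate with Asp in both compartments;
the glia add pyruvate carboxylase (CO~2~ fixed into OAA C4), the
unlabeled acetyl-CoA dilution exchange V~dil~, glutamine synthesis
V~syn~ = V~nt~ + V~pc~, and glutamine efflux V~efflux~ = V~pc~; the
neurotransmission cycle moves Glu from neuron to glia and returns Gln at
V~nt~. A brain CO~2~/bicarbonate pool collects the decarboxylations and
feeds pyruvate carboxylase, closing the refixation loop.

Atom mappings are standard TCA biochemistry. One detail matters for the
phenomenology: in citrate, the oxaloacetate arm is reversed, so OAA
C4,C3,C2 map to 2-oxoglutarate C1,C2,C3 and OAA C1 is released as
CO~2~. Pyruvate carboxylase therefore routes labeled pyruvate C3 to
Glu/Gln C2 while its unlabeled pyruvate C2 dilutes Glu/Gln C3 in the
glia -- the simulated steady state indeed shows lower Gln C3 than Glu C3
enrichment, and PC-derived glutamine is depleted in C4-C3 double
labeling, which is what makes the GlnC4 doublet/singlet pair sensitive
to V~nt~ and V~dil~ separately.

Mass balance closes exactly for every pool given the seven free fluxes
(`validate_mass_balance()` returns zeros at machine precision); glial
PDH runs at V~TCAg~ = V~g~ + V~pc~ so that every reaction rate is
nonnegative for any nonnegative free-flux vector.

**State count.** `enumerate_bonded_cumomers()` tracks, for each
non-input pool, all positional states plus all bonded order-2/3 states,
after an intact-fragment filter: a multi-carbon fragment is dropped only
when the pool is consumed and no consuming reaction transfers the
fragment intact onto adjacent product carbons (such states influence
nothing and their equations decouple exactly). In the canonical network
the filter removes precisely the three glucose fragments spanning the
aldolase-cleaved C3-C4 bond, leaving 133 coupled equations:

| pool | states | pool | states |
|------|-------|------|-------|
| brain glucose | 12 | Glu (n, g) | 12 + 12 |
| pyruvate (n, g) | 6 + 6 | Gln | 12 |
| lactate | 6 | OAA (n, g) | 9 + 9 |
| acetyl-CoA (n, g) | 3 + 3 | Asp (n, g) | 9 + 9 |
| 2-oxoglutarate (n, g) | 12 + 12 | CO~2~ | 1 |

The pool list is a reconstruction: separate neuronal and glial pyruvate
pools, a shared lactate pool, a full six-carbon brain glucose pool and a
tracked CO~2~ pool are all physically motivated choices (compartmented
glycolysis, LDH-mediated mixing, the glucose transport step, and the
anaplerotic refixation of respiratory CO~2~), and together they are what
reproduces the 133-equation system size; the CO~2~ pool barely affects
the observables (OAA C4 feeds only Asp C4), but closes the carbon
balance.

Default pool sizes: Glu 8.4 umol/g split 90/10 neuronal/glial, Gln 4.3
glial, Asp 2.5 split 60/40, brain glucose 1.2, lactate 1.0, and small
intermediate pools (pyruvate 0.15, acetyl-CoA 0.1, 2-oxoglutarate
0.2/0.1, OAA 0.1, CO~2~ 1.0). Only totals for Glu/Gln/Asp are
measured quantities; the splits and intermediates are conventional
choices that make Glu/Gln kinetics dominant, and all are configurable
through `build_default_network(config = ...)`.

## Synthetic data

`generate_dataset()` emulates the study conditions rather than any
deposited data (none exist): 180 min of sampling at 10.6 min
resolution; plasma glucose enrichment rising linearly from natural
abundance to a 0.70 plateau over a 5-min bolus (the enrichment plateau,
not the infusate volume profile, is what the model consumes) and
constant thereafter; Gaussian noise per curve with constant absolute SD
equal to the steady-state value times a curve-class relative SD -- 5%
for totals, 15% for individual multiplets, mirroring the Cramer-Rao
inclusion threshold of the spectral quantification. The observable sets
are fixed by that threshold: 6 totals (positional variant), 11
quantifiable multiplets (GluC4 S, D43; GluC3 S+T, D; GluC2 S, D23;
GlnC4 S, D43; GlnC3 S+T, D; GlnC2 S), and their union of 17 curves
(bonded variant). The C3 singlet and triplet are only reported as their
sum because their central lines overlap. The reference truth is
V~pdh,n~ = 0.40, V~g~ = 0.10, V~pc~ = 0.06, V~x~ = 0.45, V~nt~ = 0.10,
V~dil~ = 0.30, V~out~ = 0.30 umol/g/min, i.e. CMR~glc(ox)~ = 0.28 and
the middle points of the V~nt~ and V~dil~ sensitivity grids.

What the generator does *not* emulate: animal-to-animal variability,
time-varying Cramer-Rao bounds (the real per-point uncertainties shrink
as enrichment grows), spectral baseline artefacts, and correlated
quantification errors between overlapping multiplets. Passing tests
therefore demonstrate correctness of the machinery and the information
content of multiplet curves under the stated noise model, not
performance on raw spectra.

## Estimation

`fit_fluxes()` minimises the weighted sum of squares
sum(((model − data)/sd)^2) with the Levenberg-Marquardt algorithm
(`minpack.lm::nls.lm`), residuals weighted by 1/sd so that noisy curves
do not dominate the joint regression. All seven fluxes are free within
[0, 5] umol/g/min; nonnegativity is physical and the upper bound is far
above brain rates. The positional variant is fitted with the order-1
reduction of the cumomer system (identical equations for the positional
states, a third of the size).

`monte_carlo()` follows the classical parametric scheme: noise with the
experimental variance is added to the best-fit model curves, each
replicate is refitted starting from the base estimates, and the sample
of estimates is summarised by mean, SD, a maximum-likelihood gamma fit
(`MASS::fitdistr`) with its FWHM (bisection on the half-maximum
crossings of the fitted density), and the Pearson correlation matrix. A
replicate that does not converge is dropped; more than 10% failures
abort the analysis.

`sensitivity_scan()` fixes V~nt~ (default grid 0.07, 0.10, 0.20) or
V~dil~ (0.20, 0.30, 0.60) and refits the remaining fluxes, storing the
implied GluC4/GlnC4 total and multiplet curves. On synthetic data at the
reference condition this reproduces the qualitative signatures of the
method: the GlnC4 singlet falls and the doublet rises for increasing
constrained V~nt~ while the total barely moves, and V~dil~ moves the
GlnC4 singlet but not the doublet.

## Numerical choices

* **Integrator.** Explicit adaptive Dormand-Prince 5(4) (the classical
  nonstiff Runge-Kutta pairing), implemented in C++ for speed, with
  relative tolerance 1e-8 and absolute tolerance 1e-10 by default; the
  plasma input is handled as an exact piecewise-linear forcing.
  `integrate_system(engine = "r")` integrates the identical term table
  with `deSolve::lsoda` as an independent cross-check, and the test
  suite verifies agreement; a brute-force full-isotopomer simulation
  (`oracle_isotopomer_simulation()`) validates the cumomer equations on
  small networks to 1e-6.
* **Initial condition.** Natural abundance 1.1% at every position,
  independent across positions, so an order-k cumomer starts at
  0.011^k; `init_natural = FALSE` starts at zero. With the input held
  at natural abundance the state is an exact fixed point.
* **Identifiability and starts.** Fits on noiseless data recover the
  truth to better than 1% from starts perturbed by +-50%; Monte-Carlo
  refits start from the base fit.
* **Degenerate inputs.** Zero SDs fall back to unit weights; a
  constrained flux equal to its true value costs no residual; transform
  inputs violating the containment inequalities beyond tolerance raise
  errors rather than returning negative intensities.

## Problem sizes

The shipped tests and analyses run at desk scale: 133-state
integrations take milliseconds, a bonded-variant fit about a second,
and the variant comparison uses 50 Monte-Carlo replicates per variant
(the generator supports the full 500 of a production analysis at about
ten times the cost). With 50 replicates per variant at the reference
noise level, the bonded model shows a lower V~nt~-V~dil~ correlation
and a narrower V~dil~ distribution than the positional model; the
magnitude of both improvements depends on the realised noise and is
reported by the tests rather than asserted.

## Limitations

* Single-tracer glucose input only; acetate co-infusion would need an
  additional driven pool and richer glial labeling.
* Pool concentrations are constant (metabolic steady state); dynamic
  pool-size changes are out of scope.
* Two-bond couplings, carboxyl-carbon observables (C1/C5) and
  chemical-shift simulation are not modeled.
* The network is the fixed two-compartment topology; genome-scale or
  three-compartment variants are not supported.
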