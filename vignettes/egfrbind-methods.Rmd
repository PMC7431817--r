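---
title: "Models and methods: EGFR ligand-binding equilibria and homo-FRET cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: EGFR ligand-binding equilibria and homo-FRET cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrbind)
```

## The scientific problem

Equilibrium EGF binding to cells is classically summarized by a Hill
isotherm, but the Hill coefficient of a whole-cell binding curve blends two
molecular phenomena: *cooperativity* (unequal dissociation constants for the
first and second ligand binding to a receptor dimer) and *oligomerization
linkage* (liganded monomers dimerizing more or less avidly than unliganded
ones). Disentangling the two requires an explicit mass-action model of the
receptor population. `egfrbind` implements such a model for EGFR, in which
the extracellular domain (ECD) switches between a closed and an extended
conformation, the kinase domain (KD) between an inactive and an active
conformation, and dimerization proceeds along two pathways that differ in
the configuration of the kinase dimers.

## The equilibrium model

Twelve molecular species are tracked. Monomers: `CI`, `CA`, `EI`, `EA`
(closed/extended ECD crossed with inactive/active KD) and the liganded
extended monomers `EIL`, `EAL`. Dimers, which form only from extended-ECD
monomers: `DES`, `DESL`, `DES2L` (symmetric, inactive kinase dimers with 0,
1 and 2 ligands) and `DEA`, `DEAL`, `DEA2L` (asymmetric, active kinase
dimers). Nine constants govern the equilibrium:

| constant | meaning | units |
|---|---|---|
| `K1` | inactive/active KD equilibrium (monomers) | -- |
| `K2` | closed/extended ECD equilibrium | -- |
| `K3` | EGF binding to an extended monomer | nM |
| `K4` | dissociation of the symmetric-KD dimer | receptors/cell |
| `K5`, `K6` | first/second EGF binding to the symmetric-KD dimer | nM |
| `K7` | dissociation of the asymmetric-KD dimer | receptors/cell |
| `K8`, `K9` | first/second EGF binding to the asymmetric-KD dimer | nM |

Receptor species are counted in copies per cell and ligand in nM, with no
volume conversion between them; free ligand is identified with added ligand
(`depletion_check()` quantifies the error of that assumption, which is a few
percent at worst for the cell numbers and volumes of a typical suspension
assay). The model deliberately excludes binding kinetics, ECD conformations
beyond closed/extended, ligand binding to the closed ECD, and oligomers
beyond dimers.

The key modelling assumptions are: conformations of the ECD and KD are
uncoupled in monomers; only extended-ECD receptors dimerize or bind ligand;
dimerization of inactive-KD monomers produces symmetric kinase dimers and
dimerization of active-KD monomers produces asymmetric ones; and the two
dimer classes have independent ligand affinities. Erlotinib and lapatinib
(type I/II kinase inhibitors) are modelled purely as shifts of `K1`.

### Closed-form solution

Every species concentration is proportional to `[EI]` or `[EI]^2` through
the mass-action relations, so the receptor conservation law collapses to a
single quadratic `a(L)*[EI]^2 + b(L)*[EI] = Rtot` with `a, b > 0`. For
`Rtot > 0` this has exactly one positive root, which `solve_equilibrium()`
evaluates as `2*Rtot / (b + sqrt(b^2 + 4*a*Rtot))` -- algebraically equal to
the textbook root but immune to the cancellation the subtractive form
suffers when `a*Rtot << b^2` (low-expression cells). `L = 0` falls out of
the same expressions exactly (all liganded species carry a factor `L`), and
`Rtot = 0` returns the all-zero state without entering the general path. The
test suite checks the closed form against a brute-force numeric root solve
of the full 12-species system (residuals written in log space, where the
eleven mass-action relations are linear) over 1,300 random parameter draws
spanning three decades around the reference values, `Rtot` from 1e3 to 1e7
and `L` from 1e-3 to 1e3 nM, at relative tolerance 1e-8.

Bound ligand counts singly liganded species once and doubly liganded dimers
twice, so `bound -> Rtot` at saturating EGF.

### Structural identifiability: a two-dimensional gauge freedom

A central and, to our knowledge, underappreciated property of this model is
that the observable -- `bound(Rtot, L)` for any set of `(Rtot, L)` points,
even noise-free and absolutely calibrated -- does **not** determine all
eleven parameters (`K1` per condition plus `K2`-`K9`). Writing
`EI' = (1 + 1/K1)[EI]`, the observable depends on the parameters only
through

* the monomer group `S = K2 + 1` and `K3`,
* three per-condition polynomial coefficients of the dimer pathways,
  `A0 = alpha + beta`, `A1 = alpha/K5 + beta/K8`,
  `A2 = alpha/(K5*K6) + beta/(K8*K9)`, where `alpha = 1/(K4*(1+1/K1)^2)`
  and `beta = 1/(K1^2*K7*(1+1/K1)^2)`.

One exact invariance can be written down directly: for any `mu > 0`,

```
K2 -> mu*(K2 + 1) - 1,  K3 -> K3/mu,  K4 -> K4/mu^2,  K7 -> K7/mu^2
```

leaves every binding curve unchanged (numerically verified to 7e-16). A
second, independent exact invariance mixes `K5`, `K6`, `K7`, `K8` and the
`K1`s: the numeric Jacobian of a rich noiseless design (dense concentration
grid, four expression levels, three conditions) has rank 9 of 11, and
multi-start fits of noiseless synthetic data reach machine-zero residual
norms at parameter sets whose `K5` ranges from 26 to 4400 nM while
reproducing the generating curves to 1e-15 on out-of-sample grids.

Consequences drawn in this package:

* The *linkage constants* `K4*K5*K6/K3^2` and `K7*K8*K9/K3^2` are invariant
  under the first gauge transformation, which is one reason they are the
  robust summary of the fit.
* `fit_global()` by default fits all eleven parameters (the procedure used
  to produce the reference estimates); the gauge position of the result is
  then determined by the optimizer path and box bounds, not by the data.
* For parameter-recovery experiments the `fix` argument pins the two gauge
  degrees of freedom. We fix `K2` and `K5` (the null-space directions have
  their largest components there, so the conditioning of the remaining
  9-parameter problem is best); with those two held at their generating
  values, noiseless synthetic data return the other nine parameters to
  machine precision from random multi-starts.
* Beyond the two exactly flat directions the objective has two further very
  soft singular directions (singular values ~3e-3 and 8e-2 of the largest).
  These are loaded mostly on `K7` and the `K1`s, which is why realistic
  noise produces orders-of-magnitude-wide confidence intervals for `K7`
  while `K9` stays tight.

## Global fitting

`fit_global()` minimizes the summed squared deviation between measured
intensities and `scale * bound(params, Rtot, L)` over all datasets, with
`K2`-`K9` shared and `K1` free per condition. Choices that were genuinely
open, and how they were resolved:

* **Intensity scale.** How fluorescence maps to molecules/cell is not part
  of the data, so one nuisance scale is introduced per *condition* (shared
  across the expression gates of that condition, which are gated from the
  same stained sample on the same instrument settings); `scale_per =
  "dataset"` relaxes this. Scales are profiled analytically -- for fixed
  model parameters the optimal scale of a group is
  `sum(w*I*b)/sum(w*b^2)` -- so the optimizer only ever sees the eleven
  (or fewer) model parameters.
* **Weighting.** The default objective is the plain sum of squared
  deviations; `weighted = TRUE` uses `1/sem^2` weights. For the 5%-CV
  synthetic designs the weighted objective is markedly better conditioned
  (multiplicative noise makes the top of the curve dominate the unweighted
  norm), and the noisy-data tests use it.
* **Optimization.** Parameters live in log10 space inside box bounds of +/-2
  decades around reference magnitudes. Starts are a maximin Latin hypercube
  (seeded, hence reproducible), each refined by Levenberg-Marquardt
  (`minpack.lm`). Among optima whose norms tie within numerical noise the
  smallest `K7` wins, making the returned gauge position deterministic.
  Parameters ending on a box bound are flagged with a warning.
* **Confidence intervals.** "Repeat the optimization 100 times" admits two
  readings: re-starts on the same data, or refits of perturbed data. Both
  are implemented; the default is a parametric bootstrap (intensities
  perturbed by `Normal(0, sem)`, each replicate refitted from the point
  estimate plus a few fresh starts, 2.5/97.5 percentiles reported), with
  `ci_method = "restart"` giving the pure multi-start spread. Fewer than
  half the repeats converging is treated as an error rather than a result.

## Phenomenological analysis

`fit_hill()` fits `I = Imin + (Imax - Imin)/(1 + 10^(n*(log10 Kd - log10 c)))`
in log-concentration space with a small multi-start grid (`n` in 0.5/1/2,
`Kd` at the grid quartiles), `Imin` constrained non-negative and ties broken
toward the smallest `n`. Reported uncertainties are asymptotic standard
errors from the final Jacobian; errors quoted alongside published fits of
this kind are sometimes replicate-based and can be much smaller, so the two
are not directly comparable. `scatchard()` transforms a curve to
`(bound, bound/free)` using nominal free ligand.

On model-generated curves the package reproduces the characteristic
phenomenology: apparent cooperativity rises with receptor number when the
inactive kinase conformation dominates (`n` about 1.23 to 1.35 between
390,000 and 1,070,000 receptors/cell at `K1 = 104`), stays at `n ~ 1.05`
when the active conformation is stabilized (`K1 = 25`), and the
whole-population curve at 560,000 receptors/cell is described by
`n ~ 1.27`, `Kd ~ 4.8 nM` -- close to, but not identical with, the Hill
parameters estimated from the underlying experimental data, as expected for
two descriptions of the same binding surface.

## Homo-FRET cluster analysis

`anisotropy()` implements `r = (I_par - G*I_perp)/(I_par + 2*G*I_perp)`.
`model_anisotropy()` gives the anisotropy of a population in which a
fraction `mon` is monomeric and the rest sits in `N`-mers, after bleaching
to residual fraction `s`: surviving fluorophores per cluster are binomial,
each `k`-occupied cluster contributes intensity proportional to `k`, and a
fluorophore FRETting with `k - 1` partners at normalized inverse distance
`d` is depolarized by the factor `(1 + d^6)/(1 + k*d^6)`.

The typeset source of this mixture formula is ambiguous about the
prefactor; `(1 - mon)/(N*s)` is adopted because it is the unique choice
under which the intensity weights normalize (`E[k] = N*s`) and all three
physical limits hold: `r -> r1` as `s -> 0`, `r = r1` for `N = 1`, and
`r = r1` for `mon = 1`. These limits are returned exactly (by construction,
not by evaluating `0/0`). Constants follow the GFP literature: `r1 = 0.34`,
`rFRET = 0`, and `d = 1`, i.e. fluorophores one Forster distance (4.8 nm)
apart; all are exposed as arguments.

`fit_bleach_series()` searches `N` on an integer grid (1..30 by default) --
the binomial sum is only defined for integer `N`; a generalized-binomial
relaxation is available behind `relaxed = TRUE` for sensitivity analysis --
and profiles `mon` analytically per `N`, since the model is linear in
`mon`. A series statistically indistinguishable from a flat line at `r1`
carries no cluster information and is returned as the degenerate
`(N = 1, mon = 1)` with a warning. `mc_confidence()` draws each anisotropy
from `Normal(r, sd)` per point, refits, and reports percentile intervals
over (by default) 500 replicates.

## The synthetic-data generator

`simulate_binding_experiment()` emulates the statistical structure the
fitting stages assume: 3 conditions x 4 gates with receptor numbers
390,000 / 630,000 / 1,070,000 / 560,000, a 14-point two-fold dilution
series descending from 260 nM (so 0.032-260 nM, matching the span over
which such binding curves are measured; the exact published range is not
stated, and both the grid and its length are configurable), 3 replicates,
and multiplicative Gaussian noise with CV 0.05 -- multiplicative because
flow-cytometric mean intensities of bright populations have
intensity-proportional error, and 5% because that is the scale of the error
bars on published curves of this kind. Negative draws are truncated at zero
and counted. The per-condition intensity scale defaults to 2e-3 arbitrary
units per bound molecule, giving mean intensities of order 10^3.

What the generator does *not* emulate: per-cell intensity distributions and
gating (only gate-level means), instrument background and its subtraction,
ligand depletion, receptor internalization or synthesis during the assay,
and any deviation of the true biology from the twelve-species model itself.
Passing recovery tests therefore demonstrates that the estimation machinery
inverts the model correctly at realistic noise -- not that the model is
correct for real cells, nor that real data would determine the parameters
this well.

`simulate_bleach_experiment()` draws `r(s)` from the mixture model plus
Gaussian noise on a geometric bleach schedule (`0.85^k`, 15 steps), the
shape stepwise photobleaching produces in practice.

## Problem sizes and numerical tolerances

The shipped tests compare the closed-form solver with the brute-force root
solve on 300 draws in the unit tests plus 1,000 draws in the acceptance
suite (tolerance 1e-8); run the noiseless 12-dataset recovery with 15-40
Latin-hypercube starts; run bootstrap coverage with 40 repeats at 3 starts
each; and use 150-500 Monte-Carlo replicates for the cluster-fit intervals.
`scripts/acceptance.R` re-runs the noiseless recovery with 60 starts (with
deterministic seed-derived restarts in the rare event no start reaches the
zero-residual basin). Conservation is enforced at 1e-8 relative; fraction
sums at 1e-10; the optimizer runs with `ftol = ptol = 1e-15`.

## Known limitations

* Absolute values of `K2`, `K3`, `K4`, `K7` from an unconstrained fit are
  gauge positions, not measurements; only the nine identifiable
  combinations (and anything invariant, such as the linkage constants) are
  data-determined. This mirrors the very wide interval estimates such fits
  produce for `K7`.
* The bootstrap refits use a reduced start set; in multimodal regions the
  intervals can inherit local-optimum scatter (they are intentionally
  reported as repeat-fit intervals, not likelihood profiles).
* The cluster-size fit treats all clusters as a single size `N`; real
  populations with mixed cluster sizes return an effective intermediate
  value.
* The equilibrium model is for suspension cells below the membrane phase
  transition; nothing in the package addresses diffusion-limited
  redistribution or internalization.
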