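---
title: "Quantifying PVD dendritic arbor morphology, microtubule polarity, and FRAP kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PVD dendritic arbor morphology, microtubule polarity, and FRAP kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdarbor)
```

## The biological measurement

The *C. elegans* PVD neuron grows a highly stereotyped dendritic arbor: a
primary (1°) dendrite runs the length of the animal along the
anterior-posterior (A-P) axis, with one arm anterior of the soma and one
posterior. Repeating candelabra-shaped units — *menorahs* — emerge from it:
a secondary (2°) stem grows orthogonally (dorsoventrally) from the primary;
at the tertiary line it bifurcates into two tertiary (3°) arms running
along the A-P axis; and quaternary (4°) twigs rise orthogonally from the
arms. Mutations in membrane-trafficking and motor genes redistribute or
abolish these branches regionally, so the core measurement is *where along
the A-P axis branching activity lands*, not just how much of it there is.

`pvdarbor` implements that measurement on neuron skeletons in SWC format:

1. **Primary-path extraction** (`extract_primary()`): the path through the
   soma spanning the greatest anterior and posterior extents along the A-P
   axis, parameterized by signed arc length (soma = 0, anterior positive).
   Arc length along the extracted path plays the role of image
   straightening: downstream positions are 1-D coordinates along the
   primary, so pre-straightened and curved skeletons are treated alike.
   We rank candidate arms by axial extent with total arc length only as a
   tie-break, because a menorah hanging near a primary tip accumulates more
   *arc length* than the remaining stretch of primary while spanning less
   of the axis; raw longest-path extraction would walk into it.
2. **Branch-order classification** (`classify_branch_orders()`): any
   protrusion from the primary is a 2° branch, regardless of length or
   orientation — short filopodia and misoriented mutant stems count. A
   child of a 2° whose chord lies within `theta_t` of the A-P axis is a 3°;
   a child of a 3° deviating from the axis by more than `theta_q` is a
   correctly-oriented 4°. Misoriented children keep their order label but
   are flagged and excluded from the oriented counts.
3. **Region segmentation** (`segment_regions()`): the anterior extent is
   cut into three equal-length regions (+1 proximal, +2, +3 distal); the
   entire posterior extent is region -1. The posterior region is *not*
   length-matched to the anterior thirds — it is simply whatever posterior
   primary exists.
4. **Counting** (`count_by_region()`): 2° branches are assigned to regions
   by the position of their base on the primary; 3° and 4° branches are
   assigned by the base position of the secondary at the root of their
   menorah, so a menorah whose arms cross a region boundary is still
   counted in one region.
5. **Branch complexity index** (`branch_complexity()`): per region,
   the mean of three equally weighted components,

   $$\mathrm{BCI} = \tfrac13\left(\frac{n_2}{n_2^\ast} +
     \frac{n_{2\to 3}}{n_2} + \frac{n_4 / n_3}{q^\ast}\right),$$

   where $n_2$ is the secondary count, $n_{2\to 3}$ the number of
   secondaries bearing at least one tertiary, $n_4/n_3$ the mean number of
   quaternaries per tertiary, and $(n_2^\ast, q^\ast)$ the "ideal segment"
   parameters. An ideal segment in which every secondary carries a
   tertiary scores exactly 1; an empty segment scores exactly 0.

```{r quantify-demo}
sim <- simulate_arbor(builtin_profiles("wild_type"), seed = 42)
quantify_arbor(sim$arbor)[, c("region", "n2", "n2_with3", "n3", "n4", "bci")]
```

## Parameters that matter, and the choices behind them

**Orientation thresholds** `theta_t = theta_q = 45` degrees. Menorah
geometry is orthogonal: tertiaries run along the A-P axis, quaternaries
dorsoventrally. 45 degrees is the natural midline between the two regimes
and is insensitive to the simulator's orientation noise (a few degrees at
most for intact branches). Both are configurable in
`classification_params()`.

**Continuation threshold** `theta_c = 30` degrees. Skeletons encode a
tertiary arm bearing three quaternaries as a chain with three internal
branch points. At each internal branch point the most collinear child edge
(within `theta_c`) continues the same branch; all other children start
child branches. 30 degrees keeps an arm one branch across its twig
attachments while still terminating a 2° stem at its orthogonal T-junction
(the two arms leave the stem at about 90 degrees).

**Ideal-segment parameters** `n2_star = 14`, `q_star = 5`. No reference
values exist for these, so the defaults are the package's own calibration:
`n2_star` equals the wild-type simulator's expected secondary count in its
densest anterior region (uniform across regions), and `q_star = 5`
quaternaries per tertiary describes a fully elaborated menorah. Both are
explicit arguments everywhere they are used so users can recalibrate.
Components are deliberately **not clipped at 1**: anterior-shifted mutants
are *more* complex than wild type in the distal +3 region, and clipping
would erase exactly that signal.

**Degenerate regions.** With $n_2 = 0$ the tertiary fraction is defined as
0, and with $n_3 = 0$ the quaternary component is 0, so branch-poor mutants
get finite, comparable scores rather than missing values.

**Boundary convention.** Regions are half-open $[\mathrm{lo}, \mathrm{hi})$
with the distal end of +3 closed; a base exactly on a boundary belongs to
the more anterior region. This makes counting deterministic under
floating-point arc length, and shifting a base across a boundary moves
exactly one count between the two adjacent regions.

## Kymograph analysis

EB comets mark growing microtubule plus ends, so in a time-by-position
kymograph (8 frames/s by default) a comet moving away from the soma
reports a plus-end-out microtubule. `detect_comets()` uses transparent,
desk-scale machinery rather than a Hough/Radon transform: per-frame local
maxima above a robust `median + 3 MAD` threshold, log-parabolic sub-pixel
refinement (exact for an isolated Gaussian profile, which is why the
zero-noise oracle recovers slopes to numerical precision), greedy
nearest-neighbour linking with a 3 px/frame gate and 2-frame gap
tolerance, and a least-squares line fit per track. Tracks shorter than 5
frames are discarded and tracks slower than `v_min = 0.02` um/s are
treated as stalled comets and excluded from polarity counts, which follow
only directed movements. Direction is soma-relative (anterograde = away
from the soma) for dendrites and axon alike, so mirroring the position
axis of a kymograph leaves every velocity unchanged.

```{r kymo-demo}
scene <- simulate_kymograph(builtin_profiles("wild_type"), region = "-1",
                            seed = 7, overrides = list(background = 5))
classify_polarity(detect_comets(scene$kymo))
```

## FRAP analysis

Traces follow the bleach protocol (pre-bleach frames at $t<0$, a 1 s
bleach at $t=0$, recovery sampled every second for five minutes).
`normalize_trace()` divides by the pre-bleach mean, which absorbs detector
gain; `fit_recovery()` fits the single-exponential recovery
$F(t) = f_0 + (f_\infty - f_0)(1 - e^{-t/\tau})$ by Levenberg-Marquardt
least squares, with starting values taken from the trace itself (first
post-bleach point, last-decile mean, time to half recovery). The mobile
fraction is $(\min(f_\infty, 1) - f_0)/(1 - f_0)$, with the plateau
clamped at the pre-bleach level because noise can push it above 1. A
perfectly flat post-bleach trace is returned as a degenerate fit
($f_\infty = f_0$, $\tau = \infty$, mobile fraction 0) rather than an
error. The single-exponential model is the package's choice: "faster and
more complete recovery" maps onto a smaller $\tau$ and a larger mobile
fraction, which is what group comparisons need; reaction-diffusion models
are out of scope. An optional reference-region double normalization for
acquisition photobleaching is not implemented because the acquisition
protocol modeled here does not describe one.

`compare_recovery()` interpolates all post-bleach traces onto a common
grid and runs the two-way ANOVA (genotype x time) on the per-animal
intensities — ordinary, not repeated-measures, which matches the common
practice for these curves; treating time as repeated measures would
require a correlation model the data format does not carry.

## Statistics from first principles

`two_way_anova()` computes type-II sums of squares from nested
least-squares fits: each main effect is the residual-SS reduction when
added to the model containing the other main effect, and the interaction
is the further reduction from the crossed term. On balanced designs this
equals the classical decomposition exactly ($SS_{total} = \sum SS$ to
numerical precision); type II is the appropriate convention for the
unbalanced cohorts that arise when animal numbers differ by genotype.
`tukey_hsd()` uses the studentized-range distribution with Tukey-Kramer
standard errors; `multiple_t_tests()` reports unadjusted Welch tests (the
convention of Prism-style "multiple t-tests") plus a Holm-adjusted column
for transparency. `penetrance()` scores each animal against a threshold
rule — by default, complexity below 50% of the wild-type reference mean in
*both* the -1 and +1 regions, the regions where the classic
loss-of-branching phenotype manifests — and wraps the phenotypic fraction
in an exact Clopper-Pearson interval. The rule is configurable because
"has the phenotype" is not otherwise defined numerically.

## What the simulator emulates — and what it does not

`simulate_arbor()` generates arbors with known ground truth: per-region
Poisson secondary counts at uniform positions, Bernoulli(`p3`) menorah
formation, two tertiary arms per menorah trimmed so that same-side arms of
neighbouring menorahs never overlap in A-P extent (self-avoidance, with
stems bent into their corridor), Poisson(`mu4`) quaternaries per arm, and
Gaussian orientation noise throughout. Defective secondaries — the short,
misoriented filopodia characteristic of trafficking mutants — are drawn
with truncated lengths and inflated orientation noise. Arbors are 2-D
($z = 0$): all quantities of interest live in the A-P/dorsoventral plane,
as in maximum-projection-style analysis.

The wild-type and rab-10-like profiles are calibrated so the *expected*
whole-arbor totals equal the reported cohort means (wild type: 42
secondaries, 114 quaternaries; mutant: 28 and 17); per-region rates are
estimates chosen to reproduce each genotype's described regional shape
(wild type sparse in +3; the mutant anterior-shifted with a near-total
posterior loss of 3°/4° branches), since per-region reference values are
not available. The other profiles are qualitative: they reproduce
orderings (e.g. the kinesin;rab-10 double mutant peaking posteriorly), not
magnitudes. Early larval stages reuse the L4 secondary rates, so
developmental filopodia dynamics are not modeled. Nor are branch dynamics
(outgrowth/retraction), 3-D geometry, image noise, or skeletonization
artifacts — passing the simulator-based tests therefore validates the
*counting and fitting machinery*, not robustness to segmentation errors in
real micrographs.

Reproducibility: every generator takes an explicit seed; cohort members
use per-animal seeds derived from the master seed by a fixed affine map
modulo $2^{31}-1$, so cohorts are reproducible across platforms and
identical (profile, seed) pairs give byte-identical SWC output.

## Problem sizes and numerical tolerances

The package's own verification uses cohorts of 200 simulated arbors for
calibration recovery (accepting the reported means within two standard
errors of the cohort mean), 100 zero-noise arbors for the exact counting
oracle, 50 kymograph scenes and 50 FRAP traces for the noise-robustness
checks, and 2000 simulated null datasets for the type-I error and
family-wise error calibration of the ANOVA and Tukey procedures. Exact
identities (round trips, complexity normalization, zero-noise detection)
are asserted at tolerances of 1e-6 or tighter; simulation-based error
rates carry explicit binomial allowances.

## Known limitations

- Branch-order classification assumes parent pointers run from the soma
  outward (the standard SWC convention for rooted reconstructions).
- The continuation rule can, in principle, misjoin branches in skeletons
  with pathological geometry (e.g. a tertiary arm meeting its stem at a
  shallow angle); the thresholds are exposed for such data.
- Greedy nearest-neighbour linking can fragment comet tracks at crossings
  under noise; fragments keep the correct velocity sign, so polarity
  fractions are robust, but track counts can exceed comet counts in dense
  scenes.
- The penetrance rule requires a wild-type reference cohort measured with
  the same ideal-segment parameters.
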