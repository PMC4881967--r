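---
title: "SAXS-restrained hybrid sampling: model, parameters and design choices"
author: "saxsmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAXS-restrained hybrid sampling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsmc)
```

## The problem and the method

A conventional conformational sampler (in practice, a molecular dynamics
engine) explores the states favored by its force field. When the goal is to
enrich sampling toward a *known target state* — structure refinement, or the
generation of near-native ensembles — the force field alone may never take
the trajectory there. Small-angle X-ray scattering (SAXS) provides a cheap,
low-resolution fingerprint of a structure's global shape and size: a 1D
intensity profile $I(q)$ on a grid of scattering-vector magnitudes $q$.

`saxsmc` implements a hybrid scheme: an unmodified propagator advances the
chain for a fixed segment, and after every segment a Metropolis
*structure-acceptance judgment* compares the candidate's computed SAXS
profile with the target profile. The pseudo-energy of a structure is

$$E = \omega \, k_B T \, \chi,$$

where $\chi$ is a dimensionless discrepancy between the decoy and target
profiles and $\omega$ a dimensionless weight. The Metropolis ratio
$\min\{e^{-(E_n - E_{n-1})/k_B T}, 1\}$ then reduces algebraically to
$\min\{e^{-\omega(\chi_n - \chi_{n-1})}, 1\}$ — the acceptance probability is
temperature-independent given $\chi$, which the unit tests assert. On
rejection the candidate is discarded and propagation resumes from the last
accepted structure with fresh randomness — the standard hybrid-MC choice,
which preserves detailed balance for the built-in sampler. The saved decoy after
each judgment is the post-decision state, and $\chi$ of the initial structure
initializes the chain of comparisons.

## The discrepancy family

Two families of discrepancy are provided for computed profiles, each with a
$q^n$ weighting exponent $n \in \{0, \dots, 4\}$ that shifts emphasis from
the Guinier region (global size) toward the Porod region (surface detail):

* `eq1`: $\chi = \frac{c}{N} \sum_q \left| \frac{q^n \log I_{dec}(q) -
  q^n \log I_{tgt}(q)}{\log I(q_{min})_{tgt}} \right|$
* `eq2`: $\chi = \log\left[ \frac{c}{N} \sum_q \left| \frac{q^n I_{dec}(q) -
  q^n I_{tgt}(q)}{I(q_{min})_{tgt}} \right| \right]$

with amplification $c = 1000$, $N$ grid points on the default linear grid of
120 points from $q = 0.005$ to $0.6\,\text{Å}^{-1}$, and the single global
normalizer $I(q_{min})_{tgt}$ — the lowest-$q$ intensity standing in for the
forward limit $I(0)$ — inside the sum. Logarithms are base 10, the SAXS
plotting convention. The choice only rescales `eq1`'s $\chi$ by a
constant, and the acceptance layer is invariant to it up to a rescaling of
$\omega$; `eq2` shifts by an additive constant. `eq2` may legitimately return
negative values when the normalized sum is below 1; an exactly zero sum
(identical profiles) is reported as an error rather than $-\infty$.

For experimental data (`eq6`, `chiExperimental`) the computed profile is
interpolated onto the experimental grid (linear in $\log I$ over $q$), a
constant offset $\Delta_{offset}$ — the difference of the log-intensities at
the lowest shared $q$ point, standing in for the experimentally unreachable
$q = 0$; a mean over the five lowest points is available by configuration —
is removed, and each residual is weighted by the experimental per-point
log-intensity error $\delta I_{log}(q)$.

Which form should drive the pseudo-energy is an empirical question answered
by ranking: `makeDecoyPool()` emulates the calibration stage by running
unbiased control simulations from a helix, a sheet and a coil fixture at
310, 340 and 370 K and scoring every decoy against its own initial
structure's profile; `rankDiscrepancyForms()` then sorts the ten candidate
forms by the Spearman correlation between $\chi$ and RMSD. On this pooled
design the correlation decreases monotonically with $n$ for both families,
because larger $n$
weights high-$q$ detail that decorrelates from global backbone RMSD. On
narrow, single-topology pools the ordering is *not* guaranteed; topological
and thermal diversity of the pool is what produces it.

## The propagator stand-in and the fixtures

The package replaces the all-atom MD engine with a coarse-grained C$\alpha$
chain sampler, because the judgment layer only requires a propagator that
produces physically continuous candidate structures. The built-in sampler is
an internal Metropolis walker over

* harmonic virtual bonds: target 3.8 Å, force constant 20 kcal/mol/Å²;
* harmonic pseudo-angles: target 110°, 2 kcal/mol/rad² (a soft, generic
  chain-stiffness choice, deliberately without residue-specific secondary
  structure propensities);
* soft excluded volume: harmonic repulsion below 4.0 Å between beads at
  least two positions apart, 2 kcal/mol/Å².

Moves are single-bead Cartesian jitter (sd 0.15 Å), crankshaft rotations of
2–5 internal beads (sd 0.15 rad) and torsion pivots of the chain tail about
a bond axis (sd 0.1 rad); a segment is 50 internal moves by default (6 is
the analogue of the short judgment interval). These amplitudes were chosen
once as a realistic gently-diffusing regime — a 20-mer drifts roughly 1 Å
RMSD per segment — and the sampler satisfies detailed balance at its own
energy, which the tests verify against the exact Boltzmann bond-length
marginal (including the $r^2$ Cartesian measure factor) on a bonds-only
chain. `runHybrid()` equally accepts any user function
`(structure, stream) -> structure`, and `judgeExternalTrajectory()` applies
the judgment retrospectively to frames from a real MD engine (where a
rejection can only carry the reference $\chi$ forward — a filtered
re-weighting, since the engine cannot rewind).

Fixture generation (`makeFixture`) provides the mono-residue 20-mer toys the
evaluation runs on: an ideal C$\alpha$ helix (rise 1.5 Å, twist 100°, radius
2.3 Å), a two-strand extended hairpin (3.4 Å axial rise with a ±0.85 Å pleat
so consecutive C$\alpha$ distances stay at 3.8 Å), and a seeded self-avoiding
random coil with 3.8 Å steps. `perturbedStart()` manufactures starting
structures at a controlled RMSD from a target (±15 % window) by propagating
away from it, standing in for cluster-center models.

What the fixtures do *not* emulate: side chains, residue-specific form
factors, force-field secondary-structure preferences, solvent, and the
rugged energy landscape of real peptides. Passing tests on these toys
demonstrate the mechanics and the direction of the enrichment effect, not
refinement performance on real proteins.

## The scattering calculator

`debyeProfile()` evaluates the Debye sum
$I(q) = \sum_i \sum_j f_i(q) f_j(q) \frac{\sin qr_{ij}}{qr_{ij}}$ with
coarse-grained per-residue amplitudes (default: constant 1 per bead;
configurable per residue type). $\sin x / x$ switches to its series below
$10^{-4}$ to avoid 0/0. An optional hydration shell places dummy waters on a
3 Å cubic grid wherever the distance to the nearest bead lies in
(2.8, 6.0] Å — the sum of a ~3 Å first hydration layer and one 2.8 Å water
diameter — contributing with a 4 % weighting factor; it is off by default
for the coarse-grained toys and intended for all-atom work against
experimental profiles.

`guinierRg()` estimates $R_g$ from a profile over the self-consistent window
$q R_g < 1.3$. The fit of $\ln I$ vs $q^2$ carries an additional $q^4$ term
that absorbs the leading truncation error of the Guinier expansion at the
window edge, with $R_g$ taken from the $q^2$ coefficient: a plain straight
line over the same window has an irreducible ~1.7 % bias for a uniform
sphere, while the corrected fit is exact for a Gaussian profile and accurate
to ~0.1 % for the sphere. Across random coil fixtures the fitted and the
directly computed $R_g$ (`directRg`, the amplitude-weighted RMS distance
from the weighted centroid) correlate at Pearson $r > 0.99$.

## Sampling-efficiency analytics

For a trajectory with initial structure $I$ and target $T$, with
$R_1 = \mathrm{RMSD}(I, T)$:

* **actual SE** (`actualSe`): the fraction of decoys with RMSD to the target
  *strictly* below $R_1$;
* **sampling range** $R_2$ (`samplingRange`): the 95th percentile — linear
  interpolation between order statistics — of the RMSD-to-*initial* series
  (measured from the initial structure, not the trajectory centroid,
  matching the geometric construction of the hypothetical model);
* **hypothetical SE** (`hypotheticalSe`): the overlap fraction
  $|B(T, R_1) \cap B(I, R_2)| / |B(I, R_2)|$ for balls in 1, 2 or 3
  dimensions with center distance $R_1$. This reduces to $(R_1/R_2)^{dim}$
  when $R_2/R_1 \ge 2$, and to $0.5$ (1D), the circular-lens ratio (2D) and
  $\tfrac12 - \tfrac{3R_2}{16R_1}$ (3D) otherwise. All three closed forms
  are derived from the one geometric model — the 2D case from the
  circular-segment (lens) formula, the 3D case from the spherical-cap
  overlap, which with center distance $R_1$ reduces exactly to the simple
  linear expression above. All branches are continuous at $R_2/R_1 = 2$,
  bounded by $[0, 0.5]$, and validated against a Monte-Carlo ball-overlap
  integrator;
* **random baseline** (`revaProbability`): the probability that a random
  compact conformation falls within RMSD $r$ of a target, a normal CDF with
  mean $3.333\,N^{1/3}$ Å and σ = 2.0 Å for an $N$-residue chain;
* **paired comparison** (`comparePair`): $\mathrm{dRMSD}_T$ (hybrid minus
  control mean RMSD-to-target; negative = hybrid closer), ΔSE, and the
  percent SE improvement, reported to one decimal and undefined (NA) when
  the control SE is exactly zero;
* **grouping** (`groupTrajectories`): bins by $R_2/R_1 \in$ (0,1], (1,2],
  (2,∞) and by target difficulty, easy ($R_1 \le 7$ Å) vs hard ($> 7$ Å).
  The boundary $R_1 = 7$ Å exactly is assigned to the easy class by
  convention.

Secondary-structure accordance uses a C$\alpha$-geometry heuristic (helix
when the $i \to i{+}3$ distance lies in [5.0, 6.2] Å, extended when ≥ 9.5 Å,
else coil; the three C-terminal residues are coil), *not* STRIDE; accordance
numbers are internally consistent but not comparable to STRIDE-based values
and are never asserted against them.

RMSD is computed over C$\alpha$ atoms after closed-form Kabsch superposition
(SVD with reflection correction). C$\alpha$-only is the decoy-analysis convention and matches the
coarse-grained propagator; an "all"/index selection is available. The rotation matrices produced during
superposition feed the even-sampling diagnostic: axis-angle rotation vectors
of decoys superposed onto their initial structure should fill a ball
isotropically under unbiased sampling, and uniform quaternion-sampled
rotations give component means within three standard errors of zero.

## Calibration of ω and the study conditions

ω defaults to 0.2 for the 50-move judgment interval (0.4 for the short
6-move interval), the calibration that keeps the acceptance ratio of
trajectories above 40 %: on the default helix system the observed ratios are
~65–85 %. The acceptance ratio is counted per trajectory. ω = 0 reduces the
hybrid run to the control run *bitwise* at equal seeds, because propagation
and acceptance consume independent RNG streams derived from the master seed
— which is also what keeps a hybrid/control pair comparable.

The packaged evaluation (tests and `scripts/acceptance.R`) uses desk-scale
problem sizes chosen as the smallest that give stable statistics: 20 paired
runs of 250 judgments on the 20-mer helix system with starts at
$R_1 \approx 5$ Å (a detectable target, $R_2/R_1 > 1$), a ~200-decoy
calibration pool (3 topologies × 3 temperatures × 23 decoys), 200 coil
fixtures for the $R_g$ correlation, and $10^6$-sample Monte-Carlo overlap
checks. Under these conditions the hybrid arm roughly doubles the mean
actual SE of the control and lowers the mean RMSD-to-target by ~0.5 Å.

## Degenerate inputs, tie-breaks and numeric choices

* Profile grids must match exactly for computed-profile $\chi$ (no silent
  interpolation); only the experimental form interpolates.
* PDB alternate locations resolve to the highest-occupancy copy; ties go to
  altloc "A". Malformed records fail with the offending line number.
* Clustering is greedy most-neighbors-within-cutoff, a documented SPICKER-
  style surrogate rather than SPICKER's full algorithm: the seed decoy is the
  medoid/center, ties on neighbor count go to the lowest decoy index, and
  the cutoff self-adjusts by ×1.15 / ×0.85 (at most 20 times) until the top
  cluster covers 15–70 % of the decoys; an unsatisfiable coverage rule
  (e.g. indivisible duplicate decoys) returns `satisfied = FALSE` instead of
  failing.
* `hypotheticalSe` rejects non-positive radii; `actualSe` is undefined at
  $R_1 = 0$ (initial equals target) and errors.
* Superposition requires ≥ 3 non-collinear points; rotation-vector
  extraction special-cases angles near 0 and π.

## Known limitations

The propagator has no force-field realism, so force-field-vs-restraint
competition — the regime where the propagator's own preferences overwhelm
the SAXS restraint and the trajectory never converges — is only weakly
represented here, by the coil-entropy pull away from compact targets. The scattering
calculator is not a Fast-SAXS-pro or CRYSOL reimplementation: per-residue
amplitudes are generic, and no excluded-volume solvent term beyond the dummy
shell is included, so absolute $\chi$ scales are not transferable to those
programs. Dataset-bound statistics that would require hundreds of all-atom MD
trajectories (per-system RMSD gains and SE tables, absolute correlation
values) are outside what these toys can reproduce; the package's evaluation
rests on the closed-form arithmetic, the oracle-validated geometry, and the
directional, scaled-down experiments described above.
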