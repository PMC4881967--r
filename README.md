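# saxsmc

SAXS-restrained hybrid Monte Carlo sampling of peptide conformations, with a
complete sampling-efficiency evaluation framework.

## The problem

Structure refinement and the generation of near-native conformational
ensembles both need a sampler that is *enriched toward a known target state*.
A plain propagator (molecular dynamics, or any stochastic chain sampler)
goes where its energy function takes it, which is often away from the
target. A solution SAXS profile — the 1D scattering intensity I(q) — is an
experimentally cheap, low-resolution fingerprint of a structure's global
shape and size, and can serve as a soft restraint.

`saxsmc` implements the hybrid scheme: the propagator advances the chain one
segment at a time, and after each segment a Metropolis *structure-acceptance
judgment* scores the candidate by the discrepancy χ between its computed
SAXS profile and the target profile, under the pseudo-energy

    E = ω · k_B T · χ,          accept with  min{ exp(−ω Δχ), 1 }

so k_B·T cancels and the judgment is temperature-free given χ. The default
discrepancy is the log-intensity form

    χ = (c/N) Σ_q | (qⁿ log I(q))_decoy − (qⁿ log I(q))_target | / |log I(q_min)_target|

with c = 1000, n = 0 and N = 120 grid points on a linear q grid from 0.005
to 0.6 Å⁻¹; nine further variants (n = 0..4 for the log and linear forms)
and an error-weighted form for experimental profiles are provided, plus the
rank-correlation machinery that selects among them.

Everything runs on built-in coarse-grained Cα fixtures (ideal helix,
two-strand hairpin, self-avoiding coil, 20 residues by default), so no
external data are needed. The sampling-efficiency analytics quantify the
enrichment: actual SE (fraction of decoys strictly closer to the target than
the start, R < R₁), sampling range R₂ (95th-percentile RMSD from the start),
the hypothetical SE of an evenly sampling trajectory (ball-overlap geometry
in 1/2/3 dimensions, bounded by 0.5), and a random-conformation baseline
(normal CDF with mean 3.333·N^(1/3) Å, σ = 2 Å).

## Worked example

Enrich sampling toward an ideal 20-mer helix from a start ~5 Å away, and
compare against the unbiased control run with identical randomness:

```r
library(saxsmc)

target <- makeFixture(20, "helix", residueName = "ALA")
start  <- perturbedStart(target, targetRmsd = 5, seed = 1001)
r1 <- rmsdAfterSuperposition(start, target)

cfg <- mcConfig(omega = 0.2, nJudgments = 300L,
                targetProfile = debyeProfile(target), seed = 2001L)
hybrid  <- runHybrid(start, cfg, target = target)
control <- runControl(start, cfg, target = target)

hybrid
#> HybridTrajectory: 300 judgments, acceptance 64.3%
#>   chi: 8.83 -> 25.9   mean RMSD_T: 5.18 A
comparePair(hybrid, control, r1)
#> PairedComparison: dRMSD_T=-1.01 A  dSE=0.140  improvement=1400.0%
seReport(hybrid, r1, nResidues = 20)
#> SEReport: R1=4.39 A  R2=6.83 A  (R2/R1=1.56, (1,2], easy)
#>   actual SE 0.150 | hypothetical SE 1d 0.500 2d 0.322 3d 0.208
#>   Reva baseline 0.0099 | mean RMSD_T 5.18 A
```

Reading the numbers: the acceptance ratio (64 %) sits above the 40 %
calibration floor for ω = 0.2; dRMSD_T = −1.01 Å means the restrained run
sampled on average 1 Å closer to the target than the control; actual SE
0.150 says 15 % of its decoys beat the starting structure, versus 1 % for
the control (dSE = 0.140); R₂/R₁ = 1.56 > 1 marks the target as detectable
within the sampling range; and the Reva baseline says a random compact
conformation of a 20-mer would land this close to the target with
probability ~0.01.

A full pipeline — fixture targets, forward decoy generation, clustering with
the self-adjusting cutoff, top-3 cluster centers as backward starts, paired
hybrid/control runs, grouped SE summary — is available as
`pipelineDemo(readRunConfig())` or from the shell via the thin CLI:

```sh
Rscript exec/saxsmc demo --seed 1 --out demo-out
Rscript exec/saxsmc help   # fixtures, saxs, chi, run-hybrid, cluster, se-report
```

The methods vignette (`vignettes/saxs-restrained-sampling.Rmd`) documents
the model, every tunable parameter with units and defaults, the numerical
choices, and what the coarse-grained fixtures do and do not emulate.

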