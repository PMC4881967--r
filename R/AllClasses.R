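#' @import methods
NULL

#' Coarse-grained peptide structure
#'
#' A labelled, ordered 3D point set: one row of \code{coords} per atom (or
#' per C-alpha bead in the coarse-grained representation used throughout this
#' package), with parallel atom labels and residue identities. Frames of a
#' trajectory are distinguished by \code{modelId}.
#'
#' @slot coords numeric matrix, n x 3, coordinates in Angstrom.
#' @slot atomLabels character, per-point atom name (e.g. "CA").
#' @slot residueIds integer, per-point residue index; non-decreasing along
#'   the chain.
#' @slot residueNames character, per-point three-letter residue name.
#' @slot modelId integer scalar tagging the trajectory frame.
#'
#' @export
setClass("PeptideStructure",
  representation(
    coords = "matrix",
    atomLabels = "character",
    residueIds = "integer",
    residueNames = "character",
    modelId = "integer"
  ),
  prototype(
    coords = matrix(numeric(0), ncol = 3),
    atomLabels = character(0),
    residueIds = integer(0),
    residueNames = character(0),
    modelId = 1L
  )
)

setValidity("PeptideStructure", function(object) {
  n <- nrow(object@coords)
  msgs <- character(0)
  if (ncol(object@coords) != 3)
    msgs <- c(msgs, "coords must have 3 columns")
  if (length(object@atomLabels) != n)
    msgs <- c(msgs, "atomLabels length must equal number of coordinate rows")
  if (length(object@residueIds) != n)
    msgs <- c(msgs, "residueIds length must equal number of coordinate rows")
  if (length(object@residueNames) != n)
    msgs <- c(msgs, "residueNames length must equal number of coordinate rows")
  if (n > 0 && !all(is.finite(object@coords)))
    msgs <- c(msgs, "all coordinates must be finite")
  if (n > 1 && any(diff(object@residueIds) < 0))
    msgs <- c(msgs, "residue indices must be non-decreasing along the chain")
  if (length(object@modelId) != 1)
    msgs <- c(msgs, "modelId must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' One-dimensional SAXS intensity profile
#'
#' Scattering intensity I(q) on a strictly increasing grid of scattering
#' vector magnitudes q (1/Angstrom). Experimental profiles may carry
#' per-point log-intensity errors used by the experimental discrepancy score.
#'
#' @slot q numeric, strictly increasing, all > 0, in 1/Angstrom.
#' @slot intensity numeric, same length as \code{q}, all > 0
#'   (arbitrary units).
#' @slot logError numeric, either length 0 (absent) or same length as
#'   \code{q} with all entries > 0.
#'
#' @export
setClass("ScatteringProfile",
  representation(q = "numeric", intensity = "numeric", logError = "numeric"),
  prototype(q = numeric(0), intensity = numeric(0), logError = numeric(0))
)

setValidity("ScatteringProfile", function(object) {
  msgs <- character(0)
  n <- length(object@q)
  if (n > 0 && (any(!is.finite(object@q)) || any(object@q <= 0)))
    msgs <- c(msgs, "q values must be finite and > 0")
  if (n > 1 && any(diff(object@q) <= 0))
    msgs <- c(msgs, "q grid must be strictly increasing")
  if (length(object@intensity) != n)
    msgs <- c(msgs, "intensity and q must have the same length")
  if (n > 0 && (any(!is.finite(object@intensity)) || any(object@intensity <= 0)))
    msgs <- c(msgs, "intensities must be finite and > 0")
  if (length(object@logError) > 0) {
    if (length(object@logError) != n)
      msgs <- c(msgs, "logError must be absent or match the q grid length")
    else if (any(!is.finite(object@logError)) || any(object@logError <= 0))
      msgs <- c(msgs, "logError entries must be finite and > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Specification of a profile discrepancy score
#'
#' Selects one member of the discrepancy family: the log-intensity form
#' ("eq1"), the linear-intensity log-sum form ("eq2") -- each with an
#' integer q-weighting exponent n in 0..4 -- or the error-weighted
#' experimental form ("eq6", which ignores the exponent).
#'
#' @slot form character, one of "eq1", "eq2", "eq6".
#' @slot exponentN integer in 0..4; q^n weighting of the intensities.
#' @slot amplificationC numeric > 0, amplification factor (default 1000).
#' @slot qMin,qMax numeric, integration bounds in 1/Angstrom.
#' @slot offsetRule character, for "eq6": "lowest-q" (offset taken at the
#'   lowest shared grid point) or "mean5" (mean over the five lowest points).
#'
#' @export
setClass("DiscrepancySpec",
  representation(
    form = "character",
    exponentN = "integer",
    amplificationC = "numeric",
    qMin = "numeric",
    qMax = "numeric",
    offsetRule = "character"
  ),
  prototype(form = "eq1", exponentN = 0L, amplificationC = 1000,
            qMin = 0.005, qMax = 0.6, offsetRule = "lowest-q")
)

setValidity("DiscrepancySpec", function(object) {
  msgs <- character(0)
  if (!(object@form %in% c("eq1", "eq2", "eq6")))
    msgs <- c(msgs, "form must be one of 'eq1', 'eq2', 'eq6'")
  if (!(object@exponentN %in% 0:4))
    msgs <- c(msgs, "exponentN must be an integer in 0..4")
  if (object@amplificationC <= 0)
    msgs <- c(msgs, "amplificationC must be > 0")
  if (object@qMin <= 0 || object@qMax <= object@qMin)
    msgs <- c(msgs, "require 0 < qMin < qMax")
  if (!(object@offsetRule %in% c("lowest-q", "mean5")))
    msgs <- c(msgs, "offsetRule must be 'lowest-q' or 'mean5'")
  if (length(msgs)) msgs else TRUE
})

#' Coarse-grained form factor table
#'
#' Per-species scattering amplitudes used by the Debye calculator. In the
#' default one-bead-per-residue model every residue type scatters with a
#' constant amplitude; hydration-shell dummy scatterers, when enabled,
#' contribute with the water amplitude scaled by \code{hydrationWeight}.
#'
#' @slot amplitudes named numeric, scattering amplitude per species key
#'   (residue name or element).
#' @slot hydrationWeight numeric in [0, 1]; weighting of the hydration-layer
#'   dummy waters (default 0.04).
#' @slot shellThickness numeric, hydration shell thickness in Angstrom
#'   (default 6).
#'
#' @export
setClass("FormFactorTable",
  representation(amplitudes = "numeric", hydrationWeight = "numeric",
                 shellThickness = "numeric"),
  prototype(amplitudes = c(ANY = 1), hydrationWeight = 0.04,
            shellThickness = 6)
)

setValidity("FormFactorTable", function(object) {
  msgs <- character(0)
  if (length(object@amplitudes) == 0 || is.null(names(object@amplitudes)))
    msgs <- c(msgs, "amplitudes must be a non-empty named numeric vector")
  if (any(!is.finite(object@amplitudes)))
    msgs <- c(msgs, "all amplitudes must be finite")
  if (object@hydrationWeight < 0 || object@hydrationWeight > 1)
    msgs <- c(msgs, "hydrationWeight must lie in [0, 1]")
  if (object@shellThickness <= 0)
    msgs <- c(msgs, "shellThickness must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the built-in coarse-grained propagator
#'
#' Parameters of the C-alpha chain sampler that stands in for a molecular
#' dynamics engine: an internal Metropolis walker over a bonded +
#' excluded-volume energy, advanced \code{segmentLength} moves between
#' successive structure-acceptance judgments.
#'
#' @slot temperature numeric, Kelvin.
#' @slot segmentLength integer >= 1, internal moves per propagation segment.
#' @slot moveSet character subset of c("cartesian_jitter", "crankshaft",
#'   "torsion_pivot").
#' @slot jitterAmplitude numeric, Angstrom, sd of single-bead displacement.
#' @slot crankAmplitude numeric, radians, sd of crankshaft rotation.
#' @slot pivotAmplitude numeric, radians, sd of torsion-pivot rotation.
#' @slot bondLength numeric, Angstrom, virtual C-alpha bond target (3.8).
#' @slot bondK numeric, kcal/mol/A^2, harmonic bond force constant.
#' @slot angleTarget numeric, radians, pseudo-bond-angle target.
#' @slot angleK numeric, kcal/mol/rad^2, angle force constant.
#' @slot evRadius numeric, Angstrom, soft excluded-volume onset distance.
#' @slot evK numeric, kcal/mol/A^2, excluded-volume force constant.
#'
#' @export
setClass("PropagatorConfig",
  representation(
    temperature = "numeric", segmentLength = "integer",
    moveSet = "character",
    jitterAmplitude = "numeric", crankAmplitude = "numeric",
    pivotAmplitude = "numeric",
    bondLength = "numeric", bondK = "numeric",
    angleTarget = "numeric", angleK = "numeric",
    evRadius = "numeric", evK = "numeric"
  ),
  prototype(
    temperature = 310, segmentLength = 50L,
    moveSet = c("cartesian_jitter", "crankshaft", "torsion_pivot"),
    jitterAmplitude = 0.15, crankAmplitude = 0.15, pivotAmplitude = 0.1,
    bondLength = 3.8, bondK = 20, angleTarget = 110 * pi / 180, angleK = 2,
    evRadius = 4.0, evK = 2
  )
)

setValidity("PropagatorConfig", function(object) {
  msgs <- character(0)
  if (object@temperature <= 0) msgs <- c(msgs, "temperature must be > 0")
  if (object@segmentLength < 1) msgs <- c(msgs, "segmentLength must be >= 1")
  known <- c("cartesian_jitter", "crankshaft", "torsion_pivot")
  if (length(object@moveSet) == 0 || !all(object@moveSet %in% known))
    msgs <- c(msgs, "moveSet must be a non-empty subset of the known moves")
  amps <- c(object@jitterAmplitude, object@crankAmplitude,
            object@pivotAmplitude)
  if (any(amps < 0)) msgs <- c(msgs, "move amplitudes must be >= 0")
  if (object@bondLength <= 0 || object@bondK < 0 || object@angleK < 0 ||
      object@evRadius < 0 || object@evK < 0)
    msgs <- c(msgs, "bonded parameters must be non-negative (bondLength > 0)")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the hybrid sampling loop
#'
#' @slot omega numeric > 0, dimensionless weight of the SAXS pseudo-energy
#'   E = omega * kB * T * chi. Defaults to 0.2 (long judgment intervals);
#'   0.4 is the conventional choice for short intervals.
#' @slot temperature numeric, Kelvin (enters the propagator only: kB*T
#'   cancels algebraically in the acceptance probability).
#' @slot nJudgments integer >= 1, number of accept/reject judgments.
#' @slot spec a \linkS4class{DiscrepancySpec}.
#' @slot targetProfile a \linkS4class{ScatteringProfile} on the same grid the
#'   decoy profiles are computed on.
#' @slot seed integer, master seed; propagation and acceptance draws use two
#'   independent streams derived from it.
#'
#' @export
setClass("MCConfig",
  representation(
    omega = "numeric", temperature = "numeric", nJudgments = "integer",
    spec = "DiscrepancySpec", targetProfile = "ScatteringProfile",
    seed = "integer"
  ),
  prototype(omega = 0.2, temperature = 310, nJudgments = 100L, seed = 1L)
)

setValidity("MCConfig", function(object) {
  msgs <- character(0)
  if (object@omega < 0) msgs <- c(msgs, "omega must be >= 0")
  if (object@nJudgments < 1) msgs <- c(msgs, "nJudgments must be >= 1")
  if (object@temperature <= 0) msgs <- c(msgs, "temperature must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Recorded hybrid (or control) sampling trajectory
#'
#' One saved decoy per judgment (the post-decision state), together with the
#' per-judgment discrepancy, acceptance flag and RMSDs to the initial and
#' target structures.
#'
#' @slot frames list of \linkS4class{PeptideStructure}, one per judgment.
#' @slot chiSeries numeric, post-decision chi per judgment.
#' @slot accepted logical per judgment.
#' @slot rmsdToInitial,rmsdToTarget numeric per judgment, Angstrom.
#' @slot acceptanceRatio numeric, exactly \code{mean(accepted)}.
#' @slot chi0 numeric, chi of the initial structure (before judgment 1).
#' @slot omega,temperature,seed run parameters for provenance.
#' @slot valid logical; FALSE flags a trajectory aborted mid-run.
#'
#' @export
setClass("HybridTrajectory",
  representation(
    frames = "list", chiSeries = "numeric", accepted = "logical",
    rmsdToInitial = "numeric", rmsdToTarget = "numeric",
    acceptanceRatio = "numeric", chi0 = "numeric",
    omega = "numeric", temperature = "numeric", seed = "integer",
    valid = "logical"
  ),
  prototype(valid = TRUE, seed = NA_integer_, chi0 = NA_real_)
)

setValidity("HybridTrajectory", function(object) {
  msgs <- character(0)
  n <- length(object@frames)
  lens <- c(length(object@chiSeries), length(object@accepted),
            length(object@rmsdToInitial), length(object@rmsdToTarget))
  if (any(lens != n))
    msgs <- c(msgs, "all per-judgment series must have one entry per frame")
  if (n > 0 && any(!is.finite(object@chiSeries)))
    msgs <- c(msgs, "chiSeries entries must be finite")
  if (n > 0 &&
      !isTRUE(all.equal(object@acceptanceRatio, mean(object@accepted))))
    msgs <- c(msgs, "acceptanceRatio must equal mean(accepted)")
  if (length(msgs)) msgs else TRUE
})

#' Decoy clustering result
#'
#' @slot clusters list of integer vectors (decoy indices), largest first;
#'   disjoint, and their union covers all clustered decoys.
#' @slot centerIndices integer, index of the medoid (cluster seed) of each
#'   cluster; \code{centerIndices[i]} is a member of \code{clusters[[i]]}.
#' @slot centers list of \linkS4class{PeptideStructure} center models.
#' @slot finalCutoff numeric, Angstrom, the cutoff after self-adjustment.
#' @slot top1Coverage numeric in (0, 1], fraction of decoys in cluster 1.
#' @slot satisfied logical, whether the 15--70\% Top-1 coverage rule was met.
#'
#' @export
setClass("ClusterResult",
  representation(clusters = "list", centerIndices = "integer",
                 centers = "list", finalCutoff = "numeric",
                 top1Coverage = "numeric", satisfied = "logical")
)

setValidity("ClusterResult", function(object) {
  msgs <- character(0)
  idx <- unlist(object@clusters)
  if (anyDuplicated(idx))
    msgs <- c(msgs, "clusters must be disjoint")
  if (length(object@centerIndices) != length(object@clusters))
    msgs <- c(msgs, "one center per cluster required")
  else if (length(object@clusters) &&
           !all(mapply(function(c, i) i %in% c,
                       object@clusters, object@centerIndices)))
    msgs <- c(msgs, "each center must be a member of its cluster")
  if (length(object@clusters) > 1) {
    sizes <- lengths(object@clusters)
    if (any(diff(sizes) > 0))
      msgs <- c(msgs, "cluster populations must be non-increasing")
  }
  if (length(object@top1Coverage) == 1 &&
      (object@top1Coverage <= 0 || object@top1Coverage > 1))
    msgs <- c(msgs, "top1Coverage must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Sampling-efficiency report for one trajectory
#'
#' @slot r1 numeric, Angstrom: RMSD between initial and target structures.
#' @slot r2 numeric, Angstrom: sampling range, the 95th percentile of the
#'   RMSD-to-initial series.
#' @slot actualSE numeric in [0, 1]: fraction of decoys strictly closer to
#'   the target than the initial structure.
#' @slot hypotheticalSE named numeric ("1d", "2d", "3d"), each in [0, 0.5].
#' @slot revaP numeric, random-compact-conformation baseline probability.
#' @slot meanRmsdT numeric, Angstrom, mean RMSD to target over the decoys.
#' @slot ssAccordance numeric, fraction of residues whose 3-state secondary
#'   structure matches the target assignment (NA when not computed).
#' @slot ratioGroup character, R2/R1 bin: "(0,1]", "(1,2]" or "(2,Inf)".
#' @slot r1Class character, "easy" (R1 <= 7 A) or "hard" (R1 > 7 A).
#'
#' @export
setClass("SEReport",
  representation(
    r1 = "numeric", r2 = "numeric", actualSE = "numeric",
    hypotheticalSE = "numeric", revaP = "numeric", meanRmsdT = "numeric",
    ssAccordance = "numeric", ratioGroup = "character", r1Class = "character"
  ),
  prototype(ssAccordance = NA_real_)
)

setValidity("SEReport", function(object) {
  msgs <- character(0)
  if (object@r1 <= 0) msgs <- c(msgs, "r1 must be > 0")
  if (object@actualSE < 0 || object@actualSE > 1)
    msgs <- c(msgs, "actualSE must lie in [0, 1]")
  h <- object@hypotheticalSE
  if (length(h) != 3 || is.null(names(h)) ||
      !all(c("1d", "2d", "3d") %in% names(h)))
    msgs <- c(msgs, "hypotheticalSE must be named '1d', '2d', '3d'")
  else if (any(h < 0 | h > 0.5 + 1e-12))
    msgs <- c(msgs, "hypothetical SE values must lie in [0, 0.5]")
  if (length(msgs)) msgs else TRUE
})

#' Paired hybrid-vs-control comparison
#'
#' @slot dRmsdT numeric, Angstrom: mean RMSD-to-target of the hybrid run
#'   minus that of the control run (negative means the hybrid sampled
#'   closer to the target).
#' @slot dSE numeric: actual SE difference (hybrid minus control).
#' @slot improvementPct numeric: percent change of SE relative to the
#'   control, one decimal; NA when the control SE is exactly 0.
#' @slot seHybrid,seControl numeric, the two actual SE values.
#'
#' @export
setClass("PairedComparison",
  representation(dRmsdT = "numeric", dSE = "numeric",
                 improvementPct = "numeric",
                 seHybrid = "numeric", seControl = "numeric")
)
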