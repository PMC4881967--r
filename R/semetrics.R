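#' Actual sampling efficiency of a trajectory
#'
#' Fraction of decoys whose RMSD to the target is strictly smaller than R1,
#' the RMSD between the initial structure and the target.
#'
#' @param rmsdToTargetSeries numeric, per-decoy RMSD to the target (Angstrom).
#' @param r1 numeric > 0, initial-to-target RMSD.
#' @return fraction in [0, 1].
#' @export
actualSe <- function(rmsdToTargetSeries, r1) {
  if (length(rmsdToTargetSeries) == 0)
    stop("empty RMSD series", call. = FALSE)
  if (r1 <= 0)
    stop("sampling efficiency undefined for r1 = 0 (initial equals target)",
         call. = FALSE)
  mean(rmsdToTargetSeries < r1)
}

#' Sampling range R2 of a trajectory
#'
#' The 95th percentile (linear interpolation between order statistics) of the
#' per-decoy RMSD to the initial structure: the radius that encloses 95
#' percent of all decoys around the start.
#'
#' @param rmsdToInitialSeries numeric, per-decoy RMSD to the initial
#'   structure.
#' @return R2 in Angstrom.
#' @export
samplingRange <- function(rmsdToInitialSeries) {
  if (length(rmsdToInitialSeries) == 0)
    stop("empty RMSD series", call. = FALSE)
  unname(stats::quantile(rmsdToInitialSeries, 0.95, type = 7))
}

# Lens (intersection) content of two balls with radii r1 (around the target)
# and r2 (around the start) whose centers are r1 apart, divided by the
# content of the r2 ball. Exact circular-segment / spherical-cap formulas.
ballOverlapFraction <- function(r1, r2, dim) {
  d <- r1
  if (r2 >= 2 * r1) return((r1 / r2)^dim)   # small ball fully inside
  if (dim == 1) return(0.5)                 # overlap = r2, length = 2 r2
  if (dim == 2) {
    a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
    a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
    a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) *
                       (d - r1 + r2) * (d + r1 + r2))
    return((a1 + a2 - a3) / (pi * r2^2))
  }
  # dim 3: the spherical lens with center distance r1 reduces exactly to
  # 1/2 - 3 r2 / (16 r1)
  0.5 - 3 * r2 / (16 * r1)
}

#' Hypothetical sampling efficiency under even sampling
#'
#' The ball-overlap fraction |B(T, r1) intersect B(I, r2)| / |B(I, r2)| for
#' balls in 1, 2 or 3 dimensions whose centers are r1 apart: the sampling
#' efficiency an evenly sampling trajectory of range r2 would achieve on a
#' target at distance r1. Equals (r1/r2)^dim when r2/r1 >= 2 (the target ball
#' lies inside the sampling ball) and the exact lens/cap overlap ratio
#' otherwise (0.5 in 1D; 1/2 - 3 r2 / (16 r1) in 3D). Continuous at
#' r2/r1 = 2 and bounded by [0, 0.5].
#'
#' @param r1 numeric > 0, center distance = target-ball radius (Angstrom).
#' @param r2 numeric > 0, sampling-ball radius (Angstrom).
#' @param dim 1, 2 or 3.
#' @return fraction in [0, 0.5].
#' @examples
#' hypotheticalSe(1, 2, dim = 3)  # 0.125 from both branches
#' @export
hypotheticalSe <- function(r1, r2, dim = 3) {
  if (r1 <= 0 || r2 <= 0) stop("r1 and r2 must be > 0", call. = FALSE)
  if (!(dim %in% 1:3)) stop("dim must be 1, 2 or 3", call. = FALSE)
  ballOverlapFraction(r1, r2, as.integer(dim))
}

#' Monte-Carlo ball-overlap estimator
#'
#' Independent numerical oracle for \code{\link{hypotheticalSe}}: samples
#' points uniformly in the sampling ball B(I, r2) and counts the fraction
#' falling inside B(T, r1) with the centers r1 apart.
#'
#' @param r1,r2 ball radii as in \code{\link{hypotheticalSe}}.
#' @param dim 1, 2 or 3.
#' @param nSamples number of uniform samples.
#' @return list with \code{estimate} and its standard error \code{se}.
#' @export
mcBallOverlap <- function(r1, r2, dim = 3, nSamples = 1e6) {
  n <- as.integer(nSamples)
  u <- stats::runif(n)^(1 / dim) * r2        # radius with correct density
  dirs <- matrix(stats::rnorm(n * dim), n, dim)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- dirs * u
  pts[, 1] <- pts[, 1] - r1                  # target center at origin,
  inside <- rowSums(pts^2) < r1^2            # start center at (r1, 0, ...)
  p <- mean(inside)
  list(estimate = p, se = sqrt(p * (1 - p) / n))
}

#' Random-conformation baseline probability (Reva model)
#'
#' Probability that a random compact conformation of an n-residue chain falls
#' within RMSD r of a target, modeled as a normal CDF with mean
#' 3.333 * n^(1/3) Angstrom and standard deviation 2.0 Angstrom.
#'
#' @param r RMSD threshold, Angstrom (>= 0).
#' @param nResidues chain length (>= 1).
#' @return probability in (0, 1).
#' @export
revaProbability <- function(r, nResidues) {
  if (nResidues < 1) stop("nResidues must be >= 1", call. = FALSE)
  if (any(r < 0)) stop("r must be >= 0", call. = FALSE)
  stats::pnorm(r, mean = 3.333 * nResidues^(1 / 3), sd = 2.0)
}

#' Build a sampling-efficiency report for one trajectory
#'
#' @param traj a \linkS4class{HybridTrajectory} with RMSD-to-target recorded.
#' @param r1 initial-to-target RMSD, Angstrom.
#' @param nResidues chain length for the random baseline.
#' @param ssAccordance optional precomputed secondary-structure accordance.
#' @return an \linkS4class{SEReport}.
#' @export
seReport <- function(traj, r1, nResidues, ssAccordance = NA_real_) {
  rT <- rmsdToTarget(traj)
  if (any(is.na(rT)))
    stop("trajectory has no RMSD-to-target record", call. = FALSE)
  r2 <- samplingRange(rmsdToInitial(traj))
  ratio <- r2 / r1
  new("SEReport",
      r1 = r1, r2 = r2,
      actualSE = actualSe(rT, r1),
      hypotheticalSE = c("1d" = hypotheticalSe(r1, r2, 1),
                         "2d" = hypotheticalSe(r1, r2, 2),
                         "3d" = hypotheticalSe(r1, r2, 3)),
      revaP = revaProbability(r1, nResidues),
      meanRmsdT = mean(rT),
      ssAccordance = ssAccordance,
      ratioGroup = if (ratio <= 1) "(0,1]" else if (ratio <= 2) "(1,2]"
                   else "(2,Inf)",
      r1Class = if (r1 <= 7) "easy" else "hard")
}

#' Percent SE improvement of the hybrid over the control
#'
#' @param seControl,seHybrid mean actual SE of the control and hybrid arms
#'   (same units, e.g. both in percent).
#' @return percent change rounded to one decimal; NA when
#'   \code{seControl} is 0.
#' @examples
#' improvementPct(0.5, 3.9)   # 680.0
#' improvementPct(13.2, 28.9) # 118.9
#' @export
improvementPct <- function(seControl, seHybrid) {
  ifelse(seControl == 0, NA_real_,
         round((seHybrid - seControl) / seControl * 100, 1))
}

#' Compare a hybrid trajectory with its paired control
#'
#' Both runs must share the initial and target structures. Reports
#' dRMSD_T (mean RMSD-to-target of the hybrid minus the control; negative
#' means the hybrid sampled closer to the target), the actual-SE difference,
#' and the percent SE improvement.
#'
#' @param hybrid,control \linkS4class{HybridTrajectory} objects with
#'   RMSD-to-target recorded.
#' @param r1 initial-to-target RMSD shared by the pair, Angstrom.
#' @return a \linkS4class{PairedComparison}.
#' @export
comparePair <- function(hybrid, control, r1) {
  seH <- actualSe(rmsdToTarget(hybrid), r1)
  seC <- actualSe(rmsdToTarget(control), r1)
  new("PairedComparison",
      dRmsdT = mean(rmsdToTarget(hybrid)) - mean(rmsdToTarget(control)),
      dSE = seH - seC,
      improvementPct = improvementPct(seC, seH),
      seHybrid = seH, seControl = seC)
}

#' Group SE reports by R2/R1 and by R1 class
#'
#' Bins trajectories by the detectability ratio R2/R1 into (0,1], (1,2] and
#' (2,Inf), and by target difficulty into easy (R1 <= 7 Angstrom) and hard
#' (R1 > 7); reports per-bin counts and means. Bin counts over the ratio
#' bins sum to the number of input reports.
#'
#' @param reports list of \linkS4class{SEReport}.
#' @return data.frame with columns group, n, meanR2, meanR1, meanActualSE,
#'   meanRevaP.
#' @export
groupTrajectories <- function(reports) {
  if (length(reports) == 0) stop("no reports to group", call. = FALSE)
  df <- data.frame(
    r1 = vapply(reports, function(r) r@r1, numeric(1)),
    r2 = vapply(reports, function(r) r@r2, numeric(1)),
    se = vapply(reports, function(r) r@actualSE, numeric(1)),
    reva = vapply(reports, function(r) r@revaP, numeric(1)),
    ratioGroup = vapply(reports, function(r) r@ratioGroup, character(1)),
    r1Class = vapply(reports, function(r) r@r1Class, character(1))
  )
  summarize <- function(sub, label) {
    data.frame(group = label, n = nrow(sub),
               meanR2 = mean(sub$r2), meanR1 = mean(sub$r1),
               meanActualSE = mean(sub$se), meanRevaP = mean(sub$reva))
  }
  bins <- c("(0,1]", "(1,2]", "(2,Inf)")
  out <- do.call(rbind, c(
    lapply(bins, function(b) summarize(df[df$ratioGroup == b, , drop = FALSE],
                                       paste0("R2/R1 ", b))),
    lapply(c("easy", "hard"),
           function(cl) summarize(df[df$r1Class == cl, , drop = FALSE],
                                  paste0("R1 ", cl))),
    list(summarize(df, "all"))
  ))
  out[out$n > 0 | out$group == "all", , drop = FALSE]
}

## ---- Secondary structure ----------------------------------------------------

#' Three-state secondary structure from C-alpha geometry
#'
#' A lightweight geometric heuristic (not STRIDE/DSSP): residue i is called
#' helix (H) when the CA(i)-CA(i+3) distance lies in [5.0, 6.2] Angstrom,
#' extended (E) when it is >= 9.5 Angstrom, and coil (C) otherwise; the three
#' C-terminal residues, which have no i+3 partner, are coil. Accordance
#' values from this heuristic are internally consistent but not comparable to
#' STRIDE-based numbers.
#'
#' @param structure a \linkS4class{PeptideStructure} (one CA per residue).
#' @return character vector over {"H", "E", "C"}, one per residue.
#' @export
assignSecondaryStructure <- function(structure) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  ss <- rep("C", n)
  if (n >= 4) {
    for (i in seq_len(n - 3)) {
      d <- sqrt(sum((xyz[i + 3, ] - xyz[i, ])^2))
      ss[i] <- if (d >= 5.0 && d <= 6.2) "H" else if (d >= 9.5) "E" else "C"
    }
  }
  ss
}

#' Secondary-structure accordance with a target assignment
#'
#' Fraction of residues whose heuristic 3-state assignment matches the target
#' assignment string.
#'
#' @param decoy a \linkS4class{PeptideStructure}.
#' @param targetAssignment character vector over {"H","E","C"} (or a single
#'   string), one state per residue.
#' @return fraction in [0, 1].
#' @export
ssAccordance <- function(decoy, targetAssignment) {
  if (length(targetAssignment) == 1 && nchar(targetAssignment) > 1)
    targetAssignment <- strsplit(targetAssignment, "")[[1]]
  ss <- assignSecondaryStructure(decoy)
  if (length(ss) != length(targetAssignment))
    stop("target assignment length must equal the residue count",
         call. = FALSE)
  mean(ss == targetAssignment)
}
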