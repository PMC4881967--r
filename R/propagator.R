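## Boltzmann constant in kcal/mol/K, matching the kcal/mol force constants.
.kB <- 0.0019872041

#' Construct a PropagatorConfig
#'
#' Defaults give a gently fluctuating C-alpha chain: virtual bonds of
#' 3.8 Angstrom held by a 20 kcal/mol/A^2 harmonic term, a soft pseudo-angle
#' preference of 110 degrees, and soft excluded volume switching on below
#' 4 Angstrom between beads at least two positions apart. A propagation
#' segment of 50 internal moves separates successive acceptance judgments
#' (segmentLength 6 mimics the short-interval regime).
#'
#' @param temperature Kelvin.
#' @param segmentLength internal Metropolis moves per segment.
#' @param moveSet subset of c("cartesian_jitter", "crankshaft",
#'   "torsion_pivot").
#' @param jitterAmplitude,crankAmplitude,pivotAmplitude move size parameters
#'   (Angstrom / radians).
#' @param bondLength,bondK,angleTarget,angleK,evRadius,evK bonded and
#'   excluded-volume parameters (see class docs for units).
#' @return a \linkS4class{PropagatorConfig}.
#' @export
propagatorConfig <- function(temperature = 310, segmentLength = 50L,
                             moveSet = c("cartesian_jitter", "crankshaft",
                                         "torsion_pivot"),
                             jitterAmplitude = 0.15, crankAmplitude = 0.15,
                             pivotAmplitude = 0.1,
                             bondLength = 3.8, bondK = 20,
                             angleTarget = 110 * pi / 180, angleK = 2,
                             evRadius = 4.0, evK = 2) {
  new("PropagatorConfig", temperature = temperature,
      segmentLength = as.integer(segmentLength), moveSet = moveSet,
      jitterAmplitude = jitterAmplitude, crankAmplitude = crankAmplitude,
      pivotAmplitude = pivotAmplitude, bondLength = bondLength, bondK = bondK,
      angleTarget = angleTarget, angleK = angleK, evRadius = evRadius,
      evK = evK)
}

## ---- Reproducible RNG streams ----------------------------------------------

#' Independent reproducible random streams
#'
#' A stream is an environment holding a saved \code{.Random.seed}; drawing
#' through \code{withStream} swaps the stream's state in, evaluates, and
#' swaps it back out, so several streams advance independently of each other
#' and of the session RNG. The hybrid loop runs its propagator and its
#' acceptance draws on two separate streams so paired runs stay comparable.
#'
#' @param seed integer seed.
#' @param stream a stream created by \code{rngStream}.
#' @param expr expression evaluated with the stream's RNG state active.
#' @return \code{rngStream}: a stream object; \code{withStream}: the value of
#'   \code{expr}.
#' @export
rngStream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

#' @rdname rngStream
#' @export
withStream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

## ---- Chain energy -----------------------------------------------------------

# Total internal energy (kcal/mol) of a C-alpha chain: harmonic virtual
# bonds, harmonic pseudo-angles, soft harmonic excluded volume below
# evRadius between beads |i - j| >= 2.
chainEnergy <- function(xyz, config) {
  n <- nrow(xyz)
  dvec <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
  blen <- sqrt(rowSums(dvec^2))
  e <- config@bondK * sum((blen - config@bondLength)^2)
  if (config@angleK > 0 && n >= 3) {
    u <- dvec / blen
    cosang <- -rowSums(u[-(n - 1), , drop = FALSE] * u[-1, , drop = FALSE])
    cosang <- pmin(1, pmax(-1, cosang))
    e <- e + config@angleK * sum((acos(cosang) - config@angleTarget)^2)
  }
  if (config@evK > 0 && n >= 3) {
    d <- as.matrix(stats::dist(xyz))
    iu <- which(upper.tri(d) & abs(row(d) - col(d)) >= 2)
    dd <- d[iu]
    close <- dd < config@evRadius
    if (any(close))
      e <- e + config@evK * sum((config@evRadius - dd[close])^2)
  }
  e
}

checkChain <- function(xyz, bondLength = 3.8, tol = 1.0) {
  n <- nrow(xyz)
  if (n < 2) stop("chain needs at least 2 beads", call. = FALSE)
  blen <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  if (any(abs(blen - bondLength) > tol))
    stop("broken chain: consecutive C-alpha distance outside ",
         bondLength, " +/- ", tol, " A", call. = FALSE)
  invisible(TRUE)
}

# One proposed move; returns the full proposed coordinate matrix.
proposeMove <- function(xyz, config) {
  n <- nrow(xyz)
  move <- config@moveSet[sample.int(length(config@moveSet), 1)]
  prop <- xyz
  if (move == "cartesian_jitter") {
    i <- sample.int(n, 1)
    prop[i, ] <- prop[i, ] + stats::rnorm(3, sd = config@jitterAmplitude)
  } else if (move == "crankshaft" && n >= 4) {
    i <- sample.int(n - 3, 1)
    j <- i + sample.int(min(5L, n - i - 1L) - 1L + 1L, 1) + 1L
    j <- min(j, n)
    axis <- xyz[j, ] - xyz[i, ]
    nrm <- sqrt(sum(axis^2))
    if (nrm > 1e-9) {
      ang <- stats::rnorm(1, sd = config@crankAmplitude)
      rot <- rotationMatrix(axis / nrm * ang)
      idx <- (i + 1):(j - 1)
      prop[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, xyz[i, ]) %*%
                             t(rot), 2, xyz[i, ], "+")
    }
  } else if (move == "torsion_pivot" && n >= 3) {
    i <- sample.int(n - 2, 1)           # bond i -> i+1 is the axis
    axis <- xyz[i + 1, ] - xyz[i, ]
    nrm <- sqrt(sum(axis^2))
    if (nrm > 1e-9) {
      ang <- stats::rnorm(1, sd = config@pivotAmplitude)
      rot <- rotationMatrix(axis / nrm * ang)
      idx <- (i + 2):n
      prop[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, xyz[i + 1, ]) %*%
                             t(rot), 2, xyz[i + 1, ], "+")
    }
  } else {
    i <- sample.int(n, 1)
    prop[i, ] <- prop[i, ] + stats::rnorm(3, sd = config@jitterAmplitude)
  }
  prop
}

#' Advance a chain by one propagation segment
#'
#' Runs \code{segmentLength} internal Metropolis moves at the configured
#' temperature under the bonded + excluded-volume energy. This is the
#' built-in stand-in for a molecular dynamics engine: any propagator that
#' produces physically continuous candidate structures can replace it in
#' \code{\link{runHybrid}}.
#'
#' @param structure a connected C-alpha chain (consecutive distances within
#'   3.8 +/- 1.0 Angstrom).
#' @param config a \linkS4class{PropagatorConfig}.
#' @param stream RNG stream from \code{\link{rngStream}} (deterministic given
#'   the stream state); a fresh stream from seed 1 if omitted.
#' @return a new \linkS4class{PeptideStructure} after the segment.
#' @export
propagateSegment <- function(structure, config = propagatorConfig(),
                             stream = rngStream(1L)) {
  xyz <- coords(structure)
  checkChain(xyz, config@bondLength)
  e <- chainEnergy(xyz, config)
  if (!is.finite(e)) stop("non-finite chain energy", call. = FALSE)
  beta <- 1 / (.kB * config@temperature)
  withStream(stream, {
    for (k in seq_len(config@segmentLength)) {
      prop <- proposeMove(xyz, config)
      eProp <- chainEnergy(prop, config)
      if (is.finite(eProp) &&
          (eProp <= e || stats::runif(1) < exp(-beta * (eProp - e)))) {
        xyz <- prop
        e <- eProp
      }
    }
  })
  setCoords(structure, xyz)
}

## ---- Fixture generation -----------------------------------------------------

#' Generate coarse-grained peptide fixtures
#'
#' Builds 20-residue-scale C-alpha chains emulating mono-residue peptide
#' fragments with typical secondary structures: an ideal helix (rise 1.5 A
#' and 100 degree twist per residue, radius 2.3 A), a two-strand extended
#' hairpin, or a seeded self-avoiding random coil with 3.8 A steps. All
#' residues carry the same residue name (mono-residue peptides).
#'
#' @param nResidues number of residues (>= 4, default 20).
#' @param topology "helix", "sheet" or "coil".
#' @param residueName three-letter residue name applied to every bead.
#' @param seed integer seed (used by the coil generator).
#' @return a \linkS4class{PeptideStructure} with one CA bead per residue.
#' @examples
#' makeFixture(20, "helix")
#' @export
makeFixture <- function(nResidues = 20L,
                        topology = c("helix", "sheet", "coil"),
                        residueName = "ALA", seed = 1L) {
  topology <- match.arg(topology)
  n <- as.integer(nResidues)
  if (n < 4) stop("nResidues must be >= 4", call. = FALSE)
  xyz <- switch(topology,
    helix = {
      i <- seq_len(n) - 1
      ang <- i * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    },
    sheet = sheetHairpin(n),
    coil = coilWalk(n, seed)
  )
  peptideStructure(xyz, atomLabels = "CA", residueNames = residueName)
}

# Two antiparallel extended strands joined by a two-residue turn. Strand
# geometry: 3.4 A axial rise per residue with a +/-0.85 A pleat so that the
# consecutive CA distance is 3.8 A.
sheetHairpin <- function(n) {
  n1 <- ceiling((n - 2) / 2)
  n2 <- n - 2 - n1
  sep <- 4.8                       # inter-strand distance
  pleat <- sqrt(3.8^2 - 3.4^2) / 2 # +/- offset around the strand axis
  strand <- function(k, x0, dir, y) {
    i <- seq_len(k) - 1
    cbind(x0 + dir * 3.4 * i, y + pleat * (-1)^i, 0)
  }
  s1 <- strand(n1, 0, +1, 0)
  xEnd <- s1[n1, 1]
  # turn: two beads arcing over to the second strand
  t1 <- c(xEnd + 2.7, 0 + sep * 0.33, 1.9)
  t2 <- c(xEnd + 2.7, 0 + sep * 0.67, -1.1)
  s2 <- strand(n2, xEnd, -1, sep)
  xyz <- rbind(s1, t1, t2, s2)
  # small deterministic relaxation toward 3.8 A bonds across the turn
  relaxBonds(xyz)
}

# A few steepest-descent sweeps pulling consecutive distances toward 3.8 A;
# keeps hand-built geometries inside the chain-connectivity tolerance.
relaxBonds <- function(xyz, b0 = 3.8, iters = 200) {
  n <- nrow(xyz)
  for (it in seq_len(iters)) {
    d <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    err <- len - b0
    if (all(abs(err) < 0.05)) break
    adj <- d * (err / len) * 0.25
    xyz[-n, ] <- xyz[-n, ] + adj
    xyz[-1, ] <- xyz[-1, ] - adj
  }
  xyz
}

coilWalk <- function(n, seed) {
  s <- rngStream(seed)
  withStream(s, {
    for (attempt in 1:200) {
      xyz <- matrix(0, n, 3)
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in 1:50) {
          step <- stats::rnorm(3)
          step <- step / sqrt(sum(step^2)) * 3.8
          cand <- xyz[i - 1, ] + step
          if (i <= 2) { placed <- TRUE }
          else {
            prev <- xyz[seq_len(i - 2), , drop = FALSE]
            d2 <- rowSums(sweep(prev, 2, cand)^2)
            placed <- all(d2 > 4.0^2)
          }
          if (placed) { xyz[i, ] <- cand; break }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("self-avoiding walk failed; try another seed", call. = FALSE)
    xyz
  })
}

#' Perturbed starting structure at a controlled distance from a target
#'
#' Propagates away from the target with the built-in sampler until the
#' C-alpha RMSD to the target lands within +/-15 percent of
#' \code{targetRmsd}, giving a connected starting chain at a prescribed R1.
#'
#' @param target a \linkS4class{PeptideStructure}.
#' @param targetRmsd desired RMSD to the target, Angstrom (> 0).
#' @param seed integer seed (deterministic output).
#' @param config propagator configuration used for the perturbation walk; the
#'   default uses small jitter segments so the RMSD window is crossed slowly.
#' @param maxSegments bound on propagation segments before giving up.
#' @return a \linkS4class{PeptideStructure} whose RMSD to \code{target} lies
#'   in [0.85, 1.15] * targetRmsd.
#' @export
perturbedStart <- function(target, targetRmsd, seed = 1L,
                           config = propagatorConfig(temperature = 500,
                                                     segmentLength = 20L),
                           maxSegments = 5000L) {
  if (targetRmsd <= 0) stop("targetRmsd must be > 0", call. = FALSE)
  stream <- rngStream(seed)
  cur <- target
  for (k in seq_len(maxSegments)) {
    cur <- propagateSegment(cur, config, stream)
    r <- rmsdAfterSuperposition(cur, target)
    if (r >= 0.85 * targetRmsd && r <= 1.15 * targetRmsd) return(cur)
    if (r > 1.15 * targetRmsd) {
      # overshot: restart the walk with fresh randomness from the stream
      cur <- target
    }
  }
  stop("could not reach the RMSD window in ", maxSegments,
       " segments; consider a larger tolerance", call. = FALSE)
}
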