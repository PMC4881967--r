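#' Construct an MCConfig
#'
#' @param omega pseudo-energy weight (>= 0); 0.2 is the long-interval
#'   default, 0.4 the short-interval choice — both calibrated to keep the
#'   acceptance ratio of most trajectories above 40 percent.
#' @param temperature Kelvin; enters only the propagator (kB*T cancels in
#'   the acceptance probability).
#' @param nJudgments number of accept/reject judgments (>= 1).
#' @param spec \linkS4class{DiscrepancySpec} scoring decoy profiles against
#'   the target.
#' @param targetProfile target \linkS4class{ScatteringProfile}, normally on
#'   \code{\link{defaultQGrid}()}.
#' @param seed master integer seed; the propagator stream uses \code{seed}
#'   and the acceptance stream \code{seed + 1e6} so the two are independent.
#' @return an \linkS4class{MCConfig}.
#' @export
mcConfig <- function(omega = 0.2, temperature = 310, nJudgments = 100L,
                     spec = discrepancySpec(), targetProfile, seed = 1L) {
  new("MCConfig", omega = omega, temperature = temperature,
      nJudgments = as.integer(nJudgments), spec = spec,
      targetProfile = targetProfile, seed = as.integer(seed))
}

#' Metropolis acceptance probability of a structure judgment
#'
#' With pseudo-energy E = omega * kB * T * chi, the Metropolis ratio
#' min(exp(-(E_new - E_old) / (kB T)), 1) reduces to
#' min(exp(-omega * (chi_new - chi_old)), 1): the kB*T factor cancels
#' algebraically, so the probability is temperature-independent given chi.
#'
#' @param chiNew,chiOld finite discrepancy values.
#' @param omega pseudo-energy weight (>= 0).
#' @return probability in (0, 1]; exactly 1 whenever chiNew <= chiOld.
#' @examples
#' acceptanceProbability(5, 0, omega = 0.2)  # exp(-1)
#' @export
acceptanceProbability <- function(chiNew, chiOld, omega) {
  if (!all(is.finite(c(chiNew, chiOld, omega))))
    stop("acceptanceProbability requires finite inputs", call. = FALSE)
  d <- omega * (chiNew - chiOld)
  if (d <= 0) return(1)
  exp(-d)
}

# Shared engine behind runHybrid / runControl. `propagator` is either a
# PropagatorConfig (built-in sampler) or a function(structure, stream) ->
# structure. forceAccept = TRUE turns the loop into the unbiased control.
hybridLoop <- function(initial, config, propagator, forceAccept = FALSE) {
  stopifnot(is(config, "MCConfig"))
  propFun <- if (is.function(propagator)) propagator
  else function(s, stream) propagateSegment(s, propagator, stream)
  decoyProfile <- function(s) debyeProfile(s, q = qValues(config@targetProfile))
  scoreChi <- function(s)
    chiDiscrepancy(decoyProfile(s), config@targetProfile, config@spec)

  propStream <- rngStream(config@seed)
  accStream <- rngStream(config@seed + 1000000L)

  n <- config@nJudgments
  state <- initial
  chiOld <- scoreChi(state)
  chi0 <- chiOld
  framesOut <- vector("list", n)
  chis <- numeric(n)
  accepted <- logical(n)
  ok <- TRUE
  k <- 0L
  tryCatch({
    while (k < n) {
      k <- k + 1L
      cand <- propFun(state, propStream)
      chiNew <- scoreChi(cand)
      p <- acceptanceProbability(chiNew, chiOld, config@omega)
      u <- withStream(accStream, stats::runif(1))
      if (forceAccept || u < p) {
        state <- cand
        chiOld <- chiNew
        accepted[k] <- TRUE
      } else {
        accepted[k] <- FALSE   # candidate discarded; revert to last accepted
      }
      s <- state
      s@modelId <- k
      framesOut[[k]] <- s
      chis[k] <- chiOld
    }
  }, error = function(e) {
    ok <<- FALSE
    warning("sampling aborted at judgment ", k, ": ", conditionMessage(e),
            call. = FALSE)
  })
  if (!ok) {
    n <- max(k - 1L, 0L)
    framesOut <- framesOut[seq_len(n)]
    chis <- chis[seq_len(n)]
    accepted <- accepted[seq_len(n)]
  }
  rI <- vapply(framesOut, rmsdAfterSuperposition, numeric(1), b = initial)
  ## target structure is unknown here; RMSD_T filled by callers that know it
  new("HybridTrajectory", frames = framesOut, chiSeries = chis,
      accepted = accepted, rmsdToInitial = rI,
      rmsdToTarget = rep(NA_real_, length(framesOut)),
      acceptanceRatio = if (length(accepted)) mean(accepted) else NA_real_,
      chi0 = chi0, omega = config@omega, temperature = config@temperature,
      seed = config@seed, valid = ok)
}

fillRmsdToTarget <- function(traj, target) {
  if (is.null(target)) return(traj)
  traj@rmsdToTarget <- vapply(traj@frames, rmsdAfterSuperposition,
                              numeric(1), b = target)
  traj
}

#' Run the SAXS-restrained hybrid sampling loop
#'
#' Alternates propagation segments with Metropolis structure-acceptance
#' judgments on the SAXS discrepancy chi. The discrepancy of the initial
#' structure initializes chi before the first judgment; each judgment
#' propagates a segment from the last accepted structure, scores the
#' candidate's profile against the target profile, and accepts with
#' \code{\link{acceptanceProbability}}. On rejection the candidate is
#' discarded and propagation continues from the last accepted structure with
#' fresh randomness. The saved frame per judgment is the post-decision state.
#'
#' @param initial starting \linkS4class{PeptideStructure} (a connected
#'   C-alpha chain for the built-in propagator).
#' @param config an \linkS4class{MCConfig}.
#' @param propagator a \linkS4class{PropagatorConfig} for the built-in
#'   sampler, or a function \code{(structure, stream) -> structure}.
#' @param target optional target \linkS4class{PeptideStructure}; when given,
#'   per-frame RMSD to the target is recorded.
#' @return a \linkS4class{HybridTrajectory}. Runs aborted by a propagator or
#'   scoring failure return the partial trajectory flagged invalid.
#' @seealso \code{\link{runControl}} for the unbiased paired run.
#' @export
runHybrid <- function(initial, config, propagator = propagatorConfig(),
                      target = NULL) {
  fillRmsdToTarget(hybridLoop(initial, config, propagator, FALSE), target)
}

#' Run the unbiased control loop
#'
#' Identical to \code{\link{runHybrid}} except that every judgment is
#' forced-accept: pure propagation (the parallel, unrestrained control),
#' with chi still recorded for analysis. With equal seeds, an omega = 0
#' hybrid run and the control produce bitwise-identical trajectories.
#'
#' @inheritParams runHybrid
#' @return a \linkS4class{HybridTrajectory} with acceptance ratio 1.
#' @export
runControl <- function(initial, config, propagator = propagatorConfig(),
                       target = NULL) {
  fillRmsdToTarget(hybridLoop(initial, config, propagator, TRUE), target)
}

#' Apply the acceptance judgment to an externally generated trajectory
#'
#' Retrospective filtering of frames produced by an external engine (e.g. a
#' molecular dynamics trajectory read from a multi-model PDB). The first
#' frame initializes chi; each subsequent frame is judged in sequence. A
#' rejection cannot rewind the external engine, so the reference chi is
#' simply carried forward — this is a filtered re-weighting of the given
#' frames, not a resampling.
#'
#' @param frames list of \linkS4class{PeptideStructure} (>= 2 frames).
#' @param config an \linkS4class{MCConfig} (its propagator seed is unused;
#'   acceptance draws use the dedicated acceptance stream).
#' @param target optional target structure for RMSD bookkeeping.
#' @return a \linkS4class{HybridTrajectory} over frames 2..n: \code{frames}
#'   holds the judged input frames, \code{acceptedFlags} the decisions, and
#'   \code{chiSeries} the post-decision reference chi.
#' @export
judgeExternalTrajectory <- function(frames, config, target = NULL) {
  if (length(frames) < 2)
    stop("at least 2 frames required", call. = FALSE)
  scoreChi <- function(s)
    chiDiscrepancy(debyeProfile(s, q = qValues(config@targetProfile)),
                   config@targetProfile, config@spec)
  accStream <- rngStream(config@seed + 1000000L)
  chiOld <- scoreChi(frames[[1]])
  chi0 <- chiOld
  n <- length(frames) - 1L
  chis <- numeric(n)
  accepted <- logical(n)
  for (k in seq_len(n)) {
    chiNew <- scoreChi(frames[[k + 1]])
    p <- acceptanceProbability(chiNew, chiOld, config@omega)
    u <- withStream(accStream, stats::runif(1))
    if (u < p) {
      accepted[k] <- TRUE
      chiOld <- chiNew
    }
    chis[k] <- chiOld
  }
  judged <- frames[-1]
  rI <- vapply(judged, rmsdAfterSuperposition, numeric(1), b = frames[[1]])
  traj <- new("HybridTrajectory", frames = judged, chiSeries = chis,
              accepted = accepted, rmsdToInitial = rI,
              rmsdToTarget = rep(NA_real_, n),
              acceptanceRatio = mean(accepted), chi0 = chi0,
              omega = config@omega, temperature = config@temperature,
              seed = config@seed, valid = TRUE)
  fillRmsdToTarget(traj, target)
}
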