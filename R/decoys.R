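#' Generate a pooled decoy set for discrepancy calibration
#'
#' Emulates the forward-sampling stage that calibrates the discrepancy form:
#' unbiased control runs are started from one fixture per secondary-structure
#' topology at each listed temperature, and every saved decoy is scored
#' against the SAXS profile of its own initial structure. The merged pool --
#' diverse in topology and in sampling breadth -- is what the rank
#' correlation between chi and RMSD is measured on.
#'
#' @param nResidues residues per fixture (default 20).
#' @param nPerRun judgments (saved decoys) per run (default 23, giving about
#'   200 decoys over the 3 x 3 default design).
#' @param topologies fixture topologies to start from.
#' @param temperatures propagator temperatures, Kelvin.
#' @param seed integer master seed.
#' @return list with \code{structures} (decoys), \code{profiles} (their
#'   computed SAXS profiles), \code{referenceProfiles} (per decoy, the
#'   profile of its own initial structure), \code{rmsdToInitial},
#'   \code{topology} and \code{temperature} (per-decoy annotations).
#' @export
makeDecoyPool <- function(nResidues = 20L, nPerRun = 23L,
                          topologies = c("helix", "sheet", "coil"),
                          temperatures = c(310, 340, 370), seed = 1L) {
  structures <- list(); profiles <- list(); refs <- list()
  rms <- numeric(0); topo <- character(0); temp <- numeric(0)
  q <- defaultQGrid()
  for (tp in topologies) {
    init <- makeFixture(nResidues, tp, seed = seed)
    initProfile <- debyeProfile(init, q = q)
    for (Tk in temperatures) {
      cfg <- mcConfig(omega = 0, nJudgments = as.integer(nPerRun),
                      targetProfile = initProfile,
                      seed = seed + as.integer(Tk) +
                        1000L * match(tp, topologies))
      run <- runControl(init, cfg, propagatorConfig(temperature = Tk),
                        target = init)
      fr <- frames(run)
      structures <- c(structures, fr)
      profiles <- c(profiles, lapply(fr, debyeProfile, q = q))
      refs <- c(refs, rep(list(initProfile), length(fr)))
      rms <- c(rms, rmsdToInitial(run))
      topo <- c(topo, rep(tp, length(fr)))
      temp <- c(temp, rep(Tk, length(fr)))
    }
  }
  list(structures = structures, profiles = profiles,
       referenceProfiles = refs, rmsdToInitial = rms,
       topology = topo, temperature = temp)
}

#' Rank discrepancy forms on a pooled decoy set
#'
#' Scores each candidate discrepancy specification by the Spearman rank
#' correlation between chi (each decoy against its own reference profile)
#' and RMSD-to-initial over the merged pool, sorted by decreasing
#' correlation.
#'
#' @param pool a pool from \code{\link{makeDecoyPool}}.
#' @param candidates list of \linkS4class{DiscrepancySpec} (default: the ten
#'   eq1/eq2 x n = 0..4 combinations).
#' @return data.frame with columns form, exponentN, spearman.
#' @seealso \code{\link{selectBestForm}} for the single-target variant.
#' @export
rankDiscrepancyForms <- function(pool, candidates = defaultCandidates()) {
  rows <- lapply(candidates, function(sp) {
    chis <- vapply(seq_along(pool$profiles), function(i)
      chiDiscrepancy(pool$profiles[[i]], pool$referenceProfiles[[i]], sp),
      numeric(1))
    data.frame(form = sp@form, exponentN = sp@exponentN,
               spearman = spearmanRho(chis, pool$rmsdToInitial))
  })
  out <- do.call(rbind, rows)
  out[order(-out$spearman), , drop = FALSE]
}
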