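test_that("acceptance probability implements the Metropolis criterion", {
  expect_equal(acceptanceProbability(5, 10, 0.2), 1)      # downhill
  expect_equal(acceptanceProbability(7, 7, 0.2), 1)       # flat
  expect_equal(acceptanceProbability(5, 0, 0.2), exp(-1)) # uphill
  expect_equal(acceptanceProbability(10, 0, 0.4), exp(-4))
  expect_equal(acceptanceProbability(3, 0, 0), 1)         # omega = 0
  expect_equal(acceptanceProbability(-1e10, 0, 0.4), 1)   # overflow guard
  expect_gte(acceptanceProbability(1e6, 0, 0.4), 0)       # may underflow to 0
  expect_error(acceptanceProbability(NaN, 0, 0.2), "finite")
  # no temperature enters the computation at all: same chi, same probability
  expect_identical(formals(acceptanceProbability),
                   formals(function(chiNew, chiOld, omega) NULL))
})

helixSetup <- function(nJudgments = 30L, omega = 0.2, seed = 5L) {
  target <- makeFixture(20, "helix")
  tp <- debyeProfile(target)
  init <- perturbedStart(target, 4, seed = 17)
  list(target = target, init = init,
       cfg = mcConfig(omega = omega, nJudgments = nJudgments,
                      targetProfile = tp, seed = seed))
}

test_that("trajectories are reproducible and respect their invariants", {
  s <- helixSetup()
  t1 <- runHybrid(s$init, s$cfg, target = s$target)
  t2 <- runHybrid(s$init, s$cfg, target = s$target)
  expect_identical(lapply(frames(t1), coords), lapply(frames(t2), coords))
  expect_identical(chiSeries(t1), chiSeries(t2))

  expect_length(frames(t1), 30)
  expect_length(chiSeries(t1), 30)
  expect_length(acceptedFlags(t1), 30)
  expect_equal(acceptanceRatio(t1), mean(acceptedFlags(t1)))
  expect_true(all(is.finite(chiSeries(t1))))
  expect_true(all(rmsdToTarget(t1) >= 0))
  expect_true(t1@valid)
})

test_that("omega = 0 hybrid run is bitwise-identical to the control run", {
  s <- helixSetup(nJudgments = 20L, omega = 0)
  hyb <- runHybrid(s$init, s$cfg, target = s$target)
  ctl <- runControl(s$init, s$cfg, target = s$target)
  expect_equal(acceptanceRatio(hyb), 1.0)
  expect_equal(acceptanceRatio(ctl), 1.0)
  expect_identical(lapply(frames(hyb), coords), lapply(frames(ctl), coords))
  expect_identical(chiSeries(hyb), chiSeries(ctl))
  expect_identical(rmsdToTarget(hyb), rmsdToTarget(ctl))
})

test_that("an effectively infinite omega makes chi non-increasing", {
  s <- helixSetup(nJudgments = 25L, omega = 1e9)
  traj <- runHybrid(s$init, s$cfg, target = s$target)
  expect_true(all(diff(chiSeries(traj)) <= 1e-12))
  expect_lte(chiSeries(traj)[1], traj@chi0)
})

test_that("rejected judgments revert to the last accepted structure", {
  s <- helixSetup(nJudgments = 40L, omega = 5)  # strong bias: rejections occur
  traj <- runHybrid(s$init, s$cfg, target = s$target)
  acc <- acceptedFlags(traj)
  expect_true(any(!acc))
  rej <- which(!acc)
  rej <- rej[rej > 1]
  for (k in rej) {
    expect_identical(coords(frames(traj)[[k]]), coords(frames(traj)[[k - 1]]))
    expect_identical(chiSeries(traj)[k], chiSeries(traj)[k - 1])
  }
})

test_that("acceptance ratio stays above 40% at omega = 0.2 across seeds", {
  target <- makeFixture(20, "helix")
  tp <- debyeProfile(target)
  init <- perturbedStart(target, 4, seed = 17)
  ratios <- vapply(1:10, function(s) {
    cfg <- mcConfig(omega = 0.2, nJudgments = 40L, targetProfile = tp,
                    seed = 400L + s)
    acceptanceRatio(runHybrid(init, cfg, target = target))
  }, numeric(1))
  expect_true(all(ratios > 0.4))
})

test_that("pluggable propagator functions are honored", {
  s <- helixSetup(nJudgments = 10L)
  # a propagator that only translates: profile (hence chi) never changes
  shift <- function(structure, stream) {
    dx <- withStream(stream, rnorm(3))
    peptideStructure(sweep(coords(structure), 2, dx, "+"),
                     residueNames = structure@residueNames)
  }
  traj <- runHybrid(s$init, s$cfg, propagator = shift, target = s$target)
  expect_true(all(acceptedFlags(traj)))            # delta chi = 0 always
  expect_equal(chiSeries(traj), rep(traj@chi0, 10), tolerance = 1e-9)
})

test_that("external trajectories are judged sequentially with carried chi", {
  target <- makeFixture(20, "helix")
  tp <- debyeProfile(target)
  cfg <- mcConfig(omega = 0.4, nJudgments = 1L, targetProfile = tp,
                  seed = 9L)

  # single repeated frame: delta chi = 0, all accepted
  rep5 <- rep(list(target), 5)
  tr <- judgeExternalTrajectory(rep5, cfg, target = target)
  expect_true(all(acceptedFlags(tr)))
  expect_equal(acceptanceRatio(tr), 1)

  # frames with monotonically decreasing chi: all accepted
  closer <- lapply(c(6, 4.5, 3, 1.5), function(r)
    perturbedStart(target, r, seed = 21))
  chis <- vapply(closer, function(s)
    chiDiscrepancy(debyeProfile(s), tp), numeric(1))
  ord <- order(-chis)
  tr <- judgeExternalTrajectory(closer[ord], cfg, target = target)
  expect_true(all(acceptedFlags(tr)))

  expect_error(judgeExternalTrajectory(list(target), cfg), "2 frames")
})

test_that("external judgment replays exactly against hand-rolled decisions", {
  set.seed(61)
  target <- makeFixture(16, "helix")
  tp <- debyeProfile(target)
  frames100 <- lapply(1:40, function(i) {
    st <- rngStream(700 + i)
    propagateSegment(target, propagatorConfig(jitterAmplitude = 0.5), st)
  })
  cfg <- mcConfig(omega = 0.4, nJudgments = 1L, targetProfile = tp, seed = 3L)
  got <- judgeExternalTrajectory(frames100, cfg)

  # replay: same chi sequence, same dedicated uniform stream
  chis <- vapply(frames100, function(s)
    chiDiscrepancy(debyeProfile(s), tp), numeric(1))
  us <- withStream(rngStream(3L + 1000000L), runif(39))
  chiOld <- chis[1]
  expAcc <- logical(39)
  for (k in 1:39) {
    p <- min(1, exp(-0.4 * (chis[k + 1] - chiOld)))
    if (us[k] < p) {
      expAcc[k] <- TRUE
      chiOld <- chis[k + 1]
    }
  }
  expect_identical(acceptedFlags(got), expAcc)
  expect_equal(sum(acceptedFlags(got)), sum(expAcc))
})

test_that("aborted runs return a partial trajectory flagged invalid", {
  s <- helixSetup(nJudgments = 10L)
  nCalls <- 0
  failing <- function(structure, stream) {
    nCalls <<- nCalls + 1
    if (nCalls >= 4) stop("propagator exploded")
    propagateSegment(structure, propagatorConfig(), stream)
  }
  expect_warning(
    traj <- runHybrid(s$init, s$cfg, propagator = failing, target = s$target),
    "aborted")
  expect_false(traj@valid)
  expect_length(frames(traj), 3)
  expect_length(chiSeries(traj), 3)
})
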