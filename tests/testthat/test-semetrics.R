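test_that("actual SE counts strict improvements over R1", {
  expect_equal(actualSe(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(actualSe(c(3, 4, 5), 2), 0)
  expect_equal(actualSe(rep(1, 5), 1), 0)    # strict inequality
  set.seed(2)
  x <- runif(1000, 0, 10)
  expect_equal(actualSe(x, 4), sum(x < 4) / 1000)
  expect_error(actualSe(numeric(0), 1), "empty")
  expect_error(actualSe(1:3, 0), "r1")
})

test_that("sampling range is the interpolated 95th percentile", {
  expect_equal(samplingRange(rep(2.5, 10)), 2.5)
  expect_equal(samplingRange(1:100), 95.05)
  for (seed in 1:5) {
    set.seed(seed)
    x <- rexp(50)
    expect_lte(samplingRange(x), max(x))
  }
})

test_that("hypothetical SE reproduces the printed closed forms", {
  expect_equal(hypotheticalSe(2, 3, 1), 0.5)          # 1D, ratio < 2
  expect_equal(hypotheticalSe(1, 3, 1), 1 / 3)        # 1D, ratio >= 2
  expect_equal(hypotheticalSe(1, 2, 3), 0.125)        # 3D branch point
  expect_equal(0.5 - 3 * 2 / (16 * 1), 0.125)         # printed 3D form agrees
  expect_equal(hypotheticalSe(1, 1, 2), (2 * pi / 3 - sqrt(3) / 2) / pi,
               tolerance = 1e-12)                     # unit-circle lens
  expect_equal(hypotheticalSe(2, 1, 3), 0.5 - 3 * 1 / (16 * 2))
  expect_error(hypotheticalSe(0, 1, 3), "> 0")
  expect_error(hypotheticalSe(1, 1, 4), "dim")
})

test_that("hypothetical SE is continuous, bounded and monotone", {
  for (d in 1:3) {
    for (r1 in c(0.5, 1, 3, 7)) {
      eps <- 1e-9
      left <- hypotheticalSe(r1, 2 * r1 - eps, d)
      right <- hypotheticalSe(r1, 2 * r1 + eps, d)
      expect_lt(abs(left - right), 1e-6)
      expect_lt(abs(hypotheticalSe(r1, 2 * r1, d) - (0.5)^d), 1e-12)
    }
  }
  set.seed(4)
  for (i in 1:100) {
    r1 <- runif(1, 0.1, 10); r2 <- runif(1, 0.1, 20); d <- sample(3, 1)
    v <- hypotheticalSe(r1, r2, d)
    expect_gte(v, 0)
    expect_lte(v, 0.5)
  }
  # non-increasing in r2 at fixed r1 for ratio >= 2
  r2s <- seq(6, 30, by = 0.5)
  vals <- vapply(r2s, function(r2) hypotheticalSe(3, r2, 3), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("hypothetical SE agrees with the Monte-Carlo overlap oracle", {
  set.seed(17)
  for (i in 1:12) {
    r1 <- runif(1, 0.5, 8)
    r2 <- runif(1, 0.5, 16)
    d <- sample(3, 1)
    mc <- mcBallOverlap(r1, r2, d, nSamples = 2e5)
    expect_lt(abs(hypotheticalSe(r1, r2, d) - mc$estimate),
              3 * mc$se + 1e-12)
  }
})

test_that("the random-conformation baseline follows the normal model", {
  expect_equal(revaProbability(3.333 * 20^(1 / 3), 20), 0.5)
  expect_equal(revaProbability(9.047, 20), 0.5, tolerance = 1e-3)
  expect_lt(revaProbability(0, 104), 1e-4)
  expect_gt(revaProbability(30, 104), 1 - 1e-4)
  r <- seq(0, 20, by = 0.5)
  expect_true(all(diff(revaProbability(r, 20)) > 0))
  expect_error(revaProbability(-1, 20), ">= 0")
})

makeToyTrajectory <- function(rmsdT, rmsdI) {
  n <- length(rmsdT)
  new("HybridTrajectory",
      frames = rep(list(makeFixture(8, "helix")), n),
      chiSeries = rep(1, n), accepted = rep(TRUE, n),
      rmsdToInitial = rmsdI, rmsdToTarget = rmsdT,
      acceptanceRatio = 1, chi0 = 1, omega = 0.2, temperature = 310,
      seed = 1L, valid = TRUE)
}

test_that("SE reports assemble the right bins and values", {
  traj <- makeToyTrajectory(rmsdT = c(1, 2, 3, 4), rmsdI = rep(2, 4))
  rep1 <- seReport(traj, r1 = 2.5, nResidues = 20)
  expect_equal(rep1@actualSE, 0.5)
  expect_equal(rep1@r2, 2)
  expect_equal(rep1@ratioGroup, "(0,1]")     # 2 / 2.5 = 0.8
  expect_equal(rep1@r1Class, "easy")
  expect_equal(rep1@revaP, revaProbability(2.5, 20))
  expect_equal(rep1@meanRmsdT, 2.5)

  rep2 <- seReport(makeToyTrajectory(rep(5, 4), rep(16, 4)), 7, 20)
  expect_equal(rep2@ratioGroup, "(2,Inf)")
  expect_equal(rep2@r1Class, "easy")         # boundary 7 goes to easy
  rep3 <- seReport(makeToyTrajectory(rep(5, 4), rep(10, 4)), 7.01, 20)
  expect_equal(rep3@r1Class, "hard")
  expect_equal(rep3@ratioGroup, "(1,2]")
})

test_that("paired comparisons reproduce the printed improvement arithmetic", {
  expect_equal(improvementPct(0.5, 3.9), 680.0)
  expect_equal(improvementPct(13.2, 28.9), 118.9)
  expect_true(is.na(improvementPct(0, 1)))

  t1 <- makeToyTrajectory(c(1, 2, 3, 4), rep(2, 4))
  same <- comparePair(t1, t1, r1 = 2.5)
  expect_equal(same@dRmsdT, 0)
  expect_equal(same@dSE, 0)
  expect_equal(same@improvementPct, 0)

  t2 <- makeToyTrajectory(c(2, 3, 4, 5), rep(2, 4))
  cmp <- comparePair(t1, t2, r1 = 2.5)
  expect_equal(cmp@dRmsdT, -1)
  expect_equal(cmp@dSE, 0.5 - 0.25)
  expect_equal(cmp@improvementPct, 100.0)
})

test_that("grouped summaries conserve counts and average correctly", {
  reports <- list(
    seReport(makeToyTrajectory(c(1, 2), rep(2, 2)), 4, 20),    # ratio 0.5
    seReport(makeToyTrajectory(c(5, 6), rep(6, 2)), 4, 20),    # ratio 1.5
    seReport(makeToyTrajectory(c(8, 9), rep(9, 2)), 4, 20),    # ratio 2.25
    seReport(makeToyTrajectory(c(8, 9), rep(8, 2)), 9, 20)     # hard, ratio<1
  )
  tab <- groupTrajectories(reports)
  ratioRows <- tab[startsWith(tab$group, "R2/R1"), ]
  expect_equal(sum(ratioRows$n), 4)
  expect_equal(tab$n[tab$group == "all"], 4)
  easy <- tab[tab$group == "R1 easy", ]
  expect_equal(easy$n, 3)
  expect_equal(easy$meanR1, 4)
  expect_equal(easy$meanActualSE,
               mean(vapply(reports[1:3], function(r) r@actualSE, numeric(1))))
  binA <- tab[tab$group == "R2/R1 (0,1]", ]
  expect_equal(binA$n, 2)
  expect_equal(binA$meanR2, mean(c(2, 8)))
})

test_that("secondary structure accordance behaves on ideal fixtures", {
  h <- makeFixture(20, "helix")
  ssH <- assignSecondaryStructure(h)
  expect_gte(ssAccordance(h, rep("H", 20)), 0.8)
  expect_equal(ssAccordance(h, ssH), 1.0)
  expect_lte(ssAccordance(h, rep("C", 20)), 0.2)

  s <- makeFixture(20, "sheet")
  expect_gte(mean(assignSecondaryStructure(s) == "E"), 0.5)
  expect_error(ssAccordance(h, rep("H", 10)), "length")
  # string form accepted
  expect_equal(ssAccordance(h, paste(ssH, collapse = "")), 1.0)
})
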