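test_that("chi is zero for identical profiles (eq1) and errors on -Inf (eq2)", {
  p <- debyeProfile(makeFixture(20, "helix"))
  expect_equal(chiDiscrepancy(p, p, discrepancySpec("eq1")), 0)
  expect_error(chiDiscrepancy(p, p, discrepancySpec("eq2")), "zero")
})

test_that("chi reproduces the hand-computed two-point example", {
  q <- c(0.01, 0.1)
  target <- profileFrom(q, c(10, 1))
  decoy <- profileFrom(q, c(100, 10))
  # (1000/2) * (|log10(100)-log10(10)| + |log10(10)-log10(1)|) / log10(10)
  expect_equal(chiDiscrepancy(decoy, target, discrepancySpec("eq1", 0)), 1000)
})

test_that("chi matches a naive loop oracle for every form and exponent", {
  set.seed(14)
  q <- defaultQGrid()
  it <- exp(-q^2 * 30) * (1 + 0.05 * runif(120)) * 400
  id <- exp(-q^2 * 45) * (1 + 0.05 * runif(120)) * 380
  target <- profileFrom(q, it)
  decoy <- profileFrom(q, id)
  for (n in 0:4) {
    s <- 0
    for (k in seq_along(q))
      s <- s + abs(q[k]^n * log10(id[k]) - q[k]^n * log10(it[k])) /
        abs(log10(it[1]))
    expect_equal(chiDiscrepancy(decoy, target, discrepancySpec("eq1", n)),
                 1000 / 120 * s, tolerance = 1e-12)
    s2 <- 0
    for (k in seq_along(q))
      s2 <- s2 + abs(q[k]^n * id[k] - q[k]^n * it[k]) / it[1]
    expect_equal(chiDiscrepancy(decoy, target, discrepancySpec("eq2", n)),
                 log10(1000 / 120 * s2), tolerance = 1e-12)
  }
})

test_that("chi is exactly covariant in the amplification factor", {
  p1 <- debyeProfile(makeFixture(20, "helix"))
  p2 <- debyeProfile(makeFixture(20, "coil", seed = 2))
  c1 <- chiDiscrepancy(p2, p1, discrepancySpec("eq1", 0, amplificationC = 1000))
  c2 <- chiDiscrepancy(p2, p1, discrepancySpec("eq1", 0, amplificationC = 2000))
  expect_equal(c2, 2 * c1)
})

test_that("chi enforces its grid and range contracts", {
  q <- defaultQGrid()
  p <- profileFrom(q, exp(-q^2 * 30))
  pShift <- profileFrom(q + 1e-3, exp(-q^2 * 30))
  expect_error(chiDiscrepancy(p, pShift), "identical q grid")
  pshort <- profileFrom(q[1:60], exp(-q[1:60]^2 * 30))
  expect_error(chiDiscrepancy(p, pshort), "identical q grid")
  expect_error(chiDiscrepancy(p, p, discrepancySpec("eq1", qMin = 0.7,
                                                    qMax = 0.9)),
               "no grid points")
  # eq1 normalizer log I(qMin)_target = 0 (target intensity 1 at qMin)
  unitTarget <- profileFrom(q, c(1, exp(-q[-1]^2 * 30)))
  expect_error(chiDiscrepancy(p, unitTarget, discrepancySpec("eq1")),
               "normalization")
})

test_that("experimental chi absorbs constant scale and matches hand case", {
  q <- defaultQGrid()
  base <- exp(-q^2 * 40) * 200
  exp1 <- profileFrom(q, base, logError = rep(1, 120))
  calcSame <- profileFrom(q, base)
  expect_equal(chiExperimental(calcSame, exp1), 0, tolerance = 1e-12)

  calcScaled <- profileFrom(q, 10 * base)
  expect_equal(chiExperimental(calcScaled, exp1), 0, tolerance = 1e-12)

  # 3-point hand case: residuals after offset (0, .5, -.5), errors (1,.5,.5)
  q3 <- c(0.01, 0.1, 0.2)
  lexp <- c(2, 1, 0.5)
  lcal <- lexp + c(0.3, 0.8, -0.2)
  expCase <- profileFrom(q3, 10^lexp, logError = c(1, 0.5, 0.5))
  calCase <- profileFrom(q3, 10^lcal)
  expect_equal(chiExperimental(calCase, expCase), 1000 / 3 * 2,
               tolerance = 1e-9)
})

test_that("experimental chi validates errors and overlap", {
  q <- defaultQGrid()
  p <- profileFrom(q, exp(-q^2 * 30))
  expect_error(chiExperimental(p, p), "errors")
  away <- profileFrom(q + 10, exp(-q^2 * 30), logError = rep(1, 120))
  expect_error(chiExperimental(p, away), "overlap")
})

test_that("experimental chi interpolates onto the experimental grid", {
  qc <- defaultQGrid()
  qe <- seq(0.01, 0.55, length.out = 40)       # different grid
  rg2 <- 35
  calc <- profileFrom(qc, 150 * exp(-qc^2 * rg2))
  expc <- profileFrom(qe, 150 * exp(-qe^2 * rg2), logError = rep(0.1, 40))
  # same underlying curve: interpolation error only (log-linear in q)
  expect_lt(chiExperimental(calc, expc), 1)
})

test_that("spearman matches brute-force rank-then-Pearson with ties", {
  expect_equal(spearmanRho(1:10, (1:10)^3), 1)
  expect_equal(spearmanRho(1:10, -(1:10)^3), -1)
  set.seed(3)
  x <- sample(rep(1:4, 3))
  y <- sample(rep(1:3, 4))
  rx <- rank(x); ry <- rank(y)
  bruteForce <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanRho(x, y), bruteForce, tolerance = 1e-12)
  expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
  expect_error(spearmanRho(1:2, 1:2), "length")
})

test_that("selectBestForm ranks a constructed monotone spec first", {
  q <- defaultQGrid()
  target <- profileFrom(q, 400 * exp(-q^2 * 30))
  rmsd <- seq(0.5, 5, length.out = 10)
  # decoys whose log-intensity offset grows monotonically with rmsd:
  # every eq1 chi is monotone, so the top coefficient must be exactly 1
  decoys <- lapply(rmsd, function(r)
    profileFrom(q, intensities(target) * 10^(r / 10)))
  tab <- selectBestForm(decoys, rmsd, target)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$spearman >= -1 & tab$spearman <= 1))
  expect_equal(tab$spearman[1], 1.0)
  expect_error(selectBestForm(decoys[1:2], rmsd[1:2], target), "3 decoys")
})

test_that("rank correlation of eq1 decreases from n = 0 to n = 4 on a pool", {
  pool <- makeDecoyPool(nPerRun = 10L, seed = 5L)   # small pool: direction only
  tab <- rankDiscrepancyForms(pool,
                              candidates = lapply(0:4, function(n)
                                discrepancySpec("eq1", n)))
  e1 <- tab$spearman[order(tab$exponentN)]
  expect_gt(e1[1], e1[5])
})
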