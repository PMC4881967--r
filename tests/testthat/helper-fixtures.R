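# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# A ScatteringProfile straight from vectors (bypassing the Debye calculator).
profileFrom <- function(q, intensity, logError = numeric(0)) {
  new("ScatteringProfile", q = q, intensity = intensity, logError = logError)
}

# Analytic solid-sphere profile (form factor squared) on a q grid.
sphereProfile <- function(radius, q = defaultQGrid()) {
  x <- q * radius
  f <- 3 * (sin(x) - x * cos(x)) / x^3
  profileFrom(q, f^2)
}

# Naive O(n^2 * nq) double-loop Debye oracle, written independently of the
# vectorized implementation.
naiveDebye <- function(xyz, f, q) {
  n <- nrow(xyz)
  vapply(q, function(qk) {
    s <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) s <- s + f[i] * f[j]
        else {
          r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
          s <- s + f[i] * f[j] * sin(qk * r) / (qk * r)
        }
      }
    }
    s
  }, numeric(1))
}

# Random connected CA-like chain (not necessarily self-avoiding).
randomChain <- function(n, seed = 1, step = 3.8) {
  set.seed(seed)
  steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * step
  peptideStructure(rbind(c(0, 0, 0), apply(steps, 2, cumsum)))
}

# Apply a rigid transform to a structure.
rigidMove <- function(s, rot = diag(3), trans = c(0, 0, 0)) {
  x <- coords(s) %*% t(rot)
  peptideStructure(sweep(x, 2, trans, "+"),
                   atomLabels = s@atomLabels, residueIds = s@residueIds,
                   residueNames = s@residueNames, modelId = s@modelId)
}

rotZ <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# Raw (unsuperposed) RMSD.
rawRmsd <- function(a, b) sqrt(mean(rowSums((coords(a) - coords(b))^2)))
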