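#' Construct a DiscrepancySpec
#'
#' @param form "eq1" (log-intensity form), "eq2" (linear-intensity log-sum
#'   form) or "eq6" (error-weighted experimental form).
#' @param exponentN integer in 0..4, the q^n weighting exponent (ignored by
#'   "eq6").
#' @param amplificationC amplification factor c (default 1000).
#' @param qMin,qMax integration bounds, 1/Angstrom (defaults 0.005 and 0.6).
#' @param offsetRule for "eq6": "lowest-q" or "mean5" (see class docs).
#' @return a \linkS4class{DiscrepancySpec}.
#' @export
discrepancySpec <- function(form = c("eq1", "eq2", "eq6"), exponentN = 0L,
                            amplificationC = 1000, qMin = 0.005, qMax = 0.6,
                            offsetRule = c("lowest-q", "mean5")) {
  new("DiscrepancySpec", form = match.arg(form),
      exponentN = as.integer(exponentN), amplificationC = amplificationC,
      qMin = qMin, qMax = qMax, offsetRule = match.arg(offsetRule))
}

# All log-intensity work uses base-10 logs (the SAXS plotting convention);
# the Metropolis layer is invariant to this choice up to a rescaling of the
# pseudo-energy weight omega.
log10I <- function(x) log(x, base = 10)

#' Profile discrepancy chi between a decoy and a target
#'
#' The discrepancy family driving the pseudo-energy. For a shared grid q
#' restricted to [qMin, qMax] with n points and amplification factor c:
#' \itemize{
#' \item form "eq1": chi = (c/N) * sum | q^n log I_decoy - q^n log I_target |
#'   / |log I(qMin)_target|, with the single global normalizer inside the sum;
#' \item form "eq2": chi = log[ (c/N) * sum | q^n I_decoy - q^n I_target | /
#'   I(qMin)_target ] (may be negative when the normalized sum is < 1).
#' }
#' Logs are base 10. Both profiles must be on an identical q grid; no
#' interpolation is performed here (see \code{\link{chiExperimental}} for the
#' interpolating experimental form).
#'
#' @param decoy,target \linkS4class{ScatteringProfile} objects on the same
#'   grid.
#' @param spec a \linkS4class{DiscrepancySpec} with form "eq1" or "eq2".
#' @return dimensionless chi (finite).
#' @examples
#' p <- debyeProfile(makeFixture(20, "helix"))
#' chiDiscrepancy(p, p)  # identical profiles: 0
#' @export
chiDiscrepancy <- function(decoy, target, spec = discrepancySpec()) {
  if (spec@form == "eq6")
    stop("use chiExperimental() for the error-weighted experimental form",
         call. = FALSE)
  qd <- qValues(decoy)
  qt <- qValues(target)
  if (length(qd) != length(qt) || any(abs(qd - qt) > 1e-12))
    stop("decoy and target must share an identical q grid", call. = FALSE)
  keep <- qd >= spec@qMin - 1e-12 & qd <= spec@qMax + 1e-12
  if (!any(keep)) stop("no grid points inside [qMin, qMax]", call. = FALSE)
  q <- qd[keep]
  id <- intensities(decoy)[keep]
  it <- intensities(target)[keep]
  if (any(id <= 0) || any(it <= 0))
    stop("nonpositive intensity in profile", call. = FALSE)
  n <- sum(keep)
  cc <- spec@amplificationC
  w <- q^spec@exponentN
  if (spec@form == "eq1") {
    norm <- log10I(it[1])
    if (abs(norm) < 1e-12)
      stop("normalization failure: log I(qMin)_target is 0", call. = FALSE)
    chi <- (cc / n) * sum(abs(w * log10I(id) - w * log10I(it)) / abs(norm))
  } else {
    s <- (cc / n) * sum(abs(w * id - w * it) / it[1])
    if (s <= 0)
      stop("eq2 sum is zero: chi is -Inf (identical profiles)", call. = FALSE)
    chi <- log10I(s)
  }
  if (!is.finite(chi)) stop("non-finite chi", call. = FALSE)
  chi
}

#' Error-weighted discrepancy against an experimental profile
#'
#' The experimental-data form: the computed profile is interpolated (linear
#' in log I over q) onto the experimental grid restricted to [qMin, qMax];
#' the constant offset Delta_offset between the two log-intensity curves --
#' nominally their difference at q = 0, approximated at the lowest shared
#' grid point (or, with \code{offsetRule = "mean5"}, the mean over the five
#' lowest points) -- is subtracted; and each residual is weighted by the
#' experimental per-point log-intensity error:
#' chi = (c/N) * sum | log I_cal - log I_exp - Delta_offset | / deltaI_log(q).
#'
#' @param calc computed \linkS4class{ScatteringProfile}.
#' @param exp experimental \linkS4class{ScatteringProfile} carrying
#'   log-intensity errors.
#' @param spec a \linkS4class{DiscrepancySpec} (form "eq6"; the exponent is
#'   ignored).
#' @return dimensionless chi.
#' @export
chiExperimental <- function(calc, exp, spec = discrepancySpec(form = "eq6")) {
  if (length(logErrors(exp)) == 0)
    stop("experimental profile must carry log-intensity errors", call. = FALSE)
  if (any(logErrors(exp) <= 0))
    stop("all log-intensity errors must be > 0", call. = FALSE)
  qc <- qValues(calc)
  qe <- qValues(exp)
  lo <- max(min(qc), min(qe), spec@qMin)
  hi <- min(max(qc), max(qe), spec@qMax)
  keep <- qe >= lo - 1e-12 & qe <= hi + 1e-12
  if (!any(keep))
    stop("no overlap between calculated and experimental q ranges",
         call. = FALSE)
  qs <- qe[keep]
  lcal <- stats::approx(qc, log10I(intensities(calc)), xout = qs)$y
  lexp <- log10I(intensities(exp))[keep]
  derr <- logErrors(exp)[keep]
  nOff <- if (spec@offsetRule == "mean5") min(5L, length(qs)) else 1L
  offset <- mean(lcal[seq_len(nOff)] - lexp[seq_len(nOff)])
  n <- length(qs)
  (spec@amplificationC / n) * sum(abs(lcal - lexp - offset) / derr)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties (delegates to
#' \code{stats::cor}).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return coefficient in [-1, 1].
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant sequence", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Rank discrepancy forms by their correlation with RMSD
#'
#' Scores each candidate discrepancy specification by the Spearman rank
#' correlation between chi (decoy vs target profile) and the decoys' RMSD,
#' and returns the candidates sorted by decreasing correlation. This is the
#' calibration step that selects which chi form drives the pseudo-energy.
#'
#' @param decoyProfiles list of \linkS4class{ScatteringProfile} (one per
#'   decoy, same grid as \code{target}).
#' @param rmsd numeric, RMSD of each decoy (to the reference structure of
#'   \code{target}).
#' @param target target \linkS4class{ScatteringProfile}.
#' @param candidates list of \linkS4class{DiscrepancySpec}; default the ten
#'   eq1/eq2 x n = 0..4 combinations.
#' @return data.frame with columns form, exponentN, spearman, ordered by
#'   decreasing spearman.
#' @export
selectBestForm <- function(decoyProfiles, rmsd, target,
                           candidates = defaultCandidates()) {
  if (length(decoyProfiles) != length(rmsd))
    stop("one RMSD per decoy profile required", call. = FALSE)
  if (length(decoyProfiles) < 3)
    stop("at least 3 decoys required", call. = FALSE)
  rows <- lapply(candidates, function(sp) {
    chis <- vapply(decoyProfiles, chiDiscrepancy, numeric(1),
                   target = target, spec = sp)
    data.frame(form = sp@form, exponentN = sp@exponentN,
               spearman = spearmanRho(chis, rmsd))
  })
  out <- do.call(rbind, rows)
  out[order(-out$spearman), , drop = FALSE]
}

#' @rdname selectBestForm
#' @export
defaultCandidates <- function() {
  c(lapply(0:4, function(n) discrepancySpec("eq1", n)),
    lapply(0:4, function(n) discrepancySpec("eq2", n)))
}
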