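#' Pairwise RMSD matrix of a decoy set
#'
#' @param decoys list of \linkS4class{PeptideStructure} with equal point
#'   counts.
#' @return symmetric numeric matrix of superposed C-alpha RMSDs, Angstrom.
#' @export
pairwiseRmsd <- function(decoys) {
  n <- length(decoys)
  m <- matrix(0, n, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- rmsdAfterSuperposition(decoys[[i]], decoys[[j]])
    }
  }
  m
}

greedyCluster <- function(rmsdMat, cutoff) {
  n <- nrow(rmsdMat)
  remaining <- rep(TRUE, n)
  clusters <- list()
  centers <- integer(0)
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- vapply(idx, function(i)
      sum(rmsdMat[i, idx] <= cutoff), integer(1))   # neighbors incl. self
    seed <- idx[which.max(counts)]                  # ties -> lowest index
    members <- idx[rmsdMat[seed, idx] <= cutoff]
    clusters[[length(clusters) + 1L]] <- members
    centers <- c(centers, seed)
    remaining[members] <- FALSE
  }
  list(clusters = clusters, centers = centers)
}

#' Cluster decoys with a self-adjusting RMSD cutoff
#'
#' Iterative greedy clustering in the SPICKER spirit: the decoy with the most
#' neighbors within the cutoff seeds the first (largest) cluster and is its
#' center (medoid); its members are removed and the rule repeats. If the
#' largest cluster covers less than 15 percent of all decoys the cutoff is
#' increased by a factor 1.15 and clustering rerun; above 70 percent it is
#' decreased by 0.85; up to \code{maxAdjust} adjustments. When the coverage
#' rule cannot be met the best result is returned with
#' \code{satisfied = FALSE} rather than an error.
#'
#' @param decoys list of \linkS4class{PeptideStructure} (>= 3).
#' @param initialCutoff starting RMSD cutoff, Angstrom (default 4).
#' @param maxAdjust bound on cutoff adjustments (default 20).
#' @param rmsdMat optional precomputed pairwise RMSD matrix.
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterDecoys <- function(decoys, initialCutoff = 4, maxAdjust = 20L,
                          rmsdMat = NULL) {
  if (length(decoys) < 3)
    stop("at least 3 decoys required for clustering", call. = FALSE)
  if (is.null(rmsdMat)) rmsdMat <- pairwiseRmsd(decoys)
  n <- length(decoys)
  cutoff <- initialCutoff
  satisfied <- FALSE
  res <- NULL
  for (adj in seq_len(maxAdjust + 1L)) {
    res <- greedyCluster(rmsdMat, cutoff)
    coverage <- length(res$clusters[[1]]) / n
    if (coverage >= 0.15 && coverage <= 0.70) {
      satisfied <- TRUE
      break
    }
    if (adj > maxAdjust) break
    cutoff <- cutoff * (if (coverage < 0.15) 1.15 else 0.85)
  }
  ord <- order(-lengths(res$clusters),
               vapply(res$clusters, min, integer(1)))
  clusters <- res$clusters[ord]
  centers <- res$centers[ord]
  new("ClusterResult",
      clusters = clusters,
      centerIndices = centers,
      centers = decoys[centers],
      finalCutoff = cutoff,
      top1Coverage = length(clusters[[1]]) / n,
      satisfied = satisfied)
}

#' Top-k cluster center models
#'
#' Centers of the k most populated clusters, in population order; ties are
#' broken in favor of the cluster containing the lower first decoy index.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param k number of models requested (>= 1); fewer are returned when the
#'   result has fewer clusters.
#' @return list of \linkS4class{PeptideStructure} center models.
#' @export
topModels <- function(result, k = 3L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  result@centers[seq_len(min(k, length(result@clusters)))]
}
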