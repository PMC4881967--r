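#' Accessors for the core classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return \code{coords}: n x 3 numeric matrix; \code{nAtoms}, \code{nPoints},
#'   \code{nResidues}: integer; \code{qValues}, \code{intensities},
#'   \code{chiSeries}, \code{rmsdToTarget}, \code{rmsdToInitial}: numeric
#'   vectors; \code{frames}, \code{clusterMembers}, \code{clusterCenters}:
#'   lists; \code{acceptanceRatio}, \code{actualSE}: numeric scalars.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("residueNames", function(x) standardGeneric("residueNames"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("logErrors", function(x) standardGeneric("logErrors"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("chiSeries", function(x) standardGeneric("chiSeries"))
#' @rdname accessors
#' @export
setGeneric("acceptedFlags", function(x) standardGeneric("acceptedFlags"))
#' @rdname accessors
#' @export
setGeneric("acceptanceRatio", function(x) standardGeneric("acceptanceRatio"))
#' @rdname accessors
#' @export
setGeneric("rmsdToInitial", function(x) standardGeneric("rmsdToInitial"))
#' @rdname accessors
#' @export
setGeneric("rmsdToTarget", function(x) standardGeneric("rmsdToTarget"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname accessors
setMethod("coords", "PeptideStructure", function(x) x@coords)
#' @rdname accessors
setMethod("nAtoms", "PeptideStructure", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("nResidues", "PeptideStructure",
          function(x) length(unique(x@residueIds)))
#' @rdname accessors
setMethod("residueNames", "PeptideStructure", function(x) x@residueNames)

#' @rdname accessors
setMethod("qValues", "ScatteringProfile", function(x) x@q)
#' @rdname accessors
setMethod("intensities", "ScatteringProfile", function(x) x@intensity)
#' @rdname accessors
setMethod("logErrors", "ScatteringProfile", function(x) x@logError)
#' @rdname accessors
setMethod("nPoints", "ScatteringProfile", function(x) length(x@q))

#' @rdname accessors
setMethod("frames", "HybridTrajectory", function(x) x@frames)
#' @rdname accessors
setMethod("chiSeries", "HybridTrajectory", function(x) x@chiSeries)
#' @rdname accessors
setMethod("acceptedFlags", "HybridTrajectory", function(x) x@accepted)
#' @rdname accessors
setMethod("acceptanceRatio", "HybridTrajectory", function(x) x@acceptanceRatio)
#' @rdname accessors
setMethod("rmsdToInitial", "HybridTrajectory", function(x) x@rmsdToInitial)
#' @rdname accessors
setMethod("rmsdToTarget", "HybridTrajectory", function(x) x@rmsdToTarget)

#' @rdname accessors
setMethod("clusterMembers", "ClusterResult", function(x) x@clusters)
#' @rdname accessors
setMethod("clusterCenters", "ClusterResult", function(x) x@centers)

setMethod("show", "PeptideStructure", function(object) {
  cat("PeptideStructure:", nAtoms(object), "points,",
      nResidues(object), "residues, model", object@modelId, "\n")
  if (nAtoms(object) > 0) {
    rn <- unique(object@residueNames)
    cat("  residues:", paste(utils::head(rn, 5), collapse = " "),
        if (length(rn) > 5) "..." else "", "\n")
  }
})

setMethod("show", "ScatteringProfile", function(object) {
  n <- nPoints(object)
  cat("ScatteringProfile:", n, "points")
  if (n > 0)
    cat(sprintf(", q in [%.4g, %.4g] 1/A", object@q[1], object@q[n]))
  cat(if (length(object@logError)) ", with log-intensity errors" else "", "\n")
})

setMethod("show", "DiscrepancySpec", function(object) {
  cat(sprintf("DiscrepancySpec: form=%s n=%d c=%g q=[%g, %g]\n",
              object@form, object@exponentN, object@amplificationC,
              object@qMin, object@qMax))
})

setMethod("show", "HybridTrajectory", function(object) {
  n <- length(object@frames)
  cat(sprintf("HybridTrajectory: %d judgments, acceptance %.1f%%\n",
              n, 100 * object@acceptanceRatio))
  if (n > 0)
    cat(sprintf("  chi: %.3g -> %.3g   mean RMSD_T: %.2f A\n",
                object@chi0, object@chiSeries[n], mean(object@rmsdToTarget)))
  if (!object@valid) cat("  [flagged invalid: aborted run]\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d clusters, top-1 coverage %.1f%%, cutoff %.2f A%s\n",
    length(object@clusters), 100 * object@top1Coverage, object@finalCutoff,
    if (object@satisfied) "" else " (coverage rule not satisfied)"))
  cat("  sizes:", paste(utils::head(lengths(object@clusters), 8),
                        collapse = " "), "\n")
})

setMethod("show", "SEReport", function(object) {
  cat(sprintf("SEReport: R1=%.2f A  R2=%.2f A  (R2/R1=%.2f, %s, %s)\n",
              object@r1, object@r2, object@r2 / object@r1,
              object@ratioGroup, object@r1Class))
  cat(sprintf("  actual SE %.3f | hypothetical SE 1d %.3f 2d %.3f 3d %.3f\n",
              object@actualSE, object@hypotheticalSE[["1d"]],
              object@hypotheticalSE[["2d"]], object@hypotheticalSE[["3d"]]))
  cat(sprintf("  Reva baseline %.4f | mean RMSD_T %.2f A\n",
              object@revaP, object@meanRmsdT))
})

setMethod("show", "PairedComparison", function(object) {
  cat(sprintf(
    "PairedComparison: dRMSD_T=%.2f A  dSE=%.3f  improvement=%s%%\n",
    object@dRmsdT, object@dSE,
    if (is.na(object@improvementPct)) "NA"
    else format(object@improvementPct, nsmall = 1)))
})
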