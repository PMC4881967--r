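#' Construct a PeptideStructure
#'
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param atomLabels character per-point atom names (recycled if length 1).
#' @param residueIds integer per-point residue indices (default 1..n).
#' @param residueNames character per-point residue names (recycled).
#' @param modelId integer frame tag.
#' @return a \linkS4class{PeptideStructure}.
#' @examples
#' s <- peptideStructure(matrix(rnorm(60), ncol = 3))
#' nAtoms(s)
#' @export
peptideStructure <- function(coords, atomLabels = "CA",
                             residueIds = seq_len(nrow(coords)),
                             residueNames = "ALA", modelId = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  new("PeptideStructure", coords = coords,
      atomLabels = rep_len(as.character(atomLabels), n),
      residueIds = as.integer(rep_len(residueIds, n)),
      residueNames = rep_len(as.character(residueNames), n),
      modelId = as.integer(modelId))
}

setCoords <- function(x, coords) {
  x@coords <- coords
  x
}

## ---- PDB / XYZ I/O ---------------------------------------------------------

parsePdbAtomLine <- function(line, lineno) {
  # wwPDB v3.3 fixed columns
  grab <- function(a, b) trimws(substr(line, a, b))
  xyz <- suppressWarnings(as.numeric(c(grab(31, 38), grab(39, 46),
                                       grab(47, 54))))
  if (any(is.na(xyz)))
    stop("malformed coordinate field in PDB record at line ", lineno,
         call. = FALSE)
  resid <- suppressWarnings(as.integer(grab(23, 26)))
  if (is.na(resid))
    stop("malformed residue number in PDB record at line ", lineno,
         call. = FALSE)
  occ <- suppressWarnings(as.numeric(grab(55, 60)))
  list(name = grab(13, 16), altloc = grab(17, 17), resname = grab(18, 20),
       resid = resid, x = xyz[1], y = xyz[2], z = xyz[3],
       occ = if (is.na(occ)) 1 else occ)
}

# Resolve alternate locations: keep the highest-occupancy copy of each
# (residue, atom name) pair; ties go to altloc 'A' (then alphabetical).
resolveAltloc <- function(df) {
  key <- paste(df$resid, df$name)
  keep <- rep(TRUE, nrow(df))
  for (k in unique(key[df$altloc != ""])) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    sub <- df[rows, ]
    best <- rows[order(-sub$occ, sub$altloc)][1]
    keep[setdiff(rows, best)] <- FALSE
  }
  df[keep, , drop = FALSE]
}

#' Read structures from a PDB or XYZ file
#'
#' Multi-model PDB files yield one structure per MODEL record; ATOM and
#' HETATM records are both read, and alternate locations are resolved to the
#' highest-occupancy copy (ties to altloc "A").
#'
#' @param path file path.
#' @param format "pdb" or "xyz"; default guessed from the file extension.
#' @param caOnly logical; keep only C-alpha atoms (PDB input).
#' @return a list of \linkS4class{PeptideStructure}, one per model/frame.
#' @seealso \code{\link{writeStructures}}
#' @export
readStructures <- function(path, format = c("auto", "pdb", "xyz"),
                           caOnly = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0 || all(trimws(lines) == ""))
    stop("empty input file: ", path, call. = FALSE)
  if (format == "pdb") readPdbLines(lines, caOnly) else readXyzLines(lines)
}

readPdbLines <- function(lines, caOnly) {
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- list()
  curId <- 1L
  sawModel <- FALSE
  flush <- function() {
    if (length(cur) == 0) return()
    df <- do.call(rbind.data.frame, c(cur, stringsAsFactors = FALSE))
    df <- resolveAltloc(df)
    if (caOnly) df <- df[df$name == "CA", , drop = FALSE]
    if (nrow(df) == 0)
      stop("no atoms left after selection in model ", curId, call. = FALSE)
    models[[length(models) + 1L]] <<- peptideStructure(
      cbind(df$x, df$y, df$z), atomLabels = df$name,
      residueIds = df$resid, residueNames = df$resname, modelId = curId)
  }
  for (i in seq_along(lines)) {
    r <- trimws(rec[i])
    if (r == "MODEL") {
      sawModel <- TRUE
      flush(); cur <- list()
      id <- suppressWarnings(as.integer(trimws(substr(lines[i], 11, 14))))
      curId <- if (is.na(id)) length(models) + 1L else id
    } else if (r == "ENDMDL") {
      flush(); cur <- list()
      curId <- curId + 1L
    } else if (r %in% c("ATOM", "HETATM")) {
      cur[[length(cur) + 1L]] <- parsePdbAtomLine(lines[i], i)
    }
  }
  flush()
  if (length(models) == 0)
    stop("no ATOM/HETATM records found", call. = FALSE)
  models
}

readXyzLines <- function(lines) {
  models <- list()
  i <- 1L
  id <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed XYZ atom count at line ", i, call. = FALSE)
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i, call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(lengths(parts) < 4)
    if (length(bad))
      stop("malformed XYZ atom record at line ", i + 1L + bad[1], call. = FALSE)
    lab <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz)))
      stop("malformed XYZ coordinates in frame starting at line ", i,
           call. = FALSE)
    models[[id]] <- peptideStructure(xyz, atomLabels = lab, modelId = id)
    id <- id + 1L
    i <- i + 2L + n
  }
  if (length(models) == 0) stop("no XYZ frames found", call. = FALSE)
  models
}

#' Write structures to a PDB or XYZ file
#'
#' Several structures are framed as a multi-model PDB (MODEL/ENDMDL) or as
#' consecutive XYZ frames.
#'
#' @param structures a \linkS4class{PeptideStructure} or list of them.
#' @param path output file path.
#' @param format "pdb" or "xyz"; default guessed from the extension.
#' @return \code{path}, invisibly.
#' @export
writeStructures <- function(path, structures, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (is(structures, "PeptideStructure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    multi <- length(structures) > 1
    for (k in seq_along(structures)) {
      s <- structures[[k]]
      if (multi) writeLines(sprintf("MODEL     %4d", k), con)
      xyz <- coords(s)
      for (i in seq_len(nAtoms(s))) {
        writeLines(sprintf(
          "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          i, formatAtomName(s@atomLabels[i]), s@residueNames[i],
          s@residueIds[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0), con)
      }
      if (multi) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (s in structures) {
      writeLines(as.character(nAtoms(s)), con)
      writeLines(sprintf("frame %d", s@modelId), con)
      xyz <- coords(s)
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                         s@atomLabels, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

formatAtomName <- function(nm) {
  # PDB convention: atom names of <4 chars start in column 14
  ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
}

## ---- Superposition and RMSD ------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of \code{mobile} onto \code{reference} by the
#' closed-form SVD solution, with reflection correction so the returned
#' rotation is proper (det = +1).
#'
#' @param mobile,reference \linkS4class{PeptideStructure} objects, or plain
#'   n x 3 coordinate matrices, with equal point counts (n >= 3,
#'   non-collinear).
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   such that \code{mobile \%*\% t(rotation) + translation} best fits the
#'   reference, and \code{rmsd} (Angstrom) at the optimum.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' superpose(a, a)$rmsd
#' @export
superpose <- function(mobile, reference) {
  xm <- if (is(mobile, "PeptideStructure")) coords(mobile) else as.matrix(mobile)
  xr <- if (is(reference, "PeptideStructure")) coords(reference) else
    as.matrix(reference)
  if (!identical(dim(xm), dim(xr)))
    stop("mobile and reference must have the same number of points",
         call. = FALSE)
  n <- nrow(xm)
  if (n < 3) stop("at least 3 points required for superposition",
                  call. = FALSE)
  cm <- colMeans(xm)
  cr <- colMeans(xr)
  a <- sweep(xm, 2, cm)
  b <- sweep(xr, 2, cr)
  # collinearity check: rank of centered reference points
  if (min(svd(a)$d[2], svd(b)$d[2]) < 1e-8)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  h <- crossprod(a, b)               # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(sum((fitted - b)^2) / n)
  list(rotation = rot, translation = as.numeric(cr - rot %*% cm), rmsd = rmsd)
}

#' RMSD after optimal superposition
#'
#' @param a,b structures or coordinate matrices with matching selections.
#' @param selection atom-subset rule: "CA" (default) keeps C-alpha atoms of
#'   \linkS4class{PeptideStructure} inputs, "all" keeps everything; or an
#'   integer/logical index vector applied to both inputs.
#' @return RMSD in Angstrom (non-negative, symmetric in its arguments).
#' @export
rmsdAfterSuperposition <- function(a, b, selection = "CA") {
  sel <- function(s) {
    if (!is(s, "PeptideStructure")) return(as.matrix(s))
    x <- coords(s)
    if (is.character(selection)) {
      if (selection == "all") return(x)
      keep <- s@atomLabels == selection
      # coarse-grained beads may carry any single label: fall back to all
      if (!any(keep)) keep <- rep(TRUE, nrow(x))
      return(x[keep, , drop = FALSE])
    }
    x[selection, , drop = FALSE]
  }
  xa <- sel(a)
  xb <- sel(b)
  if (nrow(xa) == 0) stop("empty atom selection", call. = FALSE)
  superpose(xa, xb)$rmsd
}

#' Axis-angle rotation vector of a rotation matrix
#'
#' Returns the vector whose direction is the rotation axis and whose
#' magnitude is the rotation angle in radians (in [0, pi]). Used as the
#' even-sampling diagnostic: rotation vectors of decoys superposed onto their
#' initial structure should fill a ball isotropically under unbiased
#' sampling.
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @return numeric length-3 axis-angle vector.
#' @export
rotationVector <- function(rotation) {
  r <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(r), diag(3), tolerance = 1e-6)) ||
      det(r) < 0)
    stop("input is not a proper rotation matrix", call. = FALSE)
  cosang <- (sum(diag(r)) - 1) / 2
  cosang <- min(1, max(-1, cosang))
  ang <- acos(cosang)
  if (ang < 1e-12) return(c(0, 0, 0))
  if (pi - ang < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    m <- (r + diag(3)) / 2
    axis <- sqrt(pmax(diag(m), 0))
    k <- which.max(axis)
    if (axis[k] > 0) {
      for (j in seq_len(3)) if (j != k) axis[j] <- m[k, j] / axis[k]
    }
    axis <- axis / sqrt(sum(axis^2))
    return(axis * ang)
  }
  axis <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) /
    (2 * sin(ang))
  axis * ang
}

#' Rotation matrix from an axis-angle vector
#'
#' Inverse of \code{\link{rotationVector}} (Rodrigues formula).
#'
#' @param v numeric length-3 axis-angle vector.
#' @return 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-300) return(diag(3))
  k <- v / ang
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(ang) * kx + (1 - cos(ang)) * (kx %*% kx)
}

#' Uniform random rotation matrices
#'
#' Draws rotations uniformly over SO(3) via unit quaternions; used to
#' validate the isotropy of the rotation-vector diagnostic.
#'
#' @param n number of rotations.
#' @return list of 3 x 3 rotation matrices.
#' @export
randomRotations <- function(n) {
  lapply(seq_len(n), function(i) {
    qv <- stats::rnorm(4)
    qv <- qv / sqrt(sum(qv^2))
    w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3)
  })
}
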