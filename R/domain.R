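## Computational-domain construction from label masks: connected-component
## cleanup, boundary-face enumeration, and in-plane probing axes.

#' Build a voxelised computational domain from label masks
#'
#' Takes an integer label volume (0 = background, 1 = tumor/viable shell,
#' 2+ = interior zones), keeps the largest 6-connected tumor component
#' (dropping islands with a warning), and enumerates the tumor-bath
#' boundary faces with the face-centred Dirichlet convention
#' (\code{theta = 0.5}); phantom domains built by
#' \code{\link{makePhantomDomain}} instead carry exact sub-voxel surface
#' distances.
#'
#' @param labels integer 3-D array of zone labels
#' @param spacing voxel spacing in mm (scalar or length 3)
#' @return a \linkS4class{TumorDomain}
#' @examples
#' m <- array(0L, c(5, 5, 5)); m[3, 3, 3] <- 1L
#' nrow(buildDomain(m, 0.5)@boundaryFaces)  # 6 faces
#' @export
buildDomain <- function(labels, spacing) {
  if (length(dim(labels)) == 2) labels <- array(labels, c(dim(labels), 1))
  if (length(dim(labels)) != 3) stop("labels must be a 2-D or 3-D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  storage.mode(labels) <- "integer"
  if (!any(labels > 0)) stop("empty tumor mask")
  cc <- .largestComponent(labels > 0)
  if (cc$n > 1) {
    warning(sprintf("%d disconnected island(s) dropped; largest component kept",
                    cc$n - 1))
    labels[!cc$component] <- 0L
  }
  faces <- .enumerateFaces(labels)$boundary
  faces$theta <- 0.5
  new("TumorDomain", labelGrid = labels, spacing = spacing,
      boundaryFaces = faces, axes = list(), truth = list())
}

## point-in-tumor test at physical coordinates (mm)
.inTumor <- function(labelGrid, spacing, p) {
  i <- floor(p / spacing) + 1
  if (any(i < 1) || any(i > dim(labelGrid))) return(FALSE)
  labelGrid[i[1], i[2], i[3]] > 0
}

## chord through point p0 (mm) along in-plane unit direction d, by ray
## marching plus bisection against the voxel mask. Returns list(tneg, tpos).
.chord <- function(labelGrid, spacing, p0, d, step) {
  march <- function(sgn) {
    t <- 0
    while (.inTumor(labelGrid, spacing, p0 + sgn * (t + step) * d)) t <- t + step
    lo <- t; hi <- t + step
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (.inTumor(labelGrid, spacing, p0 + sgn * mid * d)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  list(tneg = march(-1), tpos = march(1))
}

#' Define in-plane probing axes on a domain
#'
#' In the axial plane \code{planeIndex}, the long axis (LA) is the longest
#' chord through the in-plane centroid found by a 1-degree angular search;
#' short axes pass through the same centroid perpendicular to the LA (SA,
#' and for \code{nShortAxes = 2} an additional chord at 45 degrees, SA2).
#' Axis endpoints are ordered so that the first endpoint has the smaller
#' abscissa (the "L" end); profile coordinates later run 0 (L) to 1 (R).
#' If the centroid falls outside the mask (crescent-shaped slice) the
#' nearest in-mask voxel centre is used with a warning.
#'
#' @param domain a \linkS4class{TumorDomain}
#' @param planeIndex axial (third-axis) slice index; default mid-grid
#' @param nShortAxes 1 or 2 short axes
#' @return the domain with the \code{axes} slot filled (named list with
#'   elements "LA", "SA" or "SA1"/"SA2")
#' @export
defineAxes <- function(domain, planeIndex = NULL, nShortAxes = 1) {
  stopifnot(is(domain, "TumorDomain"))
  lg <- domain@labelGrid
  h <- domain@spacing
  if (is.null(planeIndex)) planeIndex <- round(dim(lg)[3] / 2)
  slice <- lg[, , planeIndex]
  vox <- which(slice > 0, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("plane does not intersect the tumor")
  if (nrow(vox) == 1) stop("degenerate single-voxel slice: axes undefined")
  ctr <- c((mean(vox[, 1]) - 0.5) * h[1], (mean(vox[, 2]) - 0.5) * h[2],
           (planeIndex - 0.5) * h[3])
  if (!.inTumor(lg, h, ctr)) {
    warning("in-plane centroid outside the mask; using nearest in-mask voxel")
    pts <- cbind((vox[, 1] - 0.5) * h[1], (vox[, 2] - 0.5) * h[2])
    i <- which.min((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    ctr[1:2] <- pts[i, ]
  }
  step <- 0.25 * min(h[1:2])
  angles <- (0:179) * pi / 180
  lens <- numeric(length(angles))
  chords <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    d <- c(cos(angles[i]), sin(angles[i]), 0)
    ch <- .chord(lg, h, ctr, d, step)
    chords[[i]] <- ch
    lens[i] <- ch$tneg + ch$tpos
  }
  iLA <- which.max(lens)          # ties break to the smallest angle
  mkAxis <- function(i, name) {
    d <- c(cos(angles[i]), sin(angles[i]), 0)
    ch <- chords[[i]]
    pA <- ctr - ch$tneg * d
    pB <- ctr + ch$tpos * d
    ## L end = smallest abscissa (x), tie-break on y
    if (pA[1] > pB[1] || (pA[1] == pB[1] && pA[2] > pB[2])) { tmp <- pA; pA <- pB; pB <- tmp }
    list(name = name, p0 = pA, p1 = pB, length = lens[i])
  }
  axes <- list(LA = mkAxis(iLA, "LA"))
  iSA <- ((iLA - 1 + 90) %% 180) + 1
  if (is.null(chords[[iSA]])) iSA <- which.min(abs(angles - (angles[iLA] + pi / 2) %% pi))
  if (nShortAxes == 1) {
    axes$SA <- mkAxis(iSA, "SA")
  } else {
    axes$SA1 <- mkAxis(iSA, "SA1")
    i45 <- ((iLA - 1 + 45) %% 180) + 1
    axes$SA2 <- mkAxis(i45, "SA2")
    names(axes)[names(axes) == "SA1"] <- "SA1"
  }
  domain@axes <- axes
  domain
}
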