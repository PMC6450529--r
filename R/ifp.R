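## Steady interstitial fluid pressure: finite-volume Darcy solver with
## zone-wise Starling sources, and the derived interstitial velocity field.

#' Effective (equilibrium) filtration pressure
#'
#' The interstitial pressure at which net transvascular filtration stops:
#' \deqn{P_e = P_v - \sigma(\pi_v - \pi_i).}
#' This is the supremum of the achievable interstitial fluid pressure; with
#' the package's calibrated default constants it evaluates to about 1530 Pa.
#'
#' @param vc a \linkS4class{VascularConstants}
#' @return effective pressure (Pa)
#' @examples
#' effectivePressure(VascularConstants())   # ~1531.9 Pa
#' @export
effectivePressure <- function(vc = VascularConstants()) {
  vc@pv - vc@sigmaOsm * (vc@piV - vc@piI)
}

#' Starling transvascular fluid source
#'
#' Filtration rate per unit tissue volume,
#' \code{Fv = LpS/V * (Pe - Pi)} with \code{Pe} the effective filtration
#' pressure; the lymphatic drainage term is identically zero (solid tumors
#' lack functional lymphatics).
#'
#' @param piLocal local interstitial fluid pressure (Pa)
#' @param lpsv Starling coefficient LpS/V (1/(Pa s))
#' @param vc a \linkS4class{VascularConstants}
#' @return fluid source Fv (1/s)
#' @export
starlingSource <- function(piLocal, lpsv, vc = VascularConstants()) {
  if (any(lpsv < 0)) stop("lpsv must be >= 0")
  lpsv * (effectivePressure(vc) - piLocal)
}

## Resolve an lpsv specification to a per-tumor-voxel vector.
## lpsv may be: a scalar; a vector indexed by zone label (lpsv[label]); or a
## 3-D array matching the grid.
.lpsvPerCell <- function(domain, lpsv) {
  lg <- domain@labelGrid
  cells <- which(lg > 0)
  if (is.array(lpsv)) {
    stopifnot(all(dim(lpsv) == dim(lg)))
    val <- lpsv[cells]
  } else if (length(lpsv) == 1) {
    val <- rep(lpsv, length(cells))
  } else {
    val <- lpsv[lg[cells]]
  }
  if (any(is.na(val) | val < 0))
    stop("lpsv must be assigned (>= 0) to every tumor voxel")
  val
}

#' Solve the steady interstitial fluid pressure field
#'
#' Finite-volume solution of
#' \deqn{-K\nabla^2 P_i = L_pS/V\,(P_e - P_i)}
#' on the voxelised tumor domain with a 7-point stencil, Dirichlet
#' \code{Pi = 0} on the enumerated tumor-bath boundary faces (one-sided
#' fluxes through the per-face fractional surface distance \code{theta};
#' \code{theta = 0.5} is the face-centred ghost convention), solved with
#' Jacobi-preconditioned conjugate gradients.
#'
#' @param domain a \linkS4class{TumorDomain}
#' @param lpsv Starling coefficient map: scalar, per-zone-label vector, or
#'   3-D array (1/(Pa s))
#' @param vc a \linkS4class{VascularConstants}
#' @param rtol relative-residual convergence tolerance (default 1e-8; the
#'   residual history is retained so the mandated four-orders-of-magnitude
#'   drop can be verified)
#' @param maxit maximum CG iterations
#' @return a \linkS4class{FieldSolution} with the pressure field and the
#'   residual history
#' @export
solveIfp <- function(domain, lpsv, vc = VascularConstants(), rtol = 1e-8,
                     maxit = 20000L) {
  stopifnot(is(domain, "TumorDomain"))
  lg <- domain@labelGrid
  cells <- which(lg > 0)
  if (!length(cells)) stop("empty domain")
  n <- length(cells)
  id <- array(NA_integer_, dim(lg))
  id[cells] <- seq_len(n)
  hm <- domain@spacing * 1e-3            # mm -> m
  K <- vc@kTissue
  Pe <- effectivePressure(vc)
  lpsvCell <- .lpsvPerCell(domain, lpsv)

  faces <- .enumerateFaces(lg)
  fi <- faces$interior
  bf <- domain@boundaryFaces

  diag0 <- lpsvCell                       # reaction term
  iTrip <- jTrip <- integer(0); xTrip <- numeric(0)
  for (ax in 1:3) {
    w <- K / hm[ax]^2
    sel <- fi$axis == ax
    if (any(sel)) {
      a <- id[fi$a[sel]]; b <- id[fi$b[sel]]
      iTrip <- c(iTrip, a, b); jTrip <- c(jTrip, b, a)
      xTrip <- c(xTrip, rep(-w, 2 * sum(sel)))
      add <- tabulate(c(a, b), nbins = n) * w
      diag0 <- diag0 + add
    }
    selB <- bf$axis == ax
    if (any(selB)) {
      cb <- id[bf$cell[selB]]
      wb <- K / (bf$theta[selB] * hm[ax]^2)
      agg <- rowsum(wb, cb)
      dadd <- numeric(n)
      dadd[as.integer(rownames(agg))] <- agg
      diag0 <- diag0 + dadd
    }
  }
  A <- Matrix::sparseMatrix(i = c(iTrip, seq_len(n)),
                            j = c(jTrip, seq_len(n)),
                            x = c(xTrip, diag0), dims = c(n, n))
  b <- lpsvCell * Pe
  sol <- .cgSolve(A, b, rtol = rtol, maxit = maxit)

  p <- array(NA_real_, dim(lg))
  p[cells] <- sol$x
  new("FieldSolution", domain = domain, pressure = p,
      residualHistory = sol$history)
}

## Face-normal Darcy velocities (+axis convention, m/s).
## Returns list(interior = data.frame(a, b, axis, u),
##              boundary = data.frame(cell, axis, side, theta, u))
## where boundary u is in the +axis convention (outward at side=+1 means
## u > 0; outward at side=-1 means u < 0).
.faceVelocities <- function(sol, vc) {
  domain <- sol@domain
  hm <- domain@spacing * 1e-3
  K <- vc@kTissue
  p <- sol@pressure
  fi <- .enumerateFaces(domain@labelGrid)$interior
  fi$u <- -K * (p[fi$b] - p[fi$a]) / hm[fi$axis]
  bf <- domain@boundaryFaces
  bf$u <- bf$side * K * p[bf$cell] / (bf$theta * hm[bf$axis])
  list(interior = fi, boundary = bf)
}

#' Interstitial fluid velocity from the pressure field
#'
#' Darcy velocity \code{u = -K grad(Pi)}: face-normal velocities are formed
#' from pressure differences (one-sided against the zero-pressure surface at
#' the boundary faces) and averaged per voxel and axis.
#'
#' @param sol a \linkS4class{FieldSolution} with a solved pressure field
#' @param vc the \linkS4class{VascularConstants} used for the solve
#' @return the solution with the \code{velocity} slot filled (list of three
#'   voxel-centred component arrays, m/s)
#' @export
computeVelocity <- function(sol, vc = VascularConstants()) {
  stopifnot(is(sol, "FieldSolution"))
  domain <- sol@domain
  lg <- domain@labelGrid
  dims <- dim(lg)
  fv <- .faceVelocities(sol, vc)
  vel <- lapply(1:3, function(ax) array(NA_real_, dims))
  for (ax in 1:3) {
    num <- array(0, dims); den <- array(0, dims)
    fi <- fv$interior[fv$interior$axis == ax, ]
    if (nrow(fi)) {
      for (cellCol in c("a", "b")) {
        idx <- fi[[cellCol]]
        agg <- tapply(fi$u, idx, sum)
        cnt <- tapply(fi$u, idx, length)
        ii <- as.integer(names(agg))
        num[ii] <- num[ii] + agg
        den[ii] <- den[ii] + cnt
      }
    }
    bf <- fv$boundary[fv$boundary$axis == ax, ]
    if (nrow(bf)) {
      agg <- tapply(bf$u, bf$cell, sum)
      cnt <- tapply(bf$u, bf$cell, length)
      ii <- as.integer(names(agg))
      num[ii] <- num[ii] + agg
      den[ii] <- den[ii] + cnt
    }
    v <- array(NA_real_, dims)
    inside <- lg > 0 & den > 0
    v[inside] <- num[inside] / den[inside]
    vel[[ax]] <- v
  }
  names(vel) <- c("x", "y", "z")
  sol@velocity <- vel
  sol
}
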