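## Internal numerical helpers: grid bookkeeping, Krylov solvers, trilinear
## sampling. None of these are exported.

## Neighbour linear indices on a 3-D grid for a set of cells.
## dims: grid dimensions; cells: linear indices; axis in 1:3; side +1/-1.
## Returns NA where the neighbour falls outside the grid.
.shiftIndex <- function(dims, cells, axis, side) {
  ijk <- arrayInd(cells, dims)
  ijk[, axis] <- ijk[, axis] + side
  bad <- ijk[, axis] < 1 | ijk[, axis] > dims[axis]
  out <- (ijk[, 3] - 1L) * dims[1] * dims[2] + (ijk[, 2] - 1L) * dims[1] + ijk[, 1]
  out[bad] <- NA_integer_
  out
}

## Enumerate interior faces and boundary faces of the region labelGrid > 0.
## Returns list(interior = data.frame(a, b, axis), boundary = data.frame(cell,
## axis, side)). Interior faces are listed once (a < b in grid order).
.enumerateFaces <- function(labelGrid) {
  dims <- dim(labelGrid)
  cells <- which(labelGrid > 0)
  interior <- list(); boundary <- list()
  for (axis in 1:3) {
    for (side in c(1L, -1L)) {
      nb <- .shiftIndex(dims, cells, axis, side)
      nbLab <- rep(0L, length(nb))
      ok <- !is.na(nb)
      nbLab[ok] <- labelGrid[nb[ok]]
      outside <- nbLab == 0L
      boundary[[length(boundary) + 1L]] <-
        data.frame(cell = cells[outside], axis = rep(axis, sum(outside)),
                   side = rep(side, sum(outside)))
      if (side == 1L) {
        keep <- !outside
        interior[[length(interior) + 1L]] <-
          data.frame(a = cells[keep], b = nb[keep],
                     axis = rep(axis, sum(keep)))
      }
    }
  }
  list(interior = do.call(rbind, interior), boundary = do.call(rbind, boundary))
}

## Jacobi-preconditioned conjugate gradients for sparse SPD systems.
## Returns list(x, relres, iterations, history).
.cgSolve <- function(A, b, x0 = NULL, rtol = 1e-8, atol = 1e-12,
                     maxit = 10000L) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("system matrix is not positive definite on the diagonal")
  r <- b - as.numeric(A %*% x)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(n), relres = 0, iterations = 0L,
                              history = numeric()))
  z <- r / d
  p <- z
  rz <- sum(r * z)
  history <- numeric()
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / bnorm
    history[it] <- relres
    if (relres <= rtol || sqrt(sum(r^2)) <= atol)
      return(list(x = x, relres = relres, iterations = it, history = history))
    z <- r / d
    rznew <- sum(r * z)
    p <- z + (rznew / rz) * p
    rz <- rznew
  }
  stop(sprintf("CG failed to converge in %d iterations (relative residual %.3g)",
               maxit, history[length(history)]))
}

## Jacobi-preconditioned BiCGSTAB for sparse nonsymmetric systems.
.bicgstabSolve <- function(A, b, x0 = NULL, rtol = 1e-10, atol = 1e-14,
                           maxit = 10000L) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  d <- Matrix::diag(A)
  r <- b - as.numeric(A %*% x)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(n), relres = 0, iterations = 0L))
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(n)
  for (it in seq_len(maxit)) {
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    phat <- p / d
    v <- as.numeric(A %*% phat)
    alpha <- rho1 / sum(r0 * v)
    s <- r - alpha * v
    if (sqrt(sum(s^2)) / bnorm <= rtol) {
      x <- x + alpha * phat
      return(list(x = x, relres = sqrt(sum(s^2)) / bnorm, iterations = it))
    }
    shat <- s / d
    t <- as.numeric(A %*% shat)
    omega <- sum(t * s) / sum(t * t)
    x <- x + alpha * phat + omega * shat
    r <- s - omega * t
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres <= rtol || sqrt(sum(r^2)) <= atol)
      return(list(x = x, relres = relres, iterations = it))
    rho <- rho1
  }
  stop("BiCGSTAB failed to converge")
}

## Trilinear interpolation of a 3-D array at physical points (mm).
## Voxel centres sit at (index - 0.5) * spacing. Values of NA cells are
## treated as 0 with a weight renormalisation so that probes touching the
## domain edge remain usable.
.trilinear <- function(arr, spacing, pts) {
  dims <- dim(arr)
  g <- sweep(pts, 2, spacing, "/") + 0.5   # continuous index coordinates
  i0 <- floor(g)                            # lower bracketing voxel centre
  f <- g - i0
  out <- numeric(nrow(pts))
  wsum <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- pmin(pmax(i0[, 1] + dx, 1), dims[1])
    jj <- pmin(pmax(i0[, 2] + dy, 1), dims[2])
    kk <- pmin(pmax(i0[, 3] + dz, 1), dims[3])
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    v <- arr[cbind(ii, jj, kk)]
    ok <- !is.na(v)
    out[ok] <- out[ok] + w[ok] * v[ok]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  ifelse(wsum > 1e-12, out / wsum, NA_real_)
}

## Largest 6-connected component of a logical 3-D array, via vectorised
## frontier growth (one dilation per grid-diameter step).
.largestComponent <- function(mask) {
  dims <- dim(mask)
  remaining <- mask
  best <- NULL; bestSize <- 0L; ncomp <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- array(FALSE, dims)
    comp[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nbrs <- integer()
      for (axis in 1:3) for (side in c(1L, -1L)) {
        nb <- .shiftIndex(dims, frontier, axis, side)
        nb <- nb[!is.na(nb)]
        nbrs <- c(nbrs, nb)
      }
      nbrs <- unique(nbrs)
      nbrs <- nbrs[remaining[nbrs] & !comp[nbrs]]
      comp[nbrs] <- TRUE
      frontier <- nbrs
    }
    ncomp <- ncomp + 1L
    sz <- sum(comp)
    if (sz > bestSize) { best <- comp; bestSize <- sz }
    remaining <- remaining & !comp
  }
  list(component = best, n = ncomp)
}
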