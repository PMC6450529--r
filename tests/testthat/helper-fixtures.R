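## Shared fixtures: everything is generated in code at test time.

## DCE frame grid matching the acquisition protocol
dceTimes <- function(n = 550) seq(0, by = 1.344, length.out = n)

## a homogeneous sphere phantom domain
sphereDomain <- function(R, h) {
  makePhantomDomain(PhantomSpec(tumorSemiAxes = rep(R, 3), voxelSpacing = h,
                                interiorSemiAxes = c(0, 0, 0)))$domain
}

## wrap a curve matrix into a TracerCurveSet
curveSet <- function(curves, times) {
  curves <- rbind(curves)
  n <- nrow(curves)
  new("TracerCurveSet", times = times, curves = curves,
      voxelIndex = cbind(seq_len(n), rep(1L, n)),
      roiMask = array(TRUE, c(n, 1)))
}

## closed-form radial pressure solution on a homogeneous sphere:
## P(r) = Pe [1 - (R/r) sinh(alpha r/R)/sinh(alpha)], alpha = R sqrt(lpsv/K)
sphereAnalytic <- function(domain, R, lpsv, vc) {
  lg <- domain@labelGrid
  dims <- dim(lg)
  h <- domain@spacing
  cells <- which(lg > 0)
  ijk <- arrayInd(cells, dims)
  ctr <- dims * h / 2
  r <- sqrt(((ijk[, 1] - 0.5) * h[1] - ctr[1])^2 +
            ((ijk[, 2] - 0.5) * h[2] - ctr[2])^2 +
            ((ijk[, 3] - 0.5) * h[3] - ctr[3])^2)
  K <- vc@kTissue
  Pe <- effectivePressure(vc)
  Rm <- R * 1e-3
  alpha <- Rm * sqrt(lpsv / K)
  rm_ <- pmax(r, 1e-9) * 1e-3
  p <- Pe * (1 - (Rm / rm_) * sinh(alpha * rm_ / Rm) / sinh(alpha))
  p[r < 1e-9] <- Pe * (1 - alpha / sinh(alpha))
  list(cells = cells, r = r, p = p, Pe = Pe, alpha = alpha)
}

## independent combinatorial count of the exposed faces of a voxelised
## sphere of radius R (in voxels): for each axis, a grid column (fixed pair
## of transverse indices) that intersects the ball contributes exactly two
## crossing faces, so the count is 2x the number of lattice columns whose
## transverse distance from the centre is < R (per axis).
sphereFaceOracle <- function(Rvox, dims, ctr) {
  count1 <- function(ax) {
    tr <- setdiff(1:3, ax)
    idx <- expand.grid(a = seq_len(dims[tr[1]]), b = seq_len(dims[tr[2]]))
    d2 <- ((idx$a - 0.5) - ctr[tr[1]])^2 + ((idx$b - 0.5) - ctr[tr[2]])^2
    ## the column holds at least one voxel centre iff some integer offset
    ## k has d2 + (k - ctr)^2 < R^2; voxel centres are at half-integers
    hasVox <- vapply(d2, function(dd) {
      if (dd >= Rvox^2) return(FALSE)
      span <- sqrt(Rvox^2 - dd)
      any(abs((seq_len(dims[ax]) - 0.5) - ctr[ax]) < span)
    }, logical(1))
    2L * sum(hasVox)
  }
  sum(vapply(1:3, count1, integer(1)))
}
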