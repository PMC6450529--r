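## Transient drug transport: implicit (backward-Euler) finite-volume
## advection-diffusion-reaction solver over the therapy window, with a
## per-step discrete mass budget.

#' Solve the transient drug-transport equation
#'
#' Backward-Euler time integration of
#' \deqn{\partial C/\partial t = D\nabla^2 C - \nabla\cdot(uC) - S}
#' on the tumor domain, with central diffusion, first-order upwind advection
#' in conservative form (face velocities derived from the solved pressure
#' field), a lumped first-order sink \code{S = sinkRate * C}, Dirichlet
#' \code{C = cBoundary} on the tumor-bath boundary faces and zero initial
#' concentration. The combination of implicit stepping, upwinding and a
#' non-negative sink makes the scheme bounded: \code{0 <= C <= cBoundary}.
#'
#' Fluid filtered from the vasculature (the Starling source, divergence of
#' the interstitial velocity) carries no drug, so in conservative form it
#' acts as a dilution; no separate advective-loss term is needed.
#'
#' A discrete mass budget (accumulation vs boundary diffusive/advective
#' fluxes and sink losses, all evaluated on the implicit fields) is recorded
#' per step; it closes to the tolerance of the linear solver.
#'
#' @param sol a \linkS4class{FieldSolution} with a solved pressure field
#' @param tp a \linkS4class{TransportParams}
#' @param vc the \linkS4class{VascularConstants} used for the pressure solve
#' @param rtol linear-solver (BiCGSTAB) relative tolerance per step
#' @param verbose print Peclet/CFL diagnostics (default FALSE; they are
#'   always stored as attributes of the mass budget)
#' @return the solution with \code{drug} (tumor voxels x stored times),
#'   \code{drugTimes} and \code{massBudget} filled
#' @export
solveDrugTransport <- function(sol, tp = TransportParams(),
                               vc = VascularConstants(), rtol = 1e-10,
                               verbose = FALSE) {
  stopifnot(is(sol, "FieldSolution"), is(tp, "TransportParams"))
  domain <- sol@domain
  lg <- domain@labelGrid
  cells <- which(lg > 0)
  n <- length(cells)
  id <- array(NA_integer_, dim(lg))
  id[cells] <- seq_len(n)
  hm <- domain@spacing * 1e-3
  vol <- prod(hm)
  D <- tp@diffCoeff
  cB <- tp@cBoundary
  s <- tp@sinkRate
  dt <- tp@dt
  nSteps <- as.integer(round(tp@duration / dt))

  fv <- .faceVelocities(sol, vc)
  fi <- fv$interior
  bf <- fv$boundary

  ## diagnostics: cell Peclet and advective CFL
  pe <- max(abs(c(fi$u, bf$u)) * max(hm) / D)
  cfl <- max(abs(c(fi$u, bf$u))) * dt / min(hm)
  if (verbose)
    message(sprintf("transport: max face Peclet %.3g, advective CFL %.3g, %d steps",
                    pe, cfl, nSteps))

  ## Assemble the per-volume rate operator M so that dc/dt = -M c + q.
  iT <- jT <- integer(0); xT <- numeric(0)
  diag0 <- rep(s, n)
  q <- numeric(n)
  addDiag <- function(idx, w) {
    agg <- rowsum(w, idx)
    dadd <- numeric(n); dadd[as.integer(rownames(agg))] <- agg
    dadd
  }
  for (ax in 1:3) {
    h <- hm[ax]
    sel <- fi$axis == ax
    if (any(sel)) {
      a <- id[fi$a[sel]]; b <- id[fi$b[sel]]; u <- fi$u[sel]
      up <- pmax(u, 0); um <- pmin(u, 0)
      ## diffusion
      w <- D / h^2
      iT <- c(iT, a, b); jT <- c(jT, b, a); xT <- c(xT, rep(-w, 2 * length(a)))
      diag0 <- diag0 + tabulate(c(a, b), nbins = n) * w
      ## upwind advection, conservative: cell a loses u+*ca/h, gains -u-*cb/h
      diag0 <- diag0 + addDiag(a, up / h) + addDiag(b, -um / h)
      iT <- c(iT, a, b); jT <- c(jT, b, a); xT <- c(xT, um / h, -up / h)
    }
    selB <- bf$axis == ax
    if (any(selB)) {
      cb <- id[bf$cell[selB]]
      th <- bf$theta[selB]
      u <- bf$u[selB] * bf$side[selB]      # outward-positive
      up <- pmax(u, 0); um <- pmin(u, 0)
      ## one-sided diffusion against the Dirichlet surface value
      wb <- D / (th * h^2)
      diag0 <- diag0 + addDiag(cb, wb)
      q <- q + { tmp <- numeric(n); agg <- rowsum(wb * cB, cb)
                 tmp[as.integer(rownames(agg))] <- agg; tmp }
      ## advection: outflow carries the cell value, inflow carries cB
      diag0 <- diag0 + addDiag(cb, up / h)
      q <- q + { tmp <- numeric(n); agg <- rowsum(-um * cB / h, cb)
                 tmp[as.integer(rownames(agg))] <- agg; tmp }
    }
  }
  M <- Matrix::sparseMatrix(i = c(iT, seq_len(n)), j = c(jT, seq_len(n)),
                            x = c(xT, diag0), dims = c(n, n))
  A <- M + Matrix::Diagonal(n, 1 / dt)

  conc <- matrix(0, n, nSteps + 1)
  budget <- data.frame(step = seq_len(nSteps), time = dt * seq_len(nSteps),
                       accumulation = NA_real_, influx = NA_real_,
                       outflux = NA_real_, sink = NA_real_,
                       closure = NA_real_, cBoundary = cB)
  cOld <- numeric(n)
  ## boundary bookkeeping vectors for the budget
  bOut <- pmax(bf$u * bf$side, 0) / hm[bf$axis]   # 1/s per cell contribution
  bIn  <- -pmin(bf$u * bf$side, 0) / hm[bf$axis]
  bDiffW <- D / (bf$theta * hm[bf$axis]^2)
  bCell <- id[bf$cell]
  for (k in seq_len(nSteps)) {
    rhs <- cOld / dt + q
    res <- .bicgstabSolve(A, rhs, x0 = cOld, rtol = rtol)
    cNew <- res$x
    if (min(cNew) < -1e-12)
      stop(sprintf("scheme violation: negative concentration %.3g at step %d",
                   min(cNew), k))
    acc <- sum(cNew - cOld) * vol
    diffFlux <- sum(bDiffW * (cB - cNew[bCell])) * vol
    advIn <- sum(bIn * cB) * vol
    advOut <- sum(bOut * cNew[bCell]) * vol
    sink <- sum(s * cNew) * vol
    influx <- (diffFlux + advIn) * dt
    outflux <- advOut * dt
    closure <- abs(acc - influx + outflux + sink * dt) /
      max(influx, outflux + sink * dt, 1e-300)
    budget[k, c("accumulation", "influx", "outflux", "sink", "closure")] <-
      c(acc, influx, outflux, sink * dt, closure)
    conc[, k + 1] <- cNew
    cOld <- cNew
  }
  attr(budget, "maxPeclet") <- pe
  attr(budget, "advectiveCfl") <- cfl
  sol@drug <- conc
  sol@drugTimes <- dt * (0:nSteps)
  sol@massBudget <- budget
  sol
}

#' Check the imposed surface drug concentration of a transport solution
#'
#' Verifies that the Dirichlet surface value applied at every stored step
#' equals the expected instillate concentration and that no stored field
#' exceeds it (discrete maximum principle).
#'
#' @param sol a solved \linkS4class{FieldSolution}
#' @param expected expected surface concentration (mol/m^3, default the
#'   0.113 instillate value)
#' @param tol comparison tolerance
#' @return list with \code{pass} (logical), \code{message}, and
#'   \code{badSteps} (indices of offending steps, if any)
#' @export
checkBoundaryCondition <- function(sol, expected = 0.113, tol = 1e-12) {
  stopifnot(is(sol, "FieldSolution"))
  if (!nrow(sol@massBudget)) stop("no transport solution stored")
  bad <- which(abs(sol@massBudget$cBoundary - expected) > tol)
  over <- which(apply(sol@drug, 2, max) > sol@massBudget$cBoundary[1] * (1 + 1e-10))
  if (length(bad))
    return(list(pass = FALSE, badSteps = bad,
                message = sprintf("boundary value %.4g differs from expected %.4g at %d step(s)",
                                  sol@massBudget$cBoundary[bad[1]], expected,
                                  length(bad))))
  if (length(over))
    return(list(pass = FALSE, badSteps = over,
                message = "stored field exceeds the surface concentration"))
  list(pass = TRUE, badSteps = integer(),
       message = sprintf("surface concentration %.4g mol/m^3 maintained at all %d steps",
                         expected, nrow(sol@massBudget)))
}
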