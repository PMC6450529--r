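## Reported pressure and penetration metrics: axis profiles, LP50, absolute
## and relative penetration depth, penetrated volume fraction, unit
## conversion, and the solid-stress residual arithmetic.

#' Sample a field along a probing axis
#'
#' Trilinear sampling of a voxel field at \code{n} evenly spaced points
#' along an axis, from its L end (smallest abscissa) to its R end. The
#' returned profile carries both the normalised coordinate (0 to 1) and the
#' physical distance from the L end in mm.
#'
#' @param field 3-D array (NA outside the domain)
#' @param domain the \linkS4class{TumorDomain} the field lives on
#' @param axis one axis entry of \code{probeAxes(domain)}, or its name
#' @param n number of samples (>= 200)
#' @return data.frame with columns \code{s} (normalised), \code{x} (mm from
#'   the L end) and \code{value}
#' @export
extractProfile <- function(field, domain, axis, n = 201) {
  stopifnot(is(domain, "TumorDomain"))
  if (is.character(axis)) {
    if (is.null(domain@axes[[axis]])) stop("axis '", axis, "' not defined")
    axis <- domain@axes[[axis]]
  }
  n <- max(n, 200)
  s <- seq(0, 1, length.out = n)
  pts <- cbind(axis$p0[1] + s * (axis$p1[1] - axis$p0[1]),
               axis$p0[2] + s * (axis$p1[2] - axis$p0[2]),
               axis$p0[3] + s * (axis$p1[3] - axis$p0[3]))
  v <- .trilinear(field, domain@spacing, pts)
  if (all(is.na(v))) stop("axis lies outside the field")
  data.frame(s = s, x = s * axis$length, value = v)
}

#' Pressure-profile steepness: LP50
#'
#' Distance from each tumor edge (L and R end of the axis) at which the
#' pressure first reaches 50\% of the profile maximum, by linear
#' interpolation between samples; reported in mm.
#'
#' @param profile a profile data.frame from \code{\link{extractProfile}}
#' @return named numeric \code{c(L = , R = )} in mm; NA when the profile
#'   maximum is not positive
#' @export
computeLp50 <- function(profile) {
  v <- profile$value
  x <- profile$x
  pmaxv <- max(v, na.rm = TRUE)
  if (!is.finite(pmaxv) || pmaxv <= 0) return(c(L = NA_real_, R = NA_real_))
  half <- 0.5 * pmaxv
  crossFrom <- function(ord) {
    vv <- v[ord]; xx <- x[ord]
    i <- which(vv >= half)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(0)
    x0 <- xx[i - 1]; x1 <- xx[i]
    f <- (half - vv[i - 1]) / (vv[i] - vv[i - 1])
    abs(x0 + f * (x1 - x0) - xx[1])
  }
  c(L = crossFrom(seq_along(v)), R = crossFrom(rev(seq_along(v))))
}

#' Drug penetration along an axis: APD and PD\%
#'
#' Per side of the axis: the absolute penetration depth (APD) is the depth
#' of the contiguous boundary-attached segment where the concentration is
#' at least the IC50 (measured from that edge, in mm, with linear
#' interpolation of the crossing); the relative penetration PD\% is the
#' percentage of the total axis length on that side of the midpoint where
#' the concentration is at least the IC50.
#'
#' @param profile a concentration profile from \code{\link{extractProfile}}
#' @param ic50 threshold concentration (mol/m^3)
#' @return data.frame with one row per side (L, R) and columns \code{apd}
#'   (mm) and \code{pdPct} (\%)
#' @export
computePenetration <- function(profile, ic50) {
  if (ic50 <= 0) stop("ic50 must be > 0")
  v <- profile$value
  x <- profile$x
  L <- max(x)
  oneSide <- function(ord) {
    vv <- v[ord]; xx <- abs(x[ord] - x[ord][1])
    above <- !is.na(vv) & vv >= ic50
    if (!above[1]) apd <- 0
    else {
      iEnd <- which(!above)[1]        # first sample below threshold
      if (is.na(iEnd)) apd <- xx[length(xx)]
      else {
        f <- (vv[iEnd - 1] - ic50) / (vv[iEnd - 1] - vv[iEnd])
        apd <- xx[iEnd - 1] + f * (xx[iEnd] - xx[iEnd - 1])
      }
    }
    half <- xx <= L / 2
    pd <- 100 * sum(above & half) / length(xx)
    c(apd = apd, pdPct = pd)
  }
  resL <- oneSide(seq_along(v))
  resR <- oneSide(rev(seq_along(v)))
  data.frame(side = c("L", "R"), apd = c(resL["apd"], resR["apd"]),
             pdPct = c(resL["pdPct"], resR["pdPct"]), row.names = NULL)
}

#' Penetrated tumor volume fraction
#'
#' Percentage of tumor voxels whose drug concentration at the requested
#' stored time (default: end of therapy) is at least the IC50.
#'
#' @param sol a solved \linkS4class{FieldSolution}
#' @param ic50 threshold concentration (mol/m^3)
#' @param time stored time to evaluate (s); default final
#' @return percentage in [0, 100]
#' @export
computePvol <- function(sol, ic50, time = NULL) {
  stopifnot(is(sol, "FieldSolution"))
  if (!ncol(sol@drug)) stop("no drug field stored")
  j <- if (is.null(time)) ncol(sol@drug) else which.min(abs(sol@drugTimes - time))
  100 * mean(sol@drug[, j] >= ic50)
}

#' Convert mmHg to Pa
#'
#' Multiplies by 133.322 Pa/mmHg and rounds to integer pascal for
#' reporting.
#'
#' @param p pressure in mmHg
#' @return pressure in Pa (integer-rounded)
#' @examples
#' mmHgToPa(19)  # 2533
#' @export
mmHgToPa <- function(p) round(p * 133.322)

#' Solid-stress residual
#'
#' Difference between the invasively measured total tumor pressure and the
#' simulated maximal interstitial fluid pressure; under the assumption that
#' the measured total stress is the sum of fluid and solid components, this
#' residual estimates the solid-state (matrix) pressure.
#'
#' @param pmeas measured total pressure (Pa)
#' @param pmaxSim simulated maximal IFP (Pa)
#' @return residual pressure (Pa); negative values are allowed with a
#'   warning
#' @export
solidStressResidual <- function(pmeas, pmaxSim) {
  if (any(pmeas < 0) || any(pmaxSim < 0)) stop("pressures must be >= 0")
  r <- pmeas - pmaxSim
  if (any(r < 0))
    warning("measured pressure below simulated IFP: negative solid-stress residual")
  r
}
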