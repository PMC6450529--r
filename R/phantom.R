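## Synthetic phantom generation: ellipsoidal tumors with a ground-truth
## vascular map, analytic AIFs, forward-simulated tracer curves and raw
## SPGR signal series. Every downstream stage has a recovery test against
## these known truths.

#' Build a voxelised phantom tumor domain with ground-truth vascular map
#'
#' Voxelises the ellipsoidal tumor described by a \linkS4class{PhantomSpec}
#' on a regular grid (voxel centres at \code{(index - 0.5) * spacing}),
#' labels the viable shell (1) and the interior zone (2), enumerates the
#' tumor-bath boundary faces, and attaches exact per-face fractional
#' distances from each boundary voxel centre to the analytic ellipsoid
#' surface (used by the pressure/transport stencils for sub-voxel boundary
#' placement).
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return list with elements \code{domain} (a \linkS4class{TumorDomain})
#'   and \code{truth} (a \linkS4class{VascularMap} holding the per-voxel
#'   ground-truth kinetics and zone labels)
#' @examples
#' ph <- makePhantomDomain(PhantomSpec(tumorSemiAxes = c(2, 2, 2),
#'                                     voxelSpacing = 0.25,
#'                                     interiorSemiAxes = c(0, 0, 0)))
#' tumorVolume(ph$domain)   # close to 4/3*pi*8
#' @export
makePhantomDomain <- function(spec) {
  validObject(spec)
  a <- spec@tumorSemiAxes
  h <- spec@voxelSpacing
  margin <- 2 * h
  dims <- as.integer(ceiling(2 * (a + margin) / h))
  centre <- dims * h / 2
  ax <- (seq_len(dims[1]) - 0.5) * h[1] - centre[1]
  ay <- (seq_len(dims[2]) - 0.5) * h[2] - centre[2]
  az <- (seq_len(dims[3]) - 0.5) * h[3] - centre[3]
  qx <- (ax / a[1])^2
  qy <- (ay / a[2])^2
  qz <- (az / a[3])^2
  q <- outer(outer(qx, qy, "+"), qz, "+")
  label <- array(0L, dims)
  label[q < 1] <- 1L
  if (!sum(label)) stop("phantom tumor contains no voxels at this spacing")

  hasInterior <- all(spec@interiorSemiAxes > 0)
  if (hasInterior) {
    ai <- spec@interiorSemiAxes
    off <- spec@interiorOffset
    qi <- outer(outer(((ax - off[1]) / ai[1])^2, ((ay - off[2]) / ai[2])^2, "+"),
                ((az - off[3]) / ai[3])^2, "+")
    label[qi < 1 & label > 0] <- 2L
  }

  faces <- .enumerateFaces(label)$boundary
  ## exact centre-to-surface distance along each boundary face direction
  ijk <- arrayInd(faces$cell, dims)
  pos <- cbind(ax[ijk[, 1]], ay[ijk[, 2]], az[ijk[, 3]])
  rest <- sweep(pos, 2, a, "/")^2
  theta <- numeric(nrow(faces))
  for (axis in 1:3) {
    sel <- faces$axis == axis
    if (!any(sel)) next
    r2 <- rowSums(rest[sel, -axis, drop = FALSE])
    w <- a[axis] * sqrt(pmax(1 - r2, 0))
    t <- w - faces$side[sel] * pos[sel, axis]
    theta[sel] <- pmin(pmax(t / h[axis], 0.05), 1)
  }
  faces$theta <- theta

  domain <- new("TumorDomain", labelGrid = label, spacing = h,
                boundaryFaces = faces, axes = list(),
                truth = spec@truthKinetics)

  vox <- arrayInd(which(label > 0), dims)
  lab <- label[label > 0]
  zoneName <- ifelse(lab == 1L, "viable",
                     ifelse(spec@interiorPhenotype == "necrotic",
                            "necrotic", "hypoxic"))
  kin <- ifelse(lab == 1L, "viable", "interior")
  getp <- function(field) vapply(kin, function(z) spec@truthKinetics[[z]][[field]],
                                 numeric(1), USE.NAMES = FALSE)
  truth <- new("VascularMap", voxelIndex = vox,
               phi = getp("phi"), psv = getp("psv"), jvv = getp("jvv"),
               r2 = rep(1, length(lab)), zone = zoneName,
               lpsv = numeric(length(lab)))
  list(domain = domain, truth = truth)
}

#' Evaluate a bi-exponential arterial input function
#'
#' Plasma tracer concentration: zero before the bolus arrival and
#' \code{amp1*exp(-rate1*tau) + amp2*exp(-rate2*tau)} with
#' \code{tau = t - bolusArrival} afterwards.
#'
#' @param params an \linkS4class{AifParams}
#' @param times sample times (s), sorted ascending
#' @return plasma concentration at \code{times} (mM)
#' @examples
#' sampleAif(AifParams(amp1 = 1, rate1 = 0.01, amp2 = 0, bolusArrival = 0),
#'           times = 100)  # exp(-1)
#' @export
sampleAif <- function(params, times) {
  stopifnot(is(params, "AifParams"))
  if (is.unsorted(times)) stop("times must be sorted ascending")
  tau <- times - params@bolusArrival
  ifelse(tau < 0, 0,
         params@amp1 * exp(-params@rate1 * tau) +
         params@amp2 * exp(-params@rate2 * tau))
}

#' Forward-simulate an interstitial tracer curve (numerical integration)
#'
#' Integrates the two-compartment exchange model
#' \deqn{\phi\, dc/dt = PS/V\,(c_{AIF} - c) + J_v/V\,(1-\sigma)\,c_{AIF}}
#' with \code{c(0) = 0} using a stiff ODE integrator. This is the phantom
#' generator's forward model; it is numerically independent of the
#' closed-form solution used by the fitting stage
#' (\code{\link{solveTwoCompartment}}), so the two can cross-validate each
#' other.
#'
#' @param kin list with \code{phi}, \code{psv}, \code{jvv} (fraction, 1/s,
#'   1/s)
#' @param aif an \linkS4class{AifParams}
#' @param times sample times (s)
#' @param sigma tracer reflection coefficient (default 0)
#' @return interstitial tracer concentration at \code{times} (mM)
#' @export
simulateTracerCurve <- function(kin, aif, times, sigma = 0) {
  if (kin$phi <= 0) stop("phi must be > 0")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  t0 <- aif@bolusArrival
  out <- numeric(length(times))
  post <- times > t0
  if (!any(post)) return(out)
  tt <- c(t0, times[post])
  rhs <- function(t, y, p) {
    ca <- aif@amp1 * exp(-aif@rate1 * (t - t0)) +
          aif@amp2 * exp(-aif@rate2 * (t - t0))
    list((kin$psv * (ca - y[1]) + kin$jvv * (1 - sigma) * ca) / kin$phi)
  }
  sol <- deSolve::lsoda(y = 0, times = tt, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out[post] <- sol[-1, 2]
  out
}

## SPGR steady-state signal (internal forward model, shared by rendering
## and by the inversion's round-trip documentation).
.spgrSignal <- function(conc, t10, acq, scale = 1) {
  e1 <- exp(-acq@tr * (1 / t10 + acq@r1 * conc))
  al <- acq@flipAngle * pi / 180
  scale * sin(al) * (1 - e1) / (1 - e1 * cos(al))
}

#' Render a raw DCE signal series from tracer curves
#'
#' Applies the spoiled gradient-echo steady-state signal equation
#' \deqn{S = S_p \sin\alpha\,(1 - E_1)/(1 - E_1\cos\alpha),\qquad
#'       E_1 = e^{-TR\,(1/T_{10} + r_1 c)}}
#' (T2* decay neglected) to each concentration curve, with optional noise.
#' Pre-bolus frames carry the native baseline signal because the generated
#' curves are zero there.
#'
#' @param curves a \linkS4class{TracerCurveSet} of tracer concentration
#' @param acq an \linkS4class{AcquisitionParams}; flip angle must be in
#'   (0, 90] degrees for the dynamic series
#' @param t10Map native T1 per voxel (s): scalar or vector of
#'   \code{nrow(curves)}
#' @param scale proportionality constant of the signal (arbitrary units)
#' @param noiseSd additive Gaussian noise sd (signal units)
#' @param rician if TRUE, apply Rician magnitude noise
#'   (\code{sqrt((S+n1)^2+n2^2)}) instead of additive Gaussian
#' @param seed integer seed used when noise is added
#' @return matrix of signal, same shape as \code{curves@curves}
#' @export
renderSignalSeries <- function(curves, acq, t10Map, scale = 1000,
                               noiseSd = 0, rician = FALSE, seed = 1L) {
  stopifnot(is(curves, "TracerCurveSet"), is(acq, "AcquisitionParams"))
  if (acq@flipAngle <= 0 || acq@flipAngle > 90)
    stop("flip angle must be in (0, 90] degrees for the DCE forward model")
  if (acq@r1 <= 0) stop("r1 must be > 0")
  n <- nrow(curves@curves)
  t10 <- rep_len(t10Map, n)
  sig <- .spgrSignal(curves@curves, t10, acq, scale)
  if (noiseSd > 0) {
    set.seed(seed)
    if (rician) {
      n1 <- matrix(rnorm(length(sig), 0, noiseSd), nrow = n)
      n2 <- matrix(rnorm(length(sig), 0, noiseSd), nrow = n)
      sig <- sqrt((sig + n1)^2 + n2^2)
    } else {
      sig <- sig + matrix(rnorm(length(sig), 0, noiseSd), nrow = n)
    }
  }
  sig
}

#' Render a multi-TR saturation-recovery image stack for T1 mapping
#'
#' Saturation-recovery intensities \code{A*(1 - exp(-TR/T10))} per voxel
#' over a set of repetition times, emulating the variable-TR FLASH
#' acquisition used for native T1 mapping.
#'
#' @param t10Map native T1 per voxel (s)
#' @param trList repetition times (s); at least 3 distinct values
#' @param amplitude equilibrium signal amplitude A
#' @param noiseSd additive Gaussian noise sd; 0 for noiseless
#' @param seed noise seed
#' @return matrix, voxels x TR values
#' @export
renderMultiTrImages <- function(t10Map, trList = c(0.1, 0.502, 1.184, 5),
                                amplitude = 1000, noiseSd = 0, seed = 1L) {
  if (anyDuplicated(trList)) stop("duplicate TR values are not allowed")
  if (length(trList) < 3) stop("at least 3 distinct TR values are required")
  sig <- amplitude * (1 - exp(-outer(1 / t10Map, trList)))
  if (noiseSd > 0) {
    set.seed(seed)
    sig <- sig + matrix(rnorm(length(sig), 0, noiseSd), nrow = length(t10Map))
  }
  sig
}

#' Generate a complete synthetic DCE study on a phantom slice
#'
#' Convenience generator used by the end-to-end pipeline and tests: takes the
#' mid-tumor axial plane of a phantom, forward-simulates the per-zone tracer
#' curves (numerical ODE), renders the raw SPGR signal series and the
#' multi-TR T1-mapping stack, and returns everything a real study would
#' provide, together with the ground truth.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param acq an \linkS4class{AcquisitionParams}
#' @param aif an \linkS4class{AifParams}
#' @param nFrames number of dynamic frames (default 550)
#' @param planeIndex axial plane of the DCE slice (default: mid-tumor)
#' @return list with \code{domain}, \code{truth} (3-D, see
#'   \code{\link{makePhantomDomain}}), and the slice-level study:
#'   \code{times}, \code{signals}, \code{roiMask}, \code{voxelIndex},
#'   \code{t10Truth}, \code{multiTr}, \code{trList}, \code{sliceTruth}
#'   (per-voxel kinetics on the slice), \code{planeIndex}
#' @export
phantomDceStudy <- function(spec, acq = AcquisitionParams(),
                            aif = AifParams(), nFrames = 550,
                            planeIndex = NULL) {
  ph <- makePhantomDomain(spec)
  label <- ph$domain@labelGrid
  if (is.null(planeIndex)) planeIndex <- round(dim(label)[3] / 2)
  slice <- label[, , planeIndex]
  if (!any(slice > 0)) stop("DCE plane does not intersect the tumor")
  vox <- which(slice > 0, arr.ind = TRUE)
  lab <- slice[slice > 0]
  times <- seq(0, by = acq@frameInterval, length.out = nFrames)

  kinName <- ifelse(lab == 1L, "viable", "interior")
  zones <- unique(kinName)
  zoneCurve <- lapply(zones, function(z)
    simulateTracerCurve(spec@truthKinetics[[z]], aif, times))
  names(zoneCurve) <- zones
  curves <- do.call(rbind, zoneCurve[kinName])

  t10Name <- ifelse(lab == 1L, "viable", "interior")
  t10 <- unname(spec@t10[t10Name])

  roi <- slice > 0
  tcs <- new("TracerCurveSet", times = times, curves = curves,
             voxelIndex = vox, roiMask = array(roi, dim(roi)))
  signals <- renderSignalSeries(tcs, acq, t10, noiseSd = spec@noiseSd,
                                rician = spec@rician, seed = spec@seed)
  multiTr <- renderMultiTrImages(t10, noiseSd = spec@noiseSd,
                                 seed = spec@seed + 1L)

  zoneName <- ifelse(lab == 1L, "viable",
                     ifelse(spec@interiorPhenotype == "necrotic",
                            "necrotic", "hypoxic"))
  getp <- function(field) vapply(kinName, function(z)
    spec@truthKinetics[[z]][[field]], numeric(1), USE.NAMES = FALSE)
  sliceTruth <- data.frame(phi = getp("phi"), psv = getp("psv"),
                           jvv = getp("jvv"), zone = zoneName)

  ## candidate blood voxels for AIF extraction: whole-blood concentration
  ## is (1 - Hct) times the plasma AIF
  t10Blood <- 1.4
  cb <- (1 - aif@hematocrit) * sampleAif(aif, times)
  aifSignals <- .spgrSignal(matrix(cb, nrow = 5, ncol = length(times),
                                   byrow = TRUE), t10Blood, acq, 1000)
  if (spec@noiseSd > 0) {
    set.seed(spec@seed + 2L)
    aifSignals <- aifSignals +
      matrix(rnorm(length(aifSignals), 0, spec@noiseSd),
             nrow = nrow(aifSignals))
  }

  list(domain = ph$domain, truth = ph$truth, times = times,
       signals = signals, curves = tcs, roiMask = roi, voxelIndex = vox,
       t10Truth = t10, multiTr = multiTr, trList = c(0.1, 0.502, 1.184, 5),
       sliceTruth = sliceTruth, planeIndex = planeIndex,
       aifSignals = aifSignals, t10Blood = t10Blood)
}
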