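## User-facing constructors and small accessors.

#' @rdname AcquisitionParams-class
#' @param tr,te repetition and echo time (s)
#' @param flipAngle flip angle (degrees)
#' @param r1 contrast-agent relaxivity (1/(mM s))
#' @param baselineWindow pre-contrast baseline duration (s)
#' @param frameInterval temporal resolution (s)
#' @return an \linkS4class{AcquisitionParams} object
#' @examples
#' AcquisitionParams()           # the default DCE protocol
#' AcquisitionParams(tr = 0.015)
#' @export
AcquisitionParams <- function(tr = 0.012, te = 0.0034, flipAngle = 25,
                              r1 = 3.5, baselineWindow = 60,
                              frameInterval = 1.344) {
  new("AcquisitionParams", tr = tr, te = te, flipAngle = flipAngle, r1 = r1,
      baselineWindow = baselineWindow, frameInterval = frameInterval)
}

#' @rdname AifParams-class
#' @param amp1,amp2 amplitudes (mM)
#' @param rate1,rate2 decay rates (1/s)
#' @param bolusArrival bolus arrival time (s)
#' @param hematocrit hematocrit fraction
#' @param r2fit optional fit quality
#' @return an \linkS4class{AifParams} object
#' @export
AifParams <- function(amp1 = 0.8, amp2 = 0.2, rate1 = 0.02, rate2 = 0.002,
                      bolusArrival = 60, hematocrit = 0.45, r2fit = NA_real_) {
  if (amp1 < 0 || amp2 < 0)
    warning("negative AIF amplitude: allowed for fit flexibility, not for generation")
  new("AifParams", amp1 = amp1, amp2 = amp2, rate1 = rate1, rate2 = rate2,
      bolusArrival = bolusArrival, hematocrit = hematocrit, r2fit = r2fit)
}

#' @rdname VascularConstants-class
#' @param pv microvascular pressure (Pa)
#' @param sigmaOsm osmotic reflection coefficient
#' @param piV,piI vascular and interstitial osmotic pressure (Pa)
#' @param kTissue tissue hydraulic conductivity (m^2/(Pa s))
#' @return a \linkS4class{VascularConstants} object
#' @export
VascularConstants <- function(pv = 2078, sigmaOsm = 0.82, piV = 2666,
                              piI = 2000, kTissue = 3.1e-14) {
  new("VascularConstants", pv = pv, sigmaOsm = sigmaOsm, piV = piV, piI = piI,
      kTissue = kTissue)
}

#' @rdname TransportParams-class
#' @param diffCoeff drug diffusivity (m^2/s)
#' @param cBoundary surface drug concentration (mol/m^3)
#' @param duration therapy duration (s)
#' @param dt solver time step (s)
#' @param sinkRate first-order loss rate (1/s)
#' @param ic50 half-maximal inhibitory concentration (mol/m^3)
#' @return a \linkS4class{TransportParams} object
#' @export
TransportParams <- function(diffCoeff = 3e-10, cBoundary = 0.113,
                            duration = 1800, dt = 30, sinkRate = 1e-4,
                            ic50 = 5e-3) {
  new("TransportParams", diffCoeff = diffCoeff, cBoundary = cBoundary,
      duration = duration, dt = dt, sinkRate = sinkRate, ic50 = ic50)
}

#' @rdname PhantomSpec-class
#' @param tumorSemiAxes,voxelSpacing,interiorOffset,interiorSemiAxes see slots
#' @param interiorPhenotype "hypoxic" or "necrotic"
#' @param truthKinetics per-zone ground-truth kinetics
#' @param t10 per-zone native T1 (s)
#' @param noiseSd signal noise sd
#' @param rician use Rician magnitude noise instead of additive Gaussian
#' @param seed integer noise seed
#' @return a \linkS4class{PhantomSpec} object
#' @export
PhantomSpec <- function(tumorSemiAxes = c(3, 2.5, 2),
                        voxelSpacing = c(0.1, 0.1, 0.1),
                        interiorOffset = c(0.6, 0.3, 0),
                        interiorSemiAxes = c(1.2, 1, 0.8),
                        interiorPhenotype = "necrotic",
                        truthKinetics = NULL,
                        t10 = c(viable = 1.8, interior = 2.2),
                        noiseSd = 0, rician = FALSE, seed = 1L) {
  if (is.null(truthKinetics)) {
    truthKinetics <- list(
      viable = list(phi = 0.30, psv = 2e-3, jvv = 1e-4),
      interior = if (interiorPhenotype == "necrotic")
        list(phi = 0.40, psv = 0, jvv = 2e-5)
      else list(phi = 0.30, psv = 5e-4, jvv = 2e-5))
  }
  if (length(voxelSpacing) == 1) voxelSpacing <- rep(voxelSpacing, 3)
  new("PhantomSpec", tumorSemiAxes = tumorSemiAxes,
      voxelSpacing = voxelSpacing, interiorOffset = interiorOffset,
      interiorSemiAxes = interiorSemiAxes,
      interiorPhenotype = interiorPhenotype, truthKinetics = truthKinetics,
      t10 = t10, noiseSd = noiseSd, rician = rician, seed = as.integer(seed))
}

## ---- accessors -----------------------------------------------------------

#' Tumor volume of a domain
#'
#' Reconstructed volume, i.e. the number of tumor voxels times the voxel
#' volume.
#' @param domain a \linkS4class{TumorDomain}
#' @param label optional zone label; default all tumor voxels
#' @return volume in mm^3
#' @export
tumorVolume <- function(domain, label = NULL) {
  stopifnot(is(domain, "TumorDomain"))
  n <- if (is.null(label)) sum(domain@labelGrid > 0)
       else sum(domain@labelGrid == label)
  n * prod(domain@spacing)
}

#' Zone labels of a vascular map
#' @param map a \linkS4class{VascularMap}
#' @return character vector of per-voxel zone labels
#' @export
zoneLabels <- function(map) {
  stopifnot(is(map, "VascularMap"))
  map@zone
}

#' Pressure field of a solution
#' @param sol a \linkS4class{FieldSolution}
#' @return 3-D array of pressure (Pa), NA outside the tumor
#' @export
pressureField <- function(sol) {
  stopifnot(is(sol, "FieldSolution"))
  sol@pressure
}

#' Drug concentration field at a stored time
#' @param sol a \linkS4class{FieldSolution}
#' @param time requested time (s); the closest stored time is used. Default:
#'   final stored time.
#' @return 3-D array of drug concentration (mol/m^3), NA outside the tumor
#' @export
drugField <- function(sol, time = NULL) {
  stopifnot(is(sol, "FieldSolution"))
  if (!ncol(sol@drug)) stop("no drug fields stored in this solution")
  j <- if (is.null(time)) ncol(sol@drug)
       else which.min(abs(sol@drugTimes - time))
  arr <- array(NA_real_, dim(sol@domain@labelGrid))
  arr[sol@domain@labelGrid > 0] <- sol@drug[, j]
  arr
}

#' Probing axes of a domain
#' @param domain a \linkS4class{TumorDomain}
#' @return list of axes (name, endpoints in mm, length)
#' @export
probeAxes <- function(domain) {
  stopifnot(is(domain, "TumorDomain"))
  domain@axes
}
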