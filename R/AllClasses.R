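#' @import methods
#' @importFrom stats approx coef cor lm median nls optim optimize predict
#'   quantile rnorm runif runmed sd setNames
#' @importFrom utils head tail write.csv
NULL

## ---------------------------------------------------------------------------
## Parameter-set classes
## ---------------------------------------------------------------------------

#' Acquisition parameters of the dynamic contrast-enhanced series
#'
#' Scanner and sequence constants governing the conversion between spoiled
#' gradient-echo (SPGR/FLASH) signal and gadolinium concentration: repetition
#' time, echo time, flip angle, contrast-agent relaxivity, the length of the
#' pre-bolus baseline window and the frame interval of the dynamic series.
#'
#' @slot tr repetition time (s)
#' @slot te echo time (s); T2* decay is neglected in the signal model, the
#'   echo time is retained for provenance only
#' @slot flipAngle flip angle (degrees)
#' @slot r1 longitudinal relaxivity of the contrast agent (1/(mM s))
#' @slot baselineWindow duration of pre-contrast baseline signal (s)
#' @slot frameInterval temporal resolution of the dynamic series (s)
#' @export
setClass("AcquisitionParams",
  representation(tr = "numeric", te = "numeric", flipAngle = "numeric",
                 r1 = "numeric", baselineWindow = "numeric",
                 frameInterval = "numeric"),
  prototype(tr = 0.012, te = 0.0034, flipAngle = 25, r1 = 3.5,
            baselineWindow = 60, frameInterval = 1.344))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@tr <= 0) msg <- c(msg, "tr must be > 0")
  if (object@flipAngle <= 0 || object@flipAngle > 180)
    msg <- c(msg, "flipAngle must be in (0, 180] degrees")
  if (object@r1 <= 0) msg <- c(msg, "r1 must be > 0")
  if (object@baselineWindow < object@frameInterval)
    msg <- c(msg, "baselineWindow must cover at least one frame interval")
  if (length(msg)) msg else TRUE
})

#' Bi-exponential arterial input function parameters
#'
#' Analytic form of the plasma tracer concentration: zero before the bolus
#' arrival, \code{amp1*exp(-rate1*tau) + amp2*exp(-rate2*tau)} afterwards with
#' \code{tau = t - bolusArrival}. The hematocrit is carried so that
#' whole-blood concentrations can be rescaled to plasma.
#'
#' @slot amp1,amp2 amplitudes of the fast and slow component (mM)
#' @slot rate1,rate2 decay rates (1/s)
#' @slot bolusArrival bolus arrival time (s)
#' @slot hematocrit hematocrit fraction in [0, 1)
#' @slot r2fit goodness of fit when the object results from a tail fit
#'   (NA for manually specified parameters)
#' @export
setClass("AifParams",
  representation(amp1 = "numeric", amp2 = "numeric", rate1 = "numeric",
                 rate2 = "numeric", bolusArrival = "numeric",
                 hematocrit = "numeric", r2fit = "numeric"),
  prototype(amp1 = 0.8, amp2 = 0.2, rate1 = 0.02, rate2 = 0.002,
            bolusArrival = 60, hematocrit = 0.45, r2fit = NA_real_))

setValidity("AifParams", function(object) {
  msg <- character()
  if (object@rate1 <= 0 || object@rate2 <= 0) msg <- c(msg, "rates must be > 0")
  if (object@hematocrit < 0 || object@hematocrit >= 1)
    msg <- c(msg, "hematocrit must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Vascular and osmotic constants of the Starling source
#'
#' Constants of the transvascular filtration term
#' \code{Fv = LpS/V * (Pv - Pi - sigma*(piV - piI))} and the Darcy hydraulic
#' conductivity of the interstitium. Defaults are the package's calibrated
#' baseline set under which the zero-filtration equilibrium pressure is
#' approximately 1530 Pa.
#'
#' @slot pv microvascular pressure (Pa)
#' @slot sigmaOsm osmotic reflection coefficient for plasma proteins
#'   (dimensionless)
#' @slot piV vascular (plasma) osmotic pressure (Pa)
#' @slot piI interstitial osmotic pressure (Pa)
#' @slot kTissue hydraulic conductivity of the tissue (m^2/(Pa s))
#' @export
setClass("VascularConstants",
  representation(pv = "numeric", sigmaOsm = "numeric", piV = "numeric",
                 piI = "numeric", kTissue = "numeric"),
  prototype(pv = 2078, sigmaOsm = 0.82, piV = 2666, piI = 2000,
            kTissue = 3.1e-14))

setValidity("VascularConstants", function(object) {
  msg <- character()
  if (object@kTissue <= 0) msg <- c(msg, "kTissue must be > 0")
  if (object@sigmaOsm < 0 || object@sigmaOsm > 1)
    msg <- c(msg, "sigmaOsm must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Drug-transport parameters
#'
#' @slot diffCoeff interstitial diffusivity of the drug (m^2/s)
#' @slot cBoundary drug concentration maintained at the tumor surface
#'   (mol/m^3); the therapy instillate concentration
#' @slot duration simulated therapy duration (s)
#' @slot dt time step of the implicit solver (s)
#' @slot sinkRate lumped first-order loss rate (cellular uptake plus vascular
#'   resorption) (1/s)
#' @slot ic50 half-maximal inhibitory concentration used by the penetration
#'   metrics (mol/m^3)
#' @export
setClass("TransportParams",
  representation(diffCoeff = "numeric", cBoundary = "numeric",
                 duration = "numeric", dt = "numeric", sinkRate = "numeric",
                 ic50 = "numeric"),
  prototype(diffCoeff = 3e-10, cBoundary = 0.113, duration = 1800, dt = 30,
            sinkRate = 1e-4, ic50 = 5e-3))

setValidity("TransportParams", function(object) {
  msg <- character()
  if (object@diffCoeff <= 0) msg <- c(msg, "diffCoeff must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@duration < object@dt) msg <- c(msg, "duration must be >= dt")
  if (object@cBoundary <= 0) msg <- c(msg, "cBoundary must be > 0")
  if (object@sinkRate < 0) msg <- c(msg, "sinkRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic tumor phantom
#'
#' Describes an ellipsoidal tumor with an optional off-centre ellipsoidal
#' interior zone (hypoxic or necrotic phenotype), per-zone ground-truth
#' kinetic parameters, native T1 values, and the signal noise level.
#'
#' @slot tumorSemiAxes semi-axes of the tumor ellipsoid (mm)
#' @slot voxelSpacing voxel spacing (mm per axis)
#' @slot interiorOffset centre offset of the interior zone (mm)
#' @slot interiorSemiAxes semi-axes of the interior zone (mm); all-zero means
#'   a single-zone tumor
#' @slot interiorPhenotype "hypoxic" or "necrotic"
#' @slot truthKinetics list with elements \code{viable} and \code{interior},
#'   each \code{list(phi=, psv=, jvv=)} (fraction, 1/s, 1/s)
#' @slot t10 named numeric, native T1 per zone label ("viable", "interior") (s)
#' @slot noiseSd additive Gaussian noise sd on the rendered signal
#'   (signal units)
#' @slot rician if TRUE noise is applied as Rician magnitude noise instead of
#'   additive Gaussian
#' @slot seed integer seed for noise generation
#' @export
setClass("PhantomSpec",
  representation(tumorSemiAxes = "numeric", voxelSpacing = "numeric",
                 interiorOffset = "numeric", interiorSemiAxes = "numeric",
                 interiorPhenotype = "character", truthKinetics = "list",
                 t10 = "numeric", noiseSd = "numeric", rician = "logical",
                 seed = "integer"),
  prototype(tumorSemiAxes = c(3, 2.5, 2), voxelSpacing = c(0.1, 0.1, 0.1),
            interiorOffset = c(0.6, 0.3, 0), interiorSemiAxes = c(1.2, 1, 0.8),
            interiorPhenotype = "necrotic",
            truthKinetics = list(
              viable   = list(phi = 0.30, psv = 2e-3, jvv = 1e-4),
              interior = list(phi = 0.40, psv = 0,    jvv = 2e-5)),
            t10 = c(viable = 1.8, interior = 2.2),
            noiseSd = 0, rician = FALSE, seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@tumorSemiAxes <= 0)) msg <- c(msg, "tumor semi-axes must be > 0")
  if (any(object@voxelSpacing <= 0)) msg <- c(msg, "voxel spacing must be > 0")
  if (any(object@interiorSemiAxes < 0)) msg <- c(msg, "interior semi-axes must be >= 0")
  if (!object@interiorPhenotype %in% c("hypoxic", "necrotic"))
    msg <- c(msg, "interiorPhenotype must be 'hypoxic' or 'necrotic'")
  for (zn in c("viable", "interior")) {
    k <- object@truthKinetics[[zn]]
    if (is.null(k)) { msg <- c(msg, sprintf("truthKinetics$%s missing", zn)); next }
    if (k$phi <= 0 || k$phi >= 1) msg <- c(msg, sprintf("%s phi must be in (0,1)", zn))
    if (k$psv < 0 || k$jvv < 0) msg <- c(msg, sprintf("%s rates must be >= 0", zn))
  }
  if (object@interiorPhenotype == "necrotic" &&
      !is.null(object@truthKinetics$interior) &&
      object@truthKinetics$interior$psv != 0)
    msg <- c(msg, "necrotic interior zone requires psv = 0 (leak-only uptake)")
  ## interior zone must sit strictly inside the tumor: check the support
  ## ellipsoid of the interior zone against the tumor ellipsoid
  if (any(object@interiorSemiAxes > 0)) {
    th <- seq(0, pi, length.out = 25); ph <- seq(0, 2 * pi, length.out = 49)
    g <- expand.grid(th = th, ph = ph)
    pts <- cbind(object@interiorSemiAxes[1] * sin(g$th) * cos(g$ph),
                 object@interiorSemiAxes[2] * sin(g$th) * sin(g$ph),
                 object@interiorSemiAxes[3] * cos(g$th))
    pts <- sweep(pts, 2, object@interiorOffset, "+")
    q <- sweep(pts, 2, object@tumorSemiAxes, "/")
    if (any(rowSums(q^2) >= 1))
      msg <- c(msg, "interior zone escapes the tumor ellipsoid")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Data-object classes
## ---------------------------------------------------------------------------

#' Per-voxel tracer concentration time courses
#'
#' The common currency between the imaging front end and the kinetic model:
#' a time-stamp vector and one concentration curve per masked voxel.
#'
#' @slot times acquisition times (s), strictly increasing
#' @slot curves numeric matrix, one row per voxel, one column per time point
#'   (mM)
#' @slot voxelIndex integer matrix of voxel coordinates (row, col[, slice])
#' @slot roiMask logical array marking the voxels the curves belong to
#' @export
setClass("TracerCurveSet",
  representation(times = "numeric", curves = "matrix",
                 voxelIndex = "matrix", roiMask = "array"))

setValidity("TracerCurveSet", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (ncol(object@curves) != length(object@times))
    msg <- c(msg, "curves must have one column per time point")
  if (nrow(object@curves) != nrow(object@voxelIndex))
    msg <- c(msg, "one coordinate row per curve required")
  if (any(!is.finite(object@curves)))
    msg <- c(msg, "curves must be finite")
  if (nrow(object@voxelIndex) > 0) {
    inmask <- object@roiMask[object@voxelIndex]
    if (!all(inmask)) msg <- c(msg, "every curve must belong to a masked voxel")
  }
  if (length(msg)) msg else TRUE
})

#' Voxel-wise vascular parameter map
#'
#' Holds the fitted two-compartment parameters (interstitial volume fraction
#' phi, permeability-surface product PS/V, filtration rate Jv/V), the fit
#' quality, the tissue-zone label per voxel, and the rescaled Starling
#' coefficient LpS/V per voxel and per zone.
#'
#' @slot voxelIndex integer matrix of voxel coordinates
#' @slot phi interstitial volume fraction per voxel
#' @slot psv permeability-surface product per unit volume (1/s)
#' @slot jvv plasma filtration rate per unit volume (1/s)
#' @slot r2 coefficient of determination of the voxel fit
#' @slot zone character, one of "viable", "hypoxic", "necrotic", "unfit"
#' @slot lpsv rescaled Starling coefficient per voxel (1/(Pa s))
#' @slot zoneStats data.frame of per-zone mean LpS/V
#' @slot lp0 baseline vascular hydraulic conductivity (m/(Pa s))
#' @slot sv0 baseline vascular surface-to-volume ratio (1/m)
#' @export
setClass("VascularMap",
  representation(voxelIndex = "matrix", phi = "numeric", psv = "numeric",
                 jvv = "numeric", r2 = "numeric", zone = "character",
                 lpsv = "numeric", zoneStats = "data.frame",
                 lp0 = "numeric", sv0 = "numeric"),
  prototype(lp0 = 2.1e-11, sv0 = 2.0e4, zoneStats = data.frame()))

setValidity("VascularMap", function(object) {
  n <- nrow(object@voxelIndex)
  msg <- character()
  for (s in c("phi", "psv", "jvv", "r2", "zone"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have one entry per voxel", s))
  fitted <- object@zone %in% c("viable", "hypoxic")
  if (any(fitted & (object@phi <= 0 | object@phi >= 1), na.rm = TRUE))
    msg <- c(msg, "fitted voxels must have phi in (0,1)")
  if (any(object@r2 > 1 + 1e-12, na.rm = TRUE)) msg <- c(msg, "r2 must be <= 1")
  if (length(object@lpsv) && any(object@lpsv < 0, na.rm = TRUE))
    msg <- c(msg, "lpsv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Voxelised computational tumor domain
#'
#' Integer label grid (0 = background/peritoneal bath, 1 = viable shell,
#' 2+ = interior zones), physical voxel spacing, the enumerated tumor-bath
#' boundary faces (with the fractional centre-to-surface distance used by the
#' solvers), and named in-plane probing axes.
#'
#' @slot labelGrid integer 3-D array of zone labels
#' @slot spacing voxel spacing (mm per axis)
#' @slot boundaryFaces data.frame with columns \code{cell} (linear voxel
#'   index), \code{axis} (1..3), \code{side} (+1/-1) and \code{theta}
#'   (fractional distance from the voxel centre to the surface, in units of
#'   the spacing along \code{axis}; 0.5 = face-centred)
#' @slot axes list of probing axes, each \code{list(name=, p0=, p1=,
#'   length=)} with endpoints in mm
#' @slot truth ground-truth kinetics by zone for phantom domains (empty list
#'   for mask-derived domains)
#' @export
setClass("TumorDomain",
  representation(labelGrid = "array", spacing = "numeric",
                 boundaryFaces = "data.frame", axes = "list", truth = "list"),
  prototype(axes = list(), truth = list()))

setValidity("TumorDomain", function(object) {
  msg <- character()
  if (length(dim(object@labelGrid)) != 3) msg <- c(msg, "labelGrid must be 3-D")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (any(object@labelGrid < 0)) msg <- c(msg, "labels must be >= 0")
  bf <- object@boundaryFaces
  if (nrow(bf)) {
    if (!all(c("cell", "axis", "side", "theta") %in% names(bf)))
      msg <- c(msg, "boundaryFaces needs cell/axis/side/theta columns")
    else if (any(object@labelGrid[bf$cell] == 0))
      msg <- c(msg, "boundary faces must belong to tumor voxels")
  }
  if (length(msg)) msg else TRUE
})

#' Solution fields on a tumor domain
#'
#' @slot domain the \linkS4class{TumorDomain} the fields live on
#' @slot pressure steady interstitial fluid pressure (Pa), 3-D array, NA
#'   outside the tumor
#' @slot velocity list of three 3-D arrays (m/s), voxel-centred interstitial
#'   fluid velocity components
#' @slot drug matrix of drug concentration (mol/m^3): one row per tumor
#'   voxel (order of \code{which(labelGrid > 0)}), one column per stored time
#' @slot drugTimes times at which drug fields are stored (s)
#' @slot residualHistory relative residual per solver iteration (pressure
#'   solve)
#' @slot massBudget data.frame with the per-step discrete mass budget of the
#'   transport solve
#' @export
setClass("FieldSolution",
  representation(domain = "TumorDomain", pressure = "array",
                 velocity = "list", drug = "matrix", drugTimes = "numeric",
                 residualHistory = "numeric", massBudget = "data.frame"),
  prototype(velocity = list(), drug = matrix(0, 0, 0), drugTimes = numeric(),
            residualHistory = numeric(), massBudget = data.frame()))

#' Pressure and penetration report
#'
#' Per-axis/per-side pressure and penetration metrics plus per-tumor
#' summary quantities, mirroring the quantities reported for each probed
#' axis: maximal pressure, LP50 steepness, absolute penetration depth,
#' relative penetrated length, and the penetrated volume fraction.
#'
#' @slot axisTable data.frame with one row per (axis, side)
#' @slot tumorTable data.frame with one row per tumor
#' @export
setClass("PenetrationReport",
  representation(axisTable = "data.frame", tumorTable = "data.frame"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: TR %.3g ms, TE %.3g ms, FA %g deg, r1 %.3g /mM/s\n",
              1e3 * object@tr, 1e3 * object@te, object@flipAngle, object@r1))
  cat(sprintf("  baseline %g s, frame interval %.4g s\n",
              object@baselineWindow, object@frameInterval))
})

setMethod("show", "AifParams", function(object) {
  cat(sprintf("AifParams: %.3g exp(-%.3g t) + %.3g exp(-%.3g t) mM, bolus at %g s, Hct %.2f\n",
              object@amp1, object@rate1, object@amp2, object@rate2,
              object@bolusArrival, object@hematocrit))
  if (!is.na(object@r2fit)) cat(sprintf("  tail-fit R^2 = %.4f\n", object@r2fit))
})

setMethod("show", "TracerCurveSet", function(object) {
  cat(sprintf("TracerCurveSet: %d voxels x %d time points, t in [%.3g, %.3g] s\n",
              nrow(object@curves), length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "VascularMap", function(object) {
  cat(sprintf("VascularMap: %d voxels (%s)\n", nrow(object@voxelIndex),
              paste(sprintf("%s: %d", names(table(object@zone)),
                            as.integer(table(object@zone))), collapse = ", ")))
  if (nrow(object@zoneStats)) {
    cat("  zone mean LpS/V (1/(Pa s)):\n")
    print(object@zoneStats)
  }
})

setMethod("show", "TumorDomain", function(object) {
  nt <- sum(object@labelGrid > 0)
  cat(sprintf("TumorDomain: grid %s, spacing %s mm, %d tumor voxels (%.3g mm^3)\n",
              paste(dim(object@labelGrid), collapse = "x"),
              paste(signif(object@spacing, 3), collapse = "x"),
              nt, nt * prod(object@spacing)))
  cat(sprintf("  %d boundary faces, %d probing axes, zones: %s\n",
              nrow(object@boundaryFaces), length(object@axes),
              paste(sort(unique(object@labelGrid[object@labelGrid > 0])),
                    collapse = ", ")))
})

setMethod("show", "FieldSolution", function(object) {
  p <- object@pressure[object@domain@labelGrid > 0]
  cat(sprintf("FieldSolution: pressure in [%.4g, %.4g] Pa", min(p), max(p)))
  if (ncol(object@drug))
    cat(sprintf("; drug stored at %d times (final max %.4g mol/m^3)",
                ncol(object@drug), max(object@drug[, ncol(object@drug)])))
  cat("\n")
})

setMethod("show", "PenetrationReport", function(object) {
  cat("PenetrationReport\n  per-axis metrics:\n")
  print(object@axisTable, digits = 4)
  cat("  per-tumor metrics:\n")
  print(object@tumorTable, digits = 4)
})
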