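## End-to-end orchestration: configuration handling, validation, and the
## phantom -> kinetics -> pressure -> transport -> report pipeline.

#' Default pipeline configuration
#'
#' A complete nested configuration with every physical constant, unit and
#' default the pipeline uses. All constants consumed by the solvers live
#' here; nothing is hard-coded downstream.
#'
#' @return nested list; see the methods vignette for the meaning and units
#'   of every field
#' @export
defaultConfig <- function() {
  list(
    phantom = list(
      tumorSemiAxes = c(3, 2.5, 2),        # mm
      voxelSpacing = 0.2,                  # mm
      interiorOffset = c(0.6, 0.3, 0),     # mm
      interiorSemiAxes = c(1.2, 1, 0.8),   # mm
      interiorPhenotype = "necrotic",
      noiseSd = 0,                         # signal units
      seed = 1L),
    acquisition = list(
      tr = 0.012, te = 0.0034, flipAngle = 25,   # s, s, degrees
      r1 = 3.5,                                  # 1/(mM s)
      baselineWindow = 60, frameInterval = 1.344, # s
      nFrames = 550),
    aif = list(
      amp1 = 0.8, amp2 = 0.2,              # mM
      rate1 = 0.02, rate2 = 0.002,         # 1/s
      bolusArrival = 60,                   # s
      hematocrit = 0.45),
    kinetics = list(
      sigma = 0, phiRef = 0.3, r2Threshold = 0.85,
      ttpThreshold = 180, washoutThreshold = 0.2,
      lp0 = 2.1e-11,                       # m/(Pa s)
      sv0 = 2.0e4),                        # 1/m
    vascular = list(
      pv = 2078, sigmaOsm = 0.82, piV = 2666, piI = 2000,  # Pa, -, Pa, Pa
      kTissue = 3.1e-14),                  # m^2/(Pa s)
    transport = list(
      diffCoeff = 3e-10,                   # m^2/s
      cBoundary = 0.113,                   # mol/m^3
      duration = 1800, dt = 30,            # s
      sinkRate = 1e-4,                     # 1/s
      ic50 = 5e-3),                        # mol/m^3
    axes = list(nShortAxes = 1, planeIndex = NULL),
    measuredPressure = list(value = NULL, units = "Pa"),
    seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' Values found in the file override the defaults; anything omitted keeps
#' its default.
#'
#' @param path YAML file
#' @return configuration list
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge2(defaultConfig(), user)
}

#' Validate a pipeline configuration
#'
#' Range, unit and cross-field checks. Returns the issues found (empty
#' character vector when the configuration is clean); it never throws.
#'
#' @param config configuration list (see \code{\link{defaultConfig}})
#' @return character vector of issues
#' @examples
#' validateConfig(defaultConfig())   # character(0)
#' @export
validateConfig <- function(config) {
  issues <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  tp <- config$transport; acq <- config$acquisition; aif <- config$aif
  ph <- config$phantom; vc <- config$vascular; kin <- config$kinetics
  chk(is.numeric(tp$dt) && tp$dt > 0, "transport$dt must be > 0")
  chk(is.numeric(tp$duration) && tp$duration >= tp$dt,
      "transport$dt exceeds transport$duration")
  chk(tp$cBoundary > 0, "transport$cBoundary must be > 0 mol/m^3")
  chk(tp$diffCoeff > 0, "transport$diffCoeff must be > 0 m^2/s")
  chk(tp$sinkRate >= 0, "transport$sinkRate must be >= 0")
  chk(tp$ic50 > 0, "transport$ic50 must be > 0")
  chk(acq$baselineWindow >= acq$frameInterval,
      "acquisition$baselineWindow must cover at least one frameInterval")
  chk(acq$tr > 0 && acq$r1 > 0, "acquisition tr and r1 must be > 0")
  chk(acq$flipAngle > 0 && acq$flipAngle <= 90,
      "acquisition$flipAngle must be in (0, 90] degrees for the DCE series")
  chk(aif$hematocrit >= 0 && aif$hematocrit < 1,
      "aif$hematocrit out of range [0, 1)")
  chk(aif$rate1 > 0 && aif$rate2 > 0, "aif rates must be > 0")
  chk(all(ph$tumorSemiAxes > 0), "phantom$tumorSemiAxes must be > 0 mm")
  chk(all(ph$voxelSpacing > 0), "phantom$voxelSpacing must be > 0 mm")
  chk(kin$sigma >= 0 && kin$sigma < 1, "kinetics$sigma out of range [0, 1)")
  chk(kin$phiRef > 0 && kin$phiRef < 1, "kinetics$phiRef out of range (0, 1)")
  chk(vc$kTissue > 0, "vascular$kTissue must be > 0")
  chk(vc$sigmaOsm >= 0 && vc$sigmaOsm <= 1, "vascular$sigmaOsm out of range [0, 1]")
  chk(config$axes$nShortAxes %in% c(1, 2), "axes$nShortAxes must be 1 or 2")
  mp <- config$measuredPressure
  if (!is.null(mp$value))
    chk(mp$units %in% c("Pa", "mmHg"), "measuredPressure$units must be Pa or mmHg")
  ## phantom geometry consistency (interior zone strictly inside)
  spec <- try(do.call(PhantomSpec, c(ph[c("tumorSemiAxes", "voxelSpacing",
                                          "interiorOffset", "interiorSemiAxes",
                                          "interiorPhenotype", "noiseSd",
                                          "seed")])), silent = TRUE)
  if (inherits(spec, "try-error"))
    issues <- c(issues, paste("phantom:", attr(spec, "condition")$message))
  issues
}

## slice-derived zone -> LpS/V per 3-D label, per the 2-D-to-3-D
## extrapolation convention (each 3-D zone gets the mean LpS/V of the
## majority curve-shape class of its slice voxels; necrotic zones get 0).
.lpsvPerLabel <- function(domain, map, planeIndex) {
  lg <- domain@labelGrid
  lab <- lg[cbind(map@voxelIndex[, 1], map@voxelIndex[, 2],
                  rep(planeIndex, nrow(map@voxelIndex)))]
  labels <- sort(unique(lg[lg > 0]))
  zs <- setNames(map@zoneStats$lpsvMean, map@zoneStats$zone)
  out <- numeric(max(labels))
  for (l in labels) {
    zl <- map@zone[lab == l]
    if (!length(zl)) { out[l] <- 0; next }
    major <- names(sort(table(zl), decreasing = TRUE))[1]
    out[l] <- if (major %in% c("necrotic", "unfit")) 0 else zs[[major]]
  }
  out
}

#' Run the full phantom-to-report pipeline
#'
#' Executes every stage in order -- phantom generation, T1 mapping, signal
#' inversion, AIF extraction, voxel-wise kinetic fitting, zone
#' classification, LpS/V rescaling and 3-D assignment, steady pressure
#' solve, velocity, transient drug transport, and metric extraction --
#' and assembles a \linkS4class{PenetrationReport}. Deterministic given the
#' configuration seeds.
#'
#' @param config configuration list (see \code{\link{defaultConfig}});
#'   validated before anything runs
#' @param outDir optional output directory; when given, writes
#'   \code{report.csv}, \code{report.json}, NIfTI parameter/pressure maps
#'   and a VTK field file, plus a run log recording every default that
#'   fired
#' @param verbose print stage progress
#' @return list with \code{report} (a \linkS4class{PenetrationReport}),
#'   \code{solution} (\linkS4class{FieldSolution}), \code{map}
#'   (\linkS4class{VascularMap}), \code{aifFit}, \code{study}, and
#'   \code{log}
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL,
                        verbose = FALSE) {
  issues <- validateConfig(config)
  if (length(issues))
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "))
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## -- phantom ------------------------------------------------------------
  ph <- config$phantom
  acq <- do.call(AcquisitionParams,
                 config$acquisition[c("tr", "te", "flipAngle", "r1",
                                      "baselineWindow", "frameInterval")])
  aifTruth <- do.call(AifParams, config$aif)
  spec <- do.call(PhantomSpec, c(ph[c("tumorSemiAxes", "voxelSpacing",
                                      "interiorOffset", "interiorSemiAxes",
                                      "interiorPhenotype", "noiseSd",
                                      "seed")]))
  study <- stage("phantom", phantomDceStudy(
    spec, acq, aifTruth, nFrames = config$acquisition$nFrames,
    planeIndex = config$axes$planeIndex))
  note("phantom: %d tumor voxels, %d slice voxels, plane %d",
       sum(study$domain@labelGrid > 0), nrow(study$voxelIndex),
       study$planeIndex)

  ## -- DCE front end ------------------------------------------------------
  t10fit <- stage("t10", fitT10(study$multiTr, study$trList))
  rie <- stage("rie", computeRie(study$signals, study$times, acq))
  t10use <- ifelse(is.na(t10fit$t10), mean(t10fit$t10, na.rm = TRUE),
                   t10fit$t10)
  conc <- stage("concentration",
                signalToConcentration(rie$rie, acq, t10use))
  conc[is.na(conc)] <- 0
  curves <- new("TracerCurveSet", times = study$times, curves = conc,
                voxelIndex = study$voxelIndex,
                roiMask = array(study$roiMask, dim(study$roiMask)))
  aifFit <- stage("aif", extractAif(
    study$aifSignals, study$times, acq,
    candidates = seq_len(nrow(study$aifSignals)),
    t10Blood = study$t10Blood, hematocrit = config$aif$hematocrit))
  note("aif: fitted %.3g exp(-%.3g t) + %.3g exp(-%.3g t), arrival %.4g s",
       aifFit@amp1, aifFit@rate1, aifFit@amp2, aifFit@rate2,
       aifFit@bolusArrival)

  ## -- kinetics -----------------------------------------------------------
  kin <- config$kinetics
  map <- stage("kinetics", fitVoxelKinetics(
    curves, aifFit, sigma = kin$sigma, phiRef = kin$phiRef,
    r2Threshold = kin$r2Threshold))
  map <- stage("zones", classifyZones(
    map, curves, aifFit, ttpThreshold = kin$ttpThreshold,
    washoutThreshold = kin$washoutThreshold))
  map <- stage("lpsv", rescaleToLpsv(map, lp0 = kin$lp0, sv0 = kin$sv0))
  note("kinetics: %s",
       paste(sprintf("%s %d", map@zoneStats$zone, map@zoneStats$nVoxels),
             collapse = ", "))

  ## -- CFD ----------------------------------------------------------------
  vc <- do.call(VascularConstants, config$vascular)
  tp <- do.call(TransportParams, config$transport)
  lpsvByLabel <- .lpsvPerLabel(study$domain, map, study$planeIndex)
  note("lpsv per 3-D zone: %s",
       paste(signif(lpsvByLabel, 4), collapse = ", "))
  domain <- stage("axes", defineAxes(study$domain,
                                     planeIndex = study$planeIndex,
                                     nShortAxes = config$axes$nShortAxes))
  sol <- stage("ifp", solveIfp(domain, lpsvByLabel, vc))
  sol <- stage("velocity", computeVelocity(sol, vc))
  pmaxGlobal <- max(sol@pressure, na.rm = TRUE)
  note("ifp: max %.4g Pa (effective pressure %.4g Pa)", pmaxGlobal,
       effectivePressure(vc))
  sol <- stage("transport", solveDrugTransport(sol, tp, vc))
  note("transport: final max %.4g mol/m^3, worst budget closure %.3g",
       max(sol@drug[, ncol(sol@drug)]), max(sol@massBudget$closure))

  ## -- metrics ------------------------------------------------------------
  drugFinal <- drugField(sol)
  rows <- list()
  for (axName in names(domain@axes)) {
    pProf <- extractProfile(sol@pressure, domain, axName)
    cProf <- extractProfile(drugFinal, domain, axName)
    lp50 <- computeLp50(pProf)
    pen <- computePenetration(cProf, tp@ic50)
    for (sd_ in c("L", "R")) {
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axName, side = sd_,
        axisLength = domain@axes[[axName]]$length,
        pmax = max(pProf$value, na.rm = TRUE),
        lp50 = unname(lp50[sd_]),
        apd = pen$apd[pen$side == sd_],
        pdPct = pen$pdPct[pen$side == sd_])
    }
  }
  axisTable <- do.call(rbind, rows)
  pmeas <- config$measuredPressure$value
  if (!is.null(pmeas) && config$measuredPressure$units == "mmHg")
    pmeas <- mmHgToPa(pmeas)
  ss <- if (!is.null(pmeas)) solidStressResidual(pmeas, pmaxGlobal) else NA_real_
  tumorTable <- data.frame(
    volume = tumorVolume(domain),
    interiorVolume = tumorVolume(domain, label = 2L),
    pvolPct = computePvol(sol, tp@ic50),
    pmaxGlobal = pmaxGlobal,
    piMax = effectivePressure(vc),
    pmeas = if (is.null(pmeas)) NA_real_ else pmeas,
    ssPressure = ss)
  report <- new("PenetrationReport", axisTable = axisTable,
                tumorTable = tumorTable)

  ## -- artifacts ----------------------------------------------------------
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(axisTable, file.path(outDir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(axes = axisTable, tumor = tumorTable,
           zoneStats = map@zoneStats,
           aif = list(amp1 = aifFit@amp1, rate1 = aifFit@rate1,
                      amp2 = aifFit@amp2, rate2 = aifFit@rate2,
                      bolusArrival = aifFit@bolusArrival, r2 = aifFit@r2fit)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
    sp <- domain@spacing
    writeFieldNifti(sol@pressure, sp, file.path(outDir, "pressure_Pa.nii.gz"))
    writeFieldNifti(drugFinal, sp, file.path(outDir, "drug_final_molm3.nii.gz"))
    lgArr <- array(as.numeric(domain@labelGrid), dim(domain@labelGrid))
    writeVtkImage(list(pressure_Pa = sol@pressure,
                       drug_molm3 = drugFinal, zone = lgArr),
                  sp, file.path(outDir, "fields.vtk"))
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  list(report = report, solution = sol, map = map, aifFit = aifFit,
       study = study, log = logLines)
}
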