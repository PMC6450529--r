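## DCE-MRI quantification: native T1 mapping from variable-TR images,
## relative intensity enhancement, exact SPGR signal-to-concentration
## inversion, and AIF extraction with hematocrit correction.

#' Fit native T1 (T10) from variable-TR saturation-recovery images
#'
#' Per voxel, fits \code{A*(1 - exp(-TR/T10))} in least squares over the
#' acquired repetition times. The amplitude is profiled out analytically
#' (linear in A), leaving a robust 1-D optimisation over T10.
#'
#' Voxels whose signal does not increase with TR beyond noise tolerance are
#' degenerate for this model and are flagged unfittable (NA).
#'
#' @param signals matrix of intensities, voxels x TR values (non-negative)
#' @param trList repetition times (s), one per column; at least 3
#' @return list with \code{t10} (s, NA where unfittable), \code{amplitude},
#'   and \code{rss} (residual sum of squares)
#' @examples
#' sig <- renderMultiTrImages(c(1.8, 2.2))
#' fitT10(sig)$t10
#' @export
fitT10 <- function(signals, trList = c(0.1, 0.502, 1.184, 5)) {
  signals <- rbind(signals)
  if (length(trList) != ncol(signals))
    stop("one TR per signal column required")
  if (length(trList) < 3) stop("at least 3 TR points required")
  if (any(signals < 0)) stop("signals must be non-negative")
  n <- nrow(signals)
  t10 <- amp <- rss <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    s <- signals[v, ]
    rng <- diff(range(s))
    ## degenerate: flat, or decreasing with TR beyond 1% of the range
    if (rng <= 0 || cor(s, trList) <= 0 ||
        max(head(cummax(s), -1) - tail(s, -1)) > 0.25 * rng)
      next
    prof <- function(tau) {
      g <- 1 - exp(-trList / tau)
      a <- sum(s * g) / sum(g * g)
      sum((s - a * g)^2)
    }
    opt <- optimize(prof, interval = c(1e-3, 50), tol = 1e-9)
    g <- 1 - exp(-trList / opt$minimum)
    t10[v] <- opt$minimum
    amp[v] <- sum(s * g) / sum(g * g)
    rss[v] <- opt$objective
  }
  list(t10 = t10, amplitude = amp, rss = rss)
}

#' Relative intensity enhancement of a dynamic series
#'
#' \code{RIE = (S - S0)/S0} per voxel and frame, with \code{S0} the mean
#' signal over the pre-contrast baseline window.
#'
#' @param series signal matrix, voxels x frames
#' @param times frame times (s)
#' @param acq an \linkS4class{AcquisitionParams}; frames with
#'   \code{times < baselineWindow} form the baseline
#' @return list with \code{rie} (matrix), \code{s0} (vector) and
#'   \code{flagged} (logical, voxels with non-positive S0)
#' @export
computeRie <- function(series, times, acq) {
  series <- rbind(series)
  stopifnot(ncol(series) == length(times))
  base <- times < acq@baselineWindow
  if (!any(base)) stop("no baseline frame inside the baseline window")
  s0 <- unname(rowMeans(series[, base, drop = FALSE]))
  flagged <- s0 <= 0
  rie <- sweep(series, 1, s0, "-")
  rie <- sweep(rie, 1, ifelse(flagged, NA, s0), "/")
  list(rie = rie, s0 = s0, flagged = flagged)
}

#' Convert relative intensity enhancement to tracer concentration
#'
#' Exact algebraic inversion of the spoiled gradient-echo signal model
#' (T2* neglected). With \code{y = (1 + RIE) * f(E10)} where
#' \code{f(E) = (1-E)/(1-E cos a)}, the post-contrast relaxation factor is
#' \code{E1 = (1-y)/(1-y cos a)} and
#' \deqn{c = (\log E_{10} - \log E_1)/(r_1\, TR).}
#' By construction \code{c(RIE = 0) = 0} and c is strictly increasing in RIE
#' on the physical branch \code{E1} in (0, 1).
#'
#' @param rie RIE values (vector or matrix)
#' @param acq an \linkS4class{AcquisitionParams}
#' @param t10 native T1 (s): scalar or one value per row of \code{rie}
#' @return concentration (mM), same shape as \code{rie}; NA (with a warning)
#'   where the implied E1 leaves the physical branch
#' @export
signalToConcentration <- function(rie, acq, t10) {
  if (any(t10 <= 0, na.rm = TRUE)) stop("t10 must be > 0")
  al <- acq@flipAngle * pi / 180
  e10 <- exp(-acq@tr / t10)
  f10 <- (1 - e10) / (1 - e10 * cos(al))
  if (is.matrix(rie)) {
    ## per-voxel t10 recycles down the rows
    f <- rep_len(f10, nrow(rie))
    y <- sweep(1 + rie, 1, f, "*")
    e10m <- rep_len(e10, nrow(rie))
  } else {
    y <- (1 + rie) * f10
    e10m <- e10
  }
  e1 <- (1 - y) / (1 - y * cos(al))
  bad <- !(e1 > 0 & e1 < 1)
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("%d value(s) outside the physical branch flagged as NA",
                    sum(bad, na.rm = TRUE)))
    e1[bad] <- NA
  }
  conc <- if (is.matrix(rie)) sweep(-log(e1), 1, log(e10m), "+") / (acq@r1 * acq@tr)
          else (log(e10m) - log(e1)) / (acq@r1 * acq@tr)
  conc
}

#' Extract and fit an analytical arterial input function
#'
#' Inverts the signal of user-identified candidate blood voxels to
#' concentration, averages them, rescales whole-blood concentration to
#' plasma by \code{1/(1 - Hct)}, smooths with a moving median (window 5
#' frames), detects the bolus arrival (first frame above baseline mean + 5
#' baseline sd), and fits the post-peak tail to a bi-exponential decay whose
#' analytic form is returned.
#'
#' Automatic candidate-voxel detection is deliberately out of scope; the
#' caller supplies the candidate rows.
#'
#' @param series signal matrix, voxels x frames
#' @param times frame times (s)
#' @param acq an \linkS4class{AcquisitionParams}
#' @param candidates integer row indices of candidate blood voxels
#' @param t10Blood native T1 of blood used for the inversion (s)
#' @param hematocrit hematocrit fraction in [0, 1)
#' @return an \linkS4class{AifParams} with the fitted parameters, detected
#'   bolus arrival, the hematocrit used, and the tail-fit R^2 (a warning is
#'   issued below 0.9)
#' @export
extractAif <- function(series, times, acq, candidates, t10Blood = 1.4,
                       hematocrit = 0.45) {
  if (hematocrit < 0 || hematocrit >= 1) stop("hematocrit must be in [0, 1)")
  series <- rbind(series)[candidates, , drop = FALSE]
  rie <- computeRie(series, times, acq)
  conc <- signalToConcentration(rie$rie, acq, t10Blood)
  cb <- colMeans(conc, na.rm = TRUE)
  caif <- cb / (1 - hematocrit)
  caif <- runmed(caif, k = 5, endrule = "keep")

  base <- times < acq@baselineWindow
  mu <- mean(caif[base]); sdev <- sd(caif[base])
  thr <- mu + 5 * max(sdev, 1e-12)
  idx <- which(caif > thr & !base)
  if (!length(idx))
    stop("no post-bolus peak detected on the candidate-voxel mean curve")
  arrival <- times[min(idx)]

  post <- times >= arrival
  peakIdx <- which.max(caif * post)
  if (peakIdx >= length(times) - 10)
    stop("no post-bolus peak detected: curve still rising at end of series")
  ## start the tail past the median-filter half-width so the fitted segment
  ## is undistorted (the running median is exact on the monotone tail)
  startIdx <- min(peakIdx + 2L, length(times) - 20L)
  tail_t <- times[startIdx:length(times)] - arrival
  tail_c <- caif[startIdx:length(times)]

  ## starts from a log-linear split: slow component from the last third,
  ## fast component from the residual of the first third
  n <- length(tail_t)
  lateIdx <- seq(max(1, floor(2 * n / 3)), n)
  lfit <- lm(log(pmax(tail_c[lateIdx], 1e-9)) ~ tail_t[lateIdx])
  a2 <- exp(unname(coef(lfit)[1])); r2s <- max(unname(-coef(lfit)[2]), 1e-5)
  resid1 <- pmax(tail_c - a2 * exp(-r2s * tail_t), 1e-9)
  earlyIdx <- seq_len(max(3, floor(n / 3)))
  ffit <- lm(log(resid1[earlyIdx]) ~ tail_t[earlyIdx])
  a1 <- exp(unname(coef(ffit)[1])); r1s <- max(unname(-coef(ffit)[2]), 10 * r2s)

  df <- data.frame(t = tail_t, c = tail_c)
  fit <- try(minpack.lm::nlsLM(
    c ~ A1 * exp(-R1 * t) + A2 * exp(-R2 * t), data = df,
    start = list(A1 = a1, R1 = r1s, A2 = a2, R2 = r2s),
    lower = c(0, 1e-6, 0, 1e-7), upper = c(Inf, 10, Inf, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("bi-exponential tail fit failed: ", attr(fit, "condition")$message)
  cf <- coef(fit)
  pred <- predict(fit)
  r2 <- 1 - sum((tail_c - pred)^2) / sum((tail_c - mean(tail_c))^2)
  if (r2 < 0.9)
    warning(sprintf("AIF tail fit R^2 = %.3f (< 0.9)", r2))
  AifParams(amp1 = unname(cf["A1"]), rate1 = unname(cf["R1"]),
            amp2 = unname(cf["A2"]), rate2 = unname(cf["R2"]),
            bolusArrival = arrival, hematocrit = hematocrit, r2fit = r2)
}
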