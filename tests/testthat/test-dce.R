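test_that("T10 recovery is exact on noiseless data and unbiased under noise", {
  truth <- c(1.8, 0.6, 3.1)
  f <- fitT10(renderMultiTrImages(truth))
  expect_lt(max(abs(f$t10 - truth) / truth), 1e-5)

  ## constant signal across TRs is degenerate
  f2 <- fitT10(matrix(500, 1, 4))
  expect_true(is.na(f2$t10))

  ## Monte-Carlo: 1% noise, 100 seeds, median bias < 2% at the four TRs
  rec <- vapply(1:100, function(s) {
    sig <- renderMultiTrImages(1.8, noiseSd = 10, seed = s)  # 1% of A = 1000
    fitT10(sig)$t10
  }, numeric(1))
  expect_lt(abs(median(rec) - 1.8) / 1.8, 0.02)
})

test_that("RIE arithmetic and flagging", {
  acq <- AcquisitionParams(baselineWindow = 3, frameInterval = 1)
  times <- 0:9
  s0 <- 200
  ramp <- c(rep(s0, 3), s0 * (1 + (1:7) / 10))
  r <- computeRie(rbind(ramp), times, acq)
  expect_equal(r$s0, s0)
  expect_equal(as.numeric(r$rie), (ramp - s0) / s0)
  expect_equal(as.numeric(r$rie[1, 1:3]), rep(0, 3))
  ## S = 2 S0 -> RIE = 1
  expect_equal(computeRie(rbind(c(1, 1, 2)), 0:2,
                          AcquisitionParams(baselineWindow = 2,
                                            frameInterval = 1))$rie[1, 3], 1)
  z <- computeRie(rbind(rep(0, 10)), times, acq)
  expect_true(z$flagged)
})

test_that("signal inversion is the exact inverse of the SPGR forward model", {
  acq <- AcquisitionParams()   # TR 12 ms, FA 25, r1 3.5
  conc <- seq(0, 2, by = 0.01)
  for (t10 in c(0.8, 1.8, 2.5)) {
    sig <- ipcFlow:::.spgrSignal(conc, t10, acq, 1234)
    rie <- sig / sig[1] - 1
    back <- signalToConcentration(rie, acq, t10)
    expect_lt(max(abs(back - conc)), 1e-3 * 2)   # well below 0.1% of range
    expect_equal(back[1], 0)
    expect_true(all(diff(back) > 0))             # monotone physical branch
  }
  ## single-value round trip at 0.5 mM
  sig <- ipcFlow:::.spgrSignal(c(0, 0.5), 2.0, acq, 1)
  expect_equal(signalToConcentration(sig[2] / sig[1] - 1, acq, 2.0), 0.5,
               tolerance = 1e-10)
  ## out-of-branch values are flagged
  expect_warning(out <- signalToConcentration(-2, acq, 1.8), "physical")
  expect_true(is.na(out))
})

test_that("AIF extraction recovers generator parameters and scales by Hct", {
  times <- dceTimes()
  acq <- AcquisitionParams(baselineWindow = 59)
  truth <- AifParams(amp1 = 0.8, rate1 = 0.02, amp2 = 0.2, rate2 = 0.002,
                     bolusArrival = 44 * 1.344, hematocrit = 0.45)
  cb <- (1 - truth@hematocrit) * sampleAif(truth, times)
  sig <- ipcFlow:::.spgrSignal(matrix(cb, 3, length(times), byrow = TRUE),
                               1.4, acq, 1000)
  fit <- extractAif(sig, times, acq, 1:3, t10Blood = 1.4, hematocrit = 0.45)
  expect_lt(abs(fit@amp1 - truth@amp1) / truth@amp1, 0.01)
  expect_lt(abs(fit@amp2 - truth@amp2) / truth@amp2, 0.01)
  expect_lt(abs(fit@rate1 - truth@rate1) / truth@rate1, 0.01)
  expect_lt(abs(fit@rate2 - truth@rate2) / truth@rate2, 0.01)
  expect_equal(fit@bolusArrival, truth@bolusArrival)
  expect_gt(fit@r2fit, 0.999)

  ## Hct = 0 leaves blood concentration unscaled: fitted amplitudes shrink
  ## by exactly (1 - 0.45)
  fit0 <- extractAif(sig, times, acq, 1:3, t10Blood = 1.4, hematocrit = 0)
  expect_equal(fit0@amp1 / fit@amp1, 0.55, tolerance = 1e-3)

  ## flat series has no detectable bolus
  flat <- matrix(500, 2, length(times))
  expect_error(extractAif(flat, times, acq, 1:2), "peak")
})

test_that("AIF fit residuals shrink as signal noise shrinks", {
  times <- dceTimes(400)
  acq <- AcquisitionParams(baselineWindow = 59)
  truth <- AifParams(bolusArrival = 44 * 1.344)
  cb <- (1 - truth@hematocrit) * sampleAif(truth, times)
  clean <- ipcFlow:::.spgrSignal(matrix(cb, 8, length(times), byrow = TRUE),
                                 1.4, acq, 1000)
  resid <- vapply(c(4, 1, 0.25), function(sdn) {
    errs <- vapply(1:10, function(s) {
      set.seed(s)
      noisy <- clean + matrix(rnorm(length(clean), 0, sdn), nrow(clean))
      f <- extractAif(noisy, times, acq, 1:8, t10Blood = 1.4)
      abs(f@amp1 - truth@amp1)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})
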