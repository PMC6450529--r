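test_that("phantom voxel volumes match analytic ellipsoid volumes", {
  ## sphere r = 2.21 mm at 0.1 mm: reconstructed volume ~ 45 mm^3
  dom <- sphereDomain(2.21, 0.1)
  vAna <- 4 / 3 * pi * 2.21^3
  expect_lt(abs(tumorVolume(dom) - vAna) / vAna, 0.03)

  ## generic ellipsoid against brute-force voxel counting at 0.2 mm
  spec <- PhantomSpec(tumorSemiAxes = c(4, 3, 3), voxelSpacing = 0.2,
                      interiorSemiAxes = c(0, 0, 0))
  dom2 <- makePhantomDomain(spec)$domain
  vAna2 <- 4 / 3 * pi * 4 * 3 * 3
  expect_lt(abs(tumorVolume(dom2) - vAna2) / vAna2, 0.02)

  ## refinement: observed convergence order of the volume error >= 1
  err <- vapply(c(0.4, 0.2, 0.1), function(h)
    abs(tumorVolume(sphereDomain(2, h)) - 4 / 3 * pi * 8), numeric(1))
  orders <- log2(err[-length(err)] / err[-1])
  expect_gt(mean(orders), 1)
})

test_that("degenerate interior zone yields a single-zone domain", {
  spec <- PhantomSpec(interiorOffset = c(0, 0, 0),
                      interiorSemiAxes = c(0, 0, 0), voxelSpacing = 0.25)
  dom <- makePhantomDomain(spec)$domain
  expect_identical(sum(dom@labelGrid == 2L), 0L)
})

test_that("an interior zone escaping the tumor is rejected", {
  expect_error(PhantomSpec(tumorSemiAxes = c(2, 2, 2),
                           interiorOffset = c(1.5, 0, 0),
                           interiorSemiAxes = c(1, 1, 1)),
               "escapes")
})

test_that("necrotic phenotype requires a pure-leak (PS/V = 0) interior zone", {
  expect_error(PhantomSpec(
    interiorPhenotype = "necrotic",
    truthKinetics = list(viable = list(phi = 0.3, psv = 2e-3, jvv = 1e-4),
                         interior = list(phi = 0.4, psv = 1e-3, jvv = 2e-5))),
    "psv = 0")
})

test_that("sampleAif follows the bi-exponential form with bolus delay", {
  aif <- AifParams(amp1 = 1, rate1 = 0.01, amp2 = 0, bolusArrival = 50)
  expect_identical(sampleAif(aif, c(0, 25, 49.9)), rep(0, 3))
  expect_equal(sampleAif(aif, 50), 1)                     # tau = 0: amp1+amp2
  expect_equal(sampleAif(aif, 150), exp(-1))              # closed form
  aif2 <- AifParams()
  expect_equal(sampleAif(aif2, aif2@bolusArrival), aif2@amp1 + aif2@amp2)
  expect_error(sampleAif(aif, c(3, 1)), "sorted")
})

test_that("simulated tracer curves match the stiff ODE within 1e-6 and the
           closed form cross-validates the generator", {
  aif <- AifParams()
  tt <- dceTimes(300)
  for (kin in list(list(phi = 0.3, psv = 2e-3, jvv = 1e-4),
                   list(phi = 0.15, psv = 5e-4, jvv = 5e-5),
                   list(phi = 0.4, psv = 0, jvv = 2e-5))) {
    cNum <- simulateTracerCurve(kin, aif, tt)
    cAna <- solveTwoCompartment(kin, aif, tt)
    expect_lt(max(abs(cNum - cAna)) / max(cAna), 1e-6)
  }
  ## zero AIF -> zero curve; phi <= 0 rejected
  aif0 <- AifParams(amp1 = 0, amp2 = 0)
  expect_equal(max(abs(simulateTracerCurve(list(phi = 0.3, psv = 1e-3,
                                                jvv = 1e-4), aif0, tt))), 0)
  expect_error(simulateTracerCurve(list(phi = 0, psv = 1, jvv = 0), aif, tt),
               "phi")
})

test_that("rendered signal is SPGR-consistent and scale leaves RIE unchanged", {
  acq <- AcquisitionParams()
  tt <- dceTimes(120)
  kin <- list(phi = 0.3, psv = 2e-3, jvv = 1e-4)
  cc <- simulateTracerCurve(kin, AifParams(), tt)
  tcs <- curveSet(cc, tt)
  s1 <- renderSignalSeries(tcs, acq, 1.8, scale = 1000)
  s2 <- renderSignalSeries(tcs, acq, 1.8, scale = 2000)
  expect_equal(s2, 2 * s1)
  r1 <- computeRie(s1, tt, acq)$rie
  r2 <- computeRie(s2, tt, acq)$rie
  expect_equal(r1, r2)
  ## zero concentration renders the flat baseline signal
  s0 <- renderSignalSeries(curveSet(rep(0, length(tt)), tt), acq, 1.8)
  expect_equal(max(abs(s0 - s0[1])), 0)
  expect_error(renderSignalSeries(tcs, AcquisitionParams(flipAngle = 120),
                                  1.8), "flip angle")
})

test_that("fixed seeds give bit-identical noisy renderings", {
  acq <- AcquisitionParams()
  tt <- dceTimes(80)
  tcs <- curveSet(simulateTracerCurve(list(phi = 0.3, psv = 2e-3, jvv = 1e-4),
                                      AifParams(), tt), tt)
  a <- renderSignalSeries(tcs, acq, 1.8, noiseSd = 5, seed = 7L)
  b <- renderSignalSeries(tcs, acq, 1.8, noiseSd = 5, seed = 7L)
  expect_identical(a, b)
  d <- renderSignalSeries(tcs, acq, 1.8, noiseSd = 5, seed = 8L)
  expect_false(identical(a, d))
})

test_that("multi-TR stack follows saturation recovery with limits", {
  trs <- c(0.1, 0.502, 1.184, 5)
  sig <- renderMultiTrImages(1.8, trs, amplitude = 1000)
  expect_equal(as.numeric(sig), 1000 * (1 - exp(-trs / 1.8)))
  ## TR >> T10 saturates to A; TR -> 0 vanishes
  expect_equal(as.numeric(renderMultiTrImages(0.5, c(50, 60, 70))),
               rep(1000, 3), tolerance = 1e-12)
  expect_lt(renderMultiTrImages(2, c(1e-6, 1, 2))[1], 1e-3)
  expect_error(renderMultiTrImages(1.8, c(0.1, 0.1, 1)), "duplicate")
  expect_error(renderMultiTrImages(1.8, c(0.1, 1)), "3 distinct")
})
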