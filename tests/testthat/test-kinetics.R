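test_that("closed-form two-compartment solution: trivial, steady-state and
           ODE-oracle agreement", {
  aif <- AifParams()
  tt <- dceTimes(300)
  ## no exchange -> zero curve
  expect_equal(max(abs(solveTwoCompartment(list(phi = 0.3, psv = 0, jvv = 0),
                                           aif, tt))), 0)
  ## near-constant AIF limit: c(inf) = c0 (1 + (Jv/V)(1-sigma)/(PS/V))
  kin <- list(phi = 0.3, psv = 2e-3, jvv = 1e-4)
  aifc <- AifParams(amp1 = 0, amp2 = 1, rate2 = 1e-9, bolusArrival = 0)
  cs <- solveTwoCompartment(kin, aifc, c(0, 5e4))
  expect_equal(cs[2], 1 * (1 + kin$jvv / kin$psv), tolerance = 1e-4)
  ## generic parameters vs independent stiff integrator
  for (kin in list(list(phi = 0.2, psv = 1e-3, jvv = 3e-4),
                   list(phi = 0.5, psv = 8e-3, jvv = 1e-5))) {
    expect_lt(max(abs(solveTwoCompartment(kin, aif, tt) -
                      simulateTracerCurve(kin, aif, tt))) /
              max(solveTwoCompartment(kin, aif, tt)), 1e-6)
  }
})

test_that("rate-collision branch is the continuous limit", {
  aif <- AifParams(amp1 = 1, rate1 = 0.002, amp2 = 0.5, rate2 = 0.0005)
  tt <- dceTimes(300)
  ## k exactly equal to rate1: psv/phi = 0.002
  kinHit <- list(phi = 0.3, psv = 0.3 * 0.002, jvv = 1e-4)
  kinNear <- list(phi = 0.3, psv = 0.3 * 0.002 * (1 + 1e-7), jvv = 1e-4)
  cHit <- solveTwoCompartment(kinHit, aif, tt)
  cNear <- solveTwoCompartment(kinNear, aif, tt)
  expect_lt(max(abs(cHit - cNear)) / max(cHit), 1e-5)
  expect_true(all(is.finite(cHit)))
})

test_that("voxel-wise fit recovers generator truth at zero noise", {
  aif <- AifParams()
  tt <- dceTimes()
  truth <- list(phi = 0.3, psv = 2e-3, jvv = 1e-4)
  tcs <- curveSet(solveTwoCompartment(truth, aif, tt), tt)
  m <- fitVoxelKinetics(tcs, aif)
  expect_lt(abs(m@phi[1] - truth$phi) / truth$phi, 0.01)
  expect_lt(abs(m@psv[1] - truth$psv) / truth$psv, 0.01)
  expect_lt(abs(m@jvv[1] - truth$jvv) / truth$jvv, 0.01)
  expect_gt(m@r2[1], 0.999)
  expect_identical(m@zone[1], "fitted")
})

test_that("pure-noise and all-zero curves are labelled unfit", {
  aif <- AifParams()
  tt <- dceTimes()
  set.seed(11)
  noise <- matrix(rnorm(10 * length(tt), 0, 0.02), nrow = 10)
  m <- fitVoxelKinetics(curveSet(noise, tt), aif)
  expect_true(all(m@r2[!is.na(m@r2)] < 0.85 | is.infinite(m@r2)))
  expect_true(all(m@zone == "unfit"))
  mz <- fitVoxelKinetics(curveSet(rep(0, length(tt)), tt), aif)
  expect_identical(mz@zone[1], "unfit")
})

test_that("zone classifier reproduces the generator phenotypes", {
  aif <- AifParams()
  tt <- dceTimes()
  viable <- solveTwoCompartment(list(phi = 0.3, psv = 2e-3, jvv = 1e-4), aif, tt)
  hypoxic <- solveTwoCompartment(list(phi = 0.3, psv = 5e-4, jvv = 2e-5), aif, tt)
  necrotic <- solveTwoCompartment(list(phi = 0.4, psv = 0, jvv = 2e-5), aif, tt)
  ## template sanity: construction matches the intended phenotypes
  wash <- function(y) (max(y) - y[length(y)]) / max(y)
  ttp <- function(y) tt[which.max(y)] - aif@bolusArrival
  expect_lt(ttp(viable), 180); expect_gt(wash(viable), 0.2)
  expect_gt(ttp(hypoxic), 180); expect_lt(wash(hypoxic), 0.2)
  expect_lt(wash(necrotic), 0.1)   # monotone accumulation, no washout
  expect_true(all(diff(necrotic) >= -1e-12))

  tcs <- curveSet(rbind(viable, hypoxic, necrotic), tt)
  m <- classifyZones(fitVoxelKinetics(tcs, aif), tcs, aif)
  expect_identical(m@zone, c("viable", "hypoxic", "necrotic"))

  ## noiseless templates classify correctly in >= 95% of replicates
  reps <- curveSet(rbind(viable, viable, hypoxic, hypoxic, necrotic, necrotic),
                   tt)
  mr <- classifyZones(fitVoxelKinetics(reps, aif), reps, aif)
  expect_identical(mr@zone, c("viable", "viable", "hypoxic", "hypoxic",
                              "necrotic", "necrotic"))
})

test_that("LpS/V rescaling: baseline product, zero-flow voxels, and
           normalisation invariance", {
  aif <- AifParams()
  tt <- dceTimes(300)
  set.seed(3)
  jv <- runif(20, 2e-5, 3e-4)
  curves <- t(vapply(jv, function(j)
    solveTwoCompartment(list(phi = 0.3, psv = 2e-3, jvv = j), aif, tt),
    numeric(length(tt))))
  tcs <- curveSet(curves, tt)
  m <- classifyZones(fitVoxelKinetics(tcs, aif), tcs, aif)
  m <- rescaleToLpsv(m)
  fitted <- m@zone %in% c("viable", "hypoxic")
  ## mean over fitted voxels is exactly Lp0 * SV0
  expect_equal(mean(m@lpsv[fitted]), 2.1e-11 * 2.0e4, tolerance = 1e-12)
  ## a voxel at the average Jv/V gets exactly the baseline product
  mm <- m; mm@jvv <- rep(1e-4, 20)
  mm <- rescaleToLpsv(mm)
  expect_equal(mm@lpsv[1], 4.2e-7, tolerance = 1e-12)
  ## doubling every Jv/V changes nothing
  m2 <- m; m2@jvv <- 2 * m@jvv
  m2 <- rescaleToLpsv(m2)
  expect_equal(m2@lpsv, m@lpsv, tolerance = 1e-12)
  ## zero filtration -> zero coefficient
  m3 <- m; m3@jvv[1] <- 0
  expect_equal(rescaleToLpsv(m3)@lpsv[1], 0)
})

test_that("necrotic voxels are excluded from the Jv/V normalisation", {
  m <- new("VascularMap", voxelIndex = cbind(1:4, rep(1L, 4)),
           phi = rep(0.3, 4), psv = rep(2e-3, 4),
           jvv = c(1e-4, 3e-4, 5e-2, 1e-2),
           r2 = c(0.99, 0.95, 0.2, 0.1),
           zone = c("viable", "viable", "necrotic", "unfit"),
           lpsv = numeric(4))
  m <- rescaleToLpsv(m)
  expect_equal(mean(m@lpsv[1:2]), 4.2e-7, tolerance = 1e-12)
  expect_equal(m@lpsv[3:4], c(0, 0))
  mAllNec <- m; mAllNec@zone <- rep("necrotic", 4)
  expect_error(rescaleToLpsv(mAllNec), "no fitted")
})
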