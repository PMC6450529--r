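test_that("effective pressure follows the Starling equilibrium", {
  vc <- VascularConstants(pv = 2078, sigmaOsm = 0.82, piV = 2666, piI = 2000)
  expect_equal(effectivePressure(vc), 2078 - 0.82 * 666)   # 1531.88 Pa
  expect_equal(effectivePressure(VascularConstants(sigmaOsm = 0)), 2078)
  vc0 <- VascularConstants(pv = 0.82 * 666)
  expect_equal(effectivePressure(vc0), 0)
})

test_that("Starling source is linear in the pressure deficit", {
  vc <- VascularConstants()
  pe <- effectivePressure(vc)
  expect_equal(starlingSource(pe, 4.2e-7, vc), 0)
  expect_equal(starlingSource(0, 4.2e-7, vc), 4.2e-7 * pe)  # 6.43e-4 1/s
  expect_equal(starlingSource(500, 0, vc), 0)
  expect_error(starlingSource(0, -1e-9, vc), "lpsv")
})

test_that("homogeneous sphere pressure matches the radial closed form", {
  vc <- VascularConstants()
  dom <- sphereDomain(3, 0.12)
  sol <- solveIfp(dom, 4.2e-7, vc)
  ana <- sphereAnalytic(dom, 3, 4.2e-7, vc)
  err <- abs(sol@pressure[ana$cells] - ana$p)
  expect_lt(max(err) / ana$Pe, 0.02)
  expect_equal(ana$alpha, 11.04, tolerance = 0.01)
  ## residual history shows at least a 4-order drop
  rh <- sol@residualHistory
  expect_lt(rh[length(rh)], 1e-4)
})

test_that("maximum principle and trivial cases hold", {
  vc <- VascularConstants()
  pe <- effectivePressure(vc)
  dom <- sphereDomain(1.5, 0.15)
  ## zero source -> zero pressure
  s0 <- solveIfp(dom, 0, vc)
  expect_equal(max(abs(s0@pressure), na.rm = TRUE), 0)
  s1 <- solveIfp(dom, 4.2e-7, vc)
  p <- s1@pressure[dom@labelGrid > 0]
  expect_gte(min(p), 0)
  expect_lte(max(p), pe)
})

test_that("global Starling influx balances the boundary outflux", {
  vc <- VascularConstants()
  dom <- sphereDomain(1.5, 0.1)
  lpsv <- 4.2e-7
  sol <- solveIfp(dom, lpsv, vc, rtol = 1e-10)
  hm <- dom@spacing * 1e-3
  vol <- prod(hm)
  p <- sol@pressure[dom@labelGrid > 0]
  influx <- sum(lpsv * (effectivePressure(vc) - p)) * vol
  fv <- ipcFlow:::.faceVelocities(sol, vc)
  bf <- fv$boundary
  outflux <- sum(bf$u * bf$side * vol / hm[bf$axis])
  expect_lt(abs(influx - outflux) / influx, 0.01)
})

test_that("pressure is monotone in the source coefficient and a necrotic
           core only lowers it", {
  vc <- VascularConstants()
  dom <- sphereDomain(1.5, 0.15)
  pLow <- solveIfp(dom, 2e-7, vc)@pressure
  pHigh <- solveIfp(dom, 4.2e-7, vc)@pressure
  inside <- dom@labelGrid > 0
  expect_true(all(pHigh[inside] >= pLow[inside] - 1e-9))

  ## two-zone sphere with a dead core: everywhere <= homogeneous
  spec <- PhantomSpec(tumorSemiAxes = rep(1.5, 3), voxelSpacing = 0.15,
                      interiorOffset = c(0, 0, 0),
                      interiorSemiAxes = rep(0.7, 3),
                      interiorPhenotype = "necrotic")
  dom2 <- makePhantomDomain(spec)$domain
  pCore <- solveIfp(dom2, c(4.2e-7, 0), vc)@pressure
  expect_true(all(pCore[inside] <= pHigh[inside] + 1e-9))
  ## and the coarse two-zone field agrees with a finer-grid reference
  spec3 <- spec; spec3@voxelSpacing <- rep(0.075, 3)
  dom3 <- makePhantomDomain(spec3)$domain
  pFine <- solveIfp(dom3, c(4.2e-7, 0), vc)@pressure
  expect_equal(max(pCore, na.rm = TRUE), max(pFine, na.rm = TRUE),
               tolerance = 0.05)
})

test_that("velocity is Darcy-consistent: zero at the centre, radial profile
           matches the analytic gradient", {
  vc <- VascularConstants()
  dom <- sphereDomain(1.5, 0.1)
  sol <- computeVelocity(solveIfp(dom, 4.2e-7, vc), vc)
  ana <- sphereAnalytic(dom, 1.5, 4.2e-7, vc)
  K <- vc@kTissue; Rm <- 1.5e-3; alpha <- ana$alpha
  rm_ <- pmax(ana$r, 1e-6) * 1e-3
  dPdr <- -ana$Pe * Rm * ((alpha / (Rm * rm_)) * cosh(alpha * rm_ / Rm) -
                          sinh(alpha * rm_ / Rm) / rm_^2) / sinh(alpha)
  uAna <- -K * dPdr
  speed <- sqrt(sol@velocity$x[ana$cells]^2 + sol@velocity$y[ana$cells]^2 +
                sol@velocity$z[ana$cells]^2)
  sel <- ana$r > 0.3 & ana$r < 1.35      # away from r = 0 and the staircase
  expect_lt(max(abs(speed[sel] - uAna[sel])) / max(uAna[sel]), 0.03)
  ## centre velocity vanishes by symmetry
  ctrCell <- ana$cells[which.min(ana$r)]
  expect_lt(abs(sol@velocity$x[ctrCell]), 1e-2 * max(speed))
  ## uniform pressure (zero source) -> zero velocity
  s0 <- computeVelocity(solveIfp(dom, 0, vc), vc)
  expect_equal(max(abs(s0@velocity$x), na.rm = TRUE), 0)
})
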