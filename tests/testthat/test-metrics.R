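## an analytic box domain with a linear-in-x field for profile bookkeeping
boxWithField <- function(f, nx = 40, ny = 20, h = 0.2) {
  lab <- array(0L, c(nx + 2, ny + 2, 5))
  lab[2:(nx + 1), 2:(ny + 1), 2:4] <- 1L
  dom <- buildDomain(lab, h)
  dims <- dim(lab)
  arr <- array(NA_real_, dims)
  cells <- which(lab > 0)
  ijk <- arrayInd(cells, dims)
  arr[cells] <- f((ijk[, 1] - 0.5) * h, (ijk[, 2] - 0.5) * h)
  list(domain = dom, field = arr)
}

test_that("profiles: constant and linear fields sample exactly", {
  bx <- boxWithField(function(x, y) 7 + 0 * x)
  dom <- defineAxes(bx$domain)
  prof <- extractProfile(bx$field, dom, "LA")
  expect_gte(nrow(prof), 200)
  expect_equal(unique(round(prof$value, 10)), 7)
  ## linear field samples linearly, and length bookkeeping is consistent
  bx2 <- boxWithField(function(x, y) 3 * x)
  dom2 <- defineAxes(bx2$domain)
  prof2 <- extractProfile(bx2$field, dom2, "LA")
  ## the long axis of a box is its diagonal: the profile slope is the field
  ## gradient projected on the axis direction
  ax <- dom2@axes$LA
  dirx <- (ax$p1[1] - ax$p0[1]) / ax$length
  inner <- 20:180                         # away from the NA-padded surface
  slopes <- diff(prof2$value)[inner] / diff(prof2$x)[inner]
  expect_equal(unname(median(slopes)), 3 * dirx, tolerance = 0.02)
  expect_equal(prof2$s, prof2$x / dom2@axes$LA$length, tolerance = 1e-12)
})

test_that("LP50: ramp, step and tanh-family crossings", {
  mk <- function(v, L = 8) data.frame(s = seq(0, 1, length.out = length(v)),
                                      x = seq(0, L, length.out = length(v)),
                                      value = v)
  n <- 401
  x <- seq(0, 8, length.out = n)
  ## symmetric ramp 0 -> Pmax at the midpoint: LP50 = quarter length
  ramp <- pmin(x, 8 - x)
  lp <- computeLp50(mk(ramp))
  expect_equal(unname(lp["L"]), 2, tolerance = 0.01)
  expect_equal(unname(lp["R"]), 2, tolerance = 0.01)
  ## step to Pmax at the first interior sample: LP50 <= one spacing
  step <- c(0, rep(10, n - 1))
  expect_lte(max(computeLp50(mk(step))), 8 / (n - 1))
  ## plateau profile with tanh shoulders: crossing at the analytic inverse
  lam <- 0.7
  plateau <- tanh(x / lam) * tanh((8 - x) / lam)
  lpT <- computeLp50(mk(plateau))
  xAna <- lam * atanh(0.5 * max(plateau))
  expect_lt(abs(lpT["L"] - xAna), 8 / (n - 1))
  ## steeper shoulders give smaller LP50
  lpSteep <- computeLp50(mk(tanh(x / 0.3) * tanh((8 - x) / 0.3)))
  expect_lt(lpSteep["L"], lpT["L"])
  ## flat-zero profile is undefined
  expect_true(all(is.na(computeLp50(mk(rep(0, n))))))
})

test_that("penetration: saturated, decaying and empty profiles", {
  n <- 401
  L <- 6
  x <- seq(0, L, length.out = n)
  mk <- function(v) data.frame(s = x / L, x = x, value = v)
  cb <- 0.113
  ## uniform at the surface concentration: 50% per side of the midpoint
  full <- computePenetration(mk(rep(cb, n)), ic50 = 5e-3)
  expect_equal(full$pdPct, c(50, 50), tolerance = 0.5)
  expect_equal(full$apd, c(L, L), tolerance = 1e-9)
  ## exponential decay from both edges: apd = lambda ln(cb/ic50)
  lam <- 0.4
  prof <- cb * (exp(-x / lam) + exp(-(L - x) / lam))
  pen <- computePenetration(mk(prof), ic50 = 5e-3)
  apdAna <- lam * log(cb / 5e-3)
  expect_lt(abs(pen$apd[1] - apdAna), L / (n - 1))
  expect_lt(abs(pen$apd[2] - apdAna), L / (n - 1))
  ## all-below threshold
  zero <- computePenetration(mk(rep(0, n)), ic50 = 5e-3)
  expect_equal(zero$apd, c(0, 0))
  expect_equal(zero$pdPct, c(0, 0))
  ## monotone in ic50
  pen2 <- computePenetration(mk(prof), ic50 = 1e-2)
  expect_true(all(pen2$apd <= pen$apd))
  expect_true(all(pen2$pdPct <= pen$pdPct))
})

test_that("penetrated volume fraction against an analytic shell", {
  vc <- VascularConstants()
  dom <- sphereDomain(2, 0.1)
  ## synthetic radial field c(r) = cb * exp(-(R - r)/lambda)
  dims <- dim(dom@labelGrid)
  cells <- which(dom@labelGrid > 0)
  ijk <- arrayInd(cells, dims)
  ctr <- dims * 0.1 / 2
  r <- sqrt(((ijk[, 1] - 0.5) * 0.1 - ctr[1])^2 +
            ((ijk[, 2] - 0.5) * 0.1 - ctr[2])^2 +
            ((ijk[, 3] - 0.5) * 0.1 - ctr[3])^2)
  cb <- 0.113; lam <- 0.5
  cfield <- cb * exp(-(2 - r) / lam)
  sol <- new("FieldSolution", domain = dom,
             pressure = array(NA_real_, dims),
             drug = cbind(cfield), drugTimes = 1800)
  ic50 <- 5e-3
  rIn <- 2 - lam * log(cb / ic50)          # penetrated shell inner radius
  pAna <- 100 * (1 - rIn^3 / 2^3)
  expect_equal(computePvol(sol, ic50), pAna, tolerance = 2)
  ## threshold limits
  expect_equal(computePvol(sol, 1e-9), 100)
  expect_equal(computePvol(sol, 1), 0)
})

test_that("pressure unit conversion and solid-stress arithmetic", {
  expect_equal(mmHgToPa(0), 0)
  expect_equal(mmHgToPa(19), 2533)
  expect_equal(mmHgToPa(15.5), 2066)    # 2066.49 Pa exactly
  expect_equal(solidStressResidual(2067, 1385), 682)
  expect_equal(solidStressResidual(2890, 1523), 1367)
  expect_equal(solidStressResidual(2533, 1428), 1105)
  expect_equal(solidStressResidual(1500, 1500), 0)
  expect_warning(r <- solidStressResidual(1000, 1200), "negative")
  expect_equal(r, -200)
})
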