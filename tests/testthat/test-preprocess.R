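# Velocity corrections and the QC gate.

test_that("static-tissue rule keeps quiet voxels and drops moving ones", {
  d <- c(10L, 10L, 10L); nt <- 8L
  # zero everywhere -> all static
  flow0 <- uniformFlow(c(0, 0, 0), d, nt)
  expect_equal(sum(detectStaticTissue(flow0, 0.02)@data), prod(d))

  # a moving jet block (temporal std 0.5 m/s) in a zero background
  vel <- array(0, c(d, nt, 3L))
  for (t in seq_len(nt)) vel[3:5, 3:5, 3:5, t, 1L] <- 0.5 * (-1)^t
  flow <- velocityField4D(vel, 2, 25, 120)
  st <- detectStaticTissue(flow, 0.02)@data
  expect_equal(st[3:5, 3:5, 3:5], array(0, c(3, 3, 3)))
  expect_equal(sum(st), prod(d) - 27)

  # direct check of the std rule: noise sigma 0.01 everywhere vs 0.05 gate
  set.seed(5)
  veln <- array(rnorm(prod(d) * nt * 3, 0, 0.01), c(d, nt, 3L))
  flown <- velocityField4D(veln, 2, 25, 120)
  expect_equal(sum(detectStaticTissue(flown, 0.05)@data), prod(d))
})

test_that("polynomial background fit removes exactly what it models", {
  d <- c(12L, 12L, 12L); nt <- 6L
  flow0 <- uniformFlow(c(0, 0, 0), d, nt, spacing = 4)
  static <- detectStaticTissue(flow0, 0.02)

  # constant offset is a degree-0 polynomial: removed exactly
  flowC <- uniformFlow(c(0.05, 0, 0), d, nt, spacing = 4)
  corr <- correctBackground(flowC, static, order = 4L)
  expect_lt(max(abs(corr@data)), 1e-12)

  # a full degree-4 offset injected into a zero field is recovered
  spec <- phantomSpec(grid = d, spacing = 4, nFrames = nt,
                      backgroundPolyCoeffs = list(
                        c(0.05, 0.02, -0.03, 0.01, rep(0.008, 31)),
                        c(-0.02, 0.015), c(0.01)))
  dirty <- injectArtifacts(flow0, spec)
  clean <- correctBackground(dirty, static, order = 4L)
  rms <- sqrt(mean(clean@data^2))
  expect_lt(rms, 1e-9)

  # physiologic flow inside the lumen is untouched when the fit support is
  # the static tissue outside it
  vel <- array(0, c(d, nt, 3L))
  lum <- array(FALSE, d); lum[5:8, 5:8, 5:8] <- TRUE
  for (t in seq_len(nt))
    vel[, , , t, 1L] <- 0.8 * sin(2 * pi * t / nt) * lum
  flowL <- velocityField4D(vel, 4, 25, 120)
  staticOut <- detectStaticTissue(flowL, 0.02)
  expect_equal(sum(staticOut@data[lum]), 0)
  dirtyL <- injectArtifacts(flowL, spec)
  cleanL <- correctBackground(dirtyL, staticOut, order = 4L)
  expect_lt(sqrt(mean((cleanL@data - vel)^2)), 1e-9)

  # idempotence
  twice <- correctBackground(cleanL, staticOut, order = 4L)
  expect_lt(max(abs(twice@data - cleanL@data)), 1e-9)
})

test_that("background fit demands a well-posed design", {
  d <- c(12L, 12L, 12L); nt <- 4L
  flow <- uniformFlow(c(0, 0, 0), d, nt)
  # too few static voxels for 35 coefficients
  st <- array(0, d); st[1:3, 1, 1] <- 1
  expect_error(correctBackground(flow, new("StaticTissueMask", data = st)),
               "static voxels")
  # enough voxels but all co-planar: rank deficient
  st2 <- array(0, d); st2[, , 1] <- 1
  expect_error(correctBackground(flow, new("StaticTissueMask", data = st2)),
               "rank-deficient")
})

test_that("temporal unwrapping inverts aliasing and is idempotent", {
  d <- c(8L, 8L, 8L); nt <- 40L
  # sinusoid of amplitude 1.5 m/s against venc 1.2: heavily wrapped
  t <- seq_len(nt)
  vel <- array(0, c(d, nt, 3L))
  for (f in t) vel[, , , f, 1L] <- 1.5 * sin(2 * pi * (f - 1) / nt)
  truth <- velocityField4D(vel, 2, 25, venc = 120)
  wrapped <- injectArtifacts(truth, phantomSpec(grid = d, nFrames = nt,
                                                wrapVenc = 120))
  expect_gt(max(abs(wrapped@data - truth@data)), 1)   # wrapping did occur
  rec <- unwrapTemporal(wrapped)
  expect_lt(max(abs(rec@data - truth@data)), 1e-12)

  # wrap-free data are untouched
  again <- unwrapTemporal(rec)
  expect_equal(again@data, rec@data, tolerance = 0)

  # output has no consecutive jump above venc, and re-wrapping the result
  # reproduces the wrapped input
  dmax <- max(abs(apply(rec@data, c(1, 2, 3, 5), diff)))
  expect_lt(dmax, 1.2)
  rewrap <- injectArtifacts(rec, phantomSpec(grid = d, nFrames = nt,
                                             wrapVenc = 120))
  expect_lt(max(abs(rewrap@data - wrapped@data)), 1e-12)
})

test_that("single-frame spikes above venc are pulled back", {
  d <- c(8L, 8L, 8L); nt <- 10L
  vel <- array(0, c(d, nt, 3L))
  vel[, , , 5L, 1L] <- 2.0                      # jumps of 2.0 > venc 1.2
  flow <- velocityField4D(vel, 2, 25, venc = 120)
  rec <- unwrapTemporal(flow)
  jumps <- abs(diff(rec@data[1, 1, 1, , 1L]))
  expect_true(all(jumps <= 1.2 + 1e-12))
})

test_that("mask time resampling is nearest-neighbour and count-preserving", {
  set.seed(7)
  d <- c(8L, 8L, 8L)
  src <- array(rbinom(prod(d) * 30L, 1, 0.4), c(d, 30L))
  src[1, 1, 1, ] <- 1
  m <- mask4D(src, 2)
  # identity when counts match
  expect_equal(resampleMaskTime(m, 30L)@data, src)
  # 30 -> 40: every output frame is exactly one input frame
  out <- resampleMaskTime(m, 40L)
  expect_equal(nFrames(out), 40L)
  for (t in seq_len(40L)) {
    srcIdx <- (round((t - 1) * 30 / 40) %% 30) + 1
    expect_equal(out@data[, , , t], src[, , , srcIdx])
  }
  # constant-in-time mask stays constant
  cm <- mask4D(array(rep(src[, , , 1L], 5L), c(d, 5L)), 2)
  outc <- resampleMaskTime(cm, 12L)
  for (t in 1:12) expect_equal(outc@data[, , , t], src[, , , 1L])
})

test_that("inflow/outflow discrepancy gate reproduces the volume arithmetic", {
  d <- c(16L, 16L, 16L); nt <- 20L
  phases <- new("CardiacPhases", systole = 1:10, diastole = 11:20,
                eWave = integer(0), aWave = integer(0), dt = 0.025,
                eDefined = FALSE)
  mkflow <- function(vSys, vDia) {
    vel <- array(0, c(d, nt, 3L))
    vel[, , , phases@systole, 3L] <- vSys
    vel[, , , phases@diastole, 3L] <- vDia
    velocityField4D(vel, 4, 25, 120)
  }
  mv <- flowDisc(c(0, 0, 10), c(0, 0, 1), radius = 12)
  ao <- flowDisc(c(0, 0, -10), c(0, 0, 1), radius = 12)

  # identical pulse through both discs -> discrepancy 0
  qc0 <- flowDiscrepancy(mkflow(0.5, 0.5), mv, ao, phases)
  expect_equal(qc0$discrepancy, 0, tolerance = 1e-12)
  expect_true(qc0$pass)

  # volumes in ratio 60:80 -> |80-60|/70, fail
  qc1 <- flowDiscrepancy(mkflow(0.6, 0.8), mv, ao, phases)
  expect_equal(qc1$discrepancy, 20 / 70, tolerance = 1e-9)
  expect_false(qc1$pass)

  # 90:100 -> 10/95, pass
  qc2 <- flowDiscrepancy(mkflow(0.9, 1.0), mv, ao, phases)
  expect_equal(qc2$discrepancy, 10 / 95, tolerance = 1e-9)
  expect_true(qc2$pass)

  # absolute volume check: uniform 0.5 m/s over a 12 mm disc for 10 frames
  expect_equal(qc0$inflow_ml, 0.5 * pi * 0.012^2 * 10 * 0.025 * 1e6,
               tolerance = 1e-9)
})
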