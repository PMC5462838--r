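# Masked derivatives, Navier-Stokes assembly, force integration,
# projection, and the ratio metrics.

test_that("masked gradient is exact for linear fields up to the walls", {
  d <- c(10L, 10L, 10L)
  g <- hemoforce:::.coordGrids(d, hemoforce:::.centeredAffine(d, c(1, 1, 1)))
  f <- 2 * (g$X * 1e-3)                       # f = 2x with x in metres
  m <- array(TRUE, d)
  gr <- maskedGradient(f, m, spacing = c(1e-3, 1e-3, 1e-3))
  expect_equal(gr$dx, array(2, d), tolerance = 1e-12)
  expect_equal(gr$dy, array(0, d), tolerance = 1e-12)
  # constant field -> zero gradient
  gr0 <- maskedGradient(array(5, d), m, rep(1e-3, 3))
  expect_equal(gr0$dz, array(0, d), tolerance = 1e-12)
})

test_that("quadratic fields expose the one-sided boundary error exactly", {
  # f = x^2: central differences are exact, one-sided differences at the
  # wall err by h * f''/2 = h (Taylor)
  d <- c(12L, 8L, 8L)
  h <- 2e-3
  aff <- hemoforce:::.centeredAffine(d, c(2, 2, 2))
  g <- hemoforce:::.coordGrids(d, aff)
  X <- g$X * 1e-3
  f <- X^2
  m <- array(TRUE, d)
  gr <- maskedGradient(f, m, rep(h, 3))
  interior <- gr$dx[2:11, , ] - 2 * X[2:11, , ]
  expect_lt(max(abs(interior)), 1e-12)
  expect_equal(gr$dx[1, 1, 1], 2 * X[1, 1, 1] + h, tolerance = 1e-9)
  expect_equal(gr$dx[12, 1, 1], 2 * X[12, 1, 1] - h, tolerance = 1e-9)
})

test_that("mask is a hard boundary: outside voxels never contribute", {
  d <- c(10L, 10L, 10L)
  f <- array(1e6, d)                           # poison outside values
  m <- array(FALSE, d); m[4:7, 4:7, 4:7] <- TRUE
  f[m] <- 3
  gr <- maskedGradient(f, m, rep(1e-3, 3))
  expect_true(all(is.na(gr$dx[!m])))
  expect_equal(gr$dx[m], rep(0, sum(m)), tolerance = 1e-9)
  # single-voxel mask: all flagged, no error
  m1 <- array(FALSE, d); m1[5, 5, 5] <- TRUE
  gr1 <- maskedGradient(f, m1, rep(1e-3, 3))
  expect_true(is.na(gr1$dx[5, 5, 5]))
})

test_that("pressure gradient matches closed forms on the analytic phantoms", {
  # spatially uniform steady flow: all three terms vanish
  flow <- uniformFlow(c(0.5, 0, 0), c(10L, 10L, 10L), 6L)
  gp <- pressureGradientNS(flow, fullMask(c(10L, 10L, 10L), 6L))
  expect_lt(max(abs(gp@data)), 1e-10)

  # oscillating uniform: only the inertial term survives (small grid)
  osc <- genAnalytic(phantomSpec("oscillating_uniform", grid = c(10, 10, 10),
                                 nFrames = 40, dt = 25, period = 1))
  expect_lt(gradpNormError(osc), 0.005)

  # steady stagnation flow: only the convective term survives, exactly
  stag <- genAnalytic(phantomSpec("stagnation", grid = c(12, 12, 12),
                                  nFrames = 4, dt = 25))
  expect_lt(gradpNormError(stag), 1e-9)

  # frame-count mismatch is a geometry error
  expect_error(pressureGradientNS(flow, fullMask(c(10L, 10L, 10L), 5L)),
               "congruent")
})

test_that("force integration is the voxel-volume-weighted gradient sum", {
  d <- c(10L, 10L, 10L); nt <- 3L
  mask <- fullMask(d, nt, spacing = 2)
  gdat <- array(NA_real_, c(d, nt, 3L))
  gdat[, , , , 1L] <- 10                       # uniform 10 Pa/m along x
  gdat[, , , , 2L] <- 0
  gdat[, , , , 3L] <- 0
  gp <- new("PressureGradientField", data = gdat, mask = mask)
  fs <- integrateForce(gp, mask, dt = 0.025)
  expect_equal(fs@F[, 1L], rep(10 * 1000 * 8e-9, nt), tolerance = 1e-12)
  expect_equal(fs@F[, 2L], rep(0, nt))

  # flagged-missing components contribute zero
  gdat[1, 1, 1, , 1L] <- NA
  gp2 <- new("PressureGradientField", data = gdat, mask = mask)
  fs2 <- integrateForce(gp2, mask, dt = 0.025)
  expect_equal(fs2@F[, 1L], rep(10 * 999 * 8e-9, nt), tolerance = 1e-12)

  # zero gradient -> zero force
  gdat[] <- 0
  fs0 <- integrateForce(new("PressureGradientField", data = gdat,
                            mask = mask), mask, dt = 0.025)
  expect_equal(fs0@F, matrix(0, nt, 3L))
})

test_that("oscillating-uniform force magnitude follows the closed form", {
  # |F| = rho * A * (2 pi / T) * Omega * |cos|, within the O(dt^2) bound
  sp <- phantomSpec("oscillating_uniform", grid = c(10, 10, 10),
                    spacing = 2.8, nFrames = 40, dt = 25, period = 1,
                    amplitude = 0.5)
  ph <- genAnalytic(sp)
  gp <- pressureGradientNS(ph$flow, ph$mask)
  fs <- integrateForce(gp, ph$mask, dt = 0.025)
  omega <- 1000 * 2.8e-3^3
  tS <- (0:39) * 0.025
  expected <- 1060 * 0.5 * 2 * pi * abs(cos(2 * pi * tS)) * omega
  got <- sqrt(rowSums(fs@F^2))
  expect_lt(max(abs(got - expected)) / max(expected), 0.02)
})

test_that("axis frame construction is orthonormal and equivariant", {
  lm <- landmarks(c(0, 0, 0), c(0, 0, 80), c(25, 0, 75))
  fr <- buildAxisFrame(lm)
  expect_equal(fr@laxUnit, c(0, 0, 1))
  expect_equal(fr@saxUnit, c(-1, 0, 0))
  expect_lt(abs(sum(fr@laxUnit * fr@saxUnit)), 1e-12)

  # rotating the landmarks rotates the frame by exactly the same rotation
  th <- 0.7; ph <- -1.2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  R <- Rx %*% Rz
  lmR <- landmarks(R %*% c(0, 0, 0), R %*% c(0, 0, 80), R %*% c(25, 0, 75))
  frR <- buildAxisFrame(lmR)
  expect_equal(frR@laxUnit, as.numeric(R %*% fr@laxUnit), tolerance = 1e-12)
  expect_equal(frR@saxUnit, as.numeric(R %*% fr@saxUnit), tolerance = 1e-12)

  # degenerate geometry: aortic on the long axis
  expect_error(buildAxisFrame(landmarks(c(0, 0, 0), c(0, 0, 80),
                                        c(0, 0, 40) + 1e-12)),
               "degenerate|collinear")
})

test_that("force projection obeys the Pythagorean bound and 45-degree split", {
  fr <- buildAxisFrame(landmarks(c(0, 0, 0), c(0, 0, 80), c(25, 0, 75)))
  mk <- function(Fm) new("ForceSeries", F = Fm, fLax = numeric(0),
                         fSax = numeric(0), dt = 0.025)
  # F along the long axis -> zero short-axis component
  p1 <- projectForce(mk(matrix(c(0, 0, 1), 1)), fr)
  expect_equal(p1@fSax, 0)
  expect_equal(p1@fLax, 1)
  # 1 N at 45 degrees between the axes
  F45 <- matrix((fr@laxUnit + fr@saxUnit) / sqrt(2), 1)
  p2 <- projectForce(mk(F45), fr)
  expect_equal(p2@fLax, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(p2@fSax, sqrt(2) / 2, tolerance = 1e-12)
  # random forces: fLax^2 + fSax^2 <= |F|^2
  set.seed(3)
  Fr <- matrix(rnorm(300), 100, 3)
  pr <- projectForce(mk(Fr), fr)
  expect_true(all(pr@fLax^2 + pr@fSax^2 <= rowSums(Fr^2) + 1e-12))
})

test_that("peak and rms ratios follow their definitions", {
  mk <- function(sax, lax) new("ForceSeries",
                               F = cbind(sax, 0, lax), fLax = lax,
                               fSax = sax, dt = 0.025)
  fs <- mk(c(1, 0.5, 0), c(0, 2, 1))
  r <- ratioMax(fs, 1:3)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$tMaxSax, 0)        # maxima at different frames
  expect_equal(r$tMaxLax, 0.025)
  # magnitudes, sign-independent
  expect_equal(ratioMax(mk(c(-3, 0), c(2, 1)), 1:2)$ratio, 1.5)
  # zero SAx -> ratio 0; zero LAx -> undefined
  expect_equal(ratioMax(mk(c(0, 0), c(1, 2)), 1:2)$ratio, 0)
  expect_error(ratioMax(mk(c(1, 1), c(0, 0)), 1:2), "undefined")

  expect_equal(ratioRms(mk(rep(1, 4), rep(2, 4)), 1:4), 0.5)
  expect_equal(ratioRms(mk(c(3, 1, 2), c(3, 1, 2)), 1:3), 1)
  expect_equal(ratioRms(mk(c(3, 0, 0), c(0, 4, 0)), 1:3),
               sqrt(3) / sqrt(16 / 3), tolerance = 1e-12)
  # scale invariance of both ratios
  fsA <- mk(c(1, -2, 3), c(4, 5, -6))
  fsB <- mk(7.3 * c(1, -2, 3), 7.3 * c(4, 5, -6))
  expect_equal(ratioMax(fsA, 1:3)$ratio, ratioMax(fsB, 1:3)$ratio)
  expect_equal(ratioRms(fsA, 1:3), ratioRms(fsB, 1:3))
  # alternative rms-of-ratio definition differs and matches its formula
  expect_equal(ratioRms(mk(c(1, 4), c(2, 2)), 1:2, "rms_of_ratio"),
               sqrt(mean(c(0.5, 2)^2)))
})

test_that("mirror-symmetric flow yields no force along the mirror normal", {
  stag <- genAnalytic(phantomSpec("stagnation", grid = c(12, 12, 12),
                                  nFrames = 4))
  gp <- pressureGradientNS(stag$flow, stag$mask)
  fs <- integrateForce(gp, stag$mask, dt = 0.025)
  expect_lt(max(abs(fs@F)), 1e-10)
})

test_that("the full chain is invariant under a lattice rotation", {
  # rotate the dataset by 90 degrees about z (x,y) -> (-y,x): permute the
  # lattice, rotate the vector components and the landmarks; every ratio
  # must be unchanged.
  sp <- miniLVSpec(eJetAngle = 35)
  ph <- genLVPhantom(sp)
  rotArr3 <- function(a) aperm(a[, dim(a)[2L]:1, , drop = FALSE],
                               c(2L, 1L, 3L))
  d <- dim(ph$flow@data)
  nt <- d[4L]
  velR <- array(0, c(d[2L], d[1L], d[3L], nt, 3L))
  maskR <- array(0, c(d[2L], d[1L], d[3L], nt))
  for (t in seq_len(nt)) {
    vx <- ph$flow@data[, , , t, 1L]; vy <- ph$flow@data[, , , t, 2L]
    velR[, , , t, 1L] <- rotArr3(-vy)
    velR[, , , t, 2L] <- rotArr3(vx)
    velR[, , , t, 3L] <- rotArr3(ph$flow@data[, , , t, 3L])
    maskR[, , , t] <- rotArr3(ph$mask@data[, , , t])
  }
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  lmR <- landmarks(R %*% ph$landmarks@apex, R %*% ph$landmarks@mitralCenter,
                   R %*% ph$landmarks@aorticCenter,
                   R %*% ph$landmarks@mvProbe, R %*% ph$landmarks@aoProbe)
  flowR <- velocityField4D(velR, sp$spacing, sp$dt, 120)
  maskR <- mask4D(maskR, sp$spacing)

  phases <- segmentCycle(probeSpeed(ph$flow, ph$landmarks@mvProbe),
                         probeSpeed(ph$flow, ph$landmarks@aoProbe),
                         sp$dt / 1000)
  m0 <- computeSubjectMetrics(ph$flow, ph$mask, ph$landmarks, phases)
  m1 <- computeSubjectMetrics(flowR, maskR, lmR, phases)
  expect_equal(m1$ratioMaxE, m0$ratioMaxE, tolerance = 1e-9)
  expect_equal(m1$ratioMaxA, m0$ratioMaxA, tolerance = 1e-9)
  expect_equal(m1$ratioRmsFull, m0$ratioRmsFull, tolerance = 1e-9)
})

test_that("metrics report undefined E-phase fields but keep A fields", {
  ph <- genLVPhantom(miniLVSpec(eJetAngle = 20))
  phases <- segmentCycle(probeSpeed(ph$flow, ph$landmarks@mvProbe),
                         probeSpeed(ph$flow, ph$landmarks@aoProbe), 1 / 24)
  # forge an E-undefined phase set that keeps the A window
  noE <- new("CardiacPhases", systole = phases@systole,
             diastole = phases@diastole, eWave = integer(0),
             aWave = phases@aWave, dt = phases@dt, eDefined = FALSE)
  m <- computeSubjectMetrics(ph$flow, ph$mask, ph$landmarks, noE)
  expect_true(is.na(m$ratioMaxE))
  expect_true(is.na(m$ratioRmsE))
  expect_false(is.na(m$ratioMaxA))
  expect_false(m$eDefined)
})
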