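# Shared fixtures: small grids and phantom helpers built in code.

# 2-layer erosion of a 3D logical mask (the "interior" used when comparing
# discrete derivatives against closed forms: the wide second-difference
# stencil needs two in-mask neighbours each side).
erode2 <- function(m) {
  for (r in 1:2) {
    m2 <- m
    for (ax in 1:3) for (by in c(-1L, 1L))
      m2 <- m2 & hemoforce:::.shift3(m, ax, by, fill = FALSE)
    m <- m2
  }
  m
}

# Worst-case normalized gradient error of the estimator against the
# phantom's closed form, over interior voxels of all frames; normalization
# is the peak exact-gradient magnitude (so zero-crossing frames do not
# blow up a pointwise quotient).
gradpNormError <- function(phantom, constants = fluidConstants()) {
  gp <- pressureGradientNS(phantom$flow, phantom$mask, constants)
  d <- dim(phantom$mask@data)[1:3]
  nt <- nFrames(phantom$flow)
  worst <- 0; scale <- 0
  for (t in seq_len(nt)) {
    ex <- phantom$gradp(t)
    m <- erode2(array(phantom$mask@data[, , , t] > 0, d))
    scale <- max(scale, max(abs(ex)))
    for (c in 1:3) {
      e <- abs(gp@data[, , , t, c][m] - ex[, , , c][m])
      worst <- max(worst, max(e, na.rm = TRUE))
    }
  }
  worst / scale
}

# Small uniform flow field: constant vector v0 at every voxel and frame.
uniformFlow <- function(v0, d = c(10L, 10L, 10L), nt = 6L, spacing = 2,
                        dt = 25, venc = 120) {
  vel <- array(0, c(d, nt, 3L))
  for (c in 1:3) vel[, , , , c] <- v0[c]
  velocityField4D(vel, spacing, dt, venc)
}

fullMask <- function(d = c(10L, 10L, 10L), nt = 6L, spacing = 2) {
  mask4D(array(1, c(d, nt)), spacing)
}

# Reduced-size LV phantom sharing the full phantom's physical anatomy
# (same mm extents, coarser lattice and fewer frames) for cohort-scale
# tests.
miniLVSpec <- function(...) {
  phantomSpec(kind = "lv_filling", grid = c(16L, 16L, 24L), spacing = 5.6,
              nFrames = 24L, dt = 1000 / 24, ...)
}

# Two-bump transmitral speed curve plus a systolic aortic bump, the
# canonical phase-detection input. Peaks at frames 18 and 32 of 40.
speedCurves <- function(n = 40L, ePeak = 18L, aPeak = 32L, eAmp = 1,
                        aAmp = 0.7, noiseSd = 0) {
  t <- seq_len(n)
  bump <- function(center, width, amp)
    amp * exp(-((t - center) / width)^2)
  ao <- bump(7, 3, 1)
  mv <- bump(ePeak, 3, eAmp) + bump(aPeak, 2.5, aAmp)
  if (noiseSd > 0) {
    mv <- pmax(mv + rnorm(n, 0, noiseSd), 0)
    ao <- pmax(ao + rnorm(n, 0, noiseSd), 0)
  }
  list(mv = mv, ao = ao, ePeak = ePeak, aPeak = aPeak)
}
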