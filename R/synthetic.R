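# Synthetic-data generators: analytic flow fields with closed-form pressure
# gradients, an LV-like biphasic filling phantom, MRI artifact injection and
# two-group cohort simulation.
#
# The phantom velocities are kinematic constructions, not Navier-Stokes
# solutions; the pipeline estimates pressure gradients from whatever
# velocity field it is handed, and the analytic kinds carry the exact
# physics oracle.

#' Phantom specification
#'
#' Describes a synthetic 4D flow dataset. Defaults emulate a typical
#' whole-heart 4D flow acquisition: 2.8 mm isotropic voxels, 40 frames
#' over a 1 s cycle, VENC 120 cm/s.
#'
#' @param kind one of "oscillating_uniform", "stagnation", "poiseuille",
#'   "lv_filling".
#' @param grid integer(3) voxel counts (each >= 8).
#' @param spacing voxel size, mm (isotropic scalar or numeric(3)).
#' @param nFrames number of reconstructed time frames (>= 20 for
#'   "lv_filling").
#' @param dt frame interval, ms.
#' @param amplitude peak speed, m/s.
#' @param period cycle period, s (defaults to nFrames * dt).
#' @param eJetAngle,aJetAngle inflow-jet tilt from the long axis within the
#'   three-chamber plane, degrees in [0, 80].
#' @param jetRadius jet radius, mm.
#' @param noiseSigma additive Gaussian velocity noise SD, m/s.
#' @param backgroundPolyCoeffs optional list of 3 coefficient vectors (one
#'   per velocity component) over the degree-<=4 monomial basis in scaled
#'   world coordinates, used by [injectArtifacts()].
#' @param wrapVenc optional VENC (cm/s) used by [injectArtifacts()] to
#'   alias velocities into (-venc, venc].
#' @param seed RNG seed making generation fully deterministic.
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(kind = c("oscillating_uniform", "stagnation",
                                 "poiseuille", "lv_filling"),
                        grid = c(32L, 32L, 48L), spacing = 2.8,
                        nFrames = 40L, dt = 25, amplitude = 1.0,
                        period = NULL, eJetAngle = 0, aJetAngle = 0,
                        jetRadius = 10, noiseSigma = 0,
                        backgroundPolyCoeffs = NULL, wrapVenc = NULL,
                        seed = 1L) {
  kind <- match.arg(kind)
  grid <- as.integer(grid)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(grid < 8L)) stop("grid must be at least 8 voxels per axis")
  if (kind == "lv_filling" && nFrames < 20L)
    stop("the LV filling phantom needs at least 20 frames")
  if (eJetAngle < 0 || eJetAngle > 80 || aJetAngle < 0 || aJetAngle > 80)
    stop("jet angles must lie in [0, 80] degrees")
  if (is.null(period)) period <- nFrames * dt / 1000
  structure(list(kind = kind, grid = grid, spacing = spacing,
                 nFrames = as.integer(nFrames), dt = dt,
                 amplitude = amplitude, period = period,
                 eJetAngle = eJetAngle, aJetAngle = aJetAngle,
                 jetRadius = jetRadius, noiseSigma = noiseSigma,
                 backgroundPolyCoeffs = backgroundPolyCoeffs,
                 wrapVenc = wrapVenc, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Analytic flow phantoms with closed-form pressure gradients
#'
#' Three exactly solvable fields used as oracles for the pressure-gradient
#' estimator:
#' \itemize{
#' \item \code{oscillating_uniform}: v = A sin(2 pi t / T) x-hat, spatially
#'   uniform; only the inertial term survives, so
#'   grad p = -rho A (2 pi / T) cos(2 pi t / T) x-hat.
#' \item \code{stagnation}: steady planar stagnation flow v = (a x, -a y, 0)
#'   with a = A / L (L the domain half-extent); only the convective term
#'   survives: grad p = -rho a^2 (x, y, 0).
#' \item \code{poiseuille}: steady pipe flow v_z = A (1 - r^2/R^2) inside a
#'   cylinder of radius R = jetRadius; only the viscous term survives:
#'   grad p = -4 mu A / R^2 z-hat.
#' }
#'
#' @param spec a [phantomSpec()] with an analytic `kind`.
#' @param constants [fluidConstants()] used by the closed form.
#' @return list with `flow` ([VelocityField4D-class]), `mask`
#'   ([Mask4D-class]) and `gradp`, a function(frame) returning the exact
#'   pressure gradient array (nx, ny, nz, 3) in Pa/m at that frame.
#' @export
genAnalytic <- function(spec, constants = fluidConstants()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (!spec$kind %in% c("oscillating_uniform", "stagnation", "poiseuille"))
    stop("genAnalytic requires an analytic phantom kind, got ", spec$kind)
  d <- spec$grid; nt <- spec$nFrames
  affine <- .centeredAffine(d, spec$spacing)
  g <- .coordGrids(d, affine)
  Xm <- g$X * 1e-3; Ym <- g$Y * 1e-3; Zm <- g$Z * 1e-3   # world metres
  rho <- constants@rho; mu <- constants@mu
  vel <- array(0, c(d, nt, 3L))
  maskArr <- array(1, c(d, nt))

  if (spec$kind == "oscillating_uniform") {
    A <- spec$amplitude; Tp <- spec$period
    tS <- (seq_len(nt) - 1) * spec$dt / 1000
    for (t in seq_len(nt)) vel[, , , t, 1L] <- A * sin(2 * pi * tS[t] / Tp)
    gradp <- function(frame) {
      out <- array(0, c(d, 3L))
      out[, , , 1L] <- -rho * A * (2 * pi / Tp) * cos(2 * pi * tS[frame] / Tp)
      out
    }
  } else if (spec$kind == "stagnation") {
    L <- max(d * spec$spacing) / 2 * 1e-3
    a <- spec$amplitude / L
    for (t in seq_len(nt)) {
      vel[, , , t, 1L] <- a * Xm
      vel[, , , t, 2L] <- -a * Ym
    }
    gradp <- function(frame) {
      out <- array(0, c(d, 3L))
      out[, , , 1L] <- -rho * a^2 * Xm
      out[, , , 2L] <- -rho * a^2 * Ym
      out
    }
  } else {                                           # poiseuille
    R <- spec$jetRadius * 1e-3
    r2 <- Xm^2 + Ym^2
    inside <- r2 <= R^2
    vz <- spec$amplitude * (1 - r2 / R^2) * inside
    for (t in seq_len(nt)) vel[, , , t, 3L] <- vz
    maskArr <- array(rep(as.numeric(inside), nt), c(d, nt))
    gradp <- function(frame) {
      out <- array(0, c(d, 3L))
      out[, , , 3L] <- -4 * mu * spec$amplitude / R^2
      out
    }
  }
  if (spec$noiseSigma > 0)
    vel <- vel + .withSeed(spec$seed,
                           array(stats::rnorm(length(vel), 0, spec$noiseSigma),
                                 dim(vel)))
  flow <- velocityField4D(vel, spec$spacing, spec$dt, venc = 120,
                          affine = affine)
  list(flow = flow, mask = mask4D(maskArr, spec$spacing, affine = affine),
       gradp = gradp)
}

# Half-sine temporal envelope over 1-based frame window [f0, f1].
.halfSine <- function(nFrames, f0, f1) {
  env <- numeric(nFrames)
  w <- f0:f1
  env[w] <- sin(pi * (w - f0) / (f1 - f0))
  env
}

# Gaussian-profile jet along the line through `entry` (mm) with unit
# direction `dir`; returns speed multiplier array for the lattice coords.
.jetProfile <- function(X, Y, Z, entry, dir, sigma, axialDecay = 60) {
  dx <- X - entry[1L]; dy <- Y - entry[2L]; dz <- Z - entry[3L]
  s <- dx * dir[1L] + dy * dir[2L] + dz * dir[3L]   # axial distance, mm
  p2 <- dx^2 + dy^2 + dz^2 - s^2                    # transverse dist^2
  p2[p2 < 0] <- 0
  exp(-p2 / (2 * sigma^2)) * exp(-(s / axialDecay)^2) * (s >= -sigma)
}

#' LV-like biphasic filling phantom
#'
#' Generates a half-ellipsoidal left-ventricle lumen (truncated at the
#' base plane) whose short semi-axes shrink about 35% in volume during
#' systole and re-expand in diastole, filled with three Gaussian-profile
#' jets with half-sine temporal envelopes: a systolic outflow jet towards
#' the aortic orifice (frames 1-15 of 40), an E-wave inflow jet (frames
#' 19-28) and an A-wave inflow jet (frames 32-39). The inflow jets enter
#' at the mitral annulus centre and are tilted from the apex-directed long
#' axis by \code{eJetAngle} / \code{aJetAngle} within the three-chamber
#' plane, towards the inferolateral wall, which is the controllable
#' dyssynchrony surrogate: a larger E-jet angle produces a larger
#' short-to-long-axis force ratio in early filling.
#'
#' @param spec a [phantomSpec()] with `kind = "lv_filling"`.
#' @return list with `flow`, `mask` and `landmarks`.
#' @export
genLVPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"), spec$kind == "lv_filling")
  d <- spec$grid; nt <- spec$nFrames
  affine <- .centeredAffine(d, spec$spacing)
  g <- .coordGrids(d, affine)                        # mm

  # anatomy (mm): long axis near z, base plane at z = 28
  apex <- c(0, 0, -40)
  mitral <- c(12, 0, 28)
  aortic <- c(-12, 0, 26)
  lm <- landmarks(apex, mitral, aortic,
                  mvProbe = mitral + c(-0.6, 0, -4),
                  aoProbe = aortic + c(0.6, 0, -4))
  laxU <- .unitize(mitral - apex)
  saxV <- (mitral - aortic) - sum((mitral - aortic) * laxU) * laxU
  saxU <- .unitize(saxV)

  # time-varying lumen: ellipsoid centre (0,0,-5), semi-axes (ab, ab, 35)
  zc <- -5; cAx <- 35; abDia <- 26; zBase <- 28
  sysEnd <- max(3L, round(nt * 15 / 40))
  volScale <- numeric(nt)
  fr <- seq_len(nt)
  volScale[fr <= sysEnd] <- 1 - 0.35 * (1 - cos(pi * (fr[fr <= sysEnd] - 1) / (sysEnd - 1))) / 2
  volScale[fr > sysEnd] <- 0.65 + 0.35 * (1 - cos(pi * (fr[fr > sysEnd] - sysEnd) / (nt - sysEnd))) / 2

  maskArr <- array(0, c(d, nt))
  for (t in seq_len(nt)) {
    ab <- abDia * sqrt(volScale[t])
    inside <- (g$X / ab)^2 + (g$Y / ab)^2 + ((g$Z - zc) / cAx)^2 <= 1 &
      g$Z <= zBase
    maskArr[, , , t] <- as.numeric(inside)
  }

  # jet windows scaled to the frame count (defaults: 1-15, 19-28, 32-39 / 40)
  w <- function(a, b) c(max(1L, round(nt * a / 40)), min(nt, round(nt * b / 40)))
  sw <- c(1L, sysEnd); ew <- w(19, 28); aw <- w(32, 39)
  envS <- .halfSine(nt, sw[1L], sw[2L])
  envE <- .halfSine(nt, ew[1L], ew[2L])
  envA <- .halfSine(nt, aw[1L], aw[2L])

  sigma <- spec$jetRadius / 2
  jetDir <- function(angleDeg) {
    th <- angleDeg * pi / 180
    .unitize(-cos(th) * laxU + sin(th) * saxU)       # base -> apex, tilted
  }
  dE <- jetDir(spec$eJetAngle)
  dA <- jetDir(spec$aJetAngle)
  dS <- .unitize(aortic - apex)

  profE <- .jetProfile(g$X, g$Y, g$Z, mitral, dE, sigma)
  profA <- .jetProfile(g$X, g$Y, g$Z, mitral, dA, sigma)
  profS <- .jetProfile(g$X, g$Y, g$Z, apex + 15 * dS, dS, sigma)

  A0 <- spec$amplitude
  vel <- array(0, c(d, nt, 3L))
  for (t in seq_len(nt)) {
    sp <- envE[t] * A0 * profE
    for (c in 1:3) vel[, , , t, c] <- sp * dE[c]
    sp <- envA[t] * 0.6 * A0 * profA
    for (c in 1:3) vel[, , , t, c] <- vel[, , , t, c] + sp * dA[c]
    sp <- envS[t] * A0 * profS
    for (c in 1:3) vel[, , , t, c] <- vel[, , , t, c] + sp * dS[c]
  }
  if (spec$noiseSigma > 0)
    vel <- vel + .withSeed(spec$seed,
                           array(stats::rnorm(length(vel), 0, spec$noiseSigma),
                                 dim(vel)))
  flow <- velocityField4D(vel, spec$spacing, spec$dt, venc = 120,
                          affine = affine)
  list(flow = flow, mask = mask4D(maskArr, spec$spacing, affine = affine),
       landmarks = lm)
}

#' Inject MRI artifacts into a velocity field
#'
#' Adds a degree-<=4 polynomial background offset per component (the
#' eddy-current-like error the polynomial correction removes) and/or
#' aliases velocities into (-venc, venc] (the wrap the temporal unwrap
#' reverses). On well-posed inputs each injection is exactly invertible by
#' the corresponding preprocessing step.
#'
#' @param flow a [VelocityField4D-class].
#' @param spec a [phantomSpec()]; `backgroundPolyCoeffs` and `wrapVenc`
#'   control the injections (both NULL = identity).
#' @return the corrupted [VelocityField4D-class].
#' @export
injectArtifacts <- function(flow, spec) {
  stopifnot(is(flow, "VelocityField4D"), inherits(spec, "PhantomSpec"))
  vel <- flow@data
  d <- dim(vel)[1:3]; nt <- dim(vel)[4L]
  if (!is.null(spec$backgroundPolyCoeffs)) {
    co <- spec$backgroundPolyCoeffs
    stopifnot(length(co) == 3L)
    g <- .coordGrids(d, flow@affine)
    sc <- max(abs(c(g$X, g$Y, g$Z)))
    M <- .polyBasis(as.numeric(g$X) / sc, as.numeric(g$Y) / sc,
                    as.numeric(g$Z) / sc, 4L)
    for (c in 1:3) {
      cc <- co[[c]]
      if (length(cc) > ncol(M)) stop("too many polynomial coefficients")
      off <- array(M[, seq_along(cc), drop = FALSE] %*% cc, d)
      for (t in seq_len(nt)) vel[, , , t, c] <- vel[, , , t, c] + off
    }
  }
  if (!is.null(spec$wrapVenc)) {
    venc <- spec$wrapVenc / 100                       # m/s
    vel <- vel - 2 * venc * ceiling((vel - venc) / (2 * venc))
  }
  velocityField4D(vel, flow@spacing, flow@dt, flow@venc, flow@affine)
}

#' Cohort specification
#'
#' @param nPerGroup integer(2): subjects in the LBBB-like and control-like
#'   groups.
#' @param eAngleMeans,eAngleSds per-group E-jet angle distributions,
#'   degrees (group order matches `nPerGroup`).
#' @param qrsIntercept,qrsSlope,qrsNoiseSd linear model mapping the E-jet
#'   angle (deg) to a QRS duration (ms) plus Gaussian noise.
#' @param phantom template [phantomSpec()] (kind "lv_filling") whose
#'   geometry all subjects share.
#' @param seed master RNG seed.
#' @return a `CohortSpec` list.
#' @export
cohortSpec <- function(nPerGroup = c(9L, 9L),
                       eAngleMeans = c(45, 10), eAngleSds = c(8, 8),
                       qrsIntercept = 90, qrsSlope = 1.5, qrsNoiseSd = 12,
                       phantom = phantomSpec(kind = "lv_filling"),
                       seed = 1L) {
  stopifnot(all(nPerGroup >= 2L))
  structure(list(nPerGroup = as.integer(nPerGroup),
                 eAngleMeans = eAngleMeans, eAngleSds = eAngleSds,
                 qrsIntercept = qrsIntercept, qrsSlope = qrsSlope,
                 qrsNoiseSd = qrsNoiseSd, phantom = phantom,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Simulate a two-group phantom cohort
#'
#' Draws one E-jet angle per subject from its group distribution,
#' generates the corresponding LV filling phantom and an associated QRS
#' duration from a linear angle-to-QRS model with noise, emulating the
#' empirical coupling between conduction delay and filling-jet
#' discordance.
#'
#' @param spec a [cohortSpec()].
#' @return list with `datasets` (list of `gen_lv_phantom` outputs) and
#'   `covariates` (data.frame: id, group, e_angle_deg, qrs_ms, seed).
#' @export
genCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- sum(spec$nPerGroup)
  groups <- rep(c("LBBB", "non-LBBB"), spec$nPerGroup)
  gi <- rep(1:2, spec$nPerGroup)
  draws <- .withSeed(spec$seed, {
    ang <- stats::rnorm(n, spec$eAngleMeans[gi], spec$eAngleSds[gi])
    ang <- pmin(pmax(ang, 0), 80)
    qrs <- spec$qrsIntercept + spec$qrsSlope * ang +
      stats::rnorm(n, 0, spec$qrsNoiseSd)
    list(ang = ang, qrs = qrs,
         seeds = sample.int(.Machine$integer.max %/% 2L, n))
  })
  datasets <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- spec$phantom
    ps$eJetAngle <- draws$ang[i]
    ps$seed <- draws$seeds[i]
    datasets[[i]] <- genLVPhantom(ps)
  }
  covariates <- data.frame(
    id = sprintf("S%02d", seq_len(n)), group = groups,
    e_angle_deg = draws$ang, qrs_ms = draws$qrs, seed = draws$seeds,
    stringsAsFactors = FALSE)
  list(datasets = datasets, covariates = covariates)
}
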