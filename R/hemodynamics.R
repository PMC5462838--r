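# Core computation: masked finite-difference derivatives with the LV lumen
# mask as boundary condition, Navier-Stokes pressure-gradient assembly,
# volume integration into the hemodynamic force vector, anatomical axis
# projection, and the short-axis / long-axis ratio metrics.

#' Masked spatial gradient of a 3D volume
#'
#' Finite-difference gradient restricted to a binary mask, which acts as
#' the boundary condition: central differences where both axis neighbours
#' lie in the mask, one-sided differences where exactly one does, and NA
#' (flagged missing; consumers treat it as zero) where neither does.
#' Out-of-mask voxels never contribute values, so myocardial or
#' extracardiac velocities cannot contaminate intracavitary derivatives.
#'
#' @param vol 3D numeric array.
#' @param mask 3D array/logical of the same dim; TRUE/1 = inside.
#' @param spacing numeric(3) voxel spacing in metres.
#' @return list of 3 arrays (d/dx, d/dy, d/dz), units of `vol` per metre,
#'   NA outside the mask and where no in-mask neighbour exists.
#' @export
maskedGradient <- function(vol, mask, spacing) {
  stopifnot(all(dim(vol) == dim(mask)), length(spacing) == 3L)
  m <- array(mask > 0, dim(mask))
  if (!any(m)) stop("mask is empty")
  out <- vector("list", 3L)
  for (ax in 1:3) {
    h <- spacing[ax]
    mp <- .shift3(m, ax, +1L, fill = FALSE)
    mm <- .shift3(m, ax, -1L, fill = FALSE)
    vp <- .shift3(vol, ax, +1L, fill = 0)
    vm <- .shift3(vol, ax, -1L, fill = 0)
    g <- array(NA_real_, dim(vol))
    both <- m & mp & mm
    fwd <- m & mp & !mm
    bwd <- m & !mp & mm
    g[both] <- (vp[both] - vm[both]) / (2 * h)
    g[fwd] <- (vp[fwd] - vol[fwd]) / h
    g[bwd] <- (vol[bwd] - vm[bwd]) / h
    out[[ax]] <- g
  }
  names(out) <- c("dx", "dy", "dz")
  out
}

# Divergence-of-masked-gradient Laplacian of one scalar volume. The inner
# gradient's missing voxels are removed from the support of the outer pass.
.maskedLaplacian <- function(vol, mask, spacing) {
  m <- array(mask > 0, dim(mask))
  grad <- maskedGradient(vol, m, spacing)
  lap <- array(0, dim(vol))
  for (ax in 1:3) {
    g <- grad[[ax]]
    m2 <- m & !is.na(g)
    g[!m2] <- 0
    d2 <- maskedGradient(g, m2, spacing)[[ax]]
    d2[is.na(d2)] <- 0
    lap <- lap + d2
  }
  lap[!m] <- NA_real_
  lap
}

#' Navier-Stokes pressure gradient over the LV lumen
#'
#' Evaluates the momentum balance (body forces excluded)
#' \deqn{\nabla p = -\rho\,\partial v/\partial t - \rho\,(v\cdot\nabla)v
#'   + \mu \nabla^2 v}
#' at every in-mask voxel and time frame. The temporal derivative uses
#' cyclic central differences over the cardiac cycle on the full (pre-mask)
#' velocity field, since the reconstructed cycle is periodic and velocity
#' data exist beyond the moving lumen boundary; spatial derivatives use
#' [maskedGradient()] with the per-frame lumen mask as boundary condition,
#' and the Laplacian is the divergence of the masked gradient.
#'
#' @param flow a [VelocityField4D-class].
#' @param mask the paired [Mask4D-class] (same grid and frame count).
#' @param constants [fluidConstants()].
#' @return a [PressureGradientField-class] with data in Pa/m.
#' @export
pressureGradientNS <- function(flow, mask, constants = fluidConstants()) {
  stopifnot(is(flow, "VelocityField4D"), is(mask, "Mask4D"))
  if (!all(dim(flow@data)[1:4] == dim(mask@data)))
    stop("flow and mask grids are not congruent", call. = FALSE)
  nt <- nFrames(flow)
  sp <- .spacingM(flow)
  dtS <- .dtS(flow)
  rho <- constants@rho; mu <- constants@mu
  vel <- flow@data
  out <- array(NA_real_, dim(vel))

  for (t in seq_len(nt)) {
    m <- array(mask@data[, , , t] > 0, dim(vel)[1:3])
    tp <- if (t == nt) 1L else t + 1L
    tm <- if (t == 1L) nt else t - 1L
    for (c in 1:3) {
      v_c <- vel[, , , t, c]
      dvdt <- (vel[, , , tp, c] - vel[, , , tm, c]) / (2 * dtS)
      grad <- maskedGradient(v_c, m, sp)
      conv <- array(0, dim(v_c))
      for (ax in 1:3) {
        g <- grad[[ax]]
        g[is.na(g)] <- 0
        conv <- conv + vel[, , , t, ax] * g
      }
      lap <- .maskedLaplacian(v_c, m, sp)
      lap[is.na(lap)] <- 0
      gp <- -rho * dvdt - rho * conv + mu * lap
      gp[!m] <- NA_real_
      out[, , , t, c] <- gp
    }
  }
  new("PressureGradientField", data = out, mask = mask)
}

#' Integrate pressure gradients into the hemodynamic force vector
#'
#' Sums the pressure gradient over the in-mask lumen voxels, weighted by
#' the voxel volume, at every time frame: the net force (N) exchanged
#' between the blood pool and the myocardial walls. Flagged-missing
#' gradient components contribute zero.
#'
#' @param gradp a [PressureGradientField-class].
#' @param mask the [Mask4D-class] integration domain (defaults to the one
#'   carried by `gradp`).
#' @param dt frame interval in seconds, stored on the result.
#' @return a [ForceSeries-class] with the force vectors (projections
#'   unset; see [projectForce()]).
#' @export
integrateForce <- function(gradp, mask = gradp@mask, dt) {
  stopifnot(is(gradp, "PressureGradientField"))
  vvol <- prod(mask@spacing * 1e-3)                 # m^3
  nt <- dim(gradp@data)[4L]
  Fm <- matrix(0, nt, 3L)
  for (t in seq_len(nt)) {
    m <- mask@data[, , , t] > 0
    for (c in 1:3) {
      g <- gradp@data[, , , t, c]
      vals <- g[m]
      Fm[t, c] <- sum(vals[is.finite(vals)]) * vvol
    }
  }
  new("ForceSeries", F = Fm, fLax = numeric(0), fSax = numeric(0), dt = dt)
}

#' Construct the anatomical long-/short-axis frame
#'
#' The long-axis unit vector points from the apex towards the mitral
#' annulus centre (apex to base); the short-axis unit vector is the
#' component of (mitral - aortic) orthogonal to the long axis, i.e. the
#' anteroseptal-to-inferolateral direction within the three-chamber plane.
#' Orthonormality holds by construction.
#'
#' @param lm a [Landmarks-class].
#' @return an [AxisFrame-class].
#' @export
buildAxisFrame <- function(lm) {
  stopifnot(is(lm, "Landmarks"))
  laxU <- .unitize(lm@mitralCenter - lm@apex)
  w <- lm@mitralCenter - lm@aorticCenter
  saxV <- w - sum(w * laxU) * laxU
  if (sqrt(sum(saxV^2)) < 1e-9)
    stop("degenerate geometry: mitral-aortic direction parallel to the long axis",
         call. = FALSE)
  new("AxisFrame", laxUnit = laxU, saxUnit = .unitize(saxV),
      origin = lm@apex)
}

#' Project the force series onto the anatomical axes
#'
#' @param force a [ForceSeries-class].
#' @param frame an [AxisFrame-class].
#' @return the [ForceSeries-class] with `fLax` and `fSax` filled: the
#'   long-axis component is positive towards the base/atrium, the
#'   short-axis component positive towards the inferolateral wall.
#' @export
projectForce <- function(force, frame) {
  stopifnot(is(force, "ForceSeries"), is(frame, "AxisFrame"))
  new("ForceSeries", F = force@F,
      fLax = as.numeric(force@F %*% frame@laxUnit),
      fSax = as.numeric(force@F %*% frame@saxUnit),
      dt = force@dt)
}

#' Short-axis / long-axis peak-force ratio over a phase window
#'
#' The maximum absolute short-axis force component divided by the maximum
#' absolute long-axis component, each searched independently over the
#' window (the two maxima need not occur at the same frame). Absolute
#' values are used because the force polarity alternates within a filling
#' phase.
#'
#' @param force a projected [ForceSeries-class].
#' @param window integer frame indices.
#' @return list with `ratio`, `tMaxSax`, `tMaxLax` (seconds from frame 1).
#' @export
ratioMax <- function(force, window) {
  stopifnot(is(force, "ForceSeries"), length(window) >= 1L)
  if (!length(force@fLax)) stop("force series has not been projected")
  aS <- abs(force@fSax[window]); aL <- abs(force@fLax[window])
  if (max(aL) == 0) stop("ratio undefined: long-axis force is zero over the window",
                         call. = FALSE)
  list(ratio = max(aS) / max(aL),
       tMaxSax = (window[which.max(aS)] - 1L) * force@dt,
       tMaxLax = (window[which.max(aL)] - 1L) * force@dt)
}

#' Short-axis / long-axis RMS-force ratio over a phase window
#'
#' The root-mean-square of the short-axis force component over the window
#' divided by the RMS of the long-axis component: a temporally global
#' companion to [ratioMax()], less sensitive to single-frame noise.
#'
#' @param force a projected [ForceSeries-class].
#' @param window integer frame indices.
#' @param definition `"ratio_of_rms"` (default): rms(fSax)/rms(fLax);
#'   `"rms_of_ratio"`: rms over the window of the per-frame
#'   |fSax|/|fLax| ratio (alternative reading, kept behind this switch and
#'   excluded from defaults).
#' @return the dimensionless ratio.
#' @export
ratioRms <- function(force, window,
                     definition = c("ratio_of_rms", "rms_of_ratio")) {
  stopifnot(is(force, "ForceSeries"), length(window) >= 1L)
  definition <- match.arg(definition)
  if (!length(force@fLax)) stop("force series has not been projected")
  s <- force@fSax[window]; l <- force@fLax[window]
  rms <- function(x) sqrt(mean(x^2))
  if (rms(l) == 0) stop("ratio undefined: long-axis RMS force is zero",
                        call. = FALSE)
  if (definition == "ratio_of_rms") rms(s) / rms(l)
  else rms(abs(s) / abs(l))
}

#' Per-subject force-ratio metrics
#'
#' Runs the full chain pressure gradient -> force integration -> axis
#' projection and evaluates peak and RMS short/long-axis ratios over full
#' diastole and over the E- and A-wave windows. E-specific entries are NA
#' when the E/A split is undefined for the subject.
#'
#' @param flow a [VelocityField4D-class] (preprocessed).
#' @param mask the paired [Mask4D-class].
#' @param lm the [Landmarks-class].
#' @param phases a [CardiacPhases-class] from [segmentCycle()].
#' @param constants [fluidConstants()].
#' @param rmsDefinition see [ratioRms()].
#' @return a `RatioMetrics` list: ratioMaxFull/E/A, ratioRmsFull/E/A,
#'   tMaxSax, tMaxLax (named full/E/A, seconds), eDefined, and the
#'   projected `force` series.
#' @export
computeSubjectMetrics <- function(flow, mask, lm, phases,
                                  constants = fluidConstants(),
                                  rmsDefinition = "ratio_of_rms") {
  stopifnot(is(phases, "CardiacPhases"))
  gradp <- pressureGradientNS(flow, mask, constants)
  force <- integrateForce(gradp, mask, dt = .dtS(flow))
  force <- projectForce(force, buildAxisFrame(lm))

  evalWin <- function(w) {
    if (!length(w)) return(list(max = list(ratio = NA_real_, tMaxSax = NA_real_,
                                           tMaxLax = NA_real_), rms = NA_real_))
    list(max = ratioMax(force, w),
         rms = ratioRms(force, w, definition = rmsDefinition))
  }
  full <- evalWin(phases@diastole)
  ew <- evalWin(if (phases@eDefined) phases@eWave else integer(0))
  aw <- evalWin(if (phases@eDefined) phases@aWave else phases@aWave)

  structure(list(
    ratioMaxFull = full$max$ratio, ratioMaxE = ew$max$ratio,
    ratioMaxA = aw$max$ratio,
    ratioRmsFull = full$rms, ratioRmsE = ew$rms, ratioRmsA = aw$rms,
    tMaxSax = c(full = full$max$tMaxSax, E = ew$max$tMaxSax,
                A = aw$max$tMaxSax),
    tMaxLax = c(full = full$max$tMaxLax, E = ew$max$tMaxLax,
                A = aw$max$tMaxLax),
    eDefined = phases@eDefined, force = force), class = "RatioMetrics")
}

#' @export
print.RatioMetrics <- function(x, ...) {
  cat("SAx/LAx force-ratio metrics\n")
  cat(sprintf("  peak ratio: full %.3f | E %.3f | A %.3f\n",
              x$ratioMaxFull, x$ratioMaxE, x$ratioMaxA))
  cat(sprintf("  rms ratio:  full %.3f | E %.3f | A %.3f\n",
              x$ratioRmsFull, x$ratioRmsE, x$ratioRmsA))
  if (!x$eDefined) cat("  note: E-wave undefined for this subject\n")
  invisible(x)
}
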