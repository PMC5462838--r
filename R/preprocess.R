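# Phase-contrast preprocessing: static-tissue detection, polynomial
# background-phase correction, temporal phase unwrapping, mask time
# resampling, and the inflow/outflow quality-control gate.

#' Detect static thoracic tissue
#'
#' A voxel is static when both the temporal standard deviation and the
#' temporal mean of its speed fall below one threshold. Static voxels are
#' the fit support for the polynomial background correction.
#'
#' @param flow a [VelocityField4D-class].
#' @param speedStdThreshold threshold, m/s (default 0.02).
#' @return a [StaticTissueMask-class].
#' @export
detectStaticTissue <- function(flow, speedStdThreshold = 0.02) {
  stopifnot(is(flow, "VelocityField4D"), speedStdThreshold > 0)
  nt <- nFrames(flow)
  d <- dim(flow@data)[1:3]
  sp2 <- array(0, c(d, nt))
  for (t in seq_len(nt))
    sp2[, , , t] <- sqrt(flow@data[, , , t, 1L]^2 + flow@data[, , , t, 2L]^2 +
                           flow@data[, , , t, 3L]^2)
  mn <- apply(sp2, 1:3, mean)
  sdv <- sqrt(apply(sp2, 1:3, stats::var))
  static <- (sdv < speedStdThreshold) & (mn < speedStdThreshold)
  if (!any(static))
    stop("no static tissue found below the threshold", call. = FALSE)
  new("StaticTissueMask", data = array(as.numeric(static), d))
}

#' Polynomial background-phase correction
#'
#' Fits, per velocity component, a 3D polynomial of total degree `order`
#' in scaled world coordinates to the temporal-mean velocity over the
#' static-tissue voxels, and subtracts the fitted surface from every
#' frame. Models the eddy-current-like background offset, which is static
#' by definition, hence one time-invariant fit.
#'
#' @param flow a [VelocityField4D-class].
#' @param static a [StaticTissueMask-class].
#' @param order polynomial total degree (default 4).
#' @return the corrected [VelocityField4D-class].
#' @export
correctBackground <- function(flow, static, order = 4L) {
  stopifnot(is(flow, "VelocityField4D"), is(static, "StaticTissueMask"))
  d <- dim(flow@data)[1:3]
  stopifnot(all(dim(static@data) == d))
  sel <- static@data > 0
  nCoef <- choose(order + 3L, 3L)
  if (sum(sel) < nCoef)
    stop(sprintf("need at least %d static voxels for a degree-%d fit",
                 nCoef, order), call. = FALSE)
  g <- .coordGrids(d, flow@affine)
  sc <- max(abs(c(g$X, g$Y, g$Z)))
  xs <- as.numeric(g$X) / sc; ys <- as.numeric(g$Y) / sc
  zs <- as.numeric(g$Z) / sc
  Mfull <- .polyBasis(xs, ys, zs, order)
  Mfit <- Mfull[as.logical(sel), , drop = FALSE]
  qrM <- qr(Mfit)
  if (qrM$rank < ncol(Mfit))
    stop("rank-deficient polynomial design: static voxels are degenerate (e.g. co-planar)",
         call. = FALSE)
  nt <- nFrames(flow)
  vel <- flow@data
  for (c in 1:3) {
    vmean <- apply(vel[, , , , c, drop = FALSE], 1:3, mean)
    beta <- qr.coef(qrM, vmean[sel])
    offset <- array(Mfull %*% beta, d)
    for (t in seq_len(nt)) vel[, , , t, c] <- vel[, , , t, c] - offset
  }
  velocityField4D(vel, flow@spacing, flow@dt, flow@venc, flow@affine)
}

#' Temporal phase unwrapping
#'
#' Velocities outside (-venc, venc] alias by multiples of 2 venc. Scanning
#' each voxel's time series in frame order, every consecutive-frame jump
#' larger than venc is reduced by the multiple of 2 venc that minimizes
#' it; equivalently, wrapped frame-to-frame increments are re-accumulated
#' from the first frame. Idempotent on wrap-free data. The first frame is
#' taken at face value, so wraps present already at frame 1 are
#' unresolvable (as for any purely temporal algorithm).
#'
#' @param flow a [VelocityField4D-class] (its `venc` metadata is used).
#' @return the unwrapped [VelocityField4D-class].
#' @export
unwrapTemporal <- function(flow) {
  stopifnot(is(flow, "VelocityField4D"))
  venc <- .vencMs(flow)
  vel <- flow@data
  d <- dim(vel)
  nt <- d[4L]
  for (c in 1:3) {
    v <- matrix(vel[, , , , c], ncol = nt)        # voxels x frames
    dv <- v[, -1L, drop = FALSE] - v[, -nt, drop = FALSE]
    dv <- dv - 2 * venc * round(dv / (2 * venc))
    v2 <- cbind(v[, 1L], dv)
    vel[, , , , c] <- array(t(apply(v2, 1L, cumsum)), d[1:4])
  }
  velocityField4D(vel, flow@spacing, flow@dt, flow@venc, flow@affine)
}

#' Resample a mask to a new number of time frames
#'
#' Nearest-neighbour assignment in cycle-normalized time: output frame t
#' (0-based) takes source frame `round(t * nSrc / nTarget) mod nSrc`.
#' Binary-safe (no shape interpolation), matching how a cine segmentation
#' is re-timed to the 4D flow frame count.
#'
#' @param mask a [Mask4D-class].
#' @param nFramesTarget desired frame count (>= 2).
#' @return the resampled [Mask4D-class].
#' @export
resampleMaskTime <- function(mask, nFramesTarget) {
  stopifnot(is(mask, "Mask4D"), nFramesTarget >= 2L, nFrames(mask) >= 2L)
  nSrc <- nFrames(mask)
  t0 <- seq_len(nFramesTarget) - 1L
  src <- (round(t0 * nSrc / nFramesTarget) %% nSrc) + 1L
  mask4D(mask@data[, , , src, drop = FALSE], mask@spacing, mask@affine)
}

#' Oriented disc for through-plane flow measurement
#'
#' @param center numeric(3) world-mm centre.
#' @param normal numeric(3) plane normal (normalized internally).
#' @param radius disc radius, mm.
#' @return a `FlowDisc` list.
#' @export
flowDisc <- function(center, normal, radius) {
  stopifnot(length(center) == 3L, length(normal) == 3L, radius > 0)
  structure(list(center = as.numeric(center),
                 normal = .unitize(as.numeric(normal)),
                 radius = radius), class = "FlowDisc")
}

# Deterministic polar quadrature over a disc: nTheta x nR sample points
# with annulus-area weights. Returns through-plane volume flow (m^3/s) per
# frame.
.discFlow <- function(flow, disc, nTheta = 32L, nR = 8L) {
  n <- disc$normal
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unitize(ref - sum(ref * n) * n)
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  Rm <- disc$radius * 1e-3
  nt <- nFrames(flow)
  Q <- numeric(nt)
  for (j in seq_len(nR)) {
    rMid <- (j - 0.5) / nR * disc$radius             # mm
    wArea <- pi * ((j / nR)^2 - ((j - 1) / nR)^2) * Rm^2 / nTheta  # m^2
    for (k in seq_len(nTheta)) {
      th <- 2 * pi * (k - 1) / nTheta
      pt <- disc$center + rMid * (cos(th) * e1 + sin(th) * e2)
      idx <- .worldToVoxel(pt, flow@affine)
      for (t in seq_len(nt)) {
        v <- vapply(1:3, function(c) .trilinear3(flow@data[, , , t, c], idx),
                    numeric(1L))
        Q[t] <- Q[t] + sum(v * n) * wArea
      }
    }
  }
  Q
}

#' Inflow/outflow discrepancy quality control
#'
#' Integrates through-plane flow over the mitral disc across diastolic
#' frames (inflow volume) and over the aortic disc across systolic frames
#' (outflow volume), and computes the relative discrepancy
#' |in - out| / mean(in, out). Subjects with a discrepancy above 15% fail
#' the gate, the study exclusion criterion for inconsistent volumetry.
#'
#' @param flow a [VelocityField4D-class].
#' @param mvPlane,aoPlane [flowDisc()] geometry at the mitral and aortic
#'   orifices.
#' @param phases a [CardiacPhases-class].
#' @param maxDiscrepancy pass threshold (default 0.15).
#' @return a `QCReport` list: inflow_ml, outflow_ml, discrepancy, pass.
#' @export
flowDiscrepancy <- function(flow, mvPlane, aoPlane, phases,
                            maxDiscrepancy = 0.15) {
  stopifnot(is(flow, "VelocityField4D"), inherits(mvPlane, "FlowDisc"),
            inherits(aoPlane, "FlowDisc"), is(phases, "CardiacPhases"))
  dtS <- .dtS(flow)
  Qmv <- .discFlow(flow, mvPlane)
  Qao <- .discFlow(flow, aoPlane)
  inflow <- abs(sum(Qmv[phases@diastole]) * dtS) * 1e6    # ml
  outflow <- abs(sum(Qao[phases@systole]) * dtS) * 1e6
  if (mean(c(inflow, outflow)) <= 0)
    stop("QC failed: zero mean stroke volume at the valve planes", call. = FALSE)
  disc <- abs(inflow - outflow) / mean(c(inflow, outflow))
  structure(list(inflow_ml = inflow, outflow_ml = outflow,
                 discrepancy = disc, pass = disc <= maxDiscrepancy),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC: inflow %.1f ml, outflow %.1f ml, discrepancy %.1f%% -> %s\n",
              x$inflow_ml, x$outflow_ml, 100 * x$discrepancy,
              if (x$pass) "PASS" else "FAIL (>15%)"))
  invisible(x)
}
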