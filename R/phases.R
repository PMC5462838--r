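# Cardiac phase detection from speed probes at the mitral and aortic
# orifices: systole from the aortic speed bump, then E- and A-wave windows
# from the two transmitral filling peaks.

#' Speed time series at a probe point
#'
#' Trilinearly interpolates the three velocity components at a world-mm
#' point for every frame and returns the Euclidean speed.
#'
#' @param flow a [VelocityField4D-class].
#' @param point numeric(3) world-mm position (inside the field of view).
#' @return numeric vector of speeds (m/s), one per frame.
#' @export
probeSpeed <- function(flow, point) {
  stopifnot(is(flow, "VelocityField4D"), length(point) == 3L)
  idx <- .worldToVoxel(point, flow@affine)
  nt <- nFrames(flow)
  out <- numeric(nt)
  for (t in seq_len(nt)) {
    v <- vapply(1:3, function(c) .trilinear3(flow@data[, , , t, c], idx),
                numeric(1L))
    out[t] <- sqrt(sum(v^2))
  }
  out
}

# centred 3-frame moving average; end frames keep shorter windows
.smooth3 <- function(x) {
  n <- length(x)
  out <- x
  if (n >= 3L) out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  out
}

# strict-ish local maxima indices of a series (interior points only)
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

#' Segment the cardiac cycle from valve-probe speed curves
#'
#' Systole is the contiguous run of frames around the global aortic-speed
#' peak where the aortic speed stays at or above `onsetFraction` of that
#' peak; diastole is the remainder of the cycle after systole. Within
#' diastole the mitral speed (smoothed with a 3-frame moving average for
#' peak finding; interval end points use the raw series) is searched for
#' local maxima: the first is the E peak, the last the A peak, and the E/A
#' boundary is the global minimum strictly between them. Each wave starts
#' where the raw mitral speed rises above `onsetFraction` of its own peak
#' and runs to the boundary (E) or the end of diastole (A). When fewer
#' than two separable mitral peaks exist the E/A split is undefined and
#' the subject is flagged (such subjects are retained for full-diastole
#' metrics only).
#'
#' @param mvSpeed,aoSpeed equal-length (>= 10 frames) speed series, m/s.
#' @param dt frame interval, seconds.
#' @param onsetFraction threshold fraction of the respective peak
#'   (default 0.25).
#' @return a [CardiacPhases-class].
#' @export
segmentCycle <- function(mvSpeed, aoSpeed, dt, onsetFraction = 0.25) {
  n <- length(mvSpeed)
  stopifnot(length(aoSpeed) == n, n >= 10L, dt > 0, onsetFraction > 0,
            onsetFraction < 1)
  if (max(mvSpeed) <= 0)
    stop("segmentation failed: mitral speed is zero everywhere", call. = FALSE)
  if (max(aoSpeed) <= 0)
    stop("segmentation failed: aortic speed is zero everywhere", call. = FALSE)

  pk <- which.max(aoSpeed)
  thrA <- onsetFraction * aoSpeed[pk]
  s1 <- pk; while (s1 > 1L && aoSpeed[s1 - 1L] >= thrA) s1 <- s1 - 1L
  s2 <- pk; while (s2 < n && aoSpeed[s2 + 1L] >= thrA) s2 <- s2 + 1L
  systole <- s1:s2
  if (s2 >= n)
    stop("segmentation failed: no diastolic frames after systole", call. = FALSE)
  diastole <- (s2 + 1L):n

  mvS <- .smooth3(mvSpeed)
  loc <- .localMaxima(mvS)
  loc <- loc[loc %in% diastole]
  # prominence floor: candidate filling peaks must reach the onset fraction
  # of the diastolic maximum, so single-frame noise bumps near zero flow
  # cannot masquerade as E or A peaks
  loc <- loc[mvS[loc] >= onsetFraction * max(mvS[diastole])]
  eDefined <- length(loc) >= 2L
  eWave <- aWave <- integer(0)
  if (eDefined) {
    ePk <- loc[1L]; aPk <- loc[length(loc)]
    between <- (ePk + 1L):(aPk - 1L)
    if (!length(between)) {
      eDefined <- FALSE
    } else {
      b <- between[which.min(mvS[between])]
      eStart <- min(diastole)
      for (f in min(diastole):ePk)
        if (mvSpeed[f] >= onsetFraction * mvSpeed[ePk]) { eStart <- f; break }
      aStart <- b + 1L
      for (f in (b + 1L):aPk)
        if (mvSpeed[f] >= onsetFraction * mvSpeed[aPk]) { aStart <- f; break }
      eWave <- eStart:b
      aWave <- aStart:n
    }
  }
  new("CardiacPhases", systole = as.integer(systole),
      diastole = as.integer(diastole), eWave = as.integer(eWave),
      aWave = as.integer(aWave), dt = dt, eDefined = eDefined)
}
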