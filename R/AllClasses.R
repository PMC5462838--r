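#' @import methods
NULL

#' Time-resolved three-directional velocity data
#'
#' Container for 4D flow velocity data: a five-dimensional array
#' (x, y, z, frame, component) of velocities in m/s together with the
#' acquisition geometry. Metadata keep the acquisition units customary in
#' cardiovascular MR (voxel spacing in mm, frame interval in ms, velocity
#' encoding limit in cm/s); all physics code converts to SI through the
#' accessors, so the conversion happens in exactly one place.
#'
#' @slot data numeric array, dim (nx, ny, nz, nFrames, 3), velocity in m/s.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot dt frame interval in ms.
#' @slot venc velocity encoding limit in cm/s; velocities outside
#'   (-venc, venc] alias by multiples of 2 venc.
#' @slot affine 4x4 matrix mapping 0-based voxel indices to world mm.
#'
#' @export
setClass("VelocityField4D",
  representation(data = "array", spacing = "numeric", dt = "numeric",
                 venc = "numeric", affine = "matrix"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 5L || d[5L] != 3L)
      return("data must be a 5D array with 3 velocity components")
    if (d[4L] < 3L) return("at least 3 time frames are required")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive voxel edge lengths [mm]")
    if (length(object@dt) != 1L || object@dt <= 0)
      return("dt must be a single positive frame interval [ms]")
    if (length(object@venc) != 1L || object@venc <= 0)
      return("venc must be a single positive encoding velocity [cm/s]")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be a 4x4 matrix")
    if (!all(is.finite(object@data)))
      return("velocity data must be finite everywhere")
    TRUE
  })

#' Per-frame binary left-ventricular lumen mask
#'
#' The integration domain for the hemodynamic force and the boundary
#' condition for the masked spatial derivatives. One binary volume per
#' cardiac time frame, on the same voxel lattice as the paired
#' [VelocityField4D].
#'
#' @slot data array, dim (nx, ny, nz, nFrames), values 0/1.
#' @slot spacing,affine as in [VelocityField4D].
#'
#' @export
setClass("Mask4D",
  representation(data = "array", spacing = "numeric", affine = "matrix"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("mask data must be a 4D array")
    if (!all(object@data %in% c(0, 1)))
      return("mask values must be 0 or 1")
    counts <- apply(object@data, 4L, sum)
    if (any(counts < 1)) return("every frame needs at least one lumen voxel")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive voxel edge lengths [mm]")
    TRUE
  })

#' Static (non-moving) tissue mask
#'
#' Time-invariant binary volume marking thoracic voxels with negligible
#' velocity over the whole cycle, used as the fit support for polynomial
#' background-phase correction.
#'
#' @slot data 3D array of 0/1.
#' @export
setClass("StaticTissueMask",
  representation(data = "array"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (!all(object@data %in% c(0, 1))) return("values must be 0 or 1")
    TRUE
  })

#' Anatomical landmarks and valve probe points
#'
#' World-mm coordinates of the apex, mitral annulus centre and aortic
#' orifice centre (which define the long- and short-axis directions), plus
#' the two speed-probe points near the mitral and aortic valve orifices
#' used for cardiac phase detection.
#'
#' @slot apex,mitralCenter,aorticCenter numeric(3) world-mm points.
#' @slot mvProbe,aoProbe numeric(3) world-mm probe points.
#' @export
setClass("Landmarks",
  representation(apex = "numeric", mitralCenter = "numeric",
                 aorticCenter = "numeric", mvProbe = "numeric",
                 aoProbe = "numeric"),
  validity = function(object) {
    for (s in c("apex", "mitralCenter", "aorticCenter", "mvProbe", "aoProbe"))
      if (length(slot(object, s)) != 3L)
        return(sprintf("%s must be a 3-vector [mm]", s))
    if (sqrt(sum((object@apex - object@mitralCenter)^2)) < 1e-9)
      return("apex and mitral centre must be distinct")
    u <- object@mitralCenter - object@apex
    w <- object@aorticCenter - object@apex
    cr <- c(u[2L] * w[3L] - u[3L] * w[2L],
            u[3L] * w[1L] - u[1L] * w[3L],
            u[1L] * w[2L] - u[2L] * w[1L])
    if (sqrt(sum(cr^2)) < 1e-9)
      return("apex, mitral and aortic landmarks must not be collinear")
    TRUE
  })

#' Physical constants of blood
#'
#' @slot rho density in kg/m^3 (default 1060).
#' @slot mu dynamic viscosity in N s/m^2 (default 0.004).
#' @export
setClass("FluidConstants",
  representation(rho = "numeric", mu = "numeric"),
  validity = function(object) {
    if (length(object@rho) != 1L || object@rho <= 0) return("rho must be > 0")
    if (length(object@mu) != 1L || object@mu < 0) return("mu must be >= 0")
    TRUE
  })

#' Relative pressure gradient field
#'
#' The three-component pressure gradient (Pa/m) at every in-mask voxel and
#' frame, from the Navier-Stokes momentum balance. Voxels outside the mask
#' (and in-mask voxels with no in-mask neighbour along an axis) are NA;
#' consumers treat NA contributions as zero.
#'
#' @slot data array, dim (nx, ny, nz, nFrames, 3), Pa/m; NA where undefined.
#' @slot mask the [Mask4D] that defined the domain.
#' @export
setClass("PressureGradientField",
  representation(data = "array", mask = "Mask4D"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 5L || d[5L] != 3L)
      return("data must be a 5D array with 3 gradient components")
    if (!all(d[1L:4L] == dim(object@mask@data)))
      return("gradient and mask geometry must match")
    TRUE
  })

#' Anatomical long-/short-axis frame
#'
#' Orthonormal pair of direction vectors: the long axis (apex towards
#' base/atrium) and the short axis (anteroseptal towards inferolateral),
#' the latter lying in the three-chamber plane spanned by the apex, mitral
#' and aortic landmarks.
#'
#' @slot laxUnit,saxUnit unit 3-vectors.
#' @slot origin world-mm point (the apex).
#' @export
setClass("AxisFrame",
  representation(laxUnit = "numeric", saxUnit = "numeric", origin = "numeric"),
  validity = function(object) {
    if (abs(sum(object@laxUnit^2) - 1) > 1e-8) return("laxUnit must be unit length")
    if (abs(sum(object@saxUnit^2) - 1) > 1e-8) return("saxUnit must be unit length")
    if (abs(sum(object@laxUnit * object@saxUnit)) > 1e-10)
      return("axes must be orthogonal")
    TRUE
  })

#' Hemodynamic force time series
#'
#' The net force the blood pool exerts on the myocardium, per cardiac time
#' frame, with its scalar projections on the anatomical axes. The
#' long-axis component is positive when directed from apex towards the
#' base/atrium; the short-axis component is positive towards the
#' inferolateral wall.
#'
#' @slot F matrix (nFrames x 3) of force vectors in N.
#' @slot fLax,fSax numeric per-frame scalar projections in N (length 0
#'   until [projectForce()] has been applied).
#' @slot dt frame interval in seconds.
#' @export
setClass("ForceSeries",
  representation(F = "matrix", fLax = "numeric", fSax = "numeric",
                 dt = "numeric"),
  validity = function(object) {
    if (ncol(object@F) != 3L) return("F must have 3 columns")
    if (length(object@dt) != 1L || object@dt <= 0) return("dt must be > 0 [s]")
    n <- nrow(object@F)
    if (length(object@fLax) && length(object@fLax) != n)
      return("fLax length must match the number of frames")
    if (length(object@fSax) && length(object@fSax) != n)
      return("fSax length must match the number of frames")
    if (length(object@fLax) && length(object@fSax)) {
      mag <- sqrt(rowSums(object@F^2))
      if (any(abs(object@fLax) > mag + 1e-9) || any(abs(object@fSax) > mag + 1e-9))
        return("projections cannot exceed the force magnitude")
    }
    TRUE
  })

#' Cardiac cycle phase windows
#'
#' Frame windows (1-based, contiguous) for systole, diastole and the early
#' (E-wave) and late (A-wave) diastolic filling phases. The E/A split can
#' be undefined when the two filling peaks are not separable (e.g. fused
#' by a short diastasis); the subject is then flagged and excluded from
#' E/A-specific analyses only.
#'
#' @slot systole,diastole,eWave,aWave integer frame-index vectors
#'   (eWave/aWave have length 0 when undefined).
#' @slot dt frame interval in seconds.
#' @slot eDefined logical flag: TRUE when the E/A split succeeded.
#' @export
setClass("CardiacPhases",
  representation(systole = "integer", diastole = "integer",
                 eWave = "integer", aWave = "integer",
                 dt = "numeric", eDefined = "logical"),
  validity = function(object) {
    if (length(object@systole) < 1L) return("systole window is empty")
    if (length(object@diastole) < 1L) return("diastole window is empty")
    if (length(intersect(object@systole, object@diastole)))
      return("systole and diastole must not overlap")
    if (object@eDefined) {
      if (!length(object@eWave) || !length(object@aWave))
        return("eDefined implies non-empty E and A windows")
      if (!all(object@eWave %in% object@diastole) ||
          !all(object@aWave %in% object@diastole))
        return("E and A windows must lie inside diastole")
      if (length(intersect(object@eWave, object@aWave)))
        return("E and A windows must not overlap")
      if (max(object@eWave) > min(object@aWave))
        return("E wave must precede A wave")
    }
    TRUE
  })
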