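# Constructors, accessors and show methods.

#' Construct a VelocityField4D
#'
#' @param data 5D numeric array (nx, ny, nz, nFrames, 3), velocity in m/s.
#' @param spacing numeric(3) voxel edge lengths in mm.
#' @param dt frame interval in ms.
#' @param venc velocity encoding limit in cm/s.
#' @param affine optional 4x4 voxel-to-world (mm) matrix; defaults to an
#'   axis-aligned grid centred on the world origin.
#' @return A [VelocityField4D-class] object.
#' @export
velocityField4D <- function(data, spacing, dt, venc, affine = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- .centeredAffine(dim(data)[1:3], spacing)
  new("VelocityField4D", data = data, spacing = as.numeric(spacing),
      dt = as.numeric(dt), venc = as.numeric(venc), affine = affine)
}

#' Construct a Mask4D
#'
#' @param data 4D array of 0/1 (nx, ny, nz, nFrames).
#' @param spacing numeric(3) voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world (mm) matrix.
#' @return A [Mask4D-class] object.
#' @export
mask4D <- function(data, spacing, affine = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- .centeredAffine(dim(data)[1:3], spacing)
  new("Mask4D", data = data, spacing = as.numeric(spacing), affine = affine)
}

#' Construct a Landmarks object
#'
#' @param apex,mitralCenter,aorticCenter anatomical points, world mm.
#' @param mvProbe,aoProbe speed-probe points near the mitral/aortic
#'   orifices, world mm. Default to the respective orifice centres.
#' @return A [Landmarks-class] object.
#' @export
landmarks <- function(apex, mitralCenter, aorticCenter,
                      mvProbe = mitralCenter, aoProbe = aorticCenter) {
  new("Landmarks", apex = as.numeric(apex),
      mitralCenter = as.numeric(mitralCenter),
      aorticCenter = as.numeric(aorticCenter),
      mvProbe = as.numeric(mvProbe), aoProbe = as.numeric(aoProbe))
}

#' Physical constants of blood
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, N s/m^2.
#' @return A [FluidConstants-class] object.
#' @export
fluidConstants <- function(rho = 1060, mu = 0.004) {
  new("FluidConstants", rho = rho, mu = mu)
}

#' @rdname nFrames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of cardiac time frames
#'
#' @param x a [VelocityField4D-class] or [Mask4D-class].
#' @return integer frame count.
#' @export
setMethod("nFrames", "VelocityField4D", function(x) dim(x@data)[4L])

#' @rdname nFrames
#' @export
setMethod("nFrames", "Mask4D", function(x) dim(x@data)[4L])

#' @rdname velocityData
#' @export
setGeneric("velocityData", function(x) standardGeneric("velocityData"))

#' Raw velocity array (m/s)
#' @param x a [VelocityField4D-class].
#' @return the 5D velocity array.
#' @export
setMethod("velocityData", "VelocityField4D", function(x) x@data)

#' @rdname maskData
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' Raw mask array (0/1)
#' @param x a [Mask4D-class].
#' @return the 4D mask array.
#' @export
setMethod("maskData", "Mask4D", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Voxel spacing in mm
#' @param x a [VelocityField4D-class] or [Mask4D-class].
#' @return numeric(3) spacing in mm.
#' @export
setMethod("voxelSpacing", "VelocityField4D", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "Mask4D", function(x) x@spacing)

# SI accessors: the single place where acquisition units become SI.
.spacingM <- function(x) x@spacing * 1e-3
.dtS <- function(x) x@dt * 1e-3
.vencMs <- function(x) x@venc / 100

#' Frame interval in ms
#' @param x a [VelocityField4D-class].
#' @return frame interval, ms.
#' @export
frameInterval <- function(x) x@dt

#' Velocity encoding limit in cm/s
#' @param x a [VelocityField4D-class].
#' @return VENC, cm/s.
#' @export
vencLimit <- function(x) x@venc

setMethod("show", "VelocityField4D", function(object) {
  d <- dim(object@data)
  cat("VelocityField4D:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "frames\n")
  cat(sprintf("  spacing %s mm | dt %.2f ms | VENC %.0f cm/s\n",
              paste(format(object@spacing), collapse = " x "),
              object@dt, object@venc))
  cat(sprintf("  speed range %.3f .. %.3f m/s\n",
              min(abs(object@data)), max(abs(object@data))))
})

setMethod("show", "Mask4D", function(object) {
  d <- dim(object@data)
  counts <- apply(object@data, 4L, sum)
  vol <- counts * prod(object@spacing) / 1e3   # ml
  cat("Mask4D:", paste(d[1:3], collapse = " x "), "voxels,", d[4L], "frames\n")
  cat(sprintf("  lumen volume %.1f .. %.1f ml\n", min(vol), max(vol)))
})

setMethod("show", "Landmarks", function(object) {
  p <- function(v) sprintf("(%.1f, %.1f, %.1f)", v[1L], v[2L], v[3L])
  cat("Landmarks [mm]: apex", p(object@apex),
      "mitral", p(object@mitralCenter),
      "aortic", p(object@aorticCenter), "\n")
})

setMethod("show", "ForceSeries", function(object) {
  mag <- sqrt(rowSums(object@F^2))
  cat("ForceSeries:", nrow(object@F), "frames, peak |F| =",
      format(max(mag), digits = 4), "N\n")
  if (length(object@fLax))
    cat(sprintf("  peak |f_lax| %.4g N, peak |f_sax| %.4g N\n",
                max(abs(object@fLax)), max(abs(object@fSax))))
})

setMethod("show", "CardiacPhases", function(object) {
  iv <- function(w) if (length(w)) sprintf("[%d, %d]", min(w), max(w)) else "undefined"
  cat("CardiacPhases: systole", iv(object@systole),
      "diastole", iv(object@diastole),
      "| E", iv(object@eWave), "A", iv(object@aWave), "\n")
})

#' Force vectors as a matrix
#' @param x a [ForceSeries-class].
#' @return nFrames x 3 matrix of forces in N.
#' @export
forceVectors <- function(x) x@F

#' Long-axis force component per frame
#' @param x a projected [ForceSeries-class].
#' @return numeric vector, N (positive towards the base/atrium).
#' @export
forceLax <- function(x) x@fLax

#' Short-axis force component per frame
#' @param x a projected [ForceSeries-class].
#' @return numeric vector, N (positive towards the inferolateral wall).
#' @export
forceSax <- function(x) x@fSax
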