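# On-disk formats. A subject dataset is either
#  * a NIfTI directory: velocity.nii (5D: x,y,z,t,component) or three 4D
#    component files velocity_x/y/z.nii, mask.nii, and meta.yaml carrying
#    spacing/dt/venc/affine/landmarks and the on-disk velocity unit; or
#  * one HDF5 file with a group per subject holding datasets
#    velocity (t,z,y,x,3) and mask (t,z,y,x) plus the same metadata as
#    attributes (requires the rhdf5 package).
# Velocities are converted to m/s at load, whatever the on-disk unit; all
# downstream physics is SI.

.unitFactor <- function(units) {
  switch(units,
         "m/s" = 1, "cm/s" = 1e-2, "mm/s" = 1e-3,
         stop("unrecognized velocity unit: ", units, call. = FALSE))
}

.landmarksToList <- function(lm) {
  list(apex = lm@apex, mitral_center = lm@mitralCenter,
       aortic_center = lm@aorticCenter, mv_probe = lm@mvProbe,
       ao_probe = lm@aoProbe)
}

.landmarksFromList <- function(l) {
  landmarks(as.numeric(l$apex), as.numeric(l$mitral_center),
            as.numeric(l$aortic_center),
            mvProbe = as.numeric(l$mv_probe),
            aoProbe = as.numeric(l$ao_probe))
}

#' Save a subject 4D flow dataset
#'
#' @param dataset list with `flow` ([VelocityField4D-class]), `mask`
#'   ([Mask4D-class]) and `landmarks` ([Landmarks-class]).
#' @param path target directory (NIfTI) or `.h5` file (HDF5).
#' @param format "nifti" or "hdf5".
#' @param velocityUnits unit to declare and store velocities in on disk
#'   ("m/s", "cm/s" or "mm/s").
#' @param group HDF5 group name for the subject.
#' @return `path`, invisibly.
#' @export
saveFlowDataset <- function(dataset, path, format = c("nifti", "hdf5"),
                            velocityUnits = "m/s", group = "subject1") {
  format <- match.arg(format)
  fac <- .unitFactor(velocityUnits)
  flow <- dataset$flow; mask <- dataset$mask; lm <- dataset$landmarks
  stopifnot(is(flow, "VelocityField4D"), is(mask, "Mask4D"),
            is(lm, "Landmarks"))
  meta <- list(spacing_mm = flow@spacing, dt_ms = flow@dt,
               venc_cms = flow@venc, velocity_units = velocityUnits,
               affine = as.numeric(flow@affine),
               landmarks = .landmarksToList(lm))
  if (format == "nifti") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    RNifti::writeNifti(RNifti::asNifti(flow@data / fac),
                       file.path(path, "velocity.nii"))
    RNifti::writeNifti(RNifti::asNifti(mask@data),
                       file.path(path, "mask.nii"))
    yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 support requires the rhdf5 package", call. = FALSE)
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, group)
    # on-disk layout: velocity (t,z,y,x,3), mask (t,z,y,x)
    rhdf5::h5write(aperm(flow@data / fac, c(4L, 3L, 2L, 1L, 5L)), path,
                   paste0(group, "/velocity"))
    rhdf5::h5write(aperm(mask@data, c(4L, 3L, 2L, 1L)), path,
                   paste0(group, "/mask"))
    rhdf5::h5write(flow@spacing, path, paste0(group, "/spacing_mm"))
    rhdf5::h5write(flow@dt, path, paste0(group, "/dt_ms"))
    rhdf5::h5write(flow@venc, path, paste0(group, "/venc_cms"))
    rhdf5::h5write(flow@affine, path, paste0(group, "/affine"))
    rhdf5::h5write(velocityUnits, path, paste0(group, "/velocity_units"))
    for (nm in names(.landmarksToList(lm)))
      rhdf5::h5write(.landmarksToList(lm)[[nm]], path,
                     paste0(group, "/landmarks_", nm))
    rhdf5::h5closeAll()
  }
  invisible(path)
}

.loadNifti <- function(path) {
  metaFile <- file.path(path, "meta.yaml")
  if (!file.exists(metaFile))
    stop("format error: meta.yaml not found in ", path, call. = FALSE)
  meta <- yaml::read_yaml(metaFile)
  fac <- .unitFactor(meta$velocity_units)
  asPlain <- function(img) array(as.numeric(img), dim(img))
  velFile <- file.path(path, "velocity.nii")
  if (file.exists(velFile)) {
    vel <- asPlain(RNifti::readNifti(velFile))
    if (length(dim(vel)) != 5L || dim(vel)[5L] != 3L)
      stop("format error: velocity.nii must be 5D with 3 components",
           call. = FALSE)
  } else {
    comp <- file.path(path, sprintf("velocity_%s.nii", c("x", "y", "z")))
    have <- file.exists(comp)
    if (!all(have))
      stop(sprintf("format error: %d of 3 velocity component files present",
                   sum(have)), call. = FALSE)
    parts <- lapply(comp, function(f) asPlain(RNifti::readNifti(f)))
    d <- dim(parts[[1L]])
    if (length(d) != 4L || !all(vapply(parts, function(p)
      identical(dim(p), d), logical(1L))))
      stop("format error: component volumes must be congruent 4D arrays",
           call. = FALSE)
    vel <- array(0, c(d, 3L))
    for (c in 1:3) vel[, , , , c] <- parts[[c]]
  }
  maskFile <- file.path(path, "mask.nii")
  if (!file.exists(maskFile))
    stop("format error: mask.nii not found", call. = FALSE)
  maskArr <- asPlain(RNifti::readNifti(maskFile))
  list(vel = vel * fac, mask = maskArr, meta = meta)
}

.loadHdf5 <- function(path, group) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 support requires the rhdf5 package", call. = FALSE)
  on.exit(rhdf5::h5closeAll())
  nm <- rhdf5::h5ls(path)
  has <- function(d) any(nm$name == d & nm$group == paste0("/", group))
  if (!has("velocity") || !has("mask"))
    stop("format error: group must hold velocity and mask datasets",
         call. = FALSE)
  rd <- function(d) rhdf5::h5read(path, paste0(group, "/", d))
  fac <- .unitFactor(as.character(rd("velocity_units")))
  vel <- aperm(rd("velocity"), c(4L, 3L, 2L, 1L, 5L))
  maskArr <- aperm(rd("mask"), c(4L, 3L, 2L, 1L))
  lmNames <- c("apex", "mitral_center", "aortic_center", "mv_probe", "ao_probe")
  meta <- list(spacing_mm = as.numeric(rd("spacing_mm")),
               dt_ms = as.numeric(rd("dt_ms")),
               venc_cms = as.numeric(rd("venc_cms")),
               affine = as.numeric(rd("affine")),
               landmarks = stats::setNames(
                 lapply(lmNames, function(l) as.numeric(rd(paste0("landmarks_", l)))),
                 lmNames))
  list(vel = vel * fac, mask = maskArr, meta = meta)
}

#' Load a subject 4D flow dataset
#'
#' Reads the velocity volumes, the lumen mask and the landmark/metadata
#' sidecar, validates geometry congruence and returns fully constructed
#' objects with velocities in m/s regardless of the on-disk unit.
#'
#' @param path NIfTI directory or HDF5 file written by
#'   [saveFlowDataset()].
#' @param format "nifti" or "hdf5".
#' @param group HDF5 subject group name.
#' @return list with `flow`, `mask`, `landmarks`.
#' @export
loadFlowDataset <- function(path, format = c("nifti", "hdf5"),
                            group = "subject1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  raw <- if (format == "nifti") .loadNifti(path) else .loadHdf5(path, group)
  if (!all(dim(raw$vel)[1:4] == dim(raw$mask)))
    stop("geometry error: mask grid does not match the velocity grid",
         call. = FALSE)
  meta <- raw$meta
  affine <- matrix(as.numeric(meta$affine), 4L, 4L)
  flow <- velocityField4D(raw$vel, as.numeric(meta$spacing_mm),
                          as.numeric(meta$dt_ms), as.numeric(meta$venc_cms),
                          affine)
  mask <- mask4D(array(as.numeric(raw$mask > 0.5), dim(raw$mask)),
                 as.numeric(meta$spacing_mm), affine)
  list(flow = flow, mask = mask,
       landmarks = .landmarksFromList(meta$landmarks))
}

#' Save a cohort results table
#'
#' One CSV row per subject, stable column order; a save/load roundtrip
#' reproduces the values to full precision.
#'
#' @param table non-empty data.frame of per-subject results.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
saveResults <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("refusing to write an empty results table",
                              call. = FALSE)
  utils::write.csv(format(table, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Load a cohort results table written by [saveResults()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
loadResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Temporal resolution of an interleaved phase-contrast acquisition
#'
#' With N-point velocity encoding, a k-space segmentation factor k and
#' repetition time TR, each cardiac time frame costs N * k * TR
#' milliseconds. The defaults (4-point encoding, k = 3, TR = 4.4 ms) give
#' the 52.8 ms frame spacing of a typical whole-heart protocol.
#'
#' @param nEncodings velocity-encoding points per k-space line (4 for
#'   three-directional encoding with a reference).
#' @param kSegmentation k-space segmentation factor.
#' @param trMs repetition time, ms.
#' @return temporal resolution, ms.
#' @export
temporalResolution <- function(nEncodings = 4, kSegmentation = 3, trMs = 4.4) {
  stopifnot(nEncodings > 0, kSegmentation > 0, trMs > 0)
  nEncodings * kSegmentation * trMs
}
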