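## Voxel volume constructors, accessors and NIfTI I/O.

#' Create an AnnotationVolume
#'
#' @param grid 3D integer array of region labels (0 = outside the brain).
#' @param voxelSize voxel edge length(s) in micrometers; a scalar is
#'   recycled to all three axes (cubic voxels).
#' @return an [AnnotationVolume-class].
#' @examples
#' av <- AnnotationVolume(array(1L, c(2, 2, 2)), 25)
#' voxelVolumeMm3(av)  # 0.025^3
#' @export
AnnotationVolume <- function(grid, voxelSize = 25) {
  storage.mode(grid) <- "integer"
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("AnnotationVolume", grid = grid, voxelSize = as.numeric(voxelSize))
}

#' Create a ScalarVolume
#'
#' @param grid 3D numeric array (values >= 0).
#' @param voxelSize voxel edge length(s) in micrometers.
#' @param kind semantic tag: `"nissl-intensity"`, `"ish-filtered"`,
#'   `"binarized"` or `"cell-density"`.
#' @param coverage optional logical array marking covered voxels.
#' @return a [ScalarVolume-class].
#' @export
ScalarVolume <- function(grid, voxelSize = 25, kind = "ish-filtered",
                         coverage = NULL) {
  storage.mode(grid) <- "double"
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("ScalarVolume", grid = grid, voxelSize = as.numeric(voxelSize),
      kind = kind, coverage = coverage)
}

#' Volume accessors
#'
#' @param x an [AnnotationVolume-class] or [ScalarVolume-class].
#' @name volume-accessors
#' @return as documented per function.
NULL

#' @describeIn volume-accessors per-axis voxel sizes (micrometers)
#' @export
voxelSizes <- function(x) x@voxelSize

#' @describeIn volume-accessors volume of one voxel in mm^3
#' @export
voxelVolumeMm3 <- function(x) prod(x@voxelSize / 1000)

#' @describeIn volume-accessors the raw 3D array
#' @export
gridArray <- function(x) x@grid

#' @describeIn volume-accessors semantic tag of a ScalarVolume
#' @export
volumeKind <- function(x) x@kind

#' @describeIn volume-accessors logical coverage mask (always a full array)
#' @export
coverageMask <- function(x) {
  if (!is(x, "ScalarVolume") || is.null(x@coverage))
    array(TRUE, dim(x@grid))
  else x@coverage
}

## ---- NIfTI I/O ----------------------------------------------------------

#' Read/write volumes as NIfTI
#'
#' Volumes are persisted as NIfTI with the voxel size carried in the header
#' (pixdim, interpreted in micrometers). Annotation volumes are written with
#' an integer datatype. A coverage mask, when present, is written alongside
#' as `<path>.coverage.nii.gz`.
#'
#' @param x an [AnnotationVolume-class] or [ScalarVolume-class].
#' @param path target `.nii`/`.nii.gz` path.
#' @param kind semantic tag restored on read for scalar volumes.
#' @return `readAnnotationNifti`/`readScalarNifti` return the volume object.
#' @export
writeVolumeNifti <- function(x, path) {
  img <- RNifti::asNifti(x@grid, reference = NULL)
  RNifti::pixdim(img) <- x@voxelSize
  RNifti::writeNifti(img, path,
                     datatype = if (is(x, "AnnotationVolume")) "int32" else "double")
  if (is(x, "ScalarVolume") && !is.null(x@coverage)) {
    cov <- RNifti::asNifti(array(as.integer(x@coverage), dim(x@grid)))
    RNifti::pixdim(cov) <- x@voxelSize
    RNifti::writeNifti(cov, paste0(path, ".coverage.nii.gz"), datatype = "uint8")
  }
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readAnnotationNifti <- function(path) {
  img <- RNifti::readNifti(path)
  AnnotationVolume(array(as.integer(img), dim(img)[1:3]),
                   RNifti::pixdim(img)[1:3])
}

#' @rdname writeVolumeNifti
#' @export
readScalarNifti <- function(path, kind = "ish-filtered") {
  img <- RNifti::readNifti(path)
  covPath <- paste0(path, ".coverage.nii.gz")
  cov <- NULL
  if (file.exists(covPath)) {
    ci <- RNifti::readNifti(covPath)
    cov <- array(as.integer(ci) != 0L, dim(ci)[1:3])
  }
  ScalarVolume(array(as.numeric(img), dim(img)[1:3]),
               RNifti::pixdim(img)[1:3], kind = kind, coverage = cov)
}
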