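## ISH slice-stack processing: interpolation to a full volume, Otsu
## binarization, multi-experiment combination and region mean intensities.

#' Create a SliceStack
#'
#' @param slices list of non-negative numeric matrices (one per section).
#' @param positions 1-based plane indices along axis 1 of the reference
#'   volume, strictly increasing.
#' @param marker marker tag: `"GAD67"`, `"PV"`, `"SST"` or `"VIP"`.
#' @return a [SliceStack-class].
#' @export
SliceStack <- function(slices, positions, marker) {
  new("SliceStack", slices = lapply(slices, function(s) {
    storage.mode(s) <- "double"; s
  }), positions = as.integer(positions), marker = marker)
}

#' Write/read a slice stack as PNG files plus a sidecar CSV
#'
#' Each section is stored as an 8-bit grayscale PNG (`slice_<plane>.png`,
#' values min-max scaled; the scale is recorded in the sidecar) and the
#' plane positions in `positions.csv` with columns `file`, `position`,
#' `scale`.
#'
#' @param stack a [SliceStack-class].
#' @param dir directory (created if needed).
#' @param marker marker tag used on read.
#' @return `readSliceStack` returns a [SliceStack-class].
#' @export
writeSliceStack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("slice_%04d.png", stack@positions)
  scales <- vapply(stack@slices, function(s) max(s, 1e-12), numeric(1))
  for (i in seq_along(stack@slices))
    png::writePNG(stack@slices[[i]] / scales[i], file.path(dir, files[i]))
  write.csv(data.frame(file = files, position = stack@positions,
                       scale = scales, marker = stack@marker),
            file.path(dir, "positions.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeSliceStack
#' @export
readSliceStack <- function(dir, marker = NULL) {
  meta <- read.csv(file.path(dir, "positions.csv"))
  slices <- lapply(seq_len(nrow(meta)), function(i) {
    img <- png::readPNG(file.path(dir, meta$file[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img * meta$scale[i]
  })
  SliceStack(slices, meta$position,
             marker = if (is.null(marker)) meta$marker[1] else marker)
}

#' Assemble a slice stack into a full volume by linear interpolation
#'
#' Planes that coincide with an input section take its values; planes
#' between two sections are per-pixel linear interpolations by fractional
#' position; planes outside the covered range are set to 0 and marked
#' uncovered in the coverage mask.
#'
#' @param stack a [SliceStack-class].
#' @param referenceDim integer length-3 shape of the reference volume.
#' @param voxelSize voxel size in micrometers.
#' @return a [ScalarVolume-class] of kind `"ish-filtered"` with a coverage
#'   mask.
#' @export
interpolateStack <- function(stack, referenceDim, voxelSize = 25) {
  sdim <- dim(stack@slices[[1]])
  if (!identical(as.integer(sdim), as.integer(referenceDim[2:3])))
    .fail("interpolateStack", "slice shape does not match reference cross-section")
  if (min(stack@positions) < 1L || max(stack@positions) > referenceDim[1])
    .fail("interpolateStack", "slice positions outside reference extent")
  grid <- array(0, referenceDim)
  coverage <- array(FALSE, referenceDim)
  pos <- stack@positions
  lo <- min(pos); hi <- max(pos)
  for (p in lo:hi) {
    j <- findInterval(p, pos)
    if (pos[j] == p) {
      plane <- stack@slices[[j]]
    } else {
      w <- (p - pos[j]) / (pos[j + 1] - pos[j])
      plane <- (1 - w) * stack@slices[[j]] + w * stack@slices[[j + 1]]
    }
    grid[p, , ] <- plane
    coverage[p, , ] <- TRUE
  }
  ScalarVolume(grid, voxelSize, kind = "ish-filtered", coverage = coverage)
}

#' Otsu threshold of in-brain expression values
#'
#' Computes the threshold maximizing the between-class variance over a
#' 256-bin histogram of the min-max-scaled values. Only in-brain
#' (annotation != 0), covered voxels enter the histogram, so the empty
#' background cannot drag the threshold to 0.
#'
#' @param x a [ScalarVolume-class] or a numeric vector of pixel values.
#' @param annotation optional [AnnotationVolume-class] restricting to
#'   in-brain voxels.
#' @param nbins number of histogram bins.
#' @return the threshold on the original value scale.
#' @export
otsuThreshold <- function(x, annotation = NULL, nbins = 256L) {
  if (is(x, "ScalarVolume")) {
    keep <- coverageMask(x)
    if (!is.null(annotation)) keep <- keep & (annotation@grid != 0L)
    v <- x@grid[keep]
  } else v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2L || rng[1] == rng[2])
    .fail("otsuThreshold", "no threshold separates classes (constant input)")
  s <- (v - rng[1]) / (rng[2] - rng[1])
  # histogram over nbins equal bins of [0, 1]; candidate cuts at bin edges
  bin <- pmin(floor(s * nbins) + 1L, nbins)
  cnt <- tabulate(bin, nbins)
  p <- cnt / sum(cnt)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)[-nbins]
  mu0 <- cumsum(p * mids)[-nbins]
  muT <- sum(p * mids)
  bcv <- ifelse(w0 > 0 & w0 < 1, (muT * w0 - mu0)^2 / (w0 * (1 - w0)), 0)
  k <- which.max(bcv)              # cut after bin k: threshold = k/nbins
  rng[1] + (k / nbins) * (rng[2] - rng[1])
}

#' Binarize a volume at a threshold
#'
#' Pixels strictly above the threshold become 1, all others 0. The coverage
#' mask is preserved.
#'
#' @param volume a [ScalarVolume-class].
#' @param threshold finite numeric threshold.
#' @return a [ScalarVolume-class] of kind `"binarized"`.
#' @export
binarize <- function(volume, threshold) {
  stopifnot(is.finite(threshold))
  ScalarVolume((volume@grid > threshold) * 1, volume@voxelSize,
               kind = "binarized", coverage = volume@coverage)
}

#' Combine aligned experiments by voxelwise mean
#'
#' The mean is taken over the experiments that cover each voxel; the
#' combined coverage mask is the union of the input masks. Voxels covered
#' by no experiment are 0 and uncovered.
#'
#' @param volumes non-empty list of aligned [ScalarVolume-class] objects of
#'   identical shape and kind.
#' @return a [ScalarVolume-class].
#' @export
combineExperiments <- function(volumes) {
  if (length(volumes) == 0L) .fail("combineExperiments", "empty volume list")
  dims <- unique(lapply(volumes, function(v) dim(v@grid)))
  kinds <- unique(vapply(volumes, function(v) v@kind, character(1)))
  if (length(dims) > 1L) .fail("combineExperiments", "volumes differ in shape")
  if (length(kinds) > 1L) .fail("combineExperiments", "volumes differ in kind")
  acc <- array(0, dims[[1]]); n <- array(0, dims[[1]])
  for (v in volumes) {
    cov <- coverageMask(v)
    acc <- acc + v@grid * cov
    n <- n + cov
  }
  out <- ifelse(n > 0, acc / pmax(n, 1), 0)
  ScalarVolume(array(out, dims[[1]]), volumes[[1]]@voxelSize, kind = kinds,
               coverage = array(n > 0, dims[[1]]))
}

#' Region mean intensity of a binarized volume
#'
#' For every region, the mean of the binarized values over the covered
#' voxels labeled anywhere in the region's subtree (hierarchical), together
#' with the voxel support. Regions whose subtree holds no covered voxel are
#' flagged (mean NA, support 0).
#'
#' @param binarized a [ScalarVolume-class] (kind `"binarized"`, but any
#'   scalar volume is accepted, e.g. for diagnostics).
#' @param annotation the paired [AnnotationVolume-class].
#' @param hierarchy a [RegionHierarchy-class].
#' @return data.frame with columns `region_id`, `mean`, `support`,
#'   `flagged` (subtree statistics) and `own_mean`, `own_support` (voxels
#'   directly labeled with the region id only).
#' @export
regionMeanIntensity <- function(binarized, annotation, hierarchy) {
  stopifnot(identical(dim(binarized@grid), dim(annotation@grid)))
  keep <- coverageMask(binarized) & (annotation@grid != 0L)
  labs <- annotation@grid[keep]
  vals <- binarized@grid[keep]
  ids <- regionIds(hierarchy)
  f <- factor(labs, levels = ids)
  ownSum <- setNames(numeric(length(ids)), as.character(ids))
  if (length(vals)) {
    tmp <- rowsum(vals, f)                    # only levels actually present
    ownSum[rownames(tmp)] <- tmp[, 1]
  }
  ownN <- setNames(as.numeric(table(f)), as.character(ids))
  totSum <- aggregateToParents(ownSum, hierarchy)
  totN <- aggregateToParents(ownN, hierarchy)
  k <- as.character(ids)
  data.frame(region_id = ids,
             mean = ifelse(totN[k] > 0, totSum[k] / pmax(totN[k], 1), NA_real_),
             support = as.integer(totN[k]),
             flagged = totN[k] == 0,
             own_mean = ifelse(ownN[k] > 0, ownSum[k] / pmax(ownN[k], 1), NA_real_),
             own_support = as.integer(ownN[k]),
             row.names = NULL)
}
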