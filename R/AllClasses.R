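## S4 classes for the atlas pipeline. Validity methods enforce the structural
## invariants; user code should go through the accessors, not @ slots.

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' RegionHierarchy: a brain-region ontology tree
#'
#' Stores the region set of an AIBS-style ontology: one row per region with
#' id, name, acronym and parent id (NA for the root), plus precomputed depths
#' and children lists. Region id 0 is reserved for "outside the brain" and is
#' never a region.
#'
#' @slot nodes data.frame with columns `id`, `name`, `acronym`, `parent_id`.
#' @slot root integer id of the unique root.
#' @slot depth named integer vector, depth per region (root = 0).
#' @slot children named list: children ids per region id.
#' @seealso [parseHierarchy()], [regionIds()], [depthOrdering()]
#' @export
setClass("RegionHierarchy",
  representation(nodes = "data.frame", root = "integer",
                 depth = "integer", children = "list"))

setValidity("RegionHierarchy", function(object) {
  nd <- object@nodes
  msgs <- character(0)
  if (!all(c("id", "name", "acronym", "parent_id") %in% names(nd)))
    return("nodes must have columns id, name, acronym, parent_id")
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "duplicate region id")
  if (any(nd$id <= 0)) msgs <- c(msgs, "region ids must be positive (0 is reserved for outside-brain)")
  roots <- nd$id[is.na(nd$parent_id)]
  if (length(roots) != 1L) msgs <- c(msgs, "hierarchy must have exactly one root")
  nonroot <- nd[!is.na(nd$parent_id), ]
  if (!all(nonroot$parent_id %in% nd$id))
    msgs <- c(msgs, "every non-root's parent must be in the region set")
  d <- object@depth[as.character(nd$id)]
  if (any(is.na(d))) msgs <- c(msgs, "depth missing for some region")
  else {
    pd <- object@depth[as.character(nonroot$parent_id)]
    cd <- object@depth[as.character(nonroot$id)]
    if (!all(cd == pd + 1L)) msgs <- c(msgs, "depth(child) must equal depth(parent) + 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' AnnotationVolume: 3D grid of region labels
#'
#' Integer 3D array of region ids (0 = outside the brain) with per-axis voxel
#' sizes in micrometers. Axis 1 is the rostro-caudal axis by convention.
#'
#' @slot grid 3D integer array of region labels.
#' @slot voxelSize numeric length-3 voxel edge lengths (micrometers).
#' @seealso [AnnotationVolume()], [regionVolumes()]
#' @export
setClass("AnnotationVolume",
  representation(grid = "array", voxelSize = "numeric"))

setValidity("AnnotationVolume", function(object) {
  msgs <- character(0)
  if (length(dim(object@grid)) != 3L) msgs <- c(msgs, "grid must be 3D")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msgs <- c(msgs, "voxelSize must be 3 positive lengths (micrometers)")
  g <- object@grid
  if (any(g < 0) || any(g != round(g))) msgs <- c(msgs, "labels must be non-negative integers")
  if (length(msgs)) msgs else TRUE
})

#' ScalarVolume: 3D grid of non-negative scalars with a semantic tag
#'
#' Float 3D array aligned to an [AnnotationVolume-class] (same shape and
#' voxel size). `kind` records the semantics: `"nissl-intensity"`,
#' `"ish-filtered"`, `"binarized"` or `"cell-density"` (cells/mm^3). The
#' `coverage` mask flags voxels actually covered by data (e.g. planes inside
#' the imaged slice range); uncovered voxels hold 0 and are excluded from
#' region statistics.
#'
#' @slot grid 3D numeric array, values >= 0.
#' @slot voxelSize numeric length-3, micrometers.
#' @slot kind character semantic tag.
#' @slot coverage logical array of the same shape, or NULL (fully covered).
#' @seealso [ScalarVolume()], [binarize()], [regionMeanIntensity()]
#' @export
setClass("ScalarVolume",
  representation(grid = "array", voxelSize = "numeric", kind = "character",
                 coverage = "arrayOrNULL"))

setValidity("ScalarVolume", function(object) {
  msgs <- character(0)
  if (length(dim(object@grid)) != 3L) msgs <- c(msgs, "grid must be 3D")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msgs <- c(msgs, "voxelSize must be 3 positive lengths (micrometers)")
  if (any(object@grid < 0, na.rm = TRUE)) msgs <- c(msgs, "values must be >= 0")
  if (!object@kind %in% c("nissl-intensity", "ish-filtered", "binarized", "cell-density"))
    msgs <- c(msgs, "unknown kind")
  if (object@kind == "binarized" && !all(object@grid %in% c(0, 1)))
    msgs <- c(msgs, "binarized volumes may only contain 0 and 1")
  if (!is.null(object@coverage) && !identical(dim(object@coverage), dim(object@grid)))
    msgs <- c(msgs, "coverage mask must match grid shape")
  if (length(msgs)) msgs else TRUE
})

#' SliceStack: aligned 2D marker-expression sections
#'
#' A list of equally shaped non-negative 2D images with strictly increasing
#' plane positions along axis 1 of the reference volume, for one genetic
#' marker (GAD67, PV, SST or VIP).
#'
#' @slot slices list of numeric matrices.
#' @slot positions integer plane indices (1-based, strictly increasing).
#' @slot marker character marker tag.
#' @seealso [SliceStack()], [interpolateStack()]
#' @export
setClass("SliceStack",
  representation(slices = "list", positions = "integer", marker = "character"))

setValidity("SliceStack", function(object) {
  msgs <- character(0)
  if (length(object@slices) < 1L) msgs <- c(msgs, "at least one slice required")
  if (length(object@slices) != length(object@positions))
    msgs <- c(msgs, "one position per slice required")
  if (is.unsorted(object@positions, strictly = TRUE))
    msgs <- c(msgs, "positions must be strictly increasing")
  dims <- unique(lapply(object@slices, dim))
  if (length(dims) > 1L) msgs <- c(msgs, "all slices must share one shape")
  if (any(vapply(object@slices, function(s) any(s < 0), logical(1))))
    msgs <- c(msgs, "slice values must be >= 0")
  if (!object@marker %in% .MARKERS) msgs <- c(msgs, "unknown marker")
  if (length(msgs)) msgs else TRUE
})

#' TransferFunction: through-origin linear map from intensity to density
#'
#' The slope `alpha` (cells/mm^3 per unit mean binarized intensity) of the
#' through-origin least-squares fit for one marker and one region group,
#' with the standard deviation of the slope, number of points and the
#' coefficient of determination.
#'
#' @slot marker character marker tag.
#' @slot group character, one of `"cerebellum"`, `"isocortex"`, `"rest"`,
#'   or `"all"` for pooled fits.
#' @slot alpha numeric slope, >= 0 (clipped at 0 if the raw fit is negative).
#' @slot stdAlpha numeric standard deviation of the slope.
#' @slot nPoints integer number of fit points.
#' @slot r2 numeric coefficient of determination (may be NA when undefined).
#' @seealso [fitAlpha()], [predictDensity()]
#' @export
setClass("TransferFunction",
  representation(marker = "character", group = "character", alpha = "numeric",
                 stdAlpha = "numeric", nPoints = "integer", r2 = "numeric"))

setValidity("TransferFunction", function(object) {
  msgs <- character(0)
  if (object@alpha < 0) msgs <- c(msgs, "alpha must be >= 0")
  if (object@stdAlpha < 0) msgs <- c(msgs, "stdAlpha must be >= 0")
  if (!is.na(object@r2) && object@r2 > 1 + 1e-12) msgs <- c(msgs, "R^2 cannot exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' DensityEstimates: unconstrained per-region, per-type count estimates
#'
#' One row per (region, type, scope): `scope == "total"` rows cover the full
#' subtree of the region (the LP's density variables), `scope == "own"` rows
#' cover the voxels directly labeled with a parent region's id (the Eq-8
#' own-voxel term). `eta`/`sigma` are the unconstrained estimate and its
#' standard deviation in counts; `value` carries the current working value
#' (initially `eta`, updated by the capping/coherence pre-pass).
#'
#' @slot estimates data.frame with columns `region_id`, `type`, `scope`,
#'   `eta`, `sigma`, `value`, `provenance`.
#' @seealso [assembleEstimates()], [capToNeurons()], [buildLP()]
#' @export
setClass("DensityEstimates", representation(estimates = "data.frame"))

setValidity("DensityEstimates", function(object) {
  e <- object@estimates
  need <- c("region_id", "type", "scope", "eta", "sigma", "value", "provenance")
  if (!all(need %in% names(e))) return("missing estimate columns")
  msgs <- character(0)
  if (!all(e$type %in% .TYPES)) msgs <- c(msgs, "unknown neuron type")
  if (!all(e$scope %in% c("total", "own"))) msgs <- c(msgs, "scope must be total or own")
  if (any(!is.finite(e$eta)) || any(!is.finite(e$sigma)))
    msgs <- c(msgs, "eta and sigma must be finite")
  if (any(e$eta < 0) || any(e$sigma < 0)) msgs <- c(msgs, "eta and sigma must be >= 0")
  tot <- e[e$scope == "total", ]
  if (anyDuplicated(tot[c("region_id", "type")]))
    msgs <- c(msgs, "one total estimate per (region, type)")
  if (length(msgs)) msgs else TRUE
})

#' LPProblem: the weighted-slack density reconciliation program
#'
#' Linear program over count variables `x` (one per region and type, plus an
#' own-voxel variable per parent region) and slack variables `z` (one per
#' total variable). Constraints: bounds 0 <= x <= nNeu, the subtype-sum
#' window -nNeu <= nPV+nSST+nVIP-nGAD <= 0 per region, the hierarchy
#' equality per parent and type, and the slack envelope -z <= x - eta <= z.
#' The objective is sum(z/sigma).
#'
#' @slot obj numeric objective coefficients (one per column).
#' @slot mat sparse constraint matrix (`Matrix::dgCMatrix`).
#' @slot dir character constraint directions (`"<="` or `"=="`).
#' @slot rhs numeric right-hand sides.
#' @slot vars data.frame describing each column: `name`, `region_id`,
#'   `type`, `role` in `{x_total, x_own, z_total}`, `eta`, `sigma`.
#' @seealso [buildLP()], [solveLP()], [nDensityVariables()]
#' @export
setClass("LPProblem",
  representation(obj = "numeric", mat = "Matrix", dir = "character",
                 rhs = "numeric", vars = "data.frame"))

setValidity("LPProblem", function(object) {
  msgs <- character(0)
  if (length(object@obj) != ncol(object@mat)) msgs <- c(msgs, "objective length != #columns")
  if (length(object@dir) != nrow(object@mat) || length(object@rhs) != nrow(object@mat))
    msgs <- c(msgs, "dir/rhs length != #rows")
  if (!all(object@dir %in% c("<=", "==", ">="))) msgs <- c(msgs, "bad constraint direction")
  if (nrow(object@vars) != ncol(object@mat)) msgs <- c(msgs, "vars must describe every column")
  w <- object@obj[object@vars$role == "z_total"]
  if (any(!is.finite(w)) || any(w <= 0)) msgs <- c(msgs, "slack weights must be finite and > 0")
  if (length(msgs)) msgs else TRUE
})

#' LPSolution: solved, hierarchy-consistent counts
#'
#' @slot solution data.frame: one row per variable with `region_id`, `type`,
#'   `scope`, `eta`, `sigma`, `x` (corrected count), `z` (slack, totals
#'   only), `flagged` (|x - eta| > sigma, totals only).
#' @slot objective numeric optimal objective value.
#' @slot status character solver status (`"optimal"`).
#' @seealso [solveLP()], [flagCorrections()], [deriveResiduals()]
#' @export
setClass("LPSolution",
  representation(solution = "data.frame", objective = "numeric",
                 status = "character"))

## ---- show methods -------------------------------------------------------

setMethod("show", "RegionHierarchy", function(object) {
  cat(sprintf("RegionHierarchy: %d regions, depth 0..%d, root '%s' (id %d)\n",
              nrow(object@nodes), max(object@depth),
              object@nodes$acronym[object@nodes$id == object@root], object@root))
  cat(sprintf("  leaves: %d\n", length(leafIds(object))))
})

setMethod("show", "AnnotationVolume", function(object) {
  cat(sprintf("AnnotationVolume: %s voxels @ %s um, %d distinct labels (%.1f%% in-brain)\n",
              paste(dim(object@grid), collapse = "x"),
              paste(object@voxelSize, collapse = "x"),
              length(setdiff(unique(as.vector(object@grid)), 0L)),
              100 * mean(object@grid != 0)))
})

setMethod("show", "ScalarVolume", function(object) {
  cov <- if (is.null(object@coverage)) 1 else mean(object@coverage)
  cat(sprintf("ScalarVolume[%s]: %s voxels @ %s um, range [%.4g, %.4g], coverage %.1f%%\n",
              object@kind, paste(dim(object@grid), collapse = "x"),
              paste(object@voxelSize, collapse = "x"),
              min(object@grid), max(object@grid), 100 * cov))
})

setMethod("show", "SliceStack", function(object) {
  cat(sprintf("SliceStack[%s]: %d slices of %s, planes %d..%d\n",
              object@marker, length(object@slices),
              paste(dim(object@slices[[1]]), collapse = "x"),
              min(object@positions), max(object@positions)))
})

setMethod("show", "TransferFunction", function(object) {
  cat(sprintf("TransferFunction %s/%s: alpha = %.6g (sd %.3g), R^2 = %s, n = %d\n",
              object@marker, object@group, object@alpha, object@stdAlpha,
              ifelse(is.na(object@r2), "NA", sprintf("%.3f", object@r2)),
              object@nPoints))
})

setMethod("show", "DensityEstimates", function(object) {
  e <- object@estimates
  cat(sprintf("DensityEstimates: %d totals (%d regions x 4 types), %d own-voxel rows\n",
              sum(e$scope == "total"), length(unique(e$region_id[e$scope == "total"])),
              sum(e$scope == "own")))
  cat("  provenance:", paste(sprintf("%s=%d", names(table(e$provenance)),
                                     as.integer(table(e$provenance))), collapse = ", "), "\n")
})

setMethod("show", "LPProblem", function(object) {
  cat(sprintf("LPProblem: %d density variables, %d own-voxel variables, %d slacks; %d constraints\n",
              sum(object@vars$role == "x_total"), sum(object@vars$role == "x_own"),
              sum(object@vars$role == "z_total"), nrow(object@mat)))
})

setMethod("show", "LPSolution", function(object) {
  s <- object@solution
  tot <- s[s$scope == "total", ]
  cat(sprintf("LPSolution [%s]: objective %.6g; %d/%d total estimates corrected beyond sigma\n",
              object@status, object@objective, sum(tot$flagged), nrow(tot)))
})
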