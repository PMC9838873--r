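## Cell placement: acceptance-rejection voxel sampling against the cell
## density distribution, nested type labelling and in-voxel jitter.

#' Sample cell-to-voxel assignments for each region
#'
#' For every region with a positive target, voxels directly labeled with
#' the region id are sampled with probability proportional to the density
#' volume, with replacement and no per-voxel capacity, until the target
#' count is reached. Deterministic given the seed.
#'
#' @param density a [ScalarVolume-class] (cell or neuron density).
#' @param targets named numeric target counts per region id (own-voxel
#'   scope); fractional values are rounded.
#' @param annotation an [AnnotationVolume-class].
#' @param seed integer seed.
#' @return data.frame with columns `voxel` (linear index into the grid)
#'   and `region_id`, one row per cell.
#' @export
placeCells <- function(density, targets, annotation, seed = 1L) {
  set.seed(stageSeed(seed, "placeCells"))
  lab <- as.vector(annotation@grid)
  dens <- as.vector(density@grid)
  out <- vector("list", length(targets))
  ids <- as.integer(names(targets))
  for (k in seq_along(targets)) {
    n <- round(targets[[k]])
    if (n <= 0) next
    vox <- which(lab == ids[k])
    if (!length(vox) || sum(dens[vox]) <= 0)
      .fail("placeCells", "region ", ids[k],
            " has a positive target but zero total density")
    draws <- as.vector(rmultinom(1, n, dens[vox]))
    out[[k]] <- data.frame(voxel = rep(vox, draws), region_id = ids[k])
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(data.frame(voxel = integer(0), region_id = integer(0)))
  do.call(rbind, out)
}

#' Assign nested neuron-type labels to placed cells
#'
#' Within every region: a uniform subset of size nGAD is labeled
#' inhibitory; among the inhibitory cells, nPV are labeled PV, then nSST
#' of the remaining are labeled SST, then nVIP of the remaining VIP; the
#' leftover inhibitory cells are InhR and all non-inhibitory cells
#' ExcOther. Counts are exact per region and label; the selection is
#' uniform among the cells still unlabeled at each stage.
#'
#' @param cells data.frame from [placeCells()].
#' @param typeCounts data.frame with columns `region_id`, `nGAD`, `nPV`,
#'   `nSST`, `nVIP` (integer counts per region, own-voxel scope).
#' @param seed integer seed.
#' @return `cells` with an added `label` column
#'   (`PV`/`SST`/`VIP`/`InhR`/`ExcOther`).
#' @export
assignTypes <- function(cells, typeCounts, seed = 1L) {
  set.seed(stageSeed(seed, "assignTypes"))
  cells$label <- "ExcOther"
  for (i in seq_len(nrow(typeCounts))) {
    r <- typeCounts$region_id[i]
    idx <- which(cells$region_id == r)
    nGAD <- round(typeCounts$nGAD[i]); nPV <- round(typeCounts$nPV[i])
    nSST <- round(typeCounts$nSST[i]); nVIP <- round(typeCounts$nVIP[i])
    if (nGAD > length(idx) || nPV + nSST + nVIP > nGAD)
      .fail("assignTypes", "region ", r,
            ": type counts violate nPV+nSST+nVIP <= nGAD <= nNeu")
    inh <- sample(idx, nGAD)
    labels <- rep("InhR", nGAD)
    if (nGAD > 0) {
      stages <- c(PV = nPV, SST = nSST, VIP = nVIP)
      pool <- sample(nGAD)                    # uniform order of inhibitory cells
      at <- 0L
      for (lb in names(stages)) {
        if (stages[[lb]] > 0) {
          labels[pool[at + seq_len(stages[[lb]])]] <- lb
          at <- at + stages[[lb]]
        }
      }
    }
    cells$label[inh] <- labels
  }
  cells
}

#' Jitter cells to uniform positions inside their voxels
#'
#' Each cell receives a world position drawn uniformly within the bounds
#' of its voxel; the world coordinate of a voxel corner is
#' `(index - 1) * voxelSize` (0-based voxel indexing convention).
#'
#' @param cells data.frame with a `voxel` column (linear indices).
#' @param gridDim integer length-3 grid shape.
#' @param voxelSize numeric length-1 or length-3 voxel size (micrometers).
#' @param seed integer seed.
#' @return `cells` with added columns `x`, `y`, `z` (micrometers).
#' @export
jitterPositions <- function(cells, gridDim, voxelSize = 25, seed = 1L) {
  set.seed(stageSeed(seed, "jitterPositions"))
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  idx <- arrayInd(cells$voxel, gridDim)
  n <- nrow(cells)
  cells$x <- (idx[, 1] - 1 + runif(n)) * voxelSize[1]
  cells$y <- (idx[, 2] - 1 + runif(n)) * voxelSize[2]
  cells$z <- (idx[, 3] - 1 + runif(n)) * voxelSize[3]
  cells
}

#' Integer per-region label targets from solved counts
#'
#' Converts the solved fractional own-voxel counts of a region into exact
#' integer targets for the five placement labels, using largest-remainder
#' rounding so that the labels sum to the rounded neuron count of the
#' region.
#'
#' @param solution an [LPSolution-class].
#' @param nNeuOwn named numeric own-voxel neuron counts.
#' @param hierarchy a [RegionHierarchy-class].
#' @return data.frame `region_id`, `nNeu`, `nGAD`, `nPV`, `nSST`, `nVIP`,
#'   `nInhR`, `nExcOther` (all integers; `nGAD = nPV+nSST+nVIP+nInhR`).
#' @export
placementTargets <- function(solution, nNeuOwn, hierarchy) {
  s <- solution@solution
  ids <- regionIds(hierarchy)
  rows <- lapply(ids, function(r) {
    scope <- if (length(childrenOf(hierarchy, r))) "own" else "total"
    sub <- s[s$region_id == r & s$scope == scope, ]
    v <- setNames(sub$x, sub$type)[.TYPES]
    nn <- round(unname(nNeuOwn[as.character(r)]))
    inhr <- max(v["GAD67"] - sum(v[c("PV", "SST", "VIP")]), 0)
    exc <- max(nn - v["GAD67"], 0)
    parts <- roundPreserveSum(c(v["PV"], v["SST"], v["VIP"], inhr, exc), nn)
    data.frame(region_id = r, nNeu = nn,
               nGAD = sum(parts[1:4]), nPV = parts[1], nSST = parts[2],
               nVIP = parts[3], nInhR = parts[4], nExcOther = parts[5])
  })
  do.call(rbind, rows)
}
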