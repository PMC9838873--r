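## Synthetic toy brains with known ground truth. The generator emulates the
## statistical structure the pipeline assumes: a nested-box annotation
## volume whose regions carry homogeneous per-type densities satisfying all
## reconciliation constraints exactly, a Nissl volume proportional to total
## cell density, per-marker expression stacks whose region mean binarized
## intensity equals density/alpha, and a literature table with
## multiplicative log-normal noise.

#' Specification of a toy brain fixture
#'
#' The defaults define the package's standard study conditions: a 3-level
#' hierarchy (3 x 2 x 2 branching, 22 regions), a 64 x 20 x 20 grid of
#' 25 um voxels, sections every 8 planes (200 um), literature covering 50%
#' of the regions with a coefficient of variation of 0.2, and
#' marker-to-density slopes of realistic magnitude (1e5-6e5 cells/mm^3 per
#' unit intensity, denser cerebellum-like subtree).
#'
#' @param branching integer children per node at each level below the root.
#' @param gridDim integer length-3 grid shape (axis 1 = rostro-caudal).
#' @param voxelSize voxel edge (micrometers).
#' @param neuronFraction fraction of cells that are neurons.
#' @param neuronDensityRange range of per-region neuron densities
#'   (cells/mm^3) outside the cerebellum-like subtree.
#' @param cerebellumFactor density multiplier for the cerebellum-like
#'   subtree.
#' @param gadFracRange range of the GABAergic fraction of neurons.
#' @param subtypeFracRange range of the PV+SST+VIP fraction of GAD67.
#' @param trueAlpha named list per marker of named numeric
#'   `c(cerebellum=, isocortex=, rest=)` slopes.
#' @param literatureCoverage fraction of regions with literature records.
#' @param literatureCV multiplicative coefficient of variation of
#'   literature means (0 = exact).
#' @param recordsPerRegion integer range of records per (region, marker).
#' @param slicePeriod planes between sections (1 = every plane).
#' @param misalignShift integer in-plane shift (voxels) applied to
#'   sections, emulating misalignment.
#' @param seed master seed.
#' @return a list of class `"toyBrainSpec"`.
#' @export
toyBrainSpec <- function(branching = c(3, 2, 2), gridDim = c(64, 20, 20),
                         voxelSize = 25, neuronFraction = 0.5,
                         neuronDensityRange = c(3e4, 1.2e5),
                         cerebellumFactor = 3,
                         gadFracRange = c(0.08, 0.45),
                         subtypeFracRange = c(0.5, 0.9),
                         trueAlpha = list(
                           GAD67 = c(cerebellum = 6e5, isocortex = 3e5, rest = 3.5e5),
                           PV = c(cerebellum = 4.5e5, isocortex = 3e5, rest = 1.2e5),
                           SST = c(cerebellum = 1.4e5, isocortex = 2.5e5, rest = 3.2e5),
                           VIP = c(cerebellum = 4e5, isocortex = 2e5, rest = 1.5e5)),
                         literatureCoverage = 0.5, literatureCV = 0.2,
                         recordsPerRegion = c(1L, 3L), slicePeriod = 8L,
                         misalignShift = 0L, seed = 1L) {
  spec <- list(branching = branching, gridDim = gridDim, voxelSize = voxelSize,
               neuronFraction = neuronFraction,
               neuronDensityRange = neuronDensityRange,
               cerebellumFactor = cerebellumFactor,
               gadFracRange = gadFracRange, subtypeFracRange = subtypeFracRange,
               trueAlpha = trueAlpha, literatureCoverage = literatureCoverage,
               literatureCV = literatureCV, recordsPerRegion = recordsPerRegion,
               slicePeriod = as.integer(slicePeriod),
               misalignShift = as.integer(misalignShift), seed = as.integer(seed))
  stopifnot(all(branching >= 1), length(gridDim) == 3, voxelSize > 0,
            literatureCoverage >= 0, literatureCoverage <= 1,
            literatureCV >= 0, misalignShift >= 0)
  class(spec) <- "toyBrainSpec"
  spec
}

#' Noise-free variant of the standard toy spec
#'
#' Full literature coverage, zero literature noise, a section on every
#' plane and no misalignment: the pipeline's inputs then determine the
#' ground truth exactly and a correct implementation must return it
#' unchanged (LP objective 0).
#'
#' @param seed master seed.
#' @param ... overrides passed to [toyBrainSpec()].
#' @return a `"toyBrainSpec"`.
#' @export
noiselessToySpec <- function(seed = 1L, ...)
  toyBrainSpec(literatureCoverage = 1, literatureCV = 0, slicePeriod = 1L,
               misalignShift = 0L, seed = seed, ...)

#' Generate the toy atlas: hierarchy, annotation, Nissl and ground truth
#'
#' The grid (minus a 1-voxel outside-brain border) is partitioned into
#' nested boxes matching the hierarchy: every parent keeps a 2-plane slab
#' of directly-labeled voxels and splits the remainder of its box equally
#' among its children, cycling the split axis with depth. Each region's
#' own voxels carry homogeneous true densities per neuron type, drawn so
#' that all reconciliation constraints hold exactly; the first leaf of the
#' isocortex-like subtree is purely inhibitory. The Nissl volume is
#' proportional to total cell density.
#'
#' @param spec a [toyBrainSpec()].
#' @return list with `hierarchy`, `annotation` ([AnnotationVolume-class]),
#'   `nissl` ([ScalarVolume-class]), `truth` (list of named vectors: own
#'   and total counts per type, see below), `volumes`/`ownVolumes` (mm^3),
#'   `groups`, `purelyInhibitory`, `spec`. `truth$own` and `truth$total`
#'   are data.frames with columns `region_id`, `nNeu`, `nCell`, `PV`,
#'   `SST`, `VIP`, `GAD67`.
#' @export
makeToyAtlas <- function(spec) {
  set.seed(stageSeed(spec$seed, "atlas"))
  ## ---- hierarchy ----
  nodes <- data.frame(id = 1L, name = "root", acronym = "root",
                      parent_id = NA_integer_)
  nextId <- 2L
  frontier <- 1L
  for (lev in seq_along(spec$branching)) {
    newFrontier <- integer(0)
    for (p in frontier) {
      for (k in seq_len(spec$branching[lev])) {
        acr <- if (lev == 1L) c("ISO", "CB", paste0("OTH", k - 2L))[min(k, 3)]
               else paste0(nodes$acronym[nodes$id == p], ".", k)
        nodes <- rbind(nodes, data.frame(id = nextId, name = acr, acronym = acr,
                                         parent_id = p))
        newFrontier <- c(newFrontier, nextId)
        nextId <- nextId + 1L
      }
    }
    frontier <- newFrontier
  }
  hierarchy <- RegionHierarchy(nodes)
  ## ---- nested-box annotation ----
  dims <- spec$gridDim
  grid <- array(0L, dims)
  assignBox <- function(id, box, depth) {
    ch <- childrenOf(hierarchy, id)
    if (!length(ch)) {
      grid[box[[1]], box[[2]], box[[3]]] <<- id
      return(invisible(NULL))
    }
    ax <- (depth %% 3L) + 1L
    planes <- box[[ax]]
    if (length(planes) < 2L + length(ch))
      .fail("makeToyAtlas", "grid too small for hierarchy at region ", id)
    ownBox <- box; ownBox[[ax]] <- planes[1:2]
    grid[ownBox[[1]], ownBox[[2]], ownBox[[3]]] <<- id
    rest <- planes[-(1:2)]
    splits <- split(rest, cut(seq_along(rest), length(ch), labels = FALSE))
    for (k in seq_along(ch)) {
      childBox <- box; childBox[[ax]] <- splits[[k]]
      assignBox(ch[k], childBox, depth + 1L)
    }
    invisible(NULL)
  }
  assignBox(rootId(hierarchy),
            list(2:(dims[1] - 1L), 2:(dims[2] - 1L), 2:(dims[3] - 1L)), 0L)
  annotation <- AnnotationVolume(grid, spec$voxelSize)
  ## ---- groups and purely-inhibitory region ----
  hasIso <- "ISO" %in% nodes$acronym
  hasCb <- "CB" %in% nodes$acronym
  groups <- assignGroups(hierarchy,
                         isocortexRoot = if (hasIso) "ISO",
                         cerebellumRoot = if (hasCb) "CB")
  purelyInhibitory <- if (hasIso)
    intersect(leafIds(hierarchy),
              subtreeIds(hierarchy, idOfAcronym(hierarchy, "ISO")))[1]
  else integer(0)
  ## ---- ground-truth densities and counts ----
  ids <- regionIds(hierarchy)
  key <- as.character(ids)
  ownVolumes <- regionVolumes(annotation, hierarchy, hierarchical = FALSE)
  volumes <- regionVolumes(annotation, hierarchy, hierarchical = TRUE)
  dNeu <- runif(length(ids), spec$neuronDensityRange[1], spec$neuronDensityRange[2])
  dNeu[groups[key] == "cerebellum"] <- dNeu[groups[key] == "cerebellum"] * spec$cerebellumFactor
  gadFrac <- runif(length(ids), spec$gadFracRange[1], spec$gadFracRange[2])
  gadFrac[ids == purelyInhibitory] <- 1
  psum <- runif(length(ids), spec$subtypeFracRange[1], spec$subtypeFracRange[2])
  w <- matrix(runif(3 * length(ids), 0.2, 1), ncol = 3)
  w <- w / rowSums(w) * psum
  ownNeu <- setNames(dNeu * ownVolumes[key], key)
  ownGad <- ownNeu * gadFrac
  own <- data.frame(region_id = ids,
                    nNeu = unname(ownNeu),
                    nCell = unname(ownNeu / spec$neuronFraction),
                    PV = unname(ownGad * w[, 1]),
                    SST = unname(ownGad * w[, 2]),
                    VIP = unname(ownGad * w[, 3]),
                    GAD67 = unname(ownGad))
  tot <- own
  for (cl in c("nNeu", "nCell", "PV", "SST", "VIP", "GAD67")) {
    v <- setNames(own[[cl]], key)
    tot[[cl]] <- unname(aggregateToParents(v, hierarchy)[key])
  }
  ## ---- Nissl proportional to cell density ----
  dCell <- setNames(dNeu / spec$neuronFraction, key)
  nisslGrid <- array(0, dims)
  inBrain <- grid != 0L
  nisslGrid[inBrain] <- dCell[as.character(grid[inBrain])] / max(dCell)
  nissl <- ScalarVolume(nisslGrid, spec$voxelSize, kind = "nissl-intensity")
  list(hierarchy = hierarchy, annotation = annotation, nissl = nissl,
       truth = list(own = own, total = tot,
                    ownDensity = data.frame(
                      region_id = ids,
                      PV = own$PV / ownVolumes[key], SST = own$SST / ownVolumes[key],
                      VIP = own$VIP / ownVolumes[key], GAD67 = own$GAD67 / ownVolumes[key]),
                    totalDensity = data.frame(
                      region_id = ids,
                      PV = tot$PV / volumes[key], SST = tot$SST / volumes[key],
                      VIP = tot$VIP / volumes[key], GAD67 = tot$GAD67 / volumes[key])),
       volumes = volumes, ownVolumes = ownVolumes, groups = groups,
       purelyInhibitory = purelyInhibitory, spec = spec)
}

#' Render per-marker expression slice stacks from the ground truth
#'
#' Within every region's cross-section on a sampled plane, a fraction
#' `density / alpha` of the pixels (clipped to \[0, 1\] and logged when
#' clipped) is set to foreground, so that the region mean binarized
#' intensity equals the true density divided by the group's slope up to
#' pixel quantization. Sections are emitted every `slicePeriod` planes; an
#' optional in-plane shift emulates misalignment.
#'
#' @param atlas result of [makeToyAtlas()].
#' @param markers markers to render (default all four).
#' @return named list per marker of [SliceStack-class].
#' @export
makeIsh <- function(atlas, markers = .MARKERS) {
  spec <- atlas$spec
  grid <- gridArray(atlas$annotation)
  dims <- dim(grid)
  planes <- seq(2L, dims[1] - 1L, by = spec$slicePeriod)
  key <- as.character(atlas$truth$ownDensity$region_id)
  out <- list()
  for (mk in markers) {
    dens <- setNames(atlas$truth$ownDensity[[mk]], key)
    alpha <- vapply(key, function(k) atlas$spec$trueAlpha[[mk]][[atlas$groups[[k]]]],
                    numeric(1))
    frac <- pmin(dens / alpha, 1)
    if (any(dens / alpha > 1))
      warning(sprintf("%s: density/alpha > 1 in %d regions; clipped",
                      mk, sum(dens / alpha > 1)))
    # cumulative (error-diffused) rounding per region across planes, so the
    # whole-region foreground fraction matches density/alpha to ~1 pixel
    seen <- setNames(numeric(length(key)), key)
    drawn <- setNames(numeric(length(key)), key)
    slices <- vector("list", length(planes))
    for (si in seq_along(planes)) {
      p <- planes[si]
      img <- matrix(0, dims[2], dims[3])
      cross <- grid[p, , ]
      for (r in unique(cross[cross != 0L])) {
        k <- as.character(r)
        pix <- which(cross == r)          # deterministic (column-major) order
        seen[k] <- seen[k] + length(pix)
        nfg <- min(round(frac[k] * seen[k] - drawn[k]), length(pix))
        if (nfg > 0) {
          img[pix[seq_len(nfg)]] <- 1
          drawn[k] <- drawn[k] + nfg
        }
      }
      if (spec$misalignShift > 0L) {
        sh <- spec$misalignShift
        img <- rbind(matrix(0, sh, ncol(img)), img[seq_len(nrow(img) - sh), ])
      }
      slices[[si]] <- img
    }
    out[[mk]] <- SliceStack(slices, planes, marker = mk)
  }
  out
}

#' Generate a literature record table from the ground truth
#'
#' A seeded random subset of regions (fraction `literatureCoverage`)
#' receives 1-3 records per (region, marker): means are the true subtree
#' density perturbed by multiplicative log-normal noise of coefficient of
#' variation `literatureCV` (densities are positive and literature spread
#' spans multiples, so multiplicative noise is the natural model), with
#' reported standard deviations `CV * mean`. Record kinds are mixed among
#' density, count and percentage-of-neurons.
#'
#' @param atlas result of [makeToyAtlas()].
#' @param coverage,cv overrides of the spec's literature coverage and CV.
#' @param seed override of the spec's seed.
#' @return data.frame of literature records (see [readLiteratureCSV()]).
#' @export
makeLiterature <- function(atlas, coverage = NULL, cv = NULL, seed = NULL) {
  spec <- atlas$spec
  coverage <- coverage %||% spec$literatureCoverage
  cv <- cv %||% spec$literatureCV
  set.seed(stageSeed(seed %||% spec$seed, "literature"))
  ids <- regionIds(atlas$hierarchy)
  key <- as.character(ids)
  nCov <- round(coverage * length(ids))
  covered <- sort(sample(ids, nCov))
  if (!length(covered))
    return(data.frame(source_id = character(0), marker = character(0),
                      region_id = integer(0), kind = character(0),
                      value = numeric(0), std = numeric(0), comment = character(0)))
  sdlog <- sqrt(log(1 + cv^2))
  totNeu <- setNames(atlas$truth$total$nNeu, key)
  rows <- list()
  for (r in covered) {
    for (mk in .MARKERS) {
      trueDens <- atlas$truth$totalDensity[[mk]][match(r, ids)]
      k <- sample(spec$recordsPerRegion[1]:spec$recordsPerRegion[2], 1)
      for (j in seq_len(k)) {
        m <- trueDens * exp(rnorm(1, 0, sdlog))
        kind <- sample(c("density", "count", "pct_neurons"), 1,
                       prob = c(0.6, 0.3, 0.1))
        vol <- atlas$volumes[as.character(r)]
        val <- switch(kind,
                      density = m,
                      count = m * vol,
                      pct_neurons = min(m * vol / totNeu[as.character(r)] * 100, 100))
        std <- if (cv > 0) cv * val else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = sprintf("src_%d_%s_%d", r, mk, j), marker = mk,
          region_id = r, kind = kind, value = unname(val), std = unname(std),
          comment = "synthetic")
      }
    }
  }
  do.call(rbind, rows)
}

#' Build a synthetic hierarchy with an exact number of regions
#'
#' Breadth-first tree with the given branching factor, truncated at
#' exactly `n` regions. Used for structural checks at atlas scale (e.g.
#' 861 regions, the size of the adult mouse annotation ontology).
#'
#' @param n number of regions.
#' @param branching children per node.
#' @return a [RegionHierarchy-class].
#' @export
makeSyntheticHierarchy <- function(n, branching = 5L) {
  nodes <- data.frame(id = 1L, name = "root", acronym = "R1",
                      parent_id = NA_integer_)
  parent <- 1L; pi <- 1L; nch <- 0L
  while (nrow(nodes) < n) {
    id <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = id, name = paste0("R", id),
                                     acronym = paste0("R", id),
                                     parent_id = nodes$id[pi]))
    nch <- nch + 1L
    if (nch == branching) { pi <- pi + 1L; nch <- 0L }
  }
  RegionHierarchy(nodes)
}
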