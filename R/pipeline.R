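## Pipeline orchestration: Nissl calibration, ISH preparation, the
## fit-assemble-optimize core, and YAML-config-driven subcommands used by
## the command-line wrapper.

#' Calibrate cell and neuron counts from a Nissl volume
#'
#' Voxel cell density is proportional to Nissl intensity, globally scaled
#' so that the brain total equals `totalCells`; neurons are a configured
#' fraction of cells (alternatively pass per-region neuron counts
#' directly to the downstream steps). Returns per-region own-voxel and
#' hierarchical counts plus density volumes (cells/mm^3).
#'
#' @param nissl a [ScalarVolume-class] Nissl intensity volume.
#' @param annotation the paired [AnnotationVolume-class].
#' @param hierarchy a [RegionHierarchy-class].
#' @param totalCells calibrated whole-brain cell count.
#' @param neuronFraction fraction of cells that are neurons.
#' @return list with `ownCells`, `cells`, `ownNeurons`, `neurons` (named
#'   vectors per region), and `cellDensity`, `neuronDensity`
#'   ([ScalarVolume-class]).
#' @export
calibrateDensities <- function(nissl, annotation, hierarchy, totalCells,
                               neuronFraction = 0.5) {
  g <- gridArray(nissl)
  lab <- gridArray(annotation)
  tot <- sum(g[lab != 0L])
  if (tot <= 0) .fail("calibrateDensities", "zero total Nissl signal")
  cellsPerVoxel <- array(0, dim(g))
  cellsPerVoxel[lab != 0L] <- g[lab != 0L] / tot * totalCells
  vv <- voxelVolumeMm3(nissl)
  ids <- regionIds(hierarchy)
  f <- factor(lab[lab != 0L], levels = ids)
  ownCells <- setNames(numeric(length(ids)), as.character(ids))
  sums <- rowsum(cellsPerVoxel[lab != 0L], f)
  ownCells[rownames(sums)] <- sums[, 1]
  cells <- aggregateToParents(ownCells, hierarchy)
  list(ownCells = ownCells, cells = cells,
       ownNeurons = ownCells * neuronFraction,
       neurons = cells * neuronFraction,
       cellDensity = ScalarVolume(cellsPerVoxel / vv, voxelSizes(nissl),
                                  kind = "cell-density"),
       neuronDensity = ScalarVolume(cellsPerVoxel * neuronFraction / vv,
                                    voxelSizes(nissl), kind = "cell-density"))
}

#' Prepare the static context of a density-estimation run
#'
#' Computes everything that does not depend on the literature table:
#' region volumes, neuron counts (from a Nissl calibration or supplied
#' directly), per-marker binarized expression volumes and region mean
#' intensities, and the region grouping. The context is reused across the
#' literature-subsampling and hold-out experiments.
#'
#' @param hierarchy a [RegionHierarchy-class].
#' @param annotation an [AnnotationVolume-class].
#' @param ishStacks named list per marker of a [SliceStack-class] or a
#'   list of them (multiple experiments are combined by voxelwise mean of
#'   their interpolated expressions before thresholding).
#' @param nissl optional [ScalarVolume-class] (with `totalCells`,
#'   `neuronFraction`) used to derive neuron counts.
#' @param totalCells,neuronFraction Nissl calibration, see
#'   [calibrateDensities()].
#' @param nNeu,nNeuOwn named per-region neuron counts, used directly when
#'   the Nissl route is not taken.
#' @param isocortexRoot,cerebellumRoot group roots (acronym or id).
#' @return a list (context) consumed by [fitAndSolve()].
#' @export
prepareContext <- function(hierarchy, annotation, ishStacks,
                           nissl = NULL, totalCells = NULL,
                           neuronFraction = 0.5,
                           nNeu = NULL, nNeuOwn = NULL,
                           isocortexRoot = NULL, cerebellumRoot = NULL) {
  ownVolumes <- regionVolumes(annotation, hierarchy, hierarchical = FALSE)
  volumes <- regionVolumes(annotation, hierarchy, hierarchical = TRUE)
  neuronDensity <- NULL
  if (!is.null(nissl)) {
    cal <- calibrateDensities(nissl, annotation, hierarchy, totalCells,
                              neuronFraction)
    nNeu <- cal$neurons; nNeuOwn <- cal$ownNeurons
    neuronDensity <- cal$neuronDensity
  }
  if (is.null(nNeu)) .fail("prepareContext", "need either a Nissl volume or neuron counts")
  if (is.null(nNeuOwn)) {
    ids <- regionIds(hierarchy)
    childSum <- vapply(ids, function(id)
      sum(nNeu[as.character(childrenOf(hierarchy, id))]), numeric(1))
    nNeuOwn <- setNames(pmax(nNeu[as.character(ids)] - childSum, 0), as.character(ids))
  }
  dims <- dim(gridArray(annotation))
  intensities <- list()
  binarized <- list()
  for (mk in names(ishStacks)) {
    stacks <- ishStacks[[mk]]
    if (is(stacks, "SliceStack")) stacks <- list(stacks)
    vols <- lapply(stacks, interpolateStack, referenceDim = dims,
                   voxelSize = voxelSizes(annotation))
    combined <- combineExperiments(vols)
    thr <- otsuThreshold(combined, annotation)
    bin <- binarize(combined, thr)
    binarized[[mk]] <- bin
    intensities[[mk]] <- regionMeanIntensity(bin, annotation, hierarchy)
  }
  list(hierarchy = hierarchy, annotation = annotation,
       volumes = volumes, ownVolumes = ownVolumes,
       nNeu = nNeu, nNeuOwn = nNeuOwn, neuronDensity = neuronDensity,
       intensities = intensities, binarized = binarized,
       groups = assignGroups(hierarchy, isocortexRoot, cerebellumRoot))
}

#' Fit transfer functions and solve the reconciliation LP
#'
#' The literature-dependent half of the pipeline: aggregates literature
#' records into per-(region, marker) estimates (with the outlier rule and
#' the purely-inhibitory rule), builds the fit points and transfer
#' functions, assembles the unconstrained estimates, runs the
#' capping/coherence pre-pass to obtain a feasible initial solution, and
#' solves the LP.
#'
#' @param context from [prepareContext()].
#' @param records literature record data.frame.
#' @param purelyInhibitory integer region ids under the purely-inhibitory
#'   rule.
#' @param sigmaFloorFraction sigma floor fraction (default 0.1).
#' @param outlierRatio literature exclusion ratio (default 5).
#' @param dropSources sources removed entirely.
#' @param lpTol LP feasibility tolerance.
#' @return list with `literature`, `fitPoints`, `fits` (+ `fitReport`),
#'   `estimates`, `initial` (pre-pass solution and objective), `problem`,
#'   `solution`, `flags`, `residuals`, and `densities` (data.frame of
#'   solved counts and densities per region and type).
#' @export
fitAndSolve <- function(context, records, purelyInhibitory = integer(0),
                        sigmaFloorFraction = 0.1, outlierRatio = 5,
                        dropSources = character(0), lpTol = 1e-7) {
  h <- context$hierarchy
  pure <- purelyInhibitoryRecords(purelyInhibitory, context$nNeu, h)
  allRecords <- rbind(records[names(pure)], pure)
  lit <- aggregateLiterature(allRecords, context$volumes,
                             neuronCounts = context$nNeu,
                             cellCounts = NULL, dropSources = dropSources,
                             ratio = outlierRatio,
                             sigmaFloorFraction = sigmaFloorFraction)
  conv <- toCount(allRecords, context$volumes, neuronCounts = context$nNeu)
  pts <- buildFitPoints(context$intensities, conv, context$volumes,
                        purelyInhibitory = purelyInhibitory,
                        groups = context$groups)
  ft <- fitTransferFunctions(pts)
  names(lit$estimates)[names(lit$estimates) == "marker"] <- "marker"
  est <- assembleEstimates(h, lit$estimates, ft$fits, context$intensities,
                           context$volumes, context$ownVolumes, context$nNeu,
                           context$groups, purelyInhibitory,
                           sigmaFloorFraction)
  init <- initialSolution(est, context$nNeuOwn, h)
  problem <- buildLP(est, context$nNeu, h, nNeuOwn = context$nNeuOwn)
  solution <- solveLP(problem, tol = lpTol)
  flags <- flagCorrections(solution)
  residuals <- deriveResiduals(solution, context$nNeu)
  tot <- solution@solution[solution@solution$scope == "total", ]
  dens <- data.frame(tot[c("region_id", "type", "eta", "sigma", "x", "flagged")],
                     volume_mm3 = unname(context$volumes[as.character(tot$region_id)]))
  dens$density <- dens$x / dens$volume_mm3
  list(literature = lit, fitPoints = pts, fits = ft$fits, fitReport = ft$report,
       estimates = est, initial = init, problem = problem, solution = solution,
       flags = flags, residuals = residuals, densities = dens)
}

#' One-call density estimation on in-memory objects
#'
#' Convenience wrapper: [prepareContext()] followed by [fitAndSolve()].
#'
#' @inheritParams prepareContext
#' @inheritParams fitAndSolve
#' @param ... passed to [fitAndSolve()].
#' @return see [fitAndSolve()]; the context is attached as `$context`.
#' @export
estimateDensities <- function(hierarchy, annotation, ishStacks, records,
                              nissl = NULL, totalCells = NULL,
                              neuronFraction = 0.5, nNeu = NULL,
                              nNeuOwn = NULL, isocortexRoot = NULL,
                              cerebellumRoot = NULL, ...) {
  ctx <- prepareContext(hierarchy, annotation, ishStacks, nissl, totalCells,
                        neuronFraction, nNeu, nNeuOwn, isocortexRoot,
                        cerebellumRoot)
  out <- fitAndSolve(ctx, records, ...)
  out$context <- ctx
  out
}

## ---- configuration-driven subcommands ----------------------------------

#' Read and validate a pipeline configuration file
#'
#' YAML with sections `paths` (hierarchy, annotation, nissl, literature,
#' `ish: {MARKER: [stack dirs]}`), `calibration` (`total_cells`,
#' `neuron_fraction`), `groups` (`isocortex`, `cerebellum` acronyms),
#' `purely_inhibitory` (acronym list), `options` (`sigma_floor`,
#' `outlier_ratio`, `lp_tol`, `seed`) and `output` (directory).
#'
#' @param path YAML file.
#' @return list of class `"pipelineConfig"` with a `hash` attribute used
#'   for output provenance.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$options <- utils::modifyList(
    list(sigma_floor = 0.1, outlier_ratio = 5, lp_tol = 1e-7, seed = 1L),
    cfg$options %||% list())
  cfg$calibration <- utils::modifyList(
    list(total_cells = NULL, neuron_fraction = 0.5), cfg$calibration %||% list())
  raw <- paste(readLines(path), collapse = "\n")
  h <- 0; for (ch in utf8ToInt(raw)) h <- (h * 131 + ch) %% 2147483647
  attr(cfg, "hash") <- sprintf("%08x", as.integer(h))
  cfg$dir <- dirname(normalizePath(path))
  class(cfg) <- "pipelineConfig"
  cfg
}

.cfgPath <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(cfg$dir, p)
}

.loadConfigInputs <- function(cfg) {
  paths <- cfg$paths
  for (nm in c("hierarchy", "annotation")) {
    p <- .cfgPath(cfg, paths[[nm]])
    if (is.null(p) || !file.exists(p))
      .fail("pipeline", "missing input '", nm, "' (", paths[[nm]] %||% "unset", ")")
  }
  hierarchy <- parseHierarchy(.cfgPath(cfg, paths$hierarchy))
  annotation <- readAnnotationNifti(.cfgPath(cfg, paths$annotation))
  nissl <- if (!is.null(paths$nissl))
    readScalarNifti(.cfgPath(cfg, paths$nissl), kind = "nissl-intensity")
  ish <- list()
  for (mk in names(paths$ish %||% list())) {
    dirs <- paths$ish[[mk]]
    ish[[mk]] <- lapply(dirs, function(d) readSliceStack(.cfgPath(cfg, d), marker = mk))
  }
  records <- if (!is.null(paths$literature)) {
    p <- .cfgPath(cfg, paths$literature)
    if (!file.exists(p)) .fail("pipeline", "missing input 'literature' (", p, ")")
    readLiteratureCSV(p, hierarchy)
  }
  list(hierarchy = hierarchy, annotation = annotation, nissl = nissl,
       ish = ish, records = records)
}

.outDir <- function(cfg) {
  d <- .cfgPath(cfg, cfg$output$dir %||% "output") %||% "output"
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.provenance <- function(cfg)
  sprintf("# config_hash=%s seed=%d", attr(cfg, "hash"), cfg$options$seed)

.writeCsv <- function(df, cfg, name) {
  path <- file.path(.outDir(cfg), name)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.provenance(cfg), con)
  write.csv(df, con, row.names = FALSE)
  path
}

#' Pipeline subcommands
#'
#' Config-driven stages mirroring the command-line interface:
#' `runDensities` calibrates cell/neuron counts from the Nissl volume,
#' `runFit` produces the transfer-function report, `runOptimize` the
#' consistent densities and correction report, `runPlace` the cell
#' positions, `runValidate` the subsampling and hold-out reports, and
#' `runMakeFixtures` writes a complete synthetic input bundle. Every
#' output CSV starts with a provenance comment line (config hash + seed).
#'
#' @param cfg a `"pipelineConfig"` from [readPipelineConfig()].
#' @return the computed objects, invisibly; outputs are written to the
#'   configured output directory.
#' @name pipeline-subcommands
NULL

#' @rdname pipeline-subcommands
#' @export
runDensities <- function(cfg) {
  inp <- .loadConfigInputs(cfg)
  if (is.null(inp$nissl)) .fail("runDensities", "missing input 'nissl'")
  cal <- calibrateDensities(inp$nissl, inp$annotation, inp$hierarchy,
                            cfg$calibration$total_cells,
                            cfg$calibration$neuron_fraction)
  ids <- regionIds(inp$hierarchy)
  .writeCsv(data.frame(region_id = ids,
                       acronym = acronymOf(inp$hierarchy, ids),
                       nCell = unname(cal$cells[as.character(ids)]),
                       nNeu = unname(cal$neurons[as.character(ids)])),
            cfg, "region_counts.csv")
  writeVolumeNifti(cal$neuronDensity, file.path(.outDir(cfg), "neuron_density.nii.gz"))
  invisible(cal)
}

.configContext <- function(cfg, inp) {
  prepareContext(inp$hierarchy, inp$annotation, inp$ish,
                 nissl = inp$nissl, totalCells = cfg$calibration$total_cells,
                 neuronFraction = cfg$calibration$neuron_fraction,
                 isocortexRoot = cfg$groups$isocortex,
                 cerebellumRoot = cfg$groups$cerebellum)
}

.configPure <- function(cfg, hierarchy) {
  if (is.null(cfg$purely_inhibitory)) integer(0)
  else idOfAcronym(hierarchy, unlist(cfg$purely_inhibitory))
}

.configFit <- function(cfg) {
  inp <- .loadConfigInputs(cfg)
  if (is.null(inp$records)) .fail("runFit", "missing input 'literature'")
  ctx <- .configContext(cfg, inp)
  res <- fitAndSolve(ctx, inp$records,
                     purelyInhibitory = .configPure(cfg, inp$hierarchy),
                     sigmaFloorFraction = cfg$options$sigma_floor,
                     outlierRatio = cfg$options$outlier_ratio,
                     lpTol = cfg$options$lp_tol)
  res$context <- ctx
  res$inputs <- inp
  res
}

#' @rdname pipeline-subcommands
#' @export
runFit <- function(cfg) {
  res <- .configFit(cfg)
  .writeCsv(res$fitReport, cfg, "transfer_functions.csv")
  invisible(res)
}

#' @rdname pipeline-subcommands
#' @export
runOptimize <- function(cfg) {
  res <- .configFit(cfg)
  h <- res$inputs$hierarchy
  d <- res$densities
  d$acronym <- acronymOf(h, d$region_id)
  .writeCsv(d[c("region_id", "acronym", "type", "volume_mm3", "x", "density",
                "eta", "sigma", "flagged")], cfg, "consistent_densities.csv")
  .writeCsv(res$residuals, cfg, "residual_populations.csv")
  writeLPDump(res$problem, file.path(.outDir(cfg), "problem.lp.txt"))
  invisible(res)
}

#' @rdname pipeline-subcommands
#' @export
runPlace <- function(cfg) {
  res <- .configFit(cfg)
  ctx <- res$context
  targets <- placementTargets(res$solution, ctx$nNeuOwn, ctx$hierarchy)
  seed <- cfg$options$seed
  cells <- placeCells(ctx$neuronDensity,
                      setNames(targets$nNeu, targets$region_id),
                      ctx$annotation, seed = seed)
  cells <- assignTypes(cells, targets, seed = seed)
  cells <- jitterPositions(cells, dim(gridArray(ctx$annotation)),
                           voxelSizes(ctx$annotation), seed = seed)
  .writeCsv(cells[c("x", "y", "z", "region_id", "label")], cfg, "cell_positions.csv")
  .writeCsv(targets, cfg, "placement_targets.csv")
  invisible(list(cells = cells, targets = targets, result = res))
}

#' @rdname pipeline-subcommands
#' @export
runValidate <- function(cfg) {
  res <- .configFit(cfg)
  seed <- cfg$options$seed
  sub <- subsamplingExperiment(res$context, res$inputs$records,
                               purelyInhibitory = .configPure(cfg, res$inputs$hierarchy),
                               seed = seed)
  hold <- holdoutExperiment(res$context, res$inputs$records,
                            purelyInhibitory = .configPure(cfg, res$inputs$hierarchy),
                            seed = seed)
  .writeCsv(sub$summary, cfg, "subsampling_summary.csv")
  .writeCsv(sub$extrapolated, cfg, "sigma_extrapolated.csv")
  .writeCsv(hold$records, cfg, "holdout_records.csv")
  invisible(list(subsampling = sub, holdout = hold))
}

#' @rdname pipeline-subcommands
#' @param dir output directory for the fixture bundle.
#' @param spec a [toyBrainSpec()].
#' @export
runMakeFixtures <- function(dir, spec = toyBrainSpec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- makeToyAtlas(spec)
  ish <- makeIsh(atlas)
  records <- makeLiterature(atlas)
  writeHierarchyJSON(atlas$hierarchy, file.path(dir, "hierarchy.json"))
  writeVolumeNifti(atlas$annotation, file.path(dir, "annotation.nii.gz"))
  writeVolumeNifti(atlas$nissl, file.path(dir, "nissl.nii.gz"))
  for (mk in names(ish)) writeSliceStack(ish[[mk]], file.path(dir, paste0("ish_", mk)))
  write.csv(records, file.path(dir, "literature.csv"), row.names = FALSE)
  write.csv(atlas$truth$total, file.path(dir, "truth_total_counts.csv"), row.names = FALSE)
  write.csv(atlas$truth$own, file.path(dir, "truth_own_counts.csv"), row.names = FALSE)
  totalCells <- sum(atlas$truth$own$nCell)
  cfg <- list(
    paths = list(hierarchy = "hierarchy.json", annotation = "annotation.nii.gz",
                 nissl = "nissl.nii.gz", literature = "literature.csv",
                 ish = setNames(lapply(names(ish), function(mk)
                   paste0("ish_", mk)), names(ish))),
    calibration = list(total_cells = totalCells,
                       neuron_fraction = spec$neuronFraction),
    groups = list(isocortex = "ISO", cerebellum = "CB"),
    purely_inhibitory = list(acronymOf(atlas$hierarchy, atlas$purelyInhibitory)),
    options = list(seed = spec$seed),
    output = list(dir = "output"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(atlas = atlas, ish = ish, records = records,
                 config = file.path(dir, "config.yaml")))
}
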