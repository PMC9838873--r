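## Literature integration: parsing the review table, unit conversion to
## per-region counts, outlier exclusion, the purely-inhibitory rule and the
## coverage summary (per-region CV, median CV, skewness).

.KINDS <- c("density", "count", "pct_neurons", "pct_cells")

#' Read a literature review table
#'
#' Spreadsheet-style review table in CSV form: one row per
#' (source, marker, region) measurement with columns `source_id`, `marker`,
#' `region` (acronym) or `region_id`, `kind`
#' (`density` cells/mm^3 | `count` cells | `pct_neurons` | `pct_cells`),
#' `value`, `std` (may be empty) and free-text `comment`.
#'
#' @param path CSV file path.
#' @param hierarchy a [RegionHierarchy-class]; used to resolve acronyms and
#'   validate region ids.
#' @return data.frame of literature records.
#' @export
readLiteratureCSV <- function(path, hierarchy) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$region_id)) df$region_id <- idOfAcronym(hierarchy, df$region)
  if (is.null(df$std)) df$std <- NA_real_
  if (is.null(df$comment)) df$comment <- ""
  validateLiterature(df, hierarchy)
}

#' Validate literature records
#'
#' @param records data.frame of literature records.
#' @param hierarchy a [RegionHierarchy-class].
#' @return the records, invisibly validated.
#' @export
validateLiterature <- function(records, hierarchy) {
  if (!all(records$kind %in% .KINDS))
    .fail("literature", "unknown measurement kind: ",
          paste(setdiff(records$kind, .KINDS), collapse = ", "))
  if (!all(records$marker %in% .MARKERS))
    .fail("literature", "unknown marker: ",
          paste(setdiff(records$marker, .MARKERS), collapse = ", "))
  if (!all(records$region_id %in% regionIds(hierarchy)))
    .fail("literature", "region ids not in hierarchy: ",
          paste(setdiff(records$region_id, regionIds(hierarchy)), collapse = ", "))
  if (any(!is.finite(records$value)) || any(records$value < 0))
    .fail("literature", "values must be finite and >= 0")
  pct <- records$kind %in% c("pct_neurons", "pct_cells")
  if (any(records$value[pct] > 100))
    .fail("literature", "percentages must lie in [0, 100]")
  records
}

#' Convert literature records to per-region counts
#'
#' Densities are multiplied by the region volume from the annotation;
#' counts pass through; percentages of neurons (resp. cells) are taken of
#' the per-region neuron (resp. cell) counts. Standard deviations are
#' transformed by the same linear factor; absent standard deviations stay
#' absent and are resolved at aggregation time.
#'
#' @param records data.frame of literature records.
#' @param regionVolumesMm3 named numeric, hierarchical region volumes
#'   (mm^3).
#' @param neuronCounts named numeric nNeu per region (needed for
#'   `pct_neurons`).
#' @param cellCounts named numeric cell counts per region (needed for
#'   `pct_cells`).
#' @return the records with added columns `mean_count`, `std_count`.
#' @examples
#' # density 200 cells/mm^3 in a 0.5 mm^3 region -> 100 cells
#' @export
toCount <- function(records, regionVolumesMm3, neuronCounts = NULL,
                    cellCounts = NULL) {
  fac <- rep(NA_real_, nrow(records))
  rid <- as.character(records$region_id)
  for (i in seq_len(nrow(records))) {
    fac[i] <- switch(records$kind[i],
      density = {
        v <- regionVolumesMm3[rid[i]]
        if (is.na(v) || v <= 0)
          .fail("toCount", "density record for zero-volume region ", rid[i])
        v
      },
      count = 1,
      pct_neurons = {
        if (is.null(neuronCounts) || is.na(neuronCounts[rid[i]]))
          .fail("toCount", "percentage-of-neurons record without neuron counts for region ", rid[i])
        neuronCounts[rid[i]] / 100
      },
      pct_cells = {
        if (is.null(cellCounts) || is.na(cellCounts[rid[i]]))
          .fail("toCount", "percentage-of-cells record without cell counts for region ", rid[i])
        cellCounts[rid[i]] / 100
      })
  }
  records$mean_count <- records$value * fac
  records$std_count <- records$std * fac
  records
}

#' Exclude conflicting sources from one region+marker record set
#'
#' A record is excluded iff its mean is at least `ratio` (default 5) times
#' larger than every other source's mean for the region, or at most
#' 1/`ratio` of every other source's mean. With fewer than two sources
#' nothing is excluded. The rule is order-independent.
#'
#' @param records data.frame of converted records (column `mean_count`) for
#'   a single (region, marker).
#' @param ratio exclusion ratio.
#' @return list with elements `kept` and `excluded` (both data.frames; the
#'   excluded records carry a `reason` column).
#' @examples
#' # means {100, 120, 700}: 700 >= 5x both others -> excluded
#' @export
excludeOutliers <- function(records, ratio = 5) {
  if (nrow(records) < 2L)
    return(list(kept = records, excluded = records[0, , drop = FALSE]))
  m <- records$mean_count
  hi <- vapply(seq_along(m), function(i) all(m[i] >= ratio * m[-i]), logical(1))
  lo <- vapply(seq_along(m), function(i) all(m[i] <= m[-i] / ratio), logical(1))
  out <- hi | lo
  if (all(out)) out[] <- FALSE   # mutually conflicting set: keep everything
  excluded <- records[out, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(hi[out], sprintf(">=%gx all other sources", ratio),
                              sprintf("<=1/%g of all other sources", ratio))
  }
  list(kept = records[!out, , drop = FALSE], excluded = excluded)
}

#' Aggregate kept records of one region+marker into (eta, sigma)
#'
#' The estimate is the arithmetic mean of the source means and its standard
#' deviation the arithmetic mean of the available source standard
#' deviations. When no source reports a standard deviation, sigma falls
#' back to `sigmaFloorFraction * eta`.
#'
#' @param records kept records with `mean_count`, `std_count`.
#' @param sigmaFloorFraction fallback fraction (default 0.1).
#' @return named numeric `c(eta = , sigma = )`.
#' @export
aggregateRegion <- function(records, sigmaFloorFraction = 0.1) {
  stopifnot(nrow(records) >= 1L)
  eta <- mean(records$mean_count)
  stds <- records$std_count[!is.na(records$std_count)]
  sigma <- if (length(stds)) mean(stds) else sigmaFloorFraction * eta
  c(eta = eta, sigma = sigma)
}

#' Synthetic GAD67 records for purely-inhibitory regions
#'
#' Designated regions (canonically isocortex layer 1, the cerebellar
#' molecular layer and the thalamic reticular nucleus) are assumed to hold
#' only GABAergic neurons: a GAD67 count record equal to the region's
#' neuron count is emitted per region, tagged with source
#' `"purely-inhibitory-rule"`. These regions are additionally flagged for
#' exclusion from transfer-function fitting.
#'
#' @param regionIds integer ids of the purely-inhibitory regions.
#' @param neuronCounts named numeric nNeu per region.
#' @param hierarchy a [RegionHierarchy-class].
#' @return data.frame of literature-record rows (kind `"count"`).
#' @export
purelyInhibitoryRecords <- function(regionIds, neuronCounts, hierarchy) {
  if (length(regionIds) == 0L)
    return(data.frame(source_id = character(0), marker = character(0),
                      region_id = integer(0), kind = character(0),
                      value = numeric(0), std = numeric(0),
                      comment = character(0)))
  bad <- setdiff(regionIds, regionIds(hierarchy))
  if (length(bad)) .fail("purelyInhibitory", "unknown region id(s): ",
                         paste(bad, collapse = ", "))
  nn <- neuronCounts[as.character(regionIds)]
  if (anyNA(nn)) .fail("purelyInhibitory", "missing neuron counts for region(s): ",
                       paste(regionIds[is.na(nn)], collapse = ", "))
  data.frame(source_id = "purely-inhibitory-rule", marker = "GAD67",
             region_id = as.integer(regionIds), kind = "count",
             value = as.numeric(nn), std = NA_real_,
             comment = "all neurons assumed GABAergic")
}

#' Aggregate literature into per-(region, marker) estimates
#'
#' Applies unit conversion, the outlier-exclusion rule per region+marker,
#' and the mean-of-means aggregation. Optionally removes whole sources
#' everywhere (`dropSources`), mirroring the removal of globally
#' conflicting references.
#'
#' @param records raw literature records (see [readLiteratureCSV()]).
#' @param regionVolumesMm3,neuronCounts,cellCounts conversion context, see
#'   [toCount()].
#' @param dropSources character source ids removed entirely before
#'   conversion.
#' @param ratio outlier exclusion ratio.
#' @param sigmaFloorFraction see [aggregateRegion()].
#' @return list with `estimates` (data.frame `region_id`, `marker`, `eta`,
#'   `sigma`, `n_sources`) and `excluded` (data.frame of excluded records).
#' @export
aggregateLiterature <- function(records, regionVolumesMm3, neuronCounts = NULL,
                                cellCounts = NULL, dropSources = character(0),
                                ratio = 5, sigmaFloorFraction = 0.1) {
  records <- records[!records$source_id %in% dropSources, , drop = FALSE]
  conv <- toCount(records, regionVolumesMm3, neuronCounts, cellCounts)
  keys <- interaction(conv$region_id, conv$marker, drop = TRUE)
  ests <- list(); excl <- list()
  for (k in levels(keys)) {
    grp <- conv[keys == k, , drop = FALSE]
    split <- excludeOutliers(grp, ratio)
    if (nrow(split$excluded)) excl[[k]] <- split$excluded
    agg <- aggregateRegion(split$kept, sigmaFloorFraction)
    ests[[k]] <- data.frame(region_id = grp$region_id[1], marker = grp$marker[1],
                            eta = agg["eta"], sigma = agg["sigma"],
                            n_sources = nrow(split$kept), row.names = NULL)
  }
  empty <- data.frame(region_id = integer(0), marker = character(0),
                      eta = numeric(0), sigma = numeric(0),
                      n_sources = integer(0))
  list(estimates = if (length(ests)) do.call(rbind, ests) else empty,
       excluded = if (length(excl)) do.call(rbind, excl) else conv[0, , drop = FALSE])
}

#' Coverage and variability summary of the literature review
#'
#' Per marker: number of distinct sources, number (and fraction) of regions
#' covered, the per-region coefficients of variation (for regions with at
#' least two sources, on density-scale means), their median, and the
#' skewness of the CV distribution
#' `s = (1/n) * sum(((CV - mean(CV)) / sd(CV))^3)` (sample sd). The
#' skewness is NA (flagged) when fewer than two CVs exist.
#'
#' @param records literature records.
#' @param hierarchy a [RegionHierarchy-class].
#' @param regionVolumesMm3,neuronCounts,cellCounts conversion context used
#'   to express every record as a density (cells/mm^3).
#' @return list with `summary` (data.frame per marker) and `cv` (data.frame
#'   `region_id`, `marker`, `cv`).
#' @export
coverageSummary <- function(records, hierarchy, regionVolumesMm3,
                            neuronCounts = NULL, cellCounts = NULL) {
  conv <- toCount(records, regionVolumesMm3, neuronCounts, cellCounts)
  vol <- regionVolumesMm3[as.character(conv$region_id)]
  conv$density <- conv$mean_count / vol
  cvRows <- list(); sumRows <- list()
  for (mk in .MARKERS) {
    sub <- conv[conv$marker == mk, , drop = FALSE]
    regions <- unique(sub$region_id)
    cvs <- c()
    for (r in regions) {
      d <- sub$density[sub$region_id == r]
      if (length(d) >= 2L) {
        cv <- sd(d) / mean(d)
        cvs <- c(cvs, cv)
        cvRows[[length(cvRows) + 1L]] <-
          data.frame(region_id = r, marker = mk, cv = cv)
      }
    }
    skew <- if (length(cvs) >= 2L && sd(cvs) > 0)
      mean(((cvs - mean(cvs)) / sd(cvs))^3) else NA_real_
    sumRows[[mk]] <- data.frame(
      marker = mk,
      n_sources = length(unique(sub$source_id)),
      n_regions = length(regions),
      fraction_regions = length(regions) / nRegions(hierarchy),
      n_cv = length(cvs),
      median_cv = if (length(cvs)) median(cvs) else NA_real_,
      cv_skewness = skew, row.names = NULL)
  }
  list(summary = do.call(rbind, sumRows),
       cv = if (length(cvRows)) do.call(rbind, cvRows)
            else data.frame(region_id = integer(0), marker = character(0),
                            cv = numeric(0)))
}
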