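## Transfer functions: region grouping, fit-point construction,
## through-origin linear fits from region mean intensity to literature
## density, the coefficient of determination, and density prediction.

#' Assign every region to a fitting group
#'
#' Regions are grouped by subtree membership into `"cerebellum"`,
#' `"isocortex"` and `"rest"`; cell densities in the cerebellum and the
#' laminar homogeneity of the isocortex justify fitting these separately.
#' Group roots are designated by acronym (or id); regions in neither
#' subtree (including the root) map to `"rest"`. If a region sits in both
#' subtrees (impossible in a tree unless one root is an ancestor of the
#' other), the deeper root wins.
#'
#' @param hierarchy a [RegionHierarchy-class].
#' @param isocortexRoot,cerebellumRoot acronym or id of the subtree roots;
#'   NULL disables the group.
#' @return named character vector: group per region id.
#' @export
assignGroups <- function(hierarchy, isocortexRoot = NULL, cerebellumRoot = NULL) {
  resolve <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) idOfAcronym(hierarchy, x) else {
      if (!x %in% regionIds(hierarchy))
        .fail("assignGroups", "designated group root missing: ", x)
      as.integer(x)
    }
  }
  groups <- setNames(rep("rest", nRegions(hierarchy)),
                     as.character(regionIds(hierarchy)))
  iso <- resolve(isocortexRoot); cb <- resolve(cerebellumRoot)
  for (spec in list(list(id = iso, g = "isocortex"), list(id = cb, g = "cerebellum"))) {
    if (!is.null(spec$id))
      groups[as.character(subtreeIds(hierarchy, spec$id))] <- spec$g
  }
  groups
}

#' Build the transfer-function fit points
#'
#' One point per kept literature record: x = region mean intensity
#' (hierarchical), y = record density (cells/mm^3). Points are dropped
#' when the region mean intensity is 0 or unavailable, when the region is
#' flagged purely inhibitory (its "literature" value is the neuron count,
#' not an observation), or when the reported density is 0 (regions with no
#' inhibitory neurons). All points carry equal weight.
#'
#' @param intensities data.frame from [regionMeanIntensity()] for the
#'   record's marker, or a list of such data.frames keyed by marker.
#' @param records converted literature records (columns `region_id`,
#'   `marker`, `mean_count`).
#' @param regionVolumesMm3 named numeric hierarchical volumes (mm^3).
#' @param purelyInhibitory integer ids excluded from fitting.
#' @param groups named character vector from [assignGroups()] (optional;
#'   when given, a `group` column is added).
#' @return data.frame with columns `region_id`, `marker`, `group`, `x`,
#'   `y`, `weight`.
#' @export
buildFitPoints <- function(intensities, records, regionVolumesMm3,
                           purelyInhibitory = integer(0), groups = NULL) {
  getIntensity <- function(marker, rid) {
    df <- if (is.data.frame(intensities)) intensities else intensities[[marker]]
    df$mean[match(rid, df$region_id)]
  }
  x <- mapply(getIntensity, records$marker, records$region_id)
  vol <- regionVolumesMm3[as.character(records$region_id)]
  y <- records$mean_count / vol
  keep <- !is.na(x) & x > 0 & !is.na(y) & y > 0 &
    !(records$region_id %in% purelyInhibitory) &
    records$source_id != "purely-inhibitory-rule"
  out <- data.frame(region_id = records$region_id[keep],
                    marker = records$marker[keep],
                    x = unname(x[keep]), y = unname(y[keep]), weight = 1)
  out$group <- if (is.null(groups)) "all" else
    unname(groups[as.character(out$region_id)])
  out[c("region_id", "marker", "group", "x", "y", "weight")]
}

#' Through-origin least-squares fit of density on intensity
#'
#' `alpha = sum(x*y) / sum(x^2)`;
#' `std_alpha = sqrt(sum((y - alpha*x)^2) / ((n - 1) * sum(x^2)))`.
#' A negative fitted slope (possible with pathological data) is clipped to
#' 0 with a warning, since densities cannot be negative.
#'
#' @param points data.frame with columns `x`, `y` (and optionally `marker`,
#'   `group`, used to tag the result).
#' @param marker,group tags stored on the result.
#' @return a [TransferFunction-class].
#' @examples
#' fitAlpha(data.frame(x = c(1, 2, 3), y = c(1, 3, 5)))  # alpha = 22/14
#' @export
fitAlpha <- function(points, marker = NULL, group = NULL) {
  x <- points$x; y <- points$y
  if (length(x) < 2L || sum(x^2) == 0)
    .fail("fitAlpha", "insufficient fit data (need >= 2 points with nonzero x)")
  alpha <- sum(x * y) / sum(x^2)
  stdAlpha <- sqrt(sum((y - alpha * x)^2) / ((length(x) - 1) * sum(x^2)))
  if (alpha < 0) {
    warning("negative fitted slope clipped to 0")
    alpha <- 0
  }
  tf <- new("TransferFunction",
            marker = marker %||% (if (!is.null(points$marker)) points$marker[1] else "GAD67"),
            group = group %||% (if (!is.null(points$group)) points$group[1] else "all"),
            alpha = alpha, stdAlpha = stdAlpha, nPoints = length(x),
            r2 = NA_real_)
  tf@r2 <- rSquared(tf, points)
  tf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of determination of a transfer function
#'
#' Computed as
#' `sum((f(x)-mean(y))^2) / (sum((f(x)-mean(y))^2) + sum((y-f(x))^2))`.
#' Note this specific form (not the textbook `1 - SSres/SStot`): it is 1
#' exactly when all residuals vanish and 0 when the fitted values all equal
#' the mean of y. When both sums vanish the value is undefined (NA).
#'
#' @param f a [TransferFunction-class], or a function of x.
#' @param points data.frame with `x`, `y`.
#' @return numeric in \[0, 1\], or NA when undefined.
#' @export
rSquared <- function(f, points) {
  fx <- if (is(f, "TransferFunction")) f@alpha * points$x else f(points$x)
  ybar <- mean(points$y)
  ssf <- sum((fx - ybar)^2)
  ssr <- sum((points$y - fx)^2)
  if (ssf + ssr == 0) return(NA_real_)
  ssf / (ssf + ssr)
}

#' Predict a per-region count estimate from a transfer function
#'
#' eta = alpha * intensity * volume and sigma = std_alpha * intensity *
#' volume, i.e. the fitted density (and its uncertainty from the slope's
#' standard deviation) scaled to counts by the region volume. Used only
#' for regions without literature coverage.
#'
#' @param tf a [TransferFunction-class].
#' @param intensity region mean binarized intensity in \[0, 1\].
#' @param regionVolumeMm3 region volume (mm^3).
#' @return named numeric `c(eta = , sigma = )` in counts.
#' @export
predictDensity <- function(tf, intensity, regionVolumeMm3) {
  intensity <- unname(intensity); regionVolumeMm3 <- unname(regionVolumeMm3)
  c(eta = tf@alpha * intensity * regionVolumeMm3,
    sigma = tf@stdAlpha * intensity * regionVolumeMm3)
}

#' Pearson correlation diagnostic of the fit points
#'
#' @param points data.frame with `x`, `y` (>= 2 rows).
#' @return Pearson correlation of x and y; NA (flagged by warning) when
#'   either variable has zero variance.
#' @export
pearsonDiagnostic <- function(points) {
  stopifnot(nrow(points) >= 2L)
  if (sd(points$x) == 0 || sd(points$y) == 0) {
    warning("zero variance in x or y; correlation undefined")
    return(NA_real_)
  }
  cor(points$x, points$y)
}

#' Fit transfer functions per marker and region group
#'
#' Fits [fitAlpha()] separately for every (marker, group) with at least two
#' points; markers whose group has fewer points fall back to the pooled
#' per-marker fit (group `"all"`). Markers with no usable points at all
#' yield no entry.
#'
#' @param points data.frame from [buildFitPoints()].
#' @return list with `fits` (named list of [TransferFunction-class],
#'   `"marker/group"`) and `report` (data.frame mirroring the fit-report
#'   table: marker, group, alpha, std_alpha, r2, n_points).
#' @export
fitTransferFunctions <- function(points) {
  fits <- list()
  for (mk in unique(points$marker)) {
    pm <- points[points$marker == mk, , drop = FALSE]
    pooled <- if (nrow(pm) >= 2L) fitAlpha(pm, marker = mk, group = "all") else NULL
    if (!is.null(pooled)) fits[[paste(mk, "all", sep = "/")]] <- pooled
    for (g in unique(pm$group)) {
      pg <- pm[pm$group == g, , drop = FALSE]
      fits[[paste(mk, g, sep = "/")]] <-
        if (nrow(pg) >= 2L && sum(pg$x^2) > 0) fitAlpha(pg, marker = mk, group = g)
        else pooled
    }
  }
  fits <- Filter(Negate(is.null), fits)
  report <- do.call(rbind, lapply(names(fits), function(nm) {
    tf <- fits[[nm]]
    data.frame(marker = tf@marker, group = sub(".*/", "", nm),
               alpha = tf@alpha, std_alpha = tf@stdAlpha, r2 = tf@r2,
               n_points = tf@nPoints)
  }))
  list(fits = fits, report = report)
}

#' Look up the transfer function for a region
#'
#' @param fits named list from [fitTransferFunctions()].
#' @param marker marker tag.
#' @param group group label of the region.
#' @return a [TransferFunction-class] or NULL when no fit exists.
#' @export
transferFor <- function(fits, marker, group) {
  fits[[paste(marker, group, sep = "/")]] %||%
    fits[[paste(marker, "all", sep = "/")]]
}
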