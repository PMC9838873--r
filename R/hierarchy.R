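## Region-hierarchy primitives: parsing, bookkeeping, hierarchical
## aggregation and the homogeneity metric used to compare atlas alignments.

#' Construct a RegionHierarchy from a node table
#'
#' @param nodes data.frame with columns `id`, `name`, `acronym`,
#'   `parent_id` (NA for the root).
#' @return a [RegionHierarchy-class] object.
#' @examples
#' h <- RegionHierarchy(data.frame(id = 1:3, name = c("root", "a", "b"),
#'                                 acronym = c("rt", "a", "b"),
#'                                 parent_id = c(NA, 1, 1)))
#' leafIds(h)
#' @export
RegionHierarchy <- function(nodes) {
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$id))
    .fail("parseHierarchy", "duplicate region id: ",
          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  roots <- nodes$id[is.na(nodes$parent_id)]
  if (length(roots) == 0L) .fail("parseHierarchy", "missing root node")
  if (length(roots) > 1L)
    .fail("parseHierarchy", "multiple roots: ", paste(roots, collapse = ", "))
  children <- split(nodes$id[!is.na(nodes$parent_id)],
                    factor(nodes$parent_id[!is.na(nodes$parent_id)],
                           levels = nodes$id))
  names(children) <- as.character(nodes$id)
  # breadth-first depth computation; leftover nodes indicate a cycle or
  # disconnected parent reference
  depth <- setNames(rep(NA_integer_, nrow(nodes)), as.character(nodes$id))
  depth[as.character(roots)] <- 0L
  frontier <- roots
  while (length(frontier)) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    if (!length(nxt)) break
    depth[as.character(nxt)] <- depth[as.character(nodes$parent_id[match(nxt, nodes$id)])] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) {
    bad <- names(depth)[is.na(depth)]
    .fail("parseHierarchy", "unreachable node(s) (cycle or dangling parent): ",
          paste(bad, collapse = ", "))
  }
  new("RegionHierarchy", nodes = nodes, root = roots,
      depth = depth, children = children)
}

#' Parse an AIBS-style nested ontology document
#'
#' Reads a hierarchy from nested JSON (each node carrying `id`, `name`,
#' `acronym` and a `children` array). Both a raw node and the AIBS
#' `{"msg": [node]}` envelope are accepted.
#'
#' @param document path to a JSON file, a JSON string, or an already-parsed
#'   nested list.
#' @return a [RegionHierarchy-class] object.
#' @export
parseHierarchy <- function(document) {
  if (is.character(document)) {
    document <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  }
  if (!is.null(document$msg)) document <- document$msg[[1]]
  rows <- list()
  walk <- function(node, parent) {
    if (is.null(node$id)) .fail("parseHierarchy", "node without id under parent ",
                                ifelse(is.na(parent), "<root>", parent))
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.integer(node$id),
      name = ifelse(is.null(node$name), NA_character_, node$name),
      acronym = ifelse(is.null(node$acronym), NA_character_, node$acronym),
      parent_id = parent, stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, as.integer(node$id))
    invisible(NULL)
  }
  walk(document, NA_integer_)
  RegionHierarchy(do.call(rbind, rows))
}

#' Serialize a RegionHierarchy back to nested AIBS-style JSON
#'
#' @param hierarchy a [RegionHierarchy-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
writeHierarchyJSON <- function(hierarchy, path = NULL) {
  build <- function(id) {
    nd <- hierarchy@nodes[hierarchy@nodes$id == id, ]
    list(id = id, name = nd$name, acronym = nd$acronym,
         children = lapply(childrenOf(hierarchy, id), build))
  }
  js <- jsonlite::toJSON(build(rootId(hierarchy)), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

## ---- accessors ----------------------------------------------------------

#' @describeIn RegionHierarchy-accessors all region ids
#' @export
regionIds <- function(hierarchy) hierarchy@nodes$id

#' Region hierarchy accessors
#'
#' @param hierarchy a [RegionHierarchy-class].
#' @param id a region id.
#' @name RegionHierarchy-accessors
#' @return ids, depths or acronyms as documented per function.
NULL

#' @describeIn RegionHierarchy-accessors number of regions
#' @export
nRegions <- function(hierarchy) nrow(hierarchy@nodes)

#' @describeIn RegionHierarchy-accessors id of the root region
#' @export
rootId <- function(hierarchy) hierarchy@root

#' @describeIn RegionHierarchy-accessors named integer vector of depths
#' @export
regionDepths <- function(hierarchy) hierarchy@depth

#' @describeIn RegionHierarchy-accessors children ids of a region
#' @export
childrenOf <- function(hierarchy, id) {
  ch <- hierarchy@children[[as.character(id)]]
  if (is.null(ch)) integer(0) else ch
}

#' @describeIn RegionHierarchy-accessors parent id (NA for the root)
#' @export
parentOf <- function(hierarchy, id)
  hierarchy@nodes$parent_id[match(id, hierarchy@nodes$id)]

#' @describeIn RegionHierarchy-accessors ids of leaf regions
#' @export
leafIds <- function(hierarchy) {
  n <- vapply(hierarchy@children, length, integer(1))
  hierarchy@nodes$id[n[as.character(hierarchy@nodes$id)] == 0L]
}

#' @describeIn RegionHierarchy-accessors all ids in the subtree rooted at `id`
#' @export
subtreeIds <- function(hierarchy, id) {
  out <- integer(0)
  frontier <- as.integer(id)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, childrenOf, hierarchy = hierarchy),
                       use.names = FALSE)
  }
  out
}

#' @describeIn RegionHierarchy-accessors map id to acronym
#' @export
acronymOf <- function(hierarchy, id)
  hierarchy@nodes$acronym[match(id, hierarchy@nodes$id)]

#' @describeIn RegionHierarchy-accessors map acronym to id
#' @export
idOfAcronym <- function(hierarchy, acronym) {
  i <- match(acronym, hierarchy@nodes$acronym)
  if (anyNA(i)) .fail("hierarchy", "unknown acronym(s): ",
                      paste(acronym[is.na(i)], collapse = ", "))
  hierarchy@nodes$id[i]
}

#' Depth ordering of regions (deepest first)
#'
#' Returns all region ids ordered by decreasing depth in the hierarchy, ties
#' broken by ascending id. This is the processing order of the capping and
#' coherence pre-pass and a reverse topological order: every region precedes
#' its parent.
#'
#' @param hierarchy a [RegionHierarchy-class].
#' @return integer vector of region ids.
#' @export
depthOrdering <- function(hierarchy) {
  ids <- hierarchy@nodes$id
  ids[order(-hierarchy@depth[as.character(ids)], ids)]
}

## ---- hierarchical aggregation ------------------------------------------

#' Aggregate own-voxel values up the region hierarchy
#'
#' Given a per-region value covering only the voxels directly labeled with
#' each region's id, returns hierarchy-consistent totals where every
#' parent's total equals its own value plus the sum of its children's
#' totals. Leaves are unchanged.
#'
#' @param own named numeric vector (names = region ids); regions absent from
#'   the vector contribute 0.
#' @param hierarchy a [RegionHierarchy-class].
#' @return named numeric vector of totals for every region.
#' @export
aggregateToParents <- function(own, hierarchy) {
  if (any(own < 0)) .fail("aggregateToParents", "negative input values")
  ids <- hierarchy@nodes$id
  total <- setNames(.lookup0(own, ids), as.character(ids))
  for (id in depthOrdering(hierarchy)) {
    ch <- childrenOf(hierarchy, id)
    if (length(ch))
      total[as.character(id)] <- total[as.character(id)] +
        sum(total[as.character(ch)])
  }
  total
}

## ---- region volumes -----------------------------------------------------

#' Per-region volumes from an annotation volume
#'
#' Computes the volume in mm^3 of each region. The own-voxel variant counts
#' only voxels labeled exactly with the region id; the hierarchical variant
#' adds all descendants' volumes. Regions absent from the annotation get
#' volume 0 and are listed in the `coverage` attribute.
#'
#' @param annotation an [AnnotationVolume-class].
#' @param hierarchy a [RegionHierarchy-class].
#' @param hierarchical if TRUE, include descendant volumes.
#' @return named numeric vector (mm^3) for every region, with attribute
#'   `missing`: ids with no directly-labeled voxel anywhere in their subtree.
#' @examples
#' # a 2x2x2 block of one region at 25 um: 8 * 0.025^3 mm^3
#' @export
regionVolumes <- function(annotation, hierarchy, hierarchical = FALSE) {
  stopifnot(is(annotation, "AnnotationVolume"), is(hierarchy, "RegionHierarchy"))
  labels <- as.vector(annotation@grid)
  labels <- labels[labels != 0L]
  if (length(labels) && !all(unique(labels) %in% regionIds(hierarchy)))
    .fail("regionVolumes", "annotation labels not in hierarchy: ",
          paste(setdiff(unique(labels), regionIds(hierarchy)), collapse = ", "))
  vv <- prod(annotation@voxelSize / 1000)  # mm^3 per voxel
  counts <- table(factor(labels, levels = regionIds(hierarchy)))
  own <- setNames(as.numeric(counts) * vv, as.character(regionIds(hierarchy)))
  out <- if (hierarchical) aggregateToParents(own, hierarchy) else own
  attr(out, "missing") <- regionIds(hierarchy)[
    aggregateToParents(own, hierarchy) == 0]
  out
}

## ---- homogeneity metric -------------------------------------------------

#' Homogeneity metric of a neuron-count distribution
#'
#' The population standard deviation of per-region neuron counts. Smearing
#' of counts across region boundaries (atlas misalignment) averages dense
#' and sparse regions and shrinks this value, so among atlas versions the
#' one with the largest metric is the least affected by misalignment.
#' Computed over leaf regions by default to avoid double counting.
#'
#' @param counts named numeric vector of neuron counts per region id.
#' @param hierarchy a [RegionHierarchy-class].
#' @param leavesOnly restrict to leaf regions present in `counts` (default).
#' @return the population standard deviation of the counts.
#' @export
homogeneityMetric <- function(counts, hierarchy, leavesOnly = TRUE) {
  v <- counts
  if (leavesOnly) v <- counts[names(counts) %in% as.character(leafIds(hierarchy))]
  if (length(v) < 2L) .fail("homogeneityMetric", "need at least 2 regions")
  .popSd(as.numeric(v))
}

## ---- RegionCounts CSV ---------------------------------------------------

#' Read/write per-region count tables
#'
#' CSV format with columns `region_id`, `acronym`, `tag`, `value`.
#'
#' @param path file path.
#' @param counts named numeric vector (names = region ids).
#' @param hierarchy a [RegionHierarchy-class] used to fill in acronyms.
#' @param tag semantic tag (e.g. `"nNeu"`, `"nGAD"`).
#' @return `readRegionCounts`: named numeric vector with attribute `tag`.
#' @export
writeRegionCounts <- function(counts, hierarchy, tag, path) {
  ids <- as.integer(names(counts))
  write.csv(data.frame(region_id = ids, acronym = acronymOf(hierarchy, ids),
                       tag = tag, value = as.numeric(counts)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionCounts
#' @export
readRegionCounts <- function(path) {
  df <- read.csv(path)
  out <- setNames(df$value, as.character(df$region_id))
  attr(out, "tag") <- unique(df$tag)
  out
}
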