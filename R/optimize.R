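## Density reconciliation: assembly of unconstrained estimates, the
## capping/coherence pre-pass, the weighted-slack linear program and its
## post-processing (correction flags, residual populations).

#' Accessor: the estimate table of a DensityEstimates object
#' @param x a [DensityEstimates-class].
#' @return data.frame with one row per (region, type, scope).
#' @export
estimatesTable <- function(x) x@estimates

#' Assemble unconstrained (eta, sigma) estimates for every region and type
#'
#' Resolution order per (region, type): the purely-inhibitory rule (GAD67
#' equals the neuron count), then literature, then the transfer-function
#' prediction from the region mean intensity, then aggregation of the
#' children's estimates (deepest regions are resolved first, so children
#' are always available). Regions with no information at all get eta 0
#' with a floor sigma and a warning. Every region additionally receives
#' own-voxel rows (the Eq-8 `R_m\\child` term) for its directly labeled
#' voxels, predicted from the own-voxel intensity where available.
#'
#' A sigma floor of `sigmaFloorFraction * max(eta, 1)` is applied to all
#' total estimates, since the LP objective divides by sigma.
#'
#' @param hierarchy a [RegionHierarchy-class].
#' @param literature data.frame `region_id`, `marker`, `eta`, `sigma`
#'   (counts; from [aggregateLiterature()]).
#' @param fits named list of [TransferFunction-class] from
#'   [fitTransferFunctions()].
#' @param intensities list per marker of [regionMeanIntensity()]
#'   data.frames (columns `region_id`, `mean`, `own_mean`).
#' @param volumes named numeric hierarchical region volumes (mm^3).
#' @param ownVolumes named numeric own-voxel region volumes (mm^3).
#' @param nNeu named numeric hierarchical neuron counts.
#' @param groups named character region groups from [assignGroups()].
#' @param purelyInhibitory integer region ids under the purely-inhibitory
#'   rule.
#' @param sigmaFloorFraction numeric sigma floor fraction (default 0.1).
#' @return a [DensityEstimates-class].
#' @export
assembleEstimates <- function(hierarchy, literature, fits, intensities,
                              volumes, ownVolumes, nNeu, groups,
                              purelyInhibitory = integer(0),
                              sigmaFloorFraction = 0.1) {
  ids <- regionIds(hierarchy)
  ord <- depthOrdering(hierarchy)           # deepest first
  rows <- vector("list", length(ids) * 8L)
  ri <- 0L
  total <- list()                            # per type: named vector of resolved etas
  for (tp in .TYPES) total[[tp]] <- setNames(rep(NA_real_, length(ids)), as.character(ids))
  totalSigma <- total
  prov <- lapply(.TYPES, function(tp) setNames(character(length(ids)), as.character(ids)))
  names(prov) <- .TYPES
  getI <- function(mk, rid, own = FALSE) {
    df <- intensities[[mk]]
    if (is.null(df)) return(NA_real_)
    v <- if (own) df$own_mean else df$mean
    v[match(rid, df$region_id)]
  }
  unresolved <- 0L
  for (id in ord) {
    key <- as.character(id)
    for (tp in .TYPES) {
      if (tp == "GAD67" && id %in% purelyInhibitory) {
        eta <- unname(nNeu[key]); sg <- sigmaFloorFraction * max(eta, 1)
        pv <- "purely-inhibitory"
      } else {
        lit <- literature[literature$region_id == id & literature$marker == tp, , drop = FALSE]
        if (nrow(lit)) {
          eta <- lit$eta[1]; sg <- lit$sigma[1]; pv <- "literature"
        } else {
          x <- getI(tp, id)
          tf <- transferFor(fits, tp, groups[key])
          if (!is.na(x) && !is.null(tf)) {
            p <- predictDensity(tf, x, volumes[key])
            eta <- unname(p["eta"]); sg <- unname(p["sigma"]); pv <- "fitted"
          } else {
            ch <- childrenOf(hierarchy, id)
            if (length(ch)) {
              eta <- sum(total[[tp]][as.character(ch)])
              sg <- sqrt(sum(totalSigma[[tp]][as.character(ch)]^2))
              xo <- getI(tp, id, own = TRUE)
              if (!is.na(xo) && !is.null(tf)) {
                p <- predictDensity(tf, xo, ownVolumes[key])
                eta <- eta + unname(p["eta"])
                sg <- sqrt(sg^2 + unname(p["sigma"])^2)
              }
              pv <- "aggregated"
            } else {
              eta <- 0; sg <- 0; pv <- "aggregated"
              unresolved <- unresolved + 1L
            }
          }
        }
      }
      sg <- max(sg, sigmaFloorFraction * max(eta, 1))
      total[[tp]][key] <- eta; totalSigma[[tp]][key] <- sg
      prov[[tp]][key] <- pv
      ri <- ri + 1L
      rows[[ri]] <- data.frame(region_id = id, type = tp, scope = "total",
                               eta = eta, sigma = sg, value = eta,
                               provenance = pv)
    }
    # own-voxel rows for parents
    if (length(childrenOf(hierarchy, id))) {
      for (tp in .TYPES) {
        xo <- getI(tp, id, own = TRUE)
        tf <- transferFor(fits, tp, groups[key])
        if (!is.na(xo) && !is.null(tf)) {
          p <- predictDensity(tf, xo, ownVolumes[key])
          eta <- unname(p["eta"]); sg <- unname(p["sigma"]); pv <- "fitted"
        } else {
          eta <- 0; sg <- 0; pv <- "aggregated"
        }
        sg <- max(sg, sigmaFloorFraction * max(eta, 1))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(region_id = id, type = tp, scope = "own",
                                 eta = eta, sigma = sg, value = eta,
                                 provenance = pv)
      }
    }
  }
  if (unresolved > 0L)
    warning(sprintf("%d (region, type) estimates had no literature, intensity or children; eta set to 0", unresolved))
  new("DensityEstimates", estimates = do.call(rbind, rows[seq_len(ri)]))
}

## ---- S2/S3 pre-pass -----------------------------------------------------

## cap one region's 4 values to its neuron count; returns list(values, log)
.capRegion <- function(vals, etas, sigmas, nNeu) {
  log <- character(0)
  lower <- pmax(etas - sigmas, 0)
  if (vals["GAD67"] > nNeu) {
    newGad <- nNeu                      # = min(vals, nNeu) since vals > nNeu
    if (newGad < lower["GAD67"]) log <- c(log, "GAD67 capped below its interval")
    vals["GAD67"] <- newGad
  }
  sub <- c("PV", "SST", "VIP")
  if (sum(vals[sub]) > nNeu) {
    diff <- sum(vals[sub]) - nNeu
    active <- sub[vals[sub] > lower[sub]]
    while (diff > 1e-12 && length(active)) {
      red <- diff * vals[active] / sum(vals[active])
      hit <- active[vals[active] - red < lower[active]]
      if (!length(hit)) {
        vals[active] <- vals[active] - red
        diff <- 0
      } else {
        # freeze the types hitting the bottom of their interval and
        # redistribute the remainder among the others
        diff <- diff - sum(vals[hit] - lower[hit])
        vals[hit] <- lower[hit]
        active <- setdiff(active, hit)
      }
    }
    if (diff > 1e-9) log <- c(log, "subtype sum capped outside intervals (all at interval bottom)")
  }
  list(values = vals, log = log)
}

## raise GAD / lower subtypes by the smallest fraction q of sigma such that
## GAD >= PV + SST + VIP; returns list(values, q, log)
.coherRegion <- function(vals, etas, sigmas, nNeu) {
  sub <- c("PV", "SST", "VIP")
  if (vals["GAD67"] >= sum(vals[sub]) - 1e-12)
    return(list(values = vals, q = 0, log = character(0)))
  gadUp <- min(etas["GAD67"] + sigmas["GAD67"], nNeu)
  lower <- pmax(etas[sub] - sigmas[sub], 0)
  gap <- function(q)
    min(vals["GAD67"] + q * sigmas["GAD67"], gadUp) -
      sum(pmax(lower, vals[sub] - q * sigmas[sub]))
  if (gap(1) < -1e-12) {
    gadNew <- max(min(vals["GAD67"] + sigmas["GAD67"], gadUp), 0)
    s <- sum(pmax(lower, vals[sub] - sigmas[sub]))
    newSub <- if (s > 0) pmax(lower, vals[sub] - sigmas[sub]) * gadNew / s
              else rep(0, 3)
    vals[sub] <- newSub
    vals["GAD67"] <- gadNew
    return(list(values = vals, q = 1,
                log = "interval exhausted: subtypes rescaled to GAD"))
  }
  lo <- 0; hi <- 1
  if (gap(0) >= 0) hi <- 0
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    if (gap(mid) >= 0) hi <- mid else lo <- mid
  }
  q <- hi
  vals["GAD67"] <- min(vals["GAD67"] + q * sigmas["GAD67"], gadUp)
  vals[sub] <- pmax(lower, vals[sub] - q * sigmas[sub])
  list(values = vals, q = q, log = character(0))
}

## shared driver: apply a per-region kernel to the chosen scope in
## inverse-depth order
.prepass <- function(est, nNeu, hierarchy, scope, kernel) {
  df <- est@estimates
  logs <- list(); qs <- c()
  for (id in depthOrdering(hierarchy)) {
    sel <- df$region_id == id &
      df$scope == (if (scope == "own" && !length(childrenOf(hierarchy, id))) "total" else scope)
    if (!any(sel)) next
    sub <- df[sel, ]
    vals <- setNames(sub$value, sub$type)[.TYPES]
    etas <- setNames(sub$eta, sub$type)[.TYPES]
    sigmas <- setNames(sub$sigma, sub$type)[.TYPES]
    res <- kernel(vals, etas, sigmas, unname(nNeu[as.character(id)]))
    df$value[sel] <- unname(res$values[sub$type])
    if (length(res$log)) logs[[as.character(id)]] <- res$log
    if (!is.null(res$q)) qs[as.character(id)] <- res$q
  }
  out <- new("DensityEstimates", estimates = df)
  attr(out, "log") <- logs
  if (length(qs)) attr(out, "q") <- qs
  out
}

#' Cap inhibitory estimates to the neuron count (pre-pass algorithm 1)
#'
#' For every region in inverse depth order, enforces
#' `nGAD <= nNeu` and `nPV + nSST + nVIP <= nNeu` on the working values.
#' Excess subtype counts are removed proportionally to the current
#' PV/SST/VIP ratios; a value reaching the bottom of its confidence
#' interval `[eta - sigma, eta + sigma]` is frozen there and the remainder
#' is redistributed among the others. GAD67 is clipped to the neuron count
#' (inside its interval when possible). Out-of-interval clips are logged in
#' the `"log"` attribute of the result.
#'
#' @param est a [DensityEstimates-class].
#' @param nNeu named numeric neuron counts matching `scope`.
#' @param hierarchy a [RegionHierarchy-class].
#' @param scope `"total"` (default: subtree-total estimates per region) or
#'   `"own"` (per directly-labeled voxel set; leaves fall back to their
#'   total rows).
#' @return the adjusted [DensityEstimates-class] (attribute `"log"`).
#' @export
capToNeurons <- function(est, nNeu, hierarchy, scope = "total")
  .prepass(est, nNeu, hierarchy, scope, .capRegion)

#' Restore GAD67 >= PV + SST + VIP coherence (pre-pass algorithm 2)
#'
#' For every region in inverse depth order, when the subtype sum exceeds
#' GAD67, finds the smallest correction fraction q in \[0, 1\] such that
#' raising GAD67 by `q * sigma_GAD` (clamped at its interval top and the
#' neuron count) and lowering each subtype by `q * sigma` (clamped at its
#' interval bottom) restores the inequality. If q = 1 is insufficient, the
#' subtypes are rescaled proportionally to equal GAD67 and the region is
#' logged as out-of-interval. Applied after [capToNeurons()].
#'
#' @inheritParams capToNeurons
#' @return the adjusted [DensityEstimates-class] (attributes `"log"`,
#'   `"q"`).
#' @export
enforceCoherence <- function(est, nNeu, hierarchy, scope = "total")
  .prepass(est, nNeu, hierarchy, scope, .coherRegion)

#' Hierarchy-consistent initial solution from the pre-pass
#'
#' Runs the capping and coherence pre-pass on the own-voxel scope and
#' aggregates the adjusted own values up the hierarchy, yielding an x
#' vector that satisfies every LP constraint (bounds and the subtype-sum
#' window hold per voxel set, the hierarchy equality holds by
#' construction). Its objective bounds the LP optimum from above.
#'
#' @param est a [DensityEstimates-class].
#' @param nNeuOwn named numeric own-voxel neuron counts.
#' @param hierarchy a [RegionHierarchy-class].
#' @return list with `x` (data.frame region_id, type, scope, x), and
#'   `objective` (sum of |x - eta|/sigma over total estimates).
#' @export
initialSolution <- function(est, nNeuOwn, hierarchy) {
  adj <- enforceCoherence(capToNeurons(est, nNeuOwn, hierarchy, scope = "own"),
                          nNeuOwn, hierarchy, scope = "own")
  df <- adj@estimates
  rows <- list()
  for (tp in .TYPES) {
    isOwnRow <- df$type == tp &
      ((df$scope == "own") |
         (df$scope == "total" & !df$region_id %in% df$region_id[df$scope == "own"]))
    own <- setNames(df$value[isOwnRow], as.character(df$region_id[isOwnRow]))
    tot <- aggregateToParents(own, hierarchy)
    rows[[tp]] <- rbind(
      data.frame(region_id = as.integer(names(tot)), type = tp, scope = "total",
                 x = unname(tot)),
      data.frame(region_id = as.integer(names(own)), type = tp, scope = "own",
                 x = unname(own)))
  }
  x <- do.call(rbind, rows)
  tot <- df[df$scope == "total", ]
  xt <- x[x$scope == "total", ]
  m <- match(paste(tot$region_id, tot$type), paste(xt$region_id, xt$type))
  list(x = x, objective = sum(abs(xt$x[m] - tot$eta) / tot$sigma))
}

## ---- LP construction ----------------------------------------------------

#' Build the density-reconciliation linear program
#'
#' Variables: one count `x` per (region, type) covering the region's
#' subtree (the density variables), one own-voxel count per parent region
#' and type, and one slack `z` per density variable. Constraints: bounds
#' `0 <= x <= nNeu`, the subtype-sum window
#' `-nNeu <= nPV + nSST + nVIP - nGAD <= 0` per region (for both the
#' subtree totals and the own-voxel variables, so that placement
#' preconditions hold on the actually labeled voxels), the hierarchy
#' equality `x_parent = x_own + sum(x_children)` per parent and type, and
#' the slack envelope `-z <= x - eta <= z`. Objective: `sum(z / sigma)`.
#' Own-voxel variables are auxiliary: they carry no slack, matching the
#' objective's one-term-per-region-and-type structure.
#'
#' @param est a [DensityEstimates-class] (the `eta`/`sigma` of the total
#'   rows enter the envelope; `value` is ignored here).
#' @param nNeu named numeric hierarchical neuron counts per region.
#' @param hierarchy a [RegionHierarchy-class].
#' @param nNeuOwn named numeric own-voxel neuron counts; defaults to
#'   `nNeu - sum(children nNeu)` clipped at 0.
#' @return an [LPProblem-class].
#' @export
buildLP <- function(est, nNeu, hierarchy, nNeuOwn = NULL) {
  ids <- regionIds(hierarchy)
  n <- length(ids)
  key <- as.character(ids)
  if (any(is.na(nNeu[key]))) .fail("buildLP", "missing neuron counts")
  if (is.null(nNeuOwn)) {
    childSum <- vapply(ids, function(id)
      sum(nNeu[as.character(childrenOf(hierarchy, id))]), numeric(1))
    nNeuOwn <- setNames(pmax(nNeu[key] - childSum, 0), key)
  }
  df <- est@estimates
  tot <- df[df$scope == "total", ]
  if (nrow(tot) != 4L * n) .fail("buildLP", "need 4 total estimates per region")
  parents <- ids[vapply(ids, function(id) length(childrenOf(hierarchy, id)) > 0, logical(1))]
  np <- length(parents)
  nTot <- 4L * n; nOwn <- 4L * np
  xTot <- function(rpos, t) (rpos - 1L) * 4L + t
  xOwn <- function(ppos, t) nTot + (ppos - 1L) * 4L + t
  zTot <- function(rpos, t) nTot + nOwn + (rpos - 1L) * 4L + t
  ncols <- nTot + nOwn + nTot
  # eta/sigma aligned with column order
  m <- match(paste(rep(ids, each = 4), rep(.TYPES, n)),
             paste(tot$region_id, tot$type))
  etaTot <- tot$eta[m]; sigTot <- tot$sigma[m]
  if (any(sigTot <= 0)) .fail("buildLP", "sigma must be > 0 (apply the sigma floor)")

  ti <- list(); tj <- list(); tx <- list(); dir <- list(); rhs <- list()
  nr <- 0L
  addRows <- function(i, j, x, d, b) {
    k <- length(ti) + 1L
    ti[[k]] <<- i + nr; tj[[k]] <<- j; tx[[k]] <<- x
    dir[[k]] <<- d; rhs[[k]] <<- b
    nr <<- nr + length(b)
  }
  # bounds x_total <= nNeu ; x_own <= nNeuOwn
  addRows(rep(seq_len(nTot)), seq_len(nTot), rep(1, nTot),
          rep("<=", nTot), rep(nNeu[key], each = 4))
  if (np) addRows(seq_len(nOwn), nTot + seq_len(nOwn), rep(1, nOwn),
                  rep("<=", nOwn), rep(nNeuOwn[as.character(parents)], each = 4))
  # subtype-sum window per region (totals): PV+SST+VIP-GAD in [-nNeu, 0]
  cf <- c(1, 1, 1, -1)
  addRows(rep(seq_len(n), each = 4), xTot(rep(seq_len(n), each = 4), rep(1:4, n)),
          rep(cf, n), rep("<=", n), rep(0, n))
  addRows(rep(seq_len(n), each = 4), xTot(rep(seq_len(n), each = 4), rep(1:4, n)),
          rep(-cf, n), rep("<=", n), unname(nNeu[key]))
  # subtype-sum window for own-voxel variables
  if (np) {
    addRows(rep(seq_len(np), each = 4), xOwn(rep(seq_len(np), each = 4), rep(1:4, np)),
            rep(cf, np), rep("<=", np), rep(0, np))
    addRows(rep(seq_len(np), each = 4), xOwn(rep(seq_len(np), each = 4), rep(1:4, np)),
            rep(-cf, np), rep("<=", np), unname(nNeuOwn[as.character(parents)]))
  }
  # hierarchy equality per parent and type
  for (pi in seq_len(np)) {
    p <- parents[pi]
    ch <- childrenOf(hierarchy, p)
    cpos <- match(ch, ids); ppos <- match(p, ids)
    for (t in 1:4) {
      jj <- c(xTot(ppos, t), xTot(cpos, t), xOwn(pi, t))
      addRows(rep(1L, length(jj)), jj, c(1, rep(-1, length(cpos)), -1), "==", 0)
    }
  }
  # slack envelope per total variable
  s <- seq_len(nTot)
  addRows(rep(seq_len(nTot), 2L), c(xTot(rep(seq_len(n), each = 4), rep(1:4, n)), zTot(rep(seq_len(n), each = 4), rep(1:4, n))),
          c(rep(1, nTot), rep(-1, nTot)), rep("<=", nTot), etaTot)
  addRows(rep(seq_len(nTot), 2L), c(xTot(rep(seq_len(n), each = 4), rep(1:4, n)), zTot(rep(seq_len(n), each = 4), rep(1:4, n))),
          c(rep(-1, nTot), rep(-1, nTot)), rep("<=", nTot), -etaTot)

  mat <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                              dims = c(nr, ncols))
  obj <- numeric(ncols)
  obj[nTot + nOwn + s] <- 1 / sigTot
  vars <- data.frame(
    name = c(sprintf("x[%d,%s]", rep(ids, each = 4), rep(.TYPES, n)),
             if (np) sprintf("o[%d,%s]", rep(parents, each = 4), rep(.TYPES, np)),
             sprintf("z[%d,%s]", rep(ids, each = 4), rep(.TYPES, n))),
    region_id = c(rep(ids, each = 4), if (np) rep(parents, each = 4), rep(ids, each = 4)),
    type = c(rep(.TYPES, n), if (np) rep(.TYPES, np), rep(.TYPES, n)),
    role = c(rep("x_total", nTot), rep("x_own", nOwn), rep("z_total", nTot)),
    eta = c(etaTot, rep(NA_real_, nOwn), rep(NA_real_, nTot)),
    sigma = c(sigTot, rep(NA_real_, nOwn), rep(NA_real_, nTot)))
  new("LPProblem", obj = obj, mat = mat,
      dir = unlist(dir), rhs = unname(unlist(rhs)), vars = vars)
}

#' Number of density variables of an LPProblem
#'
#' One per region and neuron type (4 x number of regions); own-voxel and
#' slack variables are counted separately by [show()].
#'
#' @param problem an [LPProblem-class].
#' @return integer count.
#' @export
nDensityVariables <- function(problem) sum(problem@vars$role == "x_total")

#' Export an LPProblem to a machine-readable dump
#'
#' Writes a plain-text dump (objective, column descriptors, constraint
#' triplets) for cross-solver audits.
#'
#' @param problem an [LPProblem-class].
#' @param path output file.
#' @export
writeLPDump <- function(problem, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# density-reconciliation LP dump", con)
  writeLines("## columns: name role objective", con)
  write.table(data.frame(problem@vars$name, problem@vars$role, problem@obj),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("## constraints: row col coef dir rhs", con)
  tr <- Matrix::summary(problem@mat)
  write.table(data.frame(tr$i, tr$j, tr$x, problem@dir[tr$i], problem@rhs[tr$i]),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Solve the density-reconciliation LP
#'
#' Solves the program with the package's two-phase simplex and verifies
#' every constraint within the requested relative tolerance. `x = 0`,
#' `z = eta` is always feasible, so infeasibility indicates a malformed
#' problem and raises an error naming the violated constraints.
#'
#' @param problem an [LPProblem-class].
#' @param tol relative feasibility tolerance (default 1e-7).
#' @return an [LPSolution-class].
#' @export
solveLP <- function(problem, tol = 1e-7) {
  dirCode <- match(problem@dir, c("<=", "==", ">=")) - 1L
  res <- .simplexCpp(problem@obj, as.matrix(problem@mat), dirCode,
                     problem@rhs)
  if (!identical(res$status, "optimal"))
    .fail("solveLP", "solver status: ", res$status)
  v <- pmax(res$x, 0)              # clear roundoff-negative basic values
  lhs <- as.numeric(problem@mat %*% v)
  scale <- pmax(abs(problem@rhs), 1)
  viol <- (problem@dir == "<=" & lhs > problem@rhs + tol * scale) |
          (problem@dir == "==" & abs(lhs - problem@rhs) > tol * scale) |
          (problem@dir == ">=" & lhs < problem@rhs - tol * scale)
  if (any(viol))
    .fail("solveLP", sum(viol), " constraints violated beyond tolerance, first at row ",
          which(viol)[1])
  vars <- problem@vars
  xrows <- vars$role %in% c("x_total", "x_own")
  sol <- data.frame(region_id = vars$region_id[xrows], type = vars$type[xrows],
                    scope = ifelse(vars$role[xrows] == "x_total", "total", "own"),
                    eta = vars$eta[xrows], sigma = vars$sigma[xrows],
                    x = v[xrows], z = NA_real_, flagged = NA)
  zvals <- v[vars$role == "z_total"]
  sol$z[sol$scope == "total"] <- zvals
  sol$flagged[sol$scope == "total"] <-
    abs(sol$x[sol$scope == "total"] - sol$eta[sol$scope == "total"]) >
      sol$sigma[sol$scope == "total"] * (1 + 1e-9)
  new("LPSolution", solution = sol, objective = res$objective,
      status = res$status)
}

#' Solution accessors
#' @param x an [LPSolution-class].
#' @name LPSolution-accessors
#' @return `solutionTable`: the per-variable data.frame; `objectiveValue`:
#'   the optimal objective.
NULL

#' @describeIn LPSolution-accessors the per-variable table
#' @export
solutionTable <- function(x) x@solution

#' @describeIn LPSolution-accessors the optimal objective value
#' @export
objectiveValue <- function(x) x@objective

#' Flag corrected estimates
#'
#' An estimate is flagged when its corrected value falls outside
#' `eta +/- sigma`; a region is flagged when any of its four types is.
#'
#' @param solution an [LPSolution-class].
#' @return list with `perEstimate` (data.frame), `perRegion` (data.frame
#'   `region_id`, `flagged`) and `fractionRegionsFlagged`.
#' @export
flagCorrections <- function(solution) {
  tot <- solution@solution[solution@solution$scope == "total", ]
  perRegion <- aggregate(flagged ~ region_id, tot, any)
  list(perEstimate = tot[c("region_id", "type", "eta", "sigma", "x", "flagged")],
       perRegion = perRegion,
       fractionRegionsFlagged = mean(perRegion$flagged))
}

#' Derive the residual inhibitory and non-inhibitory populations
#'
#' `nRest = nGAD - (nPV + nSST + nVIP)` (inhibitory neurons expressing
#' none of the three markers) and `nExcOther = nNeu - nGAD` (excitatory
#' plus purely modulatory neurons), per region. The LP constraints
#' guarantee both are non-negative; a violation beyond tolerance is an
#' error.
#'
#' @param solution an [LPSolution-class].
#' @param nNeu named numeric neuron counts (matching the chosen scope).
#' @param scope `"total"` or `"own"`.
#' @param tol absolute tolerance for the non-negativity check.
#' @return data.frame `region_id`, `nRest`, `nExcOther`.
#' @export
deriveResiduals <- function(solution, nNeu, scope = "total", tol = 1e-6) {
  s <- solution@solution[solution@solution$scope == scope, ]
  w <- reshape(s[c("region_id", "type", "x")], idvar = "region_id",
               timevar = "type", direction = "wide")
  names(w) <- sub("^x\\.", "", names(w))
  rest <- w$GAD67 - (w$PV + w$SST + w$VIP)
  exc <- unname(nNeu[as.character(w$region_id)]) - w$GAD67
  scale <- pmax(abs(w$GAD67), 1)
  if (any(rest < -tol * scale) || any(exc < -tol * scale))
    .fail("deriveResiduals", "negative residual population: constraint violation")
  data.frame(region_id = w$region_id, nRest = pmax(rest, 0),
             nExcOther = pmax(exc, 0))
}
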