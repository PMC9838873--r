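# Shared fixtures and independent oracles, built once per test run.

.cache <- new.env(parent = emptyenv())

.inhibTypes <- function() c("PV", "SST", "VIP", "GAD67")

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# 4-region toy tree: root(1) -> {a(2) -> a1(4), b(3)}
tinyHierarchy <- function() {
  RegionHierarchy(data.frame(
    id = 1:4, name = c("root", "a", "b", "a1"),
    acronym = c("rt", "a", "b", "a1"), parent_id = c(NA, 1, 1, 2)))
}

# standard noisy study conditions (literature CV 0.2, coverage 0.5)
standardFixture <- function(seed = 7) memo(paste0("std", seed), {
  spec <- toyBrainSpec(seed = seed)
  atlas <- makeToyAtlas(spec)
  list(spec = spec, atlas = atlas, ish = makeIsh(atlas),
       records = makeLiterature(atlas))
})

standardContext <- function(seed = 7) memo(paste0("ctx", seed), {
  fx <- standardFixture(seed)
  prepareContext(fx$atlas$hierarchy, fx$atlas$annotation, fx$ish,
                 nissl = fx$atlas$nissl,
                 totalCells = sum(fx$atlas$truth$own$nCell),
                 neuronFraction = fx$spec$neuronFraction,
                 isocortexRoot = "ISO", cerebellumRoot = "CB")
})

standardResult <- function(seed = 7) memo(paste0("res", seed), {
  fx <- standardFixture(seed)
  res <- fitAndSolve(standardContext(seed), fx$records,
                     purelyInhibitory = fx$atlas$purelyInhibitory)
  res
})

# random reconciliation problem on a random tree with <= maxRegions regions;
# eta is drawn freely so constraints are typically violated
randomToyProblem <- function(seed, maxRegions = 12) {
  set.seed(seed)
  n <- sample(1:maxRegions, 1)
  parent <- c(NA, if (n > 1) vapply(2:n, function(i) sample(i - 1L, 1), integer(1)))
  h <- RegionHierarchy(data.frame(id = 1:n, name = paste0("r", 1:n),
                                  acronym = paste0("r", 1:n), parent_id = parent))
  key <- as.character(1:n)
  nNeuOwn <- setNames(round(runif(n, 5, 60)), key)
  nNeu <- aggregateToParents(nNeuOwn, h)
  rows <- list()
  types <- c("PV", "SST", "VIP", "GAD67")
  for (id in 1:n) {
    eta <- round(runif(4, 0, 1.3 * nNeu[as.character(id)]), 1)
    sigma <- round(pmax(0.5, eta * runif(4, 0.1, 0.5)), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = id, type = types, scope = "total", eta = eta, sigma = sigma,
      value = eta, provenance = "literature")
    if (length(childrenOf(h, id))) {
      etao <- round(runif(4, 0, nNeuOwn[as.character(id)]), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = id, type = types, scope = "own", eta = etao,
        sigma = pmax(etao, 1), value = etao, provenance = "fitted")
    }
  }
  est <- new("DensityEstimates", estimates = do.call(rbind, rows))
  list(hierarchy = h, est = est, nNeu = nNeu, nNeuOwn = nNeuOwn)
}

# Independently formulated LP for boot::simplex: the matrices are built
# dense, row by row, directly from the estimate table -- sharing no code
# with buildLP().
bootOracleObjective <- function(prob) {
  h <- prob$hierarchy; est <- prob$est@estimates
  types <- c("PV", "SST", "VIP", "GAD67")
  ids <- regionIds(h)
  parents <- ids[vapply(ids, function(i) length(childrenOf(h, i)) > 0, logical(1))]
  vn <- c(outer(types, ids, function(t, r) paste0("x.", r, ".", t)),
          if (length(parents))
            c(outer(types, parents, function(t, r) paste0("o.", r, ".", t))),
          c(outer(types, ids, function(t, r) paste0("z.", r, ".", t))))
  nv <- length(vn)
  col <- function(nm) match(nm, vn)
  A1 <- NULL; b1 <- c(); A2 <- NULL; b2 <- c(); A3 <- NULL; b3 <- c()
  r1 <- function(v, b) { A1 <<- rbind(A1, v); b1 <<- c(b1, b) }
  r2 <- function(v, b) { A2 <<- rbind(A2, v); b2 <<- c(b2, b) }
  r3 <- function(v, b) { A3 <<- rbind(A3, v); b3 <<- c(b3, b) }
  zero <- rep(0, nv)
  for (r in ids) {
    nn <- prob$nNeu[[as.character(r)]]
    for (t in types) {
      v <- zero; v[col(paste0("x.", r, ".", t))] <- 1
      r1(v, nn)                                   # x <= nNeu
    }
    v <- zero
    v[col(paste0("x.", r, ".", c("PV", "SST", "VIP")))] <- 1
    v[col(paste0("x.", r, ".GAD67"))] <- -1
    r1(v, 0)                                      # subtype sum <= GAD
    r1(-v, nn)                                    # GAD - sum <= nNeu
    sub <- est[est$region_id == r & est$scope == "total", ]
    for (t in types) {
      eta <- sub$eta[sub$type == t]
      v <- zero
      v[col(paste0("x.", r, ".", t))] <- 1
      v[col(paste0("z.", r, ".", t))] <- -1
      r1(v, eta)                                  # x - z <= eta
      v <- zero
      v[col(paste0("x.", r, ".", t))] <- 1
      v[col(paste0("z.", r, ".", t))] <- 1
      r2(v, eta)                                  # x + z >= eta
    }
  }
  for (p in parents) {
    nn <- prob$nNeuOwn[[as.character(p)]]
    for (t in types) {
      v <- zero; v[col(paste0("o.", p, ".", t))] <- 1
      r1(v, nn)
      v <- zero
      v[col(paste0("x.", p, ".", t))] <- 1
      v[col(paste0("o.", p, ".", t))] <- -1
      v[col(paste0("x.", childrenOf(h, p), ".", t))] <- -1
      r3(v, 0)                                    # hierarchy equality
    }
    v <- zero
    v[col(paste0("o.", p, ".", c("PV", "SST", "VIP")))] <- 1
    v[col(paste0("o.", p, ".GAD67"))] <- -1
    r1(v, 0)
    r1(-v, nn)
  }
  a <- rep(0, nv)
  tot <- est[est$scope == "total", ]
  for (i in seq_len(nrow(tot)))
    a[col(paste0("z.", tot$region_id[i], ".", tot$type[i]))] <- 1 / tot$sigma[i]
  out <- boot::simplex(a, A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3,
                       maxi = FALSE, n.iter = 100 * (nv + length(b1) + length(b2) + length(b3)))
  stopifnot(out$solved == 1)
  unname(out$value)
}

# exhaustive grid minimization of sum(|x - eta|/sigma) for one region
# (4 free counts) on an integer-valued problem; the constraint system is
# an interval matrix, so with integer bounds and etas the LP optimum lies
# on the integer grid
gridOracleOneRegion <- function(eta, sigma, nNeu, step = 0.5) {
  g <- seq(0, nNeu, by = step)
  grid <- expand.grid(PV = g, SST = g, VIP = g, GAD67 = g)
  ok <- grid$PV + grid$SST + grid$VIP - grid$GAD67 <= 0 &
    grid$PV + grid$SST + grid$VIP - grid$GAD67 >= -nNeu
  grid <- grid[ok, ]
  obj <- abs(grid$PV - eta["PV"]) / sigma["PV"] +
    abs(grid$SST - eta["SST"]) / sigma["SST"] +
    abs(grid$VIP - eta["VIP"]) / sigma["VIP"] +
    abs(grid$GAD67 - eta["GAD67"]) / sigma["GAD67"]
  min(obj)
}

# parent (1) + child (2) with a GAD67 deficit in the child; SST and VIP
# have eta 0 everywhere so the optimum sets them to 0 (they only tighten
# the subtype-sum constraint and add |x|/sigma penalty)
twoRegionDeficitProblem <- function() {
  h <- RegionHierarchy(data.frame(id = 1:2, name = c("p", "c"),
                                  acronym = c("p", "c"), parent_id = c(NA, 1)))
  types <- c("PV", "SST", "VIP", "GAD67")
  mk <- function(region, scope, eta)
    data.frame(region_id = region, type = types, scope = scope, eta = eta,
               sigma = c(2, 1, 1, 2), value = eta, provenance = "literature")
  est <- new("DensityEstimates", estimates = rbind(
    mk(1L, "total", c(8, 0, 0, 6)),       # parent: PV 8 exceeds GAD 6
    mk(2L, "total", c(6, 0, 0, 3)),       # child deficit: PV 6 > GAD 3
    mk(1L, "own", c(2, 0, 0, 2))))
  list(hierarchy = h, est = est, nNeu = c("1" = 20, "2" = 12),
       nNeuOwn = c("1" = 8, "2" = 12))
}

gridOracleTwoRegion <- function(prob, step = 0.5) {
  est <- prob$est@estimates
  e <- function(r, t, sc) est$eta[est$region_id == r & est$type == t & est$scope == sc]
  s <- function(r, t, sc) est$sigma[est$region_id == r & est$type == t & est$scope == sc]
  gC <- seq(0, prob$nNeu[["2"]], by = step)
  gO <- seq(0, prob$nNeuOwn[["1"]], by = step)
  grid <- expand.grid(pvC = gC, gadC = gC, pvO = gO, gadO = gO)
  ok <- grid$pvC <= grid$gadC & grid$pvO <= grid$gadO &
    grid$gadC - grid$pvC <= prob$nNeu[["2"]] &
    grid$gadO - grid$pvO <= prob$nNeuOwn[["1"]] &
    grid$pvC + grid$pvO <= prob$nNeu[["1"]] &
    grid$gadC + grid$gadO <= prob$nNeu[["1"]] &
    (grid$pvC + grid$pvO) <= (grid$gadC + grid$gadO) &
    (grid$gadC + grid$gadO) - (grid$pvC + grid$pvO) <= prob$nNeu[["1"]]
  grid <- grid[ok, ]
  obj <- abs(grid$pvC - e(2, "PV", "total")) / s(2, "PV", "total") +
    abs(grid$gadC - e(2, "GAD67", "total")) / s(2, "GAD67", "total") +
    abs(grid$pvC + grid$pvO - e(1, "PV", "total")) / s(1, "PV", "total") +
    abs(grid$gadC + grid$gadO - e(1, "GAD67", "total")) / s(1, "GAD67", "total")
  min(obj)
}

oneRegionProblem <- function(eta, sigma, nNeu) {
  h <- RegionHierarchy(data.frame(id = 1L, name = "r", acronym = "r",
                                  parent_id = NA_integer_))
  types <- c("PV", "SST", "VIP", "GAD67")
  est <- new("DensityEstimates", estimates = data.frame(
    region_id = 1L, type = types, scope = "total",
    eta = unname(eta[types]), sigma = unname(sigma[types]),
    value = unname(eta[types]), provenance = "literature"))
  list(hierarchy = h, est = est, nNeu = c("1" = nNeu),
       nNeuOwn = c("1" = nNeu))
}
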