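test_that("estimate assembly resolves every region and type with provenance", {
  fx <- standardFixture()
  res <- standardResult()
  est <- estimatesTable(res$estimates)
  tot <- est[est$scope == "total", ]
  # full cross product: 4 estimates per region
  expect_equal(nrow(tot), 4 * nRegions(fx$atlas$hierarchy))
  expect_true(all(tot$sigma > 0))
  expect_true(all(is.finite(tot$eta)))
  # purely-inhibitory region: GAD67 equals its neuron count
  pureId <- fx$atlas$purelyInhibitory
  prow <- tot[tot$region_id == pureId & tot$type == "GAD67", ]
  expect_equal(prow$provenance, "purely-inhibitory")
  ctx <- standardContext()
  expect_equal(prow$eta, unname(ctx$nNeu[as.character(pureId)]))
  # literature-covered regions carry literature provenance
  litRegions <- unique(res$literature$estimates$region_id[
    res$literature$estimates$marker == "PV"])
  litRegions <- setdiff(litRegions, pureId)
  expect_true(all(tot$provenance[tot$region_id %in% litRegions &
                                   tot$type == "PV"] == "literature"))
  # a single-region hierarchy yields exactly 4 estimates
  h1 <- RegionHierarchy(data.frame(id = 1, name = "r", acronym = "r", parent_id = NA))
  est1 <- suppressWarnings(
    assembleEstimates(h1, data.frame(region_id = integer(0), marker = character(0),
                                     eta = numeric(0), sigma = numeric(0)),
                      list(), list(), c("1" = 1), c("1" = 1), c("1" = 100),
                      c("1" = "rest")))
  expect_equal(nrow(estimatesTable(est1)), 4)
})

test_that("parent estimates without direct evidence aggregate their children", {
  # 3-region tree, literature only on the two leaves, no intensities
  h <- RegionHierarchy(data.frame(id = 1:3, name = "x", acronym = c("r", "a", "b"),
                                  parent_id = c(NA, 1, 1)))
  lit <- data.frame(region_id = c(2L, 3L), marker = "PV",
                    eta = c(100, 50), sigma = c(10, 5))
  vols <- c("1" = 3, "2" = 1, "3" = 1); nNeu <- c("1" = 1e4, "2" = 5e3, "3" = 5e3)
  est <- suppressWarnings(assembleEstimates(h, lit, list(), list(), vols, vols,
                                            nNeu, setNames(rep("rest", 3), 1:3)))
  tot <- estimatesTable(est)
  prow <- tot[tot$region_id == 1 & tot$type == "PV" & tot$scope == "total", ]
  expect_equal(prow$eta, 150)                         # children sum
  expect_equal(prow$provenance, "aggregated")
  # children sigma in quadrature, then the 0.1 * eta sigma floor
  expect_equal(prow$sigma, max(sqrt(10^2 + 5^2), 0.1 * 150))
})

test_that("the capping pre-pass follows the worked redistribution traces", {
  mkEst <- function(eta, sigma, etaGad = 10, sigmaGad = 1e6) {
    new("DensityEstimates", estimates = data.frame(
      region_id = 1L, type = c("PV", "SST", "VIP", "GAD67"), scope = "total",
      eta = c(eta, etaGad), sigma = c(sigma, sigmaGad),
      value = c(eta, etaGad), provenance = "literature"))
  }
  h1 <- RegionHierarchy(data.frame(id = 1, name = "r", acronym = "r", parent_id = NA))
  # nNeu 100, subtypes (50, 40, 30) with wide intervals:
  # diff 20 removed proportionally -> (41.67, 33.33, 25.0)
  est <- mkEst(c(50, 40, 30), c(100, 100, 100))
  out <- estimatesTable(capToNeurons(est, c("1" = 100), h1))
  expect_equal(out$value[out$type == "PV"], 50 - 20 * 50 / 120, tolerance = 1e-9)
  expect_equal(out$value[out$type == "SST"], 40 - 20 * 40 / 120, tolerance = 1e-9)
  expect_equal(out$value[out$type == "VIP"], 30 - 20 * 30 / 120, tolerance = 1e-9)
  # GAD eta 120 sigma 30, nNeu 100 -> capped to 100, inside [90, 150]
  est2 <- mkEst(c(1, 1, 1), c(1, 1, 1), etaGad = 120, sigmaGad = 30)
  out2 <- estimatesTable(capToNeurons(est2, c("1" = 100), h1))
  expect_equal(out2$value[out2$type == "GAD67"], 100)
  expect_length(attr(capToNeurons(est2, c("1" = 100), h1), "log"), 0)
  # no violation: identity
  est3 <- mkEst(c(10, 10, 10), c(1, 1, 1), etaGad = 40, sigmaGad = 5)
  out3 <- estimatesTable(capToNeurons(est3, c("1" = 100), h1))
  expect_equal(out3$value, out3$eta)
  # freeze-at-interval-bottom: PV can only drop to 45
  est4 <- mkEst(c(50, 40, 30), c(5, 100, 100))
  out4 <- estimatesTable(capToNeurons(est4, c("1" = 100), h1))
  expect_equal(out4$value[out4$type == "PV"], 45)
  expect_equal(sum(out4$value[out4$type %in% c("PV", "SST", "VIP")]), 100,
               tolerance = 1e-9)
  # SST and VIP keep their mutual ratio after redistribution
  v <- out4$value; names(v) <- out4$type
  expect_equal(v[["SST"]] / v[["VIP"]], 40 / 30, tolerance = 1e-6)
})

test_that("the coherence pre-pass solves the q fraction and rescale branches", {
  h1 <- RegionHierarchy(data.frame(id = 1, name = "r", acronym = "r", parent_id = NA))
  mkEst <- function(etas, sigmas, vals = etas) {
    new("DensityEstimates", estimates = data.frame(
      region_id = 1L, type = c("PV", "SST", "VIP", "GAD67"), scope = "total",
      eta = etas, sigma = sigmas, value = vals, provenance = "literature"))
  }
  # already coherent: identity, q = 0
  est0 <- mkEst(c(30, 20, 10, 100), c(5, 5, 5, 10))
  out0 <- enforceCoherence(est0, c("1" = 1000), h1)
  expect_equal(estimatesTable(out0)$value, estimatesTable(est0)$value)
  expect_equal(unname(attr(out0, "q")["1"]), 0)
  # GAD 90 sigma 10, subtypes summing 100 with sigmas (5, 3, 2):
  # q solves 90 + 10q = 100 - 10q -> q = 0.5; GAD 95, sum 95
  est1 <- mkEst(c(50, 30, 20, 90), c(5, 3, 2, 10))
  out1 <- enforceCoherence(est1, c("1" = 1000), h1)
  v <- estimatesTable(out1)$value; names(v) <- estimatesTable(out1)$type
  expect_equal(unname(attr(out1, "q")["1"]), 0.5, tolerance = 1e-9)
  expect_equal(v[["GAD67"]], 95, tolerance = 1e-6)
  expect_equal(sum(v[c("PV", "SST", "VIP")]), 95, tolerance = 1e-6)
  expect_equal(v[["PV"]], 50 - 0.5 * 5, tolerance = 1e-6)
  # interval exhausted: subtypes rescaled proportionally to GAD, logged
  est2 <- mkEst(c(100, 80, 60, 50), c(1, 1, 1, 2))
  out2 <- enforceCoherence(est2, c("1" = 1000), h1)
  v2 <- estimatesTable(out2)$value; names(v2) <- estimatesTable(out2)$type
  expect_equal(sum(v2[c("PV", "SST", "VIP")]), v2[["GAD67"]], tolerance = 1e-6)
  expect_true(length(attr(out2, "log")) > 0)
  # the pre-pass never leaves [eta - sigma, eta + sigma] except in the
  # logged branch
  tab <- estimatesTable(out1)
  expect_true(all(tab$value >= tab$eta - tab$sigma - 1e-9 &
                    tab$value <= tab$eta + tab$sigma + 1e-9))
})

test_that("the LP has the documented structure and variable counts", {
  # 1 region: 4 x, 4 z, bounds + subtype window + envelope; no equality
  prob1 <- oneRegionProblem(c(PV = 10, SST = 10, VIP = 10, GAD67 = 40),
                            c(PV = 1, SST = 1, VIP = 1, GAD67 = 4), 100)
  lp1 <- buildLP(prob1$est, prob1$nNeu, prob1$hierarchy, nNeuOwn = prob1$nNeuOwn)
  expect_equal(nDensityVariables(lp1), 4)
  expect_equal(ncol(lp1@mat), 8)                   # 4 x + 4 z
  expect_equal(sum(lp1@dir == "=="), 0)
  # rows: 4 bounds + 2 window + 8 envelope
  expect_equal(nrow(lp1@mat), 14)
  # 2-region (parent + child): hand-enumerated structure
  h2 <- RegionHierarchy(data.frame(id = 1:2, name = "x", acronym = c("r", "a"),
                                   parent_id = c(NA, 1)))
  est2 <- new("DensityEstimates", estimates = rbind(
    data.frame(region_id = 1L, type = .inhibTypes(), scope = "total", eta = 10,
               sigma = 1, value = 10, provenance = "literature"),
    data.frame(region_id = 2L, type = .inhibTypes(), scope = "total", eta = 5,
               sigma = 1, value = 5, provenance = "literature"),
    data.frame(region_id = 1L, type = .inhibTypes(), scope = "own", eta = 2,
               sigma = 1, value = 2, provenance = "fitted")))
  lp2 <- buildLP(est2, c("1" = 100, "2" = 60), h2, nNeuOwn = c("1" = 40, "2" = 60))
  expect_equal(nDensityVariables(lp2), 8)
  expect_equal(sum(lp2@vars$role == "x_own"), 4)
  expect_equal(sum(lp2@vars$role == "z_total"), 8)
  expect_equal(sum(lp2@dir == "=="), 4)            # one equality per type
  # hierarchy equality rows reference parent, child and own variables
  eqRows <- which(lp2@dir == "==")
  m <- as.matrix(lp2@mat[eqRows, , drop = FALSE])
  for (r in seq_along(eqRows)) {
    nz <- which(m[r, ] != 0)
    expect_setequal(unique(lp2@vars$role[nz]), c("x_total", "x_own"))
    expect_equal(sum(m[r, ]), -1)                  # +1 parent, -1 child, -1 own
  }
  expect_error(buildLP(est2, c("1" = 100), h2), "missing neuron counts")
})

test_that("solving recovers consistent estimates untouched and beats the pre-pass", {
  # eta already consistent -> x = eta, z = 0, objective 0
  h <- tinyHierarchy()
  nNeuOwn <- c("1" = 100, "2" = 100, "3" = 100, "4" = 100)
  nNeu <- aggregateToParents(nNeuOwn, h)
  ownEta <- list("1" = c(5, 5, 5, 20), "2" = c(4, 4, 4, 15),
                 "3" = c(6, 6, 6, 30), "4" = c(2, 2, 2, 10))
  rows <- list()
  for (id in 1:4) {
    tot <- Reduce(`+`, ownEta[as.character(subtreeIds(h, id))])
    rows[[length(rows) + 1]] <- data.frame(region_id = id, type = .inhibTypes(),
                                           scope = "total", eta = tot, sigma = pmax(tot, 1) * 0.1,
                                           value = tot, provenance = "literature")
    if (length(childrenOf(h, id)))
      rows[[length(rows) + 1]] <- data.frame(region_id = id, type = .inhibTypes(),
                                             scope = "own", eta = ownEta[[as.character(id)]],
                                             sigma = 1, value = ownEta[[as.character(id)]],
                                             provenance = "fitted")
  }
  est <- new("DensityEstimates", estimates = do.call(rbind, rows))
  sol <- solveLP(buildLP(est, nNeu, h, nNeuOwn = nNeuOwn))
  expect_equal(objectiveValue(sol), 0, tolerance = 1e-9)
  tot <- solutionTable(sol)
  tot <- tot[tot$scope == "total", ]
  expect_equal(tot$x, tot$eta, tolerance = 1e-7)
  expect_true(all(!tot$flagged))

  # on random problems the LP is feasible, beats the S2/S3 initial
  # solution and is idempotent
  for (s in c(11, 23, 35)) {
    prob <- randomToyProblem(s)
    lp <- buildLP(prob$est, prob$nNeu, prob$hierarchy, nNeuOwn = prob$nNeuOwn)
    sol <- solveLP(lp)
    init <- initialSolution(prob$est, prob$nNeuOwn, prob$hierarchy)
    expect_lte(objectiveValue(sol), init$objective + 1e-7)
    # idempotence: re-solving with eta <- x gives objective 0
    est2 <- estimatesTable(prob$est)
    st <- solutionTable(sol)
    m <- match(paste(est2$region_id, est2$type, est2$scope),
               paste(st$region_id, st$type, st$scope))
    est2$eta <- st$x[m]; est2$value <- est2$eta
    sol2 <- solveLP(buildLP(new("DensityEstimates", estimates = est2),
                            prob$nNeu, prob$hierarchy, nNeuOwn = prob$nNeuOwn))
    expect_equal(objectiveValue(sol2), 0, tolerance = 1e-6)
    st2 <- solutionTable(sol2)
    expect_equal(st2$x, st$x[match(paste(st2$region_id, st2$type, st2$scope),
                                   paste(st$region_id, st$type, st$scope))],
                 tolerance = 1e-5)
    # hierarchy conservation is exact (equality constraints)
    for (p in regionIds(prob$hierarchy)) {
      ch <- childrenOf(prob$hierarchy, p)
      if (!length(ch)) next
      for (tp in .inhibTypes()) {
        xt <- st$x[st$region_id == p & st$type == tp & st$scope == "total"]
        xo <- st$x[st$region_id == p & st$type == tp & st$scope == "own"]
        xc <- sum(st$x[st$region_id %in% ch & st$type == tp & st$scope == "total"])
        expect_equal(xt, xo + xc, tolerance = 1e-6)
      }
    }
  }
})

test_that("correction flags and residual populations follow the solved counts", {
  res <- standardResult()
  st <- solutionTable(res$solution)
  tot <- st[st$scope == "total", ]
  # flag definition re-checked brute force
  expect_equal(tot$flagged, abs(tot$x - tot$eta) > tot$sigma * (1 + 1e-9))
  fl <- flagCorrections(res$solution)
  expect_equal(fl$fractionRegionsFlagged,
               mean(tapply(tot$flagged, tot$region_id, any)))
  # residuals: nRest = GAD - (PV+SST+VIP) >= 0; balances hold exactly
  ctx <- standardContext()
  resid <- deriveResiduals(res$solution, ctx$nNeu)
  w <- reshape(tot[c("region_id", "type", "x")], idvar = "region_id",
               timevar = "type", direction = "wide")
  names(w) <- sub("^x\\.", "", names(w))
  m <- match(resid$region_id, w$region_id)
  expect_equal(resid$nRest, pmax(w$GAD67[m] - (w$PV[m] + w$SST[m] + w$VIP[m]), 0),
               tolerance = 1e-9)
  expect_equal(resid$nExcOther,
               pmax(unname(ctx$nNeu[as.character(resid$region_id)]) - w$GAD67[m], 0),
               tolerance = 1e-9)
  # conservation: types + residuals sum to nNeu
  expect_equal(w$PV[m] + w$SST[m] + w$VIP[m] + resid$nRest + resid$nExcOther,
               unname(ctx$nNeu[as.character(resid$region_id)]), tolerance = 1e-6)
  # hand cases
  expect_equal(100 - (30 + 20 + 10), 40)   # documented nRest identity
})

test_that("degenerate regions with no neurons are forced to zero", {
  prob <- oneRegionProblem(c(PV = 5, SST = 5, VIP = 5, GAD67 = 10),
                           c(PV = 1, SST = 1, VIP = 1, GAD67 = 1), 0)
  sol <- solveLP(buildLP(prob$est, prob$nNeu, prob$hierarchy,
                         nNeuOwn = prob$nNeuOwn))
  expect_true(all(abs(solutionTable(sol)$x) < 1e-9))
})
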