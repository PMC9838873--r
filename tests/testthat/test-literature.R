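flatHierarchy <- function(n = 5) {
  RegionHierarchy(data.frame(id = 1:n, name = paste0("n", 1:n),
                             acronym = c("rt", paste0("a", 2:n)),
                             parent_id = c(NA, rep(1, n - 1))))
}

rec <- function(region, marker = "PV", kind = "density", value = 100,
                std = NA, source = "s1") {
  data.frame(source_id = source, marker = marker, region_id = region,
             kind = kind, value = value, std = std, comment = "")
}

test_that("records convert to counts by the correct linear factors", {
  vols <- c("1" = 2, "2" = 0.5, "3" = 1)
  nNeu <- c("1" = 1e4, "2" = 5000)
  cells <- c("2" = 20000)
  r <- rbind(rec(2, kind = "density", value = 200, std = 40),
             rec(2, kind = "count", value = 317),
             rec(2, kind = "pct_neurons", value = 10, std = 2),
             rec(2, kind = "pct_cells", value = 10))
  out <- toCount(r, vols, neuronCounts = nNeu, cellCounts = cells)
  expect_equal(out$mean_count, c(100, 317, 500, 2000))
  expect_equal(out$std_count, c(20, NA, 100, NA))
  # round trip count -> density -> count via the same volume
  expect_equal(unname(out$mean_count[1] / vols["2"] * vols["2"]), out$mean_count[1])
  expect_error(toCount(rec(3, kind = "density"), c("3" = 0)), "zero-volume")
  expect_error(toCount(rec(3, kind = "pct_neurons", value = 5), vols,
                       neuronCounts = nNeu), "without neuron counts")
})

test_that("the 5x outlier rule excludes only globally conflicting sources", {
  mk <- function(means) data.frame(source_id = paste0("s", seq_along(means)),
                                   mean_count = means)
  # {100, 120, 700}: 700 is >= 5x both others
  out <- excludeOutliers(mk(c(100, 120, 700)))
  expect_equal(out$kept$mean_count, c(100, 120))
  expect_equal(out$excluded$mean_count, 700)
  # {100, 450}: ratio 4.5 < 5, nothing excluded
  out2 <- excludeOutliers(mk(c(100, 450)))
  expect_equal(nrow(out2$excluded), 0)
  # single record kept
  out3 <- excludeOutliers(mk(42))
  expect_equal(out3$kept$mean_count, 42)
  # low outlier
  out4 <- excludeOutliers(mk(c(10, 90, 100)))
  expect_equal(out4$excluded$mean_count, 10)
  # order independence
  out5 <- excludeOutliers(mk(c(700, 100, 120)))
  expect_setequal(out5$kept$mean_count, c(100, 120))
  # two-source region: never excluded unless ratio >= 5 (then both go --
  # each is 5x smaller/bigger than the other)
  out6 <- excludeOutliers(mk(c(100, 499)))
  expect_equal(nrow(out6$excluded), 0)
})

test_that("region aggregation averages means and available stds", {
  mk <- function(m, s) data.frame(mean_count = m, std_count = s)
  expect_equal(aggregateRegion(mk(100, 20)), c(eta = 100, sigma = 20))
  expect_equal(aggregateRegion(mk(c(100, 200), c(20, 40))), c(eta = 150, sigma = 30))
  # absent std: mean over the available ones
  expect_equal(aggregateRegion(mk(c(100, 200), c(20, NA))), c(eta = 150, sigma = 20))
  # no stds at all: sigma floor fraction of eta
  expect_equal(aggregateRegion(mk(c(100, 200), c(NA, NA))), c(eta = 150, sigma = 15))
  # permutation invariance and scale equivariance
  set.seed(8)
  m <- runif(5, 10, 100); s <- runif(5, 1, 10)
  a <- aggregateRegion(mk(m, s))
  expect_equal(aggregateRegion(mk(rev(m), rev(s))), a)
  expect_equal(aggregateRegion(mk(3 * m, 3 * s)), 3 * a)
})

test_that("the purely-inhibitory rule emits neuron-count GAD67 records", {
  h <- flatHierarchy()
  nNeu <- c("2" = 1000, "3" = 250)
  out <- purelyInhibitoryRecords(c(2, 3), nNeu, h)
  expect_equal(out$value, c(1000, 250))
  expect_true(all(out$marker == "GAD67"))
  expect_true(all(out$kind == "count"))
  expect_true(all(out$source_id == "purely-inhibitory-rule"))
  expect_equal(nrow(purelyInhibitoryRecords(integer(0), nNeu, h)), 0)
  expect_error(purelyInhibitoryRecords(99, nNeu, h), "unknown region")
})

test_that("aggregateLiterature combines conversion, exclusion and source drops", {
  h <- flatHierarchy()
  vols <- setNames(rep(1, 5), 1:5)
  r <- rbind(rec(2, value = 100, std = 10, source = "a"),
             rec(2, value = 120, std = 30, source = "b"),
             rec(2, value = 700, source = "c"),
             rec(3, value = 50, source = "a"))
  out <- aggregateLiterature(r, vols)
  e2 <- out$estimates[out$estimates$region_id == 2, ]
  expect_equal(e2$eta, 110)
  expect_equal(e2$sigma, 20)
  expect_equal(e2$n_sources, 2)
  expect_equal(out$excluded$source_id, "c")
  # whole-source drop removes the source everywhere
  out2 <- aggregateLiterature(r, vols, dropSources = "a")
  expect_false("a" %in% unlist(lapply(out2, `[[`, "source_id")))
  e3 <- out2$estimates[out2$estimates$region_id == 3, ]
  expect_equal(nrow(e3), 0)
})

test_that("coverage summary computes per-region CVs, medians and skewness", {
  h <- flatHierarchy(7)
  vols <- setNames(rep(1, 7), 1:7)
  # CVs {0.1, 0.2, 0.3}: median 0.2, skewness 0 by symmetry
  mkReg <- function(region, cv, n = 3) {
    m <- 100
    vals <- m + c(-1, 0, 1) * cv * m   # sample sd of c(-1,0,1) is 1
    do.call(rbind, lapply(seq_len(3), function(i)
      rec(region, value = vals[i], source = paste0("s", i))))
  }
  r <- rbind(mkReg(2, 0.1), mkReg(3, 0.2), mkReg(4, 0.3))
  out <- coverageSummary(r, h, vols)
  pv <- out$summary[out$summary$marker == "PV", ]
  expect_equal(pv$median_cv, 0.2, tolerance = 1e-10)
  expect_equal(pv$cv_skewness, 0, tolerance = 1e-10)
  expect_equal(pv$n_regions, 3)
  expect_equal(pv$n_sources, 3)
  expect_equal(pv$fraction_regions, 3 / 7)
  # CVs {0.1, 0.1, 0.7}: median 0.1, positive skewness (formula evaluation)
  r2 <- rbind(mkReg(2, 0.1), mkReg(3, 0.1), mkReg(4, 0.7))
  out2 <- coverageSummary(r2, h, vols)
  pv2 <- out2$summary[out2$summary$marker == "PV", ]
  expect_equal(pv2$median_cv, 0.1, tolerance = 1e-10)
  cvs <- c(0.1, 0.1, 0.7)
  expect_equal(pv2$cv_skewness, mean(((cvs - mean(cvs)) / sd(cvs))^3),
               tolerance = 1e-8)
  expect_gt(pv2$cv_skewness, 0)
  # fewer than 2 CVs: skewness undefined (flagged as NA)
  out3 <- coverageSummary(mkReg(2, 0.1), h, vols)
  expect_true(is.na(out3$summary$cv_skewness[out3$summary$marker == "PV"]))
  # property: any symmetric CV multiset has skewness ~ 0
  r4 <- rbind(mkReg(2, 0.05), mkReg(3, 0.15), mkReg(4, 0.25), mkReg(5, 0.35))
  out4 <- coverageSummary(r4, h, vols)
  expect_equal(out4$summary$cv_skewness[out4$summary$marker == "PV"], 0,
               tolerance = 1e-8)
})

test_that("literature CSV parsing resolves acronyms and validates fields", {
  h <- flatHierarchy()
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(source_id = "k1", marker = "SST", region = "a2",
                       kind = "density", value = 123.4, std = 5,
                       comment = "ok"), path, row.names = FALSE)
  out <- readLiteratureCSV(path, h)
  expect_equal(out$region_id, 2L)
  write.csv(data.frame(source_id = "k1", marker = "SST", region = "a2",
                       kind = "pct_neurons", value = 140), path, row.names = FALSE)
  expect_error(readLiteratureCSV(path, h), "0, 100")
  write.csv(data.frame(source_id = "k1", marker = "XYZ", region = "a2",
                       kind = "density", value = 1), path, row.names = FALSE)
  expect_error(readLiteratureCSV(path, h), "marker")
})
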