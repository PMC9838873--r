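## Validation experiments: literature subsampling (stability of the
## estimated densities as a function of the amount of literature) and
## hold-out prediction of literature values.

## draw a literature subset of fraction f that keeps every marker present
.drawSubset <- function(records, f, maxTries = 20L) {
  n <- nrow(records)
  for (t in seq_len(maxTries)) {
    idx <- sort(sample(n, max(round(f * n), 1L)))
    if (setequal(unique(records$marker[idx]), unique(records$marker)))
      return(list(idx = idx, resampled = t - 1L))
  }
  .fail("subsampling", "could not draw a subset keeping all markers after ",
        maxTries, " tries")
}

#' Literature-subsampling experiment
#'
#' Re-runs the fit-assemble-optimize pipeline with random literature
#' subsets of fraction f (several trials per fraction) and reports, per
#' region and type, the standard deviation of the solved densities across
#' trials (sigma(r, f)). As more literature is integrated the estimates
#' stabilize, so the mean sigma is expected to decrease with f. The
#' standard deviation at full coverage is extrapolated per region and
#' type by a least-squares line of sigma against f evaluated at f = 1,
#' floored at 0.
#'
#' @param context from [prepareContext()].
#' @param records full literature table.
#' @param fractions literature fractions (default 0.70 to 0.95).
#' @param trials trials per fraction (default 20).
#' @param seed integer seed.
#' @param purelyInhibitory,... passed to [fitAndSolve()].
#' @return list with `sigma` (data.frame region_id, type, fraction,
#'   sigma), `summary` (mean sigma per fraction), `extrapolated`
#'   (data.frame region_id, type, sigma100) and `resampled` (number of
#'   redrawn subsets).
#' @export
subsamplingExperiment <- function(context, records,
                                  fractions = seq(0.70, 0.95, by = 0.05),
                                  trials = 20L, seed = 1L,
                                  purelyInhibitory = integer(0), ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1), trials >= 2L)
  set.seed(stageSeed(seed, "subsampling"))
  vols <- context$volumes
  sigmaRows <- list(); resampled <- 0L
  densAt <- function(res) {
    tot <- res$densities
    setNames(tot$density, paste(tot$region_id, tot$type))
  }
  for (f in fractions) {
    draws <- matrix(NA_real_, nrow = 4L * nRegions(context$hierarchy),
                    ncol = trials)
    keyNames <- NULL
    for (tr in seq_len(trials)) {
      sub <- .drawSubset(records, f)
      resampled <- resampled + sub$resampled
      res <- fitAndSolve(context, records[sub$idx, , drop = FALSE],
                         purelyInhibitory = purelyInhibitory, ...)
      d <- densAt(res)
      if (is.null(keyNames)) keyNames <- names(d)
      draws[, tr] <- d[keyNames]
    }
    sds <- apply(draws, 1, sd)
    parts <- strsplit(keyNames, " ")
    sigmaRows[[as.character(f)]] <- data.frame(
      region_id = as.integer(vapply(parts, `[`, "", 1)),
      type = vapply(parts, `[`, "", 2),
      fraction = f, sigma = sds)
  }
  sig <- do.call(rbind, sigmaRows)
  summary <- aggregate(sigma ~ fraction, sig, mean)
  ## per-(region, type) linear extrapolation of sigma to f = 1
  keys <- unique(sig[c("region_id", "type")])
  sigma100 <- vapply(seq_len(nrow(keys)), function(i) {
    s <- sig[sig$region_id == keys$region_id[i] & sig$type == keys$type[i], ]
    if (length(unique(s$fraction)) < 2L) return(mean(s$sigma))
    fit <- lm(sigma ~ fraction, data = s)
    max(unname(predict(fit, data.frame(fraction = 1))), 0)
  }, numeric(1))
  list(sigma = sig, summary = summary,
       extrapolated = data.frame(keys, sigma100 = sigma100),
       resampled = resampled)
}

#' Hold-out prediction experiment
#'
#' Per trial, a random fraction of the literature records is held out, the
#' pipeline is run on the remainder, and the solved density of each
#' held-out record's (region, marker) is compared with the record: a
#' prediction is "within interval" when it falls inside the record's
#' mean +/- std (records without a reported std use
#' `sigmaFloorFraction * mean`).
#'
#' @param context from [prepareContext()].
#' @param records full literature table.
#' @param holdout held-out fraction in (0, 1) (default 0.1).
#' @param trials number of trials (default 5).
#' @param seed integer seed.
#' @param sigmaFloorFraction interval floor for records without std.
#' @param purelyInhibitory,... passed to [fitAndSolve()].
#' @return list with `records` (data.frame per held-out record: trial,
#'   region_id, marker, observed density, predicted density, within) and
#'   `fractionWithin`.
#' @export
holdoutExperiment <- function(context, records, holdout = 0.1, trials = 5L,
                              seed = 1L, sigmaFloorFraction = 0.1,
                              purelyInhibitory = integer(0), ...) {
  stopifnot(holdout > 0, holdout < 1)
  set.seed(stageSeed(seed, "holdout"))
  vols <- context$volumes
  conv <- toCount(records, vols, neuronCounts = context$nNeu)
  obsDens <- conv$mean_count / vols[as.character(conv$region_id)]
  obsStd <- ifelse(is.na(conv$std_count), sigmaFloorFraction * conv$mean_count,
                   conv$std_count) / vols[as.character(conv$region_id)]
  out <- list()
  for (tr in seq_len(trials)) {
    held <- sort(sample(nrow(records), max(round(holdout * nrow(records)), 1L)))
    kept <- setdiff(seq_len(nrow(records)), held)
    if (!setequal(unique(records$marker[kept]), unique(records$marker))) next
    res <- fitAndSolve(context, records[kept, , drop = FALSE],
                       purelyInhibitory = purelyInhibitory, ...)
    d <- res$densities
    pred <- d$density[match(paste(records$region_id[held], records$marker[held]),
                            paste(d$region_id, d$type))]
    out[[tr]] <- data.frame(trial = tr, region_id = records$region_id[held],
                            marker = records$marker[held],
                            observed = obsDens[held], predicted = pred,
                            within = abs(pred - obsDens[held]) <= obsStd[held])
  }
  recs <- do.call(rbind, out)
  list(records = recs, fractionWithin = mean(recs$within, na.rm = TRUE))
}
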