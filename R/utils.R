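#' Sum-preserving integer rounding (largest remainder)
#'
#' Rounds a non-negative numeric vector to integers whose sum equals
#' `round(sum(x))` (or an explicitly supplied `total`), by flooring every
#' entry and distributing the remaining units to the entries with the
#' largest fractional parts. Ties are broken by position, so the result is
#' deterministic.
#'
#' @param x non-negative numeric vector.
#' @param total integer total to preserve; defaults to `round(sum(x))`.
#' @return integer vector of the same length as `x` summing to `total`.
#' @examples
#' roundPreserveSum(c(1.4, 1.4, 1.2))  # sums to 4
#' @export
roundPreserveSum <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), is.finite(total), total >= 0)
  if (length(x) == 0L) return(integer(0))
  base <- floor(x)
  rem <- total - sum(base)
  if (rem < 0) {
    # total below the floors: take units from the smallest fractional parts
    ord <- order(x - base, seq_along(x))
    take <- ord[seq_len(min(-rem, sum(base[ord] > 0)))]
    base[take] <- pmax(base[take] - 1, 0)
    rem <- total - sum(base)
  }
  if (rem > 0) {
    ord <- order(-(x - base), seq_along(x))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' One master seed spawns per-stage sub-seeds so that stages are
#' independently reproducible. The stage name is folded into the seed with a
#' small deterministic string hash; results stay below 2^31.
#'
#' @param seed master seed (integer).
#' @param stage character stage name.
#' @return integer seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% .Machine$integer.max)
}

## internal: named numeric lookup with 0 default
.lookup0 <- function(map, keys) {
  out <- map[as.character(keys)]
  out[is.na(out)] <- 0
  unname(out)
}

## internal: stop with a stage-prefixed message
.fail <- function(stage, ...) stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)

## internal: population standard deviation
.popSd <- function(x) sqrt(mean((x - mean(x))^2))
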