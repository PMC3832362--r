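# Internal helpers: seeding, thresholding, apportionment.

#' Derive a reproducible per-item seed from a master seed
#'
#' Counter-based scheme: item `k` (and an optional `salt` distinguishing
#' independent random streams for the same item) maps to a fixed 31-bit seed,
#' so any single generated event is reproducible in isolation.
#'
#' @param master master seed (integer).
#' @param k item counter (0, 1, 2, ...).
#' @param salt stream discriminator.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, k, salt = 0) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 69069 %% m
  s <- (s + (as.numeric(k) %% m) * 40503) %% m
  s <- (s + (as.numeric(salt) %% m) * 2654435) %% m
  as.integer(s %% (m - 1))
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Between-class-variance-maximizing split of a numeric sample
#'
#' One-dimensional Otsu split on a fixed-bin histogram: the threshold
#' maximizes the between-class variance of the two resulting groups. Used to
#' calibrate bimodal intensity gates (DNA content, surface marker).
#'
#' @param x numeric vector.
#' @param nbins number of histogram bins.
#' @return list with `threshold` (numeric split point) and `strength`
#'   (between-class variance at the split divided by total variance, in
#'   `[0, 1]`; low values indicate the sample is not convincingly bimodal).
#' @export
otsu_split <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0)
    return(list(threshold = x[1], strength = 0))
  br <- seq(min(x), max(x), length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  i <- which.max(bcv)
  list(threshold = br[i + 1], strength = max(bcv) / stats::var(x) *
         length(x) / (length(x) - 1))
}

#' Largest-remainder apportionment of counts
#'
#' Splits `n` items over classes proportionally to `fractions`, assigning
#' floor counts first and distributing the remaining items by descending
#' fractional remainder (ties broken by class order). Deterministic.
#'
#' @param n total count.
#' @param fractions named numeric vector summing to 1 (within 1e-9).
#' @return named integer vector of per-class counts summing to `n`.
#' @export
apportion_counts <- function(n, fractions) {
  if (is.null(names(fractions)) || anyDuplicated(names(fractions)))
    stop("fractions must have unique names")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1 (got ", format(sum(fractions)), ")")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  quota <- n * fractions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
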