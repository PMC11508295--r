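# Internal helpers shared across modules.

#' Running mean with shrinking edge windows
#'
#' Smooths a numeric vector with a centred moving average of width `k`.
#' Near the vector ends the window is truncated to the available values,
#' so the output has the same length as the input and is bounded by the
#' input's range.
#'
#' @param x Numeric vector.
#' @param k Odd window width (number of values), `k >= 1`.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' running_mean(c(0, 3, 6, 3, 0), k = 3)
running_mean <- function(x, k = 21L) {
  stopifnot(is.numeric(x), length(k) == 1L, k >= 1L)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("`k` must be odd")
  n <- length(x)
  if (n == 0L || k == 1L) return(as.numeric(x))
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Least-squares non-increasing fit (pool-adjacent-violators)
#'
#' Fits the closest (in squared error) non-increasing sequence to `y`.
#' This is the workhorse behind the monotone distance-decay background
#' used in contact-peak calling: contact frequency is assumed to decay
#' with distance from the viewpoint, so on each side of the viewpoint the
#' background is the best monotone non-increasing approximation of the
#' observed profile.
#'
#' @param y Numeric vector ordered by increasing distance.
#' @param w Optional non-negative weights (defaults to equal weights).
#' @return Numeric vector of fitted values, non-increasing.
#' @export
#' @examples
#' pava_nonincreasing(c(5, 4, 6, 3))
pava_nonincreasing <- function(y, w = NULL) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w >= 0))
  # fit non-decreasing to the reversed vector, then reverse back
  yr <- rev(y)
  wr <- rev(w)
  means <- yr
  wts <- wr
  sizes <- rep(1L, n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    means[nb] <- yr[i]
    wts[nb] <- wr[i]
    sizes[nb] <- 1L
    while (nb > 1L && means[nb - 1L] > means[nb]) {
      wsum <- wts[nb - 1L] + wts[nb]
      m <- if (wsum > 0) (means[nb - 1L] * wts[nb - 1L] + means[nb] * wts[nb]) / wsum else
        (means[nb - 1L] + means[nb]) / 2
      means[nb - 1L] <- m
      wts[nb - 1L] <- wsum
      sizes[nb - 1L] <- sizes[nb - 1L] + sizes[nb]
      nb <- nb - 1L
    }
  }
  rev(rep(means[seq_len(nb)], times = sizes[seq_len(nb)]))
}

# Derive a reproducible 32-bit sub-seed from a base seed and a salt so that
# independent stages (genome, reads per replicate, assays) get decoupled
# streams while staying deterministic in the base seed.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (abs(as.numeric(seed)) * 48271 + sum(utf8ToInt(as.character(salt))) * 7919) %%
    2147483629
  as.integer(s + 1)
}

# 0-based half-open interval tibbles <-> IRanges (1-based closed)
tib_to_ir <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

ir_to_tib <- function(ir, chrom = NULL) {
  out <- tibble::tibble(
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir)
  )
  if (!is.null(chrom)) out <- tibble::add_column(out, chrom = chrom, .before = 1L)
  out
}

# overlap width in bp between two 0-based half-open intervals
interval_overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
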