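# Independent brute-force oracles and small shared fixtures.

# all motif start positions by direct character scan (1-based)
brute_find_sites <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  if (m == 0 || n < m) return(integer(0))
  which(vapply(seq_len(n - m + 1L),
               function(p) substr(sequence, p, p + m - 1L) == motif,
               logical(1)))
}

# least-squares non-increasing fit by exhaustive enumeration of consecutive
# block partitions (valid for short vectors): the monotone projection is
# piecewise constant on some partition with non-increasing block means.
brute_monotone_fit <- function(y) {
  n <- length(y)
  if (n == 1L) return(y)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(n - 1L) - 1L)) > 0)
    bounds <- c(0L, cuts, n)
    means <- vapply(seq_len(length(bounds) - 1L), function(b)
      mean(y[(bounds[b] + 1L):bounds[b + 1L]]), numeric(1))
    if (is.unsorted(rev(means))) next # block means must be non-increasing
    fit <- rep(means, times = diff(bounds))
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# a small, fast locus scenario for module-level tests
small_scenario <- function(seed = 1L, peaks = NULL,
                           reads_per_replicate = 1.5e5, ...) {
  locus_scenario(
    name = "toy", genome_length = 6e5, viewpoint_position = 3e5,
    planted_peaks = peaks, n_replicates = 3L,
    reads_per_replicate = reads_per_replicate, seed = seed, ...)
}

# random ACGT string
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand-rolled profile over one synthetic side grid, for direct peak-caller
# tests: `values` is the normalized signal per end (same for every
# replicate unless jitter is supplied)
toy_profile <- function(values_up, values_down, n_reps = 3, k = 1,
                        spacing = 1000) {
  n_up <- length(values_up); n_down <- length(values_down)
  vp_start <- (n_up + 1) * spacing
  vp_end <- vp_start + spacing
  viewpoint <- tibble::tibble(gene = "toy", chrom = "chrT",
                              start = vp_start, end = vp_end,
                              reading_primer = "ACGTCATG", primary = "CATG",
                              secondary = "GATC")
  pos <- c(seq_len(n_up) * spacing - spacing,
           vp_end + seq_len(n_down) * spacing)
  counts <- lapply(seq_len(n_reps), function(r) {
    tb <- tibble::tibble(
      chrom = "chrT", pos = pos,
      frag_index = seq_along(pos),
      frag_start = pos, frag_end = pos + spacing,
      side = "left",
      masked = FALSE,
      count = c(rev(values_up), values_down))
    attr(tb, "viewpoint") <- viewpoint
    tb
  })
  names(counts) <- paste0("rep", seq_len(n_reps))
  normalize_and_smooth(counts, k = k, viewpoint = viewpoint)
}
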