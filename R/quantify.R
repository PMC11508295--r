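# From raw 4C reads to normalized, smoothed per-fragment-end contact
# profiles. Mapping is exact fragment-end sequence matching against the
# unique fragment-end index: deterministic and faithful to fragment-end
# counting on error-free reads (support for real, error-containing FASTQ
# via an external aligner is out of scope).

read_fastq_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(as.character(Biostrings::readDNAStringSet(x, format = "fastq")))
  }
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x)) return(x)
  stop("reads must be a character vector, DNAStringSet, or FASTQ path")
}

#' Demultiplex reads by reading primer and trim to the captured sequence
#'
#' A read is assigned to the unique viewpoint whose reading primer is an
#' exact prefix. The captured sequence is everything from the primary-motif
#' occurrence at the primer's end onward, retaining the motif (the motif is
#' shared across the ligation junction, so the captured sequence aligns to
#' a fragment end starting with the motif). Reads matching no primer are
#' counted, not emitted.
#'
#' @param reads Character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a FASTQ file path.
#' @param viewpoints Tibble with columns `gene`, `reading_primer`,
#'   `primary` (motif); reading primers must be mutually non-prefix and
#'   terminate in the primary motif.
#' @return A list of class `demux_result`: `captured` (named list of
#'   character vectors per viewpoint), `assignment` (per-read viewpoint or
#'   `NA`), `stats` (tibble gene/n_assigned), `n_unassigned`.
#' @export
demultiplex_and_trim <- function(reads, viewpoints) {
  reads <- read_fastq_seqs(reads)
  vp <- tibble::as_tibble(viewpoints)
  stopifnot(all(c("gene", "reading_primer", "primary") %in% names(vp)))
  for (i in seq_len(nrow(vp))) {
    if (!endsWith(vp$reading_primer[i], vp$primary[i])) {
      stop("reading primer of ", vp$gene[i],
           " does not terminate in the primary motif")
    }
    for (j in seq_len(nrow(vp))) {
      if (i != j && startsWith(vp$reading_primer[i], vp$reading_primer[j])) {
        stop("reading primers of ", vp$gene[i], " and ", vp$gene[j],
             " are prefix-ambiguous")
      }
    }
  }
  assignment <- rep(NA_character_, length(reads))
  captured <- stats::setNames(vector("list", nrow(vp)), vp$gene)
  for (i in seq_len(nrow(vp))) {
    hit <- startsWith(reads, vp$reading_primer[i]) & is.na(assignment)
    assignment[hit] <- vp$gene[i]
    mlen <- nchar(vp$primary[i])
    plen <- nchar(vp$reading_primer[i])
    captured[[i]] <- substring(reads[hit], plen - mlen + 1L)
  }
  structure(list(
    captured = captured,
    assignment = assignment,
    stats = tibble::tibble(gene = vp$gene,
                           n_assigned = unname(vapply(captured, length,
                                                      integer(1)))),
    n_unassigned = sum(is.na(assignment))
  ), class = "demux_result")
}

#' Count captured sequences at unique, informative fragment ends
#'
#' A captured sequence increments the count of the fragment end whose
#' map sequence exactly equals its first `end_length` bases, provided that
#' end is unique and informative (its fragment carries the secondary
#' motif). Counts at the viewpoint fragment and its two immediate
#' neighbours are recorded but flagged `masked` (self-ligation territory).
#' Everything else — too-short captures, non-unique or blind ends,
#' trans-chromosomal matches — goes to the unmapped counter.
#'
#' @param captured Character vector of captured sequences (motif-leading).
#' @param map A [build_fragment_end_map()] result.
#' @param viewpoint One-row tibble as produced by [simulate_locus()]
#'   (needs `chrom`, `start`, `end` of the viewpoint fragment).
#' @return Tibble with one row per unique informative cis fragment end:
#'   `chrom`, `pos`, `frag_index`, `frag_start`, `frag_end`, `side`,
#'   `masked`, `count`; attribute `stats` holds mapped/unmapped totals.
#' @export
quantify_fragment_ends <- function(captured, map, viewpoint) {
  L <- attr(map, "end_length")
  vp <- tibble::as_tibble(viewpoint)
  grid <- map[map$chrom == vp$chrom & map$unique & map$has_secondary_site, ]
  grid <- dplyr::arrange(tibble::as_tibble(grid), .data$pos, .data$side)

  long_enough <- nchar(captured) >= L
  keys <- substr(captured[long_enough], 1L, L)
  idx <- match(keys, grid$seq)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(grid))
  unmapped <- sum(!long_enough) + sum(is.na(idx))

  vp_idx <- unique(map$frag_index[map$chrom == vp$chrom &
                                    map$frag_start == vp$start])
  if (length(vp_idx) != 1L) {
    stop("viewpoint interval does not coincide with a fragment of the map")
  }
  out <- tibble::tibble(
    chrom = grid$chrom, pos = grid$pos, frag_index = grid$frag_index,
    frag_start = grid$frag_start, frag_end = grid$frag_end,
    side = grid$side,
    end_id = sprintf("%07d_%s", grid$frag_index, grid$side),
    masked = grid$frag_index %in% (vp_idx + (-1:1)),
    count = counts
  )
  attr(out, "stats") <- tibble::tibble(mapped = sum(counts),
                                       unmapped = unmapped)
  attr(out, "viewpoint") <- vp
  out
}

#' Normalize to cis reads-per-million and smooth along fragment ends
#'
#' Per replicate, counts are scaled so that unmasked cis fragment ends sum
#' to one million (masked self-ligation ends are excluded from the
#' denominator but carried through, flagged, at the same scale), then a
#' running mean over `k` consecutive fragment ends is applied on each side
#' of the viewpoint independently, with shrinking windows at the
#' boundaries.
#'
#' @param counts Named list of per-replicate count tibbles from
#'   [quantify_fragment_ends()] (one element per replicate).
#' @param k Odd smoothing window in fragment ends (default 21).
#' @param viewpoint Optional one-row viewpoint tibble; defaults to the one
#'   recorded on the first count tibble.
#' @return A tibble of class `fourc_profile` with per-end, per-replicate
#'   rows: `chrom`, `pos`, `frag_index`, `frag_start`, `frag_end`, `side`
#'   (upstream/downstream of the viewpoint), `distance`, `masked`, `rep`,
#'   `raw`, `norm`, `smooth`. Attributes: `viewpoint`, `k`, `stats`.
#' @export
normalize_and_smooth <- function(counts, k = 21L, viewpoint = NULL) {
  if (is.data.frame(counts)) counts <- list(rep1 = counts)
  if (is.null(names(counts))) names(counts) <- paste0("rep", seq_along(counts))
  if (k < 1L || k %% 2L == 0L) stop("smoothing window `k` must be odd and >= 1")
  viewpoint <- viewpoint %||% attr(counts[[1L]], "viewpoint")
  if (is.null(viewpoint)) stop("supply `viewpoint`")
  vp_mid <- (viewpoint$start + viewpoint$end) / 2

  prof <- purrr::imap_dfr(counts, function(tb, rep_name) {
    tb <- tibble::as_tibble(tb)
    if (!"end_id" %in% names(tb)) {
      tb$end_id <- if (all(c("frag_index", "side") %in% names(tb))) {
        sprintf("%07d_%s", tb$frag_index, tb$side)
      } else sprintf("end%07d", seq_len(nrow(tb)))
    }
    denom <- sum(tb$count[!tb$masked])
    if (denom == 0) {
      stop("replicate ", rep_name, " has no mapped cis reads outside the viewpoint")
    }
    factor <- 1e6 / denom
    tb <- dplyr::mutate(
      tb,
      rep = rep_name,
      raw = .data$count,
      norm = .data$count * factor,
      vside = ifelse(.data$pos < vp_mid, "upstream", "downstream"),
      distance = abs(.data$pos - vp_mid)
    )
    tb <- dplyr::arrange(tb, .data$pos, .data$end_id)
    tb$smooth <- NA_real_
    for (s in c("upstream", "downstream")) {
      sel <- which(tb$vside == s & !tb$masked)
      if (length(sel) > 0) {
        ord <- sel[order(tb$distance[sel], tb$end_id[sel])]
        tb$smooth[ord] <- running_mean(tb$norm[ord], k)
      }
    }
    tb
  })
  prof <- dplyr::select(prof, "chrom", "pos", "frag_index", "frag_start",
                        "frag_end", end_side = "side", "end_id",
                        side = "vside", "distance", "masked",
                        "rep", "raw", "norm", "smooth")
  stats <- purrr::imap_dfr(counts, function(tb, nm) {
    s <- attr(tb, "stats") %||% tibble::tibble(mapped = sum(tb$count),
                                               unmapped = NA_integer_)
    tibble::add_column(s, rep = nm, .before = 1L)
  })
  structure(prof,
            class = c("fourc_profile", class(tibble::tibble())),
            viewpoint = tibble::as_tibble(viewpoint), k = as.integer(k),
            stats = stats)
}


#' @export
print.fourc_profile <- function(x, ...) {
  vp <- attr(x, "viewpoint")
  cat(sprintf("<fourc_profile> %s @ %s:[%g,%g), %d fragment ends x %d replicate(s), k = %d\n",
              vp$gene, vp$chrom, vp$start, vp$end,
              length(unique(x$pos)), length(unique(x$rep)), attr(x, "k")))
  NextMethod()
}

#' Quantify a simulated viewpoint into a contact profile
#'
#' Convenience wrapper running demultiplexing, fragment-end counting and
#' normalization/smoothing for every replicate of a [simulate_locus()]
#' result (or a named list of read vectors/FASTQ paths).
#'
#' @param sim A `locus_sim`, or a named list of per-replicate reads.
#' @param map Fragment-end map (defaults to `sim$map`).
#' @param viewpoint Viewpoint tibble (defaults to `sim$viewpoint`).
#' @param k Smoothing window (odd, default 21).
#' @param from_truth If `TRUE`, bypass the read path and build the profile
#'   from the generator's per-end truth counts (identical by construction
#'   on error-free synthetic reads; useful for simulation studies).
#' @return A `fourc_profile`.
#' @export
quantify_viewpoint <- function(sim, map = NULL, viewpoint = NULL, k = 21L,
                               from_truth = FALSE) {
  if (inherits(sim, "locus_sim")) {
    map <- map %||% sim$map
    viewpoint <- viewpoint %||% sim$viewpoint
    if (from_truth || is.null(sim$reads)) {
      return(profile_from_truth(sim, k = k))
    }
    reads <- sim$reads
  } else {
    reads <- sim
    if (is.null(map) || is.null(viewpoint)) stop("supply `map` and `viewpoint`")
  }
  counts <- purrr::map(reads, function(rd) {
    dm <- demultiplex_and_trim(rd, viewpoint)
    quantify_fragment_ends(dm$captured[[viewpoint$gene]], map, viewpoint)
  })
  normalize_and_smooth(counts, k = k, viewpoint = viewpoint)
}

# Build a profile directly from the generator's sampled per-end counts.
profile_from_truth <- function(sim, k = 21L) {
  ec <- sim$truth$end_counts
  rep_cols <- grep("^rep", names(ec), value = TRUE)
  map <- sim$map
  vp <- sim$viewpoint
  grid <- map[map$chrom == vp$chrom & map$unique & map$has_secondary_site, ]
  grid <- dplyr::arrange(tibble::as_tibble(grid), .data$pos, .data$side)
  vp_idx <- unique(map$frag_index[map$chrom == vp$chrom &
                                    map$frag_start == vp$start])
  counts <- purrr::map(rep_cols, function(rc) {
    m <- match(paste(grid$frag_index, grid$side),
               paste(ec$frag_index, ec$side))
    cnt <- ifelse(is.na(m), 0L, ec[[rc]][m])
    out <- tibble::tibble(
      chrom = grid$chrom, pos = grid$pos, frag_index = grid$frag_index,
      frag_start = grid$frag_start, frag_end = grid$frag_end,
      side = grid$side,
      masked = grid$frag_index %in% (vp_idx + (-1:1)),
      count = cnt
    )
    attr(out, "stats") <- tibble::tibble(mapped = sum(cnt), unmapped = 0L)
    attr(out, "viewpoint") <- vp
    out
  })
  names(counts) <- rep_cols
  normalize_and_smooth(counts, k = k, viewpoint = vp)
}
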