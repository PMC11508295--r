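# In-silico restriction digestion and the unique fragment-end index.
#
# 4C-seq counts reads at the ends of primary restriction fragments, so the
# quantification grid is the set of fragment-end sequences that occur exactly
# once in the genome and belong to fragments that also carry a secondary
# restriction site (fragments without one cannot circularise in the second
# digestion/ligation round and are "blind").

#' Restriction enzyme descriptor
#'
#' @param name Enzyme name, e.g. `"NlaIII"`.
#' @param motif Recognition motif (ACGT only, length >= 4). Common 4C enzymes:
#'   NlaIII `CATG`, DpnII `GATC`, Csp6I `GTAC`.
#' @return A list of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, motif) {
  motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("restriction motif must be at least 4 bp")
  if (grepl("[^ACGT]", motif)) stop("restriction motif may contain only A, C, G, T")
  structure(list(name = name, motif = motif), class = "restriction_enzyme")
}

# accept either an enzyme object or a known name
as_enzyme <- function(x) {
  if (inherits(x, "restriction_enzyme")) return(x)
  known <- c(NlaIII = "CATG", DpnII = "GATC", Csp6I = "GTAC")
  if (is.character(x) && length(x) == 1L && x %in% names(known)) {
    return(restriction_enzyme(x, known[[x]]))
  }
  stop("unknown restriction enzyme: supply a `restriction_enzyme()` or one of ",
       paste(names(known), collapse = ", "))
}

#' Find all motif occurrences in a sequence
#'
#' Returns the 1-based start positions of every (possibly overlapping)
#' occurrence of `motif` in `sequence`. `N` bases never match.
#'
#' @param sequence Character scalar or [Biostrings::DNAString] (A/C/G/T/N).
#' @param motif Character scalar, ACGT only, non-empty.
#' @return Sorted integer vector of 1-based start positions.
#' @export
#' @examples
#' find_sites("ACATGCATGT", "CATG")
find_sites <- function(sequence, motif) {
  if (!nzchar(motif)) stop("`motif` must be non-empty")
  if (grepl("[^ACGT]", motif)) stop("`motif` may contain only A, C, G, T")
  subj <- if (inherits(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  m <- Biostrings::matchPattern(motif, subj, fixed = TRUE)
  as.integer(IRanges::start(m))
}

#' In-silico digestion of a genome
#'
#' Splits every chromosome at each occurrence of the primary enzyme's motif.
#' The cut convention places each boundary at the motif start, so every
#' fragment except the first on a chromosome begins with the motif.
#' Fragments tile each chromosome exactly (0-based half-open coordinates).
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.
#' @param primary Primary restriction enzyme (object or name).
#' @return A tibble with columns `chrom`, `start`, `end`, `frag_index`
#'   (1-based ordinal along the chromosome).
#' @export
digest_genome <- function(genome, primary) {
  primary <- as_enzyme(primary)
  genome <- as_genome(genome)
  if (length(genome) == 0L || any(Biostrings::width(genome) == 0L)) {
    stop("genome must contain non-empty chromosomes")
  }
  purrr::map_dfr(names(genome), function(chr) {
    sites <- find_sites(genome[[chr]], primary$motif)
    len <- Biostrings::width(genome[chr])
    bounds <- unique(c(0L, sites - 1L, len))
    tibble::tibble(
      chrom = chr,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      frag_index = seq_len(length(bounds) - 1L)
    )
  })
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stop("genome chromosomes must be named")
    return(genome)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome chromosomes must be named")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a named DNAStringSet or character vector")
}

#' Build the unique fragment-end map
#'
#' For each primary fragment, extracts the inward-facing sequence of both
#' fragment ends. Both end sequences start with the primary motif: the left
#' end reads the first `end_length` bases of the fragment; the right end
#' reads the reverse complement of the window spanning the adjacent cut
#' site, mirroring how a read sequenced from the opposite strand crosses
#' the ligation junction (the palindromic motif is its own reverse
#' complement). Ends are flagged:
#'
#' * `has_secondary_site` — the fragment contains the secondary motif, so
#'   its ends are informative for 4C (non-blind);
#' * `unique` — the `end_length`-bp sequence occurs exactly once among all
#'   fragment-end sequences of the map and contains no `N`.
#'
#' @param fragments Fragment tibble from [digest_genome()].
#' @param genome The genome the fragments were derived from.
#' @param secondary Secondary restriction enzyme (object or name).
#' @param end_length Fragment-end sequence length in bp (default 36,
#'   minimum 16 — shorter sequences make uniqueness meaningless).
#' @param primary Primary enzyme (object or name); recorded in metadata and
#'   used for the right-end window.
#' @return A tibble of class `fragment_end_map` with one row per fragment
#'   end: `chrom`, `frag_index`, `side` ("left"/"right"), `pos` (bp of the
#'   cut-site boundary, 0-based), `frag_start`, `frag_end`, `seq`,
#'   `has_secondary_site`, `unique`. Attributes record the enzyme pair and
#'   `end_length`.
#' @export
build_fragment_end_map <- function(fragments, genome, secondary,
                                   end_length = 36L, primary = "NlaIII") {
  if (end_length < 16L) stop("`end_length` must be at least 16 bp")
  secondary <- as_enzyme(secondary)
  primary <- as_enzyme(primary)
  genome <- as_genome(genome)
  mlen <- nchar(primary$motif)

  ends <- purrr::map_dfr(split(fragments, fragments$chrom), function(fr) {
    chr <- fr$chrom[[1L]]
    seqchr <- genome[[chr]]
    len <- length(seqchr)
    frag_seqs <- Biostrings::extractAt(
      seqchr, IRanges::IRanges(start = fr$start + 1L, end = fr$end))
    has_sec <- Biostrings::vcountPattern(secondary$motif, frag_seqs, fixed = TRUE) > 0L

    # ends exist only at genuine primary cut sites (the motif is present at
    # the boundary), never at the two chromosome termini
    at_cut <- function(pos) {
      ok <- pos + mlen <= len & pos >= 0L
      ok[ok] <- as.character(Biostrings::extractAt(
        seqchr, IRanges::IRanges(pos[ok] + 1L, pos[ok] + mlen))) ==
        primary$motif
      ok
    }
    # left end: [start, start + L)
    left_ok <- fr$start + end_length <= len & at_cut(fr$start)
    left <- tibble::tibble(
      chrom = chr, frag_index = fr$frag_index, side = "left",
      pos = fr$start, frag_start = fr$start, frag_end = fr$end,
      win_start = fr$start, win_end = fr$start + end_length,
      revcomp = FALSE, has_secondary_site = has_sec, keep = left_ok
    )
    # right end: revcomp of [end - (L - mlen), end + mlen)
    right_ok <- (fr$end - (end_length - mlen) >= 0L) & (fr$end + mlen <= len) &
      at_cut(fr$end)
    right <- tibble::tibble(
      chrom = chr, frag_index = fr$frag_index, side = "right",
      pos = fr$end, frag_start = fr$start, frag_end = fr$end,
      win_start = fr$end - (end_length - mlen), win_end = fr$end + mlen,
      revcomp = TRUE, has_secondary_site = has_sec, keep = right_ok
    )
    out <- dplyr::bind_rows(left, right)
    out <- out[out$keep, , drop = FALSE]
    wins <- Biostrings::extractAt(
      seqchr, IRanges::IRanges(start = out$win_start + 1L, end = out$win_end))
    wins[out$revcomp] <- Biostrings::reverseComplement(wins[out$revcomp])
    out$seq <- as.character(wins)
    out
  })

  ends <- dplyr::arrange(ends, .data$chrom, .data$pos, .data$side)
  dup <- duplicated(ends$seq) | duplicated(ends$seq, fromLast = TRUE)
  ends$unique <- !dup & !grepl("N", ends$seq, fixed = TRUE)
  ends <- dplyr::select(ends, -"win_start", -"win_end", -"revcomp", -"keep")

  structure(
    tibble::as_tibble(ends),
    class = c("fragment_end_map", class(tibble::tibble())),
    primary = primary, secondary = secondary, end_length = as.integer(end_length),
    cut_convention = "boundary at motif start; motif retained at fragment start"
  )
}

#' @export
print.fragment_end_map <- function(x, ...) {
  pr <- attr(x, "primary"); se <- attr(x, "secondary")
  cat(sprintf(
    "<fragment_end_map> %s/%s, end length %d bp: %d ends (%d unique, %d informative)\n",
    pr$name, se$name, attr(x, "end_length"), nrow(x), sum(x$unique),
    sum(x$has_secondary_site)))
  NextMethod()
}
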