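# Epigenomic delineation of putative enhancers inside contact peaks, TAD
# assignment, reciprocal confirmation, the mutual-interaction matrix, and
# the final active-enhancer classification.
#
# A putative enhancer (PutE) is the section of a contact peak where the
# chromatin is open (ATAC and/or DNase) and carries the H3K27ac active
# enhancer mark. A PutE whose own (reciprocal) viewpoint shows a contact
# peak over the original promoter is a confirmed R-PutE, and an R-PutE
# driving at least a two-fold reporter activity is an active enhancer.

as_track <- function(x) {
  tb <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(tb)))
  tb
}

# merged IRanges per chromosome from a 0-based half-open interval tibble
track_ranges <- function(tb, chrom) {
  tb <- tb[tb$chrom == chrom, , drop = FALSE]
  IRanges::reduce(tib_to_ir(tb))
}

#' Delineate putative enhancers within contact peaks
#'
#' Per peak, computes `peak intersect open-chromatin intersect H3K27ac`,
#' where open chromatin is the union (default) or intersection of the ATAC
#' and DNase tracks; merges resulting intervals closer than `merge_gap`;
#' drops intervals shorter than `min_len`; and numbers the PutEs by
#' genomic order.
#'
#' @param peaks A `contact_peaks` object or a tibble with `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `peak_id`, `gene`.
#' @param tracks An `epigenome_tracks` list, or any list with interval
#'   tibbles `atac`, `dnase`, `h3k27ac`.
#' @param min_len Minimum PutE length in bp (default 200).
#' @param merge_gap Merge distance in bp (default 500).
#' @param open_mode `"union"` (either assay marks chromatin open; default)
#'   or `"intersection"` (both required).
#' @return Tibble of PutEs: `pute`, `name`, `chrom`, `start`, `end`,
#'   `peak_id`, `gene`, `open_evidence` (`"atac"`, `"dnase"` or `"both"`).
#' @export
delineate_putes <- function(peaks, tracks, min_len = 200, merge_gap = 500,
                            open_mode = c("union", "intersection")) {
  open_mode <- match.arg(open_mode)
  pk <- if (inherits(peaks, "contact_peaks")) peaks$peaks else
    tibble::as_tibble(peaks)
  if (!"peak_id" %in% names(pk)) pk$peak_id <- paste0("peak", seq_len(nrow(pk)))
  if (!"gene" %in% names(pk)) pk$gene <- NA_character_
  atac <- as_track(tracks$atac); dnase <- as_track(tracks$dnase)
  k27 <- as_track(tracks$h3k27ac)

  out <- purrr::map_dfr(seq_len(nrow(pk)), function(i) {
    chrom <- pk$chrom[i]
    peak_ir <- IRanges::IRanges(pk$start[i] + 1L, pk$end[i])
    a <- track_ranges(atac, chrom)
    d <- track_ranges(dnase, chrom)
    open <- if (open_mode == "union") IRanges::reduce(c(a, d)) else
      IRanges::intersect(a, d)
    iv <- IRanges::intersect(IRanges::intersect(peak_ir, open),
                             track_ranges(k27, chrom))
    iv <- IRanges::reduce(iv, min.gapwidth = merge_gap + 1L)
    iv <- iv[IRanges::width(iv) >= min_len]
    if (length(iv) == 0L) return(tibble::tibble())
    tb <- ir_to_tib(iv, chrom = chrom)
    ov_a <- IRanges::overlapsAny(iv, a)
    ov_d <- IRanges::overlapsAny(iv, d)
    tb$open_evidence <- dplyr::case_when(ov_a & ov_d ~ "both",
                                         ov_a ~ "atac",
                                         TRUE ~ "dnase")
    tb$peak_id <- pk$peak_id[i]
    tb$gene <- pk$gene[i]
    tb
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(pute = integer(0), name = character(0),
                          chrom = character(0), start = numeric(0),
                          end = numeric(0), peak_id = character(0),
                          gene = character(0), open_evidence = character(0)))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$pute <- seq_len(nrow(out))
  out$name <- paste0("PutE", out$pute)
  dplyr::select(out, "pute", "name", "chrom", "start", "end", "peak_id",
                "gene", "open_evidence")
}

#' Assign genomic elements to TADs
#'
#' An element belongs to the TAD containing its midpoint (half-open rule:
#' a midpoint on a TAD start belongs to that TAD); elements outside all
#' TADs are `NA`. If an element named `"promoter"` is present, each other
#' element is additionally classified `intra-TAD` or `inter-TAD` relative
#' to it.
#'
#' @param elements Tibble with `name`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param tads Tibble of non-overlapping TAD intervals (`chrom`, `start`,
#'   `end`), or an `epigenome_tracks` list (its `tads` element is used).
#' @return The elements tibble with `midpoint`, `tad` (id or `NA`) and,
#'   when a promoter is present, `vs_promoter`.
#' @export
assign_tads <- function(elements, tads) {
  if (inherits(tads, "epigenome_tracks")) tads <- tads$tads
  tads <- dplyr::arrange(as_track(tads), .data$chrom, .data$start)
  ov <- dplyr::group_by(tads, .data$chrom)
  bad <- dplyr::summarise(ov, bad = any(.data$start[-1] < .data$end[-dplyr::n()]))
  if (any(bad$bad)) stop("TADs overlap within a chromosome")
  tads$tad <- paste0("TAD", seq_len(nrow(tads)))

  el <- tibble::as_tibble(elements)
  el$midpoint <- floor((el$start + el$end) / 2)
  el$tad <- purrr::map_chr(seq_len(nrow(el)), function(i) {
    hit <- tads$chrom == el$chrom[i] & tads$start <= el$midpoint[i] &
      el$midpoint[i] < tads$end
    if (any(hit)) tads$tad[which(hit)[1L]] else NA_character_
  })
  if ("promoter" %in% el$name) {
    ptad <- el$tad[el$name == "promoter"][1L]
    el$vs_promoter <- dplyr::case_when(
      el$name == "promoter" ~ "promoter",
      is.na(el$tad) | is.na(ptad) ~ "unassigned",
      el$tad == ptad ~ "intra-TAD",
      TRUE ~ "inter-TAD"
    )
  }
  el
}

#' Confirm a PutE's promoter interaction from its reciprocal viewpoint
#'
#' The interaction between a promoter and a PutE is confirmed when the
#' reciprocal 4C experiment — the PutE as viewpoint — yields a contact
#' peak overlapping the promoter region (reciprocal calls use the relaxed
#' parameter set: two replicates, alphaFDR 0.2).
#'
#' @param pute One-row PutE tibble (from [delineate_putes()]).
#' @param reciprocal_peaks `contact_peaks` called from the PutE viewpoint.
#' @param promoter_region `list(chrom=, start=, end=)` of the promoter.
#' @return The PutE row with `reciprocal_confirmed` (logical),
#'   `confirming_peak` (peak id or `NA`) and `rpute_name`.
#' @export
confirm_reciprocal <- function(pute, reciprocal_peaks, promoter_region) {
  pute <- tibble::as_tibble(pute)
  ov <- promoter_overlap(reciprocal_peaks, promoter_region)
  pute$reciprocal_confirmed <- ov$overlaps
  pute$confirming_peak <- if (ov$overlaps) ov$peaks$peak_id[1L] else NA_character_
  pute$rpute_name <- ifelse(pute$reciprocal_confirmed,
                            sub("^PutE", "R-PutE", pute$name), pute$name)
  pute
}

#' Mutual-interaction matrix over viewpoint elements
#'
#' Entry (i, j) is `TRUE` when viewpoint i has a contact peak overlapping
#' element j. A mutual interaction requires both directions, so the
#' reported pair list contains the unordered pairs with `(i, j)` and
#' `(j, i)` both `TRUE`.
#'
#' @param peak_sets Named list (one entry per element, possibly including
#'   the promoter) of `contact_peaks` objects or peak tibbles; an element
#'   with no reciprocal data may be an empty tibble.
#' @param elements Tibble `name`, `chrom`, `start`, `end` covering every
#'   name in `peak_sets`.
#' @return List of class `interaction_matrix`: `matrix` (logical, rows =
#'   viewpoints, columns = target elements) and `mutual` (tibble of
#'   unordered mutual pairs `a`, `b`).
#' @export
mutual_interactions <- function(peak_sets, elements) {
  el <- tibble::as_tibble(elements)
  stopifnot(all(names(peak_sets) %in% el$name))
  nm <- el$name
  M <- matrix(FALSE, nrow = length(nm), ncol = length(nm),
              dimnames = list(viewpoint = nm, target = nm))
  for (v in names(peak_sets)) {
    pk <- peak_sets[[v]]
    pk <- if (inherits(pk, "contact_peaks")) pk$peaks else tibble::as_tibble(pk)
    if (nrow(pk) == 0L) next
    for (j in seq_along(nm)) {
      if (nm[j] == v) next
      M[v, nm[j]] <- any(pk$chrom == el$chrom[j] &
                           interval_overlap_bp(pk$start, pk$end,
                                               el$start[j], el$end[j]) > 0)
    }
  }
  pairs <- which(M & t(M) & upper.tri(M), arr.ind = TRUE)
  mutual <- tibble::tibble(a = nm[pairs[, 1L]], b = nm[pairs[, 2L]])
  # only pairs where both directions were actually measured
  measured <- nm %in% names(peak_sets)
  keep <- measured[pairs[, 1L]] & measured[pairs[, 2L]]
  mutual <- mutual[keep, , drop = FALSE]
  structure(list(matrix = M, mutual = mutual), class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d viewpoint(s), %d mutual pair(s)\n",
              nrow(x$matrix), nrow(x$mutual)))
  if (nrow(x$mutual) > 0) print(x$mutual, ...)
  invisible(x)
}

#' Classify active enhancers from confirmation status and reporter activity
#'
#' An element is an active enhancer when its promoter interaction is
#' reciprocally confirmed and its reporter fold change is at least
#' two-fold (inclusive). Elements cloned as several fragments are active
#' if any fragment is active. Elements with two-fold activity but no
#' confirmed interaction are reported separately as active regions whose
#' interaction is unconfirmed — they cannot be considered enhancers of the
#' gene.
#'
#' @param rputes Tibble from [confirm_reciprocal()] rows (needs `name`,
#'   `reciprocal_confirmed`).
#' @param reporter_results Tibble from [luciferase_fold_change()] with an
#'   `element` column mapping constructs to PutE names (a construct named
#'   `"PutE7_A"` maps to element `"PutE7"` automatically if `element` is
#'   absent).
#' @param fold_threshold Activity threshold (default 2, inclusive).
#' @return Tibble: `name`, `reciprocal_confirmed`, `fold_change` (max over
#'   the element's constructs), `active`, `category` (one of
#'   `"active enhancer"`, `"confirmed, not active"`,
#'   `"active region, interaction unconfirmed"`, `"not active"`).
#' @export
classify_active_enhancers <- function(rputes, reporter_results,
                                      fold_threshold = 2) {
  rp <- tibble::as_tibble(rputes)
  rr <- tibble::as_tibble(reporter_results)
  if (!"element" %in% names(rr)) {
    rr$element <- sub("_[A-Za-z]$", "", rr$construct)
  }
  per_el <- dplyr::summarise(dplyr::group_by(rr, .data$element),
                             fold_change = max(.data$fold_change),
                             .groups = "drop")
  missing <- setdiff(rp$name[rp$reciprocal_confirmed], per_el$element)
  if (length(missing) > 0) {
    stop("no reporter result for confirmed element(s): ",
         paste(missing, collapse = ", "))
  }
  out <- dplyr::left_join(rp, per_el, by = c(name = "element"))
  out$active <- out$reciprocal_confirmed &
    !is.na(out$fold_change) & out$fold_change >= fold_threshold
  out$category <- dplyr::case_when(
    out$active ~ "active enhancer",
    out$reciprocal_confirmed ~ "confirmed, not active",
    !is.na(out$fold_change) & out$fold_change >= fold_threshold ~
      "active region, interaction unconfirmed",
    TRUE ~ "not active"
  )
  out
}
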