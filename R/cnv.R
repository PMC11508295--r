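# SNP-array CNV screen: deterministic run-length segmentation on logR
# thresholds with the at-least-10-probes artifact filter, breakpoint
# delimitation from the nearest unaffected flanking probes, control-cohort
# filtering, and the overlap report against enhancers, contact peaks and
# TAD boundaries.
#
# Probe positions are handled as printed on arrays (1-based), and interval
# sizes follow the plain end-minus-start arithmetic used when reporting
# CNV coordinates, so printed sizes can be verified directly.

#' CNV-calling parameters
#'
#' @param min_probes Minimum consecutive supporting probes (default 10;
#'   shorter runs are treated as artifacts and discarded).
#' @param del_logR_threshold logR below this calls a deletion (default
#'   -0.3).
#' @param dup_logR_threshold logR above this calls a duplication (default
#'   +0.25).
#' @param control_max_freq Maximum tolerated carrier frequency among
#'   controls before a call is filtered as benign (default 0).
#' @return List of class `cnv_params`.
#' @export
cnv_params <- function(min_probes = 10L, del_logR_threshold = -0.3,
                       dup_logR_threshold = 0.25, control_max_freq = 0) {
  if (min_probes < 2) stop("`min_probes` must be >= 2")
  if (!(del_logR_threshold < 0 && dup_logR_threshold > 0)) {
    stop("thresholds must satisfy del < 0 < dup")
  }
  structure(list(min_probes = as.integer(min_probes),
                 del_logR_threshold = del_logR_threshold,
                 dup_logR_threshold = dup_logR_threshold,
                 control_max_freq = control_max_freq),
            class = "cnv_params")
}

#' Size of a genomic interval in the printed-coordinate arithmetic
#'
#' Returns `end - start`, the arithmetic used when reporting CNV sizes
#' from printed breakpoint coordinates.
#'
#' @param start,end Numeric positions in bp, `end >= start`. Vectorized.
#' @return `end - start` in bp.
#' @export
#' @examples
#' interval_size(3797792, 3838896) # 41104
interval_size <- function(start, end) {
  if (any(end < start)) stop("`end` must be >= `start`")
  end - start
}

#' Call CNVs from SNP-array probes
#'
#' Maximal runs of consecutive probes whose logR is beyond the relevant
#' threshold, with at least `min_probes` probes, become calls. Each call
#' carries its minimal interval (first to last supporting probe), its
#' maximal interval (nearest unaffected probe on each side), the per-side
#' breakpoint delimitation (distance between the maximal and minimal
#' bound), and the flanking probe ids.
#'
#' @param probes Tibble with `id`, `chrom`, `pos` (1-based, sorted, unique
#'   per chromosome), `logR` and optionally `BAF` (carried, not used for
#'   calling).
#' @param params A [cnv_params()].
#' @return Tibble of class `cnv_calls`: `chrom`, `type`, `n_probes`,
#'   `min_start`, `min_end`, `max_start`, `max_end`, `size`,
#'   `delim_centromeric`, `delim_telomeric`, `flank_left_id`,
#'   `flank_right_id`, `control_frequency` (`NA` until
#'   [filter_controls()]), `probe_ids` (list column).
#' @export
call_cnvs <- function(probes, params = cnv_params()) {
  pr <- tibble::as_tibble(probes)
  stopifnot(all(c("id", "chrom", "pos", "logR") %in% names(pr)))
  calls <- purrr::map_dfr(split(pr, pr$chrom), function(p) {
    if (is.unsorted(p$pos, strictly = TRUE)) {
      stop("probes must be sorted by position and unique within a chromosome")
    }
    state <- ifelse(p$logR < params$del_logR_threshold, "deletion",
                    ifelse(p$logR > params$dup_logR_threshold, "duplication",
                           "normal"))
    r <- rle(state)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values != "normal" & r$lengths >= params$min_probes
    purrr::map_dfr(which(keep), function(i) {
      s <- run_start[i]; e <- run_end[i]
      left <- if (s > 1L) s - 1L else NA_integer_
      right <- if (e < nrow(p)) e + 1L else NA_integer_
      tibble::tibble(
        chrom = p$chrom[1L],
        type = r$values[i],
        n_probes = e - s + 1L,
        min_start = p$pos[s], min_end = p$pos[e],
        max_start = if (is.na(left)) NA_real_ else p$pos[left],
        max_end = if (is.na(right)) NA_real_ else p$pos[right],
        size = interval_size(p$pos[s], p$pos[e]),
        delim_centromeric = if (is.na(left)) NA_real_ else p$pos[s] - p$pos[left],
        delim_telomeric = if (is.na(right)) NA_real_ else p$pos[right] - p$pos[e],
        flank_left_id = if (is.na(left)) NA_character_ else p$id[left],
        flank_right_id = if (is.na(right)) NA_character_ else p$id[right],
        control_frequency = NA_real_,
        probe_ids = list(p$id[s:e])
      )
    })
  })
  if (nrow(calls) == 0L) {
    calls <- tibble::tibble(
      chrom = character(0), type = character(0), n_probes = integer(0),
      min_start = numeric(0), min_end = numeric(0), max_start = numeric(0),
      max_end = numeric(0), size = numeric(0),
      delim_centromeric = numeric(0), delim_telomeric = numeric(0),
      flank_left_id = character(0), flank_right_id = character(0),
      control_frequency = numeric(0), probe_ids = list())
  }
  structure(dplyr::arrange(calls, .data$chrom, .data$min_start),
            class = c("cnv_calls", class(tibble::tibble())),
            params = params)
}

#' Filter CNV calls against a control cohort database
#'
#' A call is removed when a control CNV of the same type reciprocally
#' overlaps it by at least `reciprocal` (default 50%) and has carrier
#' frequency above `control_max_freq`. Removed calls are recorded in the
#' `removed` attribute with the matching control locus.
#'
#' @param calls A [call_cnvs()] result.
#' @param db Control database tibble: `chrom`, `start`, `end`, `type`,
#'   `freq`.
#' @param params A [cnv_params()] (supplies `control_max_freq`).
#' @param reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return The retained calls, `control_frequency` filled for matched
#'   loci; attribute `removed` holds the filtered calls.
#' @export
filter_controls <- function(calls, db, params = attr(calls, "params"),
                            reciprocal = 0.5) {
  db <- tibble::as_tibble(db)
  params <- params %||% cnv_params()
  if (nrow(calls) == 0L || nrow(db) == 0L) {
    attr(calls, "removed") <- calls[0, ]
    return(calls)
  }
  hit_freq <- purrr::map_dbl(seq_len(nrow(calls)), function(i) {
    cand <- db[db$chrom == calls$chrom[i] & db$type == calls$type[i], ]
    if (nrow(cand) == 0L) return(NA_real_)
    ov <- interval_overlap_bp(calls$min_start[i], calls$min_end[i],
                              cand$start, cand$end)
    len_call <- calls$min_end[i] - calls$min_start[i]
    rec <- ov / pmax(len_call, 1) >= reciprocal &
      ov / pmax(cand$end - cand$start, 1) >= reciprocal
    if (any(rec)) max(cand$freq[rec]) else NA_real_
  })
  calls$control_frequency <- hit_freq
  drop <- !is.na(hit_freq) & hit_freq > params$control_max_freq
  removed <- calls[drop, ]
  out <- calls[!drop, ]
  attr(out, "removed") <- removed
  attr(out, "params") <- params
  out
}

#' Overlap report of CNV calls against pipeline elements
#'
#' Annotates each call with the element classes it overlaps (active
#' enhancers, PutEs, contact peaks, TAD boundaries) and the per-element
#' overlap in bp, and flags the two situations of interest: a call
#' overlapping a contact peak but no delineated PutE, and a call spanning
#' a TAD boundary.
#'
#' @param calls A [call_cnvs()]/[filter_controls()] result.
#' @param elements Named list of interval tibbles (any of
#'   `active_enhancers`, `putes`, `peaks`, each `chrom`/`start`/`end` with
#'   an optional `name`), plus optionally `tad_boundaries` (tibble
#'   `chrom`, `pos`).
#' @param build Optional genome build label; if the calls or any element
#'   tibble carries a `build` attribute, mismatches are an error.
#' @return Tibble: one row per call x overlapped element (`element_class`,
#'   `element`, `overlap_bp`), plus per-call flags `peak_not_pute` and
#'   `disrupts_tad_boundary`; calls with no overlap get one row with
#'   `element_class = NA`.
#' @export
overlap_report <- function(calls, elements, build = NULL) {
  builds <- c(build %||% attr(calls, "build"),
              unlist(lapply(elements, attr, "build")))
  if (length(unique(builds)) > 1L) {
    stop("genome build labels differ: ", paste(unique(builds), collapse = " vs "))
  }
  classes <- intersect(c("active_enhancers", "putes", "peaks"),
                       names(elements))
  bounds <- elements$tad_boundaries
  purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    cs <- calls$min_start[i]; ce <- calls$min_end[i]
    rows <- purrr::map_dfr(classes, function(cl) {
      el <- tibble::as_tibble(elements[[cl]])
      if (nrow(el) == 0L) return(tibble::tibble())
      ov <- interval_overlap_bp(cs, ce, el$start, el$end)
      hit <- el$chrom == calls$chrom[i] & ov > 0
      if (!any(hit)) return(tibble::tibble())
      tibble::tibble(
        element_class = cl,
        element = if ("name" %in% names(el)) el$name[hit] else
          paste0(cl, which(hit)),
        overlap_bp = ov[hit])
    })
    disrupts <- !is.null(bounds) &&
      any(bounds$chrom == calls$chrom[i] & bounds$pos > cs & bounds$pos < ce)
    if (nrow(rows) == 0L) {
      rows <- tibble::tibble(element_class = NA_character_,
                             element = NA_character_, overlap_bp = 0)
    }
    tibble::add_column(
      rows,
      chrom = calls$chrom[i], type = calls$type[i],
      call_start = cs, call_end = ce,
      peak_not_pute = "peaks" %in% rows$element_class &
        !"putes" %in% rows$element_class,
      disrupts_tad_boundary = disrupts,
      .before = 1L)
  })
}
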