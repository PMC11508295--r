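# Contact-peak calling against a monotone distance-decay background.
#
# Contact frequency in cis decays monotonically with distance from the
# viewpoint; regions that exceed that decay reproducibly across replicates
# are contact peaks. The caller keeps the parameter surface of the
# viewpoint peak-calling convention used in the field (alphaFDR, qWr, qWd)
# but defines its own transparent statistic: a monotone background fitted
# by pool-adjacent-violators per side, a reproducibility gate requiring
# every replicate to exceed qWd times the background, and a windowed
# binomial sign test on positive residuals, Benjamini-Hochberg adjusted
# across all tested ends.

#' Peak-calling parameters
#'
#' @param alpha_fdr FDR level in (0,1). 0.05 for promoter viewpoints with
#'   three replicates; 0.2 for reciprocal (PutE) viewpoints with two.
#' @param q_wr Dimensionless multiplier (>= 0) on the smoothing window
#'   giving the locality of the sign test.
#' @param q_wd Background-ratio threshold (>= 1) each replicate must exceed.
#' @param min_run Minimum consecutive significant fragment ends (default 3).
#' @param merge_gap Maximum non-significant ends bridged inside a peak
#'   (default 1).
#' @param max_span Analysis window around the viewpoint in bp (default
#'   1 Mb per side, the span over which 4C signal is informative).
#' @param use_raw Use normalized-unsmoothed instead of smoothed values.
#' @return List of class `peak_call_params`.
#' @export
peak_call_params <- function(alpha_fdr = 0.05, q_wr = 1, q_wd = 1.5,
                             min_run = 3L, merge_gap = 1L, max_span = 1e6,
                             use_raw = FALSE) {
  if (alpha_fdr <= 0 || alpha_fdr >= 1) stop("`alpha_fdr` must be in (0,1)")
  if (q_wd < 1) stop("`q_wd` must be >= 1")
  if (q_wr < 0) stop("`q_wr` must be >= 0")
  if (min_run < 1) stop("`min_run` must be >= 1")
  structure(list(alpha_fdr = alpha_fdr, q_wr = q_wr, q_wd = q_wd,
                 min_run = as.integer(min_run),
                 merge_gap = as.integer(merge_gap),
                 max_span = max_span, use_raw = isTRUE(use_raw)),
            class = "peak_call_params")
}

#' Fit the monotone distance-decay background of a contact profile
#'
#' On each side of the viewpoint independently, fits a monotonically
#' non-increasing function of distance to the replicate-mean smoothed
#' profile by pool-adjacent-violators, floored at a small positive
#' pseudo-mean (0.5 normalized units) to avoid division by zero. Sides
#' with fewer than 20 informative ends are skipped with a warning.
#'
#' @param profile A [normalize_and_smooth()] profile.
#' @param max_span Restrict the fit to ends within this distance (bp).
#' @param use_raw Fit the normalized-unsmoothed values instead.
#' @param floor Background floor in normalized units (default 0.5).
#' @return Tibble `side`, `pos`, `distance`, `mean_signal`, `background`;
#'   attribute `skipped_sides` lists any skipped side.
#' @export
fit_background <- function(profile, max_span = Inf, use_raw = FALSE,
                           floor = 0.5) {
  val <- if (use_raw) "norm" else "smooth"
  base <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(tibble::as_tibble(profile), !.data$masked,
                    .data$distance <= max_span),
      .data$side, .data$end_id, .data$pos, .data$distance),
    mean_signal = mean(.data[[val]]), .groups = "drop")
  skipped <- character(0)
  out <- purrr::map_dfr(c("upstream", "downstream"), function(s) {
    sb <- dplyr::arrange(base[base$side == s, ], .data$distance, .data$end_id)
    if (nrow(sb) < 20L) {
      if (nrow(sb) > 0L) skipped <<- c(skipped, s)
      return(sb[0, ])
    }
    sb$background <- pmax(pava_nonincreasing(sb$mean_signal), floor)
    sb
  })
  if (length(skipped) > 0) {
    warning("side(s) skipped (fewer than 20 informative ends): ",
            paste(skipped, collapse = ", "))
  }
  attr(out, "skipped_sides") <- skipped
  out
}

#' Call contact peaks from replicate 4C profiles
#'
#' A fragment end is significant when (i) in every replicate the profile
#' is at least `q_wd` times the monotone background, and (ii) its windowed
#' binomial sign statistic — the number of positive residuals over all
#' replicates within a window of `q_wr * k` ends — has a
#' Benjamini-Hochberg-adjusted p-value at or below `alpha_fdr`. Runs of at
#' least `min_run` significant ends (bridging up to `merge_gap`
#' non-significant ends) become peaks; a peak spans the fragment
#' boundaries of its outermost significant ends.
#'
#' @param profile A `fourc_profile` containing at least two replicates on
#'   a shared fragment-end grid.
#' @param params A [peak_call_params()].
#' @param gene Viewpoint label for the output (defaults to the profile's).
#' @return An object of class `contact_peaks`: list with `peaks` (tibble
#'   `chrom`, `start`, `end`, `gene`, `side`, `n_ends`, `mean_enrichment`,
#'   `min_q`, `peak_id`), `ends` (per-end test statistics), `params`,
#'   `viewpoint`.
#' @export
call_peaks <- function(profile, params = peak_call_params(), gene = NULL) {
  stopifnot(inherits(params, "peak_call_params"))
  vp <- attr(profile, "viewpoint")
  gene <- gene %||% vp$gene
  k <- attr(profile, "k") %||% 21L
  prof <- dplyr::filter(tibble::as_tibble(profile), !.data$masked,
                        .data$distance <= params$max_span)
  reps <- unique(prof$rep)
  if (length(reps) < 2L) stop("peak calling requires at least 2 replicates")
  val <- if (params$use_raw) "norm" else "smooth"

  grids <- split(prof$end_id, prof$rep)
  if (length(unique(lapply(grids, sort))) != 1L) {
    stop("replicates do not share the fragment-end grid")
  }

  bg <- fit_background(profile, max_span = params$max_span,
                       use_raw = params$use_raw)

  w <- max(3L, as.integer(round(params$q_wr * k)))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L

  ends <- purrr::map_dfr(c("upstream", "downstream"), function(s) {
    sb <- bg[bg$side == s, ]
    if (nrow(sb) == 0L) return(tibble::tibble())
    sb <- dplyr::arrange(sb, .data$distance, .data$end_id)
    n <- nrow(sb)
    # replicate x end matrices aligned to sb's order
    m <- matrix(NA_real_, nrow = length(reps), ncol = n)
    for (ri in seq_along(reps)) {
      pr <- prof[prof$rep == reps[ri] & prof$side == s, ]
      m[ri, ] <- pr[[val]][match(sb$end_id, pr$end_id)]
    }
    pos_resid <- sweep(m, 2L, sb$background, ">")
    cs <- c(0L, cumsum(colSums(pos_resid)))
    i <- seq_len(n)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, n)
    succ <- cs[hi + 1L] - cs[lo]
    trials <- (hi - lo + 1L) * length(reps)
    pval <- stats::pbinom(succ - 1L, trials, 0.5, lower.tail = FALSE)
    ratio_ok <- colSums(sweep(m, 2L, params$q_wd * sb$background, ">=")) ==
      length(reps)
    tibble::tibble(
      side = s, end_id = sb$end_id, pos = sb$pos, distance = sb$distance,
      mean_signal = sb$mean_signal, background = sb$background,
      enrichment = sb$mean_signal / sb$background,
      p = pval, ratio_ok = ratio_ok
    )
  })

  if (nrow(ends) == 0L) {
    return(new_contact_peaks(empty_peaks(), ends, params, vp, gene))
  }
  ends$q <- stats::p.adjust(ends$p, method = "BH")
  ends$significant <- ends$ratio_ok & ends$q <= params$alpha_fdr

  frag_iv <- dplyr::distinct(prof, .data$end_id, .keep_all = TRUE)
  peaks <- purrr::map_dfr(c("upstream", "downstream"), function(s) {
    se <- dplyr::arrange(ends[ends$side == s, ], .data$pos, .data$end_id)
    sig <- which(se$significant)
    if (length(sig) == 0L) return(tibble::tibble())
    grp <- cumsum(c(1L, diff(sig) > params$merge_gap + 1L))
    purrr::map_dfr(split(sig, grp), function(run) {
      if (length(run) < params$min_run) return(tibble::tibble())
      iv <- frag_iv[frag_iv$end_id %in% se$end_id[run], ]
      tibble::tibble(
        chrom = vp$chrom,
        start = min(iv$frag_start), end = max(iv$frag_end),
        gene = gene, side = s, n_ends = length(run),
        mean_enrichment = mean(se$enrichment[run]),
        min_q = min(se$q[run])
      )
    })
  })
  if (nrow(peaks) > 0L) {
    peaks <- dplyr::arrange(peaks, .data$start)
    peaks$peak_id <- paste0(gene, ":peak", seq_len(nrow(peaks)))
  } else {
    peaks <- empty_peaks()
  }
  new_contact_peaks(peaks, ends, params, vp, gene)
}

empty_peaks <- function() {
  tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                 gene = character(0), side = character(0),
                 n_ends = integer(0), mean_enrichment = numeric(0),
                 min_q = numeric(0), peak_id = character(0))
}

new_contact_peaks <- function(peaks, ends, params, viewpoint, gene) {
  structure(list(peaks = peaks, ends = ends, params = params,
                 viewpoint = viewpoint, gene = gene),
            class = "contact_peaks")
}

#' @export
print.contact_peaks <- function(x, ...) {
  cat(sprintf("<contact_peaks> %s: %d peak(s) (alphaFDR = %g, qWd = %g, qWr = %g)\n",
              x$gene, nrow(x$peaks), x$params$alpha_fdr, x$params$q_wd,
              x$params$q_wr))
  if (nrow(x$peaks) > 0) print(x$peaks, ...)
  invisible(x)
}

#' Does any contact peak overlap a region?
#'
#' Half-open interval intersection (>= 1 bp) on the same chromosome.
#'
#' @param peaks A `contact_peaks` object or a peaks tibble.
#' @param region `list(chrom=, start=, end=)` (0-based half-open), or a
#'   one-row data frame with those columns.
#' @return A list: `overlaps` (logical) and `peaks` (tibble of the
#'   overlapping peaks, with `overlap_bp`).
#' @export
promoter_overlap <- function(peaks, region) {
  pk <- if (inherits(peaks, "contact_peaks")) peaks$peaks else
    tibble::as_tibble(peaks)
  region <- as.list(tibble::as_tibble(region))
  hit <- pk$chrom == region$chrom &
    interval_overlap_bp(pk$start, pk$end, region$start, region$end) > 0
  ov <- pk[hit, ]
  if (nrow(ov) > 0) {
    ov$overlap_bp <- interval_overlap_bp(ov$start, ov$end,
                                         region$start, region$end)
  }
  list(overlaps = any(hit), peaks = ov)
}
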