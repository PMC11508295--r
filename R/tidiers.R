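# broom-style tidiers and ggplot2 autoplot methods for the pipeline's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a contact-peak set
#'
#' @param x A `contact_peaks` object.
#' @param ... Unused.
#' @return The peak tibble (one row per peak).
#' @method tidy contact_peaks
#' @export
tidy.contact_peaks <- function(x, ...) x$peaks

#' One-row summary of a contact-peak call
#'
#' @param x A `contact_peaks` object.
#' @param ... Unused.
#' @method glance contact_peaks
#' @export
glance.contact_peaks <- function(x, ...) {
  tibble::tibble(
    gene = x$gene,
    n_peaks = nrow(x$peaks),
    n_ends_tested = nrow(x$ends),
    n_ends_significant = sum(x$ends$significant %||% FALSE),
    alpha_fdr = x$params$alpha_fdr,
    q_wr = x$params$q_wr,
    q_wd = x$params$q_wd
  )
}

#' Tidy a 4C contact profile
#'
#' @param x A `fourc_profile`.
#' @param ... Unused.
#' @return The profile as a plain tibble.
#' @method tidy fourc_profile
#' @export
tidy.fourc_profile <- function(x, ...) tibble::as_tibble(x)

#' Per-replicate mapping summary of a contact profile
#'
#' @param x A `fourc_profile`.
#' @param ... Unused.
#' @method glance fourc_profile
#' @export
glance.fourc_profile <- function(x, ...) {
  st <- attr(x, "stats")
  vp <- attr(x, "viewpoint")
  tibble::add_column(st, gene = vp$gene, k = attr(x, "k"), .before = 1L)
}

#' Tidy a CNV call set
#'
#' @param x A `cnv_calls` tibble.
#' @param ... Unused.
#' @return The calls without the list column.
#' @method tidy cnv_calls
#' @export
tidy.cnv_calls <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"probe_ids")
}

#' One-row summary of a CNV screen
#'
#' @param x A `cnv_calls` tibble.
#' @param ... Unused.
#' @method glance cnv_calls
#' @export
glance.cnv_calls <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_calls = nrow(x),
    n_deletions = sum(x$type == "deletion"),
    n_duplications = sum(x$type == "duplication"),
    min_probes = p$min_probes %||% NA_integer_
  )
}

#' Tidy an enhancer screen
#'
#' @param x An `enhancer_screen`.
#' @param ... Unused.
#' @return The per-element classification tibble.
#' @method tidy enhancer_screen
#' @export
tidy.enhancer_screen <- function(x, ...) x$classification

#' One-row summary of an enhancer screen
#'
#' @param x An `enhancer_screen`.
#' @param ... Unused.
#' @method glance enhancer_screen
#' @export
glance.enhancer_screen <- function(x, ...) {
  tibble::tibble(
    gene = x$sim$scenario$name,
    n_contact_peaks = nrow(x$peaks$peaks),
    n_putes = nrow(x$putes),
    n_rputes = sum(x$rputes$reciprocal_confirmed),
    n_active_enhancers = nrow(x$active_enhancers),
    n_mutual_pairs = nrow(x$interactions$mutual)
  )
}

#' Plot a 4C contact profile with its monotone background
#'
#' Smoothed per-replicate tracks, the fitted distance-decay background,
#' and (optionally) called peaks.
#'
#' @param object A `fourc_profile`.
#' @param peaks Optional `contact_peaks` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fourc_profile
#' @export
autoplot.fourc_profile <- function(object, peaks = NULL, ...) {
  tb <- dplyr::filter(tibble::as_tibble(object), !.data$masked)
  bg <- fit_background(object)
  vp <- attr(object, "viewpoint")
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$pos / 1e3)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth, group = .data$rep,
                                    colour = .data$rep), alpha = 0.6) +
    ggplot2::geom_line(data = bg, ggplot2::aes(y = .data$background),
                       colour = "black", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = (vp$start + vp$end) / 2e3,
                        colour = "red", linetype = "dotted") +
    ggplot2::labs(x = "position (kb)", y = "normalized contacts (per Mio, smoothed)",
                  colour = "replicate",
                  title = paste0(vp$gene, " viewpoint contact profile"))
  if (!is.null(peaks)) {
    pk <- if (inherits(peaks, "contact_peaks")) peaks$peaks else peaks
    if (nrow(pk) > 0) {
      p <- p + ggplot2::annotate("rect", xmin = pk$start / 1e3,
                                 xmax = pk$end / 1e3, ymin = -Inf, ymax = Inf,
                                 alpha = 0.15, fill = "firebrick")
    }
  }
  p
}

#' Plot reporter fold changes with the two-fold activity threshold
#'
#' @param object A [luciferase_fold_change()] result.
#' @param fold_threshold Threshold line (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_reporter <- function(object, fold_threshold = 2, ...) {
  tb <- dplyr::mutate(tibble::as_tibble(object),
                      construct = stats::reorder(.data$construct,
                                                 -.data$fold_change))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$construct,
                                   y = .data$fold_change,
                                   fill = .data$active)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold_change - .data$sd,
                                        ymax = .data$fold_change + .data$sd),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = fold_threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fold change vs negative control") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot SNP-array logR with CNV calls
#'
#' @param object A `cnv_calls` tibble.
#' @param probes The probe tibble the calls were made from.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnv_calls
#' @export
autoplot.cnv_calls <- function(object, probes, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(probes),
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$logR)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "logR")
  if (nrow(object) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(object),
      ggplot2::aes(xmin = .data$min_start / 1e6, xmax = .data$min_end / 1e6,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.2, inherit.aes = FALSE)
  }
  p
}
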