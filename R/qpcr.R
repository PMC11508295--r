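# Relative expression from qPCR Ct values: housekeeping-geomean
# normalization and the 2^-ddCt method.

#' Relative expression by the delta-delta-Ct method
#'
#' Per replicate, the normalizer Ct is the arithmetic mean of the
#' housekeeping Cts — Ct is a log2 quantity, so this equals the geometric
#' mean of their linear abundances and is the numerically stabler way to
#' compute it. dCt is the target Ct minus the normalizer; ddCt subtracts
#' the reference sample's mean dCt; the per-replicate fold change is
#' 2^(-ddCt). The reported fold change per sample is the geometric mean
#' over replicates (so the reference sample is exactly 1), with the
#' standard deviation of the per-replicate fold changes.
#'
#' @param cts Tibble with `sample`, `target`, `replicate`, `ct`.
#' @param target Gene of interest label.
#' @param housekeeping Two (or more) housekeeping gene labels.
#' @param reference_sample Sample all fold changes are relative to.
#' @return Tibble: `sample`, `fold_change`, `sd`, `n_replicates`,
#'   `reference`.
#' @export
#' @examples
#' cts <- tidyr::expand_grid(sample = c("ref", "s1"), replicate = 1:3,
#'                           target = c("GOI", "HK1", "HK2"))
#' cts$ct <- ifelse(cts$target == "GOI",
#'                  ifelse(cts$sample == "s1", 27, 25), 20)
#' relative_expression(cts, "GOI", c("HK1", "HK2"), "ref")
relative_expression <- function(cts, target, housekeeping,
                                reference_sample) {
  tb <- tibble::as_tibble(cts)
  stopifnot(all(c("sample", "target", "replicate", "ct") %in% names(tb)))
  if (!reference_sample %in% tb$sample) {
    stop("reference sample `", reference_sample, "` not found")
  }
  have <- dplyr::summarise(
    dplyr::group_by(tb, .data$sample),
    ok = all(c(target, housekeeping) %in% .data$target), .groups = "drop")
  if (any(!have$ok)) {
    stop("missing target or housekeeping measurements for sample(s): ",
         paste(have$sample[!have$ok], collapse = ", "))
  }
  norm <- dplyr::summarise(
    dplyr::group_by(tb[tb$target %in% housekeeping, ],
                    .data$sample, .data$replicate),
    norm_ct = mean(.data$ct), .groups = "drop")
  dct <- dplyr::mutate(
    dplyr::left_join(tb[tb$target == target, ], norm,
                     by = c("sample", "replicate")),
    dct = .data$ct - .data$norm_ct)
  ref_dct <- mean(dct$dct[dct$sample == reference_sample])
  dct$ddct <- dct$dct - ref_dct
  dct$fc_rep <- 2^(-dct$ddct)
  out <- dplyr::summarise(
    dplyr::group_by(dct, .data$sample),
    fold_change = 2^(-mean(.data$ddct)),
    sd = stats::sd(.data$fc_rep),
    n_replicates = dplyr::n(),
    .groups = "drop")
  out$sd[is.na(out$sd)] <- 0
  out$reference <- reference_sample
  out
}
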