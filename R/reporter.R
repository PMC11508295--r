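# Dual-luciferase reporter scoring: normalized activities and fold
# changes versus the negative control, with the two-fold activity rule.

#' Fold change in normalized luciferase activity
#'
#' Per well, activity is firefly/renilla. Per (construct, experiment), the
#' normalized activity is the mean over that experiment's wells; it is
#' then divided by the same experiment's negative-control activity, so
#' between-experiment transfection efficiency cancels. The reported fold
#' change is the mean of these per-experiment ratios across independent
#' experiments, with the sample standard deviation; constructs at or above
#' `fold_threshold` (two-fold, inclusive) are flagged active.
#'
#' @param wells Tibble with columns `construct`, `experiment`, `firefly`,
#'   `renilla` (both luminescence readings > 0).
#' @param negative_control Name of the negative-control construct, present
#'   in every experiment.
#' @param fold_threshold Activity threshold (default 2).
#' @return Tibble: `construct`, `fold_change`, `sd`, `n_experiments`,
#'   `active`. Results from fewer than three experiments trigger a
#'   warning (not reportable by the three-experiment convention).
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   construct = rep(c("cand", "stuffer"), each = 3),
#'   experiment = rep(1:3, times = 2),
#'   firefly = c(400, 500, 600, 100, 100, 100),
#'   renilla = 100
#' )
#' luciferase_fold_change(wells, "stuffer")
luciferase_fold_change <- function(wells, negative_control = "stuffer",
                                   fold_threshold = 2) {
  wl <- tibble::as_tibble(wells)
  stopifnot(all(c("construct", "experiment", "firefly", "renilla") %in% names(wl)))
  if (any(wl$renilla <= 0)) stop("nonpositive renilla reading")
  if (any(wl$firefly <= 0)) stop("nonpositive firefly reading")
  if (!negative_control %in% wl$construct) {
    stop("negative control `", negative_control, "` not found")
  }
  act <- dplyr::summarise(
    dplyr::group_by(wl, .data$construct, .data$experiment),
    activity = mean(.data$firefly / .data$renilla), .groups = "drop")
  ctrl <- act[act$construct == negative_control, c("experiment", "activity")]
  missing_exp <- setdiff(unique(act$experiment), ctrl$experiment)
  if (length(missing_exp) > 0) {
    stop("negative control missing in experiment(s): ",
         paste(missing_exp, collapse = ", "))
  }
  ratios <- dplyr::mutate(
    dplyr::left_join(act, ctrl, by = "experiment",
                     suffix = c("", "_ctrl")),
    ratio = .data$activity / .data$activity_ctrl)
  out <- dplyr::summarise(
    dplyr::group_by(ratios, .data$construct),
    fold_change = mean(.data$ratio),
    sd = stats::sd(.data$ratio),
    n_experiments = dplyr::n(),
    .groups = "drop")
  out$sd[is.na(out$sd)] <- 0
  out$active <- out$fold_change >= fold_threshold
  if (any(out$n_experiments < 3)) {
    warning("construct(s) with fewer than 3 independent experiments: ",
            paste(out$construct[out$n_experiments < 3], collapse = ", "))
  }
  dplyr::arrange(out, dplyr::desc(.data$fold_change))
}
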