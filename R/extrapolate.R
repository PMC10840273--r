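#' Sampling frame for stratified extrapolation
#'
#' The validation design samples episodes from three admission strata —
#' admissions with at least one positive blood culture, admissions with
#' only negative cultures, and admissions without cultures. Each stratum's
#' confusion matrix is scaled from the sampled episode count up to the
#' stratum's episode count in the full surveillance period.
#'
#' @param group character vector of stratum names, e.g. \code{"pos_bcx"},
#'   \code{"neg_bcx"}, \code{"no_bcx"}.
#' @param n_sampled_episodes episodes sampled into the validation dataset
#'   per stratum (> 0).
#' @param n_target_episodes episodes in the full target population per
#'   stratum (>= sampled).
#' @return data.frame of class \code{group_sampling_frame}.
#' @export
group_sampling_frame <- function(group, n_sampled_episodes,
                                 n_target_episodes) {
  d <- data.frame(group = as.character(group),
                  n_sampled_episodes = as.numeric(n_sampled_episodes),
                  n_target_episodes = as.numeric(n_target_episodes),
                  stringsAsFactors = FALSE)
  if (any(d$n_sampled_episodes <= 0)) {
    stop("n_sampled_episodes must be > 0", call. = FALSE)
  }
  if (any(d$n_sampled_episodes > d$n_target_episodes)) {
    stop("n_sampled_episodes must not exceed n_target_episodes",
         call. = FALSE)
  }
  if (anyDuplicated(d$group)) stop("duplicate group names", call. = FALSE)
  class(d) <- c("group_sampling_frame", "data.frame")
  d
}

#' Extrapolate per-stratum confusion matrices to the target population
#'
#' Each cell of each stratum's matrix is multiplied by that stratum's
#' target/sampled episode ratio, then cells are summed across strata. The
#' extrapolated cells are real-valued — no rounding is applied before
#' derived metrics are computed.
#'
#' @param per_group_cms named list of \code{\link{confusion_matrix}}
#'   objects, names matching \code{frames$group}.
#' @param frames a \code{\link{group_sampling_frame}}.
#' @return a real-valued \code{\link{confusion_matrix}}.
#' @export
extrapolate_counts <- function(per_group_cms, frames) {
  missing_frames <- setdiff(names(per_group_cms), frames$group)
  if (length(missing_frames)) {
    stop("no sampling frame for group(s): ",
         paste(missing_frames, collapse = ", "), call. = FALSE)
  }
  cells <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (g in names(per_group_cms)) {
    cm <- per_group_cms[[g]]
    i <- match(g, frames$group)
    scale <- frames$n_target_episodes[i] / frames$n_sampled_episodes[i]
    cells <- cells + scale * c(cm$tp, cm$fp, cm$fn, cm$tn)
  }
  confusion_matrix(cells["tp"], cells["fp"], cells["fn"], cells["tn"])
}

metric_from_cells <- function(metric, TP, FP, FN, TN) {
  switch(metric,
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    ppv = TP / (TP + FP),
    npv = TN / (TN + FN),
    auroc = (TP / (TP + FN) + TN / (TN + FP)) / 2,
    kappa = {
      n <- TP + FP + FN + TN
      po <- (TP + TN) / n
      pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
      ifelse(abs(1 - pe) < .Machine$double.eps^0.5, NA_real_,
             (po - pe) / (1 - pe))
    },
    stop("unknown metric: ", metric, call. = FALSE))
}

#' Bootstrap percentile CI for an extrapolated performance metric
#'
#' Uncertainty in the extrapolated estimates is assessed by resampling
#' before extrapolating: in every replicate, each stratum's episodes are
#' resampled with replacement (at the stratum's sampled size), the
#' per-stratum confusion matrices are rebuilt, scaled to the target
#' population and summed, and the metric recomputed. The interval is the
#' empirical 2.5th/97.5th percentile band (for the default 95\% level)
#' over the replicates. Because episodes within a stratum are exchangeable
#' given their (predicted, reference) cell, the resample is drawn as a
#' multinomial over the four cells — identical in distribution to
#' resampling episode labels individually. Replicates where the metric is
#' undefined (a zero marginal) are dropped from the percentiles and their
#' fraction reported.
#'
#' @param labels_by_group named list (one entry per stratum) of
#'   data.frames with logical columns \code{pred} and \code{ref}, one row
#'   per sampled episode.
#' @param frames a \code{\link{group_sampling_frame}} covering the groups.
#' @param metric one of \code{"sensitivity"}, \code{"specificity"},
#'   \code{"ppv"}, \code{"npv"}, \code{"kappa"}, \code{"auroc"}.
#' @param reps number of bootstrap replicates (default 10000).
#' @param seed integer RNG seed; fixed seed gives identical intervals.
#' @param level confidence level.
#' @return a \code{metric_estimate} with \code{ci_method
#'   = "bootstrap_percentile"}; attribute \code{dropped_fraction} records
#'   the share of undefined replicates.
#' @export
bootstrap_extrapolated_ci <- function(labels_by_group, frames, metric,
                                      reps = 10000L, seed = 20240205L,
                                      level = 0.95) {
  stopifnot(reps >= 1)
  missing_frames <- setdiff(names(labels_by_group), frames$group)
  if (length(missing_frames)) {
    stop("no sampling frame for group(s): ",
         paste(missing_frames, collapse = ", "), call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  TP <- FP <- FN <- TN <- numeric(reps)
  point_cells <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (g in names(labels_by_group)) {
    d <- labels_by_group[[g]]
    n_g <- nrow(d)
    if (!n_g) next
    p_cells <- c(tp = sum(d$pred & d$ref), fp = sum(d$pred & !d$ref),
                 fn = sum(!d$pred & d$ref), tn = sum(!d$pred & !d$ref))
    i <- match(g, frames$group)
    scale <- frames$n_target_episodes[i] / frames$n_sampled_episodes[i]
    point_cells <- point_cells + scale * p_cells
    draws <- stats::rmultinom(reps, n_g, p_cells / n_g)
    TP <- TP + scale * draws[1L, ]
    FP <- FP + scale * draws[2L, ]
    FN <- FN + scale * draws[3L, ]
    TN <- TN + scale * draws[4L, ]
  }
  stat <- metric_from_cells(metric, TP, FP, FN, TN)
  ok <- is.finite(stat)
  dropped <- 1 - mean(ok)
  if (!any(ok)) {
    stop("metric '", metric, "' undefined in every bootstrap replicate",
         call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(stat[ok], c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  point <- metric_from_cells(metric, point_cells["tp"], point_cells["fp"],
                             point_cells["fn"], point_cells["tn"])
  est <- metric_estimate(metric, unname(point), qs[1L], qs[2L],
                         "bootstrap_percentile",
                         n = sum(vapply(labels_by_group, nrow, integer(1))))
  attr(est, "dropped_fraction") <- dropped
  est
}
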