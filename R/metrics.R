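#' Build a 2x2 confusion matrix from aligned label vectors
#'
#' @param predicted data.frame with \code{episode_id} and a logical
#'   \code{cvc_bsi} (or \code{ha}) column, or a named logical vector.
#' @param reference same shape as \code{predicted}; must cover exactly the
#'   same episode ids.
#' @param flag which logical column to compare when data.frames are given
#'   (default \code{"cvc_bsi"}).
#' @return object of class \code{confusion_matrix}: list with integer
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @export
build_confusion <- function(predicted, reference, flag = "cvc_bsi") {
  as_named <- function(x) {
    if (is.data.frame(x)) {
      stats::setNames(as.logical(x[[flag]]), x$episode_id)
    } else {
      x
    }
  }
  p <- as_named(predicted)
  r <- as_named(reference)
  if (length(p) != length(r) || !setequal(names(p), names(r))) {
    stop("predicted and reference labels do not cover the same episodes",
         call. = FALSE)
  }
  r <- r[names(p)]
  confusion_matrix(tp = sum(p & r), fp = sum(p & !r),
                   fn = sum(!p & r), tn = sum(!p & !r))
}

#' Construct a confusion matrix from its four cells
#'
#' Cells may be real-valued (extrapolated counts are fractional by
#' design); totals must be positive.
#'
#' @param tp,fp,fn,tn cell counts.
#' @return object of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(!is.finite(cells))) {
    stop("confusion matrix cells must be finite and non-negative",
         call. = FALSE)
  }
  if (sum(cells) <= 0) {
    stop("confusion matrix total must be positive", call. = FALSE)
  }
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("pos", "neg"),
                              reference = c("pos", "neg")))
  print(m)
  invisible(x)
}

metric_estimate <- function(metric_name, point, ci_low = NA_real_,
                            ci_high = NA_real_, ci_method = "none",
                            n = NA_real_) {
  structure(list(metric_name = metric_name, point = point,
                 ci_low = ci_low, ci_high = ci_high,
                 ci_method = ci_method, n = n),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  ci <- if (x$ci_method == "none") "" else
    sprintf(" (%.3f-%.3f, %s)", x$ci_low, x$ci_high, x$ci_method)
  cat(sprintf("%s: %.3f%s\n", x$metric_name, x$point, ci))
  invisible(x)
}

#' Sensitivity, specificity, PPV and NPV with Wilson score intervals
#'
#' Point estimates are the usual ratios — sensitivity tp/(tp+fn),
#' specificity tn/(tn+fp), PPV tp/(tp+fp), NPV tn/(tn+fn). With
#' \code{ci = TRUE} (and integer-valued cells) each estimate carries a
#' Wilson score interval on its own marginal. A zero marginal makes the
#' metric undefined: it is returned as NA with a warning, never silently
#' as 0.
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @param ci attach Wilson intervals (requires integer-valued cells).
#' @param level confidence level.
#' @return named list of \code{metric_estimate}s: \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}.
#' @examples
#' binary_metrics(confusion_matrix(44, 3, 7, 4272))
#' @export
binary_metrics <- function(cm, ci = TRUE, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  defs <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn))
  integral <- all(vapply(cm, function(v) isTRUE(all.equal(v, round(v))),
                         logical(1)))
  out <- lapply(names(defs), function(nm) {
    k <- defs[[nm]][1L]; n <- defs[[nm]][2L]
    if (n == 0) {
      warning("metric '", nm, "' undefined: zero marginal", call. = FALSE)
      return(metric_estimate(nm, NA_real_, n = 0))
    }
    if (ci && integral) {
      w <- wilson_ci(k, n, level)
      metric_estimate(nm, k / n, w[1L], w[2L], "wilson", n)
    } else {
      metric_estimate(nm, k / n, n = n)
    }
  })
  stats::setNames(out, names(defs))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval based on the asymptotic variance (no continuity
#' correction): centre \eqn{(p + z^2/2n)/(1 + z^2/n)} with half-width
#' \eqn{z\sqrt{p(1-p)/n + z^2/4n^2}/(1 + z^2/n)}.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (> 0).
#' @param level confidence level.
#' @return numeric vector \code{c(low, high)}, both within [0, 1].
#' @examples
#' wilson_ci(44, 51)  # 0.743 - 0.932
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("wilson_ci: n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("wilson_ci: successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # boundary cases are exact: the interval always contains p
  lo <- if (successes == 0) 0 else max(0, centre - half)
  hi <- if (successes == n) 1 else min(1, centre + half)
  c(lo, hi)
}

#' Cohen's kappa for a 2x2 confusion matrix
#'
#' Chance-corrected agreement: \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o} and marginal chance agreement \eqn{p_e}.
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @return kappa point estimate; NA with a warning when the marginals are
#'   degenerate (\eqn{p_e = 1}).
#' @examples
#' cohens_kappa(confusion_matrix(44, 3, 7, 4272))  # 0.897
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    warning("kappa undefined: chance agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' AUROC of a single-threshold binary classifier
#'
#' A fixed rule has one operating point; the area under its two-segment
#' ROC curve is the balanced accuracy (sensitivity + specificity)/2.
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @return AUROC point estimate.
#' @examples
#' auroc_binary(confusion_matrix(44, 3, 7, 4272))  # 0.931
#' @export
auroc_binary <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  (sens + spec) / 2
}
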