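#' @title Uncertainty evaluation
#' @description ROC/AUC, uncertainty-rejection curves with global or
#'   class-specific variance thresholds, variance-quantile
#'   out-of-distribution calibration, and Gaussian-kernel density summaries
#'   of uncertainty distributions.
#' @name uncertainty-eval
NULL

#' ROC curve and trapezoidal AUC
#'
#' Scores are the predicted probability of the positive class (`"A"`).
#' Thresholds are placed at every unique score; tied scores step
#' simultaneously (diagonal segments), so the trapezoidal AUC equals the
#' pairwise probability `P(s_pos > s_neg) + 0.5 P(s_pos = s_neg)`.
#'
#' @param scores numeric vector of class-A scores in `[0, 1]`.
#' @param labels vector of `"A"`/`"B"` truth labels; both classes required.
#' @param positive which label counts as positive (default `"A"`).
#' @return a `roc_curve`: list with `points`
#'   (`data.frame(threshold, fpr, tpr)`, starting at (0,0) and ending at
#'   (1,1)) and scalar `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "A") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("AUC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # step down through unique thresholds, ties stepping together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = c(Inf, s[last]),
                                     fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

# coerce diagnoses (list of slide_diagnosis or a diagnosis table) plus
# truth into the evaluation frame used by the rejection machinery
eval_frame <- function(diagnoses, truth) {
  df <- if (is.data.frame(diagnoses)) diagnoses else diagnosis_table(diagnoses)
  if (!is.null(names(truth))) {
    missing <- setdiff(df$slide_id, names(truth))
    if (length(missing) > 0)
      stop("truth labels missing for slide(s): ", paste(missing, collapse = ", "))
    df$truth <- unname(truth[df$slide_id])
  } else {
    stopifnot(length(truth) == nrow(df))
    df$truth <- truth
  }
  df$correct <- df$label == df$truth
  # deterministic tie-break on equal sigmas: slide_id order
  df[order(-df$sigma_slide, df$slide_id), , drop = FALSE]
}

metric_value <- function(df, metric) {
  if (metric == "accuracy") return(mean(df$correct))
  if (length(unique(df$truth)) < 2) return(NA_real_) # undefined, not interpolated
  roc_auc(df$mu_slide, df$truth)$auc
}

#' Uncertainty-rejection curve
#'
#' Recomputes a performance metric after discarding the most uncertain
#' slides (largest `sigma_slide`).
#'
#' In `"global"` mode, for each fraction `f` on the removal grid the
#' `floor(f * n)` slides with the largest variance are removed and the
#' metric is recomputed on the remainder. In `"class_specific"` mode,
#' separate variance thresholds are swept for slides predicted `"A"` and
#' `"B"` (candidate thresholds are all observed per-class variances); for
#' each achievable total removed fraction the best attainable metric over
#' threshold pairs is reported, together with the thresholds achieving it.
#' Fractions at which an AUC is undefined (one class left) are reported as
#' `NA` and flagged, never interpolated.
#'
#' @param diagnoses list of `slide_diagnosis` objects (or a
#'   [diagnosis_table()] data frame).
#' @param truth `"A"`/`"B"` truth labels, either named by `slide_id` or
#'   aligned with `diagnoses`.
#' @param metric `"accuracy"` or `"auc"`.
#' @param mode `"global"` or `"class_specific"`.
#' @param fractions removal grid for global mode; the default is
#'   percentiles 0, 2, ..., 30 then 35, ..., 50.
#' @return a `rejection_curve`: list with `mode`, `metric` and `points`
#'   (`data.frame` of `fraction_removed`, `metric_value`, `n_kept`,
#'   `defined`, plus `threshold` or `threshold_A`/`threshold_B`). The
#'   fraction-0 point always equals the unrejected metric.
#' @export
rejection_curve <- function(diagnoses, truth,
                            metric = c("accuracy", "auc"),
                            mode = c("global", "class_specific"),
                            fractions = c(seq(0, 0.30, by = 0.02),
                                          seq(0.35, 0.50, by = 0.05))) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  df <- eval_frame(diagnoses, truth)
  n <- nrow(df)
  if (n < 2) stop("need at least 2 diagnoses")
  pts <- if (mode == "global") {
    do.call(rbind, lapply(fractions, function(f) {
      k <- floor(f * n + 1e-9)
      kept <- if (k == 0) df else df[-seq_len(k), , drop = FALSE]
      m <- metric_value(kept, metric)
      data.frame(fraction_removed = f,
                 metric_value = m,
                 threshold = if (k == 0) Inf else df$sigma_slide[k],
                 n_kept = nrow(kept),
                 defined = !is.na(m))
    }))
  } else {
    rejection_class_specific(df, metric)
  }
  structure(list(mode = mode, metric = metric, points = pts),
            class = "rejection_curve")
}

# exhaustive 2-d sweep: remove the kA most-uncertain predicted-A slides and
# the kB most-uncertain predicted-B slides, for all (kA, kB); report the
# best metric at each achieved total fraction
rejection_class_specific <- function(df, metric) {
  n <- nrow(df)
  ia <- which(df$label == "A") # df already sorted by decreasing sigma
  ib <- which(df$label == "B")
  res <- list()
  for (kA in 0:length(ia)) {
    for (kB in 0:length(ib)) {
      drop_idx <- c(head(ia, kA), head(ib, kB))
      kept <- if (length(drop_idx) == 0) df else df[-drop_idx, , drop = FALSE]
      if (nrow(kept) == 0) next
      m <- metric_value(kept, metric)
      res[[length(res) + 1]] <- data.frame(
        fraction_removed = (kA + kB) / n, metric_value = m,
        threshold_A = if (kA == 0) Inf else df$sigma_slide[ia[kA]],
        threshold_B = if (kB == 0) Inf else df$sigma_slide[ib[kB]],
        n_kept = nrow(kept), defined = !is.na(m))
    }
  }
  res <- do.call(rbind, res)
  out <- lapply(split(res, res$fraction_removed), function(g) {
    if (all(is.na(g$metric_value))) return(g[1, , drop = FALSE])
    g[which.max(g$metric_value), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$fraction_removed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.rejection_curve <- function(x, ...) {
  cat(sprintf("rejection_curve (%s, %s): %d points, %s at 0%% removal = %.4f\n",
              x$mode, x$metric, nrow(x$points), x$metric,
              x$points$metric_value[x$points$fraction_removed == 0][1]))
  invisible(x)
}

#' Variance threshold keeping a fraction of in-distribution cases
#'
#' `t` is the inclusive (type-1) empirical `keep_fraction`-quantile of the
#' in-distribution variances; a case is rejected iff its variance exceeds
#' `t`. The inclusive quantile is used because slide-level sample sizes are
#' small.
#'
#' @param internal_sigmas non-empty numeric vector of in-distribution
#'   dropout variances.
#' @param keep_fraction fraction in `(0, 1)` of internal cases to keep.
#' @return the variance threshold `t`.
#' @export
ood_threshold <- function(internal_sigmas, keep_fraction = 0.9) {
  if (length(internal_sigmas) == 0) stop("internal_sigmas is empty")
  if (keep_fraction <= 0 || keep_fraction >= 1)
    stop("keep_fraction must be in (0, 1)")
  s <- sort(internal_sigmas)
  s[ceiling(keep_fraction * length(s))]
}

#' Out-of-distribution rejection report
#'
#' Calibrates the variance threshold on internal cases with
#' [ood_threshold()] and reports the rejected fractions of both groups.
#'
#' @param internal_sigmas,external_sigmas non-empty numeric vectors of
#'   dropout variances.
#' @param keep_fraction fraction of internal cases to keep.
#' @return an `ood_report`: list with `threshold`,
#'   `internal_rejected_fraction`, `ood_rejected_fraction`,
#'   `keep_fraction`.
#' @export
ood_report <- function(internal_sigmas, external_sigmas, keep_fraction = 0.9) {
  if (length(external_sigmas) == 0) stop("external_sigmas is empty")
  t <- ood_threshold(internal_sigmas, keep_fraction)
  structure(list(threshold = t,
                 internal_rejected_fraction = mean(internal_sigmas > t),
                 ood_rejected_fraction = mean(external_sigmas > t),
                 keep_fraction = keep_fraction),
            class = "ood_report")
}

#' @export
print.ood_report <- function(x, ...) {
  cat(sprintf("ood_report: t = %.4g (keep %.0f%% internal) -> internal rejected %.1f%%, OOD rejected %.1f%%\n",
              x$threshold, 100 * x$keep_fraction,
              100 * x$internal_rejected_fraction,
              100 * x$ood_rejected_fraction))
  invisible(x)
}

#' Gaussian-kernel density summary of uncertainty distributions
#'
#' Per-group kernel density estimates on a shared grid spanning
#' `[0, 1.1 * max(sigma)]`. Bandwidths follow Scott's rule
#' (`1.06 * sd * n^(-1/5)`), with a configurable floor for degenerate
#' groups (zero spread), which are flagged. Because variances are
#' non-negative, mass is reflected at zero so each density integrates to 1
#' over the grid.
#'
#' @param sigmas_by_group named list of non-empty numeric vectors.
#' @param n_grid number of grid points (default 512).
#' @param bw optional fixed bandwidth overriding Scott's rule.
#' @param bw_floor lower bound on the bandwidth (default `1e-4`).
#' @return a `density_summary`: list with `grid`, `density` (named list of
#'   vectors), `bandwidth` (named numeric), `floored` (named logical).
#' @export
uncertainty_density <- function(sigmas_by_group, n_grid = 512L, bw = NULL,
                                bw_floor = 1e-4) {
  stopifnot(is.list(sigmas_by_group), length(sigmas_by_group) > 0)
  if (any(vapply(sigmas_by_group, length, 0L) == 0))
    stop("every group must be non-empty")
  hi <- max(unlist(sigmas_by_group)) * 1.1
  if (hi <= 0) hi <- bw_floor * 10
  grid <- seq(0, hi, length.out = n_grid)
  out <- list(grid = grid, density = list(), bandwidth = numeric(0),
              floored = logical(0))
  for (g in names(sigmas_by_group)) {
    x <- sigmas_by_group[[g]]
    h <- if (!is.null(bw)) bw else 1.06 * sd(x) * length(x)^(-1 / 5)
    floored <- is.na(h) || h < bw_floor
    if (floored) h <- bw_floor
    # reflected Gaussian KDE evaluated on the shared grid
    d <- vapply(grid, function(v) {
      mean(stats::dnorm(v, x, h) + stats::dnorm(-v, x, h))
    }, 0)
    out$density[[g]] <- d
    out$bandwidth[g] <- h
    out$floored[g] <- floored
  }
  structure(out, class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("density_summary: %d group(s) on a %d-point grid [0, %.3g]\n",
              length(x$density), length(x$grid), max(x$grid)))
  for (g in names(x$density))
    cat(sprintf("  %s: bandwidth %.3g%s\n", g, x$bandwidth[g],
                if (x$floored[g]) " (floored)" else ""))
  invisible(x)
}

#' Split slide uncertainties by diagnostic correctness
#'
#' @param diagnoses list of `slide_diagnosis` objects (or a
#'   [diagnosis_table()] data frame).
#' @param truth `"A"`/`"B"` truth labels (named by slide_id, or aligned).
#' @return list with `correct` and `erroneous` vectors of `sigma_slide`,
#'   plus `by_class`: the same split restricted to slides predicted `"A"`
#'   and `"B"` respectively.
#' @export
correctness_split <- function(diagnoses, truth) {
  df <- eval_frame(diagnoses, truth)
  split_of <- function(d) list(correct = d$sigma_slide[d$correct],
                               erroneous = d$sigma_slide[!d$correct])
  c(split_of(df),
    list(by_class = list(A = split_of(df[df$label == "A", , drop = FALSE]),
                         B = split_of(df[df$label == "B", , drop = FALSE]))))
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
plot.rejection_curve <- function(x, ...) {
  ok <- x$points$defined
  graphics::plot(x$points$fraction_removed[ok], x$points$metric_value[ok],
                 type = "b", pch = 16,
                 xlab = "Fraction of most-uncertain slides removed",
                 ylab = x$metric,
                 main = sprintf("Uncertainty rejection (%s thresholds)",
                                gsub("_", "-", x$mode)), ...)
  invisible(x)
}

#' @export
plot.density_summary <- function(x, ...) {
  ymax <- max(unlist(x$density))
  graphics::plot(NA, xlim = range(x$grid), ylim = c(0, ymax),
                 xlab = "dropout variance", ylab = "density",
                 main = "Uncertainty distributions", ...)
  cols <- seq_along(x$density) + 1
  for (i in seq_along(x$density))
    graphics::lines(x$grid, x$density[[i]], col = cols[i], lwd = 2)
  graphics::legend("topright", names(x$density), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
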