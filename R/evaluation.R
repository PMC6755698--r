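#' Pooled (micro-averaged) precision and recall at one threshold
#'
#' A pair (instance, label) is predicted positive iff its probability is
#' `>= t` (boundary inclusive). True/false positives and false negatives
#' are summed over all labels jointly (micro-averaging):
#' `precision = sum(tp) / (sum(tp) + sum(fp))`,
#' `recall = sum(tp) / (sum(tp) + sum(fn))`. When nothing is predicted
#' positive, precision is defined as 1.
#'
#' @param pred an [hmc_predictions()].
#' @param truth an [hmc_dataset()] aligned with `pred` (same instances;
#'   labels of `pred` must be hierarchy labels of `truth`).
#' @param t threshold in [0, 1].
#' @return named numeric vector `c(precision, recall)`.
#' @export
pooled_pr_at_threshold <- function(pred, truth, t) {
  tm <- truth_matrix_for(pred, truth)
  pos <- pred$values >= t
  tp <- sum(pos & tm == 1)
  fp <- sum(pos & tm == 0)
  fn <- sum(!pos & tm == 1)
  c(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
    recall = tp / (tp + fn))
}

truth_matrix_for <- function(pred, truth) {
  if (!setequal(pred$instance_ids, truth$ids))
    stop("prediction/truth instance ids are misaligned")
  bad <- setdiff(pred$label_order, truth$hierarchy$labels)
  if (length(bad))
    stop("prediction labels unknown to the truth hierarchy: ",
         paste(bad, collapse = ", "))
  Y <- label_matrix(truth)[pred$instance_ids, , drop = FALSE]
  Y[, pred$label_order, drop = FALSE]
}

#' Pooled precision-recall curve and its area
#'
#' Sweeps a threshold grid (0 to 1 in steps of 0.02 by default), computes
#' pooled precision/recall at each threshold, and integrates precision over
#' recall by the trapezoid rule. Grid points at which nothing is predicted
#' positive are reported in the curve (with the precision := 1 convention)
#' but excluded from the integral; the curve is anchored at
#' (recall = 0, precision of the smallest-recall retained point).
#'
#' @inheritParams pooled_pr_at_threshold
#' @param grid increasing numeric vector of thresholds.
#' @return an object of class `pooled_pr_curve`: list with `thresholds`,
#'   `points` (data.frame threshold/precision/recall), and `auprc`.
#' @export
pooled_auprc <- function(pred, truth, grid = seq(0, 1, by = 0.02)) {
  tm <- truth_matrix_for(pred, truth)
  if (sum(tm) == 0)
    stop("truth contains no positive pair; the PR curve is undefined")
  v <- as.vector(pred$values)
  z <- as.vector(tm) == 1
  n_pos <- sum(z)
  tp <- vapply(grid, function(t) sum(z & v >= t), 0)
  pp <- vapply(grid, function(t) sum(v >= t), 0)
  precision <- ifelse(pp == 0, 1, tp / pp)
  recall <- tp / n_pos
  points <- data.frame(threshold = grid, precision = precision,
                       recall = recall)
  keep <- points[pp > 0, , drop = FALSE]
  keep <- keep[order(keep$recall, -keep$precision), , drop = FALSE]
  r <- c(0, keep$recall)
  p <- c(keep$precision[1L], keep$precision)
  auprc <- sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
  structure(list(thresholds = grid, points = points, auprc = auprc),
            class = "pooled_pr_curve")
}

#' @export
print.pooled_pr_curve <- function(x, ...) {
  cat(sprintf("pooled PR curve: %d thresholds, AUPRC = %.4f\n",
              length(x$thresholds), x$auprc))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Cross-version change pairs

new_change_pair_partition <- function(label_intersection, added, removed,
                                      unchanged_neg, unchanged_pos) {
  structure(list(label_intersection = label_intersection, added = added,
                 removed = removed, unchanged_neg = unchanged_neg,
                 unchanged_pos = unchanged_pos),
            class = "change_pair_partition")
}

#' @export
print.change_pair_partition <- function(x, ...) {
  cat(sprintf(paste0("change_pair_partition: %d labels in intersection; ",
                     "added %d, removed %d, unchanged-neg %d, ",
                     "unchanged-pos %d pairs\n"),
              length(x$label_intersection), nrow(x$added), nrow(x$removed),
              nrow(x$unchanged_neg), nrow(x$unchanged_pos)))
  invisible(x)
}

#' Partition (instance, label) pairs across two dataset versions
#'
#' Restricted to the intersection of the two label sets (labels appearing
#' in only one version are not considered), every (instance, label) pair is
#' assigned to exactly one of four groups by its (old, new) membership:
#' (0,1) added, (1,0) removed, (0,0) unchanged-negative, (1,1)
#' unchanged-positive. The four groups together cover
#' `n_instances * |label_intersection|` pairs.
#'
#' @param old_test,new_test two [hmc_dataset()]s over the same instance
#'   ids (typically test splits of the old and new dataset versions).
#' @return a `change_pair_partition` with `label_intersection` and four
#'   data.frames (`instance_id`, `label`).
#' @export
identify_changed_pairs <- function(old_test, new_test) {
  sym <- c(setdiff(old_test$ids, new_test$ids),
           setdiff(new_test$ids, old_test$ids))
  if (length(sym))
    stop("instance-id mismatch between versions: ",
         paste(sym, collapse = ", "))
  inter <- intersect(old_test$hierarchy$labels, new_test$hierarchy$labels)
  ids <- old_test$ids
  O <- label_matrix(old_test)[ids, inter, drop = FALSE]
  N <- label_matrix(new_test)[ids, inter, drop = FALSE]
  code <- O * 2 + N     # 0 neg/neg, 1 added, 2 removed, 3 pos/pos
  pair_frame <- function(idx) {
    data.frame(instance_id = ids[idx[, 1L]], label = inter[idx[, 2L]],
               stringsAsFactors = FALSE)
  }
  grp <- function(k) pair_frame(which(code == k, arr.ind = TRUE))
  new_change_pair_partition(label_intersection = inter,
                            added = grp(1), removed = grp(2),
                            unchanged_neg = grp(0), unchanged_pos = grp(3))
}

pair_values <- function(pred, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  i <- match(pairs$instance_id, pred$instance_ids)
  j <- match(pairs$label, pred$label_order)
  if (anyNA(i) || anyNA(j))
    stop("predictions do not cover all pairs of the partition")
  pred$values[cbind(i, j)]
}

#' Five-number summaries of predictions per change group
#'
#' For each of the four pair groups, the number of pairs and the
#' median/quartiles/whiskers (boxplot statistics; whiskers extend to the
#' most extreme values within 1.5 IQR of the box) of the prediction
#' probabilities. Empty groups report `n = 0` and `NA` summaries.
#'
#' @param pred an [hmc_predictions()] covering all pairs.
#' @param part a `change_pair_partition`.
#' @return data.frame with one row per group: `group`, `n`,
#'   `whisker_low`, `q1`, `median`, `q3`, `whisker_high`.
#' @export
group_summary <- function(pred, part) {
  groups <- c("added", "removed", "unchanged_neg", "unchanged_pos")
  rows <- lapply(groups, function(g) {
    v <- pair_values(pred, part[[g]])
    if (length(v) == 0L)
      return(data.frame(group = g, n = 0L, whisker_low = NA_real_,
                        q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                        whisker_high = NA_real_))
    bs <- grDevices::boxplot.stats(v, do.conf = FALSE, do.out = FALSE)$stats
    data.frame(group = g, n = length(v), whisker_low = bs[1L], q1 = bs[2L],
               median = bs[3L], q3 = bs[4L], whisker_high = bs[5L])
  })
  do.call(rbind, rows)
}

#' Median prediction difference between changed and unchanged pairs
#'
#' The change-detection statistic: for `direction = "added"`,
#' `median(added) - median(unchanged_neg)`; for `direction = "removed"`,
#' `median(unchanged_pos) - median(removed)`. Both are signed so that
#' larger values mean better detection of the change.
#'
#' @inheritParams group_summary
#' @param direction `"added"` or `"removed"`.
#' @return a single number.
#' @export
median_difference <- function(pred, part,
                              direction = c("added", "removed")) {
  direction <- match.arg(direction)
  need <- if (direction == "added") c("added", "unchanged_neg")
          else c("unchanged_pos", "removed")
  v1 <- pair_values(pred, part[[need[1L]]])
  v2 <- pair_values(pred, part[[need[2L]]])
  if (length(v1) == 0L || length(v2) == 0L)
    stop("group '", need[which(c(length(v1), length(v2)) == 0L)[1L]],
         "' is empty; the median difference is undefined")
  stats::median(v1) - stats::median(v2)
}

## ---------------------------------------------------------------------------
## Friedman-Nemenyi method comparison

#' Friedman test with Nemenyi post-hoc critical distance
#'
#' Methods are ranked within each dataset (higher score is better, rank 1;
#' ties get average ranks). The Friedman chi-square statistic uses the
#' tie-corrected (Conover) form with k-1 degrees of freedom; the Nemenyi
#' critical distance is `q_alpha * sqrt(k (k + 1) / (6 N))` with `q_alpha`
#' the studentized-range quantile divided by sqrt(2). Method pairs whose
#' average ranks differ by more than the critical distance are flagged
#' significantly different.
#'
#' @param scores numeric matrix, methods x datasets; row names identify
#'   methods. No missing entries are allowed (exclude a dataset rather
#'   than imputing).
#' @param alpha significance level for the critical distance.
#' @return list with `avg_ranks` (named, smaller is better),
#'   `friedman_stat`, `p_value`, `critical_distance`,
#'   `significant_pairs` (data.frame `method1`, `method2`, `rank_diff`),
#'   `alpha`, `k`, `n_datasets`.
#' @export
friedman_nemenyi <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  k <- nrow(scores); N <- ncol(scores)
  if (k < 2L || N < 2L)
    stop("need at least 2 methods and 2 datasets")
  if (anyNA(scores))
    stop("missing scores are not allowed; drop the affected dataset")
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("method%d", seq_len(k))
  ranks <- apply(scores, 2L, function(s) rank(-s, ties.method = "average"))
  avg <- rowMeans(ranks)
  Rj <- rowSums(ranks)
  A1 <- sum(ranks^2)
  C1 <- N * k * (k + 1)^2 / 4
  stat <- if (A1 - C1 <= .Machine$double.eps) 0
          else (k - 1) * sum((Rj - N * (k + 1) / 2)^2) / (A1 - C1)
  p_value <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  q_alpha <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
  cd <- q_alpha * sqrt(k * (k + 1) / (6 * N))
  pairs <- utils::combn(rownames(scores), 2L)
  diffs <- abs(avg[pairs[1L, ]] - avg[pairs[2L, ]])
  sig <- data.frame(method1 = pairs[1L, ], method2 = pairs[2L, ],
                    rank_diff = unname(diffs),
                    stringsAsFactors = FALSE)[diffs > cd, , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(avg_ranks = avg, friedman_stat = stat, p_value = p_value,
                 critical_distance = cd, significant_pairs = sig,
                 alpha = alpha, k = k, n_datasets = N),
            class = "friedman_nemenyi")
}

#' @export
print.friedman_nemenyi <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.3f (df = %d), p = %.4g\n",
              x$friedman_stat, x$k - 1L, x$p_value))
  cat(sprintf("Nemenyi critical distance (alpha = %g): %.3f\n",
              x$alpha, x$critical_distance))
  print(sort(x$avg_ranks))
  if (nrow(x$significant_pairs))
    print(x$significant_pairs)
  else cat("no significantly different pairs\n")
  invisible(x)
}

#' Critical-difference diagram
#'
#' Plots average ranks on a horizontal axis with a bar of length equal to
#' the Nemenyi critical distance; methods connected by a bar are not
#' statistically significantly different.
#'
#' @param x a [friedman_nemenyi()] result.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.friedman_nemenyi <- function(x, ...) {
  r <- sort(x$avg_ranks)
  k <- length(r)
  graphics::plot(NA, xlim = c(1, k), ylim = c(0, k + 1), yaxt = "n",
                 xlab = "average rank", ylab = "", bty = "n", ...)
  graphics::axis(1)
  for (i in seq_len(k)) {
    graphics::points(r[i], k + 1 - i, pch = 19)
    graphics::text(r[i], k + 1 - i, names(r)[i], pos = 4, cex = 0.9)
  }
  graphics::segments(r[1L], 0.5, r[1L] + x$critical_distance, 0.5, lwd = 3)
  graphics::text(r[1L] + x$critical_distance / 2, 0.5,
                 sprintf("CD = %.2f", x$critical_distance), pos = 3,
                 cex = 0.8)
  invisible(x)
}

#' Box plot of prediction distributions per change group
#'
#' Mirrors the cross-version evaluation figures: one box per pair group,
#' drawn from the five-number summaries of [group_summary()], with group
#' sizes in parentheses.
#'
#' @param summary_df output of [group_summary()].
#' @param main plot title.
#' @export
plot_change_groups <- function(summary_df, main = "") {
  s <- summary_df[summary_df$n > 0L, , drop = FALSE]
  stats_m <- t(as.matrix(s[, c("whisker_low", "q1", "median", "q3",
                               "whisker_high")]))
  bx <- list(stats = stats_m, n = s$n, conf = NULL, out = numeric(0),
             names = sprintf("%s (%d)", s$group, s$n))
  graphics::bxp(bx, main = main, ylab = "prediction probability",
                las = 2)
  invisible(summary_df)
}

#' Aggregate prediction matrices from stochastic runs
#'
#' Element-wise mean and sample standard deviation over aligned runs, as
#' used to report stochastic methods as the mean of several runs.
#'
#' @param runs list of aligned [hmc_predictions()] (same ids and labels).
#' @return list with `mean` (an [hmc_predictions()]) and `sd` (numeric
#'   matrix; `NA` when only one run is supplied).
#' @export
aggregate_stochastic_runs <- function(runs) {
  if (length(runs) < 1L) stop("need at least one run")
  ref <- runs[[1L]]
  for (r in runs)
    if (!identical(r$instance_ids, ref$instance_ids) ||
        !identical(r$label_order, ref$label_order))
      stop("runs are misaligned (ids or label order differ)")
  arr <- simplify2array(lapply(runs, `[[`, "values"))
  m <- apply(arr, c(1L, 2L), mean)
  s <- if (length(runs) == 1L) {
    matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  } else apply(arr, c(1L, 2L), stats::sd)
  list(mean = hmc_predictions(ref$instance_ids, ref$label_order, m),
       sd = s)
}
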