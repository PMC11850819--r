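# Evaluation: accuracy/precision/recall/F1, ROC/AUC, alpha-beta grid
# sweeps, and pooling-strategy comparisons.

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean of precision and recall. Zero-denominator entries are
#' returned as `NA` and listed in `undefined` rather than coerced to 0.
#'
#' @param confusion A `confusion_counts` object (or list with TP/FP/TN/FN).
#' @return Object of class `metric_set` with fields `acc`, `precision`,
#'   `recall`, `f1`, `undefined`.
#' @export
classification_metrics <- function(confusion) {
  TP <- confusion$TP; FP <- confusion$FP
  TN <- confusion$TN; FN <- confusion$FN
  total <- TP + FP + TN + FN
  if (total == 0) {
    stop("empty-evaluation error: all confusion counts are zero", call. = FALSE)
  }
  undefined <- character()
  acc <- (TP + TN) / total
  precision <- if (TP + FP == 0) {
    undefined <- c(undefined, "precision"); NA_real_
  } else TP / (TP + FP)
  recall <- if (TP + FN == 0) {
    undefined <- c(undefined, "recall"); NA_real_
  } else TP / (TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(
    list(acc = acc, precision = precision, recall = recall, f1 = f1,
         undefined = undefined),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf("Acc=%s P=%s R=%s F1=%s\n",
              fmt(x$acc), fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  invisible(x)
}

#' Pooled bag-level score
#'
#' Collapses a scored bag to one continuous score for ROC analysis. The
#' decision rule itself is binary, so a continuous proxy is needed to sweep
#' thresholds; the default is the mean instance score, with the max and the
#' depressive-count fraction as alternatives.
#'
#' @param scored A `scored_bag`.
#' @param method `"mean"`, `"max"` or `"count_fraction"` (fraction of
#'   instances above `cutoff`).
#' @param cutoff Cutoff for `"count_fraction"`.
#' @return A single score in \[0, 1\].
#' @export
bag_score <- function(scored, method = c("mean", "max", "count_fraction"),
                      cutoff = 0.5) {
  method <- match.arg(method)
  s <- scored$scores$score
  switch(method,
         mean = mean(s),
         max = max(s),
         count_fraction = mean(s > cutoff))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique observed scores (equal scores grouped
#' into one step), points from (0,0) to (1,1), AUC by the trapezoid rule.
#'
#' @param scores Numeric vector of bag-level scores.
#' @param labels Binary gold labels aligned with `scores` (both classes
#'   must be present).
#' @return Object of class `roc_curve`: `points` (data frame with
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("class-coverage error: both classes must be present", call. = FALSE)
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 0) / n_neg,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thresholds),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<ROC> %d point(s), AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Sweep the alpha/beta grid
#'
#' Evaluates [decide_dataset()] on the full Cartesian grid of thresholds
#' and reports metrics per configuration. The best row maximizes `metric`;
#' metric ties are broken toward the smallest alpha, then the smallest
#' beta — i.e. when accuracy plateaus as alpha grows, the plateau onset is
#' reported, mirroring how threshold optima are conventionally read off a
#' flat-topped sweep.
#'
#' @param scored_bags List of labeled `scored_bag`.
#' @param alpha_grid Alpha values (default 0.50 to 1.00 in steps of 0.05 —
#'   a fine step near 1 because useful optima concentrate there).
#' @param beta_grid Beta values (default 0:10).
#' @param variant Decision-rule variant (see [decision_config()]).
#' @param metric Metric to maximize (`"acc"`, `"f1"`, `"precision"`,
#'   `"recall"`).
#' @param depressive_cutoff Passed to [decision_config()].
#' @return Object of class `mil_sweep`: `table` (one row per grid point),
#'   `best` (the arg-max row), `metric`, `variant`.
#' @export
sweep_alpha_beta <- function(scored_bags,
                             alpha_grid = seq(0.5, 1, by = 0.05),
                             beta_grid = 0:10,
                             variant = "majority_or_count",
                             metric = "acc",
                             depressive_cutoff = 0.5) {
  if (length(alpha_grid) == 0L || length(beta_grid) == 0L) {
    stop("parameter error: empty threshold grid", call. = FALSE)
  }
  stopifnot(metric %in% c("acc", "precision", "recall", "f1"))
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cfg <- decision_config(alpha = grid$alpha[k], beta = grid$beta[k],
                           depressive_cutoff = depressive_cutoff,
                           variant = variant)
    res <- decide_dataset(scored_bags, cfg)
    if (is.null(res$confusion)) {
      stop("sweep_alpha_beta: no labeled bags to evaluate", call. = FALSE)
    }
    m <- classification_metrics(res$confusion)
    data.frame(alpha = grid$alpha[k], beta = grid$beta[k],
               acc = m$acc, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  })
  tab <- do.call(rbind, rows)
  vals <- tab[[metric]]
  vals[is.na(vals)] <- -Inf
  best_idx <- order(-vals, tab$alpha, tab$beta)[1L]
  structure(
    list(table = tab, best = tab[best_idx, , drop = FALSE],
         metric = metric, variant = variant),
    class = "mil_sweep"
  )
}

#' @export
print.mil_sweep <- function(x, ...) {
  cat(sprintf("<alpha/beta sweep> %d configuration(s), variant %s, best %s:\n",
              nrow(x$table), x$variant, x$metric))
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mil_sweep <- function(x, ...) {
  # metric vs alpha at the best beta: the standard one-dimensional read-out
  bb <- x$best$beta
  sub <- x$table[x$table$beta == bb, ]
  plot(sub$alpha, sub[[x$metric]], type = "b",
       xlab = expression(alpha), ylab = x$metric,
       main = sprintf("beta = %g", bb), ...)
  invisible(x)
}

#' Compare pooling strategies against the alpha/beta rule
#'
#' Max and mean pooling threshold the pooled bag score at `cutoff`; the MIL
#' rule applies [decide_bag()] with `config`. One metrics row per method.
#'
#' @param scored_bags List of labeled `scored_bag`.
#' @param config `decision_config` for the MIL rule row.
#' @param cutoff Threshold for the pooled-score rows.
#' @return Data frame with columns `method`, `acc`, `precision`, `recall`,
#'   `f1`.
#' @export
compare_pooling <- function(scored_bags, config = decision_config(),
                            cutoff = 0.5) {
  labeled <- Filter(function(sb) !is.null(sb$bag$label), scored_bags)
  if (length(labeled) == 0L) {
    stop("compare_pooling: no labeled bags", call. = FALSE)
  }
  gold <- vapply(labeled, function(sb) sb$bag$label, integer(1))
  tally <- function(pred) {
    confusion_counts(sum(pred == 1 & gold == 1), sum(pred == 1 & gold == 0),
                     sum(pred == 0 & gold == 0), sum(pred == 0 & gold == 1))
  }
  row_for <- function(method, pred) {
    m <- classification_metrics(tally(pred))
    data.frame(method = method, acc = m$acc, precision = m$precision,
               recall = m$recall, f1 = m$f1, stringsAsFactors = FALSE)
  }
  pred_max <- vapply(labeled, function(sb) {
    as.integer(pool(sb$scores$score, "max") > cutoff)
  }, integer(1))
  pred_mean <- vapply(labeled, function(sb) {
    as.integer(pool(sb$scores$score, "mean") > cutoff)
  }, integer(1))
  pred_mil <- vapply(labeled, function(sb) decide_bag(sb, config)$label,
                     integer(1))
  rbind(row_for("max_pooling", pred_max),
        row_for("mean_pooling", pred_mean),
        row_for("mil_rule", pred_mil))
}
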