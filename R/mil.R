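# Bag-level labeling: the classical MIL rule, pooling operators, and the
# improved alpha/beta decision algorithm.

#' Decision-rule configuration
#'
#' The improved bag-level rule has two criteria over a bag's instance
#' scores:
#' \describe{
#'   \item{majority}{more than half of the instances exceed the
#'     high-confidence threshold `alpha` (strict `>` throughout);}
#'   \item{count}{more than `beta` instances are *depressive*, i.e. exceed
#'     `depressive_cutoff` (default 0.5).}
#' }
#' The default variant `"majority_or_count"` flags a bag when either
#' criterion fires. `"single_or_count"` replaces the majority criterion
#' with "any single instance exceeds `alpha`" — the reading under which one
#' high-confidence instance can directly determine the bag — and
#' `"count_only"` / `"majority_only"` run each criterion alone (useful for
#' ablations).
#'
#' @param alpha High-confidence score threshold in (0, 1].
#' @param beta Depressive-instance count threshold (nonnegative; a count
#'   unless `beta_fraction = TRUE`, in which case the threshold is
#'   `beta * n` for a bag of size n).
#' @param depressive_cutoff Score above which an instance is depressive.
#' @param variant Criterion combination, see Details.
#' @param beta_fraction Interpret `beta` as a fraction of the bag size.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(alpha = 0.95, beta = 2,
                            depressive_cutoff = 0.5,
                            variant = c("majority_or_count", "single_or_count",
                                        "count_only", "majority_only"),
                            beta_fraction = FALSE) {
  variant <- match.arg(variant)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("parameter error: alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("parameter error: beta must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(depressive_cutoff) || depressive_cutoff < 0 ||
      depressive_cutoff > 1) {
    stop("parameter error: depressive_cutoff must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, depressive_cutoff = depressive_cutoff,
         variant = variant, beta_fraction = isTRUE(beta_fraction)),
    class = "decision_config"
  )
}

#' @export
print.decision_config <- function(x, ...) {
  cat(sprintf("<decision config> alpha=%g beta=%g%s cutoff=%g variant=%s\n",
              x$alpha, x$beta, if (x$beta_fraction) " (fraction)" else "",
              x$depressive_cutoff, x$variant))
  invisible(x)
}

#' Classical MIL bag label
#'
#' A bag is positive iff it contains at least one positive instance
#' (equivalently, negative iff the instance labels sum to zero).
#'
#' @param instance_labels Nonempty vector of 0/1 instance labels.
#' @return 0 or 1.
#' @export
classical_bag_label <- function(instance_labels) {
  if (length(instance_labels) == 0L) {
    stop("empty-bag error: no instance labels", call. = FALSE)
  }
  stopifnot(all(instance_labels %in% c(0, 1)))
  if (sum(instance_labels) == 0) 0L else 1L
}

#' Pool instance scores into a bag score
#'
#' Permutation-invariant aggregation of a bag's score vector. Max pooling
#' keeps the most prominent instance; mean pooling averages all instances.
#'
#' @param scores Nonempty numeric vector of scores in \[0, 1\].
#' @param method `"max"` or `"mean"`.
#' @return A single pooled score.
#' @export
pool <- function(scores, method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(scores) == 0L) {
    stop("empty-bag error: no scores to pool", call. = FALSE)
  }
  switch(method, max = max(scores), mean = mean(scores))
}

#' Apply the improved alpha/beta decision rule to one scored bag
#'
#' Computes per-instance flags (`above_alpha` = score > alpha, `depressive`
#' = score > cutoff; boundary equality never fires a flag), both criteria,
#' and the bag label under the configured variant.
#'
#' @param scored A `scored_bag`.
#' @param config A `decision_config`.
#' @return An object of class `bag_decision` with fields `label`, `n`,
#'   `count_above_alpha`, `count_depressive`, `criterion_majority`,
#'   `criterion_count`, `per_instance_flags` and `participant_id`.
#' @export
decide_bag <- function(scored, config = decision_config()) {
  stopifnot(inherits(scored, "scored_bag"), inherits(config, "decision_config"))
  s <- scored$scores$score
  n <- length(s)
  if (n == 0L) stop("empty-bag error: no scores", call. = FALSE)
  above_alpha <- s > config$alpha
  depressive <- s > config$depressive_cutoff
  count_above <- sum(above_alpha)
  count_depr <- sum(depressive)
  criterion_majority <- count_above > n / 2
  beta_threshold <- if (config$beta_fraction) config$beta * n else config$beta
  criterion_count <- count_depr > beta_threshold
  label <- switch(config$variant,
    majority_or_count = criterion_majority || criterion_count,
    single_or_count = (count_above >= 1L) || criterion_count,
    count_only = criterion_count,
    majority_only = criterion_majority
  )
  structure(
    list(participant_id = scored$bag$participant_id,
         label = as.integer(label),
         n = n,
         count_above_alpha = count_above,
         count_depressive = count_depr,
         criterion_majority = criterion_majority,
         criterion_count = criterion_count,
         per_instance_flags = data.frame(above_alpha = above_alpha,
                                         depressive = depressive)),
    class = "bag_decision"
  )
}

#' @export
print.bag_decision <- function(x, ...) {
  cat(sprintf(
    "<decision %s> label=%d (majority=%s, count=%s); %d/%d above alpha, %d depressive\n",
    x$participant_id, x$label, x$criterion_majority, x$criterion_count,
    x$count_above_alpha, x$n, x$count_depressive))
  invisible(x)
}

#' Decide every bag in a dataset and tally confusion counts
#'
#' Applies [decide_bag()] with one configuration to all bags. Bags with
#' gold labels contribute to the confusion counts; unlabeled bags still
#' receive decisions and are reported in `n_unlabeled`. Per-bag errors are
#' collected, not fatal.
#'
#' @param scored_bags List of `scored_bag`.
#' @param config A `decision_config`.
#' @return Object of class `mil_decisions`: `decisions` (list of
#'   `bag_decision`), `confusion` (`confusion_counts` or `NULL` when no bag
#'   is labeled), `n_unlabeled`, `errors`, `config`.
#' @export
decide_dataset <- function(scored_bags, config = decision_config()) {
  decisions <- list()
  errors <- list()
  tp <- fp <- tn <- fn <- 0L
  n_unlabeled <- 0L
  for (sb in scored_bags) {
    d <- tryCatch(decide_bag(sb, config), error = function(e) e)
    if (inherits(d, "error")) {
      errors[[length(errors) + 1L]] <- list(
        participant_id = tryCatch(sb$bag$participant_id,
                                  error = function(e) NA_character_),
        message = conditionMessage(d))
      next
    }
    decisions[[length(decisions) + 1L]] <- d
    gold <- sb$bag$label
    if (is.null(gold)) {
      n_unlabeled <- n_unlabeled + 1L
    } else if (gold == 1L) {
      if (d$label == 1L) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (d$label == 1L) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  confusion <- if (tp + fp + tn + fn > 0L) {
    confusion_counts(tp, fp, tn, fn)
  } else NULL
  structure(
    list(decisions = decisions, confusion = confusion,
         n_unlabeled = n_unlabeled, errors = errors, config = config),
    class = "mil_decisions"
  )
}

#' @export
print.mil_decisions <- function(x, ...) {
  cat(sprintf("<dataset decisions> %d bag(s) decided, %d unlabeled, %d error(s)\n",
              length(x$decisions), x$n_unlabeled, length(x$errors)))
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}

#' Confusion counts
#'
#' @param TP,FP,TN,FN Nonnegative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
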