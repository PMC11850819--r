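# Instance scoring: the scorer contract, a bag-of-words logistic baseline,
# average-vote ensembling, and Monte-Carlo repeat uncertainty.

#' Wrap a scoring function as a scorer
#'
#' A scorer maps one instance to a depression confidence score in \[0, 1\]
#' (the positive-class probability). Scorers are the pluggable stand-in for
#' any instance classifier — the fitted bag-of-words baseline, a lexicon
#' heuristic, or an adapter around an external neural model. Deterministic
#' scorers must return identical values on identical input; set
#' `stochastic = TRUE` when repeated calls may differ (e.g. dropout at
#' inference), which is what [mc_uncertainty()] exploits.
#'
#' @param score_fn Function taking a `mil_instance` and returning a numeric
#'   scalar in \[0, 1\].
#' @param stochastic Whether repeated calls on the same input may differ.
#' @param name Human-readable scorer name.
#' @param coefficients Optional named numeric vector of per-token weights
#'   (exposed so explanations can be validated against them).
#' @param intercept Optional intercept that pairs with `coefficients`.
#' @return An object of class `mil_scorer`.
#' @export
mil_scorer <- function(score_fn, stochastic = FALSE, name = "custom",
                       coefficients = NULL, intercept = NULL) {
  stopifnot(is.function(score_fn))
  structure(
    list(score_fn = score_fn, stochastic = isTRUE(stochastic), name = name,
         coefficients = coefficients, intercept = intercept),
    class = "mil_scorer"
  )
}

#' @export
print.mil_scorer <- function(x, ...) {
  cat(sprintf("<scorer '%s'> %s\n", x$name,
              if (x$stochastic) "stochastic" else "deterministic"))
  if (!is.null(x$coefficients)) {
    cat(sprintf("  %d token weight(s), intercept %.4f\n",
                length(x$coefficients), x$intercept %||% 0))
  }
  invisible(x)
}

#' @export
coef.mil_scorer <- function(object, ...) {
  if (is.null(object$coefficients)) return(NULL)
  c("(Intercept)" = object$intercept %||% 0, object$coefficients)
}

score_instance <- function(scorer, instance) {
  s <- scorer$score_fn(instance)
  if (!is.numeric(s) || length(s) != 1L || is.na(s)) {
    stop("scorer contract violation: score must be a numeric scalar",
         call. = FALSE)
  }
  s
}

#' Score every instance of a bag
#'
#' Instances are scored independently and in order; no information flows
#' between instances, so permuting a bag permutes its scores identically.
#'
#' @param scorer A `mil_scorer`.
#' @param bag A `mil_bag`.
#' @return A `scored_bag`: the bag plus a data frame of scores aligned by
#'   `instance_id`.
#' @export
score_bag <- function(scorer, bag) {
  stopifnot(inherits(scorer, "mil_scorer"), inherits(bag, "mil_bag"))
  scores <- vapply(bag$instances, function(inst) {
    s <- score_instance(scorer, inst)
    if (s < 0 || s > 1) {
      stop(sprintf(
        "scorer contract violation: score %.4f outside [0, 1] for instance %d of bag %s",
        s, inst$instance_id, bag$participant_id), call. = FALSE)
    }
    s
  }, numeric(1))
  structure(
    list(bag = bag,
         scores = data.frame(
           instance_id = vapply(bag$instances, function(i) i$instance_id,
                                integer(1)),
           score = scores,
           variance = NA_real_
         )),
    class = "scored_bag"
  )
}

#' @export
print.scored_bag <- function(x, ...) {
  cat(sprintf("<scored bag %s> %d instance(s), scores in [%.3f, %.3f]\n",
              x$bag$participant_id, nrow(x$scores),
              min(x$scores$score), max(x$scores$score)))
  invisible(x)
}

#' Build a scored bag directly from a numeric score vector
#'
#' For workflows that start from precomputed instance scores (score files,
#' synthetic score generators) rather than texts. Placeholder instances are
#' created so the object satisfies the usual bag invariants.
#'
#' @param scores Numeric vector of scores in \[0, 1\].
#' @param bag Optional `mil_bag` to attach the scores to (must have
#'   matching length); if omitted a placeholder bag is built.
#' @param participant_id Id for the placeholder bag.
#' @param label Optional binary label for the placeholder bag.
#' @param variance Optional per-instance variance vector.
#' @return A `scored_bag`.
#' @export
as_scored_bag <- function(scores, bag = NULL, participant_id = "bag",
                          label = NULL, variance = NA_real_) {
  stopifnot(is.numeric(scores), length(scores) >= 1L,
            all(scores >= 0 & scores <= 1))
  if (is.null(bag)) {
    instances <- lapply(seq_along(scores), function(i) {
      new_instance(sprintf("instance-%d", i), instance_id = i)
    })
    bag <- build_bag(participant_id, instances, label = label)
  }
  stopifnot(inherits(bag, "mil_bag"), bag$n == length(scores))
  structure(
    list(bag = bag,
         scores = data.frame(
           instance_id = vapply(bag$instances, function(i) i$instance_id,
                                integer(1)),
           score = as.numeric(scores),
           variance = as.numeric(variance)
         )),
    class = "scored_bag"
  )
}

#' Fit the bag-of-words logistic baseline scorer
#'
#' A desk-scale instance scorer: binary token-presence features of the
#' instance text, a ridge-penalized logistic regression, and a logistic
#' squashing to \[0, 1\]. Training instances inherit their bag's label (the
#' standard MIL weak-label assumption — only bag-level supervision exists).
#' The fitted token weights are exposed via [coef()] so explanation methods
#' can be validated against them. The fit is deterministic.
#'
#' @param bags List of labeled `mil_bag` (both classes must be present).
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @param min_count Minimum number of training instances a token must
#'   appear in to enter the vocabulary.
#' @return A `mil_scorer` (subclass `baseline_scorer`) with `coefficients`,
#'   `intercept` and `vocabulary` fields.
#' @export
fit_baseline_scorer <- function(bags, lambda = 0.01, min_count = 1L) {
  labeled <- Filter(function(b) !is.null(b$label), bags)
  if (length(labeled) == 0L) {
    stop("fit_baseline_scorer: no labeled bags", call. = FALSE)
  }
  y <- unlist(lapply(labeled, function(b) rep(b$label, b$n)))
  if (length(unique(y)) < 2L) {
    stop("degenerate-training error: both classes must be present among bag labels",
         call. = FALSE)
  }
  texts <- unlist(lapply(labeled, function(b) {
    vapply(b$instances, function(i) i$text, character(1))
  }))
  tok_list <- lapply(texts, function(t) unique(tokenize_words(tolower(t))))
  vocab <- sort(names(which(table(unlist(tok_list)) >= min_count)))
  if (length(vocab) < 2L) {
    stop("fit_baseline_scorer: vocabulary too small to fit", call. = FALSE)
  }
  ii <- rep(seq_along(tok_list), lengths(tok_list))
  jj <- match(unlist(tok_list), vocab)
  keep <- !is.na(jj)
  x <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = 1,
                            dims = c(length(texts), length(vocab)))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  b <- as.numeric(coef(fit))
  intercept <- b[1L]
  w <- setNames(b[-1L], vocab)
  score_fn <- function(instance) {
    toks <- unique(tokenize_words(tolower(instance$text)))
    plogis(intercept + sum(w[intersect(toks, vocab)]))
  }
  sc <- mil_scorer(score_fn, stochastic = FALSE, name = "baseline_bow_logistic",
                   coefficients = w, intercept = intercept)
  sc$vocabulary <- vocab
  sc$lambda <- lambda
  class(sc) <- c("baseline_scorer", class(sc))
  sc
}

#' @export
predict.mil_scorer <- function(object, newdata, ...) {
  if (inherits(newdata, "mil_bag")) return(score_bag(object, newdata))
  stopifnot(is.list(newdata))
  lapply(newdata, function(b) score_bag(object, b))
}

#' Constant scorer
#'
#' Returns the same score for every instance; mostly useful in tests and as
#' a degenerate reference.
#'
#' @param value Score in \[0, 1\].
#' @return A deterministic `mil_scorer`.
#' @export
constant_scorer <- function(value = 0.5) {
  stopifnot(value >= 0, value <= 1)
  mil_scorer(function(instance) value, name = sprintf("constant(%g)", value))
}

#' Exactly linear token-presence scorer
#'
#' Score = `intercept + sum of weights of tokens present` (binary presence,
#' case-insensitive). The caller is responsible for choosing weights that
#' keep the score inside \[0, 1\] on the texts of interest; [score_bag()]
#' enforces the range. Because the score is exactly linear in token
#' presence, local surrogate explanations should recover the weights, which
#' makes this scorer the reference point for validating
#' [explain_instance()].
#'
#' @param coefficients Named numeric vector of token weights.
#' @param intercept Base score for an empty text.
#' @return A deterministic `mil_scorer`.
#' @export
linear_text_scorer <- function(coefficients, intercept = 0.5) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  names(coefficients) <- tolower(names(coefficients))
  mil_scorer(
    function(instance) {
      toks <- unique(tokenize_words(tolower(instance$text)))
      unname(intercept + sum(coefficients[intersect(toks, names(coefficients))]))
    },
    name = "linear_presence",
    coefficients = coefficients,
    intercept = intercept
  )
}

#' Average-vote ensemble of two scored bags
#'
#' Fuses two scorers' outputs at the instance level: each fused score is
#' exactly the arithmetic mean of the two input scores for that instance.
#'
#' @param a,b `scored_bag` objects over the same bag with identical
#'   instance alignment.
#' @return A `scored_bag` of fused scores.
#' @export
ensemble_scores <- function(a, b) {
  stopifnot(inherits(a, "scored_bag"), inherits(b, "scored_bag"))
  if (!identical(a$bag$participant_id, b$bag$participant_id) ||
      !identical(a$scores$instance_id, b$scores$instance_id)) {
    stop("alignment error: scored bags do not share participant and instance alignment",
         call. = FALSE)
  }
  out <- a
  out$scores$score <- (a$scores$score + b$scores$score) / 2
  out$scores$variance <- NA_real_
  out
}

#' Monte-Carlo repeat uncertainty for one instance
#'
#' Scores the same instance `repeats` times and returns the sample mean and
#' the population variance (divide by N) of the scores. For a deterministic
#' scorer the variance is exactly 0; for a stochastic scorer (e.g. dropout
#' kept active at inference) the variance estimates predictive uncertainty.
#' The default of 10 repeats follows the usual Monte-Carlo dropout
#' protocol.
#'
#' @param scorer A `mil_scorer`.
#' @param instance A `mil_instance`.
#' @param repeats Number of independent scorings (>= 2; default 10).
#' @param seed Optional seed for reproducibility of stochastic scorers.
#' @return List with `mean` and `variance`.
#' @export
mc_uncertainty <- function(scorer, instance, repeats = 10L, seed = NULL) {
  if (!is.numeric(repeats) || repeats < 2L) {
    stop("parameter error: repeats must be >= 2", call. = FALSE)
  }
  s <- with_seed(seed, vapply(seq_len(repeats),
                              function(i) score_instance(scorer, instance),
                              numeric(1)))
  m <- mean(s)
  list(mean = m, variance = mean((s - m)^2))
}
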