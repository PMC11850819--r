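# Shared fixtures and independent oracles used across test files.

# Write a small transcript table to a temp file and return the path.
write_toy_transcript <- function(rows, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  header <- paste(c("start_time", "stop_time", "speaker", "value"),
                  collapse = sep)
  lines <- vapply(rows, function(r) paste(r, collapse = sep), character(1))
  writeLines(c(header, lines), path)
  path
}

# A 5-turn toy session: Q1, A, A, Q2, A.
toy_session_rows <- function() {
  list(
    c("0.0", "1.0", "Ellie", "how are you doing today"),
    c("1.5", "2.0", "Participant", "i'm fine"),
    c("2.5", "3.0", "Participant", "mostly"),
    c("3.5", "4.0", "Ellie", "what do you do to relax"),
    c("4.5", "5.0", "Participant", "i listen to music")
  )
}

# Minimal scored bag built without instance objects; decide_bag needs only
# the score column and a participant id. Used where many thousands of
# decisions are enumerated.
fast_scored_bag <- function(scores, label = NULL) {
  structure(
    list(bag = structure(list(participant_id = "g", label = label,
                              n = length(scores), instances = NULL),
                         class = "mil_bag"),
         scores = data.frame(instance_id = seq_along(scores),
                             score = scores,
                             variance = rep(NA_real_, length(scores)))),
    class = "scored_bag"
  )
}

# Independent literal evaluator of the two prose decision criteria:
# (a) more than half of the instances exceed alpha;
# (b) more than beta instances exceed the depressive cutoff.
# Deliberately written as a direct transcription, separate from decide_bag.
oracle_decide <- function(scores, alpha, beta, cutoff = 0.5,
                          variant = "majority_or_count") {
  n <- length(scores)
  exceeds_alpha <- vapply(scores, function(s) s > alpha, logical(1))
  depressive <- vapply(scores, function(s) s > cutoff, logical(1))
  majority <- sum(exceeds_alpha) > n / 2
  count_rule <- sum(depressive) > beta
  verdict <- switch(variant,
    majority_or_count = majority || count_rule,
    single_or_count = any(exceeds_alpha) || count_rule,
    count_only = count_rule,
    majority_only = majority)
  as.integer(verdict)
}

# Mann-Whitney pairwise AUC oracle: over all positive-negative pairs,
# count wins, ties as 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# All multisets of size n drawn from vals (decision rules are
# permutation-invariant, which is property-tested separately, so multiset
# enumeration is exhaustive over outcomes).
multisets <- function(vals, n) {
  k <- length(vals)
  idx <- utils::combn(k + n - 1L, n)
  apply(idx, 2L, function(col) vals[col - seq_len(n) + 1L], simplify = FALSE)
}

# A stochastic scorer emitting 1 with probability p, else 0.
bernoulli_scorer <- function(p = 0.5) {
  mil_scorer(function(instance) as.numeric(runif(1) < p),
             stochastic = TRUE, name = "bernoulli")
}
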