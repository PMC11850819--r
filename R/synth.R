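# Synthetic interview and score generators. The generator encodes the
# statistical structure the MIL analysis assumes: minority-positive class
# balance, depressive signal confined to a fraction of a positive bag's
# instances, and occasional depressive-looking ("spurious") instances
# inside negative bags.

#' Configuration for the synthetic generators
#'
#' Defaults emulate the structure of the clinical interview corpora the
#' method targets: 47 participants with a 14/47 positive prevalence (the
#' usual held-out split), 40--100 question--answer instances per bag, the
#' depressive signal carried by ~20% of a positive bag's instances, and a
#' 15% chance that a negative bag contains one spurious depressive-looking
#' instance. Score distributions: truly depressive instances draw from
#' `Beta(12, 2)` (mean ~0.86, substantial mass above 0.9), ordinary
#' instances from `Beta(2, 8)` (mean 0.2), and spurious instances from
#' `Beta(6, 4)` (mean 0.6: depressive — above 0.5 — but almost never above
#' 0.9, so only positive bags place real mass beyond 0.9).
#'
#' @param n_participants Number of bags.
#' @param prevalence Positive-label probability in (0, 1).
#' @param instances_per_bag Integer range (length-2) of instances per bag.
#' @param depressive_fraction_pos Fraction of truly depressive instances
#'   inside a positive bag.
#' @param spurious_rate_neg Probability a negative bag contains one
#'   spurious depressive-looking instance.
#' @param high_shape,low_shape,spurious_shape Beta shape pairs for the
#'   three score distributions.
#' @param lexicon_depressive,lexicon_neutral Disjoint word lists for text
#'   generation.
#' @param depressive_word_rate,background_word_rate Per-word probability of
#'   drawing from the depressive lexicon in depressive vs ordinary
#'   instances.
#' @param words_per_answer Integer range of words per generated instance.
#' @param answers_per_question Integer range of consecutive answer turns an
#'   instance is split into in the emitted transcript.
#' @param questionless_rate Probability a session has no interviewer rows
#'   (those sessions are emitted answer-by-answer and never merged).
#' @param seed Default seed used by the generators.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 47L,
                         prevalence = 14 / 47,
                         instances_per_bag = c(40L, 100L),
                         depressive_fraction_pos = 0.2,
                         spurious_rate_neg = 0.15,
                         high_shape = c(12, 2),
                         low_shape = c(2, 8),
                         spurious_shape = c(6, 4),
                         lexicon_depressive = c(
                           "sad", "tired", "hopeless", "empty", "worthless",
                           "crying", "sleepless", "miserable", "lonely",
                           "numb", "exhausted", "despair"),
                         lexicon_neutral = c(
                           "weather", "coffee", "work", "music", "walking",
                           "friends", "movie", "dinner", "travel", "weekend",
                           "garden", "reading", "game", "traffic", "morning",
                           "lunch", "office", "school", "family", "beach",
                           "sport", "cooking", "dog", "cat", "book", "show",
                           "neighbor", "holiday", "shopping", "bike", "run",
                           "song", "kitchen", "project", "meeting", "phone",
                           "computer", "city", "park", "river"),
                         depressive_word_rate = 0.35,
                         background_word_rate = 0.02,
                         words_per_answer = c(5L, 25L),
                         answers_per_question = c(1L, 3L),
                         questionless_rate = 0.02,
                         seed = NULL) {
  stopifnot(prevalence > 0, prevalence < 1,
            depressive_fraction_pos >= 0, depressive_fraction_pos <= 1,
            spurious_rate_neg >= 0, spurious_rate_neg <= 1,
            length(instances_per_bag) == 2L,
            instances_per_bag[1] >= 1, diff(instances_per_bag) >= 0)
  for (sh in list(high_shape, low_shape, spurious_shape)) {
    if (length(sh) != 2L || any(!is.finite(sh)) || any(sh <= 0)) {
      stop("parameter error: Beta shapes must be two positive numbers",
           call. = FALSE)
    }
  }
  if (length(intersect(lexicon_depressive, lexicon_neutral)) > 0L) {
    stop("config error: depressive and neutral lexicons must be disjoint",
         call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         prevalence = prevalence,
         instances_per_bag = as.integer(instances_per_bag),
         depressive_fraction_pos = depressive_fraction_pos,
         spurious_rate_neg = spurious_rate_neg,
         high_shape = high_shape, low_shape = low_shape,
         spurious_shape = spurious_shape,
         lexicon_depressive = lexicon_depressive,
         lexicon_neutral = lexicon_neutral,
         depressive_word_rate = depressive_word_rate,
         background_word_rate = background_word_rate,
         words_per_answer = as.integer(words_per_answer),
         answers_per_question = as.integer(answers_per_question),
         questionless_rate = questionless_rate,
         seed = seed),
    class = "synth_config"
  )
}

default_question_bank <- function() {
  c("how are you doing today",
    "how have you been feeling lately",
    "what do you do to relax",
    "how would your best friend describe you",
    "when was the last time you felt really happy",
    "how easy is it for you to get a good night sleep",
    "what are you most proud of",
    "have you ever been diagnosed with depression",
    "what do you enjoy doing in your free time",
    "how are things at work or school",
    "tell me about your family",
    "what did you do last weekend")
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

#' Generate synthetic scored bags with gold labels
#'
#' Bag labels are Bernoulli(prevalence). A positive bag of size n draws
#' `ceiling(depressive_fraction_pos * n)` scores from the high Beta and the
#' rest from the low Beta, shuffled; a negative bag draws all scores from
#' the low Beta and, with probability `spurious_rate_neg`, replaces one by
#' a draw from the spurious Beta. Per-instance ground truth (was this
#' instance planted as depressive-looking?) is recorded in the `truth`
#' column of each bag's score table.
#'
#' @param config A `synth_config`.
#' @param seed Seed (defaults to `config$seed`); same seed, same dataset.
#' @return List of `scored_bag` with gold bag labels.
#' @export
generate_score_bags <- function(config = synth_config(), seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    lapply(seq_len(config$n_participants), function(p) {
      label <- rbinom(1L, 1L, config$prevalence)
      n_i <- sample_range(config$instances_per_bag)
      if (label == 1L) {
        k <- ceiling(config$depressive_fraction_pos * n_i)
        truth <- sample(c(rep(TRUE, k), rep(FALSE, n_i - k)))
        scores <- numeric(n_i)
        scores[truth] <- rbeta(sum(truth), config$high_shape[1],
                               config$high_shape[2])
        scores[!truth] <- rbeta(sum(!truth), config$low_shape[1],
                                config$low_shape[2])
      } else {
        truth <- rep(FALSE, n_i)
        scores <- rbeta(n_i, config$low_shape[1], config$low_shape[2])
        if (runif(1) < config$spurious_rate_neg) {
          j <- sample.int(n_i, 1L)
          truth[j] <- TRUE
          scores[j] <- rbeta(1L, config$spurious_shape[1],
                             config$spurious_shape[2])
        }
      }
      sb <- as_scored_bag(scores, participant_id = sprintf("synth-%03d", p),
                          label = label)
      sb$scores$truth <- truth
      sb
    })
  })
}

#' Generate synthetic text bags, with raw transcript rows
#'
#' End-to-end fixture for the preprocessing and scoring pipeline. Instance
#' texts are random word sequences; truly depressive instances mix words
#' from the depressive lexicon at `depressive_word_rate`, others at
#' `background_word_rate`. Each instance is also emitted as raw transcript
#' rows (one interviewer question plus 1--3 consecutive participant answer
#' turns), so reading the transcript, pairing and merging reproduces the
#' bag exactly. Question-less sessions are emitted answer-by-answer with no
#' interviewer rows.
#'
#' @param config A `synth_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return Object of class `synth_text_data`: `bags` (list of `mil_bag`
#'   with gold labels), `transcripts` (named list of transcript data frames
#'   with columns `start_time`, `stop_time`, `speaker`, `value`), `truth`
#'   (named list of per-instance logical depressive flags).
#' @export
generate_text_bags <- function(config = synth_config(), seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  qbank <- default_question_bank()
  with_seed(seed, {
    bags <- list(); transcripts <- list(); truth <- list()
    for (p in seq_len(config$n_participants)) {
      pid <- sprintf("synth-%03d", p)
      label <- rbinom(1L, 1L, config$prevalence)
      n_i <- sample_range(config$instances_per_bag)
      if (label == 1L) {
        k <- ceiling(config$depressive_fraction_pos * n_i)
        depr <- sample(c(rep(TRUE, k), rep(FALSE, n_i - k)))
      } else {
        depr <- rep(FALSE, n_i)
        if (runif(1) < config$spurious_rate_neg) {
          depr[sample.int(n_i, 1L)] <- TRUE
        }
      }
      questionless <- runif(1) < config$questionless_rate
      rows <- list(); instances <- list()
      t0 <- 0
      for (j in seq_len(n_i)) {
        L <- sample_range(config$words_per_answer)
        rate <- if (depr[j]) config$depressive_word_rate
                else config$background_word_rate
        from_dep <- runif(L) < rate
        words <- character(L)
        words[from_dep] <- sample(config$lexicon_depressive, sum(from_dep),
                                  replace = TRUE)
        words[!from_dep] <- sample(config$lexicon_neutral, sum(!from_dep),
                                   replace = TRUE)
        text <- paste(words, collapse = " ")
        if (questionless) {
          rows[[length(rows) + 1L]] <- data.frame(
            start_time = t0, stop_time = t0 + 1, speaker = "Participant",
            value = text, stringsAsFactors = FALSE)
          t0 <- t0 + 2
          instances[[length(instances) + 1L]] <-
            new_instance(text, source_question = NA_character_)
        } else {
          q <- sample(qbank, 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            start_time = t0, stop_time = t0 + 1, speaker = "Ellie",
            value = q, stringsAsFactors = FALSE)
          t0 <- t0 + 2
          a <- sample_range(config$answers_per_question)
          a <- min(a, L)
          cuts <- sort(sample(seq_len(L - 1L), a - 1L))
          bounds <- c(0L, cuts, L)
          for (s in seq_len(a)) {
            chunk <- words[(bounds[s] + 1L):bounds[s + 1L]]
            rows[[length(rows) + 1L]] <- data.frame(
              start_time = t0, stop_time = t0 + 1, speaker = "Participant",
              value = paste(chunk, collapse = " "), stringsAsFactors = FALSE)
            t0 <- t0 + 2
          }
          instances[[length(instances) + 1L]] <-
            new_instance(text, source_question = q)
        }
      }
      bags[[pid]] <- build_bag(pid, instances, label = label)
      transcripts[[pid]] <- do.call(rbind, rows)
      truth[[pid]] <- depr
    }
    structure(list(bags = unname(bags), transcripts = transcripts,
                   truth = truth),
              class = "synth_text_data")
  })
}

#' @export
print.synth_text_data <- function(x, ...) {
  labs <- vapply(x$bags, function(b) b$label, integer(1))
  cat(sprintf("<synthetic text data> %d bag(s), %d positive\n",
              length(x$bags), sum(labs)))
  invisible(x)
}

#' Write a transcript data frame as a tab-separated file
#'
#' Emits the same four-column layout [read_transcript()] consumes with the
#' `"daic_woz"` dialect.
#'
#' @param transcript Data frame with columns `start_time`, `stop_time`,
#'   `speaker`, `value`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  utils::write.table(transcript, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
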