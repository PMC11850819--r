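# Transcript preprocessing: read timestamped dialogue, pair questions with
# answers in time order, merge multi-part answers, normalize key answers,
# and assemble per-participant bags.

#' Construct a single MIL instance
#'
#' An instance is one merged participant response. `word_count` is always
#' recomputed from `text` with [tokenize_words()] so the two can never drift
#' apart.
#'
#' @param text Instance text.
#' @param source_question Interviewer question the response answers, or
#'   `NA` when the session had no question rows.
#' @param instance_id Integer id, unique within a bag (assigned by
#'   [build_bag()]).
#' @return An object of class `mil_instance`.
#' @export
new_instance <- function(text, source_question = NA_character_,
                         instance_id = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L)
  structure(
    list(
      text = text,
      word_count = n_words(text),
      source_question = as.character(source_question),
      instance_id = as.integer(instance_id),
      empty = !nzchar(trimws(text))
    ),
    class = "mil_instance"
  )
}

#' @export
print.mil_instance <- function(x, ...) {
  q <- if (is.na(x$source_question)) "<no question>" else x$source_question
  cat(sprintf("<instance %s> [%d words] Q: %s\n  %s\n",
              ifelse(is.na(x$instance_id), "?", x$instance_id),
              x$word_count, q, x$text))
  invisible(x)
}

#' Read a dialogue transcript into time-ordered utterances
#'
#' Parses a delimited transcript table (one row per dialogue turn) and
#' returns utterances sorted by start time, ties broken by input order.
#' Rows with blank text are dropped (and counted). Rows with non-numeric
#' timestamps are an error naming the offending line, unless
#' `lenient = TRUE`, in which case they are dropped and counted.
#'
#' @param path Path to the transcript file (or a connection).
#' @param dialect `"daic_woz"` (tab-separated), `"e_daic"` (comma-separated;
#'   participant-only rows permitted), or `"generic"` (separator sniffed
#'   from the header line).
#' @param interviewer_tag Speaker tag identifying the interviewer
#'   (case-insensitive; default `"Ellie"`). Every other speaker is treated
#'   as the participant.
#' @param lenient Drop malformed rows instead of erroring.
#' @return A data frame of class `mil_utterances` with columns
#'   `start_time`, `stop_time`, `speaker` (`"interviewer"` or
#'   `"participant"`), `text`; attribute `n_dropped` counts removed rows.
#' @export
read_transcript <- function(path,
                            dialect = c("daic_woz", "e_daic", "generic"),
                            interviewer_tag = "Ellie",
                            lenient = FALSE) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect,
    daic_woz = "\t",
    e_daic = ",",
    generic = {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (grepl("\t", first)) "\t" else ","
    }
  )
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character", check.names = FALSE,
                           blank.lines.skip = FALSE)
  nm <- tolower(gsub("[^a-z_]", "", gsub("[ .]", "_", tolower(names(raw)))))
  find_col <- function(cands, required_name) {
    idx <- which(nm %in% cands)
    if (length(idx) == 0L) {
      stop(sprintf("transcript format error: missing required column '%s'",
                   required_name), call. = FALSE)
    }
    idx[1L]
  }
  i_start <- find_col(c("start_time", "starttime", "start"), "start_time")
  i_stop  <- find_col(c("stop_time", "stoptime", "stop", "end_time"), "stop_time")
  i_spk   <- find_col(c("speaker"), "speaker")
  i_val   <- find_col(c("value", "text", "utterance"), "value")

  start_time <- suppressWarnings(as.numeric(raw[[i_start]]))
  stop_time <- suppressWarnings(as.numeric(raw[[i_stop]]))
  text <- raw[[i_val]]
  speaker_raw <- trimws(raw[[i_spk]])

  bad_ts <- which(is.na(start_time) | is.na(stop_time))
  if (length(bad_ts) > 0L && !lenient) {
    stop(sprintf("transcript row error: non-numeric timestamp at line %d",
                 bad_ts[1L] + 1L), call. = FALSE)  # +1 for the header line
  }
  blank <- which(!nzchar(trimws(text)))
  drop <- union(bad_ts, blank)
  n_dropped <- length(drop)
  if (n_dropped > 0L) {
    keep <- setdiff(seq_len(nrow(raw)), drop)
    start_time <- start_time[keep]
    stop_time <- stop_time[keep]
    text <- text[keep]
    speaker_raw <- speaker_raw[keep]
    message(sprintf("read_transcript: dropped %d malformed/blank row(s)",
                    n_dropped))
  }
  speaker <- ifelse(tolower(speaker_raw) == tolower(interviewer_tag),
                    "interviewer", "participant")
  ord <- order(start_time)  # stable: ties keep input order
  out <- data.frame(
    start_time = start_time[ord],
    stop_time = stop_time[ord],
    speaker = speaker[ord],
    text = text[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("mil_utterances", "data.frame")
  out
}

#' Segment time-ordered utterances into question--answer pairs
#'
#' Walks the session in timestamp order. Each maximal run of consecutive
#' participant utterances following an interviewer utterance becomes one
#' pair whose question is that interviewer utterance's text. Participant
#' turns with no preceding interviewer turn (including whole sessions that
#' lack interviewer rows) are *not* merged: each becomes its own
#' question-less pair, matching how sessions without interviewer question
#' text are handled upstream.
#'
#' @param utterances A `mil_utterances` data frame (time-sorted).
#' @return List of `qa_pair` objects: `question` (string or `NA`),
#'   `answers` (character vector), `order_index`.
#' @export
build_qa_pairs <- function(utterances) {
  if (is.null(utterances) || nrow(utterances) == 0L) {
    stop("empty-input error: no utterances to segment", call. = FALSE)
  }
  pairs <- list()
  cur_q <- NULL
  cur_answers <- character()
  flush <- function() {
    if (length(cur_answers) > 0L) {
      pairs[[length(pairs) + 1L]] <<- structure(
        list(question = cur_q %||% NA_character_,
             answers = cur_answers,
             order_index = length(pairs) + 1L),
        class = "qa_pair"
      )
    }
    cur_answers <<- character()
  }
  for (i in seq_len(nrow(utterances))) {
    if (utterances$speaker[i] == "interviewer") {
      flush()
      cur_q <- utterances$text[i]
    } else if (is.null(cur_q)) {
      # no preceding question: one pair per turn, never merged
      cur_answers <- utterances$text[i]
      flush()
    } else {
      cur_answers <- c(cur_answers, utterances$text[i])
    }
  }
  flush()
  pairs
}

#' Merge a pair's answers into one instance
#'
#' Concatenates the participant's consecutive responses to one question, in
#' original order, into a single comprehensive response.
#'
#' @param pair A `qa_pair`.
#' @param joiner Separator placed between answers (default single space).
#' @return A `mil_instance`.
#' @export
merge_answers <- function(pair, joiner = " ") {
  stopifnot(inherits(pair, "qa_pair"))
  if (length(pair$answers) == 0L) {
    stop("merge_answers: pair has no answers", call. = FALSE)
  }
  new_instance(paste(pair$answers, collapse = joiner),
               source_question = pair$question)
}

#' Rank instances by word count, longest first
#'
#' Stable sort by `word_count` descending; ties keep the original session
#' order. Longer responses are assumed richer in emotional content, so they
#' are prioritized; nothing is discarded.
#'
#' @param instances List of `mil_instance`.
#' @param top_n Optionally keep only the `top_n` longest instances
#'   (default keeps all).
#' @return Reordered list of `mil_instance`.
#' @export
rank_instances <- function(instances, top_n = NULL) {
  if (length(instances) == 0L) return(instances)
  wc <- vapply(instances, function(x) x$word_count, integer(1))
  out <- instances[order(-wc)]  # order() is stable
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, length(out)))]
  out
}

#' Default canonicalization rules for key diagnostic questions
#'
#' One built-in rule targets the prior-diagnosis question. A bare "yes" or
#' "no" answer to it carries decisive information yet has almost no words,
#' so it would be drowned out by word-count ranking; the rule replaces such
#' answers with a full canonical sentence stating the diagnosis status.
#'
#' @return List of rules, each with `pattern` (regex matched against the
#'   source question, case-insensitive), `positive`/`negative` replacement
#'   sentences, and `yes_phrases`/`no_phrases` (matched on the lowercased
#'   leading tokens of the answer).
#' @export
key_question_rules <- function() {
  list(
    list(
      pattern = "diagnos\\w*\\s+.*depress",
      positive = "I was unfortunate enough to be diagnosed with depression.",
      negative = paste0("I am healthy and have never tested positive for ",
                        "mental illness such as depression."),
      yes_phrases = c("yes", "yeah", "yep", "i have"),
      no_phrases = c("no", "nope", "never", "i haven't")
    )
  )
}

#' Replace answers to key questions with canonical sentences
#'
#' For each instance whose source question matches a rule, the text is
#' replaced byte-for-byte by the rule's positive or negative canonical
#' sentence according to a yes/no detector on the answer's leading tokens.
#' Instances matching no rule are untouched; a matched instance whose
#' answer is neither a yes nor a no is left unchanged with a warning.
#'
#' @param instances List of `mil_instance`.
#' @param rules Rules as produced by [key_question_rules()].
#' @return List of `mil_instance` with matched texts canonicalized and
#'   word counts recomputed.
#' @export
canonicalize_key_answers <- function(instances, rules = key_question_rules()) {
  lapply(instances, function(inst) {
    q <- inst$source_question
    if (is.na(q)) return(inst)
    for (rule in rules) {
      if (!grepl(rule$pattern, q, ignore.case = TRUE)) next
      toks <- tolower(tokenize_words(inst$text))
      is_yes <- any(vapply(rule$yes_phrases, starts_with_phrase,
                           logical(1), tokens = toks))
      is_no <- any(vapply(rule$no_phrases, starts_with_phrase,
                          logical(1), tokens = toks))
      if (is_no && !is_yes) {
        return(new_instance(rule$negative, source_question = q,
                            instance_id = inst$instance_id))
      }
      if (is_yes) {
        return(new_instance(rule$positive, source_question = q,
                            instance_id = inst$instance_id))
      }
      warning(sprintf(
        "canonicalize_key_answers: answer %s matches neither yes nor no; left unchanged",
        sQuote(substr(inst$text, 1, 40))), call. = FALSE)
      return(inst)
    }
    inst
  })
}

#' Remove embedded interviewer questions from an instance
#'
#' Pre-processed corpora sometimes leave the interviewer's question inside
#' the participant's response text. Any exact occurrence of a known
#' question (compared after lowercasing and stripping ASCII punctuation) is
#' removed token-wise; remaining tokens keep their original form, and the
#' word count is recomputed. If removal empties the text the returned
#' instance has `empty = TRUE`; the caller decides whether to drop it.
#'
#' @param instance A `mil_instance`.
#' @param question_bank Character vector of known interviewer questions.
#' @return A `mil_instance`.
#' @export
strip_interviewer_text <- function(instance, question_bank) {
  stopifnot(inherits(instance, "mil_instance"))
  raw_toks <- tokenize_words(instance$text)
  norm_toks <- vapply(raw_toks, function(t) normalize_text(t), character(1),
                      USE.NAMES = FALSE)
  for (q in question_bank) {
    q_toks <- tokenize_words(normalize_text(q))
    if (length(q_toks) == 0L) next
    repeat {
      hit <- find_subsequence(norm_toks, q_toks)
      if (is.na(hit)) break
      idx <- hit:(hit + length(q_toks) - 1L)
      raw_toks <- raw_toks[-idx]
      norm_toks <- norm_toks[-idx]
    }
  }
  out <- new_instance(paste(raw_toks, collapse = " "),
                      source_question = instance$source_question,
                      instance_id = instance$instance_id)
  out
}

# First start position of contiguous subsequence `needle` in `haystack`,
# NA if absent.
find_subsequence <- function(haystack, needle) {
  n <- length(haystack); m <- length(needle)
  if (m == 0L || n < m) return(NA_integer_)
  for (i in seq_len(n - m + 1L)) {
    if (identical(haystack[i:(i + m - 1L)], needle)) return(i)
  }
  NA_integer_
}

#' Assemble a participant's bag of instances
#'
#' @param participant_id Participant identifier (string).
#' @param instances Nonempty list of `mil_instance`; instance ids are
#'   (re)assigned 1..n in the given order.
#' @param label Optional binary bag label (1 = depressed).
#' @return An object of class `mil_bag` with fields `participant_id`,
#'   `instances`, `label`, `n`.
#' @export
build_bag <- function(participant_id, instances, label = NULL) {
  if (length(instances) == 0L) {
    stop("empty-bag error: a bag must contain at least one instance",
         call. = FALSE)
  }
  stopifnot(all(vapply(instances, inherits, logical(1), "mil_instance")))
  if (!is.null(label)) {
    label <- as.integer(label)
    stopifnot(length(label) == 1L, label %in% c(0L, 1L))
  }
  instances <- lapply(seq_along(instances), function(i) {
    inst <- instances[[i]]
    inst$instance_id <- i
    inst
  })
  structure(
    list(participant_id = as.character(participant_id),
         instances = instances,
         label = label,
         n = length(instances)),
    class = "mil_bag"
  )
}

#' @export
print.mil_bag <- function(x, ...) {
  lab <- if (is.null(x$label)) "unlabeled" else paste("label", x$label)
  cat(sprintf("<bag %s> %d instance(s), %s\n", x$participant_id, x$n, lab))
  invisible(x)
}

#' @export
as.data.frame.mil_bag <- function(x, ...) {
  data.frame(
    participant_id = x$participant_id,
    instance_id = vapply(x$instances, function(i) i$instance_id, integer(1)),
    question = vapply(x$instances, function(i) i$source_question, character(1)),
    text = vapply(x$instances, function(i) i$text, character(1)),
    word_count = vapply(x$instances, function(i) i$word_count, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Preprocess one transcript file into a bag
#'
#' Convenience wrapper: read, pair, merge, optionally canonicalize key
#' answers and rank by word count.
#'
#' @inheritParams read_transcript
#' @param participant_id Participant identifier for the resulting bag.
#' @param label Optional binary label.
#' @param canonicalize Apply [canonicalize_key_answers()]?
#' @param rank Apply [rank_instances()]?
#' @param rules Canonicalization rules.
#' @return A `mil_bag`.
#' @export
transcript_to_bag <- function(path, participant_id,
                              dialect = c("daic_woz", "e_daic", "generic"),
                              label = NULL, canonicalize = TRUE, rank = FALSE,
                              rules = key_question_rules(),
                              interviewer_tag = "Ellie", lenient = FALSE) {
  utt <- read_transcript(path, dialect = dialect,
                         interviewer_tag = interviewer_tag, lenient = lenient)
  pairs <- build_qa_pairs(utt)
  instances <- lapply(pairs, merge_answers)
  if (canonicalize) instances <- canonicalize_key_answers(instances, rules)
  if (rank) instances <- rank_instances(instances)
  build_bag(participant_id, instances, label = label)
}
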