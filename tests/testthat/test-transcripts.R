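# Transcript reading, question-answer pairing, merging and normalization.

test_that("read_transcript returns time-ordered utterances and maps speakers", {
  path <- write_toy_transcript(toy_session_rows())
  utt <- read_transcript(path, "daic_woz")
  expect_equal(nrow(utt), 5L)
  expect_equal(utt$speaker,
               c("interviewer", "participant", "participant",
                 "interviewer", "participant"))
  expect_equal(utt$text[2], "i'm fine")

  # rows given out of time order come back sorted by start_time
  shuffled <- toy_session_rows()[c(3, 1, 5, 2, 4)]
  utt2 <- read_transcript(write_toy_transcript(shuffled), "daic_woz")
  expect_equal(utt2$start_time, sort(utt2$start_time))
  expect_equal(utt2$text, utt$text)
})

test_that("sessions with zero interviewer rows parse without error", {
  rows <- list(c("0", "1", "Participant", "first answer"),
               c("2", "3", "Participant", "second answer"))
  utt <- read_transcript(write_toy_transcript(rows), "daic_woz")
  expect_true(all(utt$speaker == "participant"))
})

test_that("reader errors name missing columns and malformed timestamps", {
  path <- tempfile()
  writeLines(c("start_time\tstop_time\tvalue", "0\t1\thello"), path)
  expect_error(read_transcript(path, "daic_woz"), "speaker")

  bad <- write_toy_transcript(list(c("0", "1", "Ellie", "hi"),
                                   c("oops", "2", "Participant", "fine")))
  expect_error(read_transcript(bad, "daic_woz"), "line 3")
  # lenient mode drops and counts instead
  expect_message(utt <- read_transcript(bad, "daic_woz", lenient = TRUE),
                 "dropped 1")
  expect_equal(nrow(utt), 1L)
  expect_equal(attr(utt, "n_dropped"), 1L)
})

test_that("blank-text rows are dropped, not turned into empty utterances", {
  rows <- list(c("0", "1", "Ellie", "hi"),
               c("1.5", "2", "Participant", "   "),
               c("2.5", "3", "Participant", "ok"))
  expect_message(utt <- read_transcript(write_toy_transcript(rows), "daic_woz"))
  expect_equal(nrow(utt), 2L)
})

test_that("e_daic dialect reads comma-separated participant-only files", {
  rows <- list(c("0", "1", "Participant", "kind i guess"),
               c("2", "3", "Participant", "not much"))
  utt <- read_transcript(write_toy_transcript(rows, sep = ","), "e_daic")
  expect_equal(nrow(utt), 2L)
  expect_true(all(utt$speaker == "participant"))
})

test_that("build_qa_pairs groups participant runs under the preceding question", {
  path <- write_toy_transcript(toy_session_rows())
  pairs <- build_qa_pairs(read_transcript(path, "daic_woz"))
  expect_length(pairs, 2L)
  expect_equal(lengths(lapply(pairs, function(p) p$answers)), c(2L, 1L))
  expect_equal(pairs[[1]]$question, "how are you doing today")
  expect_equal(pairs[[1]]$answers, c("i'm fine", "mostly"))
  expect_equal(vapply(pairs, function(p) p$order_index, integer(1)), 1:2)
})

test_that("question-less turns each become their own pair, never merged", {
  rows <- list(c("0", "1", "Participant", "first answer"),
               c("2", "3", "Participant", "second answer"))
  pairs <- build_qa_pairs(read_transcript(write_toy_transcript(rows), "daic_woz"))
  expect_length(pairs, 2L)
  expect_true(all(is.na(vapply(pairs, function(p) p$question, character(1)))))
})

test_that("a question with no answers yields no pair; empty input errors", {
  rows <- list(c("0", "1", "Ellie", "how are you doing today"))
  pairs <- build_qa_pairs(read_transcript(write_toy_transcript(rows), "daic_woz"))
  expect_length(pairs, 0L)
  expect_error(build_qa_pairs(data.frame()), "empty")
})

test_that("merge_answers joins in order and conserves word counts", {
  pair <- structure(list(question = "q", answers = c("i'm fine", "mostly"),
                         order_index = 1L), class = "qa_pair")
  inst <- merge_answers(pair)
  expect_equal(inst$text, "i'm fine mostly")
  expect_equal(inst$word_count, 3L)

  # property: total words conserved over random answer lists
  set.seed(7)
  for (rep in 1:20) {
    answers <- vapply(seq_len(sample(1:5, 1)), function(i) {
      paste(sample(letters, sample(1:6, 1), replace = TRUE), collapse = " ")
    }, character(1))
    p <- structure(list(question = NA_character_, answers = answers,
                        order_index = 1L), class = "qa_pair")
    expect_equal(merge_answers(p)$word_count,
                 sum(vapply(answers, function(a) length(strsplit(a, " ")[[1]]),
                            integer(1))))
  }

  # internal double spaces never inflate the count
  p2 <- structure(list(question = NA_character_, answers = c("a  b", " c "),
                       order_index = 1L), class = "qa_pair")
  expect_equal(merge_answers(p2)$word_count, 3L)
})

test_that("rank_instances sorts by word count descending, stably", {
  mk <- function(txt) new_instance(txt)
  inst <- list(mk("a b c"), mk("a b c d e f g"), mk("a b c d e"))
  ranked <- rank_instances(inst)
  expect_equal(vapply(ranked, function(i) i$word_count, integer(1)),
               c(7L, 5L, 3L))
  # ties keep original order (texts distinguish the instances)
  tied <- list(mk("x y"), mk("p q"), mk("u v"))
  expect_equal(vapply(rank_instances(tied), function(i) i$text, character(1)),
               c("x y", "p q", "u v"))
  expect_equal(rank_instances(list()), list())
  # permutation property: output is a reordering of input
  expect_setequal(vapply(ranked, function(i) i$text, character(1)),
                  vapply(inst, function(i) i$text, character(1)))
})

test_that("canonicalize_key_answers emits the two canonical sentences byte-for-byte", {
  q <- "have you ever been diagnosed with depression"
  yes <- new_instance("yes", source_question = q)
  no <- new_instance("no", source_question = q)
  out <- canonicalize_key_answers(list(yes, no))
  expect_identical(out[[1]]$text,
                   "I was unfortunate enough to be diagnosed with depression.")
  expect_identical(out[[2]]$text,
                   paste0("I am healthy and have never tested positive for ",
                          "mental illness such as depression."))
  expect_equal(out[[1]]$word_count,
               length(strsplit(out[[1]]$text, " ")[[1]]))

  # leading-token variants
  for (ans in c("yeah i think so", "i have unfortunately", "yep")) {
    o <- canonicalize_key_answers(list(new_instance(ans, source_question = q)))
    expect_match(o[[1]]$text, "^I was unfortunate")
  }
  for (ans in c("never", "nope", "i haven't no")) {
    o <- canonicalize_key_answers(list(new_instance(ans, source_question = q)))
    expect_match(o[[1]]$text, "^I am healthy")
  }
})

test_that("unmatched questions and undetectable answers pass through", {
  other <- new_instance("yes", source_question = "what do you do to relax")
  expect_identical(canonicalize_key_answers(list(other))[[1]]$text, "yes")

  q <- "have you been diagnosed with depression"
  odd <- new_instance("well it's complicated", source_question = q)
  expect_warning(out <- canonicalize_key_answers(list(odd)),
                 "neither yes nor no")
  expect_identical(out[[1]]$text, "well it's complicated")
})

test_that("strip_interviewer_text removes embedded bank questions exactly", {
  bank <- c("how would your best friend describe you")
  inst <- new_instance("how would your best friend describe you kind i guess")
  out <- strip_interviewer_text(inst, bank)
  expect_equal(out$text, "kind i guess")
  expect_equal(out$word_count, 3L)

  # normalization: punctuation/case differences still match
  inst2 <- new_instance("How would your best friend describe you? kind i guess")
  expect_equal(strip_interviewer_text(inst2, bank)$text, "kind i guess")

  # no bank match is the identity
  inst3 <- new_instance("kind i guess")
  expect_equal(strip_interviewer_text(inst3, bank)$text, "kind i guess")

  # total removal flags the instance empty
  inst4 <- new_instance("how would your best friend describe you")
  out4 <- strip_interviewer_text(inst4, bank)
  expect_true(out4$empty)
  expect_equal(out4$word_count, 0L)
})

test_that("build_bag assigns ids 1..n and rejects empty bags", {
  inst <- lapply(c("a", "b c", "d"), new_instance)
  bag <- build_bag("p1", inst, label = 1)
  expect_s3_class(bag, "mil_bag")
  expect_equal(bag$n, 3L)
  expect_equal(bag$label, 1L)
  expect_equal(vapply(bag$instances, function(i) i$instance_id, integer(1)), 1:3)

  unlabeled <- build_bag("p2", inst[1])
  expect_null(unlabeled$label)
  expect_equal(unlabeled$n, 1L)

  expect_error(build_bag("p3", list()), "empty-bag")
  expect_error(build_bag("p4", inst, label = 2))
})

test_that("preprocessing is deterministic: identical input, identical bags", {
  path <- write_toy_transcript(toy_session_rows())
  b1 <- transcript_to_bag(path, "p1")
  b2 <- transcript_to_bag(path, "p1")
  expect_identical(b1, b2)
})
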