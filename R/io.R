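# JSON-lines readers/writers for bags, scored bags and decision reports.

#' Write bags as JSON lines
#'
#' One JSON object per line:
#' `{"participant_id", "label" (0/1/null), "instances": [{"id", "question",
#' "text", "word_count"}]}`.
#'
#' @param bags List of `mil_bag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bags <- function(bags, path) {
  lines <- vapply(bags, function(b) {
    obj <- list(
      participant_id = b$participant_id,
      label = if (is.null(b$label)) NULL else b$label,
      instances = lapply(b$instances, function(i) {
        list(id = i$instance_id,
             question = if (is.na(i$source_question)) NULL else i$source_question,
             text = i$text,
             word_count = i$word_count)
      })
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read bags from JSON lines
#'
#' @param path File written by [write_bags()].
#' @return List of `mil_bag`.
#' @export
read_bags <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    instances <- lapply(obj$instances, function(i) {
      new_instance(i$text,
                   source_question = i$question %||% NA_character_,
                   instance_id = i$id)
    })
    build_bag(obj$participant_id, instances, label = obj$label %||% NULL)
  })
}

#' Write scored bags as JSON lines
#'
#' One object per line: `{"participant_id", "label", "scores": [{"id",
#' "score", "variance"}]}`.
#'
#' @param scored_bags List of `scored_bag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scored_bags <- function(scored_bags, path) {
  lines <- vapply(scored_bags, function(sb) {
    obj <- list(
      participant_id = sb$bag$participant_id,
      label = if (is.null(sb$bag$label)) NULL else sb$bag$label,
      scores = lapply(seq_len(nrow(sb$scores)), function(j) {
        v <- sb$scores$variance[j]
        list(id = sb$scores$instance_id[j],
             score = sb$scores$score[j],
             variance = if (is.na(v)) NULL else v)
      })
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read scored bags from JSON lines
#'
#' Instance texts are not stored in score files; reconstructed bags carry
#' empty placeholder texts and are suitable for decision and evaluation
#' steps only.
#'
#' @param path File written by [write_scored_bags()].
#' @return List of `scored_bag`.
#' @export
read_scored_bags <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    ids <- vapply(obj$scores, function(s) as.integer(s$id), integer(1))
    sc <- vapply(obj$scores, function(s) as.numeric(s$score), numeric(1))
    vr <- vapply(obj$scores, function(s) {
      if (is.null(s$variance)) NA_real_ else as.numeric(s$variance)
    }, numeric(1))
    instances <- lapply(ids, function(i) {
      new_instance(sprintf("instance-%d", i), instance_id = i)
    })
    bag <- build_bag(obj$participant_id, instances, label = obj$label %||% NULL)
    as_scored_bag(sc, bag = bag, variance = vr)
  })
}

#' Write a dataset decision report as JSON
#'
#' @param result A `mil_decisions` object from [decide_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_decision_report <- function(result, path) {
  obj <- list(
    config = unclass(result$config),
    decisions = lapply(result$decisions, function(d) {
      list(participant_id = d$participant_id,
           label_pred = d$label,
           criterion_majority = d$criterion_majority,
           criterion_count = d$criterion_count,
           n = d$n,
           count_above_alpha = d$count_above_alpha,
           count_depressive = d$count_depressive,
           per_instance_flags = d$per_instance_flags)
    }),
    confusion = if (is.null(result$confusion)) NULL else unclass(result$confusion),
    n_unlabeled = result$n_unlabeled
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA, dataframe = "rows")
  invisible(path)
}
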