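# Shared helpers: tokenization, text normalization, seeded evaluation.

#' Whitespace tokenizer
#'
#' Splits text on runs of whitespace and drops empty tokens. This is the
#' single word-counting rule used across the package (word counts, instance
#' ranking, explanation features), so counts are consistent between modules.
#'
#' @param x Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize_words("i'm  fine   mostly")
tokenize_words <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x)) return(character())
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

n_words <- function(x) length(tokenize_words(x))

# Lowercase + strip ASCII punctuation; used for question-bank matching.
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Leading-token phrase match: does `tokens` start with the tokens of `phrase`?
starts_with_phrase <- function(tokens, phrase) {
  ptoks <- tokenize_words(tolower(phrase))
  if (length(ptoks) == 0L || length(tokens) < length(ptoks)) return(FALSE)
  identical(tokens[seq_along(ptoks)], ptoks)
}
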