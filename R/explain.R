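# Perturbation-based local surrogate explanation of one instance score
# (LIME-style): mask tokens, score the perturbed texts, fit a
# proximity-weighted sparse linear surrogate.

#' Explain one instance's score with a local linear surrogate
#'
#' The scorer is probed around one instance: the text is tokenized into
#' distinct (lowercased) word features; `n_samples` binary masks are drawn
#' uniformly over mask sizes and applied by *removing* all occurrences of
#' the masked words; each perturbed text is scored; samples are weighted by
#' `exp(-d^2 / kernel_width^2)` where `d` is the cosine distance between
#' the mask and the unperturbed all-ones mask; and a weighted ridge
#' regression is fitted, keeping the `max_features` largest-magnitude
#' weights (refitted on the retained features). Positive weights push the
#' score toward depressive.
#'
#' If the scorer returns the same value on every perturbation there is no
#' local variation to attribute: all weights are 0 and a flat-explanation
#' warning is raised.
#'
#' @param scorer A `mil_scorer`.
#' @param instance A `mil_instance` with at least one token.
#' @param n_samples Number of perturbed samples (>= 10; default 1000).
#' @param kernel_width Proximity kernel width; default
#'   `0.75 * sqrt(number of distinct tokens)`.
#' @param max_features Maximum number of features retained (default 10).
#' @param seed Optional seed; explanations are reproducible given the seed.
#' @return Object of class `mil_explanation`: `tokens`, `weights`
#'   (aligned), `intercept`, `n_samples`, `local_fit_quality` (weighted
#'   R^2), `seed`.
#' @export
explain_instance <- function(scorer, instance, n_samples = 1000L,
                             kernel_width = NULL, max_features = 10L,
                             seed = NULL) {
  stopifnot(inherits(scorer, "mil_scorer"), inherits(instance, "mil_instance"))
  toks <- tokenize_words(tolower(instance$text))
  features <- unique(toks)
  d <- length(features)
  if (d < 1L) stop("explain_instance: instance has no tokens", call. = FALSE)
  if (!is.numeric(n_samples) || n_samples < 10L) {
    stop("parameter error: n_samples must be >= 10", call. = FALSE)
  }
  kw <- kernel_width %||% (0.75 * sqrt(d))

  masks <- with_seed(seed, {
    m <- matrix(1L, nrow = n_samples, ncol = d)
    for (i in 2:n_samples) {  # row 1 keeps the original text
      k <- sample.int(d, 1L)           # number of features removed
      m[i, sample.int(d, k)] <- 0L
    }
    m
  })

  score_mask <- function(z) {
    kept <- features[z == 1L]
    txt <- paste(toks[toks %in% kept], collapse = " ")
    s <- tryCatch(score_instance(scorer, new_instance(txt)),
                  error = function(e) {
                    stop(sprintf(
                      "explain_instance: scorer failed on perturbed text (mask [%s]): %s",
                      paste(z, collapse = ""), conditionMessage(e)),
                      call. = FALSE)
                  })
    s
  }
  y <- vapply(seq_len(n_samples), function(i) score_mask(masks[i, ]),
              numeric(1))

  if (max(y) - min(y) == 0) {
    warning("flat explanation: scorer shows no local variation; all weights 0",
            call. = FALSE)
    return(structure(
      list(tokens = features, weights = rep(0, d), intercept = y[1L],
           n_samples = as.integer(n_samples), local_fit_quality = NA_real_,
           kernel_width = kw, seed = seed),
      class = "mil_explanation"
    ))
  }

  kept_frac <- rowSums(masks) / d
  cos_dist <- 1 - sqrt(kept_frac)  # cosine distance to the all-ones mask
  w <- exp(-cos_dist^2 / kw^2)

  fit_ridge <- function(Z) {
    A <- cbind(1, Z)
    p <- ncol(A)
    M <- crossprod(A, A * w) + diag(c(0, rep(1e-6, p - 1L)))
    drop(solve(M, crossprod(A, w * y)))
  }
  beta_full <- fit_ridge(masks)
  coefs <- beta_full[-1L]
  keep <- order(-abs(coefs))[seq_len(min(max_features, d))]
  keep <- sort(keep)
  beta_sel <- fit_ridge(masks[, keep, drop = FALSE])
  fitted <- drop(cbind(1, masks[, keep, drop = FALSE]) %*% beta_sel)
  wmean <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - wmean)^2)

  structure(
    list(tokens = features[keep], weights = unname(beta_sel[-1L]),
         intercept = unname(beta_sel[1L]),
         n_samples = as.integer(n_samples),
         local_fit_quality = r2, kernel_width = kw, seed = seed),
    class = "mil_explanation"
  )
}

#' @export
print.mil_explanation <- function(x, ...) {
  cat(sprintf("<explanation> %d feature(s), intercept %.4f, local R^2 %s\n",
              length(x$tokens), x$intercept,
              if (is.na(x$local_fit_quality)) "NA"
              else sprintf("%.3f", x$local_fit_quality)))
  ord <- order(-abs(x$weights))
  for (i in ord) {
    cat(sprintf("  %+0.4f  %s\n", x$weights[i], x$tokens[i]))
  }
  invisible(x)
}

#' @export
plot.mil_explanation <- function(x, ...) {
  ord <- order(abs(x$weights))
  graphics::barplot(x$weights[ord], names.arg = x$tokens[ord], horiz = TRUE,
                    las = 1, xlab = "surrogate weight",
                    col = ifelse(x$weights[ord] > 0, "firebrick", "steelblue"),
                    ...)
  invisible(x)
}

#' Serialize an explanation to JSON
#'
#' @param x A `mil_explanation`.
#' @param path Output file path.
#' @param participant_id,instance_id Optional identifiers echoed into the
#'   output.
#' @return `path`, invisibly.
#' @export
write_explanation <- function(x, path, participant_id = NA_character_,
                              instance_id = NA_integer_) {
  obj <- list(participant_id = participant_id, instance_id = instance_id,
              tokens = x$tokens, weights = x$weights,
              intercept = x$intercept, n_samples = x$n_samples,
              local_fit_quality = x$local_fit_quality,
              seed = x$seed %||% NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
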