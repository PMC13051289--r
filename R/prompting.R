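#' Select one few-shot exemplar per class from the training split
#'
#' Candidates per class are "clean, short" examples: no URL token (substring
#' "http" or "www."), no "@" character, and at most 120 characters. The
#' shortest candidate is chosen, ties resolved by a seeded shuffle. If a
#' class has no clean short example at all, the rule falls back to the
#' class's shortest example overall and records that in the `fallback` flag.
#' The selection is made once with a fixed seed and reused for every target.
#'
#' @param train A [corpus()] with at least one example per class.
#' @param seed Integer selection seed.
#' @return An `exemplar_set`: list with `examples` (named list of one
#'   (id, text, label) row per class, canonical order), `fallback` (named
#'   logical), `seed`.
#' @export
select_exemplars <- function(train, seed = 13L) {
  counts <- class_counts(train)
  if (any(counts == 0)) {
    stop("training split has empty class(es): ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  examples <- list()
  fallback <- stats::setNames(logical(6), subtype_labels())
  for (cl in subtype_labels()) {
    rows <- train[train$label == cl, , drop = FALSE]
    clean <- !grepl("http", rows$text, fixed = TRUE) &
      !grepl("www.", rows$text, fixed = TRUE) &
      !grepl("@", rows$text, fixed = TRUE) &
      nchar(rows$text) <= 120
    pool <- if (any(clean)) rows[clean, , drop = FALSE] else {
      fallback[cl] <- TRUE
      rows
    }
    # seeded shuffle, then stable pick of the shortest
    ord <- with_local_seed(mix_seed(seed, string_hash(cl)),
                           sample.int(nrow(pool)))
    pool <- pool[ord, , drop = FALSE]
    pick <- pool[which.min(nchar(pool$text)), , drop = FALSE]
    examples[[cl]] <- list(id = pick$id, text = pick$text,
                           label = as.character(pick$label))
  }
  structure(list(examples = examples, fallback = fallback,
                 seed = as.integer(seed)),
            class = "exemplar_set")
}

#' Render the fixed multiple-choice prompt for one target tweet
#'
#' Assembles, in order: a one-line instruction; the six option lines
#' "A. postpartum" ... "F. atypical" in fixed letter order; an "Examples:"
#' block of six exemplar lines "L. <text> -> L"; the target line
#' "Tweet: <text>"; and a final "Answer:" line. The `realization_index`
#' permutes only the order of the six exemplar lines (a seeded permutation);
#' instruction, option order, and target never change, which is how
#' "independent prompt realizations" are operationalized for self-consistency
#' voting.
#'
#' @param target Target text (character) or a single-row [corpus()] slice.
#' @param exemplars An [select_exemplars()] result.
#' @param realization_index Non-negative integer; 0 is the identity ordering.
#' @return A `rendered_prompt`: list with `text`, `option_letters`,
#'   `target_id`, `realization_index`.
#' @export
render_prompt <- function(target, exemplars, realization_index = 0L) {
  stopifnot(realization_index >= 0)
  if (inherits(target, "data.frame")) {
    target_id <- target$id[1]
    target_text <- target$text[1]
  } else {
    target_id <- NA_character_
    target_text <- normalize_text(target)
  }
  labs <- subtype_labels()
  option_lines <- sprintf("%s. %s", names(labs), unname(labs))
  ord <- seq_len(6)
  if (realization_index > 0) {
    ord <- with_local_seed(mix_seed(exemplars$seed, realization_index),
                           sample.int(6))
  }
  ex_lines <- vapply(ord, function(i) {
    cl <- labs[i]
    sprintf("%s. %s -> %s", names(labs)[i], exemplars$examples[[cl]]$text,
            names(labs)[i])
  }, character(1))
  text <- paste(
    c("Classify the tweet into exactly one category. Answer with a single letter.",
      option_lines,
      "Examples:",
      ex_lines,
      sprintf("Tweet: %s", target_text),
      "Answer:"),
    collapse = "\n"
  )
  structure(list(text = text, option_letters = names(labs),
                 target_id = target_id,
                 realization_index = as.integer(realization_index)),
            class = "rendered_prompt")
}

#' Score the six option letters under a next-token scorer
#'
#' The scorer contract: `scorer(prompt_text, candidates)` returns one finite
#' log-probability per candidate continuation string. Each letter is scored
#' as the maximum over its surface variants (bare letter and space-prefixed
#' letter, covering tokenizers that attach a leading space), and the six
#' letter scores are renormalized by log-sum-exp into a proper
#' log-distribution. Renormalization subtracts a common constant, so argmax
#' and the full ordering of the raw scores are preserved.
#'
#' @param scorer A scorer function.
#' @param prompt A [render_prompt()] result (or raw prompt text).
#' @return Named numeric vector of six letter log-probabilities; their
#'   exponentials sum to 1.
#' @export
score_options <- function(scorer, prompt) {
  text <- if (inherits(prompt, "rendered_prompt")) prompt$text else prompt
  letters6 <- names(subtype_labels())
  candidates <- c(letters6, paste0(" ", letters6))
  raw <- scorer(text, candidates)
  if (length(raw) != length(candidates) || any(!is.finite(raw))) {
    bad <- letters6[unique((which(!is.finite(raw)) - 1) %% 6 + 1)]
    stop("scorer returned non-finite log-probabilities for letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pooled <- pmax(raw[1:6], raw[7:12])
  logp <- pooled - log_sum_exp(pooled)
  stats::setNames(logp, letters6)
}

#' Classify one target by k-realization self-consistency voting
#'
#' Runs [score_options()] on prompt realizations `0 .. k-1`, records each
#' realization's argmax letter, and takes the majority vote. Ties on the vote
#' count are broken by the larger sum of that letter's log-probabilities
#' across realizations, then by letter order; `tie_broken` is set whenever
#' the top vote count is shared.
#'
#' @param scorer A scorer function (see [score_options()]).
#' @param target Target text or single-row corpus slice.
#' @param exemplars An [select_exemplars()] result.
#' @param k Number of prompt realizations (>= 1), default 5.
#' @return A `vote_record`: list with `scores` (k x 6 matrix of letter
#'   log-probabilities), `votes` (k argmax letters), `final_letter`,
#'   `final_label`, `tie_broken`.
#' @export
predict_with_self_consistency <- function(scorer, target, exemplars, k = 5L) {
  stopifnot(k >= 1)
  letters6 <- names(subtype_labels())
  scores <- matrix(NA_real_, nrow = k, ncol = 6,
                   dimnames = list(NULL, letters6))
  votes <- character(k)
  for (r in seq_len(k)) {
    prompt <- render_prompt(target, exemplars, realization_index = r - 1L)
    s <- score_options(scorer, prompt)
    scores[r, ] <- s
    votes[r] <- letters6[which.max(s)]
  }
  tally <- table(factor(votes, levels = letters6))
  top <- max(tally)
  leaders <- letters6[tally == top]
  tie_broken <- length(leaders) > 1
  if (tie_broken) {
    sums <- colSums(scores)[leaders]
    leaders <- leaders[sums == max(sums)]  # then letter order
  }
  final_letter <- leaders[1]
  structure(list(scores = scores, votes = votes,
                 final_letter = final_letter,
                 final_label = letter_to_label(final_letter),
                 tie_broken = tie_broken, k = as.integer(k)),
            class = "vote_record")
}

#' Run the few-shot self-consistency protocol over a corpus
#'
#' Convenience wrapper: selects exemplars from the training split once, then
#' classifies every example of `x` with [predict_with_self_consistency()].
#' No parameter updates happen anywhere in this track.
#'
#' @param scorer A scorer function.
#' @param x Corpus to classify.
#' @param train Training corpus supplying exemplars.
#' @param k Realizations per target (default 5).
#' @param seed Exemplar-selection seed.
#' @return Data frame with columns `id`, `predicted`, `tie_broken`.
#' @export
prompt_classify <- function(scorer, x, train, k = 5L, seed = 13L) {
  exemplars <- select_exemplars(train, seed = seed)
  records <- lapply(seq_len(nrow(x)), function(i) {
    predict_with_self_consistency(scorer, x[i, , drop = FALSE], exemplars, k)
  })
  data.frame(
    id = x$id,
    predicted = vapply(records, function(r) r$final_label, character(1)),
    tie_broken = vapply(records, function(r) r$tie_broken, logical(1)),
    stringsAsFactors = FALSE
  )
}
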