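#' Configuration for the synthetic tweet-corpus generator
#'
#' The generator emulates the structural properties of the curated study
#' corpus that the pipeline depends on: six mutually exclusive classes at the
#' reported proportions, short noisy texts, class-specific vocabulary with a
#' controllable amount of vocabulary shared among the clinically confusable
#' triple (major, atypical, bipolar), and occasional URL/@mention tokens that
#' exercise the exemplar-selection filters. It makes no attempt at
#' linguistically realistic tweets: lexicons are seeded pseudo-words, not
#' clinical vocabulary.
#'
#' @param n_total Number of examples to generate (default 14983, the size of
#'   the curated corpus).
#' @param proportions Six positive class fractions in canonical order;
#'   renormalized to sum to 1 (the reported percentages sum to 99.8%).
#'   Default [reported_proportions()].
#' @param overlap Fraction in \[0,1\]: probability that a content token of a
#'   major/atypical/bipolar text is drawn from the shared confusable pool
#'   instead of the class's own list. 0 gives pairwise-disjoint class
#'   vocabularies.
#' @param noise_rate Fraction of tokens drawn from a class-neutral pool.
#' @param url_mention_rate Fraction of texts receiving a synthetic URL or
#'   @mention token.
#' @param length_range Integer (min, max) tokens per text; min must be >= 3.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_total = 14983L,
                             proportions = reported_proportions(),
                             overlap = 0.5,
                             noise_rate = 0.2,
                             url_mention_rate = 0.15,
                             length_range = c(5L, 40L),
                             seed = 1L) {
  stopifnot(
    n_total >= 6,
    length(proportions) == 6, all(proportions > 0),
    overlap >= 0, overlap <= 1,
    noise_rate >= 0, noise_rate <= 1,
    url_mention_rate >= 0, url_mention_rate <= 1,
    length(length_range) == 2, length_range[1] >= 3,
    length_range[2] >= length_range[1]
  )
  structure(
    list(
      n_total = as.integer(n_total),
      proportions = proportions / sum(proportions),
      overlap = overlap,
      noise_rate = noise_rate,
      url_mention_rate = url_mention_rate,
      length_range = as.integer(length_range),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Apportion a total count over the six classes
#'
#' Largest-remainder apportionment on renormalized proportions: exact quotas
#' are floored and the remaining units go to the classes with the largest
#' fractional parts, ties broken by canonical class order. Counts always sum
#' exactly to `n_total`, and each count is within one of its exact quota.
#'
#' @param n_total Total number of examples (>= 6).
#' @param proportions Six positive fractions (renormalized internally).
#' @return Named integer vector of six counts summing to `n_total`.
#' @examples
#' allocate_counts(600, rep(1 / 6, 6))
#' allocate_counts(14983, reported_proportions())
#' @export
allocate_counts <- function(n_total, proportions = reported_proportions()) {
  stopifnot(n_total >= 6, length(proportions) == 6, all(proportions > 0))
  stats::setNames(largest_remainder(as.integer(n_total), proportions),
                  subtype_labels())
}

#' Build a seeded pseudo-word lexicon
#'
#' Generates disjoint token pools: one list per class, one shared pool sampled
#' only by the confusable triple (major, atypical, bipolar), and one
#' class-neutral noise pool. Tokens are pronounceable pseudo-words
#' (consonant-vowel syllables), so the generator never ships real clinical
#' vocabulary; the pipeline tests structure, not semantics.
#'
#' @param seed Integer seed.
#' @param class_size Tokens per class list.
#' @param shared_size Tokens in the shared confusable pool.
#' @param neutral_size Tokens in the neutral pool.
#' @return A `lexicon`: list with `classes` (named list of six character
#'   vectors), `shared`, `neutral`.
#' @export
build_lexicon <- function(seed = 1L, class_size = 40L, shared_size = 40L,
                          neutral_size = 60L) {
  total <- 6L * class_size + shared_size + neutral_size
  words <- with_local_seed(mix_seed(seed, 101L), make_pseudo_words(total))
  classes <- list()
  pos <- 0L
  for (cl in subtype_labels()) {
    classes[[cl]] <- words[pos + seq_len(class_size)]
    pos <- pos + class_size
  }
  shared <- words[pos + seq_len(shared_size)]
  pos <- pos + shared_size
  neutral <- words[pos + seq_len(neutral_size)]
  structure(list(classes = classes, shared = shared, neutral = neutral),
            class = "lexicon")
}

# Unique pronounceable pseudo-words of 2-4 consonant-vowel syllables.
make_pseudo_words <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
                  "v", "z", "ch", "sh", "th", "pl", "tr", "gr")
  vowels <- c("a", "e", "i", "o", "u", "ai", "ou", "ee")
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    ns <- sample(2:4, k, replace = TRUE)
    batch <- vapply(ns, function(s) {
      paste0(paste0(sample(consonants, s, replace = TRUE),
                    sample(vowels, s, replace = TRUE)),
             collapse = "")
    }, character(1))
    out <- unique(c(out, batch))
  }
  out[seq_len(n)]
}

# Classes whose vocabularies overlap via the shared pool.
confusable_triple <- function() c("major", "atypical", "bipolar")

#' Generate a synthetic labeled corpus
#'
#' Per-class counts come from [allocate_counts()]. Each text is a
#' space-joined token sequence: tokens are neutral-pool with probability
#' `noise_rate`; otherwise drawn from the class's own list, except that for
#' the confusable triple (major, atypical, bipolar) a content token comes
#' from the shared pool with probability `overlap`. A fraction
#' `url_mention_rate` of texts receive a synthetic URL or @mention token.
#' Text collisions are resolved by appending a disambiguating "dupN" token,
#' so generated corpora always satisfy the corpus invariants (unique ids,
#' unique texts). Fully deterministic given the config.
#'
#' @param config A [generator_config()].
#' @param lexicon Optional [build_lexicon()]; built from `config$seed` when
#'   missing.
#' @return A [corpus()] of `config$n_total` examples in seeded shuffled
#'   order, with attribute `"lexicon"` carrying the lexicon used.
#' @export
generate_corpus <- function(config = generator_config(), lexicon = NULL) {
  if (is.null(lexicon)) lexicon <- build_lexicon(config$seed)
  counts <- allocate_counts(config$n_total, config$proportions)
  triple <- confusable_triple()
  texts <- character(config$n_total)
  labels <- character(config$n_total)
  with_local_seed(mix_seed(config$seed, 202L), {
    i <- 0L
    for (cl in subtype_labels()) {
      own <- lexicon$classes[[cl]]
      in_triple <- cl %in% triple
      for (j in seq_len(counts[[cl]])) {
        len <- sample(config$length_range[1]:config$length_range[2], 1L)
        u_noise <- stats::runif(len)
        u_shared <- stats::runif(len)
        tok <- character(len)
        for (t in seq_len(len)) {
          if (u_noise[t] < config$noise_rate) {
            tok[t] <- sample(lexicon$neutral, 1L)
          } else if (in_triple && u_shared[t] < config$overlap) {
            tok[t] <- sample(lexicon$shared, 1L)
          } else {
            tok[t] <- sample(own, 1L)
          }
        }
        if (stats::runif(1) < config$url_mention_rate) {
          extra <- if (stats::runif(1) < 0.5) {
            sprintf("http://t.co/%06d", sample.int(999999L, 1L))
          } else {
            sprintf("@user%04d", sample.int(9999L, 1L))
          }
          pos <- sample.int(len + 1L, 1L) - 1L
          tok <- append(tok, extra, after = pos)
        }
        i <- i + 1L
        texts[i] <- paste(tok, collapse = " ")
        labels[i] <- cl
      }
    }
    # resolve exact-text collisions, then shuffle example order
    dup_n <- 0L
    while (anyDuplicated(texts)) {
      d <- which(duplicated(texts))
      dup_n <- dup_n + 1L
      texts[d] <- paste(texts[d], sprintf("dup%d", dup_n))
    }
    ord <- sample.int(config$n_total)
    texts <- texts[ord]
    labels <- labels[ord]
  })
  out <- corpus(texts, labels, id = sprintf("t%06d", seq_len(config$n_total)))
  attr(out, "lexicon") <- lexicon
  out
}

# Per-class lexicon hit counts for a tokenized text. Shared-pool tokens count
# as a hit for each class of the confusable triple (that is what makes them
# confusable); neutral and URL/@ tokens count for no class.
lexicon_hits <- function(tokens, lexicon) {
  hits <- stats::setNames(numeric(6), subtype_labels())
  for (cl in subtype_labels()) {
    hits[cl] <- sum(tokens %in% lexicon$classes[[cl]])
  }
  n_shared <- sum(tokens %in% lexicon$shared)
  if (n_shared > 0) {
    hits[confusable_triple()] <- hits[confusable_triple()] + n_shared
  }
  hits
}

#' Keyword-count oracle classifier
#'
#' Classifies each text by the argmax of its per-class lexicon hit counts
#' (shared-pool tokens counting for all three confusable classes), ties
#' broken by canonical class order. This trivial classifier is the
#' independent reference for the generator's confusability structure: with
#' `overlap = 0` and `noise_rate = 0` it is perfect, and as `overlap` grows
#' its errors concentrate within the major/atypical/bipolar block.
#'
#' @param x A [corpus()] produced by [generate_corpus()] (or any corpus).
#' @param lexicon The [build_lexicon()] used to generate `x`; defaults to
#'   `attr(x, "lexicon")`.
#' @return Character vector of predicted class names.
#' @export
keyword_classify <- function(x, lexicon = attr(x, "lexicon")) {
  if (is.null(lexicon)) stop("no lexicon supplied or attached", call. = FALSE)
  vapply(x$text, function(txt) {
    hits <- lexicon_hits(strsplit(txt, " ", fixed = TRUE)[[1]], lexicon)
    subtype_labels()[which.max(hits)]
  }, character(1), USE.NAMES = FALSE)
}

#' Build a deterministic mock option-letter scorer
#'
#' Returns a scorer conforming to the prompting module's next-token-scorer
#' contract: `function(prompt_text, candidates)` returning one finite
#' log-probability per candidate string. The mock extracts the target tweet
#' from the rendered prompt (the final "Tweet: ..." line), scores each option
#' letter as `sharpness` times the lexicon-hit count of that letter's class,
#' adds a small deterministic perturbation derived from the seed and the
#' prompt text (so distinct prompt realizations perturb differently while the
#' same prompt always scores identically), and log-normalizes over the six
#' letters. It is a desk-scale stand-in for a causal language model exposing
#' next-token probabilities for the option letters.
#'
#' @param lexicon A [build_lexicon()].
#' @param sharpness Non-negative scale on the lexicon-hit signal; 0 leaves
#'   only the seeded perturbation.
#' @param seed Integer seed for the perturbation.
#' @return A scorer function.
#' @export
make_mock_scorer <- function(lexicon, sharpness = 2.0, seed = 1L) {
  stopifnot(sharpness >= 0)
  force(lexicon); force(seed)
  function(prompt_text, candidates) {
    m <- regmatches(prompt_text,
                    gregexpr("(^|\n)Tweet: ([^\n]*)", prompt_text))[[1]]
    if (length(m) == 0) {
      stop("prompt has no parseable 'Tweet:' target line", call. = FALSE)
    }
    target <- sub("^\n?Tweet: ", "", m[length(m)])
    hits <- lexicon_hits(strsplit(target, " ", fixed = TRUE)[[1]], lexicon)
    perturb <- with_local_seed(mix_seed(seed, string_hash(prompt_text)),
                               stats::runif(6, -0.05, 0.05))
    raw <- stats::setNames(sharpness * hits + perturb, names(subtype_letters()))
    logp <- log_softmax(unname(raw))
    names(logp) <- unname(subtype_letters())  # letters A-F
    vapply(candidates, function(cand) {
      letter <- trimws(cand)
      if (!letter %in% names(logp)) {
        # non-letter continuations get negligible probability
        return(-50)
      }
      unname(logp[letter])
    }, numeric(1), USE.NAMES = FALSE)
  }
}
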