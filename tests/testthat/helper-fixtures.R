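# Shared fixtures built in code at test time.

# Small hand-written corpus with n texts per class, optionally dirty
# (URLs/@mentions) for exemplar-filter tests.
tiny_corpus <- function(n_per_class = 4) {
  labs <- subtype_labels()
  text <- unlist(lapply(labs, function(cl) {
    sprintf("%s tweet number %d about topic %s", cl, seq_len(n_per_class), cl)
  }))
  corpus(text, rep(labs, each = n_per_class))
}

# Separable synthetic corpus: disjoint class vocabularies, no noise.
separable_corpus <- function(n_total = 200, seed = 11, url_rate = 0.1) {
  generate_corpus(generator_config(
    n_total = n_total, overlap = 0, noise_rate = 0,
    url_mention_rate = url_rate, seed = seed
  ))
}

# Round-half-up at one decimal on the percentage scale, the convention for
# comparing against printed percentages.
pct1 <- function(x) floor(x * 10 + 0.5) / 10

# Independent textbook implementation of the metrics, used as the oracle
# against macro_metrics()/per_class_metrics(). Deliberately written from the
# formula definitions, not via the package's code paths.
oracle_metrics <- function(true, pred) {
  classes <- subtype_labels()
  prec <- rec <- f1 <- numeric(6)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(precision = prec, recall = rec, f1 = f1,
       macro_f1 = mean(f1), macro_precision = mean(prec),
       macro_recall = mean(rec), accuracy = mean(true == pred))
}

# Brute-force largest-remainder apportionment oracle.
oracle_apportion <- function(n_total, prop) {
  prop <- prop / sum(prop)
  quota <- n_total * prop
  base <- floor(quota)
  frac <- quota - base
  need <- n_total - sum(base)
  if (need > 0) {
    ord <- order(-frac, seq_along(frac))
    for (j in ord[seq_len(need)]) base[j] <- base[j] + 1
  }
  as.integer(base)
}

# Scripted scorer: returns pre-set letter log-scores call by call (used to
# construct exact vote tallies). Scores are recycled if calls exceed rows.
scripted_scorer <- function(score_matrix) {
  call_i <- 0L
  function(prompt_text, candidates) {
    call_i <<- call_i + 1L
    row <- score_matrix[(call_i - 1L) %% nrow(score_matrix) + 1L, ]
    logp <- row - max(row) - log(sum(exp(row - max(row))))
    vapply(candidates, function(cand) {
      letter <- trimws(cand)
      i <- match(letter, names(subtype_labels()))
      if (is.na(i)) -50 else logp[i]
    }, numeric(1), USE.NAMES = FALSE)
  }
}
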