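# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Unicode NFC + collapse internal whitespace runs + strip ends. This is the
# whole normalization: no negation/sarcasm handling, no lowercasing.
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

# Deterministic small non-negative integer hash of a string (for mixing text
# into seeds). Polynomial rolling hash mod 2^31 - 1.
string_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  m <- 2147483647
  for (cc in codes) h <- (h * 31 + cc) %% m
  as.integer(h)
}

# Mix several integer components into one valid 32-bit seed.
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 0
  m <- 2147483647
  for (p in parts) h <- (h * 69069 + (p %% m)) %% m
  as.integer(h)
}

# Numerically stable log(sum(exp(x))).
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Stable softmax / log-softmax for a numeric vector.
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

log_softmax <- function(x) x - log_sum_exp(x)

# Row-wise softmax for a matrix of logits.
softmax_rows <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# Largest-remainder apportionment of n_total into length(prop) integer counts
# proportional to prop (renormalized). Ties in fractional part are broken by
# position (canonical class order).
largest_remainder <- function(n_total, prop) {
  stopifnot(n_total >= 0, all(prop > 0))
  prop <- prop / sum(prop)
  quota <- n_total * prop
  base <- floor(quota)
  rem <- n_total - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order by descending fractional part, ties by position
    idx <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
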