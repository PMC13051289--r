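#' Hyperparameters of the composite training objective
#'
#' Defaults are the study's settings: class-balance `beta = 0.999`, focal
#' exponent `gamma = 2`, margin scale `c0 = 0.5`, pairwise margin
#' `delta = 0.15`, and mixing weights `lambda_rdrop = 0.5`,
#' `lambda_pair = 0.15`.
#'
#' @param beta Class-balanced weighting hyperparameter in \[0, 1).
#' @param gamma Focal exponent (>= 0); 0 recovers plain cross-entropy.
#' @param c0 LDAM margin scale (> 0); margins are `c0 * n_c^(-1/4)`.
#' @param delta Pairwise hinge margin (>= 0) for bipolar-labeled examples.
#' @param lambda_rdrop Weight of the R-Drop symmetric-KL term (>= 0).
#' @param lambda_pair Weight of the pairwise margin penalty (>= 0).
#' @return A `loss_config` list.
#' @export
loss_config <- function(beta = 0.999, gamma = 2.0, c0 = 0.5, delta = 0.15,
                        lambda_rdrop = 0.5, lambda_pair = 0.15) {
  stopifnot(beta >= 0, beta < 1, gamma >= 0, c0 > 0, delta >= 0,
            lambda_rdrop >= 0, lambda_pair >= 0)
  structure(list(beta = beta, gamma = gamma, c0 = c0, delta = delta,
                 lambda_rdrop = lambda_rdrop, lambda_pair = lambda_pair),
            class = "loss_config")
}

#' Class-balanced loss weights from class counts
#'
#' Implements the effective-number-of-samples estimator: the raw weight of
#' class c is `(1 - beta) / (1 - beta^n_c)`, then weights are normalized by
#' their across-class mean so they average exactly 1. `beta^n_c` is computed
#' as `exp(n_c * log(beta))` so large counts do not underflow the
#' intermediate power.
#'
#' @param counts Six positive integer class counts (canonical order).
#' @param beta Class-balance hyperparameter in \[0, 1).
#' @return Named numeric vector of six weights with mean 1.
#' @examples
#' class_balanced_weights(rep(100, 6), beta = 0.999)  # all 1
#' @export
class_balanced_weights <- function(counts, beta = 0.999) {
  counts <- as.numeric(counts)
  if (any(counts < 1)) {
    stop("class-balanced weight undefined for zero-count class(es): ",
         paste(which(counts < 1), collapse = ", "), call. = FALSE)
  }
  stopifnot(beta >= 0, beta < 1)
  raw <- if (beta == 0) rep(1, length(counts)) else {
    (1 - beta) / (1 - exp(counts * log(beta)))
  }
  w <- raw / mean(raw)
  if (length(w) == 6) names(w) <- subtype_labels()
  w
}

#' Label-distribution-aware margins from class counts
#'
#' The margin of class c is `c0 * n_c^(-1/4)`: rarer classes get larger
#' margins. This is the printed form, without the original LDAM formulation's
#' normalization by the maximum margin.
#'
#' @param counts Six positive integer class counts (canonical order).
#' @param c0 Margin scale (> 0), default 0.5.
#' @return Named numeric vector of six positive margins, strictly decreasing
#'   in the counts.
#' @examples
#' ldam_margins(c(16, 625, 16, 16, 16, 16))  # 0.25 and 0.10
#' @export
ldam_margins <- function(counts, c0 = 0.5) {
  counts <- as.numeric(counts)
  if (any(counts < 1)) {
    stop("LDAM margin undefined for zero-count class(es): ",
         paste(which(counts < 1), collapse = ", "), call. = FALSE)
  }
  stopifnot(c0 > 0)
  m <- c0 * counts^(-1 / 4)
  if (length(m) == 6) names(m) <- subtype_labels()
  m
}

#' Per-class statistics driving the imbalance-aware loss
#'
#' Bundles the training-split class counts with their class-balanced weights
#' and LDAM margins. Counts must come from the TRAINING split only, so no
#' frequency information leaks from validation or test.
#'
#' @param counts Six positive integer class counts, or a [corpus()] (counted
#'   via [class_counts()]).
#' @param config A [loss_config()] supplying `beta` and `c0`.
#' @return A `class_stats` list with `counts`, `weights`, `margins`.
#' @export
class_stats <- function(counts, config = loss_config()) {
  if (inherits(counts, "subtype_corpus")) counts <- class_counts(counts)
  stopifnot(length(counts) == 6)
  structure(
    list(
      counts = stats::setNames(as.integer(counts), subtype_labels()),
      weights = class_balanced_weights(counts, config$beta),
      margins = ldam_margins(counts, config$c0)
    ),
    class = "class_stats"
  )
}

# Resolve a label given as class name, option letter, or index 1..6 to an
# index into the canonical order.
label_index <- function(label) {
  if (is.numeric(label)) {
    stopifnot(label >= 1, label <= 6)
    return(as.integer(label))
  }
  label <- as.character(label)
  if (label %in% names(subtype_labels())) label <- letter_to_label(label)
  idx <- match(label, subtype_labels())
  if (is.na(idx)) stop("unknown label: ", label, call. = FALSE)
  idx
}

#' Class-balanced focal loss with an LDAM margin shift
#'
#' Subtracts the true class's margin from the true-class logit only, takes a
#' numerically stable softmax of the shifted logits, and returns the
#' class-weighted focal cross-entropy
#' `w_y * (1 - p_y)^gamma * (-log p_y)`. With `gamma = 0` and unit weights
#' this is margin-shifted cross-entropy.
#'
#' @param logits Numeric vector of six finite logits (canonical order).
#' @param label True class (name, letter, or index).
#' @param stats A [class_stats()].
#' @param config A [loss_config()].
#' @return Non-negative scalar loss.
#' @export
focal_ldam_loss <- function(logits, label, stats, config = loss_config()) {
  stopifnot(length(logits) == 6, all(is.finite(logits)))
  y <- label_index(label)
  z <- as.numeric(logits)
  z[y] <- z[y] - stats$margins[[y]]
  log_p <- log_softmax(z)
  log_py <- log_p[y]
  py <- exp(log_py)
  stats$weights[[y]] * (1 - py)^config$gamma * (-log_py)
}

# Gradient of focal_ldam_loss w.r.t. the (unshifted) logits.
focal_ldam_grad <- function(logits, label, stats, config = loss_config()) {
  y <- label_index(label)
  z <- as.numeric(logits)
  z[y] <- z[y] - stats$margins[[y]]
  p <- softmax(z)
  py <- p[y]
  log_py <- log(max(py, 1e-300))
  g <- config$gamma
  # dL/d log_py, with L = w * (1 - py)^g * (-log_py)
  dL_dlogpy <- stats$weights[[y]] *
    (g * (1 - py)^(max(g - 1, 0)) * py * log_py - (1 - py)^g)
  onehot <- numeric(6); onehot[y] <- 1
  dL_dlogpy * (onehot - p)
}

#' R-Drop consistency penalty (symmetric KL divergence)
#'
#' `0.5 * (KL(p1 || p2) + KL(p2 || p1))` between the predictive distributions
#' of two dropout-perturbed forward passes of the same input. Probabilities
#' are clipped below at 1e-12 before taking logs, so near-one-hot softmax
#' outputs are safe.
#'
#' @param p1,p2 Probability vectors of length six, each summing to 1 within
#'   1e-6.
#' @return Non-negative scalar; 0 iff the distributions coincide.
#' @export
rdrop_loss <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  if (any(p1 < 0) || any(p2 < 0) ||
      abs(sum(p1) - 1) > 1e-6 || abs(sum(p2) - 1) > 1e-6) {
    stop("rdrop_loss expects non-negative probability vectors summing to 1",
         call. = FALSE)
  }
  q1 <- pmax(p1, 1e-12)
  q2 <- pmax(p2, 1e-12)
  kl12 <- sum(q1 * (log(q1) - log(q2)))
  kl21 <- sum(q2 * (log(q2) - log(q1)))
  0.5 * (kl12 + kl21)
}

# Gradients of the symmetric KL w.r.t. the two logit vectors (probabilities
# computed internally, no clipping — callers keep logits finite).
rdrop_grad <- function(z1, z2) {
  p1 <- softmax(z1)
  p2 <- softmax(z2)
  lr <- log(pmax(p1, 1e-12)) - log(pmax(p2, 1e-12))
  kl12 <- sum(p1 * lr)
  kl21 <- -sum(p2 * lr)
  g1 <- 0.5 * (p1 * (lr - kl12) + (p1 - p2))
  g2 <- 0.5 * (p2 * (-lr - kl21) + (p2 - p1))
  list(g1 = g1, g2 = g2)
}

#' Targeted pairwise margin penalty for the bipolar class
#'
#' On bipolar-labeled examples only, two hinge terms push the bipolar logit
#' at least `delta` above the no-depression and atypical logits:
#' `max(0, delta - (z_bipolar - z_no)) + max(0, delta - (z_bipolar - z_atypical))`.
#' For any other label the penalty is zero.
#'
#' @param logits Numeric vector of six finite logits (canonical order).
#' @param label True class (name, letter, or index).
#' @param delta Hinge margin (default 0.15).
#' @return Non-negative scalar.
#' @export
pairwise_margin_penalty <- function(logits, label, delta = 0.15) {
  stopifnot(length(logits) == 6, all(is.finite(logits)), delta >= 0)
  if (label_index(label) != label_index("bipolar")) return(0)
  zb <- logits[label_index("bipolar")]
  zn <- logits[label_index("no_depression")]
  za <- logits[label_index("atypical")]
  max(0, delta - (zb - zn)) + max(0, delta - (zb - za))
}

pairwise_margin_grad <- function(logits, label, delta = 0.15) {
  g <- numeric(6)
  if (label_index(label) != label_index("bipolar")) return(g)
  ib <- label_index("bipolar")
  for (other in c("no_depression", "atypical")) {
    io <- label_index(other)
    if (delta - (logits[ib] - logits[io]) > 0) {
      g[ib] <- g[ib] - 1
      g[io] <- g[io] + 1
    }
  }
  g
}

#' Bundle two stochastic forward-pass logit vectors for one example
#'
#' @param z1,z2 Six finite logits from two dropout-perturbed forward passes
#'   of the same input.
#' @param label True class (name, letter, or index).
#' @return A `dual_pass_logits` list.
#' @export
dual_pass_logits <- function(z1, z2, label) {
  stopifnot(length(z1) == 6, length(z2) == 6,
            all(is.finite(z1)), all(is.finite(z2)))
  structure(list(z1 = as.numeric(z1), z2 = as.numeric(z2),
                 label = label_index(label)),
            class = "dual_pass_logits")
}

#' Total composite training loss for a batch
#'
#' Per example:
#' `0.5 * (focal_ldam(z1) + focal_ldam(z2))
#'  + lambda_rdrop * rdrop(softmax(z1), softmax(z2))
#'  + lambda_pair * 0.5 * (pair(z1) + pair(z2))`,
#' reduced by the mean over the batch. The pairwise penalty is averaged over
#' both stochastic passes, mirroring the focal term's treatment; the batch
#' reduction is the mean so the effective learning rate does not scale with
#' batch size.
#'
#' @param batch Non-empty list of [dual_pass_logits()].
#' @param stats A [class_stats()] computed from the training split.
#' @param config A [loss_config()].
#' @return Non-negative scalar loss.
#' @export
total_loss <- function(batch, stats, config = loss_config()) {
  if (length(batch) == 0) stop("empty batch", call. = FALSE)
  per <- vapply(batch, function(ex) {
    focal <- 0.5 * (focal_ldam_loss(ex$z1, ex$label, stats, config) +
                    focal_ldam_loss(ex$z2, ex$label, stats, config))
    rd <- config$lambda_rdrop *
      rdrop_loss(softmax(ex$z1), softmax(ex$z2))
    pr <- config$lambda_pair * 0.5 *
      (pairwise_margin_penalty(ex$z1, ex$label, config$delta) +
       pairwise_margin_penalty(ex$z2, ex$label, config$delta))
    focal + rd + pr
  }, numeric(1))
  mean(per)
}

#' Analytic gradient of [total_loss()] with respect to the logits
#'
#' Returns per-example gradients of the batch-mean total loss with respect to
#' `z1` and `z2` (each a list of six-vectors). Used by the fixture trainer
#' and checkable against central finite differences.
#'
#' @inheritParams total_loss
#' @return List with `g1` and `g2`, each a list of numeric six-vectors.
#' @export
total_loss_grad <- function(batch, stats, config = loss_config()) {
  if (length(batch) == 0) stop("empty batch", call. = FALSE)
  n <- length(batch)
  g1 <- vector("list", n)
  g2 <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- batch[[i]]
    rd <- rdrop_grad(ex$z1, ex$z2)
    g1[[i]] <- (0.5 * focal_ldam_grad(ex$z1, ex$label, stats, config) +
                config$lambda_rdrop * rd$g1 +
                config$lambda_pair * 0.5 *
                  pairwise_margin_grad(ex$z1, ex$label, config$delta)) / n
    g2[[i]] <- (0.5 * focal_ldam_grad(ex$z2, ex$label, stats, config) +
                config$lambda_rdrop * rd$g2 +
                config$lambda_pair * 0.5 *
                  pairwise_margin_grad(ex$z2, ex$label, config$delta)) / n
  }
  list(g1 = g1, g2 = g2)
}
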