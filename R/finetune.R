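#' LoRA adapter specification
#'
#' Low-rank adapters are injected into frozen projection layers; only the
#' rank-decomposed updates (and the classifier head) train. Defaults are the
#' study's settings: rank 8, scaling alpha 16, adapter dropout 0.05.
#'
#' @param rank Adapter rank r (>= 1).
#' @param alpha Scaling factor; the update is `(alpha / rank) * B %*% A`.
#' @param dropout Adapter dropout fraction in \[0, 1).
#' @param target_modules Names of the projection layers to adapt; resolved
#'   from the encoder family via [resolve_target_modules()] when `NULL`.
#' @return A `lora_spec` list.
#' @export
lora_spec <- function(rank = 8L, alpha = 16, dropout = 0.05,
                      target_modules = NULL) {
  stopifnot(rank >= 1, dropout >= 0, dropout < 1, alpha > 0)
  structure(list(rank = as.integer(rank), alpha = alpha, dropout = dropout,
                 target_modules = target_modules),
            class = "lora_spec")
}

#' Optimization and early-stopping configuration
#'
#' Defaults are the study's recipe: AdamW at learning rate 2e-4 on the
#' classifier head and LoRA parameters, decoupled weight decay 0.03, cosine
#' schedule with linear warm-up over the first 6% of steps, gradient-norm
#' clipping at 1.0, batch size 16, up to 10 epochs with early stopping on
#' validation macro-F1 (patience 2, improvement threshold 5e-4), inputs
#' truncated to 160 tokens.
#'
#' @param learning_rate Peak learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param warmup_ratio Fraction of total steps used for linear warm-up.
#' @param grad_clip Global gradient-norm ceiling.
#' @param batch_size Examples per optimization step.
#' @param max_epochs Epoch budget.
#' @param patience Epochs without sufficient improvement before stopping.
#' @param min_delta Minimum validation macro-F1 improvement that counts.
#' @param max_length Token truncation length (including special tokens).
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, weight_decay = 0.03,
                         warmup_ratio = 0.06, grad_clip = 1.0,
                         batch_size = 16L, max_epochs = 10L, patience = 2L,
                         min_delta = 5e-4, max_length = 160L, seed = 42L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, warmup_ratio >= 0,
            warmup_ratio < 1, grad_clip > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, min_delta >= 0, max_length >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 warmup_ratio = warmup_ratio, grad_clip = grad_clip,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 max_length = as.integer(max_length), seed = as.integer(seed)),
            class = "train_config")
}

#' Resolve the LoRA target projection layers for an encoder family
#'
#' DeBERTa variants expose attention projections named `query_proj`,
#' `key_proj`, `value_proj`, `dense`; other supported encoder families use
#' `query`, `key`, `value` plus the two feed-forward projections.
#'
#' @param family Encoder family or checkpoint name (matched
#'   case-insensitively on its family substring).
#' @return Character vector of projection-layer names.
#' @examples
#' resolve_target_modules("deberta-v3-large")
#' resolve_target_modules("roberta-large")
#' @export
resolve_target_modules <- function(family) {
  f <- tolower(family)
  known <- c("deberta", "roberta", "bertweet", "xlm-roberta", "mpnet",
             "albert", "bert", "fixture")
  if (grepl("deberta", f)) {
    return(c("query_proj", "key_proj", "value_proj", "dense"))
  }
  if (any(vapply(known, grepl, logical(1), x = f, fixed = TRUE))) {
    return(c("query", "key", "value", "ffn_in", "ffn_out"))
  }
  stop("unknown encoder family '", family, "'; known families: ",
       paste(known, collapse = ", "), call. = FALSE)
}

#' Learning rate at a given optimization step
#'
#' Linear warm-up from 0 to the peak rate over the first
#' `ceil(warmup_ratio * total_steps)` steps, then cosine decay to 0 at
#' `total_steps`.
#'
#' @param step Step index in `0..total_steps`.
#' @param total_steps Total planned steps (>= 1).
#' @param config A [train_config()].
#' @return Learning rate at `step`.
#' @export
lr_at_step <- function(step, total_steps, config = train_config()) {
  stopifnot(step >= 0, step <= total_steps, total_steps >= 1)
  warm <- ceiling(config$warmup_ratio * total_steps)
  if (step <= warm && warm > 0) {
    return(config$learning_rate * step / warm)
  }
  if (total_steps == warm) return(config$learning_rate)
  prog <- (step - warm) / (total_steps - warm)
  config$learning_rate * 0.5 * (1 + cos(pi * prog))
}

#' Initialize an early-stopping training state
#'
#' @return A `train_state` list: `epoch`, `best` (best validation macro-F1),
#'   `best_epoch`, `since_improvement`, `stopped`, `history` (data frame of
#'   epoch, train_loss, val_macro_f1).
#' @export
train_state <- function() {
  structure(
    list(epoch = 0L, best = -Inf, best_epoch = 0L, since_improvement = 0L,
         stopped = FALSE,
         history = data.frame(epoch = integer(), train_loss = numeric(),
                              val_macro_f1 = numeric())),
    class = "train_state"
  )
}

#' Apply one epoch's validation result to the early-stopping state
#'
#' Improvement means `val_macro_f1 >= best + min_delta`; on improvement the
#' best value and epoch update and the patience counter resets, otherwise the
#' counter increments and `stopped` is set once it reaches `patience`.
#'
#' @param state A [train_state()].
#' @param val_macro_f1 Validation macro-F1 in \[0, 1\].
#' @param config A [train_config()] (supplies `patience`, `min_delta`).
#' @param train_loss Optional train loss recorded into the history.
#' @return Updated `train_state`.
#' @export
early_stopping_update <- function(state, val_macro_f1, config = train_config(),
                                  train_loss = NA_real_) {
  stopifnot(val_macro_f1 >= 0, val_macro_f1 <= 1)
  state$epoch <- state$epoch + 1L
  if (val_macro_f1 >= state$best + config$min_delta) {
    state$best <- val_macro_f1
    state$best_epoch <- state$epoch
    state$since_improvement <- 0L
  } else {
    state$since_improvement <- state$since_improvement + 1L
    if (state$since_improvement >= config$patience) state$stopped <- TRUE
  }
  state$history <- rbind(
    state$history,
    data.frame(epoch = state$epoch, train_loss = train_loss,
               val_macro_f1 = val_macro_f1)
  )
  state
}

#' Desk-scale fixture encoder implementing the trainable-encoder contract
#'
#' A deterministic stand-in for a pretrained backbone, small enough that the
#' full fine-tuning recipe runs in seconds: texts are tokenized on
#' whitespace, head-truncated to `max_length`, hashed into a bag-of-buckets
#' feature vector, and passed through a frozen random projection (the
#' "backbone"). Training touches only the LoRA adapters injected into that
#' projection and the linear classifier head. Dropout on the hidden
#' representation provides the stochastic forward passes required by R-Drop
#' and MC-dropout.
#'
#' @param d_feat Hashed-feature dimension.
#' @param d_hidden Hidden (projection output) dimension.
#' @param dropout Hidden-representation dropout rate during training.
#' @param seed Seed for the frozen projection weights.
#' @return A `fixture_encoder` list.
#' @export
fixture_encoder <- function(d_feat = 1024L, d_hidden = 192L, dropout = 0.1,
                            seed = 42L) {
  stopifnot(d_feat >= 8, d_hidden >= 6, dropout >= 0, dropout < 1)
  W0 <- with_local_seed(mix_seed(seed, 7L), {
    matrix(stats::rnorm(d_hidden * d_feat, sd = 1 / sqrt(d_feat)),
           nrow = d_hidden, ncol = d_feat)
  })
  structure(
    list(family = "fixture", d_feat = as.integer(d_feat),
         d_hidden = as.integer(d_hidden), dropout = dropout, W0 = W0,
         lora = NULL,
         head_W = matrix(0, nrow = 6, ncol = d_hidden), head_b = numeric(6)),
    class = "fixture_encoder"
  )
}

#' Inject LoRA adapters into the fixture encoder's frozen projection
#'
#' Adds trainable factors `A` (rank x d_feat, small Gaussian init) and `B`
#' (d_hidden x rank, zero init, so training starts from the frozen backbone's
#' behaviour); the effective projection is `W0 + (alpha / rank) * B %*% A`.
#' Base weights stay frozen.
#'
#' @param encoder A [fixture_encoder()].
#' @param spec A [lora_spec()].
#' @param seed Seed for the `A` initialization.
#' @return The encoder with adapters attached.
#' @export
inject_lora <- function(encoder, spec = lora_spec(), seed = 42L) {
  stopifnot(inherits(encoder, "fixture_encoder"))
  targets <- spec$target_modules %||% resolve_target_modules(encoder$family)
  A <- with_local_seed(mix_seed(seed, 11L), {
    matrix(stats::rnorm(spec$rank * encoder$d_feat, sd = 0.02),
           nrow = spec$rank, ncol = encoder$d_feat)
  })
  encoder$lora <- list(
    A = A,
    B = matrix(0, nrow = encoder$d_hidden, ncol = spec$rank),
    rank = spec$rank, alpha = spec$alpha, dropout = spec$dropout,
    target_modules = targets
  )
  encoder
}

#' Count trainable and frozen parameters of the fixture encoder
#'
#' Under LoRA the trainable values are `rank * (d_feat + d_hidden)` for the
#' adapted projection plus the classifier head; the frozen base
#' (`d_hidden * d_feat`) does not train.
#'
#' @param encoder A [fixture_encoder()] (with or without adapters).
#' @return Named list `trainable`, `frozen`.
#' @export
parameter_counts <- function(encoder) {
  head_n <- length(encoder$head_W) + length(encoder$head_b)
  lora_n <- if (is.null(encoder$lora)) 0L else {
    length(encoder$lora$A) + length(encoder$lora$B)
  }
  list(trainable = head_n + lora_n, frozen = length(encoder$W0))
}

# Tokenize on whitespace, head-truncate to max_length tokens, hash into a
# bag-of-buckets vector, L2-normalize.
featurize <- function(encoder, texts, max_length = 160L) {
  X <- matrix(0, nrow = length(texts), ncol = encoder$d_feat)
  for (i in seq_along(texts)) {
    toks <- strsplit(texts[i], " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) > max_length) toks <- toks[seq_len(max_length)]
    buckets <- vapply(toks, function(t) string_hash(t) %% encoder$d_feat + 1L,
                      integer(1))
    x <- tabulate(buckets, nbins = encoder$d_feat)
    nrm <- sqrt(sum(x^2))
    if (nrm > 0) X[i, ] <- x / nrm
  }
  X
}

effective_projection <- function(encoder) {
  W <- encoder$W0
  if (!is.null(encoder$lora)) {
    W <- W + (encoder$lora$alpha / encoder$lora$rank) *
      (encoder$lora$B %*% encoder$lora$A)
  }
  W
}

# One forward pass. training=TRUE samples a dropout mask from the current RNG
# stream (callers seed it); training=FALSE is deterministic.
enc_forward <- function(encoder, X, training = FALSE) {
  H <- X %*% t(effective_projection(encoder))
  mask <- NULL
  Hd <- H
  p <- encoder$dropout
  if (training && p > 0) {
    mask <- matrix(stats::rbinom(length(H), 1L, 1 - p), nrow = nrow(H))
    Hd <- H * mask / (1 - p)
  }
  Z <- Hd %*% t(encoder$head_W) +
    matrix(encoder$head_b, nrow = nrow(X), ncol = 6, byrow = TRUE)
  list(Z = Z, Hd = Hd, mask = mask, X = X)
}

# Backpropagate dZ (n x 6) through one cached forward pass; returns gradients
# for the trainable parameters only (base projection is frozen).
enc_backward <- function(encoder, cache, dZ) {
  d_head_W <- t(dZ) %*% cache$Hd
  d_head_b <- colSums(dZ)
  dHd <- dZ %*% encoder$head_W
  dH <- if (is.null(cache$mask)) dHd else {
    dHd * cache$mask / (1 - encoder$dropout)
  }
  dWeff <- t(dH) %*% cache$X
  scale <- encoder$lora$alpha / encoder$lora$rank
  list(
    head_W = d_head_W,
    head_b = d_head_b,
    A = scale * (t(encoder$lora$B) %*% dWeff),
    B = scale * (dWeff %*% t(encoder$lora$A))
  )
}

get_params <- function(encoder) {
  list(head_W = encoder$head_W, head_b = encoder$head_b,
       A = encoder$lora$A, B = encoder$lora$B)
}

set_params <- function(encoder, params) {
  encoder$head_W <- params$head_W
  encoder$head_b <- params$head_b
  encoder$lora$A <- params$A
  encoder$lora$B <- params$B
  encoder
}

#' Fine-tune an encoder with the LoRA recipe and the composite loss
#'
#' Runs the full supervised-adaptation recipe at desk scale: LoRA injection
#' with frozen base weights, AdamW with decoupled weight decay, linear
#' warm-up + cosine decay, global gradient-norm clipping, two stochastic
#' (dropout-perturbed) forward passes per batch feeding [total_loss()], a
#' deterministic validation pass per epoch scored by macro-F1, early stopping
#' with patience, and restoration of the best epoch's weights. Class
#' statistics for the loss come from the training split only. Deterministic
#' given `train_cfg$seed`.
#'
#' @param encoder A [fixture_encoder()] (adapters are injected if absent).
#' @param splits A `split_bundle` from [stratified_split()].
#' @param lora A [lora_spec()].
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()]. With `lambda_rdrop = 0` the second
#'   stochastic pass still runs but contributes no consistency term.
#' @return List with `encoder` (best-epoch weights) and `state`
#'   (a `train_state` with the epoch history).
#' @export
fit <- function(encoder, splits, lora = lora_spec(),
                train_cfg = train_config(), loss_cfg = loss_config()) {
  stopifnot(inherits(encoder, "fixture_encoder"))
  stats_cls <- class_stats(class_counts(splits$train), loss_cfg)
  if (any(stats_cls$counts == 0)) {
    stop("training split has empty class(es); the loss weights are undefined",
         call. = FALSE)
  }
  X_train <- featurize(encoder, splits$train$text, train_cfg$max_length)
  y_train <- as.integer(splits$train$label)
  X_val <- featurize(encoder, splits$validation$text, train_cfg$max_length)

  n <- nrow(X_train)
  n_batches <- ceiling(n / train_cfg$batch_size)
  total_steps <- train_cfg$max_epochs * n_batches

  state <- train_state()
  best_params <- NULL

  with_local_seed(train_cfg$seed, {
    encoder <- inject_lora(encoder, lora,
                           seed = mix_seed(train_cfg$seed, 3L))
    params <- get_params(encoder)
    opt <- adamw_init(params)
    step <- 0L
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(n)
      epoch_losses <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        idx <- ord[((b - 1L) * train_cfg$batch_size + 1L):
                     min(b * train_cfg$batch_size, n)]
        Xb <- X_train[idx, , drop = FALSE]
        yb <- y_train[idx]
        f1p <- enc_forward(encoder, Xb, training = TRUE)
        f2p <- enc_forward(encoder, Xb, training = TRUE)
        batch <- lapply(seq_along(idx), function(i) {
          dual_pass_logits(f1p$Z[i, ], f2p$Z[i, ], yb[i])
        })
        epoch_losses[b] <- total_loss(batch, stats_cls, loss_cfg)
        g <- total_loss_grad(batch, stats_cls, loss_cfg)
        dZ1 <- do.call(rbind, g$g1)
        dZ2 <- do.call(rbind, g$g2)
        gr1 <- enc_backward(encoder, f1p, dZ1)
        gr2 <- enc_backward(encoder, f2p, dZ2)
        grads <- Map(`+`, gr1, gr2)
        grads <- clip_global_norm(grads, train_cfg$grad_clip)
        step <- step + 1L
        lr <- lr_at_step(step, total_steps, train_cfg)
        upd <- adamw_step(opt, params, grads, lr, train_cfg$weight_decay)
        opt <- upd$opt
        params <- upd$params
        encoder <- set_params(encoder, params)
      }
      val_pred <- subtype_labels()[
        max.col(enc_forward(encoder, X_val, training = FALSE)$Z,
                ties.method = "first")]
      val_f1 <- macro_metrics(
        confusion_matrix(as.character(splits$validation$label), val_pred)
      )$macro_f1
      prev_best_epoch <- state$best_epoch
      state <- early_stopping_update(state, val_f1, train_cfg,
                                     train_loss = mean(epoch_losses))
      if (state$best_epoch > prev_best_epoch) best_params <- params
      if (state$stopped) break
    }
  })
  if (!is.null(best_params)) encoder <- set_params(encoder, best_params)
  list(encoder = encoder, state = state)
}

#' Predict class logits, optionally averaging MC-dropout passes
#'
#' With `mc_dropout_passes = 1` this is a single deterministic forward pass
#' (dropout disabled); with more passes it is the mean of that many
#' dropout-active stochastic passes, which feeds the same argmax decoding
#' rule.
#'
#' @param encoder A trained [fixture_encoder()].
#' @param x Corpus to score.
#' @param mc_dropout_passes Number of stochastic passes (>= 1).
#' @param max_length Truncation length.
#' @param seed Seed for the stochastic passes (ignored when passes = 1).
#' @return Numeric n x 6 matrix of logits (canonical class order).
#' @export
predict_logits <- function(encoder, x, mc_dropout_passes = 1L,
                           max_length = 160L, seed = 1L) {
  stopifnot(mc_dropout_passes >= 1)
  X <- featurize(encoder, x$text, max_length)
  if (mc_dropout_passes == 1) {
    return(enc_forward(encoder, X, training = FALSE)$Z)
  }
  with_local_seed(seed, {
    acc <- matrix(0, nrow = nrow(X), ncol = 6)
    for (p in seq_len(mc_dropout_passes)) {
      acc <- acc + enc_forward(encoder, X, training = TRUE)$Z
    }
    acc / mc_dropout_passes
  })
}

#' Decode class predictions from logits
#'
#' @param logits n x 6 logit matrix from [predict_logits()].
#' @return Character vector of predicted class names (argmax, ties to the
#'   first class in canonical order).
#' @export
decode_predictions <- function(logits) {
  unname(subtype_labels()[max.col(logits, ties.method = "first")])
}

# --- AdamW -------------------------------------------------------------

adamw_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
}

adamw_step <- function(opt, params, grads, lr, weight_decay) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * grads[[nm]]
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + opt$eps) + weight_decay * params[[nm]])
  }
  list(opt = opt, params = params)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}
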