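test_that("class-balanced weights normalize to mean 1 and match direct evaluation", {
  w_eq <- class_balanced_weights(rep(250, 6), beta = 0.999)
  expect_equal(unname(w_eq), rep(1, 6), tolerance = 1e-12)

  # direct high-precision evaluation of the two raw terms and their mean
  counts <- c(10, 1000)
  beta <- 0.999
  raw <- (1 - beta) / (1 - beta^counts)
  expected <- raw / mean(raw)
  got <- class_balanced_weights(counts, beta)
  expect_equal(unname(got), expected, tolerance = 1e-12)
  expect_equal(unname(got), c(1.969, 0.031), tolerance = 1e-3)

  # beta -> 0 limit: all raws 1
  expect_equal(unname(class_balanced_weights(c(3, 9, 81, 7, 2, 500), 0)),
               rep(1, 6))

  for (cts in list(c(5, 50, 500, 5000, 17, 3), rep(7, 6), c(1, 2, 3, 4, 5, 6))) {
    expect_equal(mean(class_balanced_weights(cts, 0.999)), 1, tolerance = 1e-9)
  }
  expect_error(class_balanced_weights(c(0, 1, 1, 1, 1, 1)), "zero-count")
})

test_that("large class counts do not underflow the weight computation", {
  w <- class_balanced_weights(c(3731, 2517, 2442, 2307, 1978, 1978), 0.999)
  expect_true(all(is.finite(w)) && all(w > 0))
  expect_equal(mean(w), 1, tolerance = 1e-9)
})

test_that("LDAM margins follow c0 * n^(-1/4) and decrease in class count", {
  expect_equal(unname(ldam_margins(c(16, 625, 1, 16, 16, 16))[1:3]),
               c(0.25, 0.10, 0.5))
  cts <- c(10, 20, 40, 80, 160, 320)
  m <- ldam_margins(cts)
  expect_true(all(diff(m) < 0))  # bigger class, smaller margin
  expect_true(all(m > 0))
  expect_error(ldam_margins(rep(0, 6)), "zero-count")
})

test_that("focal-LDAM loss matches closed forms and the explicit softmax oracle", {
  stats_u <- class_stats(rep(100, 6))  # unit weights, equal margins
  cfg0 <- loss_config(gamma = 0)

  # dominant true-class logit: loss vanishes
  z <- c(50, 0, 0, 0, 0, 0)
  expect_lt(focal_ldam_loss(z, "postpartum", stats_u, cfg0), 1e-15)

  # two active classes, margins 0, unit weights, gamma 0 -> ln 2
  stats_flat <- class_stats(rep(100, 6))
  stats_flat$margins[] <- 0
  stats_flat$weights[] <- 1
  z2 <- c(0, 0, -1e9, -1e9, -1e9, -1e9)
  expect_equal(focal_ldam_loss(z2, "major", stats_flat, cfg0), log(2),
               tolerance = 1e-9)
  # gamma 2 multiplies by (1 - 1/2)^2
  expect_equal(focal_ldam_loss(z2, "major", stats_flat, loss_config(gamma = 2)),
               0.25 * log(2), tolerance = 1e-9)

  # all-zero logits, margin 0.15 on the true class: brute-force softmax oracle
  stats_m <- class_stats(rep(100, 6))
  stats_m$margins[] <- 0.15
  stats_m$weights[] <- 1
  p <- exp(-0.15) / (exp(-0.15) + 5)
  oracle <- (1 - p)^2 * (-log(p))
  expect_equal(focal_ldam_loss(rep(0, 6), "psychotic", stats_m, loss_config()),
               oracle, tolerance = 1e-12)
})

test_that("gamma = 0 with unit weights reduces to margin-shifted cross-entropy", {
  stats_cls <- class_stats(c(50, 300, 120, 80, 40, 10))
  stats_cls$weights[] <- 1
  cfg <- loss_config(gamma = 0)
  set.seed(42)
  for (i in 1:100) {
    z <- rnorm(6, sd = 2)
    y <- sample(1:6, 1)
    zs <- z
    zs[y] <- zs[y] - stats_cls$margins[[y]]
    ce <- -(zs[y] - log(sum(exp(zs))))  # independent CE oracle
    expect_equal(focal_ldam_loss(z, y, stats_cls, cfg), ce, tolerance = 1e-10)
  }
})

test_that("R-Drop is zero on identical inputs, symmetric, and matches term-by-term KL", {
  p <- c(0.3, 0.2, 0.1, 0.05, 0.05, 0.3)
  expect_equal(rdrop_loss(p, p), 0)

  set.seed(7)
  for (i in 1:20) {
    a <- softmax(rnorm(6)); b <- softmax(rnorm(6))
    expect_equal(rdrop_loss(a, b), rdrop_loss(b, a), tolerance = 1e-12)
    expect_gte(rdrop_loss(a, b), 0)
  }

  # direct term-by-term summation oracle (zeros clipped at 1e-12)
  p1 <- c(0.9, 0.1, 0, 0, 0, 0)
  p2 <- c(0.5, 0.5, 0, 0, 0, 0)
  q1 <- pmax(p1, 1e-12); q2 <- pmax(p2, 1e-12)
  oracle <- 0.5 * (sum(q1 * log(q1 / q2)) + sum(q2 * log(q2 / q1)))
  expect_equal(rdrop_loss(p1, p2), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.43944491, tolerance = 1e-6)

  expect_error(rdrop_loss(c(0.5, 0.6, 0, 0, 0, 0), p2), "summing to 1")
})

test_that("pairwise penalty is scoped to bipolar and equals its hinge arithmetic", {
  z <- rnorm(6)
  expect_equal(pairwise_margin_penalty(z, "major", 0.15), 0)
  expect_equal(pairwise_margin_penalty(rep(0, 6), "bipolar", 0.15), 0.30)
  z_ok <- c(0, 0, 1, 0, 0.2, 0.1)  # bipolar leads both by > delta
  expect_equal(pairwise_margin_penalty(z_ok, "bipolar", 0.15), 0)
  # one active hinge
  z_one <- c(0, 0, 0.1, 0, 0.2, -1)
  expect_equal(pairwise_margin_penalty(z_one, "bipolar", 0.15),
               0.15 - (0.1 - 0.2))
})

test_that("total loss is additive over its independently computed components", {
  stats_cls <- class_stats(c(50, 300, 120, 80, 40, 10))
  cfg <- loss_config()
  set.seed(13)
  batch <- lapply(1:8, function(i) {
    dual_pass_logits(rnorm(6), rnorm(6), sample(1:6, 1))
  })
  expected <- mean(vapply(batch, function(ex) {
    0.5 * (focal_ldam_loss(ex$z1, ex$label, stats_cls, cfg) +
           focal_ldam_loss(ex$z2, ex$label, stats_cls, cfg)) +
      cfg$lambda_rdrop * rdrop_loss(softmax(ex$z1), softmax(ex$z2)) +
      cfg$lambda_pair * 0.5 *
        (pairwise_margin_penalty(ex$z1, ex$label, cfg$delta) +
         pairwise_margin_penalty(ex$z2, ex$label, cfg$delta))
  }, numeric(1)))
  expect_equal(total_loss(batch, stats_cls, cfg), expected, tolerance = 1e-9)
  expect_gte(total_loss(batch, stats_cls, cfg), 0)
  expect_error(total_loss(list(), stats_cls, cfg), "empty batch")
})

test_that("degenerate configs collapse the total to its focal term", {
  stats_cls <- class_stats(c(50, 300, 120, 80, 40, 10))
  cfg00 <- loss_config(lambda_rdrop = 0, lambda_pair = 0)
  set.seed(5)
  batch <- lapply(1:5, function(i) {
    z <- rnorm(6)
    dual_pass_logits(z, z, sample(1:6, 1))
  })
  expected <- mean(vapply(batch, function(ex) {
    focal_ldam_loss(ex$z1, ex$label, stats_cls, cfg00)
  }, numeric(1)))
  expect_equal(total_loss(batch, stats_cls, cfg00), expected, tolerance = 1e-12)

  # single non-bipolar example with z1 = z2: R-Drop and pair terms vanish
  z <- rnorm(6)
  one <- list(dual_pass_logits(z, z, "major"))
  expect_equal(total_loss(one, stats_cls, loss_config()),
               focal_ldam_loss(z, "major", stats_cls, loss_config()),
               tolerance = 1e-12)
})

test_that("analytic logit gradients match central finite differences", {
  stats_cls <- class_stats(c(50, 300, 120, 80, 40, 10))
  cfg <- loss_config()
  set.seed(3)
  for (trial in 1:10) {
    z1 <- rnorm(6); z2 <- rnorm(6); y <- sample(1:6, 1)
    g <- total_loss_grad(list(dual_pass_logits(z1, z2, y)), stats_cls, cfg)
    h <- 1e-5
    for (pass in 1:2) {
      num <- vapply(1:6, function(k) {
        e <- numeric(6); e[k] <- h
        zp <- if (pass == 1) list(z1 + e, z2) else list(z1, z2 + e)
        zm <- if (pass == 1) list(z1 - e, z2) else list(z1, z2 - e)
        (total_loss(list(dual_pass_logits(zp[[1]], zp[[2]], y)), stats_cls, cfg) -
         total_loss(list(dual_pass_logits(zm[[1]], zm[[2]], y)), stats_cls, cfg)) / (2 * h)
      }, numeric(1))
      ana <- if (pass == 1) g$g1[[1]] else g$g2[[1]]
      expect_lt(max(abs(num - ana)) / max(max(abs(num)), 1e-8), 1e-4)
    }
  }
})

test_that("the minority class contributes more loss than the majority at equal logits", {
  # drastic two-class imbalance, identical (uninformative) logits
  counts <- c(1000, 10, 1000, 1000, 1000, 1000)
  stats_cls <- class_stats(counts)
  z <- rep(0, 6)
  l_major <- focal_ldam_loss(z, 1, stats_cls, loss_config())  # majority class
  l_minor <- focal_ldam_loss(z, 2, stats_cls, loss_config())  # minority class
  expect_gt(l_minor, l_major)
})

test_that("loss configuration round-trips through the pipeline config file", {
  path <- tempfile(fileext = ".yaml")
  cfg <- list(loss = loss_config(beta = 0.99, gamma = 1.5),
              lora = lora_spec(rank = 4),
              train = train_config(batch_size = 8L))
  write_pipeline_config(cfg, path)
  got <- read_pipeline_config(path)
  expect_equal(got$loss$beta, 0.99)
  expect_equal(got$loss$gamma, 1.5)
  expect_equal(got$lora$rank, 4L)
  expect_equal(got$train$batch_size, 8L)
  # defaults fill untouched sections/fields
  expect_equal(got$loss$delta, 0.15)
  expect_equal(got$train$learning_rate, 2e-4)
  writeLines("loss:\n  gamm: 2\n", path)
  expect_error(read_pipeline_config(path), "unknown field")
  unlink(path)
})
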