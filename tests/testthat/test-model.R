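test_that("initialization is seeded, bounded, and seed-sensitive", {
  m1 <- init_model(model_config(seed = 7))
  m2 <- init_model(model_config(seed = 7))
  m3 <- init_model(model_config(seed = 8))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_false(identical(m1$W1, m3$W1))
  expect_equal(m1$b1, numeric(128))
  expect_equal(m1$b2, 0)
  # Glorot bound for 260 -> 128 is sqrt(6/388) << 1
  expect_lt(max(abs(m1$W1)), 1)
  expect_lt(max(abs(m1$W1)), sqrt(6 / (260 + 128)) + 1e-12)
  expect_error(model_config(n_hidden = 0), "n_input and n_hidden")
})

test_that("forward pass matches a pencil-and-paper toy computation", {
  cfg <- model_config(n_input = 2L, n_hidden = 2L, dropout_rate = 0)
  m <- init_model(cfg)
  m$W1 <- matrix(c(1, -1, 0.5, 2), 2, 2) # columns are hidden units
  m$b1 <- c(0.1, -0.2)
  m$W2 <- matrix(c(1, -0.5), 2, 1)
  m$b2 <- 0.3
  x <- matrix(c(0.4, 0.6), 1, 2)
  # by hand: z1 = (0.4 - 0.6 + 0.1, 0.2 + 1.2 - 0.2) = (-0.1, 1.2)
  # relu -> (0, 1.2); z2 = 0 - 0.6 + 0.3 = -0.3; sigmoid(-0.3)
  expect_equal(forward_pass(m, x), 1 / (1 + exp(0.3)), tolerance = 1e-12)
})

test_that("all-zero parameters output 0.5 and inference is deterministic", {
  cfg <- model_config(n_input = 4L, n_hidden = 3L)
  m <- init_model(cfg)
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2 <- 0
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(forward_pass(m, X), rep(0.5, 5))
  expect_identical(forward_pass(m, X), forward_pass(m, X))
  # training-mode dropout with the same seed is reproducible, and differs
  # across seeds
  m2 <- init_model(cfg)
  expect_identical(forward_pass(m2, X, training = TRUE, seed = 3),
                   forward_pass(m2, X, training = TRUE, seed = 3))
  expect_error(forward_pass(m2, X[, 1:3]), "expected 4")
})

test_that("class weights equalize the weighted class masses", {
  expect_equal(class_weights(c(rep(1, 50), rep(0, 50))),
               c(positive = 1, negative = 1))
  w <- class_weights(c(rep(1, 100), rep(0, 900)))
  expect_equal(w[["positive"]], 5)
  expect_equal(w[["negative"]], 500 / 900)
  withr::with_seed(3, {
    for (i in 1:20) {
      y <- as.integer(runif(sample(10:500, 1)) < runif(1, 0.05, 0.95))
      if (length(unique(y)) < 2) next
      w <- class_weights(y)
      expect_equal(w[["positive"]] * sum(y == 1), w[["negative"]] * sum(y == 0),
                   tolerance = 1e-9)
    }
  })
  expect_error(class_weights(rep(1, 10)), "one-class")
  expect_equal(class_weights(c(0, 1, 1), scheme = "none"),
               c(positive = 1, negative = 1))
})

make_separable <- function(n, seed, d = 20L, offset = 3) {
  withr::with_seed(seed, {
    y <- as.integer(runif(n) < 0.3)
    X <- matrix(rnorm(n * d), n, d)
    X[y == 1, ] <- X[y == 1, ] + offset
  })
  list(X = X, y = y)
}

test_that("training reaches near-perfect validation kappa on separable data", {
  tr <- make_separable(2000, 21)
  va <- make_separable(500, 22)
  cfg <- model_config(n_input = 20L, n_hidden = 16L, seed = 5)
  m <- train_network(tr$X, tr$y, va$X, va$y, cfg)
  expect_true(m$trained)
  expect_gte(max(m$training_log$val_kappa, na.rm = TRUE), 0.95)
  # best-epoch restoration: stored parameters reproduce the logged best kappa
  pv <- predict_labels(m, va$X)
  expect_equal(cohens_kappa(pv, va$y),
               max(m$training_log$val_kappa, na.rm = TRUE))
  # loss trend decreases over early epochs (5-epoch window means)
  loss <- m$training_log$train_loss
  if (length(loss) >= 10) {
    expect_lt(mean(loss[6:10]), mean(loss[1:5]))
  } else {
    expect_lt(loss[length(loss)], loss[1])
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  tr <- make_separable(400, 31)
  va <- make_separable(150, 32)
  cfg <- model_config(n_input = 20L, n_hidden = 8L, seed = 11, patience = 3L)
  m1 <- train_network(tr$X, tr$y, va$X, va$y, cfg)
  m2 <- train_network(tr$X, tr$y, va$X, va$y, cfg)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$b2, m2$b2)
})

test_that("early stopping halts within patience epochs of the best epoch", {
  tr <- make_separable(600, 41)
  va <- make_separable(200, 42)
  cfg <- model_config(n_input = 20L, n_hidden = 8L, seed = 2, patience = 10L)
  m <- train_network(tr$X, tr$y, va$X, va$y, cfg)
  n_epochs <- nrow(m$training_log)
  expect_lte(n_epochs, m$best_epoch + cfg$patience)
  expect_equal(m$best_epoch,
               which.max(m$training_log$val_kappa)) # earliest max
  # no earlier epoch beat the restored parameters
  expect_equal(m$training_log$val_kappa[m$best_epoch],
               max(m$training_log$val_kappa, na.rm = TRUE))
})

test_that("training rejects degenerate inputs", {
  tr <- make_separable(100, 51)
  expect_error(
    train_network(tr$X, rep(1L, 100), tr$X, tr$y,
                  model_config(n_input = 20L, n_hidden = 4L)),
    "one-class"
  )
  expect_error(
    train_network(tr$X[0, ], integer(0), tr$X, tr$y,
                  model_config(n_input = 20L, n_hidden = 4L)),
    "non-empty"
  )
})

test_that("predicted labels are the thresholded forward pass, ties going to 1", {
  tr <- make_separable(300, 61)
  va <- make_separable(100, 62)
  cfg <- model_config(n_input = 20L, n_hidden = 4L, seed = 1, patience = 2L)
  m <- train_network(tr$X, tr$y, va$X, va$y, cfg)
  p <- forward_pass(m, va$X)
  expect_identical(predict_labels(m, va$X), as.integer(p >= 0.5))
  expect_identical(predict_labels(m, va$X, threshold = max(p)),
                   as.integer(p >= max(p))) # the max itself classifies as 1
  expect_true(any(predict_labels(m, va$X, threshold = max(p)) == 1L))
  expect_identical(predict(m, va$X, type = "label"), predict_labels(m, va$X))
  expect_equal(predict(m, va$X), p)
})

test_that("tidy and glance expose the training history", {
  tr <- make_separable(200, 71)
  va <- make_separable(80, 72)
  cfg <- model_config(n_input = 20L, n_hidden = 4L, seed = 9, patience = 2L)
  m <- train_network(tr$X, tr$y, va$X, va$y, cfg)
  td <- tidy(m)
  expect_named(td, c("epoch", "train_loss", "val_kappa"))
  g <- glance(m)
  expect_equal(g$n_epochs, nrow(td))
  expect_equal(g$n_parameters, 20 * 4 + 4 + 4 + 1)
})
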