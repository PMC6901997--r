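test_that("cross-entropy matches closed-form values", {
  # perfect one-hot prediction: zero loss
  lp <- log(matrix(c(1e-9, 1e-9, 1, 1e-9), 1, 4) /
              (1 + 3e-9))
  target <- matrix(c(0, 0, 1, 0), 1, 4)
  expect_lt(cross_entropy(target, lp), 1e-8)
  # exactly probability 1 (log 0 elsewhere) is handled
  exact <- matrix(log(c(0, 0, 1, 0)), 1, 4)
  expect_equal(cross_entropy(target, exact), 0)

  # uniform prediction over 4 classes: ln 4
  lp_u <- matrix(log(0.25), 1, 4)
  expect_equal(cross_entropy(matrix(c(1, 0, 0, 0), 1, 4), lp_u), log(4),
               tolerance = 1e-9)

  # -ln 0.8 = 0.2231
  expect_equal(cross_entropy(matrix(c(1, 0), 1, 2),
                             matrix(log(c(0.8, 0.2)), 1, 2)),
               0.2231, tolerance = 1e-3)

  expect_error(cross_entropy(matrix(0, 2, 3), matrix(0, 2, 4)),
               "dimension mismatch")
})

test_that("cross-entropy agrees with direct evaluation on random pairs", {
  withr::with_seed(10, {
    for (i in 1:100) {
      n <- sample(2:6, 1); B <- sample(1:8, 1)
      labels <- sample(n, B, replace = TRUE) - 1L
      p <- msfbcnn:::one_hot(labels, n)
      q <- matrix(stats::rexp(B * n), B, n)
      q <- q / rowSums(q)
      direct <- -mean(sapply(seq_len(B), function(b)
        sum(p[b, ] * log(q[b, ]))))
      expect_equal(cross_entropy(p, log(q)), direct, tolerance = 1e-6)
    }
  })
})

test_that("network training loss equals the loss oracle on its outputs", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 2)
  withr::with_seed(3, {
    X <- array(rnorm(3 * 60 * 5), c(3, 60, 5))
    y <- sample(0:1, 5, replace = TRUE)
  })
  st <- msfbcnn:::cpp_fbcnn_step(X, y, m$par, m$buffers, cfg, 0)
  expect_equal(st$loss, cross_entropy(msfbcnn:::one_hot(y, 2), st$logp),
               tolerance = 1e-10)
})

test_that("the unit-variance initialization has the stated moments", {
  cfg <- model_config(C = 20, T = 100, F_T = 16, N_C = 2)
  m <- build_model(cfg, init = "paper", seed = 13)
  w <- c(unlist(m$par$Wt), as.vector(m$par$Ws), as.vector(m$par$Wc))
  expect_gt(length(w), 1e4)
  expect_lt(abs(mean(w)), 0.05)
  expect_lt(abs(stats::var(w) - 1), 0.1)
  # batch-norm scales start at exactly 1, shifts at 0
  expect_true(all(m$par$g1 == 1) && all(m$par$g2 == 1))
  expect_true(all(m$par$b1 == 0) && all(m$par$b2 == 0))
  # determinism
  expect_identical(m$par, build_model(cfg, init = "paper", seed = 13)$par)
})

test_that("the scaled initialization shrinks with fan-in", {
  cfg <- model_config(C = 10, T = 100, F_T = 10, N_C = 2)
  m <- build_model(cfg, init = "scaled", seed = 1)
  expect_equal(stats::sd(m$par$Ws), 1 / sqrt(40 * 10), tolerance = 0.1)
  expect_error(initialize_weights(m, scheme = "bogus"), "arg")
})

test_that("every trainable parameter carries exactly one group tag", {
  m <- build_model(tiny_model_config(), seed = 1)
  groups <- parameter_groups(m)
  expect_setequal(names(groups), names(m$par))
  expect_true(all(groups %in% c("feature_extraction", "feature_reduction",
                                "classifier")))
  # layered factors land on the right tensors
  pol <- layered_lr_policy()
  fac <- msfbcnn:::lr_factors(m, pol)
  expect_equal(unname(fac[c("Wt", "Ws", "g1")]), rep(1 / 27, 3))
  expect_equal(unname(fac[c("Wc", "bc")]), rep(1 / 3, 2))
})

test_that("layered policy defaults follow the 1/27, 1/9, 1/3 ladder", {
  pol <- layered_lr_policy()
  base_lr <- 1e-3
  expect_equal(base_lr * pol$fe_factor, 3.7037e-5, tolerance = 1e-3)
  expect_equal(base_lr * pol$fr_factor, 1.1111e-4, tolerance = 1e-3)
  expect_equal(base_lr * pol$clf_factor, 3.3333e-4, tolerance = 1e-3)
  expect_error(layered_lr_policy(fe_factor = 0.5, clf_factor = 0.1),
               "fe_factor")
})

# quickly separable toy task: class 0 carries a strong 10 Hz rhythm
separable_toy <- function(n_per_class, t = 60, c = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    data <- array(stats::rnorm(n * c * t, sd = 0.5), c(n, c, t))
    labels <- rep(0:1, each = n_per_class)
    tt <- seq(0, t - 1) / 250
    for (i in which(labels == 0))
      data[i, , ] <- data[i, , ] +
        matrix(3 * sin(2 * pi * 10 * tt + stats::runif(1, 0, 6)), c, t,
               byrow = TRUE)
    eeg_epochs(data, labels, c("rhythm", "noise"), 250)
  })
}

test_that("training learns a separable toy problem and is reproducible", {
  train_ds <- separable_toy(30, seed = 1)
  valid_ds <- separable_toy(10, seed = 2)
  cfg <- train_config(max_epochs = 15, batch_size = 10, seed = 5)
  m <- build_model(tiny_model_config(), init = "scaled", seed = 3)
  fit <- train(m, train_ds, valid_ds, cfg)

  expect_equal(nrow(fit$history), 15L)
  best <- attr(fit$history, "best_epoch")
  expect_gte(fit$history$valid_accuracy[best], 0.9)
  # optimization sanity: loss at the selected epoch not above the first
  expect_lte(fit$history$train_loss[best], fit$history$train_loss[1])
  # best epoch attains the maximum, earliest on ties
  expect_equal(best, which.max(fit$history$valid_accuracy))

  fit2 <- train(m, train_ds, valid_ds, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$par, fit2$model$par)
  # the input model object is untouched
  expect_false(identical(fit$model$par, m$par))
  expect_identical(m$trained, FALSE)
})

test_that("training rejects empty or mismatched inputs", {
  m <- build_model(tiny_model_config(), seed = 1)
  empty <- subset_epochs(separable_toy(5), integer(0))
  expect_error(train(m, empty, NULL, train_config(max_epochs = 1)),
               "empty training set")
  wrong <- toy_epochs(n = 4, c = 5, t = 60)
  expect_error(train(m, wrong, NULL, train_config(max_epochs = 1)),
               "channels")
})

test_that("evaluation reports accuracy and a consistent confusion matrix", {
  ds <- toy_epochs(n = 40, c = 3, t = 60, n_classes = 4, seed = 5)
  m <- build_model(tiny_model_config(N_C = 4), seed = 2)
  ev <- evaluate(m, ds)
  expect_gte(ev$accuracy, 0); expect_lte(ev$accuracy, 1)
  expect_equal(sum(ev$confusion), 40)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(factor(ds$labels, levels = 0:3)))))
  expect_error(evaluate(m, subset_epochs(ds, integer(0))), "empty test set")

  # an untrained model scores at chance on average over init seeds
  accs <- vapply(1:5, function(s) {
    evaluate(build_model(tiny_model_config(N_C = 4), seed = s), ds)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.25 - 0.1)
  expect_lt(mean(accs), 0.25 + 0.1)
})

test_that("perfect predictions give a diagonal confusion matrix", {
  # force determinism by copying the model's own predictions as labels
  ds <- toy_epochs(n = 12, c = 3, t = 60, n_classes = 2, seed = 9)
  m <- build_model(tiny_model_config(), seed = 4)
  ds$labels <- predict_epochs(m, ds)$labels
  ev <- evaluate(m, ds)
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(ev$confusion) - sum(diag(ev$confusion)), 0)
})
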