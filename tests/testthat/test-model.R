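test_that("the analytic report reproduces the reference architecture", {
  cfg <- model_config(C = 22, T = 1125, F_T = 40, F_S = 40, N_C = 4)
  rep <- compute_layer_shapes(cfg)
  expect_equal(cfg$L, 71L)
  branch <- rep$n_params[grepl("temporal_conv", rep$layer)]
  expect_equal(branch, c(64, 40, 26, 16) * 40)
  expect_equal(rep$n_params[rep$layer == "spatial_conv"], 22L * 160L * 40L)
  expect_equal(rep$n_params[rep$layer == "spatial_conv"], 140800L)
  expect_equal(rep$n_params[rep$layer == "classifier_conv"],
               40L * 71L * 4L + 4L)
  expect_equal(rep$n_params[rep$layer == "batch_norm_1"], 2L * 160L)
  expect_equal(rep$n_params[rep$layer == "batch_norm_2"], 2L * 40L)
  expect_equal(attr(rep, "total"), sum(rep$n_params))
  # zero-parameter reduction stages
  expect_true(all(rep$n_params[rep$layer %in%
                    c("square", "average_pool", "log", "dropout")] == 0))
})

test_that("pooled length follows valid-pooling arithmetic", {
  expect_equal(model_config(C = 22, T = 1125, F_T = 40, N_C = 4)$L, 71L)
  expect_equal(model_config(C = 1, T = 75, F_T = 1, N_C = 2)$L, 1L)
  cfg <- model_config(C = 1, T = 75, F_T = 1, N_C = 2)
  rep <- compute_layer_shapes(cfg)
  expect_equal(rep$n_params[rep$layer == "spatial_conv"], 1L * 4L * 1L)
})

test_that("D is accepted as an alternative spec of the filter counts", {
  cfg <- model_config(C = 4, T = 200, F_T = 40, D = 2, N_C = 2)
  expect_equal(cfg$F_S, 20L)
  expect_error(model_config(C = 4, T = 200, F_T = 40, F_S = 10, D = 2),
               "F_T")
})

test_that("invalid geometry is rejected with the offending layer named", {
  expect_error(model_config(C = 2, T = 10, F_T = 2, N_C = 2),
               "temporal_conv")
  expect_error(model_config(C = 2, T = 50, F_T = 2, N_C = 2,
                            temporal_kernel_lengths = c(8, 6, 5, 4),
                            pool_length = 60), "average_pool")
  expect_error(model_config(C = 2, T = 50, F_T = 2, N_C = 2,
                            temporal_kernel_lengths = c(8, 6, 5, 4),
                            pool_length = 10, dropout_p = 1), "dropout_p")
})

test_that("built models realize the analytic shapes and counts", {
  # across a spread of random valid configurations
  withr::with_seed(21, {
    for (rep_i in 1:20) {
      C <- sample(1:6, 1); T <- sample(40:120, 1)
      ks <- sort(sample(2:min(16, T), 4), decreasing = TRUE)
      pl <- sample(5:min(20, T), 1)
      cfg <- model_config(C = C, T = T, F_T = sample(1:3, 1),
                          F_S = sample(1:3, 1),
                          N_C = sample(2:4, 1),
                          temporal_kernel_lengths = ks,
                          pool_length = pl,
                          pool_stride = sample(2:6, 1))
      m <- build_model(cfg, seed = rep_i)
      rep_ <- compute_layer_shapes(cfg)
      expect_equal(count_parameters(m), attr(rep_, "total"))
      trial <- matrix(rnorm(C * T), C, T)
      acts <- model_activations(m, trial)
      expect_equal(dim(acts$temporal), c(4L * cfg$F_T, C * T))
      expect_equal(dim(acts$spatial_bn), c(cfg$F_S, T))
      expect_equal(dim(acts$pooled), c(cfg$F_S, cfg$L))
      expect_equal(length(acts$logp), cfg$N_C)
    }
  })
})

test_that("forward yields normalized log-probabilities at full scale", {
  cfg <- model_config(C = 22, T = 1125, F_T = 40, F_S = 40, N_C = 4)
  m <- build_model(cfg, seed = 2)
  withr::with_seed(5, {
    batch <- array(rnorm(8 * 22 * 1125), c(8, 22, 1125))
  })
  lp <- forward(m, batch)
  expect_equal(dim(lp), c(8L, 4L))
  expect_equal(rowSums(exp(lp)), rep(1, 8), tolerance = 1e-6)
})

test_that("two builds with the same seed produce identical parameters", {
  cfg <- tiny_model_config()
  a <- build_model(cfg, seed = 7)
  b <- build_model(cfg, seed = 7)
  expect_identical(a$par, b$par)
  c_ <- build_model(cfg, seed = 8)
  expect_false(identical(a$par$Ws, c_$par$Ws))
})

test_that("evaluation-mode forward is deterministic despite dropout", {
  cfg <- tiny_model_config(dropout_p = 0.5)
  m <- build_model(cfg, seed = 3)
  withr::with_seed(1, {
    batch <- array(rnorm(4 * 3 * 60), c(4, 3, 60))
  })
  expect_identical(forward(m, batch), forward(m, batch))
})

test_that("the reduction stage computes log of windowed mean squares", {
  # dual route: network activations vs direct arithmetic on the same signal
  cfg <- tiny_model_config(F_S = 3)
  withr::with_seed(33, {
    for (i in 1:100) {
      m <- build_model(cfg, init = "scaled", seed = i)
      m$buffers$m2 <- rnorm(3, 0, 0.1)  # non-trivial normalization stats
      m$buffers$v2 <- runif(3, 0.5, 2)
      trial <- matrix(rnorm(3 * 60, sd = runif(1, 0.5, 2)), 3, 60)
      acts <- model_activations(m, trial)
      z <- acts$spatial_bn
      oracle <- sapply(seq_len(cfg$L), function(l) {
        idx <- (l - 1) * cfg$pool_stride + seq_len(cfg$pool_length)
        log(rowMeans(z[, idx, drop = FALSE]^2))
      })
      expect_equal(acts$log_pooled, oracle, tolerance = 1e-5)
    }
  })
})

# a model whose layers are hand-set to the identity path: branch 1 kernel
# [1] passes the signal, batch norms neutral, spatial filter picks branch 1
identity_model <- function(T, pool_length = T, pool_stride = 15) {
  cfg <- model_config(C = 1, T = T, F_T = 1, N_C = 2,
                      temporal_kernel_lengths = c(1L, 1L, 1L, 1L),
                      pool_length = pool_length, pool_stride = pool_stride,
                      dropout_p = 0)
  m <- build_model(cfg, seed = 1)
  m$par$Wt <- lapply(1:4, function(i) matrix(if (i == 1) 1 else 0, 1, 1))
  m$par$Ws <- matrix(c(1, 0, 0, 0), 1, 4)
  m$buffers <- list(m1 = rep(0, 4), v1 = rep(1, 4), m2 = 0, v2 = 1)
  m
}

test_that("band-power feature of a unit sinusoid equals log(1/2)", {
  # 10 Hz at 250 Hz over 75 samples = 3 full cycles; mean square = A^2/2
  m <- identity_model(T = 75)
  tt <- seq(0, 74) / 250
  trial <- matrix(sin(2 * pi * 10 * tt), 1, 75)
  feat <- model_activations(m, trial)$log_pooled
  expect_equal(length(feat), 1L)
  expect_equal(feat[1], log(0.5), tolerance = 0.01)

  # doubling the amplitude adds log(4) to the log-power feature
  feat2 <- model_activations(m, 2 * trial)$log_pooled
  expect_equal(feat2[1] - feat[1], log(4), tolerance = 0.01)
})

test_that("predictions have valid ranges and are order-equivariant", {
  cfg <- tiny_model_config(N_C = 3)
  m <- build_model(cfg, seed = 4)
  ds <- toy_epochs(n = 11, c = 3, t = 60, n_classes = 3, seed = 6)
  pred <- predict_epochs(m, ds)
  expect_true(all(pred$labels %in% 0:2))
  expect_equal(rowSums(pred$prob), rep(1, 11), tolerance = 1e-6)
  perm <- withr::with_seed(2, sample(11))
  pred_perm <- predict_epochs(m, subset_epochs(ds, perm))
  expect_equal(pred_perm$labels, pred$labels[perm])
  expect_equal(pred_perm$log_prob, pred$log_prob[perm, ])
})

test_that("dimension mismatches are named", {
  m <- build_model(tiny_model_config(), seed = 1)
  bad <- array(0, c(2, 5, 60))
  expect_error(forward(m, bad), "channels on axis 2")
  bad2 <- array(0, c(2, 3, 61))
  expect_error(forward(m, bad2), "time points on axis 3")
})

test_that("temporal feature maps have the documented layout", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 5)
  trial <- matrix(rnorm(3 * 60), 3, 60)
  maps <- extract_temporal_features(m, trial)
  expect_equal(dim(maps), c(8L, 60L, 3L))

  # all-zero input gives constant (batch-norm shifted) maps
  flat <- extract_temporal_features(m, matrix(0, 3, 60))
  expect_equal(max(abs(sweep(flat, 1, flat[, 1, 1]))), 0)
})

test_that("a matched temporal filter responds more to its rhythm than noise", {
  T <- 250
  cfg <- model_config(C = 1, T = T, F_T = 1, N_C = 2,
                      temporal_kernel_lengths = c(25L, 12L, 8L, 6L),
                      pool_length = 50L, pool_stride = 25L, dropout_p = 0)
  m <- build_model(cfg, seed = 1)
  # first branch: one cycle of 10 Hz as a matched filter
  tt <- seq(0, 24) / 250
  m$par$Wt[[1]] <- matrix(sin(2 * pi * 10 * tt), 1, 25)
  m$buffers$m1 <- rep(0, 4); m$buffers$v1 <- rep(1, 4)
  tt_full <- seq(0, T - 1) / 250
  sine <- matrix(sin(2 * pi * 10 * tt_full), 1, T)
  noise <- withr::with_seed(8, matrix(rnorm(T, sd = sqrt(0.5)), 1, T))
  f_sine <- extract_temporal_features(m, sine)
  f_noise <- extract_temporal_features(m, noise)
  expect_gt(mean(abs(f_sine[1, , ])), mean(abs(f_noise[1, , ])))
})

test_that("checkpoints round-trip the whole model", {
  m <- build_model(tiny_model_config(), seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$par, m$par)
  expect_identical(back$config, m$config)
})
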