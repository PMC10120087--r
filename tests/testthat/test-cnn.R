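test_that("output shape follows the padding policy", {
  expect_equal(cnn_output_shape(cnn_spec(), c(220, 220)), c(220L, 120L))
  expect_equal(cnn_output_shape(cnn_spec(padding_policy = "same_all"),
                                c(220, 220)), c(220L, 220L))
  expect_error(cnn_output_shape(cnn_spec(), c(64, 64)), "receptive span")
})

test_that("the receptive-span invariant is enforced against the cavity geometry", {
  cfg <- system_config(y = 10L)
  expect_error(build_cnn(cnn_spec(dilation = 7L), cfg), "span mismatch")
  m <- build_cnn(cnn_spec(feature_widths = c(4, 4, 2), seed = 1), cfg)
  expect_s3_class(m, "tfflim_cnn")
  expect_false(m$trained)
})

test_that("intensity-weighted MSE matches hand arithmetic", {
  pred <- matrix(c(1, 2, 3, 4), 2)
  lab <- matrix(c(1, 1, 4, 2), 2)
  q <- matrix(c(1, 2, 0.5, 3), 2)
  expect_equal(weighted_mse(pred, lab, q), (0 + 2 + 0.5 + 12) / 4)
  expect_equal(weighted_mse(pred, pred, q), 0)
  expect_equal(weighted_mse(pred, lab, q * 0 + 1), mean((pred - lab)^2))
  expect_error(weighted_mse(pred, lab[1, , drop = FALSE], q), "shape")
})

# untrained desk-geometry net used by the structural probes
probe_net <- function() build_cnn(cnn_spec(feature_widths = c(8, 8, 4),
                                           dilation = 4L,
                                           padding_policy = "same_all",
                                           seed = 2))

test_that("outputs depend only on the dilated causal receptive field", {
  # probe through the sheared-image channel: the per-image normalization
  # scale comes from the intensity channel, so an iCCD perturbation
  # leaves the preprocessing of every other pixel untouched
  m <- probe_net()
  set.seed(3)
  q <- matrix(runif(32 * 192), 32); s <- matrix(runif(32 * 192), 32)
  p0 <- predict(m, q, s)
  # rows: only the 3x3 head mixes rows, so +-1 row is the full extent
  s1 <- s; s1[10, 60] <- s1[10, 60] + 100
  p1 <- predict(m, q, s1)
  expect_identical(p0[14, 60], p1[14, 60])     # 4 rows away: untouched
  expect_false(identical(p0[11, 60], p1[11, 60]))
  # columns: 3 dilated layers span +-(3*5*4) plus +-1 from the head
  s2 <- s; s2[20, 40] <- s2[20, 40] + 100
  p2 <- predict(m, q, s2)
  expect_false(identical(p0[20, 44], p2[20, 44]))  # inside the span
  valid_cols <- which(attr(p0, "valid")[20, ])
  untouched <- valid_cols[abs(valid_cols - 40) > 3 * 5 * 4 + 1]
  expect_identical(p0[20, untouched], p2[20, untouched])
})

test_that("inference is deterministic and finite on degenerate input", {
  m <- probe_net()
  q <- matrix(0, 64, 64)
  p <- predict(m, q, q)
  expect_true(all(is.finite(p[attr(p, "valid")])))
  set.seed(9)
  q2 <- matrix(runif(64 * 64), 64); s2 <- matrix(runif(64 * 64), 64)
  expect_identical(predict(m, q2, s2), predict(m, q2, s2))
})

# tiny deterministic dataset shared by the training checks
tiny_dataset <- function(n = 12) {
  dir <- file.path(tempdir(), sprintf("tfflim-tinyds-%d", n))
  if (!file.exists(file.path(dir, "manifest.json"))) {
    cfg <- system_config(y = 4L)
    spec <- phantom_spec("mixed", fov = c(24, 48), margin = 20, seed = 8,
                         bead_params = list(
                           list(radius = 3, lifetime = 2.1, count = 4),
                           list(radius = 5, lifetime = 4.0, count = 2)))
    generate_dataset(n, spec, cfg, detector_config(), dir, seed = 8)
  }
  dir
}

test_that("a zero learning rate leaves the convolution weights unchanged", {
  dir <- tiny_dataset()
  spec <- cnn_spec(feature_widths = c(6, 4, 2), dilation = 4L,
                   padding_policy = "same_all", seed = 3)
  m0 <- build_cnn(spec)
  m1 <- train_cnn(dir, m0, train_config(epochs = 1, batch_size = 4,
                                        lr_initial = 0, lr_decay = 1,
                                        seed = 4), quiet = TRUE)
  for (l in 1:4) expect_identical(m1$layers[[l]]$W, m0$layers[[l]]$W)
})

test_that("short training reduces the training loss and is seed-deterministic", {
  dir <- tiny_dataset()
  tc <- train_config(epochs = 4, batch_size = 4, lr_initial = 3e-3,
                     lr_decay = 0.95, seed = 4)
  spec <- cnn_spec(feature_widths = c(8, 6, 4), dilation = 4L,
                   padding_policy = "same_all", seed = 3)
  m1 <- train_cnn(dir, spec, tc, quiet = TRUE)
  expect_lt(tail(m1$history$train, 1), m1$history$train[1])
  expect_true(all(is.finite(m1$history$val)))
  m2 <- train_cnn(dir, spec, tc, quiet = TRUE)
  expect_identical(m1$layers, m2$layers)
})

test_that("predictions are clipped to the training label range with masked margins", {
  dir <- tiny_dataset()
  m <- train_cnn(dir, cnn_spec(feature_widths = c(6, 4, 2), dilation = 4L,
                               padding_policy = "same_all", seed = 3),
                 train_config(epochs = 1, batch_size = 4, seed = 4),
                 quiet = TRUE)
  set.seed(5)
  q <- matrix(runif(24 * 48, 0, 5000), 24)
  s <- matrix(runif(24 * 48, 0, 5000), 24)
  p <- predict(m, q, s)
  ok <- attr(p, "valid")
  expect_true(all(p[ok] >= m$label_range[1] - 1e-9 &
                    p[ok] <= m$label_range[2] + 1e-9))
  expect_true(all(is.na(p[!ok])))
  expect_false(any(ok[, 1:20]))               # padded margin masked
})
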