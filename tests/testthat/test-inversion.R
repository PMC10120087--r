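test_that("amplitude from the CMOS closed form inverts exactly", {
  expect_equal(amplitude_from_cmos(matrix(6), matrix(3), k = 1), matrix(2))
  expect_equal(amplitude_from_cmos(matrix(0), matrix(3)), matrix(0))
  cfg <- narrow_config()
  set.seed(2)
  tau <- matrix(runif(4 * 20, 0.5, 4), 4)
  a <- matrix(runif(4 * 20, 1, 30), 4)
  q <- simulate_cmos(tau, a, cfg, fov_width = ncol(tau))
  expect_equal(amplitude_from_cmos(q, tau, cfg$k), a)
  expect_error(amplitude_from_cmos(matrix(1), matrix(0.001)), "floor")
})

# small shared instance for cost/gradient checks (8x8, N = 2)
ir_instance <- function(seed = 7, noise = FALSE) {
  cfg <- system_config(y = 3L, n_replicas = 3L,
                       replica_weights = replica_weights(n = 3), dt = 0.02)
  set.seed(seed)
  tau <- matrix(runif(64, 0.8, 3), 8)
  a <- matrix(runif(64, 50, 200), 8)
  q <- cfg$k * a * tau
  s <- simulate_iccd(tau, a, cfg, dark_outside = TRUE)
  if (noise) s <- sample_noisy_iccd(s, detector_config(), seed = seed)
  list(cfg = cfg, tau = tau, q = q, s = s)
}

test_that("the cost vanishes at the truth and reduces to the regularizer", {
  inst <- ir_instance()
  ir0 <- ir_config(alpha = 0, mask_frac = 0)
  expect_equal(ir_cost(inst$tau, inst$q, inst$s, inst$cfg, ir0), 0,
               tolerance = 1e-18)
  ir1 <- ir_config(alpha = 0.37, mask_frac = 0)
  expect_equal(ir_cost(inst$tau, inst$q, inst$s, inst$cfg, ir1),
               0.37 * sum(inst$tau^2))
  expect_error(ir_cost(inst$tau * NA, inst$q, inst$s, inst$cfg), "NaN")
})

test_that("the cost matches a brute-force independent recomputation", {
  inst <- ir_instance()
  set.seed(9)
  tau_try <- matrix(runif(64, 0.5, 4), 8)
  ir <- ir_config(alpha = 1e-3, mask_frac = 0, squared_data_term = FALSE)
  cfg <- inst$cfg
  # independent render: plain loops over replicas and pixels
  pred <- matrix(0, 8, 8)
  for (n in 0:2) {
    for (j in 1:8) {
      src <- j - n * cfg$y
      if (src < 1) next
      Avals <- inst$q[, src] / (cfg$k * tau_try[, src])
      I_n <- vapply(tau_try[, src],
                    function(tv) oracle_gate_integral(cfg, n, tv), numeric(1))
      pred[, j] <- pred[, j] + cfg$replica_weights[n + 1] * Avals * I_n
    }
  }
  oracle <- sqrt(sum((pred - inst$s)^2)) + 1e-3 * sum(tau_try^2)
  expect_equal(ir_cost(tau_try, inst$q, inst$s, cfg, ir), oracle,
               tolerance = 1e-10)
})

test_that("the analytic gradient matches central finite differences", {
  for (sq in c(TRUE, FALSE)) {
    inst <- ir_instance(seed = 3 + sq, noise = TRUE)
    ir <- ir_config(alpha = 1e-3, mask_frac = 0, squared_data_term = sq)
    set.seed(5)
    tau0 <- matrix(runif(64, 0.6, 3.5), 8)
    g <- ir_gradient(tau0, inst$q, inst$s, inst$cfg, ir)
    h <- 1e-5
    fd <- matrix(0, 8, 8)
    for (i in seq_len(64)) {
      tp <- tau0; tp[i] <- tp[i] + h
      tm <- tau0; tm[i] <- tm[i] - h
      fd[i] <- (ir_cost(tp, inst$q, inst$s, inst$cfg, ir) -
                  ir_cost(tm, inst$q, inst$s, inst$cfg, ir)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("the gradient vanishes at the global minimum of noise-free data", {
  inst <- ir_instance()
  ir0 <- ir_config(alpha = 0, mask_frac = 0)
  g <- ir_gradient(inst$tau, inst$q, inst$s, inst$cfg, ir0)
  expect_lt(max(abs(g)), 1e-10)
})

test_that("flat-phantom retrieval recovers the truth within 1%", {
  cfg <- desk_config()
  tau <- matrix(1, 24, 70); a <- matrix(1000, 24, 70)
  q <- cfg$k * a * tau
  s <- simulate_iccd(tau, a, cfg, dark_outside = TRUE)
  fit <- tfflim_retrieve(q, s, cfg,
                         ir_config(init = "constant", init_range = c(2, 2)))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$tau_hat[fit$mask] - 1)), 0.01)
  expect_true(all(diff(fit$cost_trace) <= 1e-12))
})

test_that("initialization at the truth of clean data terminates immediately", {
  inst <- ir_instance()
  # render the measurement through the amplitude-from-intensity path so
  # the cost at the truth is exactly zero
  s_exact <- simulate_iccd(inst$tau, inst$q / (inst$cfg$k * inst$tau),
                           inst$cfg, dark_outside = TRUE)
  fit <- tfflim_retrieve(inst$q, s_exact, inst$cfg,
                         ir_config(alpha = 0, mask_frac = 0,
                                   init = "provided"),
                         tau_init = inst$tau)
  expect_true(fit$converged)
  expect_equal(fit$n_iter, 0L)
})

test_that("retrieval error shrinks monotonically with the photon budget", {
  cfg <- narrow_config()
  tau <- matrix(1, 16, 40)
  det <- detector_config()
  errs <- vapply(c(500, 5000, 50000), function(budget) {
    a <- matrix(budget / (1 * sum(cfg$replica_weights)), 16, 40)
    q <- cfg$k * a * tau
    s <- simulate_iccd(tau, a, cfg, dark_outside = TRUE)
    sn <- sample_noisy_iccd(s, det, seed = 11)
    fit <- tfflim_retrieve(q, sn, cfg,
                           ir_config(init = "constant", init_range = c(2, 2),
                                     max_iter = 250))
    median(abs(fit$tau_hat[fit$mask] - 1))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("retrieval is equivariant under row permutations", {
  inst <- ir_instance(noise = TRUE)
  ir <- ir_config(init = "constant", init_range = c(1.5, 1.5), max_iter = 25)
  fit1 <- tfflim_retrieve(inst$q, inst$s, inst$cfg, ir)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  fit2 <- tfflim_retrieve(inst$q[perm, ], inst$s[perm, ], inst$cfg, ir)
  expect_equal(fit2$tau_hat, fit1$tau_hat[perm, ])
})

test_that("invalid inputs are rejected", {
  inst <- ir_instance()
  bad <- inst$q; bad[1, 1] <- NA
  expect_error(tfflim_retrieve(bad, inst$s, inst$cfg), "NaN/Inf")
})
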