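test_that("replica weights follow the geometric splitting law", {
  expect_equal(replica_weights(0.5, 0.5, 3), c(0.5, 0.25, 0.125))
  w <- replica_weights(0.515, 0.485, 6)
  expect_equal(w[1], 0.515)
  expect_equal(w[6], 0.515 * 0.485^5)
  expect_true(all(diff(w) < 0))
  expect_equal(replica_weights(1, 0, 2), c(1, 0))
  expect_error(replica_weights(0.6, 0.6, 3), "sum to 1")
})

test_that("gate profile evaluates correctly and the smoothed shape has a rectangular limit", {
  rect <- gate_profile("rectangular", t_start = 1, width = 2)
  expect_equal(gate_values(rect, c(0.5, 1.5, 3, 3.5)), c(0, 1, 1, 0))
  tg <- seq(0, 5, by = 0.01)
  sm <- gate_profile("smoothed_flat_top", t_start = 1, width = 2,
                     edge_sigma = 1e-9)
  # away from the exact edges the vanishing-sigma limit is the rectangle
  interior <- abs(tg - 1) > 1e-6 & abs(tg - 3) > 1e-6
  expect_equal(gate_values(sm, tg)[interior], gate_values(rect, tg)[interior],
               tolerance = 1e-12)
  g <- gate_values(gate_profile(edge_sigma = 0.3), tg)
  expect_true(all(g >= 0 & g <= 1))
  expect_error(gate_values(rect, c(1, 0.5)), "increasing")
})

test_that("single-pixel iCCD signal matches the closed-form gate integral", {
  for (tau0 in c(0.5, 1, 2.5)) {
    cfg <- system_config(y = 0L, n_replicas = 1L, replica_weights = 1,
                         gate = gate_profile("rectangular", t_start = 0,
                                             width = 10 * tau0),
                         dt = 0.01, t_max = 10 * tau0 + 0.5)
    s <- simulate_iccd(matrix(tau0, 1, 1), matrix(1, 1, 1), cfg)
    expect_equal(as.numeric(s), tau0 * (1 - exp(-10)), tolerance = 1e-3)
  }
})

test_that("discretization error halves at least when dt halves", {
  err_at <- function(dt) {
    cfg <- system_config(y = 0L, n_replicas = 1L, replica_weights = 1,
                         gate = gate_profile("rectangular", t_start = 0.4,
                                             width = 3),
                         dt = dt, t_max = 4)
    s <- as.numeric(simulate_iccd(matrix(1, 1, 1), matrix(1, 1, 1), cfg))
    exact <- exp(-0.4) - exp(-3.4)            # tau = 1, window [0.4, 3.4]
    abs(s - exact)
  }
  e1 <- err_at(0.02); e2 <- err_at(0.01)
  expect_lt(e2, e1 / 1.9)
  expect_lt(e2 / (exp(-0.4) - exp(-3.4)), 1e-3)
})

test_that("replica bookkeeping matches a brute-force per-replica oracle", {
  cfg <- system_config(y = 12L, n_replicas = 3L,
                       replica_weights = replica_weights(n = 3), dt = 0.01)
  H <- 3; Wseed <- 64
  tau <- matrix(1.7, H, Wseed); a <- matrix(0, H, Wseed)
  a[2, 30] <- 100   # single source whose full replica chain stays in view
  s <- simulate_iccd(tau, a, cfg, fov_width = 40)
  m <- Wseed - 40                             # upstream margin present
  for (n in 0:2) {
    out_col <- 30 - m + n * cfg$y
    expect_equal(s[2, out_col],
                 cfg$replica_weights[n + 1] * 100 *
                   oracle_gate_integral(cfg, n, 1.7),
                 tolerance = 1e-8)
  }
  expect_equal(sum(s > 0), 3)                 # nothing else lit
})

test_that("late-gate replica ratios follow the shifted-exponential law", {
  cfg <- system_config(y = 12L, n_replicas = 3L,
                       replica_weights = replica_weights(n = 3),
                       gate = gate_profile("rectangular", t_start = 3.2,
                                           width = 2), dt = 0.005, t_max = 5.5)
  tau0 <- 2
  H <- 2; Wseed <- 64
  tau <- matrix(tau0, H, Wseed); a <- matrix(0, H, Wseed)
  a[1, 30] <- 50
  s <- simulate_iccd(tau, a, cfg, fov_width = 40)
  m <- Wseed - 40
  r <- cfg$replica_weights
  for (n in 0:1) {
    ratio <- s[1, 30 - m + (n + 1) * cfg$y] / s[1, 30 - m + n * cfg$y]
    expect_equal(ratio, (r[n + 2] / r[n + 1]) * exp(cfg$t_c / tau0),
                 tolerance = 1e-6)
  }
})

test_that("simulation is linear in amplitude and zero without fluorophores", {
  cfg <- narrow_config()
  set.seed(1)
  tau <- matrix(runif(6 * 30, 0.5, 4), 6)
  a <- matrix(runif(6 * 30, 0, 50), 6)
  s1 <- simulate_iccd(tau, a, cfg)
  s2 <- simulate_iccd(tau, 3.5 * a, cfg)
  expect_equal(s2, 3.5 * s1, ignore_attr = TRUE)
  expect_true(all(simulate_iccd(tau, a * 0, cfg) == 0))
  expect_true(all(simulate_cmos(tau, a * 0, cfg) == 0))
  expect_true(all(s1 >= 0))
})

test_that("CMOS closed form is exact and the numeric path agrees", {
  cfg <- system_config(y = 0L, n_replicas = 1L, replica_weights = 1)
  q <- simulate_cmos(matrix(3, 1, 1), matrix(2, 1, 1), cfg)
  expect_identical(as.numeric(q), 6)
  for (tau0 in c(0.8, 2, 5)) {
    qn <- simulate_cmos(matrix(tau0, 1, 1), matrix(2, 1, 1), cfg,
                        method = "numeric", horizon_taus = 20)
    expect_equal(as.numeric(qn), 2 * tau0, tolerance = 1e-3)
  }
})

test_that("CMOS-derived amplitude reinserted reproduces the iCCD render bit-for-bit", {
  cfg <- narrow_config()
  set.seed(4)
  tau <- matrix(runif(5 * 36, 0.5, 4), 5)
  a <- matrix(runif(5 * 36, 1, 20), 5)
  q_seed <- cfg$k * a * tau
  s1 <- simulate_iccd(tau, a, cfg)
  s2 <- simulate_iccd(tau, q_seed / (cfg$k * tau), cfg)
  # identical up to one round-off in the amplitude division
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-12)
})

test_that("valid region excludes the upstream shear band", {
  cfg <- system_config(y = 10L, n_replicas = 6L)
  mask <- valid_region(cfg, c(8, 220))
  expect_false(any(mask[, 1:50]))
  expect_true(all(mask[, 51:220]))
  expect_true(all(valid_region(system_config(y = 10L, n_replicas = 1L,
                                             replica_weights = 1),
                               c(4, 60))))
  expect_true(all(valid_region(system_config(y = 0L), c(4, 6))))
  expect_error(valid_region(cfg, c(8, 50)), "too narrow")
})

test_that("geometry violations and invalid maps are rejected", {
  cfg <- system_config(y = 10L)
  tau <- matrix(1, 4, 30); a <- matrix(1, 4, 30)
  expect_error(simulate_iccd(tau, a, cfg), "seed too small")
  tau_bad <- matrix(1, 4, 80); tau_bad[2, 3] <- -1
  expect_error(simulate_iccd(tau_bad, matrix(1, 4, 80), cfg), "> 0")
  expect_error(simulate_iccd(matrix(1, 4, 80), matrix(1, 5, 80), cfg),
               "share one shape")
})

test_that("a tilted shear direction displaces replicas off the nominal axis", {
  cfg0 <- system_config(y = 10L, n_replicas = 2L,
                        replica_weights = replica_weights(n = 2))
  cfg_t <- system_config(y = 10L, n_replicas = 2L, tilt = 15,
                         replica_weights = replica_weights(n = 2))
  H <- 21; Wseed <- 50
  tau <- matrix(1, H, Wseed); a <- matrix(0, H, Wseed)
  a[11, 25] <- 100   # direct pass lands at output column 11
  s0 <- simulate_iccd(tau, a, cfg0, fov_width = 36)
  st <- simulate_iccd(tau, a, cfg_t, fov_width = 36)
  # replica 1: centroid row moves by y*sin(15 deg) ~ 2.6 px
  rows <- 1:H
  col0 <- which.max(colSums(s0))              # direct pass, same in both
  rep_cols0 <- (col0 + 8):(col0 + 12)
  cen0 <- sum(rows * rowSums(s0[, rep_cols0])) / sum(s0[, rep_cols0])
  cent <- sum(rows * rowSums(st[, rep_cols0])) / sum(st[, rep_cols0])
  expect_equal(cent - cen0, 10 * sin(15 * pi / 180), tolerance = 0.15)
})
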