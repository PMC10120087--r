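# Small shared fixtures. Geometry shorthand: "narrow" configs keep the
# shear margin small so inverse-retrieval tests stay fast.

desk_config <- function(dt = 0.02, ...) system_config(dt = dt, ...)

narrow_config <- function(y = 3L, n_replicas = 3L, dt = 0.02, ...) {
  system_config(y = y, n_replicas = n_replicas,
                replica_weights = replica_weights(n = n_replicas),
                dt = dt, ...)
}

# Independent trapezoidal gate-decay integral (plain loops, no package
# internals): int G(t) exp((ts - t)/tau) H(t - ts) dt, integrated over the
# support where the decay has started and the gate is open
oracle_gate_integral <- function(cfg, n, tau) {
  tg <- seq(cfg$t0, cfg$t_max, by = cfg$dt)
  g <- gate_values(cfg$gate, tg)
  ts <- cfg$t0 + n * cfg$t_c
  keep <- tg >= ts & g > 1e-14
  f <- (g * exp((ts - tg) / tau))[keep]
  t_k <- tg[keep]
  sum((utils::head(f, -1) + utils::tail(f, -1)) / 2 * diff(t_k))
}
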