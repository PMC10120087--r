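# tfflim

Single-shot time-folded fluorescence lifetime imaging (FLIM) in R:
forward simulation, intensifier noise modelling, Bayesian uncertainty
bounds, regularized inverse retrieval, spectral shear calibration, and a
physics-inspired dilated convolutional network — plus the synthetic
phantom generation needed to exercise all of it without experimental
data.

## The problem

Conventional FLIM scans a gate (or a confocal spot) to sample the
fluorescence decay sequentially. A time-folded system instead sends the
fluorescence through a recirculating optical cavity: each round trip
produces a replica delayed by the round-trip time `t_c ≈ 0.59 ns` and
displaced by `y` pixels on a time-gated intensified camera (iCCD), so a
single exposure records several time windows of the decay side by side.
A synchronized CMOS camera records the time-integrated intensity. The
clean iCCD signal at a pixel is the gate-weighted, replica-summed decay

    s[i,j] = sum_n r_n ∫ G(t) A[i,j-ny] exp((t0 + n t_c - t)/tau[i,j-ny]) H(t - t0 - n t_c) dt

and the CMOS pixel records `q = k A tau`. The package implements this
forward model and three ways to invert it:

* a **Bayesian lower bound** on the relative lifetime uncertainty versus
  true lifetime and photon budget (per-pixel replica measurements,
  Gaussian iCCD noise model, uniform lifetime prior on 0.02–20 ns);
* **inverse retrieval** (`tfflim_retrieve()`): projected gradient
  descent on `||P(tau) - s||² + alpha ||tau||²` with the analytic
  adjoint gradient, the CMOS image supplying the decay amplitude;
* a **dilated CNN** (`build_cnn()`, `train_cnn()`): three (11 × 1)
  convolutions dilated by the replica separation — so each output sees
  exactly the pixels causally linked to it through the cavity — and a
  3×3 smoothing head, trained with intensity-weighted MSE on synthetic
  triplets.

`estimate_shear()` calibrates the replica separation and the tilt of the
shear direction from a measured image alone (matched filtering of the
log power spectrum against the replica comb), and `rectify()` removes
the tilt before reconstruction.

## A worked example

Simulate a two-population bead slide, add intensifier noise, and retrieve
the lifetime map:

```r
library(tfflim)

cfg <- system_config(dt = 0.04)          # cavity, gate, shear defaults
det <- detector_config(dqe = 1)          # budgets in detected quanta

spec <- phantom_spec("beads", fov = c(32, 128), margin = 0,
                     bead_params = list(
                       list(radius = 4, lifetime = 2.1, count = 5),
                       list(radius = 8, lifetime = 4.0, count = 2)),
                     intensity_range = c(1, 1), seed = 11)
ph <- make_phantom(spec)
# scale every bead to ~50,000 detected quanta
rsum <- sum(cfg$replica_weights)
for (tv in c(2.1, 4)) {
  sel <- ph$tau == tv & ph$a > 0
  nb <- if (tv == 2.1) 5 else 2
  ph$a[sel] <- ph$a[sel] * (5e4 * nb) / (sum(ph$a[sel]) * tv * rsum)
}
q  <- simulate_cmos(ph$tau, ph$a, cfg, fov_width = 128)
s  <- simulate_iccd(ph$tau, ph$a, cfg, dark_outside = TRUE)
sn <- sample_noisy_iccd(s, det, seed = 99)

fit <- tfflim_retrieve(q, sn, cfg,
                       ir_config(init = "constant", init_range = c(0.5, 5)))
summary(fit)
#> Retrieval: 500 iterations (converged: FALSE), cost 17911.7
#>   valid pixels: 569; lifetime quartiles 2.43 / 3.5 / 5.05 ns

median(fit$tau_hat[fit$mask & ph$tau == 2.1 & q > 0.05 * max(q)])
#> [1] 2.130679
median(fit$tau_hat[fit$mask & ph$tau == 4.0 & q > 0.05 * max(q)])
#> [1] 4.222983
```

The two dye populations (2.1 ns and 4.0 ns) come back within a few
percent at this photon budget; the longer lifetime carries the larger
pixel-to-pixel spread, as the uncertainty analysis predicts.

The uncertainty bound itself:

```r
uc <- uncertainty_curve(5000)            # 5,000 detected quanta
print(uc)
#> Lifetime-uncertainty lower bound, 5000 photons: min 3.03% at 1.31 ns
#>   (max 23.3% over [0.1, 10] ns)
plot(uc)
```

A command-line front end over the same functions is installed at
`inst/scripts/tfflim` with subcommands `simulate-dataset`, `retrieve`,
`uncertainty`, `calibrate`, `train` and `predict`.

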