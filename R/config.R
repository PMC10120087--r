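#' Replica power weights from a beamsplitter splitting ratio
#'
#' The cavity beamsplitter divides the signal at every round trip, so the
#' n-th replica carries a geometrically shrinking power fraction. With a
#' splitting ratio \code{ratio_a:ratio_b} the default law is
#' \deqn{r_n = \rho_a \rho_b^n,\qquad n = 0, \dots, N,}
#' i.e. the direct pass takes the \code{ratio_a} port and every additional
#' round trip multiplies by \code{ratio_b} (mirrors assumed lossless).
#'
#' @param ratio_a Fraction of power leaving the cavity on the direct pass.
#' @param ratio_b Fraction of power re-entering the cavity per round trip.
#'   \code{ratio_a + ratio_b} must equal 1 (within 1e-6).
#' @param n Number of weights to return (direct pass included), >= 1.
#' @return Numeric vector \code{r_0 .. r_{n-1}}, strictly decreasing for
#'   ratios in (0, 1).
#' @examples
#' replica_weights(0.5, 0.5, 3)        # 0.5 0.25 0.125
#' replica_weights(0.515, 0.485, 6)    # measured 51.5:48.5 splitter
#' @export
replica_weights <- function(ratio_a = 0.515, ratio_b = 0.485, n = 6L) {
  stopifnot(is.numeric(ratio_a), is.numeric(ratio_b), length(ratio_a) == 1,
            length(ratio_b) == 1, n >= 1)
  if (ratio_a < 0 || ratio_b < 0)
    stop("splitting ratios must be non-negative", call. = FALSE)
  if (abs(ratio_a + ratio_b - 1) > 1e-6)
    stop("splitting ratios must sum to 1 (got ", ratio_a + ratio_b, ")",
         call. = FALSE)
  ratio_a * ratio_b^(seq_len(n) - 1)
}

#' Temporal gate profile of the intensifier
#'
#' Describes the transmission window \eqn{G(t)} of the time-gated
#' intensifier: a flat top of a given width, optionally with
#' Gaussian-smoothed edges (the rectangle convolved with a Gaussian of
#' scale \code{edge_sigma}).
#'
#' The default opening time and width were calibrated once, on the default
#' cavity and detector, so that the relative lifetime-uncertainty curve
#' attains its minimum near 1 ns (the regime the instrument is designed
#' for); see the methods vignette.
#'
#' @param shape \code{"smoothed_flat_top"} or \code{"rectangular"}.
#' @param t_start Gate opening time (ns), measured on the same clock as
#'   the decay start \code{t0} of [system_config()].
#' @param width Gate duration (ns), > 0.
#' @param edge_sigma Edge smoothing scale (ns); 0 gives a hard rectangle.
#' @return Object of class \code{"tfflim_gate"}.
#' @seealso [gate_values()]
#' @export
gate_profile <- function(shape = c("smoothed_flat_top", "rectangular"),
                         t_start = 3.2, width = 8.0, edge_sigma = 0.05) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(t_start), length(t_start) == 1, is.finite(t_start))
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0)
    stop("gate width must be a positive number", call. = FALSE)
  if (!is.numeric(edge_sigma) || edge_sigma < 0)
    stop("edge_sigma must be >= 0", call. = FALSE)
  if (shape == "rectangular") edge_sigma <- 0
  structure(list(shape = shape, t_start = t_start, width = width,
                 edge_sigma = edge_sigma),
            class = "tfflim_gate")
}

#' @export
print.tfflim_gate <- function(x, ...) {
  cat(sprintf("Gate profile: %s, open [%.3g, %.3g] ns, edge sigma %.3g ns\n",
              x$shape, x$t_start, x$t_start + x$width, x$edge_sigma))
  invisible(x)
}

#' System configuration for the time-folded cavity forward model
#'
#' Collects the cavity, shear, gate and replica-weight parameters shared
#' by the forward model, the inverse retrieval and the uncertainty
#' analysis.
#'
#' The cavity retards each replica by the round-trip time \code{t_c}
#' (default 0.59 ns) and displaces it by \code{y} pixels along the column
#' (shear) axis. \code{n_replicas} counts the direct pass plus round
#' trips; the default 6 corresponds to five round trips, beyond which
#' replicas carry too little signal to matter.
#'
#' @param t_c Cavity round-trip time (ns), > 0.
#' @param y Shear per round trip (integer pixels, along columns).
#' @param tilt Deviation of the shear direction from the column axis
#'   (degrees); the forward model assumes 0, calibration estimates it.
#' @param n_replicas Number of replica terms including the direct pass.
#' @param replica_weights Power fractions \code{r_0..r_N}; defaults to
#'   [replica_weights()] with the measured 51.5:48.5 splitting ratio.
#' @param gate A [gate_profile()].
#' @param t0 Decay start time (ns).
#' @param dt Time-grid step for quadrature (ns), default 0.01.
#' @param t_max Integration horizon (ns); default gate end + 1 ns.
#' @param k CMOS/iCCD amplitude ratio factor (dimensionless), > 0.
#' @return Object of class \code{"tfflim_config"}.
#' @examples
#' cfg <- system_config(y = 10)
#' cfg
#' @export
system_config <- function(t_c = 0.59, y = 10L, tilt = 0, n_replicas = 6L,
                          replica_weights = NULL, gate = gate_profile(),
                          t0 = 0, dt = 0.01, t_max = NULL, k = 1) {
  if (!is.numeric(t_c) || t_c <= 0) stop("t_c must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 1) stop("n_replicas must be >= 1", call. = FALSE)
  y <- as.integer(y)
  if (y < 0) stop("y must be a non-negative integer pixel count", call. = FALSE)
  if (!inherits(gate, "tfflim_gate")) stop("gate must be a gate_profile()",
                                           call. = FALSE)
  if (is.null(replica_weights))
    replica_weights <- replica_weights(n = n_replicas)
  if (length(replica_weights) != n_replicas)
    stop("replica_weights must have length n_replicas", call. = FALSE)
  if (any(replica_weights < 0))
    stop("replica weights must be >= 0", call. = FALSE)
  if (any(diff(replica_weights) > 1e-12))
    stop("replica weights must be non-increasing", call. = FALSE)
  if (is.null(t_max)) t_max <- gate$t_start + gate$width + 1
  if (t_max <= t0) stop("t_max must exceed t0", call. = FALSE)
  structure(list(t_c = t_c, y = y, tilt = tilt, n_replicas = n_replicas,
                 replica_weights = as.numeric(replica_weights), gate = gate,
                 t0 = t0, dt = dt, t_max = t_max, k = k),
            class = "tfflim_config")
}

#' @export
print.tfflim_config <- function(x, ...) {
  cat("Time-folded FLIM system configuration\n")
  cat(sprintf("  cavity round trip t_c = %.3g ns, %d replica terms (N = %d round trips)\n",
              x$t_c, x$n_replicas, x$n_replicas - 1L))
  cat(sprintf("  shear y = %d px per round trip (tilt %.3g deg)\n", x$y, x$tilt))
  cat(sprintf("  replica weights: %s\n",
              paste(signif(x$replica_weights, 3), collapse = " ")))
  cat(sprintf("  time grid: t0 = %.3g, dt = %.3g, t_max = %.3g ns; k = %.3g\n",
              x$t0, x$dt, x$t_max, x$k))
  print(x$gate)
  invisible(x)
}

#' Detector (iCCD) noise configuration
#'
#' Noise budget of the intensified CCD: Poisson signal noise on the
#' photoelectrons (quantum efficiency \code{dqe}), dark-current and
#' clock-induced-charge noise, all amplified by the intensifier gain and
#' its excess noise factor, plus post-amplification readout noise.
#'
#' The defaults follow published figures for a gated iCCD of the class
#' used for this instrument: DQE 20\% above 500 nm, readout noise 8 e-,
#' dark noise 0.03 e-/s, zero clock-induced charge. The noise factor of
#' microchannel-plate amplification is not published for the exact tube;
#' 1.5 is a typical value for modern Gen 2/3 intensifiers and its effect
#' on the uncertainty bound is linear (see the methods vignette).
#'
#' @param dqe Detector quantum efficiency, in (0, 1].
#' @param sigma_readout Readout noise (electrons, RMS).
#' @param dark_rate Dark-current noise rate (electrons^2/s, i.e. variance
#'   accumulated per second of exposure).
#' @param sigma_clc Clock-induced charge noise (electrons, RMS).
#' @param noise_factor Excess noise factor F of the amplification, >= 1.
#' @param gain Effective intensifier gain M within the gate, > 0.
#' @param exposure_s Exposure time (s).
#' @return Object of class \code{"tfflim_detector"}.
#' @export
detector_config <- function(dqe = 0.20, sigma_readout = 8, dark_rate = 0.03,
                            sigma_clc = 0, noise_factor = 1.5, gain = 100,
                            exposure_s = 1) {
  if (!is.numeric(dqe) || dqe <= 0 || dqe > 1)
    stop("dqe must be in (0, 1]", call. = FALSE)
  if (sigma_readout < 0 || dark_rate < 0 || sigma_clc < 0)
    stop("noise terms must be >= 0", call. = FALSE)
  if (noise_factor < 1) stop("noise_factor must be >= 1", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (exposure_s < 0) stop("exposure_s must be >= 0", call. = FALSE)
  structure(list(dqe = dqe, sigma_readout = sigma_readout,
                 dark_rate = dark_rate, sigma_clc = sigma_clc,
                 noise_factor = noise_factor, gain = gain,
                 exposure_s = exposure_s),
            class = "tfflim_detector")
}

#' @export
print.tfflim_detector <- function(x, ...) {
  cat(sprintf(paste0("iCCD detector: DQE %.3g, readout %.3g e-, dark %.3g e-^2/s, ",
                     "CIC %.3g e-, F %.3g, gain %.3g, exposure %.3g s\n"),
              x$dqe, x$sigma_readout, x$dark_rate, x$sigma_clc,
              x$noise_factor, x$gain, x$exposure_s))
  invisible(x)
}

#' Inverse-retrieval configuration
#'
#' Parameters of the projected gradient descent used by
#' [tfflim_retrieve()].
#'
#' @param alpha L2 regularization weight on the lifetime map (default
#'   1e-3, selected once on synthetic data over a log grid).
#' @param max_iter Iteration cap.
#' @param rel_tol Relative cost-change stopping threshold.
#' @param tau_floor Lower clamp on lifetimes (ns); matches the lower edge
#'   of the lifetime prior.
#' @param init \code{"random"} (uniform in \code{init_range}),
#'   \code{"constant"} (midpoint of \code{init_range}) or
#'   \code{"provided"} (pass \code{tau_init} to [tfflim_retrieve()]).
#' @param init_range Initialization interval (ns).
#' @param armijo_c Sufficient-decrease constant of the backtracking line
#'   search, in (0, 1).
#' @param shrink Backtracking step multiplier, in (0, 1).
#' @param seed RNG seed for the random initialization.
#' @param squared_data_term If \code{TRUE} (default), use the squared L2
#'   norm \eqn{\|P(\tau)-\hat s\|_2^2} for the data term — the "mean
#'   squared error" the descent is described as minimizing, whose
#'   gradient vanishes smoothly at an exact fit. \code{FALSE} uses the
#'   unsquared norm as printed in the cost definition; its normalized-
#'   residual gradient is singular at the optimum and converges far more
#'   slowly.
#' @param mask_frac Pixels whose time-integrated intensity falls below
#'   this fraction of the image maximum are excluded from the data term
#'   and flagged invalid (they carry no usable lifetime information).
#' @return Object of class \code{"tfflim_ir_config"}.
#' @export
ir_config <- function(alpha = 1e-3, max_iter = 500L, rel_tol = 1e-6,
                      tau_floor = 0.02, init = c("random", "constant", "provided"),
                      init_range = c(0.5, 5), armijo_c = 1e-4, shrink = 0.5,
                      seed = NULL, squared_data_term = TRUE, mask_frac = 0.02) {
  init <- match.arg(init)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (tau_floor <= 0) stop("tau_floor must be > 0", call. = FALSE)
  if (shrink <= 0 || shrink >= 1) stop("shrink must be in (0, 1)", call. = FALSE)
  if (armijo_c <= 0 || armijo_c >= 1) stop("armijo_c must be in (0, 1)", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  stopifnot(length(init_range) == 2, init_range[1] > 0,
            init_range[2] >= init_range[1])
  structure(list(alpha = alpha, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, tau_floor = tau_floor, init = init,
                 init_range = as.numeric(init_range), armijo_c = armijo_c,
                 shrink = shrink, seed = seed,
                 squared_data_term = isTRUE(squared_data_term),
                 mask_frac = mask_frac),
            class = "tfflim_ir_config")
}

# internal: check a lifetime map
check_tau <- function(tau) {
  if (!is.matrix(tau) || !is.numeric(tau))
    stop("lifetime map must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("lifetime map must be finite and > 0 everywhere", call. = FALSE)
  invisible(tau)
}

# internal: check an amplitude map
check_amp <- function(a) {
  if (!is.matrix(a) || !is.numeric(a))
    stop("amplitude map must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0))
    stop("amplitude map must be finite and >= 0 everywhere", call. = FALSE)
  invisible(a)
}
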