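#' Evaluate the gate profile on a time grid
#'
#' Returns the intensifier transmission \eqn{G(t)} at the requested
#' times. The rectangular shape is 1 on \code{[t_start, t_start + width]}
#' and 0 outside; the smoothed flat top is the same rectangle convolved
#' with a Gaussian of scale \code{edge_sigma}, i.e.
#' \eqn{\Phi((t-a)/\sigma) - \Phi((t-b)/\sigma)}.
#'
#' @param gate A [gate_profile()].
#' @param t_grid Strictly increasing numeric vector of times (ns).
#' @return Numeric vector of values in \code{[0, 1]}.
#' @export
gate_values <- function(gate, t_grid) {
  stopifnot(inherits(gate, "tfflim_gate"), is.numeric(t_grid))
  if (length(t_grid) > 1 && any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing", call. = FALSE)
  a <- gate$t_start
  b <- gate$t_start + gate$width
  if (gate$shape == "rectangular" || gate$edge_sigma == 0) {
    as.numeric(t_grid >= a & t_grid <= b)
  } else {
    stats::pnorm((t_grid - a) / gate$edge_sigma) -
      stats::pnorm((t_grid - b) / gate$edge_sigma)
  }
}

# Internal: uniform quadrature grid covering [t0, t_max] with trapezoid
# weights, restricted to points where the gate is effectively open. The
# end points of the retained support get half weight: for a rectangular
# gate the integrand jumps there, and full-weight end points would leave
# an O(dt) error (for smoothed gates the boundary values are ~0, so the
# halving is harmless).
gate_quadrature <- function(cfg) {
  t_grid <- seq(cfg$t0, cfg$t_max, by = cfg$dt)
  g <- gate_values(cfg$gate, t_grid)
  keep <- g > 1e-14
  t_k <- t_grid[keep]
  gw <- (g * cfg$dt)[keep]
  if (length(gw)) gw[c(1, length(gw))] <- gw[c(1, length(gw))] / 2
  list(t = t_k, gw = gw)
}

# Internal: gate-integrated decay factors for replica n.
#   I_n(tau)  = int G(t) exp((ts_n - t)/tau) H(t - ts_n) dt,  ts_n = t0 + n t_c
#   dI_n/dtau = int G(t) exp(-(t - ts_n)/tau) (t - ts_n)/tau^2 H(.) dt
# Vectorized over tau; duplicates are collapsed before the exp/matmul.
decay_gate_integrals <- function(tau, cfg, n, quad = gate_quadrature(cfg),
                                 deriv = FALSE) {
  ts_n <- cfg$t0 + n * cfg$t_c
  keep <- quad$t >= ts_n
  out_I <- numeric(length(tau))
  out_dI <- if (deriv) numeric(length(tau)) else NULL
  if (any(keep)) {
    dt_pos <- quad$t[keep] - ts_n
    gw <- quad$gw[keep]
    # the Heaviside truncation can cut into the gate support: the first
    # retained point then sits on a jump of the integrand and takes half
    # weight (same trapezoid end-point rule as at the gate edges)
    if (sum(keep) < length(quad$t) && length(gw) > 1) gw[1] <- gw[1] / 2
    u <- unique(tau)
    idx <- match(tau, u)
    E <- exp(-outer(1 / u, dt_pos))      # |unique tau| x |t|
    I_u <- as.vector(E %*% gw)
    out_I <- I_u[idx]
    if (deriv) {
      dI_u <- as.vector(E %*% (gw * dt_pos)) / u^2
      out_dI <- dI_u[idx]
    }
  }
  if (deriv) list(I = out_I, dI = out_dI) else list(I = out_I)
}

# Internal renderer shared by simulate_iccd() and the inverse-retrieval
# forward operator. tau/a have width out_width + extra columns on the
# upstream (left) side; replicas displace content by +y columns per round
# trip. When zero_fill is TRUE, missing upstream sources contribute zero
# instead of raising an error (used for marginless measured FOVs).
render_iccd <- function(tau, a, cfg, out_width = NULL, zero_fill = FALSE) {
  check_tau(tau); check_amp(a)
  if (!all(dim(tau) == dim(a)))
    stop("tau and a must share one shape", call. = FALSE)
  H <- nrow(tau); Wseed <- ncol(tau)
  margin <- (cfg$n_replicas - 1L) * cfg$y
  if (is.null(out_width)) out_width <- Wseed - margin
  if (out_width < 1)
    stop("seed too small for the shear extent: need width > ",
         margin, " columns", call. = FALSE)
  m <- Wseed - out_width                 # upstream margin actually present
  if (m < margin && !zero_fill)
    stop("seed too small for the shear extent: seed must be at least ",
         margin, " columns wider than the output FOV", call. = FALSE)
  quad <- gate_quadrature(cfg)
  s <- matrix(0, H, out_width)
  tilt_rad <- cfg$tilt * pi / 180
  for (n in seq_len(cfg$n_replicas) - 1L) {
    dcol <- n * cfg$y * cos(tilt_rad)     # replica displacement vector
    drow <- n * cfg$y * sin(tilt_rad)
    c0 <- round(dcol); r0 <- round(drow)
    I_n <- decay_gate_integrals(as.vector(tau), cfg, n, quad)$I
    emitted <- cfg$replica_weights[n + 1L] * a * matrix(I_n, H)
    # fractional part of a tilted displacement: exact sub-pixel shift by
    # a Fourier phase ramp on a zero-padded copy (phase-true, unlike
    # bilinear splatting); the integer part is plain index arithmetic
    if (abs(dcol - c0) > 1e-9 || abs(drow - r0) > 1e-9)
      emitted <- subpixel_shift(emitted, drow - r0, dcol - c0)
    shift <- m - c0                       # output col j <- seed col j + shift
    jmin <- max(1L, 1L - shift)
    if (jmin > out_width) next
    rows_out <- max(1L, 1L + r0):min(H, H + r0)
    if (!length(rows_out)) next
    s[rows_out, jmin:out_width] <- s[rows_out, jmin:out_width] +
      emitted[rows_out - r0, (jmin:out_width) + shift, drop = FALSE]
  }
  # the band-limited sub-pixel shift rings marginally below zero at sharp
  # edges; physical intensity is non-negative
  if (tilt_rad != 0) s <- pmax(s, 0)
  s
}

# Internal: exact sub-pixel image shift via a Fourier phase ramp, on a
# zero-padded copy so the periodic wrap-around cannot reach the image.
subpixel_shift <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  Hp <- H + 8L; Wp <- W + 8L
  padded <- matrix(0, Hp, Wp)
  padded[1:H, 1:W] <- m
  fr <- c(0:(Hp %/% 2), -((Hp - Hp %/% 2 - 1):1)) / Hp
  fc <- c(0:(Wp %/% 2), -((Wp - Wp %/% 2 - 1):1)) / Wp
  ramp <- exp(-2i * pi * (outer(fr * dr, rep(1, Wp)) +
                            outer(rep(1, Hp), fc * dc)))
  out <- Re(stats::fft(stats::fft(padded) * ramp, inverse = TRUE)) / (Hp * Wp)
  out[1:H, 1:W]
}

#' Simulate the single-shot sheared iCCD image (noise free)
#'
#' Renders the gate-integrated, replica-summed signal
#' \deqn{s_{i,j} = \sum_{n=0}^{N} r_n \int G(t)\, A_{i,j-ny}\,
#'   e^{(t_0 + n t_c - t)/\tau_{i,j-ny}}\, H(t - t_0 - n t_c)\, dt}
#' on the configured time grid (trapezoidal quadrature). The seed maps
#' must be at least \code{(n_replicas-1)*y} columns wider than the output
#' field of view: replicas displace content downstream (towards higher
#' column indices), so the upstream margin supplies the sources that
#' shear into view.
#'
#' @param tau Lifetime map (ns), numeric matrix, all values > 0.
#' @param a Amplitude map (photons/ns scale), same shape, >= 0.
#' @param cfg A [system_config()].
#' @param fov_width Output width in columns; default seed width minus the
#'   shear margin.
#' @param dark_outside If \code{TRUE}, sources upstream of the seed are
#'   taken as dark (zero amplitude) instead of requiring a seed margin —
#'   appropriate for scenes known to have no fluorophores outside the
#'   supplied maps, and the convention the inverse retrieval assumes for
#'   a measured field of view.
#' @return Matrix of clean detector-plane signal (photocathode photons
#'   per pixel), with attribute \code{is_noisy = FALSE}.
#' @seealso [simulate_cmos()], [sample_noisy_iccd()], [valid_region()]
#' @export
simulate_iccd <- function(tau, a, cfg, fov_width = NULL,
                          dark_outside = FALSE) {
  if (dark_outside && is.null(fov_width)) fov_width <- ncol(tau)
  s <- render_iccd(tau, a, cfg, out_width = fov_width,
                   zero_fill = dark_outside)
  attr(s, "is_noisy") <- FALSE
  s
}

#' Simulate the time-integrated CMOS image
#'
#' The CMOS camera integrates the full decay, so each pixel records
#' \eqn{q_{i,j} = k A_{i,j} \tau_{i,j}} (the closed form of
#' \eqn{k \int A e^{(t_0-t)/\tau} dt}). The output is cropped to the same
#' field of view as [simulate_iccd()] so the two images are aligned.
#'
#' @inheritParams simulate_iccd
#' @param method \code{"closed"} (exact) or \code{"numeric"} (trapezoidal
#'   integration out to \code{horizon_taus} lifetimes, as a cross-check).
#' @param horizon_taus Integration horizon for the numeric path, in units
#'   of the local lifetime.
#' @return Matrix of time-integrated intensity (counts).
#' @export
simulate_cmos <- function(tau, a, cfg, fov_width = NULL,
                          method = c("closed", "numeric"), horizon_taus = 20) {
  method <- match.arg(method)
  check_tau(tau); check_amp(a)
  if (!all(dim(tau) == dim(a)))
    stop("tau and a must share one shape", call. = FALSE)
  margin <- (cfg$n_replicas - 1L) * cfg$y
  W <- if (is.null(fov_width)) ncol(tau) - margin else fov_width
  if (W < 1)
    stop("seed too small for the shear extent", call. = FALSE)
  m <- ncol(tau) - W
  if (m < 0) stop("fov_width exceeds the seed width", call. = FALSE)
  cols <- (m + 1L):ncol(tau)
  tau_f <- tau[, cols, drop = FALSE]
  a_f <- a[, cols, drop = FALSE]
  if (method == "closed") {
    q <- cfg$k * a_f * tau_f
  } else {
    u <- unique(as.vector(tau_f))
    I_u <- vapply(u, function(tv) {
      tg <- seq(0, horizon_taus * tv, by = cfg$dt)
      w <- rep(cfg$dt, length(tg)); w[c(1, length(tg))] <- cfg$dt / 2
      sum(w * exp(-tg / tv))
    }, numeric(1))
    q <- cfg$k * a_f * matrix(I_u[match(as.vector(tau_f), u)], nrow(tau_f))
  }
  q
}

#' Mask of pixels whose full replica chain is observed
#'
#' A detector pixel in column \eqn{j} sums contributions from source
#' columns \eqn{j - ny}; pixels near the upstream edge of a measured
#' field of view receive replicas of sources that were never observed.
#' The valid region excludes that band of \code{(n_replicas-1)*y} columns.
#'
#' @param cfg A [system_config()].
#' @param fov_shape Integer vector \code{c(rows, cols)}.
#' @return Logical matrix, \code{TRUE} where the full chain is in view.
#' @export
valid_region <- function(cfg, fov_shape) {
  stopifnot(length(fov_shape) == 2)
  H <- as.integer(fov_shape[1]); W <- as.integer(fov_shape[2])
  margin <- (cfg$n_replicas - 1L) * cfg$y
  if (W <= margin)
    stop("field of view too narrow: needs more than ", margin, " columns",
         call. = FALSE)
  mask <- matrix(TRUE, H, W)
  if (margin > 0) mask[, seq_len(margin)] <- FALSE
  mask
}
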