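#' Decay amplitude from the time-integrated CMOS image
#'
#' Inverts the CMOS closed form \eqn{q = k A \tau}:
#' \eqn{A_{i,j} = q_{i,j} / (k \tau_{i,j})}. Used inside the inverse
#' retrieval so that the lifetime map is the only unknown.
#'
#' @param q CMOS image (counts), numeric matrix.
#' @param tau Lifetime map (ns), same shape, all values >= \code{tau_floor}.
#' @param k CMOS/iCCD amplitude ratio factor, > 0.
#' @param tau_floor Lower validity clamp (ns).
#' @return Amplitude map.
#' @export
amplitude_from_cmos <- function(q, tau, k = 1, tau_floor = 0.02) {
  stopifnot(is.matrix(q), all(dim(q) == dim(tau)), k > 0)
  if (any(tau < tau_floor))
    stop("tau below the floor (", tau_floor, " ns)", call. = FALSE)
  q / (k * tau)
}

# Internal: forward operator of the inverse retrieval, P(tau).
# Operates on FOV-sized maps; replica sources upstream of the FOV are
# unobserved and contribute zero (those columns are masked out of the
# data term by valid_region()).
ir_forward <- function(tau, q, cfg) {
  A <- q / (cfg$k * tau)
  render_iccd(tau, A, cfg, out_width = ncol(tau), zero_fill = TRUE)
}

# Internal: data-term mask. The fit uses every FOV pixel with usable
# signal: the replica chain is lower-triangular along the shear axis, so
# dropping the upstream columns from the data term would leave the
# problem underdetermined. Reliability (full chain in view) is tracked
# separately by valid_region() on the result.
ir_mask <- function(q, cfg, ir) {
  q >= ir$mask_frac * max(q)
}

#' Cost of a lifetime map under the regularized retrieval model
#'
#' \deqn{C(\tau) = \|P(\tau) - \hat s\|_2 + \alpha \|\tau\|_2^2,}
#' where \eqn{P} renders the iCCD image from \eqn{\tau} and the
#' CMOS-derived amplitude. The data term is the unsquared L2 norm (the
#' printed form of the cost); set \code{squared_data_term} in
#' [ir_config()] for the squared variant, whose gradient is regular at an
#' exact fit. The data norm runs over the
#' above-threshold pixels; the regularizer runs over the full map.
#'
#' @param tau Lifetime map (ns), FOV-sized.
#' @param q CMOS image, FOV-sized.
#' @param s_hat Measured (noisy) iCCD image, FOV-sized.
#' @param cfg A [system_config()].
#' @param ir An [ir_config()].
#' @param mask Optional logical data-term mask; default keeps pixels
#'   above the low-signal threshold.
#' @return Scalar cost.
#' @export
ir_cost <- function(tau, q, s_hat, cfg, ir = ir_config(), mask = NULL) {
  if (any(!is.finite(tau)) || any(!is.finite(q)) || any(!is.finite(s_hat)))
    stop("NaN/Inf in inputs", call. = FALSE)
  stopifnot(all(dim(tau) == dim(q)), all(dim(tau) == dim(s_hat)))
  if (is.null(mask)) mask <- ir_mask(q, cfg, ir)
  res <- (ir_forward(tau, q, cfg) - s_hat)[mask]
  data_term <- if (ir$squared_data_term) sum(res^2) else sqrt(sum(res^2))
  data_term + ir$alpha * sum(tau^2)
}

#' Analytic gradient of the retrieval cost
#'
#' Adjoint-form gradient: each lifetime pixel accumulates the
#' (normalized) residual at every detector pixel its replicas feed,
#' weighted by the partial derivative of the gate-integrated decay with
#' the CMOS-derived amplitude substituted,
#' \deqn{\partial P_{i,j+ny} / \partial \tau_{i,j} =
#'   r_n \frac{q_{i,j}}{k} \frac{d}{d\tau}\!\left[\frac{I_n(\tau)}{\tau}\right],}
#' plus the per-pixel regularizer gradient \eqn{2 \alpha \tau_{i,j}}.
#'
#' @inheritParams ir_cost
#' @return Gradient matrix, same shape as \code{tau}.
#' @export
ir_gradient <- function(tau, q, s_hat, cfg, ir = ir_config(), mask = NULL) {
  if (any(!is.finite(tau)) || any(tau < ir$tau_floor))
    stop("tau must be finite and >= tau_floor", call. = FALSE)
  if (is.null(mask)) mask <- ir_mask(q, cfg, ir)
  W <- ncol(tau)
  res <- ir_forward(tau, q, cfg) - s_hat
  res[!mask] <- 0
  if (ir$squared_data_term) {
    wres <- 2 * res
  } else {
    nrm <- sqrt(sum(res^2))
    wres <- if (nrm > 0) res / nrm else res * 0
  }
  quad <- gate_quadrature(cfg)
  grad <- 2 * ir$alpha * tau
  for (n in seq_len(cfg$n_replicas) - 1L) {
    ny <- n * cfg$y
    if (ny >= W) next
    src <- 1:(W - ny)                      # source col c feeds output c + ny
    tau_s <- tau[, src, drop = FALSE]
    gi <- decay_gate_integrals(as.vector(tau_s), cfg, n, quad, deriv = TRUE)
    ddtau <- (gi$dI - gi$I / as.vector(tau_s)) / as.vector(tau_s)  # d/dtau[I/tau]
    grad[, src] <- grad[, src] +
      cfg$replica_weights[n + 1L] * (q[, src, drop = FALSE] / cfg$k) *
      matrix(ddtau, nrow(tau)) * wres[, src + ny, drop = FALSE]
  }
  grad
}

#' Retrieve a lifetime map by projected gradient descent
#'
#' Minimizes the regularized cost of [ir_cost()] by gradient descent with
#' Armijo backtracking line search and projection onto
#' \eqn{\tau \ge \tau_{floor}} after every step. The CMOS image supplies
#' the decay amplitude at each iterate, so the lifetime map is the only
#' optimization variable. Only the valid region (full replica chain in
#' view) with sufficient signal is fitted; the returned mask flags which
#' pixels are reliable.
#'
#' @param q CMOS image (counts), FOV-sized matrix.
#' @param s_hat Measured iCCD image, FOV-sized matrix.
#' @param cfg A [system_config()].
#' @param ir An [ir_config()].
#' @param tau_init Initial lifetime map for \code{init = "provided"}.
#' @return Object of class \code{"tfflim_ir"}: \code{tau_hat},
#'   \code{cost_trace}, \code{n_iter}, \code{converged}, \code{mask}
#'   (reliable pixels: full replica chain in view and usable signal),
#'   \code{data_mask} (pixels entering the data term), plus the
#'   configurations used.
#' @examples
#' \donttest{
#' cfg <- system_config(y = 4, n_replicas = 6)
#' ph <- make_phantom(phantom_spec("flat", fov = c(24, 24), margin = 20,
#'                                 flat_tau = 1, flat_amp = 1000, seed = 1))
#' q <- simulate_cmos(ph$tau, ph$a, cfg)
#' s <- simulate_iccd(ph$tau, ph$a, cfg)
#' fit <- tfflim_retrieve(q, s, cfg, ir_config(init = "constant",
#'                                             init_range = c(2, 2),
#'                                             max_iter = 50))
#' summary(fit)
#' }
#' @export
tfflim_retrieve <- function(q, s_hat, cfg, ir = ir_config(), tau_init = NULL) {
  stopifnot(is.matrix(q), all(dim(q) == dim(s_hat)))
  if (any(!is.finite(q)) || any(!is.finite(s_hat)))
    stop("NaN/Inf in inputs", call. = FALSE)
  mask <- ir_mask(q, cfg, ir)
  tau <- switch(ir$init,
    random = {
      if (!is.null(ir$seed)) set.seed(ir$seed)
      matrix(stats::runif(length(q), ir$init_range[1], ir$init_range[2]),
             nrow(q))
    },
    constant = matrix(mean(ir$init_range), nrow(q), ncol(q)),
    provided = {
      if (is.null(tau_init)) stop("init = 'provided' needs tau_init",
                                  call. = FALSE)
      check_tau(tau_init)
      tau_init
    })
  tau <- pmax(tau, ir$tau_floor)
  cost <- ir_cost(tau, q, s_hat, cfg, ir, mask)
  trace <- cost
  converged <- FALSE
  beta <- NULL
  iter <- 0L
  while (iter < ir$max_iter) {
    iter <- iter + 1L
    g <- ir_gradient(tau, q, s_hat, cfg, ir, mask)
    g2 <- sum(g^2)
    if (g2 < 1e-30 || cost < 1e-30) { converged <- TRUE; iter <- iter - 1L; break }
    if (is.null(beta)) beta <- 0.1 * mean(tau) / max(abs(g))
    else beta <- beta / ir$shrink         # let the step grow again
    accepted <- FALSE
    for (bt in 1:60) {
      tau_new <- pmax(tau - beta * g, ir$tau_floor)
      cost_new <- ir_cost(tau_new, q, s_hat, cfg, ir, mask)
      if (!is.finite(cost_new)) {
        err <- simpleError(paste0("non-finite cost at iteration ", iter))
        err$cost_trace <- trace
        stop(err)
      }
      if (cost_new <= cost - ir$armijo_c * beta * g2) { accepted <- TRUE; break }
      beta <- beta * ir$shrink
    }
    if (!accepted) { converged <- TRUE; break }   # no descent direction left
    rel_change <- (cost - cost_new) / max(cost, .Machine$double.eps)
    tau <- tau_new
    cost <- cost_new
    trace <- c(trace, cost)
    if (rel_change < ir$rel_tol) { converged <- TRUE; break }
  }
  rel_mask <- valid_region(cfg, dim(q)) & mask
  structure(list(tau_hat = tau, cost_trace = trace, n_iter = iter,
                 converged = converged, mask = rel_mask, data_mask = mask,
                 q = q, s_hat = s_hat,
                 cfg = cfg, ir = ir, call = match.call()),
            class = "tfflim_ir")
}

#' @export
print.tfflim_ir <- function(x, ...) {
  cat(sprintf("Inverse lifetime retrieval: %d iterations, %sconverged\n",
              x$n_iter, if (x$converged) "" else "NOT "))
  cat(sprintf("  final cost %.6g; %d/%d pixels in the valid fit region\n",
              utils::tail(x$cost_trace, 1), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
summary.tfflim_ir <- function(object, ...) {
  tau_ok <- object$tau_hat[object$mask]
  out <- list(n_iter = object$n_iter, converged = object$converged,
              cost = utils::tail(object$cost_trace, 1),
              n_valid = sum(object$mask),
              tau_quartiles = stats::quantile(tau_ok, c(0.25, 0.5, 0.75)))
  class(out) <- "summary.tfflim_ir"
  out
}

#' @export
print.summary.tfflim_ir <- function(x, ...) {
  cat(sprintf("Retrieval: %d iterations (converged: %s), cost %.6g\n",
              x$n_iter, x$converged, x$cost))
  cat(sprintf("  valid pixels: %d; lifetime quartiles %.3g / %.3g / %.3g ns\n",
              x$n_valid, x$tau_quartiles[1], x$tau_quartiles[2],
              x$tau_quartiles[3]))
  invisible(x)
}

#' @export
coef.tfflim_ir <- function(object, ...) object$tau_hat

#' @export
fitted.tfflim_ir <- function(object, ...)
  ir_forward(object$tau_hat, object$q, object$cfg)

#' @export
residuals.tfflim_ir <- function(object, ...) {
  r <- object$s_hat - fitted(object)
  r[!object$mask] <- NA_real_
  r
}

#' @export
plot.tfflim_ir <- function(x, what = c("map", "cost"), ...) {
  what <- match.arg(what)
  if (what == "cost") {
    graphics::plot(seq_along(x$cost_trace) - 1, x$cost_trace, type = "l",
                   xlab = "iteration", ylab = "cost", log = "y", ...)
  } else {
    tau_show <- x$tau_hat
    tau_show[!x$mask] <- NA
    graphics::image(t(tau_show)[, nrow(tau_show):1],
                    col = grDevices::hcl.colors(64, "viridis"),
                    axes = FALSE, main = "retrieved lifetime (ns)", ...)
  }
  invisible(x)
}
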