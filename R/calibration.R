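#' Estimate replica separation and shear tilt from an iCCD image
#'
#' The cavity replicas are delayed, displaced echoes of one scene, so the
#' 2-D power spectrum of the image is modulated along the shear direction
#' by the comb factor \eqn{|\sum_n r_n e^{2\pi i f n y}|^2}. The estimator
#' works on the log power spectrum, where that modulation is additive and
#' has the closed form \eqn{2 \sum_k (\rho^k/k) \cos(2\pi k y u)} for a
#' geometric weight law (u is the frequency component along the shear
#' direction). The Hann-windowed, zero-padded spectrum is projected onto
#' candidate shear directions within an angular tolerance of the nominal
#' (column) axis — projection along the true direction aligns the comb
#' oscillation and averages out scene speckle — and each projected
#' profile is matched-filtered against the comb template over a fine
#' separation grid, which uses every visible harmonic with the correct
#' relative phase. Isotropic scene structure (e.g. ring artifacts of
#' compact objects) scores equally at every candidate angle and is
#' removed by subtracting the across-angle mean. The tilt is the angle
#' maximizing the match and the separation the best template period,
#' refined by local quadratic fits.
#'
#' @param s iCCD image matrix (>= 2 visible replicas).
#' @param max_tilt Angular search tolerance around the column axis
#'   (degrees).
#' @param tilt_step Angular search step (degrees).
#' @param pad Zero-padding factor of the FFT grid.
#' @param sep_range Searched separation range (pixels).
#' @param rho Nominal cavity return fraction of the template (the
#'   geometric decay of the replica weights); the match is insensitive to
#'   moderate mismatch.
#' @param min_peak_snr Minimum ratio of the angle-contrasted match peak
#'   to the standard deviation of the searched region; below it the
#'   estimate is rejected.
#' @return List with \code{separation} (pixels), \code{tilt} (degrees)
#'   and \code{peak_snr}. On failure an error carries the diagnostic
#'   angle-by-separation score map in its \code{scores} field.
#' @export
estimate_shear <- function(s, max_tilt = 10, tilt_step = 0.25, pad = 4,
                           sep_range = c(3, ncol(s) / 3), rho = 0.485,
                           min_peak_snr = 6.5) {
  stopifnot(is.matrix(s), nrow(s) >= 8, ncol(s) >= 8)
  H <- nrow(s); W <- ncol(s)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  sw <- (s - mean(s)) * outer(hann(H), hann(W))
  Hp <- pad * H; Wp <- pad * W
  padded <- matrix(0, Hp, Wp)
  padded[1:H, 1:W] <- sw
  P <- Mod(stats::fft(padded))^2
  fy <- c(0:(Hp %/% 2), -((Hp - Hp %/% 2 - 1):1)) / Hp   # cycles/px
  fx <- c(0:(Wp %/% 2), -((Wp - Wp %/% 2 - 1):1)) / Wp
  FY <- matrix(fy, Hp, Wp)
  FX <- matrix(fx, Hp, Wp, byrow = TRUE)
  sel <- FX > 0 & sqrt(FX^2 + FY^2) <= 0.55   # Hermitian half-plane
  px <- FX[sel]; py <- FY[sel]
  plog <- log(P[sel] + max(P) * 1e-12)
  du <- 1 / Wp
  nb <- floor(0.5 / du)
  ubreaks <- seq(0, by = du, length.out = nb + 1)
  cwin <- hann(nb)
  cpad <- 8L * 2^ceiling(log2(nb))             # fine quefrency grid
  dq <- 1 / (cpad * du)                        # quefrency step, pixels
  angles <- seq(-max_tilt, max_tilt, by = tilt_step) * pi / 180
  Fc <- matrix(0i, length(angles), cpad %/% 2)
  for (a in seq_along(angles)) {
    u <- cos(angles[a]) * px + sin(angles[a]) * py
    bins <- findInterval(u, ubreaks)
    keep <- bins >= 1 & bins <= nb
    prof <- numeric(nb)
    tot <- rowsum(plog[keep], bins[keep])
    cnt <- rowsum(rep(1, sum(keep)), bins[keep])
    prof[as.integer(rownames(tot))] <- tot / cnt
    prof <- (prof - mean(prof)) * cwin
    Fc[a, ] <- stats::fft(c(prof, numeric(cpad - nb)))[1:(cpad %/% 2)]
  }
  # matched filter against the log-comb template: harmonics k at
  # quefrency k*y with amplitudes rho^k/k and locked (positive cosine)
  # phase
  seps <- seq(sep_range[1], sep_range[2], by = dq)
  ak <- rho^(1:4) / (1:4)
  score <- matrix(0, length(angles), length(seps))
  for (k in 1:4) {
    idx <- round(k * seps / dq) + 1L
    ok <- idx <= ncol(Fc)
    score[, ok] <- score[, ok] + ak[k] * Re(Fc[, idx[ok], drop = FALSE])
  }
  # isotropic scene structure scores near-identically at every angle; the
  # replica echo is directional. Remove a per-separation linear trend in
  # angle (plain mean subtraction leaves slowly varying structure maximal
  # at the band edges).
  th <- angles - mean(angles)
  score <- sweep(score, 2, colMeans(score))
  score <- score - outer(th, colSums(th * score) / sum(th^2))
  inner <- abs(th) <= max(th) - 2 * tilt_step * pi / 180
  masked <- score
  masked[!inner, ] <- -Inf
  peak <- which(masked == max(masked), arr.ind = TRUE)[1, ]
  a0 <- peak[1]; q0 <- peak[2]
  # noise scale from the score map away from the echo ridge (the ridge
  # spans a few degrees and a few percent in separation)
  far <- abs(matrix(seps, length(angles), length(seps), byrow = TRUE) -
               seps[q0]) > 0.15 * seps[q0] |
    abs(matrix(angles - angles[a0], length(angles), length(seps))) >
      4 * pi / 180
  snr <- max(score) / stats::sd(score[far])
  if (snr < min_peak_snr) {
    err <- simpleError(paste0("no significant directional echo (SNR ",
                              signif(snr, 3), "); cannot estimate shear"))
    err$scores <- score
    stop(err)
  }
  qrefine <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (!is.finite(den) || den >= 0) 0 else min(1, max(-1, 0.5 * (ym - yp) / den))
  }
  # tilt pass: re-weight harmonics upward (amplitude rho^k instead of
  # rho^k/k) — high harmonics carry the sharpest angular response
  idxs <- round((1:4) * seps[q0] / dq) + 1L
  okk <- idxs <= ncol(Fc)
  tcurve <- as.vector(Re(Fc[, idxs[okk], drop = FALSE] %*% rho^(which(okk))))
  at <- which.max(tcurve)
  dth <- if (at > 1 && at < length(angles))
    qrefine(tcurve[at - 1], tcurve[at], tcurve[at + 1]) else 0
  dq0 <- if (q0 > 1 && q0 < length(seps))
    qrefine(score[a0, q0 - 1], score[a0, q0], score[a0, q0 + 1]) else 0
  list(separation = seps[q0] + dq0 * dq,
       tilt = (angles[at] * 180 / pi) + dth * tilt_step,
       peak_snr = snr)
}

#' Rectify a tilted iCCD image
#'
#' Rotates the image by \code{-tilt} about its center with bilinear
#' resampling so the replica shear aligns with the column axis.
#' Out-of-frame pixels are set to \code{NA} and flagged in the attached
#' \code{"valid"} attribute. A tilt of exactly 0 is a bit-exact
#' pass-through.
#'
#' @param s iCCD image matrix.
#' @param tilt Tilt to remove (degrees), \code{|tilt| < 45}.
#' @return Rectified matrix with attribute \code{valid} (logical matrix,
#'   \code{FALSE} where resampling left the frame).
#' @export
rectify <- function(s, tilt) {
  stopifnot(is.matrix(s), abs(tilt) < 45)
  if (tilt == 0) {
    attr(s, "valid") <- matrix(TRUE, nrow(s), ncol(s))
    return(s)
  }
  H <- nrow(s); W <- ncol(s)
  th <- -tilt * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gj <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  gi <- matrix(seq_len(H), H, W) - cy
  # inverse map: sample the source at the back-rotated coordinate
  si <- cos(th) * gi - sin(th) * gj + cy
  sj <- sin(th) * gi + cos(th) * gj + cx
  i0 <- floor(si); j0 <- floor(sj)
  wi <- si - i0; wj <- sj - j0
  inside <- i0 >= 1 & i0 + 1 <= H & j0 >= 1 & j0 + 1 <= W
  out <- matrix(NA_real_, H, W)
  idx <- which(inside)
  at <- function(di, dj) s[cbind(i0[idx] + di, j0[idx] + dj)]
  out[idx] <- (1 - wi[idx]) * (1 - wj[idx]) * at(0L, 0L) +
    (1 - wi[idx]) * wj[idx] * at(0L, 1L) +
    wi[idx] * (1 - wj[idx]) * at(1L, 0L) +
    wi[idx] * wj[idx] * at(1L, 1L)
  attr(out, "valid") <- inside
  out
}
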