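#' Architecture of the physics-inspired dilated CNN
#'
#' The network maps the concatenated (CMOS, iCCD) pair to a lifetime map
#' with three dilated convolutional layers followed by a 3x3 head. The
#' dilated kernels are (kernel x 1) along the shear axis with a dilation
#' equal to the replica separation, so each feature sees exactly the
#' pixels that are causally linked to a target pixel through the cavity
#' replicas; the 3x3 head mimics learned sliding-window binning.
#'
#' @param feature_widths Feature-map counts of the three dilated layers.
#' @param kernel Dilated kernel extent along the shear axis (odd).
#' @param dilation Dilation rate (pixels); must equal the replica shear
#'   \code{y} of the paired [system_config()] so that
#'   \code{dilation * (kernel - 1)} spans the full replica chain both ways.
#' @param head_kernel Extent of the final smoothing kernel.
#' @param padding_policy \code{"valid_first"} (no padding in the first
#'   dilated layer, zero same-padding afterwards; the output shrinks by
#'   \code{dilation*(kernel-1)} columns) or \code{"same_all"} (zero
#'   same-padding throughout; used for small training crops).
#' @param seed RNG seed for the weight initialization.
#' @return Object of class \code{"tfflim_cnn_spec"}.
#' @export
cnn_spec <- function(feature_widths = c(256, 64, 16), kernel = 11L,
                     dilation = 10L, head_kernel = 3L,
                     padding_policy = c("valid_first", "same_all"),
                     seed = NULL) {
  padding_policy <- match.arg(padding_policy)
  stopifnot(length(feature_widths) == 3, all(feature_widths >= 1),
            kernel %% 2 == 1, kernel >= 3, dilation >= 1,
            head_kernel %% 2 == 1)
  structure(list(feature_widths = as.integer(feature_widths),
                 kernel = as.integer(kernel), dilation = as.integer(dilation),
                 head_kernel = as.integer(head_kernel),
                 padding_policy = padding_policy, seed = seed),
            class = "tfflim_cnn_spec")
}

#' Output shape of the CNN for a given input shape
#'
#' @param spec A [cnn_spec()].
#' @param input_shape \code{c(rows, cols)} of the input images.
#' @return \code{c(rows, cols)} of the predicted lifetime map.
#' @export
cnn_output_shape <- function(spec, input_shape) {
  span <- spec$dilation * (spec$kernel - 1L)
  W <- if (spec$padding_policy == "valid_first")
    input_shape[2] - span else input_shape[2]
  if (W < 1) stop("input narrower than the receptive span (", span + 1,
                  " px)", call. = FALSE)
  c(as.integer(input_shape[1]), as.integer(W))
}

#' Build the dilated CNN with randomly initialized weights
#'
#' @param spec A [cnn_spec()].
#' @param cfg Optional [system_config()]; when given, the receptive-span
#'   invariant \code{dilation*(kernel-1) == 2*(n_replicas-1)*y} is
#'   enforced so the kernel is centered on the direct pass and reaches
#'   the farthest replica in both directions.
#' @return Object of class \code{"tfflim_cnn"} (untrained).
#' @export
build_cnn <- function(spec, cfg = NULL) {
  stopifnot(inherits(spec, "tfflim_cnn_spec"))
  if (!is.null(cfg)) {
    span <- spec$dilation * (spec$kernel - 1L)
    need <- 2L * (cfg$n_replicas - 1L) * cfg$y
    if (span != need)
      stop("receptive span mismatch: dilation*(kernel-1) = ", span,
           " but the replica chain needs ", need, call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  widths <- c(2L, spec$feature_widths)
  layers <- vector("list", 4)
  for (l in 1:3) {
    fan_in <- widths[l] * spec$kernel
    layers[[l]] <- list(
      type = "dilated",
      pad = if (l == 1 && spec$padding_policy == "valid_first") "valid" else "same",
      kernel = spec$kernel, dilation = spec$dilation,
      W = array(stats::rnorm(widths[l + 1] * widths[l] * spec$kernel,
                             sd = sqrt(2 / fan_in)),
                dim = c(widths[l + 1], widths[l], spec$kernel)),
      b = numeric(widths[l + 1]))
  }
  hk <- spec$head_kernel
  fan_in <- widths[4] * hk * hk
  layers[[4]] <- list(type = "head", pad = "same", kernel = hk, dilation = 1L,
                      W = array(stats::rnorm(widths[4] * hk * hk,
                                             sd = sqrt(2 / fan_in)),
                                dim = c(1L, widths[4], hk * hk)),
                      b = 0)
  structure(list(spec = spec, layers = layers, trained = FALSE,
                 norm = NULL, label_range = NULL, history = NULL),
            class = "tfflim_cnn")
}

#' @export
print.tfflim_cnn <- function(x, ...) {
  cat(sprintf("Dilated lifetime CNN: 2 -> %s -> 1 channels, (%d x 1) kernels, dilation %d, %dx%d head [%s]\n",
              paste(x$spec$feature_widths, collapse = " -> "),
              x$spec$kernel, x$spec$dilation, x$spec$head_kernel,
              x$spec$head_kernel,
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history))
    cat(sprintf("  %d epochs: validation loss %.4g -> %.4g\n",
                nrow(x$history), x$history$val[1],
                x$history$val[nrow(x$history)]))
  invisible(x)
}

# ---- index plans -----------------------------------------------------------

# Pixel index block: pixels (i in rows) x (j in cols) x (b in 1..B) in an
# H x W x B stack, i fastest, then j, then b. Row/col subsets must be
# passed in the same order for input and output sides of a tap.
idx_block <- function(rows, cols, H, W, B) {
  base <- as.vector(outer((cols - 1L) * H, (0:(B - 1L)) * (H * W), `+`))
  rep(base, each = length(rows)) + rows
}

# Build the tap index plan for every layer at a given geometry.
cnn_plan <- function(model, H, W, B) {
  spec <- model$spec
  plan <- vector("list", length(model$layers))
  Wi <- as.integer(W)
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    K <- lay$kernel; d <- lay$dilation
    if (lay$type == "dilated") {
      half <- (K - 1L) %/% 2L
      if (lay$pad == "valid") {
        Wo <- Wi - d * (K - 1L)
        if (Wo < 1) stop("input narrower than the receptive span", call. = FALSE)
        taps <- lapply(1:K, function(m) {
          oc <- 1:Wo; ic <- oc + (m - 1L) * d
          list(o = idx_block(1:H, oc, H, Wo, B),
               i = idx_block(1:H, ic, H, Wi, B), m = m)
        })
      } else {
        Wo <- Wi
        taps <- list()
        for (m in 1:K) {
          off <- (m - 1L - half) * d
          oc <- seq_len(Wo)
          oc <- oc[oc + off >= 1 & oc + off <= Wi]
          if (!length(oc)) next
          taps[[length(taps) + 1]] <-
            list(o = idx_block(1:H, oc, H, Wo, B),
                 i = idx_block(1:H, oc + off, H, Wi, B), m = m)
        }
      }
    } else {                              # 3x3 head, same padding
      half <- (K - 1L) %/% 2L
      Wo <- Wi
      taps <- list()
      m <- 0L
      for (dj in -half:half) for (di in -half:half) {
        m <- m + 1L
        or <- seq_len(H); or <- or[or + di >= 1 & or + di <= H]
        oc <- seq_len(Wo); oc <- oc[oc + dj >= 1 & oc + dj <= Wi]
        if (!length(or) || !length(oc)) next
        taps[[length(taps) + 1]] <-
          list(o = idx_block(or, oc, H, Wo, B),
               i = idx_block(or + di, oc + dj, H, Wi, B), m = m)
      }
    }
    plan[[l]] <- list(W_in = Wi, W_out = Wo,
                      o0 = lapply(taps, function(tp) tp$o - 1L),
                      i0 = lapply(taps, function(tp) tp$i - 1L),
                      m0 = vapply(taps, function(tp) tp$m - 1L, integer(1)),
                      P_in = H * Wi * B, P_out = H * Wo * B)
    Wi <- Wo
  }
  attr(plan, "H") <- H; attr(plan, "B") <- B
  attr(plan, "W_in") <- as.integer(W); attr(plan, "W_out") <- Wi
  plan
}

# ---- forward / backward ----------------------------------------------------

# The per-tap convolutions run in compiled code (src/cnn_ops.cpp);
# plans carry 0-based index vectors for the C++ side.

cnn_forward <- function(model, X, plan, keep = FALSE) {
  acts <- if (keep) vector("list", length(model$layers)) else NULL
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    pl <- plan[[l]]
    Y <- cnn_tap_conv(X, lay$W, pl$o0, pl$i0, pl$m0, as.numeric(lay$b),
                      pl$P_out)
    out <- if (lay$type == "dilated") Y * (Y > 0) else Y   # ReLU on hidden
    if (keep) acts[[l]] <- list(X = X, out = out)
    X <- out
  }
  if (keep) list(out = X, acts = acts) else X
}

cnn_backward <- function(model, fwd, dOut, plan) {
  grads <- vector("list", length(model$layers))
  dY <- dOut
  for (l in rev(seq_along(model$layers))) {
    lay <- model$layers[[l]]
    pl <- plan[[l]]
    ac <- fwd$acts[[l]]
    if (lay$type == "dilated")            # ReLU mask on this layer's output
      dY <- dY * (ac$out > 0)
    g <- cnn_tap_backward(dY, ac$X, lay$W, pl$o0, pl$i0, pl$m0, pl$P_in,
                          l > 1L)
    grads[[l]] <- list(W = g$dW, b = as.numeric(g$db))
    if (l > 1) dY <- g$dX
  }
  grads
}

# ---- loss ------------------------------------------------------------------

#' Intensity-weighted mean squared error
#'
#' Training loss of the lifetime CNN:
#' \deqn{L = \frac{1}{NM} \sum_{i,j} q_{i,j} (\hat\tau_{i,j} - \tau_{i,j})^2.}
#' High-intensity pixels have intrinsically low lifetime variance, so an
#' error there signals poor fitting rather than poor SNR and is weighted
#' up.
#'
#' @param pred Predicted lifetime map (matrix).
#' @param label Ground-truth lifetime map, same shape.
#' @param q Intensity weights (CMOS image), same shape.
#' @return Scalar loss.
#' @export
weighted_mse <- function(pred, label, q) {
  if (!all(dim(pred) == dim(label)) || !all(dim(pred) == dim(q)))
    stop("shape mismatch between pred, label and q", call. = FALSE)
  mean(q * (pred - label)^2)
}

# ---- training --------------------------------------------------------------

#' Training configuration for the lifetime CNN
#'
#' @param epochs Training epochs.
#' @param batch_size Images per gradient step; the small default trades
#'   arithmetic efficiency for more optimizer steps per epoch, which
#'   measurably helps at desk-scale dataset sizes.
#' @param lr_initial Initial Adam learning rate.
#' @param lr_decay Per-epoch exponential decay of the learning rate.
#' @param split Train/validation/test fractions (used when the dataset
#'   manifest does not record a split), summing to 1.
#' @param seed RNG seed for shuffling and initialization.
#' @return Object of class \code{"tfflim_train_config"}.
#' @export
train_config <- function(epochs = 20L, batch_size = 2L, lr_initial = 3e-3,
                         lr_decay = 0.95, split = c(0.75, 0.125, 0.125),
                         seed = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_initial >= 0,
            lr_decay > 0, lr_decay <= 1)
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_decay = lr_decay,
                 split = split, seed = seed),
            class = "tfflim_train_config")
}

# Internal: read a generated dataset directory into memory.
load_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  items <- man$items
  list(manifest = man,
       q = lapply(items$cmos, function(f) read_image(file.path(dir, f))),
       s = lapply(items$iccd, function(f) read_image(file.path(dir, f))),
       tau = lapply(items$tau, function(f) read_image(file.path(dir, f))),
       split = items$split)
}

# Internal: stack image pairs into a channel x pixel matrix chunk. Both
# channels of a pair are divided by the same per-image scale, so the
# CMOS/iCCD and inter-replica ratios that encode lifetime are preserved
# and inference is invariant to exposure and photon budget.
stack_batch <- function(qs, ss, scales) {
  rbind(q = unlist(mapply(function(m, sc) as.vector(m) / sc, qs, scales,
                          SIMPLIFY = FALSE)),
        s = unlist(mapply(function(m, sc) as.vector(m) / sc, ss, scales,
                          SIMPLIFY = FALSE)))
}

# Internal: per-image normalization scale (99th percentile of the CMOS
# channel, floored to avoid division by ~0 on empty frames).
image_scale <- function(q) max(stats::quantile(q, 0.99, names = FALSE),
                               .Machine$double.eps)

# Internal: crop labels/weights to the network output geometry and build
# the loss mask (borders touched by zero padding are excluded).
output_window <- function(spec, H, W) {
  span2 <- spec$dilation * (spec$kernel - 1L) %/% 2L
  if (spec$padding_policy == "valid_first") {
    cols <- (span2 + 1L):(W - span2)
    mask_cols <- seq_along(cols)
  } else {
    cols <- seq_len(W)
    mask_cols <- (span2 + 1L):(W - span2)
    if (span2 + 1L > W - span2)
      stop("crop too narrow for the receptive span", call. = FALSE)
  }
  hh <- (spec$head_kernel - 1L) %/% 2L
  mask <- matrix(FALSE, H, length(cols))
  mask[(hh + 1L):(H - hh), mask_cols] <- TRUE
  list(cols = cols, mask = mask)
}

#' Train the lifetime CNN on a generated dataset
#'
#' Optimizes the intensity-weighted MSE with Adam and an exponentially
#' decaying learning rate, logging train and validation loss per epoch.
#' Fully deterministic for fixed seeds.
#'
#' @param dataset Path to a dataset directory written by
#'   [generate_dataset()] (containing \code{manifest.json}).
#' @param model A [build_cnn()] model, or a [cnn_spec()] (a fresh model
#'   is built).
#' @param tc A [train_config()].
#' @param cfg Optional [system_config()] for the receptive-span check.
#' @param quiet Suppress the per-epoch progress line.
#' @return The trained \code{"tfflim_cnn"} with \code{history} (data
#'   frame of per-epoch train/validation loss) and recorded input
#'   normalization.
#' @export
train_cnn <- function(dataset, model = cnn_spec(), tc = train_config(),
                      cfg = NULL, quiet = FALSE) {
  if (inherits(model, "tfflim_cnn_spec")) model <- build_cnn(model, cfg)
  stopifnot(inherits(model, "tfflim_cnn"), inherits(tc, "tfflim_train_config"))
  ds <- load_dataset(dataset)
  n <- length(ds$q)
  split <- ds$split
  if (is.null(split)) {
    bounds <- round(cumsum(tc$split) * n)
    split <- rep(c("train", "val", "test"), times = diff(c(0, bounds)))
  }
  tr <- which(split == "train"); va <- which(split == "val")
  if (!length(tr)) stop("dataset has no training items", call. = FALSE)
  H <- nrow(ds$q[[1]]); W <- ncol(ds$q[[1]])
  scales <- vapply(ds$q, image_scale, numeric(1))
  ow <- output_window(model$spec, H, W)
  lab <- lapply(ds$tau, function(m) m[, ow$cols, drop = FALSE])
  wgt <- lapply(seq_len(n), function(i)
    ds$q[[i]][, ow$cols, drop = FALSE] / scales[i])
  if (!is.null(tc$seed)) set.seed(tc$seed)
  if (!model$trained)                     # start the head at the label mean
    model$layers[[4]]$b <- mean(unlist(lab[tr]))
  adam <- lapply(model$layers, function(l)
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  plans <- list()
  get_plan <- function(B) {
    key <- as.character(B)
    if (is.null(plans[[key]]))
      plans[[key]] <<- cnn_plan(model, H, W, B)
    plans[[key]]
  }
  batch_loss <- function(idx, grad = FALSE, lr = 0) {
    B <- length(idx)
    plan <- get_plan(B)
    X <- stack_batch(ds$q[idx], ds$s[idx], scales[idx])
    fwd <- cnn_forward(model, X, plan, keep = grad)
    pred <- if (grad) fwd$out else fwd
    labv <- unlist(lapply(lab[idx], as.vector))
    wv <- unlist(lapply(wgt[idx], as.vector))
    mv <- rep(as.vector(ow$mask), B)
    wv <- wv * mv
    err <- as.vector(pred) - labv
    denom <- sum(mv)
    loss <- sum(wv * err^2) / denom
    if (!grad) return(loss)
    dOut <- matrix(2 * wv * err / denom, 1)
    grads <- cnn_backward(model, fwd, dOut, plan)
    t <<- t + 1
    for (l in seq_along(model$layers)) {
      g <- grads[[l]]
      st <- adam[[l]]
      st$mW <- b1 * st$mW + (1 - b1) * g$W
      st$vW <- b2 * st$vW + (1 - b2) * g$W^2
      st$mb <- b1 * st$mb + (1 - b1) * g$b
      st$vb <- b2 * st$vb + (1 - b2) * g$b^2
      adam[[l]] <<- st
      corr <- sqrt(1 - b2^t) / (1 - b1^t)
      model$layers[[l]]$W <<- model$layers[[l]]$W -
        lr * corr * st$mW / (sqrt(st$vW) + eps)
      model$layers[[l]]$b <<- model$layers[[l]]$b -
        lr * corr * st$mb / (sqrt(st$vb) + eps)
    }
    loss
  }
  eval_loss <- function(ids) {
    if (!length(ids)) return(NA_real_)
    chunks <- split(ids, ceiling(seq_along(ids) / tc$batch_size))
    tot <- vapply(chunks, function(ch) batch_loss(ch) * length(ch), numeric(1))
    sum(tot) / length(ids)
  }
  history <- data.frame(epoch = seq_len(tc$epochs), train = NA_real_,
                        val = NA_real_)
  for (ep in seq_len(tc$epochs)) {
    lr <- tc$lr_initial * tc$lr_decay^(ep - 1)
    ord <- sample(tr)
    chunks <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    tl <- vapply(chunks, function(ch) {
      l <- batch_loss(ch, grad = TRUE, lr = lr)
      if (!is.finite(l))
        stop("divergent loss at epoch ", ep, call. = FALSE)
      l * length(ch)
    }, numeric(1))
    history$train[ep] <- sum(tl) / length(ord)
    history$val[ep] <- eval_loss(va)
    if (!quiet)
      message(sprintf("epoch %3d  lr %.2e  train %.5g  val %.5g",
                      ep, lr, history$train[ep], history$val[ep]))
  }
  model$trained <- TRUE
  model$norm <- "per_image_q99"
  model$label_range <- range(unlist(lab[tr]))
  model$history <- history
  model
}

#' Predict a lifetime map from a (CMOS, iCCD) image pair
#'
#' Applies the trained network with the per-image normalization used at
#' training time (both channels scaled by the CMOS 99th percentile, so
#' predictions are invariant to exposure). Predictions are clipped to the
#' training label range;
#' border pixels touched by zero padding are set to \code{NA} and
#' flagged in the \code{"valid"} attribute.
#'
#' @param object A trained \code{"tfflim_cnn"}.
#' @param cmos CMOS image matrix.
#' @param iccd iCCD image matrix, same shape.
#' @param ... Unused.
#' @return Lifetime map (ns) of the network's output shape.
#' @export
predict.tfflim_cnn <- function(object, cmos, iccd, ...) {
  stopifnot(is.matrix(cmos), all(dim(cmos) == dim(iccd)))
  H <- nrow(cmos); W <- ncol(cmos)
  plan <- cnn_plan(object, H, W, 1L)
  X <- stack_batch(list(cmos), list(iccd), image_scale(cmos))
  out <- cnn_forward(object, X, plan)
  ow <- output_window(object$spec, H, W)
  pred <- matrix(as.vector(out), H)
  if (!is.null(object$label_range))
    pred <- pmin(pmax(pred, object$label_range[1]), object$label_range[2])
  pred[!ow$mask] <- NA_real_
  attr(pred, "valid") <- ow$mask
  attr(pred, "input_cols") <- ow$cols
  pred
}
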