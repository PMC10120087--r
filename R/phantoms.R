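#' Specification of a synthetic phantom scene
#'
#' Describes an amplitude + lifetime seed pair for the forward model.
#' Seed maps carry an upstream margin along the shear axis so that
#' replicas originating outside the cropped field of view are present,
#' mirroring the larger-seed / smaller-image recipe used to build
#' training data.
#'
#' @param kind One of \code{"beads"} (anti-aliased disks at random
#'   non-overlapping centers with per-population lifetimes),
#'   \code{"cell_like"} (thin bright wall-like ridges of a smoothed
#'   random field on a dim background), \code{"random_texture"}
#'   (smooth random amplitude and lifetime fields), \code{"flat"}
#'   (constant maps) or \code{"mixed"} (each dataset item samples one of
#'   the previous kinds).
#' @param fov Output dimensions \code{c(rows, cols)} in pixels.
#' @param margin Upstream seed margin (columns); must be at least
#'   \code{(n_replicas-1)*y} of the paired [system_config()].
#' @param lifetime_range Lifetime label interval (ns), default 0.1 to 8.
#' @param intensity_range Amplitude interval (photons/ns scale).
#' @param bead_params List of populations, each
#'   \code{list(radius = px, lifetime = ns, count = n)}. The defaults
#'   mirror two bead dye populations with literature lifetimes of 2.1 and
#'   4.0 ns (radii standing in for 2 and 4 um beads).
#' @param flat_tau,flat_amp Constants for the \code{"flat"} kind.
#' @param background_tau Lifetime placeholder (ns) where the amplitude is
#'   zero (a lifetime is undefined without signal; the value is never
#'   weighted in losses or retrievals).
#' @param texture List of texture parameters for the random-field kinds:
#'   \code{sigma} (smoothing scale, px), \code{wall_width} (ridge width
#'   of the cell-like walls, in field SD units), \code{background_frac}
#'   (off-structure amplitude as a fraction of the structure amplitude).
#' @param seed RNG seed; identical specs and seeds give identical maps.
#' @return Object of class \code{"tfflim_phantom_spec"}.
#' @export
phantom_spec <- function(kind = c("beads", "cell_like", "random_texture",
                                  "flat", "mixed"),
                         fov = c(64L, 64L), margin = 20L,
                         lifetime_range = c(0.1, 8),
                         intensity_range = c(50, 2000),
                         bead_params = list(
                           list(radius = 4, lifetime = 2.1, count = 6),
                           list(radius = 8, lifetime = 4.0, count = 3)),
                         flat_tau = 1, flat_amp = 1, background_tau = 1,
                         texture = list(sigma = 4, wall_width = 0.12,
                                        background_frac = 0.05),
                         seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(fov) == 2, all(fov >= 8), margin >= 0,
            length(lifetime_range) == 2, lifetime_range[1] > 0,
            diff(lifetime_range) >= 0, length(intensity_range) == 2,
            intensity_range[1] >= 0)
  structure(list(kind = kind, fov = as.integer(fov), margin = as.integer(margin),
                 lifetime_range = as.numeric(lifetime_range),
                 intensity_range = as.numeric(intensity_range),
                 bead_params = bead_params, flat_tau = flat_tau,
                 flat_amp = flat_amp, background_tau = background_tau,
                 texture = texture, seed = seed),
            class = "tfflim_phantom_spec")
}

# Internal: periodic Gaussian smoothing via FFT (used for random fields).
gauss_blur_fft <- function(m, sigma) {
  H <- nrow(m); W <- ncol(m)
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  ker <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(m) * ker, inverse = TRUE)) / (H * W)
}

# Internal: log-uniform draw over an interval (intensities span decades).
runif_log <- function(n, range)
  exp(stats::runif(n, log(range[1]), log(range[2])))

# Internal: standardized smooth random field.
smooth_field <- function(H, W, sigma) {
  f <- gauss_blur_fft(matrix(stats::rnorm(H * W), H, W), sigma)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic phantom
#'
#' Renders the amplitude and lifetime seed maps described by a
#' [phantom_spec()]. Map size is \code{fov} plus the margin columns on
#' the upstream side of the shear axis.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements \code{a} (amplitude map), \code{tau}
#'   (lifetime map, ns) and \code{kind}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "tfflim_phantom_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
  }
  kind <- spec$kind
  if (kind == "mixed") {
    # bead scenes dominate the pool: sparse scenes with separable
    # replicas are the regime lifetime retrieval is designed around
    kind <- sample(c("flat", "beads", "cell_like", "random_texture"), 1,
                   prob = c(0.2, 0.4, 0.2, 0.2))
    if (kind == "flat") {
      # mixed-mode flat scenes draw their constants so the training
      # distribution covers the whole lifetime/intensity domain
      lr <- spec$lifetime_range
      spec$flat_tau <- exp(stats::runif(1, log(lr[1]), log(lr[2])))
      spec$flat_amp <- runif_log(1, spec$intensity_range)
    }
  }
  H <- spec$fov[1]; W <- spec$fov[2] + spec$margin
  lo <- spec$lifetime_range[1]; hi <- spec$lifetime_range[2]
  amp <- matrix(0, H, W)
  tau <- matrix(spec$background_tau, H, W)
  if (kind == "flat") {
    amp[] <- spec$flat_amp
    tau[] <- spec$flat_tau
  } else if (kind == "beads") {
    placed <- matrix(numeric(0), 0, 3)    # cy, cx, r
    for (pop in spec$bead_params) {
      r <- pop$radius
      if (H - r <= 1 + r || W - r <= 1 + r)
        stop("infeasible bead packing: radius-", r,
             " beads do not fit in a ", H, " x ", W, " seed", call. = FALSE)
      for (b in seq_len(pop$count)) {
        ok <- FALSE
        for (try in 1:200) {
          cy <- stats::runif(1, 1 + r, H - r)
          cx <- stats::runif(1, 1 + r, W - r)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
                  placed[, 3] + r + 1)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("infeasible bead packing: could not place a radius-", r,
               " bead after 200 tries", call. = FALSE)
        placed <- rbind(placed, c(cy, cx, r))
        peak <- runif_log(1, spec$intensity_range)
        ys <- max(1, floor(cy - r - 1)):min(H, ceiling(cy + r + 1))
        xs <- max(1, floor(cx - r - 1)):min(W, ceiling(cx + r + 1))
        d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
        alpha <- pmin(1, pmax(0, r + 0.5 - d))
        amp[ys, xs] <- amp[ys, xs] + peak * alpha
        tau[ys, xs][alpha > 0] <- pop$lifetime
      }
    }
  } else if (kind == "cell_like") {
    f <- smooth_field(H, W, spec$texture$sigma)
    walls <- exp(-(f / spec$texture$wall_width)^2)   # thin ridges at f = 0
    peak <- runif_log(1, spec$intensity_range)
    amp <- peak * (spec$texture$background_frac +
                     (1 - spec$texture$background_frac) * walls)
    g <- smooth_field(H, W, 2 * spec$texture$sigma)
    tau <- exp(log(lo) + stats::pnorm(g) * (log(hi) - log(lo)))
  } else {                                # random_texture
    f <- smooth_field(H, W, spec$texture$sigma)
    g <- smooth_field(H, W, spec$texture$sigma)
    lo_a <- spec$intensity_range[1]
    amp <- lo_a * (spec$intensity_range[2] / lo_a)^stats::pnorm(f)
    tau <- exp(log(lo) + stats::pnorm(g) * (log(hi) - log(lo)))
  }
  list(a = amp, tau = tau, kind = kind)
}

#' Generate a synthetic dataset of image triplets
#'
#' For each item: draws a phantom, renders the clean CMOS and iCCD
#' images, samples intensifier noise on the iCCD, crops the lifetime
#' label to the field of view, and writes the triplet as 32-bit float
#' TIFFs plus a JSON manifest recording every seed and configuration so
#' the dataset can be regenerated bit-identically.
#'
#' @param n Number of triplets.
#' @param spec A [phantom_spec()]; its \code{margin} must cover the shear
#'   extent of \code{cfg}.
#' @param cfg A [system_config()].
#' @param det A [detector_config()].
#' @param out Output directory (created if needed).
#' @param split Train/validation/test fractions, summing to 1.
#' @param seed Master seed for the per-item seeds; defaults to
#'   \code{spec$seed}.
#' @return The manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
generate_dataset <- function(n, spec, cfg, det, out,
                             split = c(0.75, 0.125, 0.125), seed = spec$seed) {
  stopifnot(inherits(spec, "tfflim_phantom_spec"),
            inherits(cfg, "tfflim_config"),
            inherits(det, "tfflim_detector"), n >= 1)
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  margin <- (cfg$n_replicas - 1L) * cfg$y
  if (spec$margin < margin)
    stop("phantom margin (", spec$margin, ") below the shear extent (",
         margin, ")", call. = FALSE)
  if (is.null(seed)) seed <- 1L
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  item_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  bounds <- round(cumsum(split) * n)
  assignment <- rep(c("train", "val", "test"), times = diff(c(0, bounds)))
  items <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- spec
    spec_i$seed <- item_seeds[2 * i - 1]
    ph <- tryCatch(make_phantom(spec_i), error = function(e)
      stop("item ", i, ": ", conditionMessage(e), call. = FALSE))
    s <- simulate_iccd(ph$tau, ph$a, cfg, fov_width = spec$fov[2])
    s_noisy <- sample_noisy_iccd(s, det, seed = item_seeds[2 * i])
    q <- simulate_cmos(ph$tau, ph$a, cfg, fov_width = spec$fov[2])
    label <- ph$tau[, (ncol(ph$tau) - spec$fov[2] + 1):ncol(ph$tau),
                    drop = FALSE]
    files <- sprintf("item_%04d_%s.tif", i, c("cmos", "iccd", "tau"))
    res <- tryCatch({
      write_image(q, file.path(out, files[1]))
      write_image(s_noisy, file.path(out, files[2]))
      write_image(label, file.path(out, files[3]))
    }, error = function(e)
      stop("I/O failure at item ", i, ": ", conditionMessage(e),
           call. = FALSE))
    items[[i]] <- list(index = i, kind = ph$kind,
                       phantom_seed = item_seeds[2 * i - 1],
                       noise_seed = item_seeds[2 * i],
                       split = assignment[i],
                       cmos = files[1], iccd = files[2], tau = files[3])
  }
  manifest <- list(n = n, seed = seed, split = split,
                   fov = spec$fov,
                   system = config_to_list(cfg),
                   detector = config_to_list(det),
                   phantom = config_to_list(spec),
                   items = items)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Regenerate a dataset from its manifest
#'
#' Re-runs [generate_dataset()] with the configurations and master seed
#' recorded in a manifest; output files are bit-identical to the original
#' run.
#'
#' @param manifest_path Path to a \code{manifest.json}.
#' @param out Output directory.
#' @return The manifest of the regenerated dataset, invisibly.
#' @export
regenerate_dataset <- function(manifest_path, out) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  sys_vals <- man$system
  sys_vals$gate <- apply_section(gate_profile, sys_vals$gate, "system/gate")
  cfg <- apply_section(system_config, sys_vals, "system")
  det <- apply_section(detector_config, man$detector, "detector")
  ph_vals <- man$phantom
  if (!is.null(ph_vals$bead_params) && is.data.frame(ph_vals$bead_params))
    ph_vals$bead_params <- lapply(seq_len(nrow(ph_vals$bead_params)),
                                  function(i) as.list(ph_vals$bead_params[i, ]))
  spec <- apply_section(phantom_spec, ph_vals, "phantom")
  generate_dataset(man$n, spec, cfg, det, out, split = man$split,
                   seed = man$seed)
}
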