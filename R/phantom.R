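# Synthetic terahertz wheat-kernel phantoms.
#
# Real THz reflectance images of wheat show bright kernel-shaped blobs on an
# exactly-zero (background-removed) field; as mold progresses, the kernel
# interior loses intensity and gains texture as nutrients are consumed. The
# phantoms model those *spatial* statistics only: rotated elliptical kernels
# with a smooth radial reflectance profile, multiplicative interior speckle,
# and a suppressed-intensity patch whose area fraction grows with mold level.
# No spectral/physical wave propagation is modelled.

#' Phantom image configuration
#'
#' @param canvas_h,canvas_w canvas size in pixels (>= 32).
#' @param n_kernels wheat kernels per image.
#' @param kernel_axis_range min/max semi-axis length in pixels; kernels must
#'   fit inside the canvas.
#' @param mold_level ordinal contamination grade 0-3 (normal, slight,
#'   moderate, serious).
#' @param speckle_amp multiplicative interior speckle amplitude in `[0, 1]`;
#'   default `0.05 + 0.1 * mold_level`.
#' @param decay_frac fraction of each kernel interior covered by a
#'   suppressed-intensity patch, in `[0, 1]`; default `0.15 * mold_level`.
#' @param seed RNG seed; the same (config, seed) gives bit-identical images.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(canvas_h = 64L, canvas_w = 64L, n_kernels = 3L,
                           kernel_axis_range = c(6, 12), mold_level = 0L,
                           speckle_amp = NULL, decay_frac = NULL, seed = 1L) {
  if (canvas_h < 32L || canvas_w < 32L)
    stop("phantom canvas must be at least 32 x 32")
  if (mold_level < 0L || mold_level > 3L)
    stop("mold_level must be an integer in 0..3")
  if (length(kernel_axis_range) != 2L || any(kernel_axis_range <= 0))
    stop("kernel_axis_range must be two positive lengths")
  if (2 * max(kernel_axis_range) >= min(canvas_h, canvas_w))
    stop("kernel axes do not fit inside the canvas")
  m <- as.integer(mold_level)
  cfg <- list(canvas_h = as.integer(canvas_h), canvas_w = as.integer(canvas_w),
              n_kernels = as.integer(n_kernels),
              kernel_axis_range = as.numeric(kernel_axis_range),
              mold_level = m,
              speckle_amp = if (is.null(speckle_amp)) 0.05 + 0.1 * m else speckle_amp,
              decay_frac = if (is.null(decay_frac)) 0.15 * m else decay_frac,
              seed = as.integer(seed))
  if (cfg$speckle_amp < 0 || cfg$speckle_amp > 1)
    stop("speckle_amp must lie in [0, 1]")
  if (cfg$decay_frac < 0 || cfg$decay_frac > 1)
    stop("decay_frac must lie in [0, 1]")
  class(cfg) <- "phantom_config"
  cfg
}

# intensity multiplier inside the suppressed (moldy) patch
.decay_suppression <- 0.35

#' Render a clean phantom image
#'
#' Places `n_kernels` non-overlapping rotated ellipses (best effort, up to 50
#' placement retries each) on an exactly-zero background. Each kernel carries
#' a smooth radial reflectance profile peaking at its centre, multiplicative
#' speckle of amplitude `speckle_amp`, and a suppressed-intensity sub-ellipse
#' covering `decay_frac` of its area. The same random draws are consumed at
#' every mold level, so for a fixed seed the levels differ only through the
#' speckle amplitude and decay fraction.
#'
#' @param cfg a [phantom_config()].
#' @return numeric matrix in `[0, 1]`, zero outside the kernels.
#' @export
#' @examples
#' img <- render_phantom(phantom_config(seed = 7))
#' range(img)
render_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    H <- cfg$canvas_h; W <- cfg$canvas_w
    img <- matrix(0, H, W)
    occupied <- matrix(FALSE, H, W)
    placed <- 0L
    for (kn in seq_len(cfg$n_kernels)) {
      ok <- FALSE
      for (try in seq_len(50L)) {
        a <- stats::runif(1, cfg$kernel_axis_range[1], cfg$kernel_axis_range[2])
        b <- stats::runif(1, cfg$kernel_axis_range[1], cfg$kernel_axis_range[2])
        theta <- stats::runif(1, 0, pi)
        marg <- ceiling(1.2 * max(a, b)) + 1
        cy <- stats::runif(1, marg + 1, H - marg)
        cx <- stats::runif(1, marg + 1, W - marg)
        peak <- stats::runif(1, 0.65, 0.95)
        # always consume the texture draws so the RNG stream is identical
        # across mold levels
        poff_r <- stats::runif(1, 0, 1)
        poff_t <- stats::runif(1, 0, 2 * pi)
        y0 <- max(1L, floor(cy - marg)); y1 <- min(H, ceiling(cy + marg))
        x0 <- max(1L, floor(cx - marg)); x1 <- min(W, ceiling(cx + marg))
        yy <- matrix(seq(y0, y1) - cy, y1 - y0 + 1L, x1 - x0 + 1L)
        xx <- matrix(seq(x0, x1) - cx, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE)
        u <- cos(theta) * xx + sin(theta) * yy
        v <- -sin(theta) * xx + cos(theta) * yy
        r2 <- (u / a)^2 + (v / b)^2
        mask <- r2 <= 1
        # inflated footprint keeps a separation gap between kernels so that
        # painted masks never touch
        mask_gap <- r2 <= 1.4
        spk <- stats::runif(sum(mask), -1, 1)
        if (any(occupied[y0:y1, x0:x1][mask_gap])) next
        intensity <- peak * (1 - r2[mask])^0.7
        intensity <- intensity * (1 + cfg$speckle_amp * spk)
        if (cfg$decay_frac > 0) {
          s <- sqrt(cfg$decay_frac)
          # sub-ellipse centre offset in normalised elliptical coordinates,
          # constrained so the patch stays inside the kernel
          or <- poff_r * (1 - s)
          ou <- or * cos(poff_t); ov <- or * sin(poff_t)
          rp2 <- ((u[mask] / a - ou)^2 + (v[mask] / b - ov)^2) / s^2
          intensity[rp2 <= 1] <- intensity[rp2 <= 1] * .decay_suppression
        }
        sub <- img[y0:y1, x0:x1]
        sub[mask] <- pmin(pmax(intensity, 0), 1)
        img[y0:y1, x0:x1] <- sub
        occ <- occupied[y0:y1, x0:x1]
        occ[mask_gap] <- TRUE
        occupied[y0:y1, x0:x1] <- occ
        ok <- TRUE
        break
      }
      if (ok) placed <- placed + 1L
    }
    if (placed < cfg$n_kernels)
      warning(sprintf("placed %d of %d kernels after retries", placed,
                      cfg$n_kernels))
    img
  })
}

#' Noise specification
#'
#' @param kind one of `"awgn_snr"` (white Gaussian noise at a target SNR),
#'   `"awgn_sigma"` (fixed standard deviation), `"power_drift"` (row-wise
#'   multiplicative source-power fluctuation).
#' @param snr_db target signal-to-noise ratio in dB; signal power is the mean
#'   squared clean intensity over the whole image.
#' @param sigma noise standard deviation in intensity units (>= 0).
#' @param drift_amp relative gain amplitude in `[0, 1)`.
#' @param seed RNG seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(kind = c("awgn_snr", "awgn_sigma", "power_drift"),
                       snr_db = NULL, sigma = NULL, drift_amp = NULL,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "awgn_snr" && (is.null(snr_db) || !is.finite(snr_db)))
    stop("awgn_snr requires a finite snr_db")
  if (kind == "awgn_sigma" && (is.null(sigma) || sigma < 0))
    stop("awgn_sigma requires sigma >= 0")
  if (kind == "power_drift" &&
      (is.null(drift_amp) || drift_amp < 0 || drift_amp >= 1))
    stop("power_drift requires drift_amp in [0, 1)")
  structure(list(kind = kind, snr_db = snr_db, sigma = sigma,
                 drift_amp = drift_amp, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add noise to a clean image
#'
#' For `awgn_snr` the injected zero-mean Gaussian noise has variance
#' `mean(clean^2) / 10^(snr_db / 10)`. The result is clipped to `[0, 1]`
#' after noise addition; the empirical SNR (measured before clipping as
#' `10*log10(sum(clean^2) / sum(noise^2))`) is attached as attribute
#' `snr_db_empirical`.
#'
#' @param clean numeric matrix in `[0, 1]`.
#' @param spec a [noise_spec()].
#' @return noisy matrix in `[0, 1]` with attribute `snr_db_empirical`.
#' @export
add_noise <- function(clean, spec) {
  stopifnot(inherits(spec, "noise_spec"), is.matrix(clean))
  with_seed(spec$seed, {
    noisy_pre <- switch(spec$kind,
      awgn_snr = {
        p <- mean(clean^2)
        v <- p / 10^(spec$snr_db / 10)
        clean + stats::rnorm(length(clean), 0, sqrt(v))
      },
      awgn_sigma = clean + stats::rnorm(length(clean), 0, spec$sigma),
      power_drift = {
        H <- nrow(clean)
        g <- cumsum(stats::rnorm(H))
        g <- g - mean(g)
        win <- max(3L, H %/% 8L)
        gs <- as.numeric(stats::filter(g, rep(1 / win, win), sides = 2))
        gs[is.na(gs)] <- g[is.na(gs)]
        mx <- max(abs(gs))
        if (mx > 0) gs <- gs / mx
        clean * (1 + spec$drift_amp * gs)
      },
      stop("unknown noise kind: ", spec$kind))
    noise <- noisy_pre - clean
    snr_emp <- if (sum(noise^2) > 0)
      10 * log10(sum(clean^2) / sum(noise^2)) else Inf
    noisy <- pmin(pmax(noisy_pre, 0), 1)
    attr(noisy, "snr_db_empirical") <- snr_emp
    noisy
  })
}

#' Generate paired clean/noisy phantoms for all four mold levels
#'
#' Produces `n_per_level` pairs at each mold level 0-3. Sample `i` (0-based
#' global index over levels) renders its phantom with seed `master_seed + i`
#' and draws its noise with seed `master_seed + 100000 + i`, so the whole
#' dataset is a pure function of the configuration and master seed.
#'
#' @param n_per_level pairs per mold level (>= 1).
#' @param phantom_cfg a [phantom_config()] template; its `mold_level`,
#'   `speckle_amp`, `decay_frac` and `seed` fields are overridden per sample.
#' @param noise a [noise_spec()] template; its `seed` is overridden.
#' @param master_seed integer master seed.
#' @return list of pairs: `id`, `clean`, `noisy`, `mold_level`, `seed`.
#' @export
generate_pairs <- function(n_per_level, phantom_cfg = phantom_config(),
                           noise = noise_spec("awgn_snr", snr_db = 30),
                           master_seed = 1L) {
  stopifnot(n_per_level >= 1L)
  pairs <- vector("list", 4L * n_per_level)
  idx <- 0L
  for (m in 0:3) {
    for (i in seq_len(n_per_level)) {
      pc <- phantom_cfg
      pc$mold_level <- m
      pc$speckle_amp <- 0.05 + 0.1 * m
      pc$decay_frac <- 0.15 * m
      pc$seed <- as.integer(master_seed + idx)
      ns <- noise
      ns$seed <- as.integer(master_seed + 100000L + idx)
      clean <- render_phantom(pc)
      noisy <- add_noise(clean, ns)
      idx <- idx + 1L
      pairs[[idx]] <- list(id = sprintf("L%d_%03d", m, i), clean = clean,
                           noisy = noisy, mold_level = m, noise = ns,
                           seed = pc$seed)
    }
  }
  pairs
}

#' Generate a phantom dataset on disk
#'
#' Writes 16-bit grayscale TIFF pairs (clean and noisy) for all four mold
#' levels plus a CSV manifest. With `cube_layers` each sample becomes a
#' multi-page TIFF frequency cube whose kernel intensity decreases slowly
#' across layers; noise is drawn independently per layer.
#'
#' @inheritParams generate_pairs
#' @param out_dir output directory (created if missing).
#' @param cube_layers `NULL` for 2-D images, or the number of cube layers.
#' @return the manifest data.frame (invisibly), with columns `id`,
#'   `mold_level`, `clean_path`, `noisy_path`, `noise_kind`, `snr_db`, `seed`.
#' @export
generate_dataset <- function(n_per_level, phantom_cfg = phantom_config(),
                             noise = noise_spec("awgn_snr", snr_db = 30),
                             out_dir, master_seed = 1L, cube_layers = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  pairs <- generate_pairs(n_per_level, phantom_cfg, noise, master_seed)
  rows <- lapply(pairs, function(p) {
    cp <- file.path(out_dir, paste0(p$id, "_clean.tif"))
    np <- file.path(out_dir, paste0(p$id, "_noisy.tif"))
    if (is.null(cube_layers)) {
      write_image(p$clean, cp)
      write_image(p$noisy, np)
    } else {
      scales <- seq(1, 0.85, length.out = cube_layers)
      cl <- lapply(scales, function(s) p$clean * s)
      ns <- lapply(seq_len(cube_layers), function(l) {
        sp <- p$noise
        sp$seed <- as.integer(sp$seed + 1000L * l)
        add_noise(cl[[l]], sp)
      })
      write_image(simplify2array(cl), cp)
      write_image(simplify2array(ns), np)
    }
    data.frame(id = p$id, mold_level = p$mold_level, clean_path = cp,
               noisy_path = np, noise_kind = p$noise$kind,
               snr_db = if (is.null(p$noise$snr_db)) NA_real_ else p$noise$snr_db,
               seed = p$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
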