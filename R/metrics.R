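# Image-quality metrics: MSE training loss, PSNR and SSIM.
#
# The training loss is the standard mean squared error over all pixels; the
# published formula for it is typographically corrupt (sign flipped, square
# missing) but the surrounding text names it "mean square error", so the
# standard definition is implemented. PSNR is 10*log10(L^2 / MSE). SSIM uses
# the canonical 11x11 Gaussian window (sigma 1.5) with k1 = 0.01, k2 = 0.03;
# a global single-window variant is available.

#' Mean squared error
#'
#' `(1/N) * sum((y - yhat)^2)` over all pixels. Accepts matrices/arrays or
#' lists of them (a batch); batch elements are pooled pixel-wise, so for
#' same-sized images the result equals the mean of per-image MSEs.
#'
#' @param pred,target numeric arrays of identical shape, or lists of them.
#' @return non-negative scalar.
#' @export
mse_loss <- function(pred, target) {
  if (is.list(pred)) pred <- unlist(pred, use.names = FALSE)
  if (is.list(target)) target <- unlist(target, use.names = FALSE)
  if (length(pred) != length(target))
    stop("mse_loss: shapes differ (", length(pred), " vs ", length(target),
         " pixels)")
  mean((as.numeric(pred) - as.numeric(target))^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(L^2 / MSE(x, y))`. Identical images have zero MSE; the
#' documented sentinel `Inf` is returned in that case.
#'
#' @param x,y images of identical shape (reference and test).
#' @param L dynamic range of pixel values (1 for unit-scaled images, 255 for
#'   8-bit).
#' @return PSNR in decibels (possibly `Inf`).
#' @export
#' @examples
#' psnr(matrix(0, 4, 4), matrix(0.1, 4, 4))  # 20 dB
psnr <- function(x, y, L = 1) {
  stopifnot(L > 0)
  m <- mse_loss(x, y)
  if (m == 0) return(Inf)
  10 * log10(L^2 / m)
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

# valid-mode separable windowed filtering via banded matrix products:
# returns the (H-size+1) x (W-size+1) map of local weighted sums.
win_filter <- function(x, g) {
  H <- nrow(x); W <- ncol(x); n <- length(g)
  Bh <- matrix(0, H, H - n + 1L)
  for (i in seq_len(H - n + 1L)) Bh[i:(i + n - 1L), i] <- g
  Bw <- matrix(0, W, W - n + 1L)
  for (i in seq_len(W - n + 1L)) Bw[i:(i + n - 1L), i] <- g
  crossprod(Bh, x) %*% Bw
}

#' Structural similarity index (SSIM)
#'
#' Computes the local-statistics SSIM map under a Gaussian window (size 11,
#' sigma 1.5; weighted population moments) and returns its mean:
#' `((2*mux*muy + c1) * (2*sxy + c2)) / ((mux^2 + muy^2 + c1) *
#' (sx2 + sy2 + c2))` with `c1 = (k1*L)^2`, `c2 = (k2*L)^2`. The `"global"`
#' window computes a single statistic over the whole image instead.
#'
#' @inheritParams psnr
#' @param k1,k2 stabilisation constants.
#' @param window `"gaussian"` (local, the reference convention) or
#'   `"global"`.
#' @param win_size,sigma Gaussian window size and width.
#' @return scalar in `[-1, 1]` (1 for identical images).
#' @export
ssim <- function(x, y, L = 1, k1 = 0.01, k2 = 0.03,
                 window = c("gaussian", "global"), win_size = 11L,
                 sigma = 1.5) {
  window <- match.arg(window)
  if (!all(dim(x) == dim(y))) stop("ssim: images must share a shape")
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  if (window == "global") {
    mux <- mean(x); muy <- mean(y)
    sx2 <- mean((x - mux)^2); sy2 <- mean((y - muy)^2)
    sxy <- mean((x - mux) * (y - muy))
    return(((2 * mux * muy + c1) * (2 * sxy + c2)) /
             ((mux^2 + muy^2 + c1) * (sx2 + sy2 + c2)))
  }
  if (min(dim(x)) < win_size)
    stop("image smaller than the SSIM window (", win_size,
         "); use a smaller window or window = \"global\"")
  g <- gaussian_kernel_1d(win_size, sigma)
  mux <- win_filter(x, g); muy <- win_filter(y, g)
  sx2 <- win_filter(x * x, g) - mux^2
  sy2 <- win_filter(y * y, g) - muy^2
  sxy <- win_filter(x * y, g) - mux * muy
  num <- (2 * mux * muy + c1) * (2 * sxy + c2)
  den <- (mux^2 + muy^2 + c1) * (sx2 + sy2 + c2)
  mean(num / den)
}

#' Per-mold-level metric report
#'
#' Groups (clean, denoised) pairs by mold level and reports the per-level
#' mean PSNR and SSIM with group sizes, the shape in which denoising results
#' are tabulated.
#'
#' @param pairs list of lists with fields `clean`, `denoised` and
#'   `mold_level`.
#' @param L dynamic range passed to [psnr()] / [ssim()].
#' @param ... further arguments passed to [ssim()].
#' @return data.frame with columns `mold_level`, `n`, `psnr_db`, `ssim`.
#' @export
evaluate_set <- function(pairs, L = 1, ...) {
  stopifnot(length(pairs) >= 1L)
  levels <- vapply(pairs, function(p) p$mold_level, numeric(1))
  present <- sort(unique(levels))
  missing_lv <- setdiff(0:3, present)
  if (length(missing_lv) > 0)
    warning("no pairs for mold level(s) ", paste(missing_lv, collapse = ", "),
            "; omitted from report")
  rows <- lapply(present, function(m) {
    ps <- pairs[levels == m]
    pv <- vapply(ps, function(p) psnr(p$clean, p$denoised, L), numeric(1))
    sv <- vapply(ps, function(p) ssim(p$clean, p$denoised, L, ...), numeric(1))
    data.frame(mold_level = m, n = length(ps), psnr_db = mean(pv),
               ssim = mean(sv))
  })
  do.call(rbind, rows)
}

#' Write a metric report to CSV and JSON
#'
#' @param report data.frame from [evaluate_set()].
#' @param path output path without extension; `.csv` and `.json` are written.
#' @param config optional configuration list echoed into the JSON.
#' @export
write_metrics_report <- function(report, path, config = NULL) {
  utils::write.csv(report, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(report = report, config = config),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
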