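# Image reading/writing (16-bit TIFF/PNG), tiled whole-image denoising and
# the denoise command with its JSON sidecar.

#' Read a grayscale image
#'
#' Reads PNG or TIFF into a numeric matrix scaled to `[0, 1]` by the
#' container's bit depth (the readers already return unit-scaled values).
#' RGB images are converted by luminance average with a warning. Multi-page
#' TIFF cubes return an `H x W x layers` array. The source bit depth is
#' attached as attribute `bit_depth` so that the metric dynamic range can be
#' chosen accordingly.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix (or array for cubes) in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, " (no such file)")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    if (length(pages) > 1L) {
      # multi-page cube: layers are frequency slices, never colour channels
      img <- simplify2array(lapply(pages, as.matrix))
      attr(img, "bit_depth") <- bits
      return(img)
    }
    img <- pages[[1]]
  } else {
    stop("cannot read image: ", path, " (unsupported format '", ext, "')")
  }
  d <- dim(img)
  if (length(d) == 3L && d[3] %in% c(2L, 3L, 4L)) {
    warning("multi-channel image converted to grayscale by luminance average: ",
            path)
    img <- apply(img[, , 1:min(3, d[3]), drop = FALSE], c(1, 2), mean)
  }
  attr(img, "bit_depth") <- bits
  img
}

#' Write a grayscale image (losslessly)
#'
#' 16-bit TIFF by default. Out-of-range values are clamped to `[0, 1]` with a
#' warning. A 3-D array is written as a multi-page TIFF cube. PNG output is
#' 8-bit (the PNG writer's native depth here); use TIFF to preserve 16-bit
#' dynamic range.
#'
#' @param img numeric matrix (or `H x W x layers` array) in `[0, 1]`.
#' @param path output path; format chosen by extension.
#' @param bit_depth 8 or 16 (TIFF only).
#' @export
write_image <- function(img, path, bit_depth = 16L) {
  if (min(img) < 0 || max(img) > 1) {
    warning("image values outside [0, 1] clamped before writing: ", path)
    img <- pmin(pmax(img, 0), 1)
  }
  ext <- tolower(tools::file_ext(path))
  # quantize by rounding (the writers truncate), so the round trip error is
  # at most half a grey level
  levels <- 2^bit_depth - 1
  img <- round(img * levels) / levels
  if (ext == "png") {
    if (bit_depth != 8L)
      warning("PNG output is written at 8-bit depth; use TIFF for 16-bit")
    png::writePNG(as.matrix(img), path)
  } else if (ext %in% c("tif", "tiff")) {
    what <- if (length(dim(img)) == 3L)
      lapply(seq_len(dim(img)[3]), function(l) img[, , l]) else img
    tiff::writeTIFF(what, path, bits.per.sample = as.integer(bit_depth),
                    compression = "none")
  } else {
    stop("unsupported output format: ", ext)
  }
  invisible(path)
}

feather_weights <- function(len, ov_lo, ov_hi) {
  w <- rep(1, len)
  if (ov_lo > 0) w[seq_len(ov_lo)] <- seq_len(ov_lo) / (ov_lo + 1)
  if (ov_hi > 0) w[len - seq_len(ov_hi) + 1L] <- seq_len(ov_hi) / (ov_hi + 1)
  w
}

tile_starts <- function(n, tile, overlap) {
  if (n <= tile) return(1L)
  st <- seq(1L, n - tile + 1L, by = tile - overlap)
  if (st[length(st)] + tile - 1L < n) st <- c(st, n - tile + 1L)
  unique(st)
}

#' Denoise a whole image, tiling large inputs
#'
#' Images larger than `tile` pixels per side are processed in overlapping
#' tiles (default 256 with 16 pixels of overlap) and re-assembled by linear
#' feathering in the overlap, bounding memory use for arbitrarily large
#' scans.
#'
#' @param model a `grrdb_model`.
#' @param img numeric matrix in `[0, 1]`.
#' @param tile tile side in pixels.
#' @param overlap overlap between adjacent tiles in pixels.
#' @param clip clip the result to `[0, 1]`.
#' @return denoised matrix of the same shape.
#' @export
denoise_image <- function(model, img, tile = 256L, overlap = 16L,
                          clip = TRUE) {
  H <- nrow(img); W <- ncol(img)
  if (H <= tile && W <= tile) return(grrdb_predict(model, img, clip = clip))
  acc <- matrix(0, H, W)
  wt <- matrix(0, H, W)
  for (sy in tile_starts(H, tile, overlap)) {
    for (sx in tile_starts(W, tile, overlap)) {
      ey <- min(sy + tile - 1L, H); ex <- min(sx + tile - 1L, W)
      p <- grrdb_predict(model, img[sy:ey, sx:ex], clip = FALSE)
      wy <- feather_weights(ey - sy + 1L, if (sy > 1L) overlap else 0L,
                            if (ey < H) overlap else 0L)
      wx <- feather_weights(ex - sx + 1L, if (sx > 1L) overlap else 0L,
                            if (ex < W) overlap else 0L)
      w2 <- outer(wy, wx)
      acc[sy:ey, sx:ex] <- acc[sy:ey, sx:ex] + p * w2
      wt[sy:ey, sx:ex] <- wt[sy:ey, sx:ex] + w2
    }
  }
  out <- acc / wt
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Denoise image files with a checkpoint
#'
#' Loads a checkpoint, denoises one image file (or every PNG/TIFF in a
#' directory), writes 16-bit TIFF outputs and a JSON sidecar recording the
#' checkpoint MD5 hash and the full model configuration. Existing outputs
#' are never overwritten unless `force = TRUE`.
#'
#' @param checkpoint path to a checkpoint from [save_checkpoint()].
#' @param in_path input image file or directory.
#' @param out_path output file (single input) or directory.
#' @param tile,overlap tiling parameters, see [denoise_image()].
#' @param force overwrite existing outputs.
#' @return character vector of written output paths, invisibly.
#' @export
denoise_command <- function(checkpoint, in_path, out_path, tile = 256L,
                            overlap = 16L, force = FALSE) {
  model <- load_checkpoint(checkpoint)
  files <- if (dir.exists(in_path))
    list.files(in_path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  else in_path
  if (length(files) == 0L) stop("no input images found in ", in_path)
  outs <- if (dir.exists(in_path))
    file.path(out_path, paste0(tools::file_path_sans_ext(basename(files)),
                               "_denoised.tif"))
  else out_path
  sidecar <- paste0(tools::file_path_sans_ext(outs[1]), "_sidecar.json")
  for (f in c(outs, sidecar))
    if (file.exists(f) && !force)
      stop("output exists (use force = TRUE to overwrite): ", f)
  if (dir.exists(in_path) && !dir.exists(out_path))
    dir.create(out_path, recursive = TRUE)
  for (i in seq_along(files)) {
    img <- read_image(files[i])
    if (length(dim(img)) == 3L) {
      den <- simplify2array(lapply(seq_len(dim(img)[3]), function(l)
        denoise_image(model, img[, , l], tile, overlap)))
    } else {
      den <- denoise_image(model, img, tile, overlap)
    }
    write_image(den, outs[i])
  }
  jsonlite::write_json(
    list(checkpoint = checkpoint,
         checkpoint_md5 = unname(tools::md5sum(checkpoint)),
         config = unclass(model$config), inputs = files, outputs = outs,
         tile = tile, overlap = overlap,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(outs)
}
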