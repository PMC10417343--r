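# Independent reference implementations used as oracles. All are written as
# direct loops over the mathematical definitions and share no code with the
# package's computational path.

# plain cross-correlation, zero "same" padding, stride 1
naive_conv2d <- function(x, w, b, dilation = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  ctr <- (k - 1) / 2
  y <- array(0, c(H, W, Cout))
  for (o in seq_len(Cout)) {
    for (h in seq_len(H)) for (wi in seq_len(W)) {
      acc <- b[o]
      for (c in seq_len(Cin)) for (i in seq_len(k)) for (j in seq_len(k)) {
        hh <- h + dilation * (i - 1 - ctr)
        ww <- wi + dilation * (j - 1 - ctr)
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
          acc <- acc + w[i, j, c, o] * x[hh, ww, c]
      }
      y[h, wi, o] <- acc
    }
  }
  y
}

# depthwise with channel multiplier; w dim (k, k, mult, C)
naive_dwconv2d <- function(x, w, b, dilation = 1L, mult = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  k <- dim(w)[1]
  ctr <- (k - 1) / 2
  y <- array(0, c(H, W, C * mult))
  for (c in seq_len(C)) for (m in seq_len(mult)) {
    o <- (c - 1) * mult + m
    for (h in seq_len(H)) for (wi in seq_len(W)) {
      acc <- b[o]
      for (i in seq_len(k)) for (j in seq_len(k)) {
        hh <- h + dilation * (i - 1 - ctr)
        ww <- wi + dilation * (j - 1 - ctr)
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
          acc <- acc + w[i, j, m, c] * x[hh, ww, c]
      }
      y[h, wi, o] <- acc
    }
  }
  y
}

naive_lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# channel-wise mean/max pooling maps computed per pixel
naive_chan_pool <- function(x) {
  d <- dim(x)
  mn <- matrix(0, d[1], d[2]); mx <- matrix(0, d[1], d[2])
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
    mn[h, w] <- mean(x[h, w, ])
    mx[h, w] <- max(x[h, w, ])
  }
  list(mean = mn, max = mx)
}

# global average/max channel vectors computed per channel
naive_global_pool <- function(x) {
  C <- dim(x)[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(x[, , c])
    mx[c] <- max(x[, , c])
  }
  list(avg = avg, max = mx)
}

# windowed SSIM by explicit loop over valid window positions
naive_ssim <- function(x, y, L = 1, k1 = 0.01, k2 = 0.03, win = 11L,
                       sigma = 1.5) {
  r <- (win - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2)); g1 <- g1 / sum(g1)
  g2 <- as.numeric(outer(g1, g1))
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (h in seq_len(H - win + 1L)) for (w in seq_len(W - win + 1L)) {
    px <- as.numeric(x[h:(h + win - 1L), w:(w + win - 1L)])
    py <- as.numeric(y[h:(h + win - 1L), w:(w + win - 1L)])
    mux <- sum(g2 * px); muy <- sum(g2 * py)
    sx2 <- sum(g2 * px * px) - mux^2
    sy2 <- sum(g2 * py * py) - muy^2
    sxy <- sum(g2 * px * py) - mux * muy
    vals <- c(vals, ((2 * mux * muy + c1) * (2 * sxy + c2)) /
                ((mux^2 + muy^2 + c1) * (sx2 + sy2 + c2)))
  }
  mean(vals)
}

# connected foreground components by breadth-first flood fill,
# 8-connectivity
flood_fill_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  ncomp <- 0L
  for (h0 in seq_len(H)) for (w0 in seq_len(W)) {
    if (!mask[h0, w0] || lab[h0, w0] > 0L) next
    ncomp <- ncomp + 1L
    queue <- matrix(c(h0, w0), 1, 2)
    lab[h0, w0] <- ncomp
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (dh in -1:1) for (dw in -1:1) {
        hh <- p[1] + dh; ww <- p[2] + dw
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= W &&
            mask[hh, ww] && lab[hh, ww] == 0L) {
          lab[hh, ww] <- ncomp
          queue <- rbind(queue, c(hh, ww))
        }
      }
    }
  }
  ncomp
}

# run a block's forward on a plain array (no tape) and return a plain array
run_block <- function(block, x) {
  out <- block$fn(grrdb:::ag_input(x))
  out$value
}

rand_fm <- function(H, W, C, sd = 1) array(stats::rnorm(H * W * C, 0, sd), c(H, W, C))
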