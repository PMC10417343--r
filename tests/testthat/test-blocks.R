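# Unit tests per network block: closed-form limits, residual identities and
# agreement with naive loop oracles on small random inputs.

desk8 <- function(...) model_config(base_channels = 8L, ...)

test_that("LKA block reduces to identity / zero in the attention limits", {
  set.seed(21)
  cfg <- desk8()
  blk <- grrdb:::new_lka(8L, cfg)
  x <- rand_fm(8, 8, 8)
  # zero path weights, pointwise bias 1 -> attention map A = 1 -> out = x
  grrdb:::zero_params(blk)
  blk$layers$pw$params$b$value[] <- 1
  expect_equal(run_block(blk, x), x)
  # everything zero -> A = 0 -> out = 0
  blk$layers$pw$params$b$value[] <- 0
  expect_equal(run_block(blk, x), x * 0)
})

test_that("LKA block matches the naive convolution-composition oracle", {
  set.seed(22)
  cfg <- model_config(base_channels = 4L, ca_reduction = 2L)
  blk <- grrdb:::new_lka(4L, cfg)
  x <- rand_fm(8, 8, 4)
  ly <- blk$layers
  a <- naive_dwconv2d(x, ly$dw$params$w$value, ly$dw$params$b$value, 1L, 1L)
  a <- naive_dwconv2d(a, ly$dwd$params$w$value, ly$dwd$params$b$value,
                      cfg$lka_dilation, 1L)
  a <- naive_conv2d(a, ly$pw$params$w$value, ly$pw$params$b$value)
  expect_lt(max(abs(run_block(blk, x) - a * x)), 1e-5)
})

test_that("ghost convolution: channel bookkeeping and parameter savings", {
  # published example: 64 -> 64, ratio 2, 3x3 primary, no bias
  g <- grrdb:::new_ghost_conv(64L, 64L, ratio = 2L, k = 3L, bias = FALSE)
  expect_equal(grrdb:::count_params(g), 64 * 32 * 9 + 32 * 9)  # 18720
  expect_equal(64 * 64 * 9, 36864)
  expect_gt(1 - grrdb:::count_params(g) / (64 * 64 * 9), 0.49)
  # ratio 1 degenerates to a plain convolution
  g1 <- grrdb:::new_ghost_conv(4L, 8L, ratio = 1L, k = 3L)
  expect_identical(g1$layers$primary$kind, "conv")
  expect_identical(dim(run_block(g1, rand_fm(8, 8, 4)))[3], 8L)
  # requested output channels always honoured, including non-divisible
  # primary/cheap splits
  for (co in c(4L, 6L, 8L)) {
    gc_ <- grrdb:::new_ghost_conv(4L, co, ratio = 2L, k = 3L)
    expect_identical(dim(run_block(gc_, rand_fm(8, 8, 4)))[3], co)
  }
  expect_error(grrdb:::new_ghost_conv(4L, 6L, ratio = 4L), "divisible")
})

test_that("ghost convolution matches its primary + cheap map construction", {
  set.seed(23)
  g <- grrdb:::new_ghost_conv(4L, 8L, ratio = 2L, k = 3L)
  x <- rand_fm(8, 8, 4)
  p <- naive_conv2d(x, g$layers$primary$params$w$value,
                    g$layers$primary$params$b$value)
  q <- naive_dwconv2d(p, g$layers$cheap$params$w$value,
                      g$layers$cheap$params$b$value, 1L, g$split$mult)
  ref <- array(c(p, q[, , seq_len(g$split$cheap)]), c(8, 8, 8))
  expect_lt(max(abs(run_block(g, x) - ref)), 1e-5)
})

test_that("ghost-LKA block is an exact identity at zero weights and its
           residual term is recoverable", {
  set.seed(24)
  cfg <- desk8()
  blk <- grrdb:::new_ghost_lka(8L, cfg)
  x <- rand_fm(8, 8, 8)
  out <- run_block(blk, x)
  expect_identical(dim(out), dim(x))
  # removing the residual sum changes the output by exactly x
  z <- run_block(blk$layers$ghost,
                 run_block(blk$layers$lka, x))
  expect_lt(max(abs((out - x) - z)), 1e-10)
  grrdb:::zero_params(blk)
  expect_equal(run_block(blk, x), x)
})

test_that("dense block: identity at zero weights, concat widths, oracle", {
  set.seed(25)
  cfg <- desk8()
  db <- grrdb:::new_dense_block(8L, cfg)
  # conv k receives C + (k-1) * growth input channels
  expect_equal(db$widths, 8 + (0:4) * cfg$growth)
  expect_equal(vapply(db$layers, function(l) l$cin, numeric(1),
                      USE.NAMES = FALSE), as.numeric(db$widths))
  x <- rand_fm(8, 8, 8)
  # naive forward replay with loop convolutions
  feats <- list(x)
  for (i in 1:4) {
    inp <- if (i == 1) x else array(unlist(feats), c(8, 8, db$widths[i]))
    feats[[i + 1]] <- naive_lrelu(
      naive_conv2d(inp, db$layers[[i]]$params$w$value,
                   db$layers[[i]]$params$b$value), cfg$lrelu_slope)
  }
  last <- naive_conv2d(array(unlist(feats), c(8, 8, db$widths[5])),
                       db$layers[[5]]$params$w$value,
                       db$layers[[5]]$params$b$value)
  expect_lt(max(abs(run_block(db, x) - (x + cfg$res_scale * last))), 1e-5)
  grrdb:::zero_params(db)
  expect_equal(run_block(db, x), x)
  # a zero residual scale makes the block the identity regardless of weights
  cfg0 <- desk8()
  cfg0$res_scale <- 0
  db0 <- grrdb:::new_dense_block(8L, cfg0)
  expect_equal(run_block(db0, x), x)
})

test_that("RRDB: nested residual identity and closed-form propagation", {
  set.seed(26)
  cfg <- desk8()
  blk <- grrdb:::new_rrdb(8L, cfg)
  x <- rand_fm(8, 8, 8)
  grrdb:::zero_params(blk)
  expect_equal(run_block(blk, x), x)
  # single dense block, all weights zero except an identity-initialized last
  # conv: dense output (1 + beta) * x; the outer interpolation gives
  # x + beta * ((1 + beta) * x - x) = (1 + beta^2) * x = 1.04 * x at beta 0.2
  cfg1 <- desk8(n_dense_per_rrdb = 1L)
  blk1 <- grrdb:::new_rrdb(8L, cfg1)
  grrdb:::zero_params(blk1)
  wlast <- blk1$layers$dense1$layers$conv5$params$w$value
  for (c in 1:8) wlast[2, 2, c, c] <- 1  # centre tap on the x-part of the concat
  blk1$layers$dense1$layers$conv5$params$w$value <- wlast
  expect_equal(run_block(blk1, x), 1.04 * x, tolerance = 1e-12)
})

test_that("spatial attention: sigmoid(0) limit, pooling oracle, weight range", {
  set.seed(27)
  sa <- grrdb:::new_spatial_attention()
  x <- rand_fm(8, 8, 4)
  pooled <- naive_chan_pool(x)
  # zero conv -> weight map 0.5 everywhere -> s1 = x / 2
  grrdb:::zero_params(sa)
  expect_equal(run_block(sa, x), 0.5 * x)
  # random conv against the naive pipeline
  sa2 <- grrdb:::new_spatial_attention()
  stacked <- array(c(pooled$mean, pooled$max), c(8, 8, 2))
  wmap <- sigmoid_ref(naive_conv2d(stacked, sa2$layers$conv$params$w$value,
                                   sa2$layers$conv$params$b$value)[, , 1])
  expect_true(all(wmap > 0 & wmap < 1))
  expect_lt(max(abs(run_block(sa2, x) - x * as.numeric(wmap))), 1e-5)
})

test_that("channel attention: sigmoid(0) limit, pooling oracle, permutation
           invariance", {
  set.seed(28)
  ca <- grrdb:::new_channel_attention(4L, reduction = 2L)
  x <- rand_fm(8, 8, 4)
  grrdb:::zero_params(ca)
  expect_equal(run_block(ca, x), 0.5 * x)
  ca2 <- grrdb:::new_channel_attention(4L, reduction = 2L)
  gp <- naive_global_pool(x)
  mlp <- function(v) {
    h <- pmax(ca2$layers$fc1$params$w$value %*% v +
                ca2$layers$fc1$params$b$value, 0)
    as.numeric(ca2$layers$fc2$params$w$value %*% h +
                 ca2$layers$fc2$params$b$value)
  }
  wch <- sigmoid_ref(mlp(gp$avg) + mlp(gp$max))
  ref <- x
  for (c in 1:4) ref[, , c] <- x[, , c] * wch[c]
  expect_lt(max(abs(run_block(ca2, x) - ref)), 1e-5)
  # channel weights are invariant to any spatial permutation of the input
  perm <- sample(64)
  xp <- x
  for (c in 1:4) xp[, , c] <- matrix(as.numeric(x[, , c])[perm], 8, 8)
  outp <- run_block(ca2, xp)
  wp <- outp[, , 1][xp[, , 1] != 0] / xp[, , 1][xp[, , 1] != 0]
  expect_equal(unique(round(wp, 10)), round(wch[1], 10))
  expect_error(grrdb:::new_channel_attention(6L, reduction = 4L),
               "divisible")
})

test_that("DAB weighted fusion matches the elementwise oracle and its limits", {
  set.seed(29)
  d <- c(8, 8, 4)
  s1 <- rand_fm(8, 8, 4); s2 <- rand_fm(8, 8, 4); xo <- rand_fm(8, 8, 4)
  w <- array(runif(prod(d)), d)
  ref <- array(0, d)
  for (i in seq_along(ref))
    ref[i] <- w[i] * s1[i] + xo[i] * (1 - w[i]) + w[i] * s2[i] +
      xo[i] * (1 - w[i])
  expect_lt(max(abs(dab_combine(s1, s2, xo, w) - ref)), 1e-6)
  # saturated limits
  expect_equal(dab_combine(s1, s2, xo, w * 0 + 1), s1 + s2)
  expect_equal(dab_combine(s1, s2, xo, w * 0), 2 * xo)
  # the literal (asymmetric) published variant differs through Xout * W
  lit <- dab_combine(s1, s2, xo, w, literal = TRUE)
  expect_lt(max(abs(lit - (ref - xo * (1 - w) + xo * w))), 1e-10)
})

test_that("DAB block preserves shape and gates strictly inside (0, 1)", {
  set.seed(30)
  cfg <- desk8()
  blk <- grrdb:::new_dab(8L, cfg)
  x <- rand_fm(8, 8, 8)
  out <- run_block(blk, x)
  expect_identical(dim(out), dim(x))
  expect_true(all(is.finite(out)))
  # the two fusion variants disagree for a generic input
  cfg_lit <- desk8(eq3_literal = TRUE)
  blk_lit <- grrdb:::new_dab(8L, cfg_lit)
  for (nm in names(blk$layers)) {
    for (pn in names(blk$layers[[nm]]$params))
      blk_lit$layers[[nm]]$params[[pn]]$value <-
        blk$layers[[nm]]$params[[pn]]$value
    if (!is.null(blk$layers[[nm]]$layers))
      for (ln in names(blk$layers[[nm]]$layers))
        for (pn in names(blk$layers[[nm]]$layers[[ln]]$params))
          blk_lit$layers[[nm]]$layers[[ln]]$params[[pn]]$value <-
            blk$layers[[nm]]$layers[[ln]]$params[[pn]]$value
  }
  expect_gt(max(abs(run_block(blk_lit, x) - out)), 1e-8)
})
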