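# Network building blocks: LKA, ghost convolution, Ghost-LKA, dense block,
# RRDB, spatial / channel attention and the dual-attention block (DAB).
# Every block maps an (H, W, C) feature map to the same shape.

#' Large-kernel attention block
#'
#' Decomposes a large-kernel convolution into a 5x5 depthwise convolution, a
#' 7x7 depthwise dilated convolution (dilation 3) and a 1x1 pointwise
#' convolution. The result is used as a multiplicative attention map:
#' `out = A(x) * x` elementwise, so the block modulates rather than replaces
#' its input. The effective receptive field of the decomposition matches a
#' 23x23 kernel at a fraction of the parameters.
#'
#' @param C number of channels.
#' @param cfg a [model_config()].
#' @return block object with `$fn(x)` operating on autodiff nodes.
#' @keywords internal
new_lka <- function(C, cfg) {
  dw <- new_dwconv(C, k = cfg$lka_dw_kernel, dilation = 1L)
  dwd <- new_dwconv(C, k = cfg$lka_dwd_kernel, dilation = cfg$lka_dilation)
  pw <- new_conv(C, C, k = 1L)
  obj <- list(kind = "lka", layers = list(dw = dw, dwd = dwd, pw = pw))
  obj$fn <- function(x) {
    a <- pw$fn(dwd$fn(dw$fn(x)))
    ag_mul(a, x)
  }
  obj
}

ghost_split <- function(cout, ratio) {
  primary <- cout %/% ratio
  cheap <- cout - primary
  mult <- if (cheap > 0) ceiling(cheap / primary) else 0L
  list(primary = primary, cheap = cheap, mult = as.integer(mult))
}

#' Ghost convolution
#'
#' Produces `cout / ratio` "intrinsic" feature maps with an ordinary
#' convolution and generates the remaining maps by cheap 3x3 depthwise
#' (linear) operations on the intrinsic maps, then concatenates both sets.
#' With `ratio = 1` it degenerates to a plain convolution. The primary
#' channel count is `floor(cout / ratio)`; cheap maps fill the remainder.
#'
#' @param cin,cout input / output channel counts.
#' @param ratio integer >= 1; `cout` must be divisible by `ratio`.
#' @param k primary kernel size.
#' @param bias include bias terms.
#' @keywords internal
new_ghost_conv <- function(cin, cout, ratio = 2L, k = 3L, bias = TRUE,
                           init_scale = 1) {
  if (cout %% ratio != 0)
    stop("ghost_conv: out_channels (", cout, ") not divisible by ratio (", ratio, ")")
  if (ratio == 1L) {
    primary <- new_conv(cin, cout, k = k, bias = bias, init_scale = init_scale)
    obj <- list(kind = "ghost_conv", ratio = 1L, layers = list(primary = primary))
    obj$fn <- function(x) primary$fn(x)
    return(obj)
  }
  sp <- ghost_split(cout, ratio)
  primary <- new_conv(cin, sp$primary, k = k, bias = bias,
                      init_scale = init_scale)
  cheap <- new_dwconv(sp$primary, k = 3L, mult = sp$mult, bias = bias)
  obj <- list(kind = "ghost_conv", ratio = ratio, split = sp,
              layers = list(primary = primary, cheap = cheap))
  obj$fn <- function(x) {
    p <- primary$fn(x)
    q <- cheap$fn(p)
    if (sp$cheap < sp$primary * sp$mult) q <- ag_slice_c(q, 1L, sp$cheap)
    ag_concat_c(list(p, q))
  }
  obj
}

#' Ghost-LKA block
#'
#' Large-kernel attention followed by a ghost-style channel split: the LKA
#' output passes through a 3x3 convolution producing `C / ghost_ratio`
#' convolved maps, cheap depthwise operations generate the remaining maps,
#' both sets are concatenated back to `C` channels, and the result is summed
#' elementwise with the block input (residual connection).
#' @inheritParams new_lka
#' @keywords internal
new_ghost_lka <- function(C, cfg) {
  lka <- new_lka(C, cfg)
  # the block is residual (out = ghost(lka(x)) + x); down-scaled init keeps
  # the residual branch small at the start of training
  ghost <- new_ghost_conv(C, C, ratio = cfg$ghost_ratio, k = 3L,
                          init_scale = 0.1)
  obj <- list(kind = "ghost_lka", layers = list(lka = lka, ghost = ghost))
  obj$fn <- function(x) ag_add(ghost$fn(lka$fn(x)), x)
  obj
}

#' Densely connected convolution block
#'
#' `n_conv_per_dense` 3x3 convolutions; convolution `k` sees the channel
#' concatenation of the block input and every previous convolution output
#' (`growth` channels each). All but the last convolution are followed by a
#' leaky ReLU; the last maps back to `C` channels. The block output is the
#' inner residual `x + res_scale * conv_last(...)`.
#' @inheritParams new_lka
#' @keywords internal
new_dense_block <- function(C, cfg) {
  g <- cfg$growth
  n <- cfg$n_conv_per_dense
  widths <- C + (seq_len(n) - 1L) * g
  convs <- vector("list", n)
  # dense residual trunks train from a near-identity start; the customary
  # down-scaled (x0.1) initialization keeps the stacked residual
  # contributions from inflating trunk activations
  for (i in seq_len(n - 1L))
    convs[[i]] <- new_conv(widths[i], g, k = 3L, init_scale = 0.1)
  convs[[n]] <- new_conv(widths[n], C, k = 3L, init_scale = 0.1)
  names(convs) <- paste0("conv", seq_len(n))
  obj <- list(kind = "dense_block", widths = widths, layers = convs)
  obj$fn <- function(x) {
    feats <- list(x)
    for (i in seq_len(n - 1L)) {
      inp <- if (length(feats) == 1L) x else ag_concat_c(feats)
      feats[[i + 1L]] <- ag_lrelu(convs[[i]]$fn(inp), cfg$lrelu_slope)
    }
    d <- convs[[n]]$fn(ag_concat_c(feats))
    ag_add(x, ag_scale(d, cfg$res_scale))
  }
  obj
}

#' Residual-in-residual dense block (RRDB)
#'
#' Chains `n_dense_per_rrdb` dense blocks (each internally residual with
#' scaling `res_scale`) and wraps the chain in an outer residual
#' interpolation: `x + res_scale * (chain(x) - x)`. Written this way the
#' outer mapping scales only the *learned* part of the chain, so a block
#' with all weights zeroed is an exact identity — the property the nested
#' residual design exists to provide.
#' @inheritParams new_lka
#' @keywords internal
new_rrdb <- function(C, cfg) {
  dbs <- lapply(seq_len(cfg$n_dense_per_rrdb), function(i) new_dense_block(C, cfg))
  names(dbs) <- paste0("dense", seq_along(dbs))
  obj <- list(kind = "rrdb", layers = dbs)
  obj$fn <- function(x) {
    d <- x
    for (db in dbs) d <- db$fn(d)
    # x + beta * (d - x); this form is bit-exact when the chain is the
    # identity (d - x is exactly zero)
    ag_add(x, ag_scale(ag_sub(d, x), cfg$res_scale))
  }
  obj
}

#' Spatial attention
#'
#' Channel-wise mean and max maps are concatenated (2 channels), passed
#' through a 7x7 convolution and a sigmoid to a single-channel weight map in
#' (0, 1), which is broadcast-multiplied with the input.
#' @keywords internal
new_spatial_attention <- function() {
  conv <- new_conv(2L, 1L, k = 7L, gain = 1)
  obj <- list(kind = "spatial_attention", layers = list(conv = conv))
  obj$fn <- function(x) {
    pooled <- ag_concat_c(list(ag_chan_mean(x), ag_chan_max(x)))
    w <- ag_sigmoid(conv$fn(pooled))
    ag_mul_map(x, w)
  }
  obj
}

#' Channel attention
#'
#' Global average- and max-pooled channel vectors pass through a shared
#' two-layer bottleneck (C -> C/reduction -> C with ReLU between), are
#' summed and sigmoided to per-channel weights in (0, 1) that rescale the
#' input channel-wise.
#' @param C channels; must be divisible by `reduction`.
#' @param reduction bottleneck reduction factor.
#' @keywords internal
new_channel_attention <- function(C, reduction = 4L) {
  if (C %% reduction != 0)
    stop("channel_attention: channels (", C, ") not divisible by reduction (",
         reduction, ")")
  fc1 <- new_fc(C, C %/% reduction)
  fc2 <- new_fc(C %/% reduction, C)
  obj <- list(kind = "channel_attention", layers = list(fc1 = fc1, fc2 = fc2))
  mlp <- function(v) fc2$fn(ag_relu(fc1$fn(v)))
  obj$fn <- function(x) {
    w <- ag_sigmoid(ag_add(mlp(ag_gap(x)), mlp(ag_gmp(x))))
    ag_mul_channel(x, w)
  }
  obj
}

#' Weighted fusion of the dual-attention branches
#'
#' Pure array combination used inside the DAB: given spatial branch `s1`,
#' channel branch `s2`, convolutional feature branch `xout` and a weight map
#' `w` in (0, 1), returns `w*s1 + xout*(1-w) + w*s2 + xout*(1-w)`. The
#' `literal` variant replaces the first complementary factor by `w` (the
#' asymmetric published form, kept for comparison).
#'
#' @param s1,s2,xout,w numeric arrays of a common shape.
#' @param literal use the asymmetric variant.
#' @return numeric array of the same shape.
#' @export
dab_combine <- function(s1, s2, xout, w, literal = FALSE) {
  second <- if (literal) w else (1 - w)
  w * s1 + xout * second + w * s2 + xout * (1 - w)
}

#' Dual-attention block (DAB)
#'
#' Runs spatial and channel attention in parallel (`s1`, `s2`), fuses them as
#' `Xa = s1 + s2`, derives a weight map `W = sigmoid(local(Xa) + global(Xa))`
#' from a local 3x3 convolution and a pooled-bottleneck global branch, and
#' combines with the convolutional feature branch `Xout = ReLU(Conv3x3(x))`
#' via [dab_combine()]. Stride 1 throughout: the branch must merge with a
#' full-resolution trunk.
#' @inheritParams new_lka
#' @keywords internal
new_dab <- function(C, cfg) {
  conv_feat <- new_conv(C, C, k = 3L)
  sa <- new_spatial_attention()
  ca <- new_channel_attention(C, cfg$ca_reduction)
  local_conv <- new_conv(C, C, k = 3L, gain = 1)
  gfc1 <- new_fc(C, C %/% cfg$ca_reduction)
  gfc2 <- new_fc(C %/% cfg$ca_reduction, C)
  obj <- list(kind = "dab",
              layers = list(conv_feat = conv_feat, sa = sa, ca = ca,
                            local_conv = local_conv, gfc1 = gfc1, gfc2 = gfc2))
  obj$fn <- function(x) {
    d <- fm_dims(x$value)
    xout <- ag_relu(conv_feat$fn(x))
    s1 <- sa$fn(x)
    s2 <- ca$fn(x)
    xa <- ag_add(s1, s2)
    loc <- local_conv$fn(xa)
    glo <- ag_bcast_hw(gfc2$fn(ag_relu(gfc1$fn(ag_gap(xa)))), d[1], d[2])
    w <- ag_sigmoid(ag_add(loc, glo))
    second <- if (isTRUE(cfg$eq3_literal)) w else ag_one_minus(w)
    ag_add(ag_add(ag_mul(w, s1), ag_mul(xout, second)),
           ag_add(ag_mul(w, s2), ag_mul(xout, ag_one_minus(w))))
  }
  obj
}
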