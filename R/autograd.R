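# Reverse-mode automatic differentiation on a dynamic tape.
#
# A node is an environment holding `value` (numeric array), `grad`
# (accumulated cotangent, NULL until backward reaches it), `parents` and a
# `backward` closure returning one gradient per parent. Only derived nodes
# are recorded on the tape; parameters and inputs are leaves. Feature maps
# are H x W x C arrays (channel-last, column-major), channel statistics are
# plain vectors, losses are scalars.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

#' Start recording operations on a fresh gradient tape
#'
#' Subsequent tensor operations are recorded so that [ag_backward()] can
#' propagate gradients. Call [ag_tape_stop()] (or let a helper do it) once the
#' backward pass is done; forward passes executed without an active tape incur
#' no recording cost.
#' @return The tape environment, invisibly.
#' @keywords internal
ag_tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  .ag$tape <- t
  invisible(t)
}

#' @rdname ag_tape_start
#' @keywords internal
ag_tape_stop <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

ag_record <- function(nd) {
  t <- .ag$tape
  if (!is.null(t)) {
    n <- t$n + 1L
    if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[n]] <- nd
    t$n <- n
  }
  nd
}

ag_node <- function(value, parents = NULL, backward = NULL, param = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  class(nd) <- "ag_node"
  if (!is.null(parents)) ag_record(nd)
  nd
}

#' Create a learnable parameter / a non-learnable input leaf
#' @param value numeric array.
#' @return An autodiff node.
#' @keywords internal
ag_param <- function(value) {
  if (!is.double(value)) storage.mode(value) <- "double"
  ag_node(value, param = TRUE)
}

#' @rdname ag_param
#' @keywords internal
ag_input <- function(value) {
  if (!is.double(value)) storage.mode(value) <- "double"
  ag_node(value)
}

is_ag_node <- function(x) inherits(x, "ag_node")

#' Backpropagate from a scalar loss node
#'
#' Walks the active tape in reverse creation order and accumulates gradients
#' into every reachable leaf (parameters keep their `grad` until reset by the
#' optimizer step).
#' @param loss scalar node produced under an active tape.
#' @keywords internal
ag_backward <- function(loss) {
  t <- .ag$tape
  if (is.null(t)) stop("ag_backward(): no active tape; call ag_tape_start() first")
  loss$grad <- 1
  for (i in rev(seq_len(t$n))) {
    nd <- t$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    # free intermediate state as soon as it has been consumed
    nd$grad <- NULL
    nd$backward <- NULL
    nd$parents <- NULL
  }
  invisible(loss)
}

# ---- shape helpers ----------------------------------------------------------

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("feature maps must be H x W x C arrays")
  d
}

# ---- convolution ops --------------------------------------------------------

# x: (H,W,C) node; w: (k,k,Cin,Cout) param node; b: (Cout) param node.
ag_conv2d <- function(x, w, b, k, dilation = 1L) {
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, k, dilation)
  ag_node(y, list(x, w, b), function(nd) {
    g <- cpp_conv2d_bwd(x$value, w$value, nd$grad, k, dilation)
    list(g$dx, g$dw, as.numeric(g$db))
  })
}

# depthwise, w: (k,k,mult,C) param node; output has C*mult channels ordered
# c1m1, c1m2, ..., c2m1, ...
ag_dwconv2d <- function(x, w, b, k, dilation = 1L, mult = 1L) {
  y <- cpp_dwconv2d_fwd(x$value, w$value, b$value, k, dilation, mult)
  ag_node(y, list(x, w, b), function(nd) {
    g <- cpp_dwconv2d_bwd(x$value, w$value, nd$grad, k, dilation, mult)
    list(g$dx, g$dw, as.numeric(g$db))
  })
}

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(nd) list(nd$grad, nd$grad))
}

ag_mul <- function(a, b) {
  ag_node(a$value * b$value, list(a, b),
          function(nd) list(nd$grad * b$value, nd$grad * a$value))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(nd) list(nd$grad, -nd$grad))
}

ag_scale <- function(x, s) {
  ag_node(x$value * s, list(x), function(nd) list(nd$grad * s))
}

ag_one_minus <- function(x) {
  ag_node(1 - x$value, list(x), function(nd) list(-nd$grad))
}

ag_relu <- function(x) {
  m <- x$value > 0
  ag_node(x$value * m, list(x), function(nd) list(nd$grad * m))
}

ag_lrelu <- function(x, slope = 0.2) {
  f <- slope + (1 - slope) * (x$value > 0)
  ag_node(x$value * f, list(x), function(nd) list(nd$grad * f))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(nd) list(nd$grad * s * (1 - s)))
}

# ---- channel bookkeeping ----------------------------------------------------

ag_concat_c <- function(xs) {
  ds <- lapply(xs, function(x) fm_dims(x$value))
  H <- ds[[1]][1]; W <- ds[[1]][2]
  Cs <- vapply(ds, function(d) d[3], numeric(1))
  v <- array(unlist(lapply(xs, function(x) x$value), use.names = FALSE),
             c(H, W, sum(Cs)))
  ends <- cumsum(Cs)
  starts <- ends - Cs + 1
  ag_node(v, xs, function(nd) {
    lapply(seq_along(xs), function(i)
      nd$grad[, , starts[i]:ends[i], drop = FALSE])
  })
}

ag_slice_c <- function(x, from, to) {
  d <- fm_dims(x$value)
  ag_node(x$value[, , from:to, drop = FALSE], list(x), function(nd) {
    g <- array(0, d)
    g[, , from:to] <- nd$grad
    list(g)
  })
}

# ---- pooling / reductions ---------------------------------------------------

# channel-wise mean over C -> (H,W,1)
ag_chan_mean <- function(x) {
  d <- fm_dims(x$value)
  m <- x$value
  dim(m) <- c(d[1] * d[2], d[3])
  v <- array(rowMeans(m), c(d[1], d[2], 1))
  ag_node(v, list(x), function(nd) {
    list(array(rep(as.numeric(nd$grad), d[3]) / d[3], d))
  })
}

# channel-wise max over C -> (H,W,1)
ag_chan_max <- function(x) {
  d <- fm_dims(x$value)
  m <- x$value
  dim(m) <- c(d[1] * d[2], d[3])
  idx <- max.col(m, ties.method = "first")
  sel <- cbind(seq_len(nrow(m)), idx)
  v <- array(m[sel], c(d[1], d[2], 1))
  ag_node(v, list(x), function(nd) {
    g <- matrix(0, nrow(m), d[3])
    g[sel] <- as.numeric(nd$grad)
    dim(g) <- d
    list(g)
  })
}

# global average pool -> length-C vector
ag_gap <- function(x) {
  d <- fm_dims(x$value)
  m <- x$value
  dim(m) <- c(d[1] * d[2], d[3])
  ag_node(colMeans(m), list(x), function(nd) {
    list(array(rep(nd$grad, each = d[1] * d[2]) / (d[1] * d[2]), d))
  })
}

# global max pool -> length-C vector
ag_gmp <- function(x) {
  d <- fm_dims(x$value)
  m <- x$value
  dim(m) <- c(d[1] * d[2], d[3])
  idx <- apply(m, 2, which.max)
  sel <- cbind(idx, seq_len(d[3]))
  ag_node(m[sel], list(x), function(nd) {
    g <- matrix(0, d[1] * d[2], d[3])
    g[sel] <- nd$grad
    dim(g) <- d
    list(g)
  })
}

# fully connected on a channel vector; w: (Cout,Cin), b: (Cout)
ag_dense <- function(v, w, b) {
  y <- as.numeric(w$value %*% v$value) + b$value
  ag_node(y, list(v, w, b), function(nd) {
    list(as.numeric(crossprod(w$value, nd$grad)),
         outer(nd$grad, v$value),
         nd$grad)
  })
}

# broadcast a length-C vector to (H,W,C)
ag_bcast_hw <- function(v, H, W) {
  C <- length(v$value)
  ag_node(array(rep(v$value, each = H * W), c(H, W, C)), list(v), function(nd) {
    g <- nd$grad
    dim(g) <- c(H * W, C)
    list(colSums(g))
  })
}

# multiply (H,W,C) by per-channel weights (length C)
ag_mul_channel <- function(x, v) {
  d <- fm_dims(x$value)
  vb <- rep(v$value, each = d[1] * d[2])
  ag_node(x$value * vb, list(x, v), function(nd) {
    gm <- nd$grad * x$value
    dim(gm) <- c(d[1] * d[2], d[3])
    list(nd$grad * vb, colSums(gm))
  })
}

# multiply (H,W,C) by a single-channel weight map (H,W,1), broadcast over C
ag_mul_map <- function(x, m) {
  d <- fm_dims(x$value)
  mv <- as.numeric(m$value)
  ag_node(x$value * mv, list(x, m), function(nd) {
    gm <- nd$grad * x$value
    dim(gm) <- c(d[1] * d[2], d[3])
    list(nd$grad * mv, array(rowSums(gm), c(d[1], d[2], 1)))
  })
}

# clamp to [0, 1] with subgradient (zero outside the active range)
ag_clamp01 <- function(x) {
  m <- x$value > 0 & x$value < 1
  ag_node(pmin(pmax(x$value, 0), 1), list(x),
          function(nd) list(nd$grad * m))
}

# mean squared error against a fixed target array -> scalar node
ag_mse <- function(x, target) {
  dres <- x$value - target
  n <- length(dres)
  ag_node(sum(dres * dres) / n, list(x), function(nd) {
    list((2 / n) * dres * nd$grad)
  })
}
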