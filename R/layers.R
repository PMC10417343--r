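# Layer constructors. Each returns a list with the parameter nodes, a
# `fn(x)` forward closure operating on autodiff nodes, and enough metadata
# for introspection (parameter counting, architecture description).

kaiming_sd <- function(fan_in, gain = sqrt(2)) gain / sqrt(fan_in)

#' @keywords internal
new_conv <- function(cin, cout, k = 3L, dilation = 1L, bias = TRUE,
                     zero_init = FALSE, gain = sqrt(2), init_scale = 1) {
  w0 <- if (zero_init) array(0, c(k, k, cin, cout)) else
    array(stats::rnorm(k * k * cin * cout, 0,
                       init_scale * kaiming_sd(k * k * cin, gain)),
          c(k, k, cin, cout))
  w <- ag_param(w0)
  b <- ag_param(numeric(cout))
  params <- if (bias) list(w = w, b = b) else list(w = w)
  obj <- list(kind = "conv", k = k, dilation = dilation, cin = cin, cout = cout,
              bias = bias, params = params)
  obj$fn <- function(x) ag_conv2d(x, w, b, k, dilation)
  obj
}

#' @keywords internal
new_dwconv <- function(C, k, dilation = 1L, mult = 1L, bias = TRUE,
                       zero_init = FALSE, gain = sqrt(2)) {
  w0 <- if (zero_init) array(0, c(k, k, mult, C)) else
    array(stats::rnorm(k * k * mult * C, 0, kaiming_sd(k * k, gain)),
          c(k, k, mult, C))
  w <- ag_param(w0)
  b <- ag_param(numeric(C * mult))
  params <- if (bias) list(w = w, b = b) else list(w = w)
  obj <- list(kind = "dwconv", k = k, dilation = dilation, cin = C,
              cout = C * mult, mult = mult, bias = bias, params = params)
  obj$fn <- function(x) ag_dwconv2d(x, w, b, k, dilation, mult)
  obj
}

#' @keywords internal
new_fc <- function(cin, cout, bias = TRUE) {
  w <- ag_param(matrix(stats::rnorm(cout * cin, 0, kaiming_sd(cin)), cout, cin))
  b <- ag_param(numeric(cout))
  params <- if (bias) list(w = w, b = b) else list(w = w)
  obj <- list(kind = "fc", cin = cin, cout = cout, bias = bias, params = params)
  obj$fn <- function(v) ag_dense(v, w, b)
  obj
}

# Recursively collect parameter nodes from nested layer/block structures.
collect_params <- function(x, prefix = "") {
  if (is_ag_node(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (!is.list(x)) return(list())
  out <- list()
  nms <- names(x)
  for (i in seq_along(x)) {
    el <- x[[i]]
    if (is.function(el)) next
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    child <- if (is_ag_node(el) || is.list(el))
      collect_params(el, paste0(prefix, if (nzchar(prefix)) "." else "", nm))
    else list()
    out <- c(out, child)
  }
  out
}

# Total learnable scalars in a nested structure.
count_params <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
}

# Set every parameter in a structure to zero (used by the residual-identity
# property checks).
zero_params <- function(x) {
  for (p in collect_params(x)) p$value[] <- 0
  invisible(x)
}
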