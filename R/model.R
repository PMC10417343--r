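# Model configuration, assembly of the full G-RRDB network, prediction,
# introspection and checkpointing.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic package code funnels through
# this so that (config, seed) pairs give bit-identical results.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Architecture configuration for the G-RRDB denoiser
#'
#' All architecture hyperparameters in one validated list. The defaults
#' follow the published design: 3 Ghost-LKA blocks in front of a trunk of 5
#' RRDBs (each 3 dense blocks of 5 convolutions, growth `base_channels / 2`),
#' a residual branch of 2 serial DABs, residual scaling 0.2, leaky-ReLU slope
#' 0.2, ghost ratio 2, and the large-kernel attention decomposition 5x5
#' depthwise + 7x7 depthwise dilated (dilation 3) + 1x1.
#'
#' @param in_channels image channels (1 for intensity maps).
#' @param base_channels trunk width C. 64 at paper scale; see [desk_config()]
#'   for the reduced desk-scale preset.
#' @param n_ghost_lka,n_rrdb,n_dab block counts.
#' @param n_dense_per_rrdb dense blocks per RRDB.
#' @param n_conv_per_dense convolutions per dense block.
#' @param growth channels added by each dense convolution; default
#'   `base_channels / 2`.
#' @param res_scale residual scaling factor in (0, 1].
#' @param lrelu_slope negative slope of the leaky ReLU.
#' @param ghost_ratio ghost convolution ratio (>= 1); `base_channels` must be
#'   divisible by it.
#' @param lka_dw_kernel,lka_dwd_kernel,lka_dilation large-kernel attention
#'   decomposition sizes.
#' @param ca_reduction channel-attention bottleneck reduction; must divide
#'   `base_channels`.
#' @param global_skip add the network input to the final convolution output
#'   (predict the image, not the residual noise).
#' @param eq3_literal use the asymmetric published form of the DAB fusion
#'   (see [dab_combine()]).
#' @return A `grrdb_config` list.
#' @export
#' @examples
#' cfg <- model_config(base_channels = 16)
#' cfg$growth
model_config <- function(in_channels = 1L,
                         base_channels = 64L,
                         n_ghost_lka = 3L,
                         n_rrdb = 5L,
                         n_dab = 2L,
                         n_dense_per_rrdb = 3L,
                         n_conv_per_dense = 5L,
                         growth = NULL,
                         res_scale = 0.2,
                         lrelu_slope = 0.2,
                         ghost_ratio = 2L,
                         lka_dw_kernel = 5L,
                         lka_dwd_kernel = 7L,
                         lka_dilation = 3L,
                         ca_reduction = 4L,
                         global_skip = TRUE,
                         eq3_literal = FALSE) {
  cfg <- list(in_channels = as.integer(in_channels),
              base_channels = as.integer(base_channels),
              n_ghost_lka = as.integer(n_ghost_lka),
              n_rrdb = as.integer(n_rrdb),
              n_dab = as.integer(n_dab),
              n_dense_per_rrdb = as.integer(n_dense_per_rrdb),
              n_conv_per_dense = as.integer(n_conv_per_dense),
              growth = as.integer(if (is.null(growth)) base_channels / 2 else growth),
              res_scale = res_scale,
              lrelu_slope = lrelu_slope,
              ghost_ratio = as.integer(ghost_ratio),
              lka_dw_kernel = as.integer(lka_dw_kernel),
              lka_dwd_kernel = as.integer(lka_dwd_kernel),
              lka_dilation = as.integer(lka_dilation),
              ca_reduction = as.integer(ca_reduction),
              global_skip = isTRUE(global_skip),
              eq3_literal = isTRUE(eq3_literal))
  validate_config(cfg)
  class(cfg) <- "grrdb_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid model config: field '", field, "' ", why, call. = FALSE)
  chk(cfg$in_channels >= 1L, "in_channels", "must be >= 1")
  chk(cfg$base_channels >= 2L, "base_channels", "must be >= 2")
  chk(cfg$ghost_ratio >= 1L, "ghost_ratio", "must be >= 1")
  chk(cfg$base_channels %% cfg$ghost_ratio == 0L, "base_channels",
      paste0("must be divisible by ghost_ratio (", cfg$ghost_ratio, ")"))
  chk(cfg$res_scale > 0 && cfg$res_scale <= 1, "res_scale", "must lie in (0, 1]")
  chk(cfg$n_ghost_lka >= 0L, "n_ghost_lka", "must be >= 0")
  chk(cfg$n_rrdb >= 1L, "n_rrdb", "must be >= 1")
  chk(cfg$n_dab >= 0L, "n_dab", "must be >= 0")
  chk(cfg$n_conv_per_dense >= 2L, "n_conv_per_dense", "must be >= 2")
  chk(cfg$growth >= 1L, "growth", "must be >= 1")
  chk(cfg$base_channels %% cfg$ca_reduction == 0L, "ca_reduction",
      paste0("must divide base_channels (", cfg$base_channels, ")"))
  chk(cfg$lka_dw_kernel %% 2L == 1L, "lka_dw_kernel", "must be odd")
  chk(cfg$lka_dwd_kernel %% 2L == 1L, "lka_dwd_kernel", "must be odd")
  invisible(cfg)
}

#' Desk-scale configuration preset
#'
#' Same topology as [model_config()] with `base_channels = 16`, sized so that
#' training and evaluation complete in minutes on a single CPU core.
#' @param ... overrides passed to [model_config()].
#' @export
desk_config <- function(...) model_config(base_channels = 16L, ...)

#' Assemble the G-RRDB denoising network
#'
#' Builds: a 3x3 head convolution (`in_channels -> C`), `n_ghost_lka`
#' Ghost-LKA blocks in series, `n_rrdb` RRDBs in series producing the trunk
#' output, a residual branch of `n_dab` serial DABs merged additively with
#' the trunk, two 3x3 convolution + ReLU layers, and a final 1x1 convolution
#' back to `in_channels`. With `global_skip` the input image is added to the
#' final convolution output, and with `zero_init_tail` the final convolution
#' starts at zero so the untrained network is the identity on images.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed controlling weight initialization (Kaiming
#'   fan-in); `NULL` uses the current RNG state.
#' @param zero_init_tail zero-initialize the final 1x1 convolution.
#' @return A `grrdb_model` object: `$config`, `$params` (named list of
#'   parameter nodes), `$forward` (node -> node), `$blocks` (named block
#'   list), `$seed`.
#' @export
#' @examples
#' m <- build_grrdb(desk_config(), seed = 1)
#' img <- matrix(runif(32 * 32), 32, 32)
#' out <- grrdb_predict(m, img)
build_grrdb <- function(cfg, seed = NULL, zero_init_tail = TRUE) {
  stopifnot(inherits(cfg, "grrdb_config"))
  validate_config(cfg)
  builder <- function() {
    C <- cfg$base_channels
    blocks <- list(head = new_conv(cfg$in_channels, C, k = 3L))
    if (cfg$n_ghost_lka > 0L)
      for (i in seq_len(cfg$n_ghost_lka))
        blocks[[paste0("ghost_lka", i)]] <- new_ghost_lka(C, cfg)
    for (i in seq_len(cfg$n_rrdb))
      blocks[[paste0("rrdb", i)]] <- new_rrdb(C, cfg)
    if (cfg$n_dab > 0L)
      for (i in seq_len(cfg$n_dab))
        blocks[[paste0("dab", i)]] <- new_dab(C, cfg)
    blocks$tail1 <- new_conv(C, C, k = 3L)
    blocks$tail2 <- new_conv(C, C, k = 3L)
    blocks$out <- new_conv(C, cfg$in_channels, k = 1L, zero_init = zero_init_tail)
    blocks
  }
  blocks <- if (is.null(seed)) builder() else with_seed(seed, builder())

  forward <- function(x) {
    h <- blocks$head$fn(x)
    if (cfg$n_ghost_lka > 0L)
      for (i in seq_len(cfg$n_ghost_lka)) h <- blocks[[paste0("ghost_lka", i)]]$fn(h)
    for (i in seq_len(cfg$n_rrdb)) h <- blocks[[paste0("rrdb", i)]]$fn(h)
    trunk <- h
    if (cfg$n_dab > 0L) {
      b <- trunk
      for (i in seq_len(cfg$n_dab)) b <- blocks[[paste0("dab", i)]]$fn(b)
      h <- ag_add(trunk, b)
    }
    h <- ag_relu(blocks$tail1$fn(h))
    h <- ag_relu(blocks$tail2$fn(h))
    y <- blocks$out$fn(h)
    if (cfg$global_skip) y <- ag_add(y, x)
    y
  }

  model <- list(config = cfg, blocks = blocks,
                params = collect_params(blocks), forward = forward,
                seed = seed, zero_init_tail = zero_init_tail)
  class(model) <- "grrdb_model"
  model
}

#' Number of learnable parameters
#' @param model a `grrdb_model` (or any nested block structure).
#' @return integer count of learnable scalars.
#' @export
grrdb_param_count <- function(model) {
  if (inherits(model, "grrdb_model")) return(count_params(model$blocks))
  count_params(model)
}

#' Run the denoiser on a single image
#'
#' @param model a `grrdb_model`.
#' @param img numeric matrix in `[0, 1]` (one intensity channel).
#' @param clip clip the output back to `[0, 1]` (stored-image semantics).
#' @return a matrix of the same dimensions.
#' @export
grrdb_predict <- function(model, img, clip = TRUE) {
  stopifnot(is.matrix(img))
  x <- ag_input(array(img, c(nrow(img), ncol(img), model$config$in_channels)))
  y <- model$forward(x)$value[, , 1]
  if (clip) y <- pmin(pmax(y, 0), 1)
  y
}

#' @export
print.grrdb_model <- function(x, ...) {
  cat("G-RRDB denoiser\n")
  cat(sprintf("  channels: %d, ghost-LKA: %d, RRDB: %d, DAB: %d\n",
              x$config$base_channels, x$config$n_ghost_lka,
              x$config$n_rrdb, x$config$n_dab))
  cat(sprintf("  parameters: %s\n",
              format(grrdb_param_count(x), big.mark = ",")))
  invisible(x)
}

#' Per-block architecture summary
#'
#' @param model a `grrdb_model`.
#' @return data.frame with block name, kind and parameter count.
#' @export
grrdb_describe <- function(model) {
  rows <- lapply(names(model$blocks), function(nm) {
    b <- model$blocks[[nm]]
    data.frame(block = nm, kind = b$kind, n_params = count_params(b))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(block = "total", kind = "",
                        n_params = sum(out$n_params)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights together with the full architecture
#' configuration; a YAML copy of the configuration is written alongside for
#' inspection. Loading against an explicit `config` rejects any mismatch.
#'
#' @param model a `grrdb_model`.
#' @param path checkpoint file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  weights <- lapply(model$params, function(p) p$value)
  saveRDS(list(config = unclass(model$config), weights = weights,
               zero_init_tail = model$zero_init_tail,
               package_version = as.character(utils::packageVersion("grrdb"))),
          path)
  yaml_path <- paste0(tools::file_path_sans_ext(path), "_config.yaml")
  yaml::write_yaml(unclass(model$config), yaml_path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config optional [model_config()] the checkpoint must match.
#' @return `load_checkpoint` returns the restored `grrdb_model`.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config)
  if (!is.null(config) && !identical(unclass(cfg), unclass(config)))
    stop("checkpoint config does not match the requested config")
  model <- build_grrdb(cfg, seed = 0L, zero_init_tail = ck$zero_init_tail)
  if (!identical(sort(names(model$params)), sort(names(ck$weights))))
    stop("checkpoint weights do not match the architecture")
  for (nm in names(ck$weights)) {
    p <- model$params[[nm]]
    if (!identical(dim(p$value), dim(ck$weights[[nm]])) &&
        length(p$value) != length(ck$weights[[nm]]))
      stop("checkpoint weight '", nm, "' has incompatible shape")
    p$value <- ck$weights[[nm]]
  }
  model
}
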