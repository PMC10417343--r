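# Training loop (Adam on the MSE loss), stratified data split, graded-noise
# robustness harness and ablation runner.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam, initial learning rate 1e-3,
#' batch size 8, 70 epochs, 9:1 train/test split. The learning rate is
#' constant (only the initial rate is specified by the protocol); pass a
#' function of the epoch index as `lr_schedule` to override.
#'
#' @param lr learning rate.
#' @param batch_size images per optimizer step.
#' @param epochs training epochs.
#' @param split train fraction in (0, 1).
#' @param seed RNG seed for shuffling.
#' @param lr_schedule `NULL`, or `function(epoch) -> lr`.
#' @param verbose print per-epoch losses.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, batch_size = 8L, epochs = 70L,
                         split = 0.9, seed = 0L, lr_schedule = NULL,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1L, epochs >= 1L, split > 0, split < 1, lr > 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split = split,
                 seed = as.integer(seed), lr_schedule = lr_schedule,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adam_step <- function(st, grad_scale = 1, lr = NULL) {
  st$t <- st$t + 1L
  lr <- if (is.null(lr)) st$lr else lr
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad * grad_scale
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    p$value <- p$value - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
    p$grad <- NULL
  }
  invisible(st)
}

#' Stratified train/test split of a dataset manifest
#'
#' Splits sample ids stratified by mold level at the given train ratio. The
#' partition is exact (no overlap, union is everything) and deterministic
#' given the seed. A level with fewer than 2 samples is kept whole in the
#' training set with a warning.
#'
#' @param manifest data.frame with columns `id` and `mold_level` (as written
#'   by [generate_dataset()]), or a pair list from [generate_pairs()].
#' @param ratio train fraction (default 0.9).
#' @param seed RNG seed.
#' @return list with character vectors `train_ids` and `test_ids`.
#' @export
split_dataset <- function(manifest, ratio = 0.9, seed = 0L) {
  if (is.list(manifest) && !is.data.frame(manifest))
    manifest <- data.frame(
      id = vapply(manifest, function(p) p$id, character(1)),
      mold_level = vapply(manifest, function(p) p$mold_level, numeric(1)))
  stopifnot(nrow(manifest) >= 1L, ratio > 0, ratio < 1)
  with_seed(seed, {
    test_ids <- character(0)
    for (m in sort(unique(manifest$mold_level))) {
      ids <- manifest$id[manifest$mold_level == m]
      if (length(ids) < 2L) {
        warning("mold level ", m, " has fewer than 2 samples; kept in train")
        next
      }
      n_test <- round(length(ids) * (1 - ratio))
      if (n_test > 0)
        test_ids <- c(test_ids, sample(ids, n_test))
    }
    list(train_ids = setdiff(manifest$id, test_ids), test_ids = test_ids)
  })
}

#' Train a G-RRDB model
#'
#' Minimizes `mse_loss(model(noisy), clean)` with Adam. Gradients are
#' averaged over each batch; per-epoch mean losses are recorded and the
#' weights from the epoch with the lowest training loss are restored into
#' the model at the end (no validation data are consulted).
#'
#' @param model a `grrdb_model` from [build_grrdb()]; modified in place and
#'   returned.
#' @param pairs training pairs: list of lists with `clean` and `noisy`
#'   matrices.
#' @param cfg a [train_config()].
#' @return list with `model`, `loss_history` (length `epochs`), `best_epoch`
#'   and `trained_ids` (ids seen during training, for leak audits).
#' @export
grrdb_train <- function(model, pairs, cfg = train_config()) {
  stopifnot(inherits(model, "grrdb_model"), length(pairs) >= 1L)
  n <- length(pairs)
  opt <- adam_new(model$params, lr = cfg$lr)
  loss_history <- numeric(cfg$epochs)
  best <- Inf
  best_epoch <- NA_integer_
  best_weights <- NULL
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      lr_e <- if (is.null(cfg$lr_schedule)) cfg$lr else cfg$lr_schedule(epoch)
      ep_loss <- 0
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        batch <- ord[s:min(s + cfg$batch_size - 1L, n)]
        for (p in model$params) p$grad <- NULL
        for (bi in batch) {
          pr <- pairs[[bi]]
          ag_tape_start()
          x <- ag_input(array(pr$noisy, c(nrow(pr$noisy), ncol(pr$noisy), 1L)))
          out <- model$forward(x)
          # optimize the stored-image semantics that evaluation uses:
          # outputs are clamped to [0, 1] before the pixel loss
          loss <- ag_mse(ag_clamp01(out), array(pr$clean, dim(x$value)))
          if (!is.finite(loss$value))
            stop(sprintf("non-finite loss (lr=%g, epoch=%d, sample=%d)",
                         lr_e, epoch, bi))
          ag_backward(loss)
          ag_tape_stop()
          ep_loss <- ep_loss + loss$value
        }
        adam_step(opt, grad_scale = 1 / length(batch), lr = lr_e)
      }
      loss_history[epoch] <- ep_loss / n
      if (cfg$verbose)
        message(sprintf("epoch %d/%d  mean loss %.6g", epoch, cfg$epochs,
                        loss_history[epoch]))
      if (loss_history[epoch] < best) {
        best <- loss_history[epoch]
        best_epoch <- epoch
        best_weights <- lapply(model$params, function(p) p$value)
      }
    }
  })
  if (!is.null(best_weights))
    for (nm in names(best_weights)) model$params[[nm]]$value <- best_weights[[nm]]
  list(model = model, loss_history = loss_history, best_epoch = best_epoch,
       trained_ids = vapply(pairs, function(p) p$id %||% NA_character_,
                            character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a model on paired test data
#'
#' Denoises each noisy test image and reports per-mold-level mean PSNR/SSIM
#' against the clean references via [evaluate_set()].
#'
#' @param model a `grrdb_model`, or `NULL` for the identity (reports the
#'   noisy-input baseline metrics).
#' @param pairs test pairs (lists with `clean`, `noisy`, `mold_level`).
#' @param L dynamic range for the metrics.
#' @return data.frame from [evaluate_set()].
#' @export
evaluate_model <- function(model, pairs, L = 1) {
  ev <- lapply(pairs, function(p) {
    den <- if (is.null(model)) p$noisy else grrdb_predict(model, p$noisy)
    list(clean = p$clean, denoised = den, mold_level = p$mold_level)
  })
  evaluate_set(ev, L = L)
}

#' Graded-noise robustness harness
#'
#' For each noise level, generates paired phantom data at that SNR, obtains a
#' model (trains one per level by default, or reuses `model` across levels),
#' and tabulates noisy-input and denoised metrics per level.
#'
#' @param levels_db Gaussian-noise levels in dB (default 20/30/40/50).
#' @param n_per_level pairs per mold level at each noise level.
#' @param phantom_cfg a [phantom_config()] template.
#' @param model optional fixed `grrdb_model` applied at every level; `NULL`
#'   with `train = TRUE` trains a fresh model per level.
#' @param model_cfg [model_config()] used when training per level.
#' @param train_cfg [train_config()] used when training per level.
#' @param train train a model per level (ignored when `model` is given).
#' @param master_seed seed for data generation.
#' @return data.frame with one row per level: input and (if a model was
#'   available) denoised mean PSNR/SSIM over the test split.
#' @export
noise_robustness <- function(levels_db = c(20, 30, 40, 50), n_per_level = 10L,
                             phantom_cfg = phantom_config(), model = NULL,
                             model_cfg = desk_config(),
                             train_cfg = train_config(epochs = 5L),
                             train = FALSE, master_seed = 1L) {
  rows <- lapply(levels_db, function(db) {
    pairs <- generate_pairs(n_per_level, phantom_cfg,
                            noise_spec("awgn_snr", snr_db = db), master_seed)
    sp <- split_dataset(pairs, ratio = train_cfg$split, seed = train_cfg$seed)
    ids <- vapply(pairs, function(p) p$id, character(1))
    test <- pairs[ids %in% sp$test_ids]
    if (length(test) == 0L) {
      warning("test split is empty at this dataset size; evaluating on all pairs")
      test <- pairs
    }
    inp <- evaluate_model(NULL, test)
    mdl <- model
    if (is.null(mdl) && train) {
      mdl <- build_grrdb(model_cfg, seed = train_cfg$seed)
      grrdb_train(mdl, pairs[ids %in% sp$train_ids], train_cfg)
    }
    row <- data.frame(snr_db = db,
                      input_psnr_db = mean(inp$psnr_db),
                      input_ssim = mean(inp$ssim))
    if (!is.null(mdl)) {
      den <- evaluate_model(mdl, test)
      row$psnr_db <- mean(den$psnr_db)
      row$ssim <- mean(den$ssim)
    }
    row
  })
  do.call(rbind, rows)
}

variant_config <- function(variant, base_cfg) {
  switch(variant,
    baseline = { cfg <- base_cfg; cfg$n_ghost_lka <- 0L; cfg$n_dab <- 0L; cfg },
    baseline_dab = { cfg <- base_cfg; cfg$n_ghost_lka <- 0L; cfg },
    grrdb = base_cfg,
    stop("unknown ablation variant: ", variant))
}

#' Ablation runner
#'
#' Trains the requested architecture variants (`baseline`: RRDB trunk only;
#' `baseline_dab`: trunk + DAB branch; `grrdb`: full model) on identical data
#' and seeds and reports per-variant parameter counts and test metrics. A
#' checksum of the training inputs is recorded so identical-data runs can be
#' audited.
#'
#' @param variants subset of `c("baseline", "baseline_dab", "grrdb")`.
#' @param pairs paired dataset (e.g. from [generate_pairs()]).
#' @param base_cfg full-model [model_config()].
#' @param train_cfg a [train_config()].
#' @param train fit each variant (otherwise report untrained models, which is
#'   useful for bookkeeping checks).
#' @return data.frame: variant, n_params, psnr_db, ssim, data_checksum.
#' @export
ablate <- function(variants = c("baseline", "baseline_dab", "grrdb"), pairs,
                   base_cfg = desk_config(), train_cfg = train_config(),
                   train = TRUE) {
  stopifnot(length(variants) >= 1L)
  sp <- split_dataset(pairs, ratio = train_cfg$split, seed = train_cfg$seed)
  ids <- vapply(pairs, function(p) p$id, character(1))
  train_pairs <- pairs[ids %in% sp$train_ids]
  test_pairs <- pairs[ids %in% sp$test_ids]
  if (length(test_pairs) == 0L) {
    warning("test split is empty at this dataset size; evaluating on all pairs")
    test_pairs <- pairs
  }
  checksum <- sprintf("%.10e", sum(vapply(train_pairs, function(p)
    sum(p$noisy) + sum(p$clean), numeric(1))))
  rows <- lapply(variants, function(v) {
    cfg <- variant_config(v, base_cfg)
    mdl <- build_grrdb(cfg, seed = train_cfg$seed)
    if (train) grrdb_train(mdl, train_pairs, train_cfg)
    rep <- evaluate_model(mdl, test_pairs)
    data.frame(variant = v, n_params = grrdb_param_count(mdl),
               psnr_db = mean(rep$psnr_db), ssim = mean(rep$ssim),
               data_checksum = checksum)
  })
  do.call(rbind, rows)
}
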