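# Training harness: stratified splitting, optimization behaviour, identity
# starts, evaluation plumbing, robustness table and ablation bookkeeping.

small_pairs <- function(n_per_level, snr = 20, seed = 1, size = 32L) {
  suppressWarnings(generate_pairs(
    n_per_level,
    phantom_config(canvas_h = size, canvas_w = size,
                   n_kernels = 2L, kernel_axis_range = c(3, 6)),
    noise_spec("awgn_snr", snr_db = snr), master_seed = seed))
}

test_that("stratified split is exact, leak-free and deterministic", {
  pairs <- small_pairs(10)
  sp <- split_dataset(pairs, ratio = 0.9, seed = 0)
  expect_length(sp$train_ids, 36)
  expect_length(sp$test_ids, 4)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  ids <- vapply(pairs, function(p) p$id, character(1))
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  # one test sample per level
  lv <- substr(sp$test_ids, 2, 2)
  expect_equal(sort(lv), c("0", "1", "2", "3"))
  expect_identical(sp, split_dataset(pairs, ratio = 0.9, seed = 0))
  # the partition depends on the seed: some other seed must pick a
  # different hold-out set
  others <- vapply(1:5, function(s)
    identical(sp$test_ids, split_dataset(pairs, ratio = 0.9, seed = s)$test_ids),
    logical(1))
  expect_false(all(others))
})

test_that("split partitions random manifests exactly at any ratio", {
  set.seed(60)
  for (i in 1:5) {
    n <- sample(8:40, 1)
    manifest <- data.frame(id = sprintf("s%03d", 1:n),
                           mold_level = sample(0:3, n, replace = TRUE))
    ratio <- runif(1, 0.6, 0.95)
    sp <- suppressWarnings(split_dataset(manifest, ratio = ratio, seed = i))
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), manifest$id)
    # per-level test fraction within one sample of the global ratio
    for (m in unique(manifest$mold_level)) {
      ids <- manifest$id[manifest$mold_level == m]
      if (length(ids) < 2) next
      n_test <- sum(sp$test_ids %in% ids)
      expect_lt(abs(n_test - length(ids) * (1 - ratio)), 1)
    }
  }
  expect_warning(
    sp1 <- split_dataset(data.frame(id = c("a", "b", "c"),
                                    mold_level = c(0, 0, 1))),
    "fewer than 2")
  expect_setequal(sp1$train_ids, c("a", "b", "c"))  # tiny level kept whole
})

test_that("identity-started training on clean pairs keeps the loss at zero", {
  pairs <- lapply(1:6, function(i) {
    img <- suppressWarnings(
      render_phantom(phantom_config(canvas_h = 32L, canvas_w = 32L,
                                    n_kernels = 2L,
                                    kernel_axis_range = c(3, 6), seed = i)))
    list(id = paste0("p", i), clean = img, noisy = img, mold_level = 0)
  })
  m <- build_grrdb(model_config(base_channels = 8L), seed = 0)
  fit <- grrdb_train(m, pairs, train_config(epochs = 2L, batch_size = 4L,
                                            seed = 0))
  expect_length(fit$loss_history, 2)
  expect_equal(fit$loss_history, c(0, 0))
})

test_that("a short training run reduces the training loss", {
  pairs <- small_pairs(4, snr = 20, seed = 2)  # 16 pairs, strong noise
  m <- build_grrdb(model_config(base_channels = 8L), seed = 0)
  fit <- grrdb_train(m, pairs, train_config(epochs = 3L, batch_size = 8L,
                                            seed = 0))
  expect_length(fit$loss_history, 3)
  expect_lt(fit$loss_history[3], fit$loss_history[1])
  expect_true(is.finite(fit$best_epoch))
})

test_that("evaluation of the identity equals the noisy-input baseline and is
           reproducible", {
  pairs <- small_pairs(2, seed = 3)
  rep1 <- evaluate_model(NULL, pairs)
  rep2 <- evaluate_model(NULL, pairs)
  expect_identical(rep1, rep2)
  manual <- mean(vapply(pairs[1:2], function(p) psnr(p$clean, p$noisy),
                        numeric(1)))
  expect_equal(rep1$psnr_db[1], manual)
  # zero-tail identity model reproduces the baseline exactly
  m <- build_grrdb(model_config(base_channels = 8L), seed = 0)
  expect_equal(evaluate_model(m, pairs), rep1)
})

test_that("noise robustness table: input quality is monotone in SNR", {
  tab <- suppressWarnings(
    noise_robustness(levels_db = c(20, 30, 40, 50), n_per_level = 3L,
                     phantom_cfg = phantom_config(canvas_h = 32L,
                                                  canvas_w = 32L,
                                                  n_kernels = 2L,
                                                  kernel_axis_range = c(3, 6)),
                     master_seed = 4))
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$input_psnr_db) > 0))
  expect_true(all(diff(tab$input_ssim) > 0))
  expect_lt(tab$input_psnr_db[tab$snr_db == 20],
            tab$input_psnr_db[tab$snr_db == 50])
})

test_that("ablation bookkeeping: identical data, parameter ordering", {
  pairs <- small_pairs(3, seed = 5)
  tab <- suppressWarnings(
    ablate(pairs = pairs, base_cfg = model_config(base_channels = 8L),
           train_cfg = train_config(epochs = 1L, seed = 0), train = FALSE))
  expect_equal(tab$variant, c("baseline", "baseline_dab", "grrdb"))
  expect_length(unique(tab$data_checksum), 1)
  expect_gt(tab$n_params[tab$variant == "grrdb"],
            tab$n_params[tab$variant == "baseline_dab"])
  expect_gt(tab$n_params[tab$variant == "baseline_dab"],
            tab$n_params[tab$variant == "baseline"])
  tab1 <- suppressWarnings(
    ablate(variants = "baseline", pairs = pairs,
           base_cfg = model_config(base_channels = 8L),
           train_cfg = train_config(epochs = 1L, seed = 0), train = FALSE))
  expect_equal(nrow(tab1), 1)
})

test_that("training aborts with a diagnostic on a non-finite loss", {
  pairs <- small_pairs(1, seed = 6)
  m <- build_grrdb(model_config(base_channels = 8L), seed = 0)
  m$params[[1]]$value[1] <- NaN
  expect_error(grrdb_train(m, pairs, train_config(epochs = 1L, seed = 0)),
               "non-finite loss")
})
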