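test_that("receptive field follows the dilated-convolution formula", {
  expect_equal(receptive_field(3, 1), 3)
  expect_equal(receptive_field(3, 2), 5)
  # independent oracle: enumerate tap positions of a dilated 1-D kernel
  span <- function(k, d) diff(range((0:(k - 1)) * d)) + 1
  expect_equal(receptive_field(5, 3), span(5, 3))
  for (k in c(3, 5, 7)) for (d in 1:4)
    expect_equal(receptive_field(k, d), span(k, d))
  expect_error(receptive_field(4, 1), "odd")
  expect_error(receptive_field(-3, 1), "odd")
  expect_error(receptive_field(3, 0), "dilation")
})

test_that("receptive field is monotone in kernel size and dilation", {
  grid <- expand.grid(k = c(3, 5, 7, 9), d = 1:5)
  rf <- mapply(receptive_field, grid$k, grid$d)
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$k[j] >= grid$k[i] && grid$d[j] >= grid$d[i])
      expect_gte(rf[j], rf[i])
  }
})

test_that("patch extraction tiles the image and reassembly is lossless", {
  x <- matrix(rnorm(64 * 64), 64, 64)
  ep <- extract_patches(x, patch_spec(32, 32))
  expect_length(ep$patches, 4)
  expect_identical(reassemble(ep$patches, ep$placement, "mean"), x)
  # patch size equal to image size: identity
  ep1 <- extract_patches(x, patch_spec(64, 64))
  expect_length(ep1$patches, 1)
  expect_identical(ep1$patches[[1]], x)
  # 100x100, size 64, stride 32: 3 positions per axis
  y <- matrix(rnorm(1e4), 100, 100)
  ep2 <- extract_patches(y, patch_spec(64, 32, "reflect"))
  expect_length(ep2$patches, 9)
  expect_equal(dim(reassemble(ep2$patches, ep2$placement, "mean")), c(100, 100))
  expect_error(extract_patches(matrix(numeric(0), 0, 0)), "empty")
})

test_that("overlapping patch predictions aggregate by mean and max", {
  pl <- data.frame(x0 = c(0L, 0L), y0 = c(0L, 16L))
  attr(pl, "orig_dim") <- c(32L, 48L)
  attr(pl, "padded_dim") <- c(32L, 48L)
  attr(pl, "size") <- 32L
  pp <- list(matrix(2, 32, 32), matrix(4, 32, 32))
  mn <- reassemble(pp, pl, "mean")
  expect_equal(unique(as.vector(mn[, 17:32])), 3)   # (2 + 4) / 2 in overlap
  expect_equal(unique(as.vector(mn[, 1:16])), 2)
  mx <- reassemble(pp, pl, "max")
  expect_equal(unique(as.vector(mx[, 17:32])), 4)
  expect_error(reassemble(pp[1], pl), "placement")
})

test_that("dice+bce loss has its closed-form values and minimum", {
  t1 <- matrix(1, 8, 8)
  expect_lt(dice_bce_loss(t1, t1), 1e-5)
  # probabilities 0.5 on all-ones target: BCE term is ln 2
  half <- matrix(0.5, 8, 8)
  parts <- dice_bce_loss(half, t1, gradient = TRUE)
  expect_equal(parts$bce, log(2), tolerance = 1e-12)
  # empty target and zero probabilities: smoothing makes the Dice term
  # vanish (up to the log-clipping offset)
  z <- matrix(0, 8, 8)
  parts0 <- dice_bce_loss(z, z, gradient = TRUE)
  expect_lt(abs(parts0$dice), 1e-5)
  expect_error(dice_bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "mismatch")
  # minimised only at the target
  set.seed(1)
  noisy <- pmin(pmax(t1 - matrix(abs(rnorm(64, 0, 0.2)), 8, 8), 0), 1)
  expect_gt(dice_bce_loss(noisy, t1), dice_bce_loss(t1, t1))
})

test_that("augmentation is seeded, keeps masks binary, and scales only the image", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  msk <- disk_mask(8, 32)
  a1 <- augment_pair(img, msk, seed = 5)
  a2 <- augment_pair(img, msk, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0, 1)))
  # intensity scaling must not touch the mask
  a3 <- augment_pair(img, msk, seed = 5, intensity_range = c(2, 2))
  expect_identical(a1$mask, a3$mask)
  # pure flips preserve the foreground pixel count and are involutive
  a4 <- augment_pair(img, msk, seed = 11, rotation_range = 0,
                     zoom_range = c(1, 1), intensity_range = c(1, 1))
  expect_equal(sum(a4$mask), sum(msk))
  a5 <- augment_pair(a4$image, a4$mask, seed = 11, rotation_range = 0,
                     zoom_range = c(1, 1), intensity_range = c(1, 1))
  expect_equal(a5$image, img)
  expect_equal(a5$mask, msk)
})

test_that("plateau scheduler halves after the patience window and floors", {
  s <- plateau_scheduler(1e-4, factor = 0.5, patience = 5, lr_min = 1e-6)
  s$step(0.5)
  lrs <- vapply(1:10, function(i) s$step(0.4), numeric(1))
  expect_equal(lrs[4], 1e-4)           # not yet triggered
  expect_equal(lrs[5], 5e-5)           # first plateau trigger
  expect_equal(lrs[10], 2.5e-5)        # second consecutive trigger
  # improvement resets the stale counter
  s2 <- plateau_scheduler(1e-4, 0.5, 3, 1e-6)
  s2$step(0.1); s2$step(0.05); s2$step(0.2)
  expect_equal(s2$lr, 1e-4)
  # floor
  s3 <- plateau_scheduler(2e-6, 0.5, 1, 1e-6)
  s3$step(1); s3$step(0); s3$step(0)
  expect_equal(s3$lr, 1e-6)
})

test_that("training is deterministic under a fixed seed and rejects empty data", {
  spec <- fusiform_spec(r0 = 0.6, rmax = 0.9, n_slices = 2, grid = 32,
                        pixel_size = 1, slice_spacing = 4, noise_sd = 5, seed = 5)
  vol <- make_volume(spec)
  ds <- lapply(1:2, function(i) list(image = vol$images[, , i], mask = vol$masks[[i]]))
  cfg <- unet_config(depth = 2, base_channels = 4, patch = patch_spec(32),
                     learning_rate = 1e-3, seed = 9)
  h1 <- train_unet(ds, cfg, epochs = 2)$history
  h2 <- train_unet(ds, cfg, epochs = 2)$history
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 2)
  expect_true(all(c("epoch", "lr", "loss", "train_dice") %in% names(h1)))
  expect_error(train_unet(list(), cfg), "empty")
})

test_that("prediction returns binary masks of the input shape", {
  spec <- fusiform_spec(r0 = 0.6, rmax = 0.9, n_slices = 2, grid = 32,
                        pixel_size = 1, slice_spacing = 4, noise_sd = 5, seed = 5)
  vol <- make_volume(spec)
  ds <- lapply(1:2, function(i) list(image = vol$images[, , i], mask = vol$masks[[i]]))
  cfg <- unet_config(depth = 2, base_channels = 4, patch = patch_spec(32),
                     learning_rate = 1e-3, seed = 9)
  fit <- train_unet(ds, cfg, epochs = 2)
  pred <- predict_masks(fit$model, vol$images)
  expect_length(pred, 2)
  expect_equal(dim(pred[[1]]), c(32, 32))
  expect_true(all(unlist(pred) %in% c(0L, 1L)))
})
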