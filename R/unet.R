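# Dilated U-Net built on the compiled conv/pool/upsample primitives.
#
# Encoder stage s applies a 3x3 convolution with dilation rate
# dilation_schedule[s] followed by ReLU; stages below the bottleneck are
# followed by 2x2 max pooling, with the pre-pool activation kept as the
# skip connection.  The decoder mirrors this with nearest-neighbour
# upsampling, skip concatenation and a 3x3 convolution.  A final 1x1
# convolution plus sigmoid yields the per-pixel foreground probability.

stage_channels <- function(config) config$base_channels * 2^(seq_len(config$depth) - 1)

he_init <- function(c_out, c_in, k) {
  w <- matrix(rnorm(c_out * c_in * k * k) * sqrt(2 / (c_in * k * k)), c_out, c_in * k * k)
  list(w = w, b = rep(0, c_out))
}

#' Initialise a dilated U-Net model
#'
#' Weights use He initialisation driven by R's RNG, so a fixed
#' `config$seed` gives a reproducible model.
#'
#' @param config A [unet_config()].
#' @return A `unet_model` object (configuration + parameter arrays).
#' @export
unet_init <- function(config = unet_config()) {
  set.seed(config$seed)
  D <- config$depth
  ch <- stage_channels(config)
  enc <- vector("list", D)
  cin <- 1L
  for (s in seq_len(D)) {
    enc[[s]] <- he_init(ch[s], cin, 3L)
    cin <- ch[s]
  }
  dec <- vector("list", D - 1L)
  for (s in seq_len(D - 1L)) {
    dec[[s]] <- he_init(ch[s], ch[s + 1L] + ch[s], 3L)
  }
  out <- he_init(1L, ch[1L], 1L)
  structure(list(config = config, enc = enc, dec = dec, out = out),
            class = "unet_model")
}

relu <- function(x) { x[x < 0] <- 0; x }

as_cube <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L))

unet_forward <- function(model, image, cache = FALSE) {
  cfg <- model$config
  D <- cfg$depth
  sched <- cfg$dilation_schedule
  h <- if (is.matrix(image)) as_cube(image) else image
  cc <- list(enc = vector("list", D), pool = vector("list", D - 1L),
             dec = vector("list", D - 1L))
  skips <- vector("list", D - 1L)
  for (s in seq_len(D)) {
    x_in <- h
    z <- cpp_conv2d_forward(x_in, model$enc[[s]]$w, model$enc[[s]]$b, 3L, sched[s])
    a <- relu(z)
    if (cache) cc$enc[[s]] <- list(x = x_in, mask = z > 0)
    if (s < D) {
      skips[[s]] <- a
      mp <- cpp_maxpool2_forward(a)
      if (cache) cc$pool[[s]] <- list(idx = mp$idx, d = dim(a))
      h <- mp$y
    } else h <- a
  }
  for (s in rev(seq_len(D - 1L))) {
    up <- cpp_upsample2(h)
    du <- dim(up); ds <- dim(skips[[s]])
    cat_in <- array(0, c(du[1], du[2], du[3] + ds[3]))
    cat_in[, , seq_len(du[3])] <- up
    cat_in[, , du[3] + seq_len(ds[3])] <- skips[[s]]
    z <- cpp_conv2d_forward(cat_in, model$dec[[s]]$w, model$dec[[s]]$b, 3L, 1L)
    a <- relu(z)
    if (cache) cc$dec[[s]] <- list(x = cat_in, mask = z > 0, up_ch = du[3])
    h <- a
  }
  zout <- cpp_conv2d_forward(h, model$out$w, model$out$b, 1L, 1L)
  logit <- zout[, , 1]
  if (cache) cc$out_x <- h
  list(prob = 1 / (1 + exp(-logit)), logit = logit,
       cache = if (cache) cc else NULL)
}

unet_backward <- function(model, cache, grad_logit) {
  cfg <- model$config
  D <- cfg$depth
  sched <- cfg$dilation_schedule
  grads <- list(enc = vector("list", D), dec = vector("list", D - 1L))
  g <- as_cube(grad_logit)
  bw <- cpp_conv2d_backward(cache$out_x, model$out$w, g, 1L, 1L)
  grads$out <- list(w = bw$gw, b = bw$gb)
  g <- bw$gx
  gskip <- vector("list", D - 1L)
  for (s in seq_len(D - 1L)) {        # reverse of the decoder loop
    g <- g * cache$dec[[s]]$mask
    bw <- cpp_conv2d_backward(cache$dec[[s]]$x, model$dec[[s]]$w, g, 3L, 1L)
    grads$dec[[s]] <- list(w = bw$gw, b = bw$gb)
    uc <- cache$dec[[s]]$up_ch
    gcat <- bw$gx
    gskip[[s]] <- gcat[, , uc + seq_len(dim(gcat)[3] - uc), drop = FALSE]
    g <- cpp_upsample2_backward(gcat[, , seq_len(uc), drop = FALSE])
  }
  for (s in rev(seq_len(D))) {
    g <- g * cache$enc[[s]]$mask
    bw <- cpp_conv2d_backward(cache$enc[[s]]$x, model$enc[[s]]$w, g, 3L, sched[s])
    grads$enc[[s]] <- list(w = bw$gw, b = bw$gb)
    if (s > 1L) {
      pl <- cache$pool[[s - 1L]]
      g <- cpp_maxpool2_backward(bw$gx, pl$idx, pl$d[1], pl$d[2])
      g <- g + gskip[[s - 1L]]
    }
  }
  grads
}

# flatten model parameters / gradients into a single list of arrays so the
# Adam update is a plain loop
param_refs <- function(model) {
  refs <- list()
  for (s in seq_along(model$enc)) refs[[length(refs) + 1L]] <- c("enc", s)
  for (s in seq_along(model$dec)) refs[[length(refs) + 1L]] <- c("dec", s)
  refs[[length(refs) + 1L]] <- c("out", NA)
  refs
}

get_param <- function(obj, ref) if (is.na(ref[2])) obj[[ref[1]]] else obj[[ref[1]]][[as.integer(ref[2])]]

set_param <- function(model, ref, val) {
  if (is.na(ref[2])) model[[ref[1]]] <- val
  else model[[ref[1]]][[as.integer(ref[2])]] <- val
  model
}

adam_state_init <- function(model) {
  refs <- param_refs(model)
  st <- lapply(refs, function(r) {
    p <- get_param(model, r)
    list(mw = p$w * 0, vw = p$w * 0, mb = p$b * 0, vb = p$b * 0)
  })
  list(refs = refs, st = st, t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (i in seq_along(state$refs)) {
    r <- state$refs[[i]]
    p <- get_param(model, r); g <- get_param(grads, r)
    s <- state$st[[i]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    p$w <- p$w - lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    p$b <- p$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state$st[[i]] <- s
    model <- set_param(model, r, p)
  }
  list(model = model, state = state)
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Tracks the best value of a maximised metric (e.g. validation Dice).
#' After `patience` consecutive epochs without improvement the learning
#' rate is multiplied by `factor` (never below `lr_min`) and the stale
#' counter resets.
#'
#' @param lr Initial learning rate.
#' @param factor Multiplicative reduction factor (default 0.5).
#' @param patience Stale epochs tolerated before reducing (default 5).
#' @param lr_min Learning-rate floor (default 1e-6).
#' @param min_delta Minimum improvement that resets the counter.
#' @return An environment with `step(metric)` returning the learning rate
#'   to use next, and fields `lr`, `best`, `wait`.
#' @export
plateau_scheduler <- function(lr, factor = 0.5, patience = 5L, lr_min = 1e-6,
                              min_delta = 1e-6) {
  env <- new.env()
  env$lr <- lr; env$best <- -Inf; env$wait <- 0L
  env$step <- function(metric) {
    if (metric > env$best + min_delta) {
      env$best <- metric; env$wait <- 0L
    } else {
      env$wait <- env$wait + 1L
      if (env$wait >= patience) {
        env$lr <- max(env$lr * factor, lr_min)
        env$wait <- 0L
      }
    }
    env$lr
  }
  env
}

normalize_image <- function(img) {
  s <- sd(img)
  if (s < 1e-12) return(img - mean(img))
  (img - mean(img)) / s
}

# build the training tile set: each image is patched per the config and
# tiles paired with the matching mask tiles
make_tiles <- function(dataset, patch) {
  tiles <- list()
  for (d in dataset) {
    ep <- extract_patches(d$image, patch)
    mp <- extract_patches(d$mask, patch)
    for (i in seq_along(ep$patches)) {
      m <- mp$patches[[i]]
      m[m < 0.5] <- 0; m[m >= 0.5] <- 1   # reflect padding keeps masks binary anyway
      tiles[[length(tiles) + 1L]] <- list(image = ep$patches[[i]], mask = m)
    }
  }
  tiles
}

#' Train the dilated U-Net
#'
#' Full-batch/mini-batch Adam training with the combined Dice + BCE loss,
#' plateau learning-rate halving and early stopping on validation Dice
#' (training Dice when no validation set is given). All randomness
#' (initialisation, shuffling, augmentation) is derived from
#' `config$seed`, so a rerun with the same inputs reproduces the same
#' loss history.
#'
#' @param dataset List of `list(image=, mask=)` pairs (matrices).
#' @param config A [unet_config()].
#' @param epochs Maximum number of epochs.
#' @param validation Optional held-out list of pairs for the scheduler and
#'   early stopping.
#' @param augment Logical; apply random flips/rotation/zoom/intensity
#'   augmentation to each training tile every epoch.
#' @param normalize Logical; standardise each image to zero mean and unit
#'   variance before patching (recommended).
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained `unet_model`) and `history`
#'   (data.frame of epoch, lr, loss, train_dice, val_dice).
#' @export
train_unet <- function(dataset, config = unet_config(), epochs = 50L,
                       validation = NULL, augment = FALSE,
                       normalize = TRUE, verbose = FALSE) {
  if (length(dataset) == 0) stop_aaawall("empty training dataset")
  model <- unet_init(config)
  prep <- function(set) lapply(set, function(d) {
    list(image = if (normalize) normalize_image(d$image) else d$image, mask = d$mask)
  })
  tiles <- make_tiles(prep(dataset), config$patch)
  val_tiles <- if (!is.null(validation)) make_tiles(prep(validation), config$patch)
  state <- adam_state_init(model)
  sched <- plateau_scheduler(config$learning_rate, config$lr_factor,
                             config$lr_patience, config$lr_min)
  best_metric <- -Inf; stale <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                     train_dice = numeric(), val_dice = numeric())
  lr <- config$learning_rate
  set.seed(config$seed + 1L)
  for (epoch in seq_len(epochs)) {
    ord <- sample(length(tiles))
    ep_loss <- 0; ep_dice <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      gacc <- NULL; n_in_batch <- length(bt)
      for (ti in bt) {
        tl <- tiles[[ti]]
        if (augment) {
          tl <- augment_pair(tl$image, tl$mask,
                             seed = config$seed + 7919L * epoch + ti)
        }
        fw <- unet_forward(model, tl$image, cache = TRUE)
        ls <- dice_bce_loss(fw$prob, tl$mask, gradient = TRUE)
        ep_loss <- ep_loss + ls$loss
        ep_dice <- ep_dice + hard_dice(fw$prob, tl$mask)
        gr <- unet_backward(model, fw$cache, ls$grad_logit)
        gacc <- if (is.null(gacc)) gr else add_grads(gacc, gr)
      }
      gacc <- scale_grads(gacc, 1 / n_in_batch)
      up <- adam_step(model, gacc, state, lr)
      model <- up$model; state <- up$state
    }
    ep_loss <- ep_loss / length(tiles); ep_dice <- ep_dice / length(tiles)
    val_dice <- if (!is.null(val_tiles)) {
      mean(vapply(val_tiles, function(tl)
        hard_dice(unet_forward(model, tl$image)$prob, tl$mask), numeric(1)))
    } else NA_real_
    metric <- if (is.na(val_dice)) ep_dice else val_dice
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr, loss = ep_loss,
                                   train_dice = ep_dice, val_dice = val_dice))
    lr <- sched$step(metric)
    if (metric > best_metric + 1e-6) { best_metric <- metric; stale <- 0L }
    else {
      stale <- stale + 1L
      if (stale >= config$stop_patience) {
        if (verbose) message(sprintf("early stop at epoch %d", epoch))
        break
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  dice %.4f  val %.4f",
                      epoch, lr, ep_loss, ep_dice, val_dice))
  }
  list(model = model, history = hist)
}

add_grads <- function(a, b) {
  refs <- c(lapply(seq_along(a$enc), function(s) c("enc", s)),
            lapply(seq_along(a$dec), function(s) c("dec", s)), list(c("out", NA)))
  for (r in refs) {
    pa <- get_param(a, r); pb <- get_param(b, r)
    pa$w <- pa$w + pb$w; pa$b <- pa$b + pb$b
    a <- set_param(a, r, pa)
  }
  a
}

scale_grads <- function(a, f) {
  refs <- c(lapply(seq_along(a$enc), function(s) c("enc", s)),
            lapply(seq_along(a$dec), function(s) c("dec", s)), list(c("out", NA)))
  for (r in refs) {
    pa <- get_param(a, r)
    pa$w <- pa$w * f; pa$b <- pa$b * f
    a <- set_param(a, r, pa)
  }
  a
}

#' Predict per-slice binary masks
#'
#' Each slice is standardised, patched per the model's patch spec, run
#' through the network, reassembled (mean aggregation over overlaps) and
#' thresholded. Optionally only the largest connected foreground
#' component is kept, reflecting that each slice contains a single outer
#' wall.
#'
#' @param model A trained `unet_model`.
#' @param stack A matrix (single slice), a 3-D array `(x, y, slice)`, or a
#'   list of matrices.
#' @param threshold Binarisation threshold (default 0.5).
#' @param largest_component Keep only the largest foreground component.
#' @param normalize Standardise each slice as during training.
#' @return List of binary mask matrices, one per slice.
#' @export
predict_masks <- function(model, stack, threshold = 0.5,
                          largest_component = TRUE, normalize = TRUE) {
  slices <- if (is.matrix(stack)) list(stack)
  else if (is.array(stack) && length(dim(stack)) == 3)
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  else if (is.list(stack)) stack
  else stop_aaawall("unsupported image stack type")
  lapply(slices, function(sl) {
    img <- if (normalize) normalize_image(sl) else sl
    ep <- extract_patches(img, model$config$patch)
    preds <- lapply(ep$patches, function(p) unet_forward(model, p)$prob)
    prob <- reassemble(preds, ep$placement, "mean")
    mask <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
    if (largest_component && sum(mask) > 0) mask <- largest_component_mask(mask)
    mask
  })
}

largest_component_mask <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}
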