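#' Effective receptive field of a dilated convolution
#'
#' A dilated convolution with kernel size `k` and dilation rate `d` spaces
#' its taps `d` pixels apart, so a single layer sees
#' `RF = (k - 1) * d + 1` pixels along each axis. With `d = 1` this reduces
#' to the ordinary kernel size.
#'
#' @param k Odd positive integer kernel size (pixels).
#' @param d Integer dilation rate, `>= 1`.
#' @return Receptive field in pixels.
#' @examples
#' receptive_field(3, 1) # 3
#' receptive_field(3, 2) # 5
#' @export
receptive_field <- function(k, d) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k) || k %% 2 == 0)
    stop_aaawall("kernel size 'k' must be a positive odd integer, got %s", format(k))
  if (!is.numeric(d) || length(d) != 1 || d < 1 || d != round(d))
    stop_aaawall("dilation rate 'd' must be an integer >= 1, got %s", format(d))
  (k - 1) * d + 1
}

#' Patch specification for patch-based processing
#'
#' Large slices are broken into square patches so that training and
#' inference operate on manageable tiles; with `stride == size` the tiles
#' partition the (padded) image and reassembly is lossless.
#'
#' @param size Patch edge length in pixels.
#' @param stride Step between patch origins in pixels, `0 < stride <= size`.
#' @param padding Padding mode used when the image does not tile exactly:
#'   `"reflect"` (default) or `"zero"`.
#' @return A `patch_spec` object.
#' @export
patch_spec <- function(size = 64, stride = size, padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  if (stride <= 0 || stride > size)
    stop_aaawall("patch stride must satisfy 0 < stride <= size")
  structure(list(size = as.integer(size), stride = as.integer(stride),
                 padding = padding), class = "patch_spec")
}

#' U-Net configuration
#'
#' Architectural and optimisation settings for the dilated U-Net. The
#' dilation schedule assigns one dilation rate per encoder stage; the
#' default `c(1, 2, 3, 1)` starts with ordinary convolutions, widens the
#' receptive field mid-encoder, and returns to rate 1. Optimisation
#' defaults (Adam at 1e-4, plateau learning-rate halving with patience 5
#' down to 1e-6, batch size 16, early-stopping patience 5) follow common
#' practice for this segmentation task; all are configurable.
#'
#' @param dilation_schedule Integer vector of dilation rates per encoder
#'   stage; recycled/truncated to `depth`.
#' @param base_channels Channels of the first encoder stage; stage `s` has
#'   `base_channels * 2^(s-1)`.
#' @param depth Number of encoder stages (the last is the bottleneck).
#' @param patch A [patch_spec()].
#' @param learning_rate,lr_factor,lr_patience,lr_min Adam initial learning
#'   rate and ReduceLROnPlateau settings (multiplicative factor, epochs of
#'   patience on validation Dice, floor).
#' @param batch_size Mini-batch size.
#' @param stop_patience Early-stopping patience (epochs without validation
#'   Dice improvement).
#' @param seed Integer seed fixing weight initialisation, shuffling and
#'   augmentation.
#' @return A `unet_config` object.
#' @export
unet_config <- function(dilation_schedule = c(1L, 2L, 3L, 1L),
                        base_channels = 16L, depth = 4L,
                        patch = patch_spec(64),
                        learning_rate = 1e-4, lr_factor = 0.5,
                        lr_patience = 5L, lr_min = 1e-6,
                        batch_size = 16L, stop_patience = 5L,
                        seed = 1L) {
  if (depth < 2) stop_aaawall("U-Net depth must be >= 2")
  sched <- rep_len(as.integer(dilation_schedule), depth)
  structure(list(dilation_schedule = sched,
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), patch = patch,
                 learning_rate = learning_rate, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), lr_min = lr_min,
                 batch_size = as.integer(batch_size),
                 stop_patience = as.integer(stop_patience),
                 seed = as.integer(seed)),
            class = "unet_config")
}
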