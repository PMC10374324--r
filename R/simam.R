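# SimAM: parameter-free attention. Each activation t of a channel gets a
# closed-form minimal energy
#   e*(t) = 4 (sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 + 2 lambda)
# where mu and sigma^2 are the mean and population variance over all M
# pixels of that channel. The refined map is sigmoid(1/e*) * x: pixels far
# from the channel mean (low energy) are emphasized, capturing the spatial
# suppression effect of active neurons.

#' Per-channel mean and population variance
#'
#' @param channel numeric matrix (H x W), one channel of a feature map.
#' @return named numeric vector \code{c(mean, variance)}; the variance is
#'   the population form (divide by M, not M - 1).
#' @export
channelStatistics <- function(channel) {
  v <- as.numeric(channel)
  if (length(v) < 2L) stop("a channel needs at least 2 pixels for a variance")
  if (any(!is.finite(v))) stop("channel values must be finite")
  mu <- mean(v)
  c(mean = mu, variance = mean((v - mu)^2))
}

#' Minimal-energy map of one channel
#'
#' @param channel numeric matrix (H x W).
#' @param lambda regularization, default 1e-4.
#' @return matrix of minimal energies, same shape; a constant channel gives
#'   the analytic value 2 everywhere.
#' @export
minimalEnergyMap <- function(channel, lambda = 1e-4) {
  if (lambda <= 0) stop("lambda must be positive")
  s <- channelStatistics(channel)
  d2 <- (channel - s["mean"])^2
  4 * (s["variance"] + lambda) / (d2 + 2 * s["variance"] + 2 * lambda)
}

#' SimAM refinement of a feature map
#'
#' Applies \code{sigmoid(1 / e*)} as a multiplicative 3-D weight, channel by
#' channel. Adds no learnable parameters and preserves the input shape. A
#' 1 x 1 spatial map has no defined variance and is passed through with a
#' warning.
#'
#' @param feature numeric array (H, W, C).
#' @param lambda regularization, default 1e-4.
#' @return refined array, same shape.
#' @export
simamRefine <- function(feature, lambda = 1e-4) {
  assert_image(feature)
  d <- dim(feature)
  if (d[1] * d[2] < 2L) {
    warning("1x1 spatial map: SimAM variance undefined, passing through")
    return(feature)
  }
  out <- feature
  for (c in seq_len(d[3])) {
    e <- minimalEnergyMap(feature[, , c], lambda)
    out[, , c] <- plogis(1 / e) * feature[, , c]
  }
  out
}

# autodiff version used inside the network; composed from primitive ops so
# the gradient is exact. x: (H,W,C) tensor.
ad_simam <- function(x, lambda = 1e-4) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  M <- H * W
  if (M < 2L) return(x)
  mu <- ad_chan_bcast(ad_chan_mean(x), H, W)
  dev <- ad_sub(x, mu)
  d2 <- ad_square(dev)
  s2 <- ad_chan_mean(d2)
  num <- ad_chan_bcast(ad_scale(ad_add(s2, lambda), 4), H, W)
  den <- ad_add(d2, ad_chan_bcast(ad_add(ad_scale(s2, 2), 2 * lambda), H, W))
  estar <- ad_div(num, den)
  w <- ad_sigmoid(ad_div(ad_tensor(array(1, d)), estar))
  ad_mul(w, x)
}
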