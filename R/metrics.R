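# Image-quality metrics: MSE, SNR, PSNR, universal quality index (Q),
# SSIM, Pearson correlation, and intensity-difference statistics.
# Conventions: statistics use the sample (n-1) denominator; degenerate
# cases return documented sentinels (+Inf for log-ratios on identical
# images, NA for undefined correlation-type factors) rather than erroring,
# so batch sweeps never abort.

#' Mean squared error between two images
#' @param x,y numeric matrices of identical size.
#' @return Mean of squared pixel differences.
#' @export
mse <- function(x, y) {
  check_image(x, "x"); check_image(y, "y"); check_same_shape(x, y)
  mean((x - y)^2)
}

#' Signal-to-noise ratio (dB) of a filtered image against the native image
#'
#' `SNR = 10 log10( sum(s^2) / sum((s - shat)^2) )` with `s` the filtered
#' image and `shat` the native (noise-free) reference -- note the
#' role-asymmetry: the signal power in the numerator is that of the
#' filtered image. Returns `Inf` for identical images.
#'
#' @param filtered filtered image `s`.
#' @param native noise-free reference `shat`.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(filtered, native) {
  check_image(filtered, "filtered"); check_image(native, "native")
  check_same_shape(filtered, native)
  den <- sum((filtered - native)^2)
  if (den == 0) return(Inf)
  10 * log10(sum(filtered^2) / den)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `PSNR = 10 log10(peak^2 / MSE)`; `Inf` for identical images.
#'
#' @param x,y numeric matrices of identical size.
#' @param peak intensity peak (1 on the normalized scale).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr_db <- function(x, y, peak = 1) {
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Universal image quality index (Q-index)
#'
#' Product of three factors -- linear correlation, luminance similarity and
#' contrast similarity:
#' `Q = (sxy / (sx sy)) * (2 xbar ybar / (xbar^2 + ybar^2)) *
#'      (2 sx sy / (sx^2 + sy^2))`, bounded in `[-1, 1]`.
#' Returns `NA` when either image has zero variance (undefined correlation
#' factor).
#'
#' @param x,y numeric matrices of identical size.
#' @return Q in `[-1, 1]`, or `NA` for degenerate input.
#' @export
q_index <- function(x, y) {
  check_image(x, "x"); check_image(y, "y"); check_same_shape(x, y)
  xv <- as.vector(x); yv <- as.vector(y)
  sx <- sd(xv); sy <- sd(yv)
  if (sx == 0 || sy == 0) return(NA_real_)
  sxy <- cov(xv, yv)
  mx <- mean(xv); my <- mean(yv)
  lum <- if (mx == 0 && my == 0) 0 else 2 * mx * my / (mx^2 + my^2)
  (sxy / (sx * sy)) * lum * (2 * sx * sy / (sx^2 + sy^2))
}

#' Structural similarity index (SSIM)
#'
#' `SSIM = l^alpha * c^beta * s^gamma` with luminance
#' `l = (2 mx my + C1) / (mx^2 + my^2 + C1)`, contrast
#' `c = (2 sx sy + C2) / (sx^2 + sy^2 + C2)` and structure
#' `s = (sxy + C3) / (sx sy + C3)`. Constants follow the standard choice
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2` with dynamic range
#' `L = 1`. The default `mode = "global"` uses whole-image statistics
#' (sample denominator); `mode = "window"` averages SSIM over sliding
#' square windows.
#'
#' @param x,y numeric matrices of identical size.
#' @param alpha,beta,gamma exponents of the three factors.
#' @param mode `"global"` or `"window"`.
#' @param window window side for `mode = "window"`.
#' @param L dynamic range entering the stabilizing constants.
#' @return SSIM value (in `[0, 1]` for non-negative images).
#' @export
ssim <- function(x, y, alpha = 1, beta = 1, gamma = 1,
                 mode = c("global", "window"), window = 8, L = 1) {
  check_image(x, "x"); check_image(y, "y"); check_same_shape(x, y)
  mode <- match.arg(mode)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2; C3 <- C2 / 2
  one <- function(xv, yv) {
    mx <- mean(xv); my <- mean(yv)
    sx <- sd(xv); sy <- sd(yv); sxy <- cov(xv, yv)
    l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
    cc <- (2 * sx * sy + C2) / (sx^2 + sy^2 + C2)
    ss <- (sxy + C3) / (sx * sy + C3)
    l^alpha * cc^beta * ss^gamma
  }
  if (mode == "global") return(one(as.vector(x), as.vector(y)))
  H <- nrow(x); W <- ncol(x)
  w <- min(window, H, W)
  vals <- numeric(0)
  for (i in seq_len(H - w + 1)) {
    for (j in seq_len(W - w + 1)) {
      vals <- c(vals, one(as.vector(x[i:(i + w - 1), j:(j + w - 1)]),
                          as.vector(y[i:(i + w - 1), j:(j + w - 1)])))
    }
  }
  mean(vals)
}

#' Pearson correlation between two images
#'
#' Product-moment correlation over all pixels; `NA` if either image is
#' constant.
#'
#' @param x,y numeric matrices of identical size.
#' @return Correlation in `[-1, 1]` or `NA`.
#' @export
pearson_corr <- function(x, y) {
  check_image(x, "x"); check_image(y, "y"); check_same_shape(x, y)
  if (sd(as.vector(x)) == 0 || sd(as.vector(y)) == 0) return(NA_real_)
  cor(as.vector(x), as.vector(y))
}

#' Intensity-difference statistics between native and filtered images
#'
#' Per-pixel intensity difference `ID = |native - filtered| * 100`
#' (percent of the `[0, 1]` range), summarized by its median, the center of
#' the most populated histogram bin (mode), and its sample variance.
#'
#' @param native noise-free reference.
#' @param filtered filtered image.
#' @param n_bins number of histogram bins over `[0, 100]` used for the mode.
#' @return A list with `median_pct`, `mode_pct`, `variance` and the pooled
#'   `id` values (invisibly usable for pooling across runs).
#' @export
intensity_diff_stats <- function(native, filtered, n_bins = 256) {
  check_image(native, "native"); check_image(filtered, "filtered")
  check_same_shape(native, filtered)
  id <- as.vector(abs(native - filtered)) * 100
  id_stats_from_values(id, n_bins)
}

# Shared summary used for pooled ID distributions too. A degenerate
# (constant) difference distribution reports itself as the mode exactly.
id_stats_from_values <- function(id, n_bins = 256) {
  if (max(id) - min(id) < 1e-9) {
    return(list(median_pct = stats::median(id), mode_pct = stats::median(id),
                variance = 0, n = length(id)))
  }
  breaks <- seq(0, max(100, max(id)), length.out = n_bins + 1)
  counts <- tabulate(findInterval(id, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  mode_bin <- which.max(counts)
  list(median_pct = stats::median(id),
       mode_pct = (breaks[mode_bin] + breaks[mode_bin + 1]) / 2,
       variance = if (length(id) > 1) stats::var(id) else 0,
       n = length(id))
}

#' Full metric report for one image pair
#'
#' Convenience wrapper computing MSE, SNR, PSNR, Q-index, SSIM and Pearson
#' correlation for a (reference, image) pair in one call.
#'
#' @param reference noise-free reference image.
#' @param image image under evaluation (e.g. a filter output).
#' @return A one-row `data.frame` with columns `mse`, `snr_db`, `psnr_db`,
#'   `q_index`, `ssim`, `corr`.
#' @export
metric_report <- function(reference, image) {
  data.frame(mse = mse(image, reference),
             snr_db = snr_db(image, reference),
             psnr_db = psnr_db(image, reference),
             q_index = q_index(image, reference),
             ssim = ssim(image, reference),
             corr = pearson_corr(image, reference))
}
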