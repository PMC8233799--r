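# Dynamic-noise robustness characterization: metric-vs-intensity curves,
# pooled intensity-difference distributions, and filter-vs-filter
# percentage comparisons.

#' Describe a named filter configuration
#'
#' Filter banks in the sweep functions are lists of these entries. For the
#' non-local family (`"nlm"`, `"rnlm"`, `"rnlm_star"`) supply
#' [filter_params()]; for `"average"`/`"median"` a kernel size; `"identity"`
#' passes images through (the corrupt-vs-native baseline). `sigma = "auto"`
#' uses the current Rician noise level as the bias-correction sigma (0 for
#' other noise families); a number fixes it.
#'
#' @param method one of `"nlm"`, `"rnlm"`, `"rnlm_star"`, `"average"`,
#'   `"median"`, `"identity"`.
#' @param params a [filter_params()] for the non-local methods.
#' @param kernel odd kernel size for the local methods.
#' @param sigma `"auto"` or a fixed non-negative number.
#' @param name label used in result tables (defaults to a readable
#'   method/kernel tag).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(method = c("rnlm_star", "rnlm", "nlm", "average",
                                   "median", "identity"),
                        params = filter_params(), kernel = 5, sigma = "auto",
                        name = NULL) {
  method <- match.arg(method)
  if (is.null(name)) {
    name <- switch(method,
                   average = paste0("average", kernel, "x", kernel),
                   median = paste0("median", kernel, "x", kernel),
                   method)
  }
  structure(list(method = method, params = params, kernel = kernel,
                 sigma = sigma, name = name), class = "filter_spec")
}

# Apply a filter_spec; `level`/`family` supply the sigma hint for "auto".
apply_filter <- function(img, fs, level = 0, family = "rician") {
  stopifnot(inherits(fs, "filter_spec"))
  sig <- if (identical(fs$sigma, "auto")) {
    if (family == "rician") level else 0
  } else fs$sigma
  switch(fs$method,
         nlm = nlm_filter(img, fs$params),
         rnlm = rnlm_filter(img, fs$params, sigma = sig),
         rnlm_star = rnlm_star_filter(img, fs$params, sigma = sig),
         average = average_filter(img, fs$kernel),
         median = median_filter(img, fs$kernel),
         identity = img)
}

add_noise_family <- function(img, family, level, seed) {
  switch(family,
         rician = add_rician(img, level, seed),
         salt_pepper = add_salt_pepper(img, level, seed),
         speckle = add_speckle(img, level, seed),
         stop("unknown noise family: ", family, call. = FALSE))
}

check_levels <- function(family, levels) {
  if (length(levels) == 0 || any(!is.finite(levels)))
    stop("levels must be finite", call. = FALSE)
  if (any(diff(levels) <= 0) && length(levels) > 1)
    stop("levels must be strictly increasing", call. = FALSE)
  if (any(levels < 0)) stop("negative noise level", call. = FALSE)
  if (family == "salt_pepper" && any(levels > 1))
    stop("salt-and-pepper density must lie in [0, 1]", call. = FALSE)
  invisible(NULL)
}

#' Metric-vs-noise-intensity robustness curve
#'
#' For each noise level, every image is corrupted (seeded), filtered, and
#' scored against its noise-free original with SSIM, SNR, PSNR, Q-index and
#' Pearson correlation; metrics are averaged over the image set. The
#' default nine levels span `[0.1, 0.9]`, tracing the filter's behavior
#' under dynamically worsening conditions.
#'
#' @param images non-empty list of noise-free images.
#' @param family `"rician"`, `"salt_pepper"` or `"speckle"`.
#' @param filter a [filter_spec()].
#' @param levels strictly increasing noise intensities.
#' @param seed integer seed; corruption seeds depend on
#'   `(seed, image, level)` only.
#' @return A data.frame (class `robustness_curve`) with columns `level`,
#'   `ssim`, `snr_db`, `psnr_db`, `q_index`, `corr`; attributes `family`
#'   and `filter` carry the configuration.
#' @export
noise_sweep <- function(images, family, filter,
                        levels = seq(0.1, 0.9, by = 0.1), seed = 1) {
  if (length(images) == 0) stop("images must be non-empty", call. = FALSE)
  check_levels(family, levels)
  stopifnot(inherits(filter, "filter_spec"))
  rows <- lapply(seq_along(levels), function(li) {
    per_img <- vapply(seq_along(images), function(ii) {
      native <- images[[ii]]
      noisy <- add_noise_family(native, family, levels[li],
                                derive_seed(seed, ii, li))
      filt <- apply_filter(noisy, filter, levels[li], family)
      c(ssim(filt, native), snr_db(filt, native), psnr_db(filt, native),
        q_index(filt, native), pearson_corr(filt, native))
    }, numeric(5))
    rowMeans(per_img)
  })
  out <- data.frame(level = levels, do.call(rbind, rows))
  names(out) <- c("level", "ssim", "snr_db", "psnr_db", "q_index", "corr")
  attr(out, "family") <- family
  attr(out, "filter") <- filter$name
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' Pooled intensity-difference distributions per filter setting
#'
#' For every filter-bank entry, pools the per-pixel intensity differences
#' (percent of range) between the noise-free images and the filtered
#' corrupted images across all noise levels, and summarizes each pooled
#' distribution by its median, histogram mode and variance.
#'
#' @inheritParams noise_sweep
#' @param filter_bank non-empty list of [filter_spec()] entries.
#' @param n_bins histogram bins for the mode.
#' @return A data.frame with one row per filter entry: `filter`,
#'   `median_pct`, `mode_pct`, `variance`, `n` (pooled pixel count).
#' @export
id_distribution_study <- function(images, family, filter_bank,
                                  levels = seq(0.1, 0.9, by = 0.1), seed = 1,
                                  n_bins = 256) {
  if (length(filter_bank) == 0) stop("filter bank must be non-empty", call. = FALSE)
  if (length(images) == 0) stop("images must be non-empty", call. = FALSE)
  check_levels(family, levels)
  rows <- lapply(filter_bank, function(fs) {
    pooled <- unlist(lapply(seq_along(levels), function(li) {
      unlist(lapply(seq_along(images), function(ii) {
        native <- images[[ii]]
        noisy <- add_noise_family(native, family, levels[li],
                                  derive_seed(seed, ii, li))
        filt <- apply_filter(noisy, fs, levels[li], family)
        as.vector(abs(native - filt)) * 100
      }))
    }))
    st <- id_stats_from_values(pooled, n_bins)
    data.frame(filter = fs$name, median_pct = st$median_pct,
               mode_pct = st$mode_pct, variance = st$variance, n = st$n)
  })
  do.call(rbind, rows)
}

#' Percentage difference between two filters across a noise sweep
#'
#' Runs the same seeded sweep for both filters (identical corruptions) and
#' reports `Diff = 100 * (mean_A - mean_B) / mean_B` for mean SSIM and mean
#' correlation, means taken over all levels and images. Positive values
#' mean filter A outperforms filter B.
#'
#' @inheritParams noise_sweep
#' @param filter_a,filter_b [filter_spec()] entries (A is typically the
#'   candidate, B the baseline the difference is relative to).
#' @return A list with `diff_ssim_pct`, `diff_corr_pct` (possibly `NA` if a
#'   baseline mean is zero) and the two underlying curves.
#' @export
compare_filters <- function(images, family, filter_a, filter_b,
                            levels = seq(0.1, 0.9, by = 0.1), seed = 1) {
  curve_a <- noise_sweep(images, family, filter_a, levels, seed)
  curve_b <- noise_sweep(images, family, filter_b, levels, seed)
  pct <- function(a, b) {
    mb <- mean(b)
    if (mb == 0) NA_real_ else 100 * (mean(a) - mb) / mb
  }
  list(diff_ssim_pct = pct(curve_a$ssim, curve_b$ssim),
       diff_corr_pct = pct(curve_a$corr, curve_b$corr),
       curve_a = curve_a, curve_b = curve_b)
}
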