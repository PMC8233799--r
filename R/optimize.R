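# Random-search optimization of the filter parameters: sample n parameter
# combinations, score each by mean MSE against noise-free references over a
# set of images and Rician noise levels, return the minimizer.

#' Parameter ranges for the random search
#'
#' Sampling ranges for the four optimized parameters. Continuous parameters
#' (`h`, `degc`) are drawn uniformly from an interval; discrete parameters
#' (`radp`, `omega`) uniformly from an integer set. `rads` is held fixed
#' during optimization (the search-window size is not part of the search).
#'
#' @param h numeric interval within `(0, 1]`.
#' @param degc positive numeric interval; the default upper end covers the
#'   optima observed on MR data.
#' @param radp integer set of patch radii.
#' @param omega integer set of transition slopes.
#' @param rads fixed search-window radius attached to every sampled
#'   combination.
#' @return An object of class `param_ranges`.
#' @export
param_ranges <- function(h = c(0.01, 1), degc = c(0.5, 10), radp = 1:5,
                         omega = 1:8, rads = 10) {
  stopifnot(length(h) == 2, h[1] > 0, h[2] <= 1, h[1] <= h[2],
            length(degc) == 2, degc[1] > 0, degc[1] <= degc[2],
            length(radp) >= 1, all(radp >= 1),
            length(omega) >= 1, all(omega >= 1),
            rads >= max(radp))
  structure(list(h = h, degc = degc, radp = as.integer(radp),
                 omega = as.integer(omega), rads = as.integer(rads)),
            class = "param_ranges")
}

#' Sample random filter-parameter combinations
#'
#' Draws `n` independent combinations from the given ranges. Draws are made
#' trial by trial from a single seeded stream, so the first `m < n` samples
#' of a larger run coincide with a run of size `m` (nested-seed prefix
#' property).
#'
#' @param ranges a [param_ranges()].
#' @param n number of combinations (>= 1).
#' @param seed integer seed.
#' @return A list of `n` [filter_params()] objects.
#' @export
sample_params <- function(ranges, n, seed) {
  stopifnot(inherits(ranges, "param_ranges"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      h <- runif(1, ranges$h[1], ranges$h[2])
      degc <- runif(1, ranges$degc[1], ranges$degc[2])
      radp <- ranges$radp[sample.int(length(ranges$radp), 1)]
      omega <- ranges$omega[sample.int(length(ranges$omega), 1)]
      filter_params(h = h, radp = radp, rads = ranges$rads, degc = degc,
                    omega = omega)
    })
  })
}

#' Score one parameter combination by mean MSE
#'
#' For every (image, sigma) pair the image is corrupted with Rician noise,
#' filtered with the particle-preserving Rician filter, and the MSE against
#' the noise-free image recorded; the grand mean over all pairs is
#' returned. Corruption seeds depend only on `(seed, image index, sigma
#' index)` -- not on the parameters -- so different trials face identical
#' corruptions and their scores are directly comparable.
#'
#' @param params a [filter_params()] combination.
#' @param images non-empty list of noise-free images.
#' @param sigmas non-empty vector of Rician noise levels; the reference
#'   evaluation setting is `c(0.05, 0.1, 0.15, 0.2, 0.3)`.
#' @param seed integer seed for the corruptions.
#' @return Mean MSE (single number).
#' @export
score_params <- function(params, images, sigmas = c(0.05, 0.1, 0.15, 0.2, 0.3),
                         seed = 1) {
  if (length(images) == 0 || length(sigmas) == 0)
    stop("images and sigmas must be non-empty", call. = FALSE)
  vals <- numeric(0)
  for (i in seq_along(images)) {
    for (j in seq_along(sigmas)) {
      noisy <- add_rician(images[[i]], sigmas[j], derive_seed(seed, i, j))
      filt <- rnlm_star_filter(noisy, params, sigma = sigmas[j])
      vals <- c(vals, mse(filt, images[[i]]))
    }
  }
  mean(vals)
}

#' Random-search optimization of the filter parameters
#'
#' Samples `n` combinations, scores each with [score_params()], and returns
#' the combination minimizing the mean MSE (ties broken by first
#' occurrence). The full trial table is retained so the MSE spectrum across
#' combinations can be inspected.
#'
#' @inheritParams score_params
#' @param ranges a [param_ranges()].
#' @param n number of sampled combinations.
#' @return An object of class `rnlm_opt`: list with `best`
#'   ([filter_params()]), `best_mse`, `trials` (data.frame of sampled
#'   values and their mean MSE), `n`, `seed`.
#' @export
optimize_filter_params <- function(ranges, images,
                                   sigmas = c(0.05, 0.1, 0.15, 0.2, 0.3),
                                   n = 100, seed = 1) {
  cands <- sample_params(ranges, n, seed)
  scores <- vapply(cands, score_params, numeric(1),
                   images = images, sigmas = sigmas, seed = seed)
  best_i <- which.min(scores)   # first occurrence on ties
  trials <- data.frame(
    h = vapply(cands, `[[`, numeric(1), "h"),
    degc = vapply(cands, `[[`, numeric(1), "degc"),
    radp = vapply(cands, `[[`, integer(1), "radp"),
    omega = vapply(cands, `[[`, integer(1), "omega"),
    mse = scores)
  structure(list(best = cands[[best_i]], best_mse = scores[best_i],
                 trials = trials, n = as.integer(n), seed = as.integer(seed)),
            class = "rnlm_opt")
}

#' @export
print.rnlm_opt <- function(x, ...) {
  cat("Random-search filter optimization:", x$n, "trials, seed", x$seed, "\n")
  cat(sprintf("  best mean MSE %.6g at h=%.3f, degc=%.3f, radp=%d, omega=%d\n",
              x$best_mse, x$best$h, x$best$degc, x$best$radp, x$best$omega))
  invisible(x)
}

#' Variance of optimized parameters across repeated runs
#'
#' Sample variance (n-1 denominator) of each selected parameter across two
#' or more optimization results, characterizing how stable the selected
#' optimum is across seeds or noise conditions.
#'
#' @param results list of at least two `rnlm_opt` objects.
#' @return A data.frame with one row per parameter (`h`, `degc`, `radp`,
#'   `omega`) and its variance.
#' @export
param_variance_report <- function(results) {
  if (length(results) < 2)
    stop("need at least 2 optimization results", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "rnlm_opt")))
  get <- function(f) vapply(results, function(r) as.numeric(r$best[[f]]),
                            numeric(1))
  data.frame(parameter = c("h", "degc", "radp", "omega"),
             variance = c(var(get("h")), var(get("degc")),
                          var(get("radp")), var(get("omega"))))
}
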