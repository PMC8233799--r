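#' Filter parameter vector for the non-local means family
#'
#' Bundles the tunable parameters shared by [nlm_filter()], [rnlm_filter()]
#' and [rnlm_star_filter()]:
#'
#' * `h` — smoothing decay in `(0, 1]` on the normalized intensity scale;
#'   patch weights are `exp(-d2 / h^2)` where `d2` is the kernel-weighted
#'   mean squared patch difference. Larger `h` smooths more.
#' * `radp` — patch radius (patches are `(2 radp + 1)^2` pixels).
#' * `rads` — search-window radius (`rads >= radp`); the window is clipped
#'   at image borders and weights renormalized.
#' * `degc` — transition position of the pixel-similarity terms: the
#'   intensity difference at which the pixel similarity drops to 1/2.
#' * `omega` — integer slope of that transition (larger = sharper).
#' * `a` — spatial std (pixels) of the Gaussian patch kernel used in the
#'   patch distance; `Inf` (default) gives the uniform kernel.
#'
#' The defaults are the averaged optimum reported by the random-search
#' optimization on musculoskeletal MR data (`h = 0.8`, `radp = 3`,
#' `omega = 4`, `degc = 6.65`), with `rads = 10` (a 21x21 search window).
#'
#' @param h smoothing decay, in `(0, 1]`.
#' @param radp patch radius, integer >= 1.
#' @param rads search-window radius, integer >= `radp`.
#' @param degc pixel-similarity transition position, > 0.
#' @param omega pixel-similarity transition slope, integer >= 1.
#' @param a patch-kernel std in pixels, > 0 or `Inf` for uniform.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(h = 0.8, radp = 3, rads = 10, degc = 6.65,
                          omega = 4, a = Inf) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0 || h > 1)
    stop("h must lie in (0, 1]", call. = FALSE)
  if (radp < 1) stop("radp must be >= 1", call. = FALSE)
  if (rads < radp) stop("rads must be >= radp", call. = FALSE)
  if (!is.numeric(degc) || degc <= 0) stop("degc must be > 0", call. = FALSE)
  if (omega < 1) stop("omega must be >= 1", call. = FALSE)
  if (!(is.infinite(a) || (is.numeric(a) && a > 0)))
    stop("a must be > 0 or Inf", call. = FALSE)
  structure(list(h = h, radp = as.integer(radp), rads = as.integer(rads),
                 degc = degc, omega = as.integer(omega), a = a),
            class = "filter_params")
}

check_filter_input <- function(img, params) {
  check_image(img)
  stopifnot(inherits(params, "filter_params"))
  if (2 * params$rads + 1 > min(dim(img)))
    stop("image smaller than the search window (2*rads+1)", call. = FALSE)
  invisible(NULL)
}

#' Extract a local patch around a pixel
#'
#' Returns the intensity patch used in the patch-similarity computation,
#' with mirror padding at borders. The `contiguous` dialect reads the
#' `(2 radp + 1)^2` neighborhood directly; the `stride2` dialect samples
#' the dilated grid at offsets `{-2 radp, ..., -2, 0, 2, ..., 2 radp}` per
#' axis.
#'
#' @param img numeric matrix.
#' @param center integer `c(row, col)` (1-based).
#' @param radp patch radius.
#' @param dialect `"contiguous"` (default) or `"stride2"`.
#' @return A `(2 radp + 1) x (2 radp + 1)` numeric matrix.
#' @export
extract_patch <- function(img, center, radp, dialect = c("contiguous", "stride2")) {
  check_image(img)
  dialect <- match.arg(dialect)
  stride <- if (dialect == "stride2") 2L else 1L
  H <- nrow(img); W <- ncol(img)
  r <- center[1]; c <- center[2]
  if (r < 1 || r > H || c < 1 || c > W) stop("center out of bounds", call. = FALSE)
  refl <- function(i, n) {
    while (any(bad <- (i < 1 | i > n))) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  off <- seq(-radp, radp) * stride
  img[refl(r + off, H), refl(c + off, W), drop = FALSE]
}

#' Patch similarity weight
#'
#' `exp(-d2 / h^2)` where `d2` is the kernel-weighted mean of squared
#' differences between two equally sized patches (kernel weights sum to 1;
#' uniform when `a = Inf`).
#'
#' @param p1,p2 numeric patches of identical size.
#' @param h smoothing decay (> 0).
#' @param a patch-kernel std in pixels or `Inf` for uniform weights.
#' @return A similarity in `(0, 1]`.
#' @export
patch_similarity <- function(p1, p2, h, a = Inf) {
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  if (length(p1) != length(p2)) stop("patch sizes differ", call. = FALSE)
  if (is.infinite(a)) {
    kw <- rep(1 / length(p1), length(p1))
  } else {
    radp <- (nrow(as.matrix(p1)) - 1) / 2
    off <- seq(-radp, radp)
    g <- exp(-outer(off^2, off^2, "+") / (2 * a^2))
    kw <- as.vector(g / sum(g))
  }
  d2 <- sum(kw * (as.vector(p1) - as.vector(p2))^2)
  exp(-d2 / h^2)
}

#' Pixel-intensity similarity
#'
#' Decreasing function of the absolute intensity difference:
#' `rho = 1 / (1 + (|yi - yj| / degc)^omega)`, equal to 1 for identical
#' intensities and 1/2 at a difference of `degc`.
#'
#' @param yi,yj pixel intensities (vectorized).
#' @param degc transition position (> 0).
#' @param omega transition slope (integer >= 1).
#' @return Similarities in `[0, 1]`.
#' @export
pixel_similarity <- function(yi, yj, degc, omega) {
  if (degc <= 0) stop("degc must be > 0", call. = FALSE)
  1 / (1 + (abs(yi - yj) / degc)^omega)
}

#' Particle-preserving self-weight scale
#'
#' Increasing function of the intensity difference between the center pixel
#' and its most similar non-central neighbor:
#' `theta = 1 + (2 radp + 1)^2 / (1 + (degc / |yi - yk|)^omega)`, with the
#' analytic limit `theta = 1` at `yi = yk`. For high-contrast particles
#' (difference well above `degc`) theta approaches `1 + (2 radp + 1)^2`,
#' boosting the self-weight so the particle survives the averaging.
#'
#' @param yi,yk pixel intensities.
#' @param radp patch radius entering the `(2 radp + 1)^2` ceiling.
#' @param degc transition position (> 0).
#' @param omega transition slope.
#' @return Scales `>= 1`.
#' @export
self_weight_scale <- function(yi, yk, radp, degc, omega) {
  if (degc <= 0) stop("degc must be > 0", call. = FALSE)
  d <- abs(yi - yk)
  out <- 1 + (2 * radp + 1)^2 / (1 + (degc / d)^omega)
  out[d == 0] <- 1
  out
}

#' Non-local means filter
#'
#' Estimates each pixel as the similarity-weighted average of pixels in its
#' search window; weights come from patch distances, and the self-weight is
#' set to the maximum non-central weight to avoid over-weighting the center.
#'
#' @param img numeric matrix.
#' @param params a [filter_params()].
#' @param dialect patch sampling dialect, `"contiguous"` or `"stride2"`.
#' @return Filtered matrix.
#' @export
nlm_filter <- function(img, params = filter_params(),
                       dialect = c("contiguous", "stride2")) {
  check_filter_input(img, params)
  stride <- if (match.arg(dialect) == "stride2") 2L else 1L
  .nlm_family_cpp(img, params$h, params$radp, params$rads, params$degc,
                  params$omega, params$a, 0, 0L, stride, TRUE)
}

#' Rician-corrected non-local means filter
#'
#' Non-local means adapted to magnitude MR data: the weighted average is
#' taken over squared intensities, the Rician bias `2 sigma^2` subtracted,
#' and (by default) the square root taken back to intensity units:
#' `xhat = sqrt(max(sum_j w_ij y_j^2 - 2 sigma^2, 0))`. Weights are the
#' same patch-similarity weights as [nlm_filter()].
#'
#' @inheritParams nlm_filter
#' @param sigma Rician noise level (>= 0), e.g. from
#'   [estimate_sigma_background()].
#' @param sqrt_output apply the final square root (default `TRUE`); `FALSE`
#'   reproduces the squared-magnitude estimator without back-transform.
#' @return Filtered matrix, non-negative.
#' @export
rnlm_filter <- function(img, params = filter_params(), sigma = 0,
                        dialect = c("contiguous", "stride2"),
                        sqrt_output = TRUE) {
  check_filter_input(img, params)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stride <- if (match.arg(dialect) == "stride2") 2L else 1L
  .nlm_family_cpp(img, params$h, params$radp, params$rads, params$degc,
                  params$omega, params$a, sigma, 1L, stride, sqrt_output)
}

#' Optimized particle-preserving Rician non-local means filter
#'
#' The package's core filter. Non-central weights combine patch and pixel
#' similarity, `phi* = phi * rho`, so only pixels that resemble the center
#' both in patch structure and in raw intensity contribute strongly. The
#' self-weight is the maximum non-central weight rescaled by the
#' particle-preserving factor `theta` ([self_weight_scale()]), which grows
#' towards `1 + (2 radp + 1)^2` when the center pixel differs sharply from
#' even its best-matching neighbor -- exactly the situation at a tiny
#' high-contrast particle. The normalized weights enter the same
#' Rician-corrected estimator as [rnlm_filter()].
#'
#' @inheritParams rnlm_filter
#' @return Filtered matrix, non-negative.
#' @export
rnlm_star_filter <- function(img, params = filter_params(), sigma = 0,
                             dialect = c("contiguous", "stride2"),
                             sqrt_output = TRUE) {
  check_filter_input(img, params)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stride <- if (match.arg(dialect) == "stride2") 2L else 1L
  .nlm_family_cpp(img, params$h, params$radp, params$rads, params$degc,
                  params$omega, params$a, sigma, 2L, stride, sqrt_output)
}

#' Inspect the normalized weight field at one pixel
#'
#' Diagnostic access to the weights a filter variant actually uses at a
#' given center: the returned matrix covers the border-clipped search
#' window and sums to 1.
#'
#' @inheritParams nlm_filter
#' @param center integer `c(row, col)` (1-based).
#' @param variant `"nlm"` (patch-only weights, also used by the plain
#'   Rician filter) or `"rnlm_star"`.
#' @return A list with `weights` (matrix over the clipped window),
#'   `row_range`, `col_range` (1-based inclusive bounds), and `center`.
#' @export
compute_weight_field <- function(img, center, params = filter_params(),
                                 variant = c("nlm", "rnlm_star"),
                                 dialect = c("contiguous", "stride2")) {
  check_filter_input(img, params)
  variant <- match.arg(variant)
  stride <- if (match.arg(dialect) == "stride2") 2L else 1L
  r <- as.integer(center[1]); c <- as.integer(center[2])
  if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img))
    stop("center out of bounds", call. = FALSE)
  res <- .weight_field_cpp(img, r - 1L, c - 1L, params$h, params$radp,
                           params$rads, params$degc, params$omega, params$a,
                           if (variant == "rnlm_star") 1L else 0L, stride)
  res$center <- c(r, c)
  res
}
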