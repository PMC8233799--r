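#' Corrupt an image with Rician noise
#'
#' Simulates the magnitude of a complex Gaussian measurement around each
#' true intensity: `M = sqrt((A + n1)^2 + n2^2)` with `n1, n2` independent
#' zero-mean Gaussians of standard deviation `sigma`. This is the standard
#' noise model of magnitude MR images; it obeys `E[M^2] = A^2 + 2 sigma^2`
#' and is biased upward in low-signal regions. The output is non-negative
#' and is not clipped at 1.
#'
#' @param img numeric matrix on the `[0, 1]` scale.
#' @param sigma Gaussian component standard deviation (>= 0).
#' @param seed integer seed; the generator is a pure function of
#'   `(img, sigma, seed)`.
#' @return A numeric matrix of the same size, all values >= 0.
#' @export
add_rician <- function(img, sigma, seed) {
  check_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("sigma must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(abs(img))
  with_seed(seed, {
    n1 <- matrix(rnorm(length(img), sd = sigma), nrow(img))
    n2 <- matrix(rnorm(length(img), sd = sigma), nrow(img))
    sqrt((img + n1)^2 + n2^2)
  })
}

#' Rician probability density
#'
#' Density of the observed magnitude `M` given true intensity `A` and
#' Gaussian component std `sigma`:
#' `p(M) = (M / sigma^2) exp(-(M^2 + A^2) / (2 sigma^2)) I0(A M / sigma^2)`
#' for `M >= 0` and 0 otherwise. Evaluated with the exponentially scaled
#' Bessel function so large arguments do not overflow. With `A = 0` it
#' reduces to the Rayleigh density.
#'
#' @param M observed magnitudes (vectorized); negative values get density 0.
#' @param A true intensity (>= 0).
#' @param sigma Gaussian component std (> 0).
#' @return Density values, same length as `M`.
#' @export
rician_pdf <- function(M, A, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  if (any(A < 0)) stop("A must be non-negative", call. = FALSE)
  s2 <- sigma^2
  d <- numeric(length(M))
  ok <- M >= 0
  # I0(z) * exp(-(M^2+A^2)/(2 s2)) = besselI(z,0,scaled) * exp(-(M-A)^2/(2 s2))
  d[ok] <- (M[ok] / s2) * exp(-(M[ok] - A)^2 / (2 * s2)) *
    besselI(A * M[ok] / s2, 0, expon.scaled = TRUE)
  d
}

#' Corrupt an image with salt-and-pepper noise
#'
#' Each pixel is independently replaced with probability `d` (the noise
#' density); replaced pixels become 0 ("pepper") or 1 ("salt") with equal
#' probability. Remaining pixels are untouched.
#'
#' @param img numeric matrix on the `[0, 1]` scale.
#' @param d corruption density in `[0, 1]`.
#' @param seed integer seed.
#' @return Corrupted matrix.
#' @export
add_salt_pepper <- function(img, d, seed) {
  check_image(img)
  if (!is.numeric(d) || length(d) != 1 || d < 0 || d > 1)
    stop("density d must lie in [0, 1]", call. = FALSE)
  if (d == 0) return(img)
  with_seed(seed, {
    hit <- matrix(runif(length(img)) < d, nrow(img))
    salt <- matrix(runif(length(img)) < 0.5, nrow(img))
    out <- img
    out[hit & salt] <- 1
    out[hit & !salt] <- 0
    out
  })
}

#' Corrupt an image with speckle noise
#'
#' Multiplicative granular noise `J = I + n * I` with `n` i.i.d. zero-mean
#' of variance `v`. The multiplier is uniform on
#' `[-sqrt(3 v), sqrt(3 v)]` by default (the common `imnoise`-style
#' convention) or Gaussian with `family = "gaussian"`.
#'
#' @param img numeric matrix on the `[0, 1]` scale.
#' @param v multiplier variance (>= 0).
#' @param seed integer seed.
#' @param family `"uniform"` (default) or `"gaussian"` multiplier.
#' @return Corrupted matrix (not clipped).
#' @export
add_speckle <- function(img, v, seed, family = c("uniform", "gaussian")) {
  check_image(img)
  family <- match.arg(family)
  if (!is.numeric(v) || length(v) != 1 || v < 0)
    stop("variance v must be non-negative", call. = FALSE)
  if (v == 0) return(img)
  with_seed(seed, {
    n <- if (family == "uniform") {
      half <- sqrt(3 * v)
      runif(length(img), -half, half)
    } else {
      rnorm(length(img), sd = sqrt(v))
    }
    img + matrix(n, nrow(img)) * img
  })
}

#' Estimate the Rician noise level from a background region
#'
#' In signal-free background the squared magnitude satisfies
#' `E[M^2] = 2 sigma^2`, so `sigma = sqrt(mean(M^2) / 2)` over a
#' user-supplied background mask.
#'
#' @param img numeric matrix (noisy magnitude image).
#' @param background_mask logical matrix selecting at least 100 background
#'   pixels.
#' @return Estimated `sigma` (single number).
#' @export
estimate_sigma_background <- function(img, background_mask) {
  check_image(img)
  if (!is.logical(background_mask) || !identical(dim(background_mask), dim(img)))
    stop("background_mask must be a logical matrix matching the image",
         call. = FALSE)
  n <- sum(background_mask)
  if (n < 100)
    stop("background mask must select at least 100 pixels", call. = FALSE)
  sqrt(mean(img[background_mask]^2) / 2)
}
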