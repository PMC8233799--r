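#' Specification of a synthetic MR-like phantom
#'
#' Describes a noise-free test image made of horizontal, smoothly shaded
#' tissue-like bands with optional small high-contrast disc "particles" --
#' stand-ins for the tiny lesions whose preservation particle-aware
#' denoising targets. The same spec drives both [make_phantom()] and
#' [particle_mask()], so particle ground truth is always available.
#'
#' @param size integer vector `c(height, width)`, both at least 16.
#' @param n_bands number of horizontal tissue bands (>= 1). A single band
#'   yields a constant background (the degenerate flat phantom).
#' @param n_particles number of non-overlapping high-contrast discs (>= 0).
#' @param particle_radius_px disc radius in pixels (>= 1).
#' @param particle_contrast intensity added on top of the local background,
#'   in `(0, 1]`; particle values are clipped at 1.
#' @param edge_blur_sigma Gaussian blur std (pixels) applied after drawing
#'   bands and particles; 0 keeps hard edges and exact particle contrast.
#' @param seed integer seed; equal seeds give bit-identical phantoms.
#' @return An object of class `phantom_spec` (a named list).
#' @export
phantom_spec <- function(size = c(64, 64), n_bands = 4, n_particles = 6,
                         particle_radius_px = 1, particle_contrast = 0.5,
                         edge_blur_sigma = 0, seed = 1) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 16))
    stop("phantom size must be at least 16x16", call. = FALSE)
  if (n_bands < 1) stop("n_bands must be >= 1", call. = FALSE)
  if (n_particles < 0) stop("n_particles must be >= 0", call. = FALSE)
  if (particle_radius_px < 1) stop("particle_radius_px must be >= 1", call. = FALSE)
  if (particle_contrast <= 0 || particle_contrast > 1)
    stop("particle_contrast must lie in (0, 1]", call. = FALSE)
  if (edge_blur_sigma < 0) stop("edge_blur_sigma must be >= 0", call. = FALSE)
  if (2 * particle_radius_px + 1 > min(size))
    stop("particle radius larger than the image", call. = FALSE)
  structure(list(size = size, n_bands = as.integer(n_bands),
                 n_particles = as.integer(n_particles),
                 particle_radius_px = as.integer(particle_radius_px),
                 particle_contrast = particle_contrast,
                 edge_blur_sigma = edge_blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic internal layout shared by make_phantom() and particle_mask():
# band levels, per-band gradients and particle centres, all drawn from the
# spec seed.
phantom_layout <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  with_seed(spec$seed, {
    nb <- spec$n_bands
    # band means kept <= ~0.49 so a default 0.5-contrast particle stays in range
    levels <- if (nb == 1) 0.35 else sample(seq(0.15, 0.45, length.out = nb))
    grad_amp <- if (nb == 1) 0 else 0.04
    bounds <- round(seq(0, H, length.out = nb + 1))
    # non-overlapping particle centres fully inside the image
    r <- spec$particle_radius_px
    centers <- matrix(numeric(0), ncol = 2)
    if (spec$n_particles > 0) {
      tries <- 0
      while (nrow(centers) < spec$n_particles) {
        cand <- c(sample(seq(r + 1, H - r), 1), sample(seq(r + 1, W - r), 1))
        ok <- nrow(centers) == 0 ||
          all(sqrt(rowSums((t(t(centers) - cand))^2)) > 2 * r + 2)
        if (ok) centers <- rbind(centers, cand)
        tries <- tries + 1
        if (tries > 10000)
          stop("could not place non-overlapping particles; reduce n_particles",
               call. = FALSE)
      }
    }
    list(levels = levels, grad_amp = grad_amp, bounds = bounds,
         centers = centers)
  })
}

#' Generate a synthetic MR-like phantom image
#'
#' Renders the noise-free image described by a [phantom_spec()]: horizontal
#' bands with distinct mean levels and a gentle within-band intensity
#' gradient, hard particle discs added on top, then an optional Gaussian
#' edge blur. All intensities lie in `[0, 1]`.
#'
#' @param spec a [phantom_spec()].
#' @return A numeric matrix in `[0, 1]`.
#' @export
make_phantom <- function(spec) {
  lay <- phantom_layout(spec)
  H <- spec$size[1]; W <- spec$size[2]
  img <- matrix(0, H, W)
  for (b in seq_len(spec$n_bands)) {
    rows <- (lay$bounds[b] + 1):lay$bounds[b + 1]
    nr <- length(rows)
    ramp <- if (nr > 1) seq(-lay$grad_amp, lay$grad_amp, length.out = nr) else 0
    img[rows, ] <- lay$levels[b] + ramp
  }
  if (spec$n_particles > 0) {
    mask <- rasterize_discs(lay$centers, spec$particle_radius_px, H, W)
    img[mask] <- pmin(1, img[mask] + spec$particle_contrast)
  }
  if (spec$edge_blur_sigma > 0) img <- gaussian_blur(img, spec$edge_blur_sigma)
  pmin(pmax(img, 0), 1)
}

rasterize_discs <- function(centers, radius, H, W) {
  mask <- matrix(FALSE, H, W)
  if (nrow(centers) == 0) return(mask)
  for (k in seq_len(nrow(centers))) {
    cr <- centers[k, 1]; cc <- centers[k, 2]
    rr <- max(1, cr - radius):min(H, cr + radius)
    for (i in rr) {
      for (j in max(1, cc - radius):min(W, cc + radius)) {
        if ((i - cr)^2 + (j - cc)^2 <= radius^2) mask[i, j] <- TRUE
      }
    }
  }
  mask
}

#' Ground-truth particle mask for a phantom
#'
#' Boolean matrix that is `TRUE` exactly at pixels belonging to the
#' particles [make_phantom()] draws for the same spec.
#'
#' @param spec a [phantom_spec()].
#' @return A logical matrix of the phantom's size.
#' @export
particle_mask <- function(spec) {
  lay <- phantom_layout(spec)
  rasterize_discs(lay$centers, spec$particle_radius_px,
                  spec$size[1], spec$size[2])
}
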