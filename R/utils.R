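# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 1000003
  for (k in seq_along(idx)) {
    s <- (s * 8191 + as.double(idx[k]) * 524287 + k) %% 2147483647
  }
  as.integer(s)
}

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  invisible(img)
}

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("images must have identical dimensions", call. = FALSE)
  invisible(NULL)
}

# Separable Gaussian blur with mirror padding; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(m) {
    n <- nrow(m)
    idx <- vapply(seq_len(n), function(i) {
      j <- i + seq(-rad, rad)
      j[j < 1] <- 1 - j[j < 1]        # mirror: 0 -> 1, -1 -> 2
      j[j > n] <- 2 * n + 1 - j[j > n]
      j
    }, integer(2 * rad + 1))
    out <- matrix(0, n, ncol(m))
    for (t in seq_len(2 * rad + 1)) out <- out + k[t] * m[idx[t, ], , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(img))))
}
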