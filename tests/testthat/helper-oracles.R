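# Independent brute-force references used only by the tests. These share no
# array code with the package: plain quadruple loops and scalar arithmetic.

# Mirror reflection (edge duplicated), 1-based.
refl1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# Naive per-pixel NLM / RNLM / RNLM* reference. Small images only.
oracle_nlm_family <- function(img, params, sigma = 0,
                              variant = c("nlm", "rnlm", "rnlm_star"),
                              stride = 1, apply_sqrt = TRUE) {
  variant <- match.arg(variant)
  H <- nrow(img); W <- ncol(img)
  radp <- params$radp; rads <- params$rads
  off <- seq(-radp, radp)
  if (is.infinite(params$a)) {
    kmat <- matrix(1, length(off), length(off))
  } else {
    kmat <- exp(-outer((off * stride)^2, (off * stride)^2, "+") /
                  (2 * params$a^2))
  }
  kmat <- kmat / sum(kmat)
  getpatch <- function(r, c) {
    p <- matrix(0, length(off), length(off))
    for (ii in seq_along(off)) {
      for (jj in seq_along(off)) {
        p[ii, jj] <- img[refl1(r + off[ii] * stride, H),
                         refl1(c + off[jj] * stride, W)]
      }
    }
    p
  }
  out <- matrix(0, H, W)
  for (r in 1:H) {
    for (c in 1:W) {
      r0 <- max(1, r - rads); r1 <- min(H, r + rads)
      c0 <- max(1, c - rads); c1 <- min(W, c + rads)
      pc <- getpatch(r, c)
      wmat <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
      best <- -1; bk <- NULL
      for (jr in r0:r1) {                     # raster order
        for (jc in c0:c1) {
          if (jr == r && jc == c) next
          d2 <- sum(kmat * (pc - getpatch(jr, jc))^2)
          phi <- exp(-d2 / params$h^2)
          w <- if (variant == "rnlm_star") {
            phi / (1 + (abs(img[r, c] - img[jr, jc]) / params$degc)^params$omega)
          } else phi
          wmat[jr - r0 + 1, jc - c0 + 1] <- w
          if (w > best) { best <- w; bk <- c(jr, jc) }
        }
      }
      self <- if (variant == "rnlm_star") {
        dd <- abs(img[r, c] - img[bk[1], bk[2]])
        theta <- if (dd == 0) 1 else
          1 + (2 * radp + 1)^2 / (1 + (params$degc / dd)^params$omega)
        best * theta
      } else max(best, 0)
      wmat[r - r0 + 1, c - c0 + 1] <- self
      tot <- sum(wmat)
      if (tot <= 0) {
        wmat[, ] <- 0
        wmat[r - r0 + 1, c - c0 + 1] <- 1
        tot <- 1
      }
      wmat <- wmat / tot
      ywin <- img[r0:r1, c0:c1]
      if (variant == "nlm") {
        out[r, c] <- sum(wmat * ywin)
      } else {
        v <- max(sum(wmat * ywin^2) - 2 * sigma^2, 0)
        out[r, c] <- if (apply_sqrt) sqrt(v) else v
      }
    }
  }
  out
}

# Connected-component count (4-connectivity flood fill) above a threshold.
oracle_count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0
  for (r in 1:H) {
    for (c in 1:W) {
      if (!mask[r, c] || seen[r, c]) next
      n <- n + 1
      queue <- list(c(r, c)); seen[r, c] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
              mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  n
}

# Pixel-domain fuzzy c-means loop (no histogram weighting).
oracle_fcm <- function(x, C, m = 2, tol = 1e-6, max_iter = 300) {
  x <- as.vector(x)
  v <- as.numeric(quantile(x, probs = (seq_len(C) - 0.5) / C))
  if (any(duplicated(v))) {
    vals <- sort(unique(x))
    v <- vals[round(seq(1, length(vals), length.out = C))]
  }
  N <- length(x)
  u <- matrix(0, N, C)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(N)) {
      d <- abs(x[i] - v)
      if (any(d == 0)) {
        u[i, ] <- (d == 0) / sum(d == 0)
      } else {
        inv <- d^(-2 / (m - 1))
        u[i, ] <- inv / sum(inv)
      }
    }
    um <- u^m
    v_new <- as.vector(t(um) %*% x) / colSums(um)
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  sort(v)
}

# Reference SSIM values via scikit-image for a list of image pairs
# (win_size = full image side, uniform window, data_range 1).
skimage_ssim <- function(pairs) {
  dir <- tempfile("ssimref")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  for (i in seq_along(pairs)) {
    write.table(pairs[[i]]$x, file.path(dir, paste0("x", i, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
    write.table(pairs[[i]]$y, file.path(dir, paste0("y", i, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  script <- paste(
    "import sys, numpy as np",
    "from skimage.metrics import structural_similarity as ssim",
    "n = int(sys.argv[1]); d = sys.argv[2]",
    "for i in range(1, n + 1):",
    "    x = np.loadtxt(f'{d}/x{i}.csv', delimiter=',')",
    "    y = np.loadtxt(f'{d}/y{i}.csv', delimiter=',')",
    "    print(float(ssim(x, y, win_size=x.shape[0], data_range=1.0,",
    "               gaussian_weights=False)))",
    sep = "\n")
  sf <- file.path(dir, "ref.py")
  writeLines(script, sf)
  out <- system2("python", c(sf, length(pairs), dir), stdout = TRUE)
  as.numeric(out)
}

# Seeded random test image in [lo, hi].
rand_img <- function(h, w, seed, lo = 0, hi = 1) {
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}
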