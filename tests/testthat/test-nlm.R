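params_small <- function(...) {
  defaults <- list(h = 0.5, radp = 2, rads = 4, degc = 0.3, omega = 3)
  args <- utils::modifyList(defaults, list(...))
  do.call(filter_params, args)
}

test_that("extract_patch reads neighborhoods with mirror padding in both dialects", {
  img <- matrix(seq_len(25) / 25, 5, 5)
  # interior contiguous patch is the sub-grid read directly
  expect_equal(extract_patch(img, c(3, 3), 1), img[2:4, 2:4])
  # corner patch equals explicit mirror padding: index -? reflects off the edge
  p <- extract_patch(img, c(1, 1), 1)
  expect_equal(p, img[c(1, 1, 2), c(1, 1, 2)])
  # stride2 dialect samples the dilated grid
  img7 <- matrix(seq_len(49), 7, 7) / 49
  expect_equal(extract_patch(img7, c(4, 4), 1, dialect = "stride2"),
               img7[c(2, 4, 6), c(2, 4, 6)])
  # constant image gives a constant patch
  expect_true(all(extract_patch(matrix(0.3, 6, 6), c(2, 5), 2) == 0.3))
})

test_that("patch similarity follows the Gaussian-of-distance algebra", {
  p1 <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9), 3, 3)
  expect_equal(patch_similarity(p1, p1, h = 0.5), 1)
  # doubling the difference raises phi to the 4th power
  p2 <- p1 + 0.1
  p3 <- p1 + 0.2
  phi1 <- patch_similarity(p1, p2, h = 0.8)
  phi2 <- patch_similarity(p1, p3, h = 0.8)
  expect_equal(phi2, phi1^4, tolerance = 1e-12)
  # scalar hand computation: uniform kernel, mean squared diff
  q1 <- matrix(c(0, 0.5, 1, 0.25, 0.75, 0.5, 1, 0, 0.5), 3, 3)
  q2 <- matrix(c(0.1, 0.4, 0.9, 0.35, 0.75, 0.6, 0.8, 0.2, 0.45), 3, 3)
  d2 <- mean((q1 - q2)^2)
  expect_equal(patch_similarity(q1, q2, h = 0.8), exp(-d2 / 0.8^2))
  expect_error(patch_similarity(p1, p2, h = 0), "> 0")
})

test_that("pixel similarity and self-weight scale hit their closed-form anchors", {
  expect_equal(pixel_similarity(0.4, 0.4, degc = 0.2, omega = 5), 1)
  for (om in c(1, 2, 4, 7)) {
    expect_equal(pixel_similarity(0.1, 0.1 + 0.2, degc = 0.2, omega = om), 0.5)
  }
  expect_equal(pixel_similarity(0, 0.4, degc = 0.2, omega = 4), 1 / 17)
  expect_error(pixel_similarity(0, 1, degc = 0, omega = 2), "> 0")

  expect_equal(self_weight_scale(0.3, 0.3, radp = 3, degc = 0.2, omega = 4), 1)
  expect_equal(self_weight_scale(0, 1e9, radp = 3, degc = 0.2, omega = 4), 50,
               tolerance = 1e-6)
  expect_equal(self_weight_scale(0.1, 0.3, radp = 3, degc = 0.2, omega = 4),
               1 + 49 / 2)
})

test_that("fast filters match the naive loop oracle on small seeded images", {
  p <- params_small()
  for (seed in c(1, 2, 3)) {
    img <- rand_img(16, 16, seed)
    for (variant in c("nlm", "rnlm", "rnlm_star")) {
      fast <- switch(variant,
                     nlm = nlm_filter(img, p),
                     rnlm = rnlm_filter(img, p, sigma = 0.1),
                     rnlm_star = rnlm_star_filter(img, p, sigma = 0.1))
      ref <- oracle_nlm_family(img, p, sigma = 0.1, variant = variant)
      expect_lt(max(abs(fast - ref)), 1e-8)
    }
  }
  # stride2 dialect and the Gaussian patch kernel agree with the oracle too
  img <- rand_img(16, 16, 9)
  pg <- params_small(a = 1.5)
  expect_lt(max(abs(rnlm_star_filter(img, pg, sigma = 0.05, dialect = "stride2") -
                    oracle_nlm_family(img, pg, sigma = 0.05,
                                      variant = "rnlm_star", stride = 2))),
            1e-8)
  # literal no-sqrt estimator agrees as well
  expect_lt(max(abs(rnlm_filter(img, pg, sigma = 0.05, sqrt_output = FALSE) -
                    oracle_nlm_family(img, pg, sigma = 0.05, variant = "rnlm",
                                      apply_sqrt = FALSE))),
            1e-8)
})

test_that("constant and near-zero-h inputs reproduce themselves", {
  const <- matrix(0.42, 12, 12)
  p <- params_small(rads = 3)
  expect_equal(nlm_filter(const, p), const)
  expect_equal(rnlm_filter(const, p, sigma = 0), const)
  expect_equal(rnlm_star_filter(const, p, sigma = 0), const)
  # constant at sqrt(2)*sigma: the bias subtraction cancels exactly
  sig <- 0.2
  c2 <- matrix(sqrt(2) * sig, 12, 12)
  expect_equal(rnlm_filter(c2, p, sigma = sig), matrix(0, 12, 12))
  # h -> 0+: weights collapse onto identical patches of a step image
  step <- matrix(0.2, 16, 16); step[, 9:16] <- 0.8
  ph <- params_small(h = 1e-3)
  expect_lt(max(abs(nlm_filter(step, ph) - step)), 1e-6)
  expect_lt(max(abs(oracle_nlm_family(step, ph, variant = "nlm") - step)), 1e-6)
})

test_that("weight fields are normalized and expose the particle self-weight boost", {
  img <- rand_img(12, 12, 4)
  p <- params_small(rads = 3)
  for (variant in c("nlm", "rnlm_star")) {
    for (r in 1:12) {
      for (c in 1:12) {
        wf <- compute_weight_field(img, c(r, c), p, variant)
        expect_lt(abs(sum(wf$weights) - 1), 1e-10)
        expect_true(all(wf$weights >= 0))
      }
    }
  }
  # constant image: uniform weights over the clipped window
  wf <- compute_weight_field(matrix(0.5, 12, 12), c(6, 6), p, "nlm")
  expect_equal(wf$weights,
               matrix(1 / 49, 7, 7))
  # at a particle center the rnlm_star self-weight share exceeds the nlm share
  spec <- phantom_spec(c(32, 32), n_bands = 1, n_particles = 1,
                       particle_radius_px = 1, particle_contrast = 0.5, seed = 2)
  ph <- make_phantom(spec)
  ctr <- which(particle_mask(spec), arr.ind = TRUE)[1, ]
  pp <- params_small(degc = 0.2)
  self_share <- function(variant) {
    wf <- compute_weight_field(ph, ctr, pp, variant)
    wf$weights[ctr[1] - wf$row_range[1] + 1, ctr[2] - wf$col_range[1] + 1]
  }
  expect_gt(self_share("rnlm_star"), self_share("nlm"))
})

test_that("filters are shift-equivariant away from borders and bounded", {
  img <- rand_img(20, 20, 6)
  p <- params_small(radp = 1, rads = 3)
  shift <- function(m, k) m[c((k + 1):nrow(m), 1:k), ]
  f1 <- rnlm_star_filter(shift(img, 5), p, sigma = 0.05)
  f2 <- shift(rnlm_star_filter(img, p, sigma = 0.05), 5)
  interior <- 6:10   # rows whose search window + patches avoid borders/wrap in both
  expect_lt(max(abs(f1[interior, ] - f2[interior, ])), 1e-8)

  out_nlm <- nlm_filter(img, p)
  expect_true(all(out_nlm >= min(img) - 1e-12 & out_nlm <= max(img) + 1e-12))
  out_star <- rnlm_star_filter(img, p, sigma = 0.1)
  expect_true(all(out_star >= 0 & out_star <= max(img) + 1e-12))
})

test_that("degc -> Inf collapses the optimized filter onto plain RNLM", {
  img <- rand_img(16, 16, 8)
  p_inf <- params_small(degc = 1e9)
  p <- params_small()
  expect_lt(max(abs(rnlm_star_filter(img, p_inf, sigma = 0.1) -
                    rnlm_filter(img, p, sigma = 0.1))), 1e-10)
})

test_that("images smaller than the search window are rejected", {
  expect_error(nlm_filter(rand_img(8, 8, 1), filter_params(rads = 10)),
               "search window")
  expect_error(rnlm_filter(rand_img(16, 16, 1), params_small(), sigma = -1),
               ">= 0")
})
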