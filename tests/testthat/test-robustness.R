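tiny_phantoms <- function(n = 2, size = 24)
  lapply(seq_len(n), function(i)
    make_phantom(phantom_spec(c(size, size), n_bands = 3, n_particles = 2,
                              seed = 10 + i)))

fast_star <- function(...) filter_spec("rnlm_star",
  params = filter_params(h = 0.6, radp = 1, rads = 3, degc = 0.2, omega = 4), ...)

test_that("zero noise with the identity filter gives perfect metrics", {
  curve <- noise_sweep(tiny_phantoms(1), "rician", filter_spec("identity"),
                       levels = 0, seed = 1)
  expect_equal(curve$ssim, 1)
  expect_equal(curve$q_index, 1)
  expect_identical(curve$snr_db, Inf)
  expect_identical(curve$psnr_db, Inf)
})

test_that("sweeps reproduce a manual pipeline and are seed-deterministic", {
  imgs <- tiny_phantoms(1)
  fs <- fast_star()
  curve <- noise_sweep(imgs, "salt_pepper", fs, levels = 0.3, seed = 5)
  # manual composition through the public API
  noisy <- add_salt_pepper(imgs[[1]], 0.3, rnlmstar:::derive_seed(5, 1, 1))
  filt <- rnlm_star_filter(noisy, fs$params, sigma = 0)  # auto-sigma: 0 off-Rician
  expect_equal(curve$ssim, ssim(filt, imgs[[1]]))
  expect_equal(curve$snr_db, snr_db(filt, imgs[[1]]))
  expect_equal(curve$q_index, q_index(filt, imgs[[1]]))

  c2 <- noise_sweep(imgs, "salt_pepper", fs, levels = 0.3, seed = 5)
  expect_identical(curve, c2)
  expect_error(noise_sweep(imgs, "salt_pepper", fs, levels = c(0.5, 2)), "density")
  expect_error(noise_sweep(list(), "rician", fs), "non-empty")
})

test_that("identity-filter curves equal the corrupt-vs-native baseline", {
  imgs <- tiny_phantoms(1)
  lv <- c(0.2, 0.5)
  curve <- noise_sweep(imgs, "rician", filter_spec("identity"), levels = lv,
                       seed = 3)
  for (k in seq_along(lv)) {
    noisy <- add_rician(imgs[[1]], lv[k], rnlmstar:::derive_seed(3, 1, k))
    expect_equal(curve$ssim[k], ssim(noisy, imgs[[1]]))
    expect_equal(curve$psnr_db[k], psnr_db(noisy, imgs[[1]]))
  }
})

test_that("pooled intensity-difference studies keep exact bookkeeping", {
  imgs <- tiny_phantoms(2, size = 20)
  lv <- c(0.1, 0.3, 0.5)
  tab <- id_distribution_study(imgs, "rician",
                               list(filter_spec("identity"),
                                    filter_spec("median", kernel = 3)),
                               levels = lv, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n, rep(2 * 3 * 20 * 20, 2))
  # identity at zero noise: all-zero stats
  tab0 <- id_distribution_study(imgs, "rician", list(filter_spec("identity")),
                                levels = 0, seed = 2)
  expect_equal(tab0$median_pct, 0)
  expect_equal(tab0$variance, 0)
  expect_error(id_distribution_study(imgs, "rician", list(), levels = lv),
               "non-empty")
})

test_that("filter comparisons report relative percentage differences", {
  imgs <- tiny_phantoms(1)
  fs <- fast_star()
  same <- compare_filters(imgs, "rician", fs, fs, levels = c(0.2, 0.4), seed = 4)
  expect_equal(same$diff_ssim_pct, 0)
  expect_equal(same$diff_corr_pct, 0)

  cmp <- compare_filters(imgs, "salt_pepper", fs,
                         filter_spec("average", kernel = 3),
                         levels = c(0.2, 0.4, 0.6), seed = 4)
  # hand-computed from the two returned 3-level curves
  expect_equal(cmp$diff_ssim_pct,
               100 * (mean(cmp$curve_a$ssim) - mean(cmp$curve_b$ssim)) /
                 mean(cmp$curve_b$ssim))
  expect_equal(cmp$diff_corr_pct,
               100 * (mean(cmp$curve_a$corr) - mean(cmp$curve_b$corr)) /
                 mean(cmp$curve_b$corr))
})

test_that("the optimized filter beats a plain one under salt-and-pepper noise", {
  # particle phantoms; identical corruptions for both filters by shared seed
  imgs <- lapply(1:2, function(i)
    make_phantom(phantom_spec(c(24, 24), n_bands = 2, n_particles = 3,
                              particle_contrast = 0.5, seed = 30 + i)))
  # degc = 1: pixel similarity suppresses impulse neighbours in the average
  # without letting the self-weight boost dominate at corrupted centres
  p <- filter_params(h = 0.6, radp = 1, rads = 3, degc = 1, omega = 4)
  cmp <- compare_filters(imgs, "salt_pepper",
                         filter_spec("rnlm_star", params = p),
                         filter_spec("rnlm", params = p),
                         levels = c(0.2, 0.4, 0.6), seed = 8)
  expect_gt(cmp$diff_ssim_pct, 0)
})
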