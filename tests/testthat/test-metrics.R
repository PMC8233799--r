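test_that("mse, snr and psnr hit their closed forms and oracles", {
  x <- rand_img(15, 15, 1)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x, x + 0.1), 0.01)
  y <- rand_img(15, 15, 2)
  expect_equal(mse(x, y), sum((x - y)^2) / length(x), tolerance = 1e-14)
  expect_equal(mse(x, y), mse(y, x))

  expect_identical(snr_db(x, x), Inf)
  s <- matrix(1, 10, 10); shat <- matrix(0.9, 10, 10)
  expect_equal(snr_db(s, shat), 20)
  # scalar oracle + role asymmetry (numerator is the filtered image's power)
  expect_equal(snr_db(x, y), 10 * log10(sum(x^2) / sum((x - y)^2)),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(snr_db(x, y), snr_db(y, x))))

  expect_identical(psnr_db(x, x), Inf)
  z <- x + 0.1
  expect_equal(psnr_db(x, z), 20)
  expect_equal(psnr_db(x, y, peak = 0.5),
               10 * log10(0.25 / mse(x, y)), tolerance = 1e-10)
  expect_error(mse(x, rand_img(10, 10, 1)), "dimensions")
})

test_that("q_index is the product of its three factors and handles degeneracy", {
  x <- rand_img(15, 15, 3, lo = 0.1, hi = 0.9)
  expect_equal(q_index(x, x), 1)
  y <- rand_img(15, 15, 4, lo = 0.1, hi = 0.9)
  xv <- as.vector(x); yv <- as.vector(y)
  ref <- (cov(xv, yv) / (sd(xv) * sd(yv))) *
    (2 * mean(xv) * mean(yv) / (mean(xv)^2 + mean(yv)^2)) *
    (2 * sd(xv) * sd(yv) / (var(xv) + var(yv)))
  expect_equal(q_index(x, y), ref, tolerance = 1e-10)
  expect_true(abs(q_index(x, y)) <= 1)
  expect_equal(q_index(x, y), q_index(y, x))
  # y = -x with zero-mean x: correlation -1 but zero luminance kills the product
  x0 <- matrix(c(rep(-0.3, 112), 0, rep(0.3, 112)), 15, 15)  # exact zero mean
  expect_equal(q_index(x0, -x0), 0)
  expect_true(is.na(q_index(x, matrix(0.5, 15, 15))))
})

test_that("global ssim matches scalar evaluation and an independent reference", {
  x <- rand_img(15, 15, 5)
  expect_equal(ssim(x, x), 1)
  # constant pair: contrast/structure factors are constants-only
  a <- matrix(0.2, 10, 10); b <- matrix(0.8, 10, 10)
  C1 <- 0.01^2; C2 <- 0.03^2; C3 <- C2 / 2
  l <- (2 * 0.2 * 0.8 + C1) / (0.04 + 0.64 + C1)
  expect_equal(ssim(a, b), l * 1 * 1)
  expect_equal(ssim(a, b), ssim(b, a))

  pairs <- lapply(1:5, function(i)
    list(x = rand_img(15, 15, 100 + i), y = rand_img(15, 15, 200 + i)))
  ref <- skimage_ssim(pairs)
  got <- vapply(pairs, function(p) ssim(p$x, p$y), numeric(1))
  expect_lt(max(abs(got - ref)), 1e-6)

  # windowed mode returns the mean over sliding windows, still 1 on identity
  expect_equal(ssim(x, x, mode = "window", window = 8), 1)
})

test_that("correlation and monotonicity properties hold", {
  x <- rand_img(20, 20, 6)
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, 2 * x + 3), 1)
  y <- rand_img(20, 20, 7)
  expect_equal(pearson_corr(x, y), cor(as.vector(x), as.vector(y)))
  expect_true(is.na(pearson_corr(x, matrix(1, 20, 20))))

  # growing noise: mse strictly increases, ssim strictly decreases
  set.seed(11)
  noise <- matrix(rnorm(400), 20, 20)
  eps <- c(0.02, 0.05, 0.1, 0.2)
  mses <- vapply(eps, function(e) mse(x, x + e * noise), numeric(1))
  ssims <- vapply(eps, function(e) ssim(x, x + e * noise), numeric(1))
  expect_true(all(diff(mses) > 0))
  expect_true(all(diff(ssims) < 0))
})

test_that("intensity-difference statistics match quantile/histogram oracles", {
  x <- rand_img(16, 16, 8)
  st0 <- intensity_diff_stats(x, x)
  expect_equal(st0$median_pct, 0)
  expect_equal(st0$mode_pct, 0)
  expect_equal(st0$variance, 0)

  st <- intensity_diff_stats(x, x + 0.1)
  expect_equal(st$median_pct, 10)
  expect_equal(st$mode_pct, 10)
  expect_equal(st$variance, 0)

  y <- rand_img(16, 16, 9)
  st2 <- intensity_diff_stats(x, y, n_bins = 64)
  id <- abs(as.vector(x) - as.vector(y)) * 100
  expect_equal(st2$median_pct, median(id))
  expect_equal(st2$variance, var(id))
  breaks <- seq(0, 100, length.out = 65)
  h <- hist(id, breaks = breaks, plot = FALSE)
  expect_equal(st2$mode_pct, h$mids[which.max(h$counts)])

  rep <- metric_report(x, x)
  expect_equal(rep$mse, 0)
  expect_equal(rep$ssim, 1)
  expect_identical(rep$snr_db, Inf)
})
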