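test_that("Gaussian PSF kernel matches its closed form", {
  k <- make_psf(2)
  c0 <- k$half_width + 1
  expect_equal(k$kernel[c0 + 1, c0] / k$kernel[c0, c0], exp(-1 / 8))
  expect_equal(sum(k$kernel), 1)
  # radial symmetry
  k5 <- make_psf(2, half_width = 5)
  expect_equal(k5$kernel[6 + 3, 6 + 4], k5$kernel[6 + 4, 6 + 3])
  expect_equal(k5$kernel[6 + 3, 6 + 4], k5$kernel[6 - 3, 6 - 4])
  expect_equal(which.max(k5$kernel), (6 - 1) * 11 + 6)  # centre is the max
  expect_error(make_psf(0), "sigma_b")
  expect_error(make_psf(-1), "sigma_b")
})

test_that("TV objective evaluates fidelity and penalty terms", {
  psf <- make_psf(1)
  f <- matrix(2, 6, 6)
  expect_equal(tv_objective(f, f, psf, 0.1), 0)
  # constant offset: pure fidelity, |d| per pixel
  g <- f + 0.25
  expect_equal(tv_objective(f, g, psf, 0.1), 0.25 * 36)
  # unit step edge, identity psf, f = g: objective = lambda * number of unit
  # jumps of the forward-difference gradient (4 rows with one jump each)
  idpsf <- make_psf(1e-3, half_width = 1)
  step <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  expect_equal(tv_objective(step, step, idpsf, 0.01), 0.01 * 4)
  expect_error(tv_objective(matrix(0, 2, 2), matrix(0, 3, 3), psf, 0.1), "shape")
})

test_that("TV-l1 deblurring descends the objective and improves PSNR", {
  psf_id <- make_psf(1e-3, half_width = 1)
  g0 <- matrix(3, 16, 16)
  expect_equal(as.numeric(tv_l1_deblur(g0, psf_id)), as.numeric(g0))

  set.seed(20)
  n_desc <- n_gain <- 0
  for (r in 1:10) {
    sb <- sample(c(1, 2), 1)
    psf <- make_psf(sb)
    f <- piecewise_slice(32) * runif(1, 0.5, 2)
    g <- cpp_conv2d_sym(f, psf$kernel)
    fs <- tv_l1_deblur(g, psf)
    if (tv_objective(fs, g, psf, 0.01) <= tv_objective(g, g, psf, 0.01)) n_desc <- n_desc + 1
    if (psnr(fs, f) > psnr(g, f)) n_gain <- n_gain + 1
    tr <- attr(fs, "objective_trace")
    expect_true(all(diff(tr) <= 1e-9))
  }
  expect_equal(n_desc, 10)
  expect_equal(n_gain, 10)
  expect_error(tv_l1_deblur(matrix(c(1, NA, 1, 1), 2), make_psf(1)), "finite")
})

test_that("MMWF window statistics match hand computation", {
  s <- mmwf_window_stats(rep(3, 9))
  expect_equal(s$mu_bar, 3)
  expect_equal(s$sigma_n_sq, 0)
  s2 <- mmwf_window_stats(c(0, 0, 0, 0, 10, 0, 0, 0, 0))
  expect_equal(s2$mu_bar, 0)
  expect_equal(s2$sigma_n_sq, 800 / 81)
  expect_equal(mmwf_window_stats(c(1, 2, 3, 4))$mu_bar, 2.5)
  expect_error(mmwf_window_stats(numeric(0)), "nonempty")
})

test_that("MMWF matches the per-pixel brute-force oracle", {
  set.seed(77)
  for (r in 1:20) {
    x <- matrix(runif(256), 16)
    w <- sample(c(3, 5), 1)
    expect_lt(max(abs(mmwf_denoise(x, mmwf_config(w)) - brute_mmwf(x, w))), 1e-9)
  }
})

test_that("MMWF limiting cases: identity, median filter, worked example", {
  set.seed(8)
  x <- matrix(runif(64), 8)
  expect_equal(mmwf_denoise(x, mmwf_config(3, "fixed", 0)), x)

  # gamma^2 equal to every local variance reduces to the local median map
  cst <- matrix(rep(c(0, 1), 32), 8)  # checkerboard stripes: constant local var
  st <- cpp_local_median_var(cst, 3)
  expect_equal(length(unique(round(as.numeric(st$var), 12))), 1)
  out <- mmwf_denoise(cst, mmwf_config(3, "fixed", st$var[1, 1]))
  expect_equal(out, st$median)

  s <- matrix(0, 5, 5); s[3, 3] <- 10
  out2 <- mmwf_denoise(s, mmwf_config(3, "fixed", 2))
  expect_equal(out2[3, 3], (1 - 2 / (800 / 81)) * 10)
})

test_that("volume restoration is slice-wise and method-dispatching", {
  set.seed(15)
  v <- random_volume(c(12, 12, 5))
  expect_identical(restore_volume(v, restoration_config("none")), v)

  z <- array(0, c(12, 12, 3))
  expect_equal(as.numeric(restore_volume(z, restoration_config("deblur", sigma_b = 1))),
               rep(0, length(z)))

  cfg <- restoration_config("denoise", mmwf = mmwf_config(3))
  rv <- restore_volume(v, cfg)
  for (s in 1:5)
    expect_equal(rv[, , s], mmwf_denoise(v[, , s], cfg$mmwf))

  bad <- restoration_config("none"); bad$method <- "sharpen"
  expect_error(restore_volume(v, bad), "unknown")
})

test_that("restoration is shift-equivariant away from boundaries", {
  set.seed(21)
  f <- piecewise_slice(32)
  g <- cpp_conv2d_sym(f, make_psf(1)$kernel) + matrix(rnorm(1024, 0, 0.02), 32)
  shift <- function(m, k) m[c((nrow(m) - k + 1):nrow(m), 1:(nrow(m) - k)), ]
  inner <- 10:22
  # fixed gamma^2 makes the filter purely local; the global
  # mean-of-local-variances rule depends on boundary windows by design
  cfgm <- mmwf_config(3, "fixed", 0.02^2)
  a <- mmwf_denoise(shift(g, 2), cfgm)
  b <- shift(mmwf_denoise(g, cfgm), 2)
  expect_lt(max(abs(a[inner, inner] - b[inner, inner])), 1e-9)
})

test_that("restoration gain: denoising improves PSNR on noise-only slices", {
  set.seed(33)
  gains <- replicate(10, {
    f <- piecewise_slice(32)
    g <- f + matrix(rnorm(1024, 0, 0.15), 32)
    psnr(mmwf_denoise(g, mmwf_config(5)), f) - psnr(g, f)
  })
  expect_gt(mean(gains), 0)
})
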