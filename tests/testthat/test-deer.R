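test_that("dipolar kernel: t = 0 row, quadrature agreement, r-scaling", {
  r <- c(2, 3.5, 5)
  t <- c(0, 0.3, 1)
  K <- dipolar_kernel(r, t)
  expect_equal(K[1, ], rep(1, 3), ignore_attr = TRUE)
  expect_equal(K[3, 1], kernel_quadrature(2, 1), tolerance = 1e-6)
  expect_equal(K[2, 2], kernel_quadrature(3.5, 0.3), tolerance = 1e-6)
  # slower oscillation at larger r: first zero crossing later for r = 5
  tt <- seq(0, 3, by = 0.005)[-1]
  k2 <- dipolar_kernel(c(2, 5), c(0, tt))[-1, ]
  expect_lt(min(which(k2[, 1] < 0)), min(which(k2[, 2] < 0)))
  expect_error(dipolar_kernel(c(-1, 2), t), "positive")
})

test_that("simulate_trace limiting cases are exact", {
  r <- seq(1, 8, by = 0.02)
  P <- distance_distribution(r, dnorm(r, 4, 0.3))
  tg <- seq(0, 3, length.out = 200)
  bg <- background_model(k = 0.15, lambda = 0.3)
  # lambda -> 0: pure background
  tr0 <- simulate_trace(P, bg, tg, noise_sd = 0, lambda_override = 0)
  expect_equal(tr0$v, exp(-0.15 * tg), tolerance = 1e-12)
  # delta distribution, k = 0: v = 1 - lambda + lambda K(t, r0)
  Pd <- distance_distribution(r, dnorm(r, 3, 1e-4))
  trd <- simulate_trace(Pd, background_model(0, 0.3), tg, noise_sd = 0)
  Kcol <- dipolar_kernel(3, tg[-1])
  expect_equal(trd$v[-1], 0.7 + 0.3 * as.numeric(Kcol), tolerance = 1e-4)
  # determinism
  t1 <- simulate_trace(P, bg, tg, noise_sd = 0.02, seed = 7)
  t2 <- simulate_trace(P, bg, tg, noise_sd = 0.02, seed = 7)
  expect_identical(t1$v, t2$v)
})

test_that("background fit recovers k and lambda on a noise-free trace", {
  ds <- make_deer_dataset(noise_sd = 0)
  fit <- fit_background(ds$trace)
  expect_equal(fit$background$k, 0.2, tolerance = 0.01)  # within 1%
  expect_lt(abs(fit$background$lambda - 0.3), 0.01)      # within 0.01 absolute
  expect_equal(fit$form_factor$f[1], 1)
})

test_that("background fit on a modulation-free trace raises a fit error", {
  r <- seq(1, 8, by = 0.02)
  P <- distance_distribution(r, dnorm(r, 4, 0.3))
  tr <- simulate_trace(P, background_model(0.2, 0.3), seq(0, 3, length.out = 200),
                       noise_sd = 0, lambda_override = 0)
  expect_error(fit_background(tr), "modulation depth")
})

test_that("power scaling: identity at n = 2, square root at n = 3, invertible", {
  f <- form_factor(c(0, 0.5, 1), c(1, 0.81, 0.81))
  expect_equal(power_scale(f, 2)$f, f$f)
  expect_equal(power_scale(f, 3)$f, c(1, 0.9, 0.9))
  back <- power_scale(f, 3)$f^2
  expect_equal(back[-1], f$f[-1], tolerance = 1e-12)
  expect_error(power_scale(f, 1), "n_spins")
})

test_that("noise-free inversions recover delta and Gaussian distributions", {
  r <- seq(1, 10, by = 0.02)
  tg <- seq(0, 3.2, length.out = 320)
  # delta at 3 nm
  Pd <- distance_distribution(r, dnorm(r, 3, 1e-3))
  trd <- simulate_trace(Pd, background_model(0, 0.3), tg, noise_sd = 0)
  fd <- form_factor(tg, (trd$v - 0.7) / 0.3)
  pd <- tikhonov_invert(fd)
  expect_equal(find_modes(pd), 3, tolerance = 0.021)
  # Gaussian 4.5 / 0.3 through the full pipeline
  ds <- make_deer_dataset(noise_sd = 0)
  pg <- tikhonov_invert(fit_background(ds$trace)$form_factor)
  expect_equal(distribution_mean(pg), 4.5, tolerance = 0.05 / 4.5)
  sd_rec <- sqrt(sum((pg$r - distribution_mean(pg))^2 * pg$p) * 0.02)
  expect_equal(sd_rec, 0.3, tolerance = 0.2)
})

test_that("fnnls agrees with the reference non-negative solver", {
  set.seed(4)
  A <- matrix(rnorm(60 * 15), 60, 15)
  xtrue <- pmax(rnorm(15), 0)
  b <- A %*% xtrue + rnorm(60, 0, 0.01)
  x1 <- spinsight:::fnnls(crossprod(A), as.numeric(crossprod(A, b)))
  x2 <- pracma::lsqnonneg(A, as.numeric(b))$x
  expect_equal(x1, x2, tolerance = 1e-6)
  expect_true(all(x1 >= 0))
})

test_that("regularization ladder: residual non-increasing as alpha decreases", {
  ds <- make_deer_dataset(noise_sd = 0.01, seed = 2)
  f <- fit_background(ds$trace)$form_factor
  ladder <- 10^seq(-2, 4, length.out = 7)
  res <- vapply(ladder, function(a)
    tikhonov_invert(f, alpha = a)$metadata$residual_norm, 0)
  expect_true(all(diff(res) >= -1e-8))  # ascending alpha -> ascending residual
  semi <- vapply(ladder, function(a)
    tikhonov_invert(f, alpha = a)$metadata$seminorm, 0)
  expect_true(all(diff(semi) <= 1e-8))  # and smoother solutions
})

test_that("advisory distance ceiling follows the cube-root rule", {
  expect_equal(max_reliable_distance(2), 5)
  expect_equal(max_reliable_distance(16), 10)
  tm <- seq(0.5, 16, by = 0.5)
  expect_true(all(diff(max_reliable_distance(tm)) > 0))
  expect_error(max_reliable_distance(0), "positive")
})

test_that("trace ASCII round trip preserves signal and metadata", {
  ds <- make_deer_dataset(noise_sd = 0.01, seed = 3)
  f <- withr::local_tempfile(fileext = ".dat")
  write_trace(ds$trace, f)
  tr <- read_trace(f)
  expect_equal(tr$v, ds$trace$v, tolerance = 1e-10)
  expect_equal(tr$meta$lambda, 0.3)
  expect_equal(tr$meta$k, 0.2)
})
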