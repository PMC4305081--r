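test_that("background subtraction removes smooth structure, keeps blobs", {
  # uniform image -> all zero
  flat <- matrix(5, 48, 48)
  expect_true(all(subtract_background(flat, 8) == 0))

  # output is never negative
  set.seed(6)
  img <- matrix(runif(48 * 48, 0, 10), 48)
  expect_gte(min(subtract_background(img, 8)), 0)

  # blobs on a smooth gradient: gradient removed, peak heights preserved
  sim <- simulate_image_pair(image_sim_params(
    shape = c(64, 64), n_slices = 1, n_shared = 3, n_private = 0,
    gradient_amp = 20, noise_sd = 0))
  raw <- sim$r[[1]]
  sub <- subtract_background(raw, 12)
  for (i in seq_len(nrow(sim$centers))) {
    px <- round(c(sim$centers$row[i], sim$centers$col[i]))
    true_amp <- raw[px[1], px[2]] -
      sim$params$gradient_amp * (px[1] / 64 + px[2] / 64) / 2
    expect_lt(abs(sub[px[1], px[2]] - true_amp) / true_amp, 0.05)
  }
  # background pixels far from blobs are near zero
  far <- sub[1:5, 1:5]
  expect_lt(max(far), 0.05 * max(sub))

  expect_error(subtract_background(flat, 0), "positive")
  expect_error(subtract_background(flat, 100), "extent")
})

test_that("z-projection is the per-pixel sum or maximum", {
  st <- array(0, dim = c(3, 3, 3))
  st[, , 1] <- 2; st[, , 2] <- 5; st[, , 3] <- 3
  expect_equal(z_project(st, "max"), matrix(5, 3, 3))
  expect_equal(z_project(st, "sum"), matrix(10, 3, 3))
  expect_equal(z_project(st, "sum", 2), matrix(5, 3, 3))  # identity

  set.seed(14)
  stack <- lapply(1:4, function(i) matrix(runif(25), 5))
  brute <- Reduce(`+`, stack)
  expect_equal(z_project(stack, "sum"), brute)
  expect_error(z_project(stack, "sum", integer(0)), "empty")
  expect_error(z_project(stack, "sum", 9), "outside")
})

test_that("PDM matches the defining formula and covariance identity", {
  # hand-evaluated 2x2 example
  r <- matrix(c(1, 1, 3, 3), 2)       # columns (1,1) and (3,3)
  g <- matrix(c(1, 3, 3, 1), 2)
  m <- compute_pdm(r, g)
  expect_equal(m$mean_r, 2)
  expect_equal(m$mean_g, 2)
  expect_equal(m$pdm, matrix(c(1, -1, 1, -1), 2))

  # self-colocalization is non-negative
  set.seed(23)
  x <- matrix(runif(100), 10)
  expect_true(all(compute_pdm(x, x)$pdm >= 0))

  # mean PDM = population covariance, to near machine precision
  a <- matrix(rnorm(400, 50, 10), 20)
  b <- 0.5 * a + matrix(rnorm(400, 0, 5), 20)
  mm <- compute_pdm(a, b)
  pop_cov <- mean((a - mean(a)) * (b - mean(b)))
  expect_equal(mm$summary$mean_pdm, pop_cov, tolerance = 1e-12)
  n <- length(a)
  expect_equal(mm$summary$mean_pdm, cov(c(a), c(b)) * (n - 1) / n,
               tolerance = 1e-12)

  # shift invariance / scale equivariance
  shifted <- compute_pdm(a + 100, b)
  expect_equal(shifted$pdm, mm$pdm, tolerance = 1e-12)
  scaled <- compute_pdm(3 * a, b)
  expect_equal(scaled$pdm, 3 * mm$pdm, tolerance = 1e-12)

  # independent channels: mean PDM within 3 SE of zero
  set.seed(77)
  u <- matrix(rnorm(1e4), 100); v <- matrix(rnorm(1e4), 100)
  ind <- compute_pdm(u, v)
  se <- sd(c((u - mean(u)) * (v - mean(v)))) / 100
  expect_lt(abs(ind$summary$mean_pdm), 3 * se)

  # masking and degenerate inputs
  mask <- matrix(FALSE, 2, 2); mask[1, ] <- TRUE
  mk <- compute_pdm(r, g, mask)
  expect_true(all(is.na(mk$pdm[2, ])))
  expect_equal(mk$mean_r, 2)
  expect_error(compute_pdm(r, g, matrix(c(TRUE, FALSE, FALSE, FALSE), 2)),
               "2 pixels")
  const <- compute_pdm(matrix(2, 3, 3), matrix(rnorm(9), 3))
  expect_true(const$constant)
  expect_true(all(const$pdm == 0))
})

test_that("PDM summaries and rendering behave on constructed maps", {
  r <- matrix(c(1, 2, 3, 4), 2); g <- r
  m <- compute_pdm(r, g)
  expect_equal(m$summary$fraction_positive, 1)

  # antisymmetric map: fraction positive one half, mean zero
  a <- matrix(c(1, 1, 3, 3), 2); b <- matrix(c(1, 3, 1, 3), 2)
  ms <- compute_pdm(a, b)
  expect_equal(ms$summary$fraction_positive, 0.5)
  expect_equal(ms$summary$mean_pdm, 0)

  png <- tempfile(fileext = ".png")
  s <- pdm_summary(m, png)
  expect_true(file.exists(png))
  expect_equal(s$n_pixels, 4)
})

test_that("shared structure drives positive PDM on generator images", {
  # no shared blobs, only private: mean PDM near zero over background
  sim0 <- simulate_image_pair(image_sim_params(amp_shared = 0,
                                               n_private = 0,
                                               gradient_amp = 0,
                                               noise_sd = 2), seed = 4)
  r0 <- z_project(sim0$r, "sum"); g0 <- z_project(sim0$g, "sum")
  m0 <- compute_pdm(r0, g0)
  dr <- r0 - mean(r0); dg <- g0 - mean(g0)
  se <- sd(c(dr * dg)) / sqrt(length(r0))
  expect_lt(abs(m0$summary$mean_pdm), 3 * se)

  # identical structure, no noise: PDM >= 0 everywhere after projection
  sim1 <- simulate_image_pair(image_sim_params(n_private = 0,
                                               noise_sd = 0), seed = 5)
  m1 <- compute_pdm(z_project(sim1$r, "sum"), z_project(sim1$g, "sum"))
  expect_gte(min(m1$pdm), 0)

  # default params: shared pixels colocalize more than private pixels
  sim2 <- simulate_image_pair(image_sim_params(), seed = 6)
  m2 <- compute_pdm(z_project(sim2$r, "sum"), z_project(sim2$g, "sum"))
  fp_shared <- mean(m2$pdm[sim2$labels == "shared"] > 0)
  fp_private <- mean(m2$pdm[sim2$labels %in%
                              c("private_r", "private_g")] > 0)
  expect_gt(fp_shared, fp_private)
})
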