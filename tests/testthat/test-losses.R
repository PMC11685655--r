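test_that("least-squares adversarial losses hit their fixed points", {
  expect_equal(lsgan_losses(rep(1, 4), rep(0, 4))$discriminator_loss, 0)
  expect_equal(lsgan_losses(rep(0.5, 3), rep(0.5, 3))$discriminator_loss, 0.5)
  expect_equal(lsgan_losses(rep(0.2, 3), rep(1, 5))$generator_loss, 0)
  expect_error(lsgan_losses(numeric(0), 1), "non-empty")
})

test_that("cycle loss matches a per-pixel brute-force oracle", {
  # perfect reconstruction
  a <- rand_tile(4, 4, 1, seed = 1)
  expect_equal(cycle_loss(a, a, a, a), 0)
  # reconstruction offset by a constant in one direction only
  expect_equal(cycle_loss(list(a$pixels), list(a$pixels + 0.25),
                          list(a$pixels), list(a$pixels)),
               0.25, tolerance = 1e-12)
  # random pair vs double-loop evaluation
  set.seed(2)
  x <- array(runif(16), c(4, 4, 1)); rx <- array(runif(16), c(4, 4, 1))
  y <- array(runif(16), c(4, 4, 1)); ry <- array(runif(16), c(4, 4, 1))
  oracle <- 0
  for (i in 1:4) for (j in 1:4) {
    oracle <- oracle + abs(rx[i, j, 1] - x[i, j, 1]) + abs(ry[i, j, 1] - y[i, j, 1])
  }
  expect_equal(cycle_loss(x, rx, y, ry), oracle / 16, tolerance = 1e-12)
  expect_error(cycle_loss(x, array(0, c(2, 2, 1)), y, ry), "shape")
})

test_that("cycle loss is symmetric under jointly swapping the two sides", {
  set.seed(3)
  mk <- function() array(runif(25), c(5, 5, 1))
  a <- mk(); ra <- mk(); b <- mk(); rb <- mk()
  expect_equal(cycle_loss(a, ra, b, rb), cycle_loss(b, rb, a, ra))
})

test_that("SSIM loss composes from the metric and stays in [0, 4]", {
  a <- rand_tile(8, 8, 1, seed = 4)
  expect_equal(ssim_loss(a, a, a, a), 0)
  set.seed(5)
  x <- array(runif(64), c(8, 8, 1)); rx <- array(runif(64), c(8, 8, 1))
  y <- array(runif(64), c(8, 8, 1)); ry <- array(runif(64), c(8, 8, 1))
  got <- ssim_loss(x, rx, y, ry)
  want <- 2 - ssim_global_bruteforce(x, rx) - ssim_global_bruteforce(y, ry)
  expect_equal(got, want, tolerance = 1e-10)
  expect_gte(got, 0)
  expect_lte(got, 4)
})

test_that("saliency mask follows the sigmoid soft-threshold contract", {
  expect_equal(saliency_mask(0.5, 0.5), 0.5)
  expect_lt(abs(saliency_mask(0.9, 0.5) - 1), 1e-15)
  expect_lt(saliency_mask(0.1, 0.5), 1e-15)
  expect_equal(saliency_mask(0.49, 0.5), 1 / (1 + exp(1)), tolerance = 1e-12)
  # monotone nondecreasing in x, bounded by [0, 1] (saturation touches the
  # bounds only to within floating-point resolution)
  xs <- seq(0, 1, by = 0.01)
  m <- saliency_mask(xs, 0.37)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 0 & m <= 1))
  near <- abs(xs - 0.37) < 0.05
  expect_true(all(m[near] > 0 & m[near] < 1))
})

test_that("high-gain saliency mask converges to the hard indicator", {
  set.seed(6)
  x <- runif(500)
  keep <- abs(x - 0.5) >= 0.01
  soft <- saliency_mask(x, 0.5, gain = 1e4)
  hard <- as.numeric(x > 0.5)
  expect_lt(max(abs(soft[keep] - hard[keep])), 1e-10)
})

test_that("saliency loss vanishes for mask-preserving maps and matches brute force", {
  cfg <- loss_config(threshold_A = 0.5, threshold_B = 0.5)
  a <- rand_tile(6, 6, 1, seed = 7)
  expect_equal(saliency_loss(a, a, a, a, cfg), 0)
  # binary image, any map preserving the super/sub-threshold sets
  bin <- array(rep(c(0, 1), 18), c(6, 6, 1))
  moved <- bin * 0.2 + 0.8 * bin   # 0 -> 0, 1 -> 1 (identical sets)
  expect_lt(saliency_loss(bin, moved, bin, bin, cfg), 1e-10)
  # random case vs per-pixel evaluation of the two mask terms
  set.seed(8)
  x <- array(runif(16), c(4, 4, 1)); gx <- array(runif(16), c(4, 4, 1))
  y <- array(runif(16), c(4, 4, 1)); gy <- array(runif(16), c(4, 4, 1))
  cfg2 <- loss_config(threshold_A = 0.3, threshold_B = 0.6)
  sig <- function(v, t) 1 / (1 + exp(-100 * (v - t)))
  oracle <- 0
  for (i in 1:4) for (j in 1:4) {
    oracle <- oracle + abs(sig(x[i, j, 1], 0.3) - sig(gx[i, j, 1], 0.6)) / 16 +
      abs(sig(y[i, j, 1], 0.6) - sig(gy[i, j, 1], 0.3)) / 16
  }
  expect_equal(saliency_loss(x, gx, y, gy, cfg2), oracle, tolerance = 1e-12)
})

test_that("total loss assembles the weighted sum and flags bad terms", {
  cfg0 <- loss_config(lambda_cyc = 0, xi_ssim = 0, rho_saliency = 0,
                      threshold_A = 0.5, threshold_B = 0.5)
  expect_equal(total_loss(1.5, 2.5, 9, 9, 9, cfg0)$total, 4)
  cfg <- loss_config(lambda_cyc = 10, xi_ssim = 5, rho_saliency = 0.5,
                     threshold_A = 0.5, threshold_B = 0.5)
  expect_equal(total_loss(1, 1, 2, 3, 4, cfg)$total, 39)
  # nondecreasing in each weight for nonnegative components
  base <- total_loss(1, 1, 2, 3, 4, cfg)$total
  cfg_up <- loss_config(lambda_cyc = 11, xi_ssim = 5, rho_saliency = 0.5,
                        threshold_A = 0.5, threshold_B = 0.5)
  expect_gte(total_loss(1, 1, 2, 3, 4, cfg_up)$total, base)
  expect_error(total_loss(1, NaN, 2, 3, 4, cfg), "gan_backward")
})

test_that("loss configuration validates weights and thresholds", {
  expect_error(loss_config(lambda_cyc = -1), "lambda_cyc")
  expect_error(loss_config(threshold_A = 1.5), "thresholds")
  expect_s3_class(loss_config(), "loss_config")
})
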