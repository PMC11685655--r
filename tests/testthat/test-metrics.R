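test_that("PSNR reproduces its closed-form anchor cases", {
  a <- rand_tile(8, 8, 1, seed = 1)
  expect_identical(psnr(a, a), Inf)
  zero <- array(0, c(8, 8, 1)); full <- array(1, c(8, 8, 1))
  expect_equal(psnr(zero, full, max_value = 1), 0)
  # MSE = MAX^2 / 100 -> 20 dB
  test <- array(0.1, c(8, 8, 1))
  expect_equal(psnr(zero, test, max_value = 1), 20)
  # raw-ratio mode computes the unlogged ratio
  expect_equal(psnr(zero, test, max_value = 1, raw_ratio = TRUE), 1000)
  expect_error(psnr(zero, array(0, c(4, 4, 1))), "shape")
})

test_that("PCC matches a from-scratch covariance computation", {
  a <- rand_tile(5, 5, 1, seed = 2)
  expect_equal(pcc(a, a), 1)
  centred <- a$pixels - mean(a$pixels)
  expect_equal(pcc(centred, -centred + 0.3), -1)
  set.seed(3)
  x <- array(runif(25), c(5, 5, 1)); y <- array(runif(25), c(5, 5, 1))
  xv <- as.vector(x); yv <- as.vector(y)
  oracle <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  expect_equal(pcc(x, y), oracle, tolerance = 1e-12)
  expect_error(pcc(array(0.5, c(5, 5, 1)), x), "constant")
})

test_that("global SSIM evaluates the formula term by term", {
  a <- rand_tile(8, 8, 1, seed = 4)
  gp <- ssim_params(mode = "global")
  expect_equal(ssim_index(a, a, gp), 1)
  # constant images: sigma terms vanish, second factor is c2/c2 = 1
  ca <- array(0.2, c(8, 8, 1)); cb <- array(0.8, c(8, 8, 1))
  want <- (2 * 0.2 * 0.8 + 1e-4) / (0.2^2 + 0.8^2 + 1e-4)
  expect_equal(ssim_index(ca, cb, gp), want, tolerance = 1e-12)
  expect_equal(want, 0.4706661, tolerance = 1e-6)   # 0.3201 / 0.6801
  set.seed(5)
  x <- array(runif(64), c(8, 8, 1)); y <- array(runif(64), c(8, 8, 1))
  expect_equal(ssim_index(x, y, gp), ssim_global_bruteforce(x, y),
               tolerance = 1e-10)
})

test_that("windowed SSIM matches a brute-force sliding-window oracle", {
  set.seed(6)
  x <- matrix(runif(12 * 12), 12, 12)
  y <- pmin(pmax(x + rnorm(144, 0, 0.1), 0), 1)
  p <- ssim_params(mode = "windowed", window_size = 5, window_sigma = 1.5)
  got <- ssim_index(array(x, c(12, 12, 1)), array(y, c(12, 12, 1)), p)
  # independent loop over all valid 5x5 windows
  k <- dnorm(-2:2, sd = 1.5); w <- outer(k, k); w <- w / sum(w)
  vals <- c()
  for (i in 1:8) for (j in 1:8) {
    wx <- x[i:(i + 4), j:(j + 4)]; wy <- y[i:(i + 4), j:(j + 4)]
    mx <- sum(w * wx); my <- sum(w * wy)
    vx <- sum(w * wx^2) - mx^2; vy <- sum(w * wy^2) - my^2
    cv <- sum(w * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + p$c1) * (2 * cv + p$c2)) /
                ((mx^2 + my^2 + p$c1) * (vx + vy + p$c2)))
  }
  expect_equal(got, mean(vals), tolerance = 1e-10)
  expect_equal(ssim_index(array(x, c(12, 12, 1)), array(x, c(12, 12, 1)), p), 1)
})

test_that("FID reproduces Gaussian closed forms and vanishes on identical sets", {
  set.seed(7)
  X <- matrix(rnorm(200), 50, 4)
  expect_lt(fid(X, X), 1e-8)
  # exact moments supplied directly: N(0,1) vs N(3,1) -> 9; var 1 vs 4 -> 1
  expect_equal(fid_from_moments(0, matrix(1), 3, matrix(1)), 9, tolerance = 1e-6)
  expect_equal(fid_from_moments(0, matrix(1), 0, matrix(4)), 1, tolerance = 1e-6)
  Y <- matrix(rnorm(200, 1), 50, 4)
  expect_equal(fid(X, Y), fid(Y, X), tolerance = 1e-9)
  expect_gte(fid(X, Y), 0)
  expect_error(fid(X, matrix(0, 5, 3)), "dimension")
})

test_that("FID sample estimate converges to the closed form in 1-D", {
  set.seed(8)
  X <- matrix(rnorm(1e4, 0, 1)); Y <- matrix(rnorm(1e4, 3, 1))
  expect_equal(fid(X, Y), 9, tolerance = 0.05)
})

test_that("the FID matrix square root is validated by squaring", {
  set.seed(9)
  A <- crossprod(matrix(rnorm(36), 6, 6)) / 6 + diag(6) * 0.1
  B <- crossprod(matrix(rnorm(36), 6, 6)) / 6 + diag(6) * 0.1
  P <- A %*% B
  S <- Re(pracma::sqrtm(P)$B)
  expect_lt(norm(S %*% S - P, "F") / norm(P, "F"), 1e-6)
})

test_that("KID equals a double-loop unbiased estimator and is symmetric", {
  kpoly <- function(x, y) (sum(x * y) / length(x) + 1)^3
  expect_equal(kpoly(rep(0, 5), rep(0, 5)), 1)   # kernel at the origin
  set.seed(10)
  for (n in c(3, 6, 10)) {
    X <- matrix(rnorm(n * 4), n, 4); Y <- matrix(rnorm(n * 4, 0.5), n, 4)
    acc_xx <- 0; acc_yy <- 0; acc_xy <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i != j) {
        acc_xx <- acc_xx + kpoly(X[i, ], X[j, ])
        acc_yy <- acc_yy + kpoly(Y[i, ], Y[j, ])
      }
      acc_xy <- acc_xy + kpoly(X[i, ], Y[j, ])
    }
    oracle <- acc_xx / (n * (n - 1)) + acc_yy / (n * (n - 1)) - 2 * acc_xy / n^2
    expect_equal(kid(X, Y), oracle, tolerance = 1e-12)
    expect_equal(kid(X, Y), kid(Y, X), tolerance = 1e-12)
  }
  expect_error(kid(matrix(0, 1, 2), matrix(0, 5, 2)), "at least 2")
})

test_that("KID is an unbiased null estimator under equal distributions", {
  set.seed(11)
  vals <- replicate(200, {
    X <- matrix(rnorm(20 * 3), 20, 3)
    Y <- matrix(rnorm(20 * 3), 20, 3)
    kid(X, Y)
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("subset-averaged KID is deterministic given its seed", {
  set.seed(12)
  X <- matrix(rnorm(30 * 4), 30, 4); Y <- matrix(rnorm(30 * 4, 1), 30, 4)
  a <- kid(X, Y, subset_size = 10, n_subsets = 5, seed = 99)
  b <- kid(X, Y, subset_size = 10, n_subsets = 5, seed = 99)
  expect_identical(a, b)
})

test_that("the frozen embedding is deterministic and named", {
  emb <- embedding_pool_project()
  t0 <- rand_tile(32, 32, 2, seed = 13)
  v1 <- emb$embed(t0); v2 <- emb$embed(t0)
  expect_identical(v1, v2)
  expect_length(v1, emb$d)
  expect_match(emb$name, "pool8-proj32")
  # a second instance built later gives the same projection
  emb2 <- embedding_pool_project()
  expect_identical(emb2$embed(t0), v1)
})

test_that("evaluating a set against itself gives the perfect-score report", {
  ds <- generate_dataset(5, seed = 14, field_size_px = 32,
                         scene_params = list(n_nuclei = 2,
                                             nucleus_axes_px = list(a = c(3, 5), b = c(2, 3)),
                                             n_filaments = 1))
  rep_ <- evaluate_sets(ds$B, ds$B, pairing = 1:5,
                        ssim_parameters = ssim_params(mode = "global"))
  expect_identical(rep_$psnr_db[["mean"]], Inf)
  expect_equal(rep_$ssim[["mean"]], 1)
  expect_equal(rep_$pcc[["mean"]], 1)
  expect_lt(rep_$fid, 1e-8)
  expect_identical(rep_$n_pairs, 5L)
  expect_match(rep_$embedding, "pool")
  # aggregation equals an independent pass over the per-pair list
  expect_equal(rep_$ssim[["sd"]], sd(rep_$per_pair$ssim))
  expect_error(evaluate_sets(ds$B, ds$B, pairing = 1:3), "pairing")
})
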