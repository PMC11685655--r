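# shared fixtures and independent oracles, built in code at test time

# random image tile in [0, 1]
rand_tile <- function(h = 8, w = h, c = 1, seed = NULL,
                      channels = c("gray1", "rgb3", "stain2")[match(c, c(1, 3, 2))]) {
  if (!is.null(seed)) set.seed(seed)
  image_tile(array(runif(h * w * c), dim = c(h, w, c)), channels)
}

# central-difference numeric gradient of scalar-valued f at x
num_grad <- function(f, x, eps = 1e-6) {
  gr <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    gr[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force global SSIM, term by term (population moments)
ssim_global_bruteforce <- function(a, b, c1 = 1e-4, c2 = 9e-4) {
  a <- as.vector(a); b <- as.vector(b)
  n <- length(a)
  mu_a <- sum(a) / n
  mu_b <- sum(b) / n
  var_a <- sum((a - mu_a)^2) / n
  var_b <- sum((b - mu_b)^2) / n
  cov_ab <- sum((a - mu_a) * (b - mu_b)) / n
  ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
}

# small toy generator/discriminator configs used across tests
toy_gen_spec <- function() generator_spec(base_channels = 4L, n_residual_blocks = 1L)
toy_disc_spec <- function(input_size = 32L) {
  discriminator_spec(base_channels = 4L, n_blocks = 3L, fc_width = 16L,
                     input_size = input_size)
}
toy_model <- function(seed = 1L, input_size = 32L,
                      domains = list(A = "gray1", B = "stain2")) {
  translation_model(toy_gen_spec(), toy_disc_spec(input_size), seed = seed,
                    domains = domains)
}
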