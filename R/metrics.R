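# Evaluation stack: peak signal-to-noise ratio, Pearson correlation,
# structural similarity, and the set-level Frechet / kernel distances between
# feature-embedding distributions.

#' SSIM parameters
#'
#' @param c1,c2 stabilising constants; defaults `(0.01 L)^2` and `(0.03 L)^2`
#'   per the standard SSIM reference
#' @param dynamic_range value-range width `L`
#' @param mode `"windowed"` (sliding Gaussian window, the reporting standard)
#'   or `"global"` (one evaluation over the whole image; the differentiable
#'   form used in the training loss and in oracle tests)
#' @param window_size,window_sigma Gaussian window shape for windowed mode
#' @return object of class `ssim_params`
#' @export
ssim_params <- function(c1 = (0.01 * dynamic_range)^2,
                        c2 = (0.03 * dynamic_range)^2,
                        dynamic_range = 1,
                        mode = c("windowed", "global"),
                        window_size = 11L, window_sigma = 1.5) {
  mode <- match.arg(mode)
  stopifnot(c1 > 0, c2 > 0, dynamic_range > 0, window_size %% 2 == 1)
  structure(list(c1 = c1, c2 = c2, dynamic_range = dynamic_range, mode = mode,
                 window_size = as.integer(window_size), window_sigma = window_sigma),
            class = "ssim_params")
}

default_global_ssim_params <- function() ssim_params(mode = "global")

.as_plane <- function(x) {
  x <- if (inherits(x, "image_tile")) x$pixels else x
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  x
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX_I^2 / MSE)` in decibels, with the mean square error taken
#' over all pixels and channels. Identical images give `+Inf`. With
#' `raw_ratio = TRUE` the unlogged ratio `10 * MAX_I^2 / MSE` is returned
#' instead.
#'
#' @param reference,test arrays or [image_tile]s of identical shape
#' @param max_value maximum possible value of the reference image
#' @param raw_ratio return the plain ratio instead of decibels
#' @return decibels (or ratio), `+Inf` when MSE is zero
#' @export
psnr <- function(reference, test, max_value = 1, raw_ratio = FALSE) {
  a <- .as_plane(reference); b <- .as_plane(test)
  if (!identical(dim(a), dim(b))) stop("shape mismatch between reference and test")
  stopifnot(max_value > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  if (raw_ratio) 10 * max_value^2 / mse else 10 * log10(max_value^2 / mse)
}

#' Pearson correlation coefficient between two images
#'
#' Cross-covariance over the pooled pixels divided by the two standard
#' deviations.
#'
#' @param a,b arrays or [image_tile]s of identical shape, non-constant
#' @return correlation in `[-1, 1]`
#' @export
pcc <- function(a, b) {
  x <- as.vector(.as_plane(a)); y <- as.vector(.as_plane(b))
  if (length(x) != length(y)) stop("shape mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("PCC undefined for a constant image (zero variance)")
  }
  stats::cor(x, y)
}

# Gaussian window, normalised
.ssim_window <- function(size, sigma) {
  r <- (size - 1L) / 2L
  k <- stats::dnorm(-r:r, sd = sigma)
  w <- outer(k, k)
  w / sum(w)
}

# valid-mode weighted local filtering used by windowed SSIM
.wfilter <- function(m, w) {
  s <- nrow(w)
  H <- nrow(m); W <- ncol(m)
  Ho <- H - s + 1L; Wo <- W - s + 1L
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    out <- out + w[i, j] * m[i:(i + Ho - 1L), j:(j + Wo - 1L)]
  }
  out
}

#' Structural similarity index
#'
#' Global mode evaluates the SSIM formula once from whole-image moments
#' (population variances); windowed mode averages the per-window formula over
#' sliding Gaussian-weighted windows (valid region), the conventional
#' reporting form. Multi-channel images are averaged over channels.
#'
#' @param a,b arrays or [image_tile]s of identical shape
#' @param params an [ssim_params]
#' @return value in `[-1, 1]`; identical images give exactly 1
#' @export
ssim_index <- function(a, b, params = ssim_params()) {
  x <- .as_plane(a); y <- .as_plane(b)
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  c1 <- params$c1; c2 <- params$c2
  per_chan <- function(xm, ym) {
    if (params$mode == "global") {
      mx <- mean(xm); my <- mean(ym)
      vx <- mean(xm^2) - mx^2; vy <- mean(ym^2) - my^2
      cv <- mean(xm * ym) - mx * my
      ((2 * mx * my + c1) * (2 * cv + c2)) /
        ((mx^2 + my^2 + c1) * (vx + vy + c2))
    } else {
      s <- min(params$window_size, nrow(xm), ncol(xm))
      if (s %% 2 == 0) s <- s - 1L
      w <- .ssim_window(s, params$window_sigma)
      mx <- .wfilter(xm, w); my <- .wfilter(ym, w)
      vx <- .wfilter(xm^2, w) - mx^2
      vy <- .wfilter(ym^2, w) - my^2
      cv <- .wfilter(xm * ym, w) - mx * my
      mean(((2 * mx * my + c1) * (2 * cv + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  vals <- vapply(seq_len(dim(x)[3]), function(ch) per_chan(x[, , ch], y[, , ch]), 1.0)
  mean(vals)
}

## ---- set-level distances ----

#' Frechet distance between Gaussian fits of two feature sets
#'
#' `||mu_X - mu_Y||^2 + Tr(S_X + S_Y - 2 (S_X S_Y)^(1/2))` from the sample
#' means and covariances of the embedded images.
#'
#' @param features_x,features_y numeric matrices (n x d), one embedding per row
#' @param eps ridge added to near-singular covariances before the matrix
#'   square root
#' @return nonnegative real
#' @export
fid <- function(features_x, features_y, eps = 1e-6) {
  features_x <- as.matrix(features_x); features_y <- as.matrix(features_y)
  if (ncol(features_x) != ncol(features_y)) stop("feature dimension mismatch")
  fid_from_moments(colMeans(features_x), stats::cov(features_x),
                   colMeans(features_y), stats::cov(features_y), eps = eps)
}

#' Frechet distance from supplied Gaussian moments
#'
#' @param mu_x,mu_y mean vectors
#' @param sigma_x,sigma_y covariance matrices
#' @param eps ridge for near-singular covariances
#' @return nonnegative real
#' @export
fid_from_moments <- function(mu_x, sigma_x, mu_y, sigma_y, eps = 1e-6) {
  sigma_x <- as.matrix(sigma_x); sigma_y <- as.matrix(sigma_y)
  d <- length(mu_x)
  prod_ <- sigma_x %*% sigma_y
  s <- tryCatch(pracma::sqrtm(prod_)$B, error = function(e) NULL)
  if (is.null(s) || any(!is.finite(s))) {
    reg <- eps * diag(d)
    prod_ <- (sigma_x + reg) %*% (sigma_y + reg)
    s <- pracma::sqrtm(prod_)$B
  }
  s <- Re(s)
  val <- sum((mu_x - mu_y)^2) + sum(diag(sigma_x + sigma_y - 2 * s))
  max(val, 0)
}

# polynomial kernel matrix (x'y / d + 1)^3 between rows of X and Y
.kid_kernel <- function(X, Y, degree = 3, gamma = NULL, coef0 = 1) {
  d <- ncol(X)
  if (is.null(gamma)) gamma <- 1 / d
  (gamma * tcrossprod(X, Y) + coef0)^degree
}

#' Kernel inception distance (unbiased squared MMD)
#'
#' Unbiased estimator of the squared maximum mean discrepancy between the two
#' embedded sets under the polynomial kernel `k(x, y) = (x'y / d + 1)^3`; the
#' estimate can be slightly negative. Optionally averaged over random subsets
#' of fixed size.
#'
#' @param features_x,features_y numeric matrices (n x d), `n >= 2`
#' @param degree,coef0 polynomial kernel parameters
#' @param subset_size,n_subsets when both set, average the estimator over
#'   `n_subsets` random subsets of `subset_size` rows each
#' @param seed seed for subset sampling
#' @return real number
#' @export
kid <- function(features_x, features_y, degree = 3, coef0 = 1,
                subset_size = NULL, n_subsets = NULL, seed = 1) {
  X <- as.matrix(features_x); Y <- as.matrix(features_y)
  if (nrow(X) < 2 || nrow(Y) < 2) stop("KID needs at least 2 samples per set")
  if (ncol(X) != ncol(Y)) stop("feature dimension mismatch")
  one <- function(X, Y) {
    m <- nrow(X); n <- nrow(Y)
    Kxx <- .kid_kernel(X, X, degree, coef0 = coef0)
    Kyy <- .kid_kernel(Y, Y, degree, coef0 = coef0)
    Kxy <- .kid_kernel(X, Y, degree, coef0 = coef0)
    (sum(Kxx) - sum(diag(Kxx))) / (m * (m - 1)) +
      (sum(Kyy) - sum(diag(Kyy))) / (n * (n - 1)) -
      2 * mean(Kxy)
  }
  if (is.null(subset_size) || is.null(n_subsets)) return(one(X, Y))
  stopifnot(subset_size >= 2, subset_size <= nrow(X), subset_size <= nrow(Y))
  vals <- with_local_seed(seed, {
    vapply(seq_len(n_subsets), function(i) {
      one(X[sample.int(nrow(X), subset_size), , drop = FALSE],
          Y[sample.int(nrow(Y), subset_size), , drop = FALSE])
    }, 1.0)
  })
  mean(vals)
}

## ---- feature embedding ----

#' Deterministic lightweight feature embedding
#'
#' Average-pools the channel-mean image to an 8 x 8 grid and applies a fixed
#' seeded random projection to `dim` dimensions. Fully offline and
#' deterministic: the same image always maps to the same vector. Set-level
#' scores are only comparable within one embedding, which every report names.
#'
#' @param dim embedding dimension
#' @param pool pooled grid side
#' @param seed seed of the frozen projection matrix
#' @return object of class `feature_embedding` with elements `embed`
#'   (function image -> vector), `d`, and `name`
#' @export
embedding_pool_project <- function(dim = 32L, pool = 8L, seed = 90210L) {
  P <- with_local_seed(seed,
    matrix(stats::rnorm(pool * pool * dim, sd = 1 / sqrt(pool * pool)),
           pool * pool, dim))
  name <- sprintf("pool%d-proj%d-v1", pool, dim)
  embed <- function(img) {
    a <- .as_plane(img)
    gray <- if (dim(a)[3] > 1) apply(a, c(1, 2), mean) else a[, , 1]
    h <- nrow(gray); w <- ncol(gray)
    ri <- cut(seq_len(h), pool, labels = FALSE)
    ci <- cut(seq_len(w), pool, labels = FALSE)
    pooled <- rowsum(t(rowsum(gray, ri)), ci) /
      tcrossprod(tabulate(ci, pool), tabulate(ri, pool))
    as.vector(crossprod(P, as.vector(t(pooled))))
  }
  structure(list(embed = embed, d = as.integer(dim), name = name),
            class = "feature_embedding")
}

#' Embed every tile of a dataset into feature space
#' @param dataset a [domain_dataset] or list of tiles/arrays
#' @param embedding a [feature_embedding]
#' @return matrix (n x d)
#' @export
embed_dataset <- function(dataset, embedding) {
  tiles <- if (inherits(dataset, "domain_dataset")) dataset$tiles else dataset
  t(vapply(tiles, embedding$embed, numeric(embedding$d)))
}

## ---- report ----

#' Evaluate a generated image set against a reference set
#'
#' Pairwise metrics (PSNR, PCC, SSIM) need a pairing index and are reported
#' as mean and standard deviation over pairs; FID and KID are computed once
#' per set from the named feature embedding and need no pairing.
#'
#' @param generated,reference [domain_dataset]s (or lists of tiles)
#' @param pairing integer vector mapping generated index -> reference index,
#'   or `NULL` for set-level metrics only
#' @param embedding a [feature_embedding]
#' @param ssim_parameters an [ssim_params] for the pairwise SSIM
#' @param max_value `MAX_I` for PSNR
#' @return object of class `metric_report`
#' @export
evaluate_sets <- function(generated, reference, pairing = NULL,
                          embedding = embedding_pool_project(),
                          ssim_parameters = ssim_params(),
                          max_value = 1) {
  g_tiles <- if (inherits(generated, "domain_dataset")) generated$tiles else generated
  r_tiles <- if (inherits(reference, "domain_dataset")) reference$tiles else reference
  per_pair <- NULL
  if (!is.null(pairing)) {
    stopifnot(length(pairing) == length(g_tiles), all(pairing >= 1),
              all(pairing <= length(r_tiles)))
    per_pair <- data.frame(
      psnr_db = vapply(seq_along(g_tiles), function(i)
        psnr(r_tiles[[pairing[i]]], g_tiles[[i]], max_value), 1.0),
      pcc = vapply(seq_along(g_tiles), function(i)
        pcc(r_tiles[[pairing[i]]], g_tiles[[i]]), 1.0),
      ssim = vapply(seq_along(g_tiles), function(i)
        ssim_index(r_tiles[[pairing[i]]], g_tiles[[i]], ssim_parameters), 1.0))
  }
  FX <- embed_dataset(g_tiles, embedding)
  FY <- embed_dataset(r_tiles, embedding)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  structure(list(
    per_pair = per_pair,
    psnr_db = if (!is.null(per_pair)) agg(per_pair$psnr_db),
    pcc = if (!is.null(per_pair)) agg(per_pair$pcc),
    ssim = if (!is.null(per_pair)) agg(per_pair$ssim),
    fid = fid(FX, FY),
    kid = kid(FX, FY),
    n_pairs = if (!is.null(pairing)) length(pairing) else 0L,
    n_images = c(generated = length(g_tiles), reference = length(r_tiles)),
    embedding = embedding$name),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  if (!is.null(x$per_pair)) {
    cat(sprintf("  PSNR: %.3f +/- %.3f dB  (n = %d pairs)\n",
                x$psnr_db["mean"], x$psnr_db["sd"], x$n_pairs))
    cat(sprintf("  PCC:  %.4f +/- %.4f\n", x$pcc["mean"], x$pcc["sd"]))
    cat(sprintf("  SSIM: %.4f +/- %.4f\n", x$ssim["mean"], x$ssim["sd"]))
  }
  cat(sprintf("  FID: %.6g   KID: %.6g   (embedding %s, n = %d vs %d)\n",
              x$fid, x$kid, x$embedding, x$n_images[1], x$n_images[2]))
  invisible(x)
}
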