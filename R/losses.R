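# The training objective: least-squares adversarial terms, cycle consistency,
# SSIM, and the saliency-mask constraint, plus their weighted sum. These are
# the numeric (array-level) definitions; the trainer evaluates the same
# expressions on the autodiff tape and the two routes are tested against each
# other.

#' Loss configuration
#'
#' Weights and thresholds of the full objective
#' `L = L_GAN(G_A, D_B) + L_GAN(G_B, D_A) + lambda * L_CYC + xi * L_SSIM +
#' rho * L_S`.
#'
#' @param lambda_cyc weight of the cycle-consistency loss (default 10, the
#'   CycleGAN convention)
#' @param xi_ssim weight of the SSIM loss
#' @param rho_saliency weight of the saliency loss
#' @param threshold_A,threshold_B segmentation thresholds for the soft
#'   saliency masks of domains A and B (`NA` means: pick by Otsu's method
#'   over a sample of training tiles at training start)
#' @param sigmoid_gain gain of the soft threshold sigmoid (default 100)
#' @return object of class `loss_config`
#' @export
loss_config <- function(lambda_cyc = 10, xi_ssim = 1, rho_saliency = 1,
                        threshold_A = NA_real_, threshold_B = NA_real_,
                        sigmoid_gain = 100) {
  stopifnot(lambda_cyc >= 0, xi_ssim >= 0, rho_saliency >= 0, sigmoid_gain > 0)
  for (t in c(threshold_A, threshold_B)) {
    if (!is.na(t) && (t < 0 || t > 1)) stop("thresholds must lie in [0, 1]")
  }
  structure(list(lambda_cyc = lambda_cyc, xi_ssim = xi_ssim,
                 rho_saliency = rho_saliency,
                 threshold_A = threshold_A, threshold_B = threshold_B,
                 sigmoid_gain = sigmoid_gain),
            class = "loss_config")
}

.as_batch <- function(x) {
  if (inherits(x, "image_tile") || is.numeric(x)) list(x) else x
}
.px <- function(x) if (inherits(x, "image_tile")) x$pixels else x

#' Least-squares adversarial losses
#'
#' The discriminator regresses real scores to 1 and fake scores to 0:
#' `d_loss = mean((D_real - 1)^2) + mean(D_fake^2)`. The generator drives its
#' fakes toward the real target: `g_loss = mean((D_fake - 1)^2)`.
#'
#' @param d_real_scores,d_fake_scores numeric vectors of discriminator scores
#' @return list with `discriminator_loss` and `generator_loss`
#' @export
lsgan_losses <- function(d_real_scores, d_fake_scores) {
  if (length(d_real_scores) == 0 || length(d_fake_scores) == 0) {
    stop("score sets must be non-empty")
  }
  list(discriminator_loss = mean((d_real_scores - 1)^2) + mean(d_fake_scores^2),
       generator_loss = mean((d_fake_scores - 1)^2))
}

#' Cycle-consistency loss
#'
#' Per-pixel mean absolute deviation between each image and its
#' round-trip reconstruction, summed over the two directions:
#' `mean |G_B(G_A(a)) - a| + mean |G_A(G_B(b)) - b|`, averaged over pixels
#' and batch so the value is resolution-invariant.
#'
#' @param a_batch,reconstructed_a,b_batch,reconstructed_b arrays,
#'   [image_tile]s, or lists of them
#' @return nonnegative scalar
#' @export
cycle_loss <- function(a_batch, reconstructed_a, b_batch, reconstructed_b) {
  l1 <- function(xs, ys) {
    xs <- .as_batch(xs); ys <- .as_batch(ys)
    stopifnot(length(xs) == length(ys))
    mean(vapply(seq_along(xs), function(i) {
      x <- .px(xs[[i]]); y <- .px(ys[[i]])
      if (!identical(dim(x) %||% length(x), dim(y) %||% length(y))) {
        stop("shape mismatch between image and reconstruction")
      }
      mean(abs(y - x))
    }, 1.0))
  }
  l1(a_batch, reconstructed_a) + l1(b_batch, reconstructed_b)
}

#' SSIM loss
#'
#' `mean(1 - SSIM(a, G_B(G_A(a)))) + mean(1 - SSIM(b, G_A(G_B(b))))`, with
#' SSIM evaluated by [ssim_index]. Inputs are expected in `[0, 1]`.
#'
#' @inheritParams cycle_loss
#' @param ssim_params an [ssim_params] object (default: global mode, the
#'   differentiable whole-image statistic used during training)
#' @return value in `[0, 4]`
#' @export
ssim_loss <- function(a_batch, reconstructed_a, b_batch, reconstructed_b,
                      ssim_params = NULL) {
  if (is.null(ssim_params)) ssim_params <- default_global_ssim_params()
  side <- function(xs, ys) {
    xs <- .as_batch(xs); ys <- .as_batch(ys)
    stopifnot(length(xs) == length(ys))
    mean(vapply(seq_along(xs), function(i) {
      1 - ssim_index(.px(xs[[i]]), .px(ys[[i]]), ssim_params)
    }, 1.0))
  }
  side(a_batch, reconstructed_a) + side(b_batch, reconstructed_b)
}

#' Soft saliency mask
#'
#' Per-pixel `sigmoid((x - threshold) * gain)`: a smooth, monotone surrogate
#' of the hard threshold indicator. At the default gain of 100 the mask
#' saturates to {0, 1} within 1e-15 once `|x - threshold| >= 0.4`.
#'
#' @param x array or [image_tile] with intensities in the value range the
#'   threshold refers to
#' @param threshold segmentation threshold
#' @param gain sigmoid gain
#' @return array of mask values in (0, 1), same shape as `x`
#' @export
saliency_mask <- function(x, threshold, gain = 100) {
  x <- .px(x)
  1 / (1 + exp(-(x - threshold) * gain))
}

#' Saliency (content-mask consistency) loss
#'
#' L1 distance between the soft mask of each input and the soft mask of its
#' translation, under the source and target thresholds respectively, averaged
#' per pixel and batch and summed over the two directions.
#'
#' @param a_batch,g_a_outputs domain-A inputs and their A-to-B translations
#' @param b_batch,g_b_outputs domain-B inputs and their B-to-A translations
#' @param config a [loss_config] carrying `threshold_A`, `threshold_B` and
#'   `sigmoid_gain`
#' @return nonnegative scalar
#' @export
saliency_loss <- function(a_batch, g_a_outputs, b_batch, g_b_outputs, config) {
  stopifnot(inherits(config, "loss_config"),
            !is.na(config$threshold_A), !is.na(config$threshold_B))
  side <- function(xs, ys, t_in, t_out) {
    xs <- .as_batch(xs); ys <- .as_batch(ys)
    stopifnot(length(xs) == length(ys))
    mean(vapply(seq_along(xs), function(i) {
      x <- .px(xs[[i]]); y <- .px(ys[[i]])
      if (length(x) != length(y)) stop("shape mismatch between input and translation")
      mean(abs(saliency_mask(x, t_in, config$sigmoid_gain) -
               saliency_mask(y, t_out, config$sigmoid_gain)))
    }, 1.0))
  }
  side(a_batch, g_a_outputs, config$threshold_A, config$threshold_B) +
    side(b_batch, g_b_outputs, config$threshold_B, config$threshold_A)
}

#' Assemble the full objective from its components
#'
#' `total = gan_forward + gan_backward + lambda * cycle + xi * ssim +
#' rho * saliency`; the breakdown is retained for logging.
#'
#' @param gan_forward,gan_backward,cycle,ssim,saliency component values
#' @param config a [loss_config]
#' @return object of class `loss_breakdown` (a named list incl. `total`)
#' @export
total_loss <- function(gan_forward, gan_backward, cycle, ssim, saliency, config) {
  comps <- c(gan_forward = gan_forward, gan_backward = gan_backward,
             cycle = cycle, ssim = ssim, saliency = saliency)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad)) stop("non-finite loss component(s): ", paste(bad, collapse = ", "))
  structure(list(gan_forward = gan_forward, gan_backward = gan_backward,
                 cycle = cycle, ssim = ssim, saliency = saliency,
                 total = gan_forward + gan_backward + config$lambda_cyc * cycle +
                   config$xi_ssim * ssim + config$rho_saliency * saliency),
            class = "loss_breakdown")
}

#' Hard-mask intersection-over-union between an image and its translation
#'
#' Thresholds both images (channel-maximum intensity for multi-channel input,
#' i.e. "any stain present") and reports IoU of the binary masks; the
#' monitoring statistic behind the saliency-constraint ablations.
#'
#' @param x,y arrays or [image_tile]s in `[0, 1]`
#' @param threshold_x,threshold_y hard thresholds
#' @return IoU in `[0, 1]` (1 when both masks are empty)
#' @export
saliency_iou <- function(x, y, threshold_x = 0.5, threshold_y = threshold_x) {
  flat <- function(a) {
    if (length(dim(a)) == 3) {
      a <- if (dim(a)[3] > 1) apply(a, c(1, 2), max) else a[, , 1]
    }
    a
  }
  gx <- flat(.px(x)); gy <- flat(.px(y))
  mx <- gx >= threshold_x; my <- gy >= threshold_y
  u <- sum(mx | my)
  if (u == 0) return(1)
  sum(mx & my) / u
}
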