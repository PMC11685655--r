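# Gradient-weighted class activation mapping over the generator's residual
# blocks: where does the translation "look" when producing its output?

#' Channel-weighted activation map from activations and their gradients
#'
#' Core Grad-CAM arithmetic: per-channel weights are the spatial means of the
#' gradient, the map is the ReLU of the weighted activation sum.
#'
#' @param activations (h, w, c) array
#' @param gradients (h, w, c) array, same shape
#' @return nonnegative (h, w) matrix
#' @export
gradcam_core <- function(activations, gradients) {
  stopifnot(identical(dim(activations), dim(gradients)))
  d <- dim(activations)
  w <- colMeans(matrix(gradients, d[1] * d[2], d[3]))
  m <- matrix(matrix(activations, d[1] * d[2], d[3]) %*% w, d[1], d[2])
  m[m < 0] <- 0
  m
}

#' Grad-CAM heatmap of a generator residual block
#'
#' Runs the generator on `x`, backpropagates a scalar reduction of the output
#' to the chosen residual block, and returns the ReLU'd channel-weighted
#' activation map, bilinearly resized to the input size and max-normalised to
#' 1 when nonzero.
#'
#' @param model_part generator part of a [translation_model] (list with
#'   `params`, `spec`)
#' @param x (H, W, 3) array in `[-1, 1]` or an [image_tile] (converted and
#'   remapped automatically)
#' @param target_layer residual block index in
#'   `[1, spec$n_residual_blocks]`
#' @param target scalar reduction of the generator output driving the
#'   gradients: `"mean"`, `"sum"`, or a numeric weight array of the output's
#'   shape (heatmap of `sum(weights * output)`)
#' @return (H, W) matrix, `>= 0` everywhere, max equal to 1 unless the map is
#'   identically zero
#' @export
gradcam_heatmap <- function(model_part, x, target_layer = 1L, target = "mean") {
  spec <- model_part$spec
  if (target_layer < 1 || target_layer > spec$n_residual_blocks) {
    stop(sprintf("target_layer %d out of range [1, %d]",
                 target_layer, spec$n_residual_blocks))
  }
  if (inherits(x, "image_tile")) x <- tile_to_net(x)
  g <- ad_graph()
  fw <- gen_forward_graph(g, model_part$params, spec, ad_leaf(g, x),
                          record_residuals = TRUE)
  root <- if (is.character(target)) {
    switch(match.arg(target, c("mean", "sum")),
           mean = ad_mean(g, fw$out),
           sum = ad_sum(g, fw$out))
  } else {
    stopifnot(identical(dim(target), dim(fw$out$value)))
    ad_wsum(g, fw$out, target)
  }
  ad_backward(g, root)
  act <- fw$residuals[[target_layer]]
  cam <- gradcam_core(act$value, act$grad)
  d <- dim(x)
  cam <- bilinear_resize(array(cam, dim = c(dim(cam), 1L)), d[1], d[2])[, , 1]
  cam[cam < 0] <- 0
  m <- max(cam)
  if (m > 0) cam <- cam / m
  cam
}
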