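# small shared helpers

clip01 <- function(x) pmin(pmax(x, 0), 1)

# run code under a temporary RNG state so library functions stay
# deterministic without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stable 31-bit sub-seed from a master seed and a stream label
#'
#' Labelled sub-seed derivation keeps independent random streams (scene
#' sampling, weight initialisation, shuffling) stable when unrelated
#' configuration changes.
#'
#' @param seed integer master seed
#' @param label character stream label
#' @return integer seed below 2^31
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% .Machine$integer.max)
}

#' Otsu threshold of a grayscale image
#'
#' Maximises between-class variance over a fixed-bin histogram. Used to pick
#' default saliency thresholds from a sample of training tiles.
#'
#' @param x numeric vector/matrix/array of intensities in `[0, 1]`
#' @param levels number of histogram bins
#' @return threshold in `[0, 1]`
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.vector(x)
  h <- tabulate(pmin(pmax(floor(v * levels) + 1L, 1L), levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, levels)
  bcv[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(bcv)]
}
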