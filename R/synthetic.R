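# Synthetic microscopy scenes: elliptical nuclei (blue plane) and smooth
# actin-like filaments (green plane), rendered at high resolution, mixed into
# an unlabeled intensity image, and degraded by a Gaussian point-spread
# function to the low-resolution domain. Every rendering is a deterministic
# function of the scene description, so downstream stages can be tested with
# exact ground truth and no external data.

#' Sample a reproducible synthetic cell scene
#'
#' Nucleus centres, semi-axes and orientations plus filament control points
#' are drawn from the given ranges under a local RNG stream, so the same seed
#' and parameters always give an identical scene.
#'
#' @param seed integer seed for the scene
#' @param field_size_px side of the square field in pixels
#' @param n_nuclei number of elliptical nuclei
#' @param nucleus_axes_px ranges for the semi-axes, as
#'   `list(a = c(min, max), b = c(min, max))` in pixels (a >= b is enforced
#'   per nucleus)
#' @param n_filaments number of actin-like filaments
#' @param n_control_points control points per filament spline
#' @param filament_width_px stroke width in pixels (>= 1)
#' @param background_level background intensity in `[0, 1]`
#' @param noise_sd additive Gaussian noise s.d. applied to the low-resolution
#'   rendering
#' @param no_overlap if `TRUE`, nuclei are placed so their bounding circles
#'   are pairwise disjoint (rejection sampling)
#' @param max_attempts placement attempts per nucleus before giving up in
#'   `no_overlap` mode
#' @return object of class `scene_spec`
#' @export
sample_scene <- function(seed,
                         field_size_px = 256L,
                         n_nuclei = 6L,
                         nucleus_axes_px = list(a = c(10, 18), b = c(6, 11)),
                         n_filaments = 4L,
                         n_control_points = 4L,
                         filament_width_px = 3,
                         background_level = 0.05,
                         noise_sd = 0.02,
                         no_overlap = FALSE,
                         max_attempts = 200L) {
  stopifnot(field_size_px >= 8, n_nuclei >= 0, n_filaments >= 0,
            filament_width_px >= 1,
            diff(nucleus_axes_px$a) >= 0, diff(nucleus_axes_px$b) >= 0)
  sc <- with_local_seed(seed, {
    a <- if (n_nuclei > 0) stats::runif(n_nuclei, nucleus_axes_px$a[1], nucleus_axes_px$a[2]) else numeric(0)
    b <- if (n_nuclei > 0) stats::runif(n_nuclei, nucleus_axes_px$b[1], nucleus_axes_px$b[2]) else numeric(0)
    sw <- a < b
    tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
    th <- if (n_nuclei > 0) stats::runif(n_nuclei, 0, pi) else numeric(0)
    margin <- if (n_nuclei > 0) a + 2 else 0
    centers <- matrix(0, n_nuclei, 2)
    if (n_nuclei > 0) {
      if (no_overlap) {
        rad <- a + 1   # bounding radius per nucleus
        for (i in seq_len(n_nuclei)) {
          placed <- FALSE
          for (att in seq_len(max_attempts)) {
            cand <- stats::runif(2, margin[i], field_size_px - margin[i])
            ok <- TRUE
            if (i > 1) {
              dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - cand)^2))
              ok <- all(dd >= rad[i] + rad[seq_len(i - 1)])
            }
            if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
          }
          if (!placed) {
            stop(sprintf(paste0("could not place %d non-overlapping nuclei of radius ~%.0f px ",
                                "in a %d px field after %d attempts; reduce the density"),
                         n_nuclei, max(rad), field_size_px, max_attempts))
          }
        }
      } else {
        centers <- cbind(stats::runif(n_nuclei, margin, field_size_px - margin),
                         stats::runif(n_nuclei, margin, field_size_px - margin))
      }
    }
    ctrl <- lapply(seq_len(n_filaments), function(i) {
      cbind(stats::runif(n_control_points, 1, field_size_px),
            stats::runif(n_control_points, 1, field_size_px))
    })
    list(centers = centers, a = a, b = b, theta = th, ctrl = ctrl)
  })
  structure(list(seed = as.integer(seed),
                 field_size_px = as.integer(field_size_px),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_centers = sc$centers,
                 nucleus_a_px = sc$a, nucleus_b_px = sc$b,
                 nucleus_theta = sc$theta,
                 n_filaments = as.integer(n_filaments),
                 filament_control_points = sc$ctrl,
                 filament_width_px = filament_width_px,
                 background_level = background_level,
                 noise_sd = noise_sd),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec seed %d: %d px field, %d nuclei, %d filaments>\n",
              x$seed, x$field_size_px, x$n_nuclei, x$n_filaments))
  invisible(x)
}

# Centripetal-flavoured Catmull-Rom sampling through control points
# (uniform parameterisation; endpoints duplicated), ~2 samples per pixel
.catmull_rom <- function(P, samples_per_seg = 64L) {
  n <- nrow(P)
  if (n < 2) return(P)
  Pp <- rbind(P[1, ], P, P[n, ])
  t <- seq(0, 1, length.out = samples_per_seg)
  out <- NULL
  for (i in seq_len(n - 1)) {
    p0 <- Pp[i, ]; p1 <- Pp[i + 1, ]; p2 <- Pp[i + 2, ]; p3 <- Pp[i + 3, ]
    q <- 0.5 * (outer(rep(1, length(t)), 2 * p1) +
                outer(t, p2 - p0) +
                outer(t^2, 2 * p0 - 5 * p1 + 4 * p2 - p3) +
                outer(t^3, -p0 + 3 * p1 - 3 * p2 + p3))
    out <- rbind(out, q)
  }
  out
}

# rasterise ellipses with a soft edge; full intensity so the half-intensity
# contour coincides with the exact ellipse boundary
.render_nuclei <- function(scene, intensity = 1) {
  n <- scene$field_size_px
  img <- matrix(0, n, n)
  for (i in seq_len(scene$n_nuclei)) {
    cx <- scene$nucleus_centers[i, 1]; cy <- scene$nucleus_centers[i, 2]
    a <- scene$nucleus_a_px[i]; b <- scene$nucleus_b_px[i]
    th <- scene$nucleus_theta[i]
    r <- a + 2
    rows <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
    dy <- rows - cy
    dx <- cols - cx
    # rotated normalized radius on the local grid (rows = y, cols = x)
    X <- outer(dy * 0, dx, "+")   # dx broadcast across rows
    Y <- outer(dy, dx * 0, "+")
    u <- (X * cos(th) + Y * sin(th)) / a
    v <- (-X * sin(th) + Y * cos(th)) / b
    s <- sqrt(u^2 + v^2)
    # soft edge over ~1 px at the boundary (feather width relative to b)
    w <- 1 / b
    val <- intensity * clip01((1 + w - s) / (2 * w))
    img[rows, cols] <- pmax(img[rows, cols], val)
  }
  img
}

# rasterise filaments as stamped disks along the sampled spline, then feather
.render_filaments <- function(scene, intensity = 0.7) {
  n <- scene$field_size_px
  img <- matrix(0, n, n)
  rad <- scene$filament_width_px / 2
  ir <- ceiling(rad)
  off <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  off <- off[off$dr^2 + off$dc^2 <= (rad + 0.25)^2, ]
  for (f in scene$filament_control_points) {
    pts <- .catmull_rom(f)
    # resample evenly (~0.7 px spacing) along arc length
    seg <- sqrt(rowSums(diff(pts)^2))
    cs <- c(0, cumsum(seg))
    if (max(cs) > 0) {
      ss <- seq(0, max(cs), by = 0.7)
      pts <- cbind(stats::approx(cs, pts[, 1], ss, ties = "ordered")$y,
                   stats::approx(cs, pts[, 2], ss, ties = "ordered")$y)
    }
    pr <- round(pts[, 2]); pc <- round(pts[, 1])   # (x, y) -> (col, row)
    for (i in seq_len(nrow(pts))) {
      rr <- pr[i] + off$dr; cc <- pc[i] + off$dc
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      img[cbind(rr[ok], cc[ok])] <- intensity
    }
  }
  if (any(img > 0)) img <- gaussian_blur(img, sigma = 1) * 1.0
  clip01(img)
}

#' Convert a PSF full width at half maximum to a Gaussian sigma in pixels
#'
#' `sigma_px = fwhm_um / (2 * sqrt(2 * log(2)) * pixel_size_um)`.
#'
#' @param psf_fwhm_um full width at half maximum in micrometres
#' @param pixel_size_um micrometres per pixel
#' @return sigma in pixels
#' @export
fwhm_to_sigma_px <- function(psf_fwhm_um, pixel_size_um) {
  stopifnot(psf_fwhm_um > 0, pixel_size_um > 0)
  psf_fwhm_um / (2 * sqrt(2 * log(2)) * pixel_size_um)
}

#' Separable Gaussian blur with reflective boundary handling
#'
#' Reflective (whole-sample symmetric) padding makes the blur conserve total
#' intensity exactly for a normalised kernel.
#'
#' @param x matrix or (H, W, C) array
#' @param sigma Gaussian sigma in pixels
#' @param radius kernel half-width (default `ceiling(4 * sigma)`)
#' @return blurred image of the same shape
#' @export
gaussian_blur <- function(x, sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  blur1 <- function(m) {
    n <- nrow(m)
    r <- min(radius, n - 1L)   # symmetric padding cannot exceed the image
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    # symmetric padding: ..., x[2], x[1] | x[1..n] | x[n], x[n-1], ...
    pad_idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    P <- m[pad_idx, , drop = FALSE]
    # banded convolution as a dense matmul (n + 2r -> n)
    K <- matrix(0, n, n + 2 * r)
    for (t in seq_along(k)) K[cbind(seq_len(n), seq_len(n) + t - 1)] <- k[t]
    K %*% P
  }
  one <- function(m) t(blur1(t(blur1(m))))
  if (is.matrix(x)) return(one(x))
  d <- dim(x)
  out <- x
  for (ch in seq_len(d[3])) out[, , ch] <- one(x[, , ch])
  out
}

#' Render the three coupled views of a scene
#'
#' Produces the high-resolution stained image (blue = nuclei, green =
#' F-actin), its unlabeled grayscale rendering (a nonnegative channel mixture
#' plus background), and the low-resolution unlabeled image (Gaussian PSF
#' blur of the unlabeled image plus additive noise, clipped to `[0, 1]`).
#'
#' @param scene a `scene_spec` from [sample_scene]
#' @param psf_fwhm_um PSF full width at half maximum (default 6.6 um, the
#'   lateral resolution of the low-resolution modality)
#' @param pixel_size_um micrometres per pixel (default 0.31)
#' @param mixture weights `c(blue, green)` of the unlabeled channel mixture
#' @return list of class `rendered_triplet` with elements `hr_stained`,
#'   `hr_unlabeled`, `lr_unlabeled` (all [image_tile]) and `scene`
#' @export
render_triplet <- function(scene, psf_fwhm_um = 6.6, pixel_size_um = 0.31,
                           mixture = c(blue = 0.6, green = 0.4)) {
  if (psf_fwhm_um <= 0) stop("psf_fwhm_um must be > 0")
  if (psf_fwhm_um <= pixel_size_um) stop("psf_fwhm_um must exceed pixel_size_um")
  blue <- .render_nuclei(scene)
  green <- .render_filaments(scene)
  n <- scene$field_size_px
  hr_stained <- image_tile(array(c(blue, green), dim = c(n, n, 2L)),
                           "stain2", pixel_size_um = pixel_size_um)
  unl <- clip01(mixture[[1]] * blue + mixture[[2]] * green + scene$background_level)
  hr_unlabeled <- image_tile(unl, "gray1", pixel_size_um = pixel_size_um)
  sig <- fwhm_to_sigma_px(psf_fwhm_um, pixel_size_um)
  lr <- gaussian_blur(unl, sig)
  if (scene$noise_sd > 0) {
    noise <- with_local_seed(derive_seed(scene$seed, "lr_noise"),
                             matrix(stats::rnorm(n * n, 0, scene$noise_sd), n, n))
    lr <- lr + noise
  }
  lr <- clip01(lr)
  structure(list(hr_stained = hr_stained,
                 hr_unlabeled = hr_unlabeled,
                 lr_unlabeled = image_tile(lr, "gray1", pixel_size_um = pixel_size_um),
                 scene = scene),
            class = "rendered_triplet")
}

#' Generate unpaired (or paired) synthetic two-domain datasets
#'
#' Domain A holds low-resolution unlabeled tiles, domain B high-resolution
#' stained tiles. In unpaired mode (the training condition) the two domains
#' are rendered from disjoint scene seeds; in paired mode each A tile is
#' linked to its ground-truth B tile through the returned pairing index
#' (evaluation only — training never consults it).
#'
#' @param n_scenes scenes per domain
#' @param seed master seed
#' @param paired logical
#' @param field_size_px field side in pixels
#' @param scene_params extra arguments passed to [sample_scene]
#' @param psf_fwhm_um,pixel_size_um,mixture rendering parameters, see
#'   [render_triplet]
#' @return list with `A`, `B` ([domain_dataset]) and `pairing` (integer
#'   vector mapping A index to B index, or `NULL`)
#' @export
generate_dataset <- function(n_scenes, seed, paired = FALSE,
                             field_size_px = 256L, scene_params = list(),
                             psf_fwhm_um = 6.6, pixel_size_um = 0.31,
                             mixture = c(blue = 0.6, green = 0.4)) {
  stopifnot(n_scenes >= 1)
  mk <- function(s) {
    do.call(sample_scene, c(list(seed = s, field_size_px = field_size_px),
                            scene_params))
  }
  seeds_A <- vapply(seq_len(n_scenes), function(i) derive_seed(seed, paste0("sceneA", i)), 1L)
  seeds_B <- if (paired) seeds_A
             else vapply(seq_len(n_scenes), function(i) derive_seed(seed, paste0("sceneB", i)), 1L)
  tiles_A <- vector("list", n_scenes)
  tiles_B <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    ta <- render_triplet(mk(seeds_A[i]), psf_fwhm_um, pixel_size_um, mixture)
    tiles_A[[i]] <- ta$lr_unlabeled
    tb <- if (paired) ta else render_triplet(mk(seeds_B[i]), psf_fwhm_um, pixel_size_um, mixture)
    tiles_B[[i]] <- tb$hr_stained
  }
  list(A = domain_dataset(tiles_A, "A", paste0("sceneA", seeds_A)),
       B = domain_dataset(tiles_B, "B", paste0("sceneB", seeds_B)),
       pairing = if (paired) seq_len(n_scenes) else NULL)
}
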