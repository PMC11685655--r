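# Image containers, reading/writing, tiling, augmentation, normalisation and
# cross-validation fold construction for the two unpaired domains.

#' Construct an image tile
#'
#' The atom of both image domains: a 2-D image stored as an (H, W, C) array
#' with channel semantics, a value range and a physical pixel size.
#'
#' @param pixels numeric matrix (H x W) or array (H x W x C)
#' @param channels one of `"gray1"` (single intensity plane), `"rgb3"`
#'   (red/green/blue) or `"stain2"` (two fluorescence planes, blue = nuclei,
#'   green = F-actin)
#' @param value_range closed interval the intensities live in
#' @param pixel_size_um micrometres per pixel
#' @return object of class `image_tile`
#' @export
image_tile <- function(pixels, channels = c("gray1", "rgb3", "stain2"),
                       value_range = c(0, 1), pixel_size_um = 0.31) {
  channels <- match.arg(channels)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  nc <- dim(pixels)[3]
  want <- c(gray1 = 1L, rgb3 = 3L, stain2 = 2L)[[channels]]
  if (nc != want) {
    stop(sprintf("channel layout '%s' needs %d plane(s), got %d", channels, want, nc))
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (any(pixels < value_range[1] - 1e-9) || any(pixels > value_range[2] + 1e-9)) {
    stop("pixel intensities fall outside value_range")
  }
  structure(list(pixels = pixels, channels = channels,
                 value_range = as.numeric(value_range),
                 pixel_size_um = pixel_size_um),
            class = "image_tile")
}

#' @export
print.image_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_tile %dx%d %s, range [%g, %g], %g um/px>\n",
              d[1], d[2], x$channels, x$value_range[1], x$value_range[2],
              x$pixel_size_um))
  invisible(x)
}

#' @export
dim.image_tile <- function(x) dim(x$pixels)

#' Bundle tiles into a domain dataset
#'
#' @param tiles list of [image_tile] sharing shape and channel layout
#' @param domain `"A"` (source, low-resolution label-free) or `"B"` (target,
#'   high-resolution stained)
#' @param slide_ids character vector, one whole-slide identifier per tile
#' @return object of class `domain_dataset`
#' @export
domain_dataset <- function(tiles, domain = c("A", "B"), slide_ids = NULL) {
  domain <- match.arg(domain)
  stopifnot(length(tiles) > 0)
  d0 <- dim(tiles[[1]]$pixels); ch0 <- tiles[[1]]$channels
  for (t in tiles) {
    if (!identical(dim(t$pixels), d0) || !identical(t$channels, ch0)) {
      stop("all tiles in a domain_dataset must share shape and channel layout")
    }
  }
  if (is.null(slide_ids)) slide_ids <- rep("slide1", length(tiles))
  stopifnot(length(slide_ids) == length(tiles))
  structure(list(tiles = tiles, domain = domain,
                 slide_ids = as.character(slide_ids)),
            class = "domain_dataset")
}

#' @export
length.domain_dataset <- function(x) length(x$tiles)

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset %s: %d tiles from %d slide(s), %s>\n",
              x$domain, length(x$tiles), length(unique(x$slide_ids)),
              x$tiles[[1]]$channels))
  invisible(x)
}

## ---- reading / writing ----

#' Read an image file into an [image_tile]
#'
#' TIFF (preferred; 16-bit preserved by scaling with the dtype maximum) and
#' PNG are supported. Three-channel files are imported as `rgb3` unless
#' `channels = "stain2"`, in which case the blue and green planes are taken
#' and the red plane dropped.
#'
#' @param path file path (.tif/.tiff/.png)
#' @inheritParams image_tile
#' @return an [image_tile] with `value_range` `[0, 1]`
#' @export
read_image <- function(path, channels = NULL, pixel_size_um = 0.31) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)                      # already scaled to [0,1]
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package not available")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (is.matrix(a)) {
    image_tile(a, channels %||% "gray1", pixel_size_um = pixel_size_um)
  } else if (identical(channels, "stain2")) {
    image_tile(array(c(a[, , 3], a[, , 2]), dim = c(dim(a)[1:2], 2L)),
               "stain2", pixel_size_um = pixel_size_um)
  } else if (dim(a)[3] >= 3) {
    image_tile(a[, , 1:3], channels %||% "rgb3", pixel_size_um = pixel_size_um)
  } else stop("unexpected channel count in ", path)
}

#' Write an [image_tile] to TIFF or PNG
#'
#' Stained (`stain2`) tiles are exported as RGB with the blue plane in the B
#' position, green in G, and R zeroed.
#'
#' @param tile an [image_tile]
#' @param path output path (.tif/.tiff/.png)
#' @param bits bit depth for TIFF output
#' @export
write_image <- function(tile, path, bits = 16L) {
  px <- tile$pixels
  rng <- tile$value_range
  px <- (px - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  a <- switch(tile$channels,
    gray1  = px[, , 1],
    rgb3   = px,
    stain2 = {
      d <- dim(px)
      array(c(matrix(0, d[1], d[2]), px[, , 2], px[, , 1]), dim = c(d[1], d[2], 3L))
    })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package not available")
    png::writePNG(a, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

## ---- tiling ----

#' Cut a whole-slide image into square tiles
#'
#' Deterministic grid tiling in row-major order (left to right within a tile
#' row, tile rows top to bottom). A seeded random-offset mode jitters the grid
#' origin for training-set harvesting.
#'
#' @param image an [image_tile]
#' @param tile_size tile side in pixels
#' @param stride grid step in pixels; `stride < tile_size` gives overlap
#' @param random_offset jitter the grid origin uniformly within the stride
#' @param seed seed for the jitter (required when `random_offset`)
#' @return list of [image_tile]; empty (with a warning) if the image is
#'   smaller than `tile_size` in either dimension
#' @export
tile_image <- function(image, tile_size, stride = tile_size,
                       random_offset = FALSE, seed = NULL) {
  stopifnot(tile_size >= 1, stride >= 1)
  d <- dim(image$pixels)
  if (d[1] < tile_size || d[2] < tile_size) {
    warning(sprintf("image (%dx%d) smaller than tile_size %d; returning no tiles",
                    d[1], d[2], tile_size))
    return(list())
  }
  off <- c(0L, 0L)
  if (random_offset) {
    stopifnot(!is.null(seed))
    off <- with_local_seed(seed, sample.int(stride, 2L) - 1L)
    off <- pmin(off, c(d[1], d[2]) - tile_size)
  }
  n_r <- (d[1] - off[1] - tile_size) %/% stride + 1L
  n_c <- (d[2] - off[2] - tile_size) %/% stride + 1L
  tiles <- vector("list", n_r * n_c)
  k <- 0L
  for (i in seq_len(n_r)) {
    r0 <- off[1] + (i - 1L) * stride
    for (j in seq_len(n_c)) {
      c0 <- off[2] + (j - 1L) * stride
      k <- k + 1L
      tiles[[k]] <- image_tile(
        image$pixels[r0 + seq_len(tile_size), c0 + seq_len(tile_size), , drop = FALSE],
        image$channels, image$value_range, image$pixel_size_um)
    }
  }
  tiles
}

#' Reassemble non-overlapping tiles into one image
#'
#' Inverse of [tile_image] at `stride = tile_size` on an exactly divisible
#' image; tiles must be in row-major order.
#'
#' @param tiles list of square [image_tile]s of equal size
#' @param n_tile_rows,n_tile_cols grid shape
#' @return an [image_tile]
#' @export
stitch_tiles <- function(tiles, n_tile_rows, n_tile_cols) {
  stopifnot(length(tiles) == n_tile_rows * n_tile_cols)
  ts <- dim(tiles[[1]]$pixels)[1]
  nc <- dim(tiles[[1]]$pixels)[3]
  out <- array(0, dim = c(n_tile_rows * ts, n_tile_cols * ts, nc))
  k <- 0L
  for (i in seq_len(n_tile_rows)) for (j in seq_len(n_tile_cols)) {
    k <- k + 1L
    out[(i - 1L) * ts + seq_len(ts), (j - 1L) * ts + seq_len(ts), ] <-
      tiles[[k]]$pixels
  }
  image_tile(out, tiles[[1]]$channels, tiles[[1]]$value_range,
             tiles[[1]]$pixel_size_um)
}

## ---- augmentation ----

.aug_one <- function(px, op) {
  d <- dim(px)
  switch(op,
    hflip  = px[, d[2]:1, , drop = FALSE],
    vflip  = px[d[1]:1, , , drop = FALSE],
    rot90  = aperm(px, c(2, 1, 3))[d[2]:1, , , drop = FALSE],
    rot180 = px[d[1]:1, d[2]:1, , drop = FALSE],
    rot270 = aperm(px, c(2, 1, 3))[, d[1]:1, , drop = FALSE],
    stop("unknown augmentation op: ", op))
}

#' Augment tiles by exact dihedral transforms
#'
#' Returns the original tiles followed by each requested transform of each
#' tile. All transforms are pixel permutations (no interpolation), so they
#' are exactly invertible.
#'
#' @param tiles non-empty list of [image_tile]
#' @param ops subset of `c("hflip", "vflip", "rot90", "rot180", "rot270")`
#' @return list of [image_tile] of length `length(tiles) * (1 + length(ops))`
#' @export
augment_tiles <- function(tiles, ops = c("hflip", "vflip", "rot90", "rot180", "rot270")) {
  stopifnot(length(tiles) > 0)
  ops <- match.arg(ops, several.ok = TRUE)
  d <- dim(tiles[[1]]$pixels)
  if (d[1] != d[2] && any(ops %in% c("rot90", "rot270"))) {
    stop("rot90/rot270 on non-square tiles would change the tile shape")
  }
  out <- tiles
  for (op in ops) {
    out <- c(out, lapply(tiles, function(t) {
      image_tile(.aug_one(t$pixels, op), t$channels, t$value_range, t$pixel_size_um)
    }))
  }
  out
}

## ---- normalisation ----

#' Percentile normalisation to [0, 1]
#'
#' Linearly maps the `lo_percentile`/`hi_percentile` intensity quantiles to
#' 0/1 and clips. A constant image has no dynamic range; it is returned as
#' all zeros with a warning.
#'
#' @param image an [image_tile]
#' @param lo_percentile,hi_percentile quantile fractions, `0 <= lo < hi <= 1`
#' @param median_filter apply a 3x3 median pre-filter (noise suppression;
#'   off by default)
#' @return an [image_tile] with `value_range` `[0, 1]`
#' @export
normalize_image <- function(image, lo_percentile = 0, hi_percentile = 1,
                            median_filter = FALSE) {
  stopifnot(lo_percentile >= 0, hi_percentile <= 1, lo_percentile < hi_percentile)
  px <- image$pixels
  if (median_filter) px <- median_filter3(px)
  q <- stats::quantile(px, c(lo_percentile, hi_percentile), names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps) {
    warning("constant image: zero dynamic range, returning all-zeros tile")
    px[] <- 0
  } else {
    px <- clip01((px - q[1]) / (q[2] - q[1]))
  }
  image_tile(px, image$channels, c(0, 1), image$pixel_size_um)
}

#' 3x3 median filter (edge-replicated), per channel
#' @param px (H, W, C) array or matrix
#' @return filtered array of the same shape
#' @export
median_filter3 <- function(px) {
  m <- is.matrix(px)
  if (m) px <- array(px, dim = c(dim(px), 1L))
  d <- dim(px)
  out <- px
  for (ch in seq_len(d[3])) {
    sl <- px[, , ch]
    # gather the 9 edge-replicated neighbours as columns
    idx_r <- function(s) pmin(pmax(seq_len(d[1]) + s, 1L), d[1])
    idx_c <- function(s) pmin(pmax(seq_len(d[2]) + s, 1L), d[2])
    stack <- vapply(1:9, function(k) {
      sr <- ((k - 1) %% 3) - 1; sc <- ((k - 1) %/% 3) - 1
      as.vector(sl[idx_r(sr), idx_c(sc)])
    }, numeric(d[1] * d[2]))
    out[, , ch] <- matrix(apply(stack, 1, stats::median), d[1], d[2])
  }
  if (m) out[, , 1] else out
}

## ---- cross-validation folds ----

#' Build k-fold cross-validation splits over whole slides
#'
#' Slides are assigned to validation folds round-robin in input order, so the
#' folds are a deterministic partition: validation sets are disjoint and
#' cover all slides exactly once. For 4 slides and `k = 4` every fold trains
#' on 3 slides and validates on 1.
#'
#' @param slide_ids character vector of slide identifiers (ordered)
#' @param k number of folds, `2 <= k <= length(slide_ids)`
#' @return list of fold splits, each `list(fold_index, train_slide_ids,
#'   val_slide_ids)`
#' @export
make_cv_folds <- function(slide_ids, k) {
  slide_ids <- as.character(slide_ids)
  n <- length(slide_ids)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop(sprintf("k = %d folds but only %d slides", k, n))
  if (anyDuplicated(slide_ids)) stop("slide_ids must be unique")
  fold_of <- ((seq_len(n) - 1L) %% k) + 1L
  lapply(seq_len(k), function(i) {
    list(fold_index = i,
         train_slide_ids = slide_ids[fold_of != i],
         val_slide_ids = slide_ids[fold_of == i])
  })
}

## ---- dataset manifest ----

#' Write a dataset manifest (file path, domain label, slide id) as JSON
#' @param df data.frame with columns `path`, `domain`, `slide_id`
#' @param path output JSON path
#' @export
write_manifest <- function(df, path) {
  stopifnot(all(c("path", "domain", "slide_id") %in% names(df)))
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset manifest written by [write_manifest]
#' @param path JSON path
#' @return data.frame with columns `path`, `domain`, `slide_id`
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
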