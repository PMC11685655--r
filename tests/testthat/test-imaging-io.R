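test_that("image_tile validates channel layout, range and pixel size", {
  expect_s3_class(rand_tile(8, 8, 1), "image_tile")
  expect_error(image_tile(array(0, c(4, 4, 2)), "gray1"), "plane")
  expect_error(image_tile(array(2, c(4, 4, 1)), "gray1"), "value_range")
  expect_error(image_tile(array(0, c(4, 4, 1)), "gray1", pixel_size_um = 0),
               "pixel_size_um")
})

test_that("grid tiling count matches the closed-form formula", {
  img <- rand_tile(512, 512, 1, seed = 1)
  expect_length(tile_image(img, 256, 256), 4)
  expect_length(tile_image(img, 256, 128), 9)
  # general formula on an asymmetric case
  img2 <- rand_tile(300, 200, 1, seed = 2)
  ts <- 64; st <- 48
  want <- (((300 - ts) %/% st) + 1) * (((200 - ts) %/% st) + 1)
  expect_length(tile_image(img2, ts, st), want)
})

test_that("tiling an undersized image warns and returns no tiles", {
  img <- rand_tile(200, 200, 1, seed = 3)
  expect_warning(tiles <- tile_image(img, 256, 256), "smaller than tile_size")
  expect_length(tiles, 0)
})

test_that("tiles inherit pixel size and value range; stitching inverts tiling", {
  img <- image_tile(array(runif(128 * 128 * 2), c(128, 128, 2)), "stain2",
                    pixel_size_um = 0.62)
  tiles <- tile_image(img, 32, 32)
  expect_equal(tiles[[1]]$pixel_size_um, 0.62)
  expect_equal(tiles[[1]]$value_range, img$value_range)
  back <- stitch_tiles(tiles, 4, 4)
  expect_identical(back$pixels, img$pixels)
})

test_that("augmentation multiplies tiles and transforms are exact permutations", {
  tiles <- lapply(1:10, function(i) rand_tile(16, 16, 1, seed = i))
  out <- augment_tiles(tiles)
  expect_length(out, 60)
  const <- image_tile(array(0.5, c(8, 8, 1)), "gray1")
  for (op in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    aug <- augment_tiles(list(const), op)
    expect_identical(aug[[2]]$pixels, const$pixels)
  }
})

test_that("augmentations satisfy the dihedral group relations", {
  t0 <- rand_tile(12, 12, 3, seed = 9)
  ap <- function(x, op) augment_tiles(list(x), op)[[2]]
  expect_identical(ap(ap(t0, "hflip"), "hflip")$pixels, t0$pixels)   # involution
  expect_identical(ap(ap(t0, "vflip"), "vflip")$pixels, t0$pixels)
  expect_identical(ap(ap(t0, "rot180"), "rot180")$pixels, t0$pixels)
  expect_identical(ap(ap(t0, "rot90"), "rot270")$pixels, t0$pixels)  # inverses
  r4 <- Reduce(function(x, .) ap(x, "rot90"), 1:4, accumulate = FALSE, init = t0)
  expect_identical(r4$pixels, t0$pixels)                             # order 4
  expect_identical(ap(ap(t0, "rot90"), "rot90")$pixels, ap(t0, "rot180")$pixels)
  expect_identical(ap(ap(t0, "hflip"), "vflip")$pixels, ap(t0, "rot180")$pixels)
})

test_that("rotating a non-square tile by 90 degrees is rejected", {
  t0 <- image_tile(array(0.1, c(8, 16, 1)), "gray1")
  expect_error(augment_tiles(list(t0), "rot90"), "non-square")
  expect_length(augment_tiles(list(t0), c("hflip", "vflip", "rot180")), 4)
})

test_that("percentile normalisation maps quantiles to [0, 1] endpoints", {
  px <- array(seq(10, 200, length.out = 64), c(8, 8, 1))
  t0 <- image_tile(px, "gray1", value_range = c(0, 255))
  out <- normalize_image(t0, 0, 1)
  expect_equal(min(out$pixels), 0)
  expect_equal(max(out$pixels), 1)
  # idempotence on an already-normalised image
  again <- normalize_image(out, 0, 1)
  expect_lt(max(abs(again$pixels - out$pixels)), 1e-12)
})

test_that("interior percentile normalisation matches a per-pixel affine oracle", {
  vals <- seq(0, 250, by = 50)
  px <- array(rep(vals, length.out = 36), c(6, 6, 1))
  t0 <- image_tile(px, "gray1", value_range = c(0, 255))
  out <- normalize_image(t0, 0.1, 0.9)
  q <- quantile(px, c(0.1, 0.9), names = FALSE)
  oracle <- pmin(pmax((px - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(out$pixels, oracle, tolerance = 1e-12)
  expect_true(all(out$pixels[px <= q[1]] == 0))
  expect_true(all(out$pixels[px >= q[2]] == 1))
})

test_that("constant image normalisation warns and returns zeros", {
  t0 <- image_tile(array(0.7, c(8, 8, 1)), "gray1")
  expect_warning(out <- normalize_image(t0), "constant")
  expect_true(all(out$pixels == 0))
})

test_that("cross-validation folds form the 3-train/1-val slide partition", {
  folds <- make_cv_folds(c("s1", "s2", "s3", "s4"), 4)
  expect_length(folds, 4)
  for (f in folds) {
    expect_length(f$val_slide_ids, 1)
    expect_length(f$train_slide_ids, 3)
    expect_length(intersect(f$train_slide_ids, f$val_slide_ids), 0)
  }
  vals <- unlist(lapply(folds, `[[`, "val_slide_ids"))
  expect_setequal(vals, c("s1", "s2", "s3", "s4"))
  expect_false(anyDuplicated(vals) > 0)
})

test_that("fold construction partitions any slide set for any valid k", {
  for (n in c(5, 7, 12)) for (k in c(2, 3, 5)) {
    ids <- paste0("slide", seq_len(n))
    folds <- make_cv_folds(ids, k)
    vals <- unlist(lapply(folds, `[[`, "val_slide_ids"))
    expect_setequal(vals, ids)
    expect_length(vals, n)   # no repeats
    for (f in folds) {
      expect_setequal(union(f$train_slide_ids, f$val_slide_ids), ids)
    }
  }
  expect_error(make_cv_folds(c("a", "b"), 3), "folds")
})

test_that("TIFF round trip preserves tiles and stained export zeroes red", {
  dir <- withr::local_tempdir()
  t0 <- rand_tile(16, 16, 2, seed = 5)
  p <- file.path(dir, "t.tif")
  write_image(t0, p)
  back <- read_image(p, channels = "stain2")
  expect_equal(back$pixels, t0$pixels, tolerance = 2e-5)  # 16-bit quantisation
  rgb <- read_image(p)     # raw rgb3 view
  expect_true(all(rgb$pixels[, , 1] == 0))
  expect_equal(rgb$pixels[, , 2], t0$pixels[, , 2], tolerance = 2e-5)
  expect_equal(rgb$pixels[, , 3], t0$pixels[, , 1], tolerance = 2e-5)
})

test_that("manifest writes and reads the path/domain/slide table", {
  dir <- withr::local_tempdir()
  df <- data.frame(path = c("a.tif", "b.tif"), domain = c("A", "B"),
                   slide_id = c("s1", "s1"))
  p <- file.path(dir, "manifest.json")
  write_manifest(df, p)
  back <- read_manifest(p)
  expect_equal(back$path, df$path)
  expect_equal(back$domain, df$domain)
  expect_equal(back$slide_id, df$slide_id)
})
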