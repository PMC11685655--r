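# Morphometric readouts from stained (real or virtually stained) tiles:
# nucleus count / area / aspect ratio from the blue (Hoechst-analog) plane,
# fibroblast area from the green (FITC-phalloidin-analog) plane.

#' Split a stained tile into its blue and green planes
#'
#' @param stained an [image_tile] with `stain2` or `rgb3` channels; for
#'   `rgb3` the red plane is ignored (with a message)
#' @return list of two `gray1` [image_tile]s named `blue` and `green`
#' @export
split_channels <- function(stained) {
  stopifnot(inherits(stained, "image_tile"))
  px <- stained$pixels
  gr <- function(m) image_tile(m, "gray1", stained$value_range, stained$pixel_size_um)
  if (stained$channels == "stain2") {
    list(blue = gr(px[, , 1]), green = gr(px[, , 2]))
  } else if (stained$channels == "rgb3") {
    message("rgb3 input: red plane ignored for morphometry")
    list(blue = gr(px[, , 3]), green = gr(px[, , 2]))
  } else {
    stop("split_channels needs a stain2 or rgb3 tile, got gray1")
  }
}

#' Recombine blue and green planes into a stained tile
#' @param blue,green `gray1` [image_tile]s of identical shape
#' @return a `stain2` [image_tile]
#' @export
merge_channels <- function(blue, green) {
  d <- dim(blue$pixels)
  stopifnot(identical(d, dim(green$pixels)))
  image_tile(array(c(blue$pixels[, , 1], green$pixels[, , 1]),
                   dim = c(d[1], d[2], 2L)),
             "stain2", blue$value_range, blue$pixel_size_um)
}

#' Label 8-connected foreground components
#'
#' Connected-component labelling with 8-connectivity (edge- and
#' corner-adjacent pixels join), built on graph components.
#'
#' @param mask logical matrix
#' @return integer matrix of labels (0 = background)
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(fg) == 0) return(lab)
  id <- integer(H * W)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% H) + 1L
  cc <- ((fg - 1L) %/% H) + 1L
  edges <- NULL
  for (s in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      edges <- rbind(edges, cbind(id[fg[ok][hit]], id[nb[hit]]))
    }
  }
  gph <- igraph::make_graph(edges = t(edges %||% matrix(0L, 0, 2)), n = length(fg),
                            directed = FALSE)
  memb <- igraph::components(gph)$membership
  lab[fg] <- as.integer(memb)
  lab
}

#' Nucleus morphometry from the blue plane
#'
#' Hard-thresholds the plane, removes components below `min_area_px`, labels
#' 8-connected components, and reports per nucleus the area (pixel count
#' scaled by the pixel area) and the aspect ratio of the equivalent
#' second-moment ellipse (major/minor, clamped to >= 1).
#'
#' @param blue a `gray1` [image_tile] (or matrix) with intensities in `[0, 1]`
#' @param threshold hard segmentation threshold, or `"otsu"`
#' @param min_area_px minimum component area in pixels (speckle suppression)
#' @param pixel_size_um micrometres per pixel (taken from the tile if given)
#' @return list with `n_nuclei`, `areas_um2`, `aspect_ratios`, `centroids`
#' @export
nucleus_features <- function(blue, threshold = 0.5, min_area_px = 20L,
                             pixel_size_um = NULL) {
  if (inherits(blue, "image_tile")) {
    if (is.null(pixel_size_um)) pixel_size_um <- blue$pixel_size_um
    blue <- blue$pixels[, , 1]
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 0.31
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(blue)
  lab <- label_components(blue >= threshold)
  n <- max(lab)
  if (n == 0) {
    return(list(n_nuclei = 0L, areas_um2 = numeric(0),
                aspect_ratios = numeric(0), centroids = matrix(0, 0, 2)))
  }
  H <- nrow(lab)
  idx <- which(lab > 0)
  lv <- lab[idx]
  rr <- ((idx - 1L) %% H) + 1L
  cv <- ((idx - 1L) %/% H) + 1L
  sizes <- tabulate(lv, n)
  keep <- which(sizes >= min_area_px)
  areas <- numeric(0); aspects <- numeric(0); cents <- NULL
  for (comp in keep) {
    sel <- lv == comp
    y <- rr[sel]; x <- cv[sel]
    my <- mean(y); mx <- mean(x)
    # central second moments of the pixel set
    muyy <- mean((y - my)^2) + 1 / 12   # + pixel self-moment
    muxx <- mean((x - mx)^2) + 1 / 12
    muxy <- mean((x - mx) * (y - my))
    ev <- eigen(matrix(c(muyy, muxy, muxy, muxx), 2, 2), symmetric = TRUE)$values
    ev <- pmax(ev, 1e-12)
    aspects <- c(aspects, max(1, sqrt(ev[1] / ev[2])))
    areas <- c(areas, sizes[comp] * pixel_size_um^2)
    cents <- rbind(cents, c(my, mx))
  }
  list(n_nuclei = length(keep), areas_um2 = areas, aspect_ratios = aspects,
       centroids = cents %||% matrix(0, 0, 2))
}

#' Fibroblast (F-actin) area from the green plane
#'
#' Number of pixels at or above the threshold, scaled by the pixel area.
#'
#' @param green a `gray1` [image_tile] (or matrix) in `[0, 1]`
#' @param threshold hard threshold
#' @param pixel_size_um micrometres per pixel (taken from the tile if given)
#' @return area in square micrometres
#' @export
fibroblast_area <- function(green, threshold = 0.5, pixel_size_um = NULL) {
  if (inherits(green, "image_tile")) {
    if (is.null(pixel_size_um)) pixel_size_um <- green$pixel_size_um
    green <- green$pixels[, , 1]
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 0.31
  sum(green >= threshold) * pixel_size_um^2
}

#' Full morphometric record for one stained tile
#'
#' @param stained a `stain2` (or `rgb3`) [image_tile]
#' @param tile_id identifier stored in the record
#' @param nucleus_threshold,fibroblast_threshold hard thresholds
#' @param min_area_px minimum nucleus area in pixels
#' @return one-row data.frame: `tile_id`, `n_nuclei`, mean nucleus area and
#'   aspect ratio, `fibroblast_area_um2`, `pixel_size_um`; per-nucleus lists
#'   attached as attribute `"per_nucleus"`
#' @export
cell_features <- function(stained, tile_id = "tile1", nucleus_threshold = 0.5,
                          fibroblast_threshold = 0.5, min_area_px = 20L) {
  ch <- split_channels(stained)
  nf <- nucleus_features(ch$blue, nucleus_threshold, min_area_px)
  fa <- fibroblast_area(ch$green, fibroblast_threshold)
  out <- data.frame(tile_id = tile_id,
                    n_nuclei = nf$n_nuclei,
                    mean_nucleus_area_um2 = if (nf$n_nuclei) mean(nf$areas_um2) else NA_real_,
                    mean_nucleus_aspect = if (nf$n_nuclei) mean(nf$aspect_ratios) else NA_real_,
                    fibroblast_area_um2 = fa,
                    pixel_size_um = stained$pixel_size_um)
  attr(out, "per_nucleus") <- nf
  out
}
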