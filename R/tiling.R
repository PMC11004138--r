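## Slide raster handling: tissue masking, tiling, augmentation.

#' Create a slide image object
#'
#' Wraps an RGB raster and its physical resolution.  Pixels are stored as
#' an `H x W x 3` array of intensities in `[0, 1]`; `mpp` is the microns
#' per pixel at full resolution (0.5 corresponds to a 20x scan).
#'
#' @param pixels numeric `H x W x 3` array in `[0, 1]`.
#' @param slide_id character identifier.
#' @param mpp microns per pixel, positive.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, slide_id, mpp = 0.5) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("slide '%s': pixels must be an H x W x 3 color array", slide_id)
  if (!is.numeric(mpp) || mpp <= 0) stopf("mpp must be > 0")
  structure(
    list(slide_id = as.character(slide_id), pixels = pixels, mpp = mpp,
         width_px = dim(pixels)[2], height_px = dim(pixels)[1]),
    class = "slide_image")
}

#' Read a slide image from a PNG or TIFF raster
#'
#' Plain raster files carry no resolution metadata, so `mpp` must be
#' supplied (default 0.5 um/px, a 20x scan).
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param mpp microns per pixel at full resolution.
#' @param slide_id identifier; defaults to the file name without extension.
#' @return A [slide_image()].
#' @export
read_slide_image <- function(path, mpp = 0.5, slide_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stopf("unsupported image format '%s'", ext))
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  slide_image(px, slide_id %||% tools::file_path_sans_ext(basename(path)),
              mpp = mpp)
}

#' Compute a tissue mask by hysteresis thresholding
#'
#' The slide is downsampled, converted to HSV, and its saturation channel
#' is used as the tissue response: stained tissue is strongly saturated
#' while the glass background is near-white.  Pixels with response at
#' least `high_thresh` seed the mask; it grows through 8-connected pixels
#' with response at least `low_thresh` (hysteresis), which keeps weakly
#' stained regions attached to strongly stained tissue and drops isolated
#' background noise.
#'
#' @param slide a [slide_image()].
#' @param low_thresh,high_thresh hysteresis thresholds in `[0, 1]`,
#'   `low_thresh <= high_thresh`.
#' @param downsample integer downsampling factor for the working
#'   thumbnail (mask grid dims are `ceiling(slide dims / downsample)`).
#' @return An object of class `tissue_mask`: a binary `grid` matrix plus
#'   the `downsample` factor and original slide dimensions.
#' @export
compute_tissue_mask <- function(slide, low_thresh = 0.05,
                                high_thresh = 0.15, downsample = 32L) {
  stopifnot(inherits(slide, "slide_image"))
  if (low_thresh < 0 || high_thresh > 1 || low_thresh > high_thresh)
    stopf("need 0 <= low_thresh <= high_thresh <= 1")
  downsample <- as.integer(downsample)
  if (downsample < 1) stopf("downsample must be a positive integer")
  mh <- as.integer(ceiling(slide$height_px / downsample))
  mw <- as.integer(ceiling(slide$width_px / downsample))
  thumb <- resize_bilinear(slide$pixels, mh, mw)
  resp <- saturation_channel(thumb)
  strong <- resp >= high_thresh
  weak <- resp >= low_thresh
  grid <- hysteresis_grow(strong, weak)
  if (!any(grid))
    warnf("slide '%s': no tissue found; mask is empty", slide$slide_id)
  structure(list(grid = grid, downsample = downsample,
                 slide_dim = c(slide$height_px, slide$width_px)),
            class = "tissue_mask")
}

## HSV saturation of an H x W x 3 array: (max - min) / max, 0 where max = 0.
saturation_channel <- function(px) {
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

## Grow `strong` seeds through `weak` support with 8-connectivity by
## iterated dilation to a fixed point.
hysteresis_grow <- function(strong, weak) {
  cur <- strong & weak
  repeat {
    grown <- dilate8(cur) & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- p[2:(nr + 1L), 2:(nc + 1L)]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- out | p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}

#' Cut a slide into fixed-size tiles over its tissue mask
#'
#' Tiles lie on a non-overlapping grid anchored at pixel (0, 0) with
#' stride `side_px`; a tile is kept when the fraction of its footprint
#' covered by the tissue mask is at least `min_tissue_fraction`.
#' Coordinates are 0-based full-resolution pixel offsets of the top-left
#' corner, with half-open extents `[x, x + side_px)`.
#'
#' @param slide a [slide_image()].
#' @param mask a [compute_tissue_mask()] result aligned to `slide`.
#' @param side_px tile side in pixels (256 at 20x is 128 um).
#' @param min_tissue_fraction minimum mask coverage in `(0, 1]`.
#' @param out_px if non-`NULL`, each patch is bilinearly resized to
#'   `out_px x out_px` after extraction (compact storage for training).
#' @param keep_patch set `FALSE` to return coordinates and tissue
#'   fractions only.
#' @return A list of `tile` objects (`slide_id`, `x`, `y`, `side_px`,
#'   `patch`, `tissue_fraction`, `typicality`).
#' @export
extract_tiles <- function(slide, mask, side_px = 256L,
                          min_tissue_fraction = 0.05, out_px = NULL,
                          keep_patch = TRUE) {
  stopifnot(inherits(slide, "slide_image"), inherits(mask, "tissue_mask"))
  if (min_tissue_fraction <= 0 || min_tissue_fraction > 1)
    stopf("min_tissue_fraction must be in (0, 1]")
  side_px <- as.integer(side_px)
  W <- slide$width_px; H <- slide$height_px
  if (W < side_px || H < side_px) {
    warnf("slide '%s' (%d x %d) smaller than one %d-px tile",
          slide$slide_id, W, H, side_px)
    return(list())
  }
  xs <- seq.int(0L, W - side_px, by = side_px)
  ys <- seq.int(0L, H - side_px, by = side_px)
  fr <- tile_tissue_fractions(mask, xs, ys, side_px)
  tiles <- list()
  for (j in seq_along(xs)) for (i in seq_along(ys)) {
    f <- fr[i, j]
    if (f < min_tissue_fraction) next
    x <- xs[j]; y <- ys[i]
    patch <- NULL
    if (keep_patch) {
      patch <- slide$pixels[(y + 1L):(y + side_px), (x + 1L):(x + side_px), ,
                            drop = FALSE]
      if (!is.null(out_px) && out_px != side_px)
        patch <- resize_bilinear(patch, as.integer(out_px), as.integer(out_px))
    }
    tiles[[length(tiles) + 1L]] <- structure(
      list(slide_id = slide$slide_id, x = x, y = y, side_px = side_px,
           patch = patch, tissue_fraction = f, typicality = NA_real_),
      class = "tile")
  }
  tiles
}

## Mean mask coverage of each tile footprint; exact when the mask
## downsample divides side_px, otherwise cell-centre approximation.
tile_tissue_fractions <- function(mask, xs, ys, side_px) {
  ds <- mask$downsample
  g <- mask$grid
  out <- matrix(0, length(ys), length(xs))
  if (side_px %% ds == 0L) {
    cells <- side_px %/% ds
    for (j in seq_along(xs)) for (i in seq_along(ys)) {
      r0 <- ys[i] %/% ds; c0 <- xs[j] %/% ds
      rr <- (r0 + 1L):min(r0 + cells, nrow(g))
      cc <- (c0 + 1L):min(c0 + cells, ncol(g))
      out[i, j] <- sum(g[rr, cc]) / (cells * cells)
    }
  } else {
    centers_r <- ((seq_len(nrow(g)) - 0.5) * ds)
    centers_c <- ((seq_len(ncol(g)) - 0.5) * ds)
    for (j in seq_along(xs)) for (i in seq_along(ys)) {
      rr <- which(centers_r >= ys[i] & centers_r < ys[i] + side_px)
      cc <- which(centers_c >= xs[j] & centers_c < xs[j] + side_px)
      out[i, j] <- if (length(rr) && length(cc))
        mean(g[rr, cc, drop = FALSE]) else 0
    }
  }
  out
}

#' Physical side length of a tile in microns
#'
#' At a 20x scan (0.5 um per pixel) a 256-pixel tile covers
#' 128 um x 128 um of tissue.
#'
#' @param side_px tile side in pixels.
#' @param mpp microns per pixel.
#' @return Side length in microns.
#' @export
tile_physical_side_um <- function(side_px = 256, mpp = 0.5) {
  if (mpp <= 0) stopf("mpp must be > 0")
  side_px * mpp
}

#' Tile index as a data frame
#'
#' @param tiles list of tiles from [extract_tiles()].
#' @return data.frame with columns `slide_id`, `x`, `y`, `tissue_fraction`.
#' @export
tile_index <- function(tiles) {
  data.frame(
    slide_id = vapply(tiles, `[[`, "", "slide_id"),
    x = vapply(tiles, `[[`, 0L, "x"),
    y = vapply(tiles, `[[`, 0L, "y"),
    tissue_fraction = vapply(tiles, `[[`, 0, "tissue_fraction"))
}

#' Stochastic augmentation parameters
#'
#' The training transform applied to tiles: a right-angle rotation drawn
#' from `rotation_set`, an optional horizontal flip, a random area crop
#' resized back to the original side, and color jitter (multiplicative
#' brightness, contrast and saturation factors drawn from `1 +/- half
#' width`, additive hue shift within `+/- hue`).
#'
#' @param brightness,contrast,saturation,hue non-negative jitter
#'   half-widths (hue is a fraction of the full hue circle).
#' @param rotation_set subset of `c(0, 90, 180, 270)` degrees.
#' @param crop_scale `(lo, hi)` area-fraction range in `(0, 1]`.
#' @param flip enable random horizontal flips.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(brightness = 0.25, contrast = 0.25,
                           saturation = 0.25, hue = 0.05,
                           rotation_set = c(0, 90, 180, 270),
                           crop_scale = c(0.8, 1.0), flip = TRUE) {
  if (any(c(brightness, contrast, saturation, hue) < 0))
    stopf("jitter half-widths must be >= 0")
  if (!all(rotation_set %in% c(0, 90, 180, 270)))
    stopf("rotation_set must be a subset of {0, 90, 180, 270}")
  if (length(crop_scale) != 2L || crop_scale[1] > crop_scale[2] ||
      crop_scale[1] <= 0 || crop_scale[2] > 1)
    stopf("crop_scale must be (lo, hi) with 0 < lo <= hi <= 1")
  structure(list(brightness = brightness, contrast = contrast,
                 saturation = saturation, hue = hue,
                 rotation_set = rotation_set, crop_scale = crop_scale,
                 flip = isTRUE(flip)),
            class = "augment_params")
}

#' Identity augmentation (no-op transform)
#' @return An `augment_params` object whose transform is the identity.
#' @export
augment_identity <- function() {
  augment_params(brightness = 0, contrast = 0, saturation = 0, hue = 0,
                 rotation_set = 0, crop_scale = c(1, 1), flip = FALSE)
}

#' Apply the stochastic training transform to a tile
#'
#' Draws rotation, flip, crop and color-jitter factors from the current
#' RNG stream, so the same seed reproduces the same output.  Degenerate
#' parameters (zero half-widths, `rotation_set = 0`, `crop_scale =
#' c(1, 1)`, no flip) give the identity.
#'
#' @param tile a `tile` object or a bare `H x W x 3` patch array.
#' @param params an [augment_params()].
#' @return Same type as the input, with the transformed patch; shape and
#'   value range are preserved.
#' @export
augment_tile <- function(tile, params = augment_params()) {
  if (inherits(tile, "tile")) {
    if (is.null(tile$patch)) stopf("tile has no pixel patch")
    tile$patch <- augment_patch(tile$patch, params)
    return(tile)
  }
  augment_patch(tile, params)
}

augment_patch <- function(patch, params) {
  side <- dim(patch)[1]
  ## rotation
  if (length(params$rotation_set) > 1L || params$rotation_set[1] != 0) {
    ang <- params$rotation_set[sample.int(length(params$rotation_set), 1L)]
    patch <- rot90k(patch, (ang %/% 90) %% 4)
  }
  ## horizontal flip
  if (params$flip && runif(1) < 0.5)
    patch <- patch[, rev(seq_len(dim(patch)[2])), , drop = FALSE]
  ## random resized crop (area fraction drawn from crop_scale)
  cs <- params$crop_scale
  if (cs[1] < 1 || cs[2] < 1) {
    s <- runif(1, cs[1], cs[2])
    cside <- max(1L, round(side * sqrt(s)))
    if (cside < side) {
      x0 <- sample.int(side - cside + 1L, 1L)
      y0 <- sample.int(side - cside + 1L, 1L)
      patch <- patch[y0:(y0 + cside - 1L), x0:(x0 + cside - 1L), ,
                     drop = FALSE]
      patch <- resize_bilinear(patch, side, side)
    }
  }
  ## color jitter
  if (params$brightness > 0)
    patch <- patch * runif(1, 1 - params$brightness, 1 + params$brightness)
  if (params$contrast > 0) {
    g <- mean(gray_channel(patch))
    patch <- g + runif(1, 1 - params$contrast, 1 + params$contrast) *
      (patch - g)
  }
  if (params$saturation > 0) {
    g <- gray_channel(patch)
    f <- runif(1, 1 - params$saturation, 1 + params$saturation)
    for (c in 1:3) patch[, , c] <- g + f * (patch[, , c] - g)
  }
  patch[patch < 0] <- 0
  patch[patch > 1] <- 1
  if (params$hue > 0)
    patch <- shift_hue(patch, runif(1, -params$hue, params$hue))
  patch
}

## k quarter-turns counter-clockwise of an H x W x C array.
rot90k <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  for (i in seq_len(k)) {
    a <- aperm(a, c(2, 1, 3))
    a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  }
  a
}

gray_channel <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

## Hue rotation by `dh` (fraction of the hue circle) through HSV space.
shift_hue <- function(px, dh) {
  d <- dim(px)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  h <- (hsv[1, ] + dh) %% 1
  rgb <- hsv_to_rgb(h, hsv[2, ], hsv[3, ])
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), dim = d)
}

## Vectorized HSV -> RGB (h, s, v in [0, 1]); returns a 3 x n matrix.
hsv_to_rgb <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Write tiles to PNG files with an index CSV
#'
#' Files are named `<slide_id>_x<x>_y<y>.png`; the index lists
#' `slide_id`, `x`, `y`, `tissue_fraction`.
#'
#' @param tiles list of tiles with patches.
#' @param dir output directory (created if needed).
#' @return Invisibly, the index data frame.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in tiles) {
    if (is.null(t$patch)) stopf("tile at (%d, %d) has no patch", t$x, t$y)
    png::writePNG(t$patch,
                  file.path(dir, sprintf("%s_x%d_y%d.png",
                                         t$slide_id, t$x, t$y)))
  }
  idx <- tile_index(tiles)
  write.csv(idx, file.path(dir, "tile_index.csv"), row.names = FALSE)
  invisible(idx)
}
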