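## Probability heatmaps: thumbnail rendering of per-tile typicalities.

#' Render a tile-probability heatmap
#'
#' Produces a thumbnail-resolution RGB raster in which each tile
#' footprint is filled with the colormap value of its probability (blue
#' for low, red for high by default; the map is monotone in
#' probability).  Areas without tiles keep the background color.
#'
#' @param tiles list of `tile` objects with `typicality` set (e.g. from
#'   [predict_slide()] written back onto the tiles), or a data.frame
#'   with columns `x`, `y`, `side_px`, `typicality`.
#' @param slide_dim `c(height_px, width_px)` of the slide at full
#'   resolution.
#' @param downsample thumbnail downsampling factor.
#' @param low_col,high_col colormap endpoints.
#' @param background background color.
#' @param file optional PNG path to write.
#' @return Invisibly, the `H x W x 3` thumbnail array.
#' @export
render_heatmap <- function(tiles, slide_dim, downsample = 32L,
                           low_col = "blue", high_col = "red",
                           background = "white", file = NULL) {
  if (is.data.frame(tiles)) {
    df <- tiles
  } else {
    df <- tile_index(tiles)
    df$side_px <- vapply(tiles, `[[`, 0L, "side_px")
    df$typicality <- vapply(tiles, `[[`, 0, "typicality")
  }
  if (anyNA(df$typicality)) stopf("tile typicalities must be set")
  H <- as.integer(ceiling(slide_dim[1] / downsample))
  W <- as.integer(ceiling(slide_dim[2] / downsample))
  bg <- col2rgb(background) / 255
  img <- array(rep(bg, each = H * W), dim = c(H, W, 3L))
  ramp <- grDevices::colorRamp(c(low_col, high_col))
  for (i in seq_len(nrow(df))) {
    x <- df$x[i]; y <- df$y[i]; side <- df$side_px[i]
    if (x < 0 || y < 0 || x + side > slide_dim[2] ||
        y + side > slide_dim[1])
      stopf("tile at (%d, %d) outside slide bounds", x, y)
    cols <- (floor(x / downsample) + 1L):ceiling((x + side) / downsample)
    rows <- (floor(y / downsample) + 1L):ceiling((y + side) / downsample)
    rows <- rows[rows <= H]; cols <- cols[cols <= W]
    rgbv <- ramp(df$typicality[i]) / 255
    for (c in 1:3) img[rows, cols, c] <- rgbv[c]
  }
  if (!is.null(file)) png::writePNG(img, file)
  invisible(img)
}
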