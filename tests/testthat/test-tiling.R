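test_that("tissue mask is empty on a uniform white slide", {
  sl <- slide_image(array(1, c(512, 512, 3)), "white")
  expect_warning(m <- compute_tissue_mask(sl), "no tissue")
  expect_true(all(m$grid == 0))
})

test_that("tissue mask recovers a saturated square exactly", {
  px <- array(1, c(512, 512, 3))
  px[101:300, 151:350, 2] <- 0   # pure magenta block
  sl <- slide_image(px, "square")
  m <- compute_tissue_mask(sl, downsample = 1L)
  truth <- matrix(FALSE, 512, 512)
  truth[101:300, 151:350] <- TRUE
  iou <- sum(m$grid & truth) / sum(m$grid | truth)
  expect_equal(iou, 1.0)
})

test_that("mask agrees with a flood-fill reference hysteresis", {
  withr::with_seed(4, {
    for (rep in 1:3) {
      resp <- matrix(runif(40 * 40), 40, 40)
      ## build an HSV image whose saturation equals resp exactly:
      ## r = 1, g = b = 1 - resp
      px <- array(1, c(40, 40, 3))
      px[, , 2] <- 1 - resp
      px[, , 3] <- 1 - resp
      sl <- slide_image(px, "rand")
      m <- compute_tissue_mask(sl, 0.5, 0.93, downsample = 1L)
      expect_equal(m$grid, ref_hysteresis(resp, 0.5, 0.93))
    }
  })
})

test_that("mask grows monotonically as thresholds are lowered", {
  withr::with_seed(9, {
    px <- array(runif(64 * 64 * 3, 0.3, 1), c(64, 64, 3))
    sl <- slide_image(px, "m")
    hi <- compute_tissue_mask(sl, 0.2, 0.5, downsample = 1L)
    lo <- compute_tissue_mask(sl, 0.1, 0.4, downsample = 1L)
    expect_true(all(lo$grid[hi$grid]))
  })
})

test_that("mask recovers the synthetic generator's tissue region", {
  g <- generate_slide(0, NA, synthetic_spec(image_size = 768L), seed = 1)
  m <- compute_tissue_mask(g$slide)
  gt <- g$truth$mask_grid
  iou <- sum(m$grid & gt) / sum(m$grid | gt)
  expect_gte(iou, 0.90)
})

test_that("tile grid covers a fully-tissue slide without overlap", {
  px <- array(0.5, c(1024, 1024, 3))
  px[, , 2] <- 0.1                       # saturated everywhere
  sl <- slide_image(px, "full")
  m <- compute_tissue_mask(sl)
  tiles <- extract_tiles(sl, m, keep_patch = FALSE)
  expect_length(tiles, 16L)
  idx <- tile_index(tiles)
  expect_setequal(unique(idx$x), c(0, 256, 512, 768))
  expect_setequal(unique(idx$y), c(0, 256, 512, 768))
  expect_false(anyDuplicated(idx[c("x", "y")]) > 0)
  ## every tile inside the slide
  expect_true(all(idx$x + 256 <= 1024 & idx$y + 256 <= 1024))
})

test_that("empty masks and undersized slides yield no tiles", {
  sl <- slide_image(array(1, c(512, 512, 3)), "w")
  m <- suppressWarnings(compute_tissue_mask(sl))
  expect_length(extract_tiles(sl, m), 0L)
  small <- slide_image(array(0.2, c(100, 100, 3)), "small")
  msk <- suppressWarnings(compute_tissue_mask(small))
  expect_warning(t2 <- extract_tiles(small, msk), "smaller")
  expect_length(t2, 0L)
})

test_that("raising min_tissue_fraction keeps a subset of tiles", {
  g <- generate_slide(0, NA, synthetic_spec(image_size = 768L,
                                            tissue_coverage = 0.4),
                      seed = 3)
  m <- compute_tissue_mask(g$slide)
  loose <- tile_index(extract_tiles(g$slide, m, min_tissue_fraction = 0.05,
                                    keep_patch = FALSE))
  tight <- tile_index(extract_tiles(g$slide, m, min_tissue_fraction = 0.5,
                                    keep_patch = FALSE))
  expect_true(all(paste(tight$x, tight$y) %in% paste(loose$x, loose$y)))
})

test_that("a 256-px tile at 20x covers 128 microns", {
  expect_identical(tile_physical_side_um(256, 0.5), 128)
})

test_that("degenerate augmentation parameters give the identity", {
  p <- flat_patch()
  p[5:10, 5:10, 1] <- 0.1
  out <- augment_tile(p, augment_identity())
  expect_identical(out, p)
})

test_that("augmentation is reproducible and shape/range preserving", {
  withr::with_seed(31, patch <- array(runif(32 * 32 * 3), c(32, 32, 3)))
  ap <- augment_params()
  a1 <- withr::with_seed(7, augment_tile(patch, ap))
  a2 <- withr::with_seed(7, augment_tile(patch, ap))
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(patch))
  expect_true(all(a1 >= 0 & a1 <= 1))
  a3 <- withr::with_seed(8, augment_tile(patch, ap))
  expect_false(identical(a1, a3))
})

test_that("two half-turn rotations restore the original patch", {
  withr::with_seed(5, patch <- array(runif(16 * 16 * 3), c(16, 16, 3)))
  ap <- augment_params(brightness = 0, contrast = 0, saturation = 0,
                       hue = 0, rotation_set = 180, crop_scale = c(1, 1),
                       flip = FALSE)
  expect_equal(augment_tile(augment_tile(patch, ap), ap), patch)
})
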