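spec768 <- synthetic_spec(image_size = 768L)

test_that("negative slides carry no witness tiles", {
  g <- generate_slide(0, NA, spec768, seed = 2)
  expect_equal(sum(g$truth$tiles$witness), 0L)
  expect_identical(g$truth$label, 0L)
  expect_error(generate_slide(1, 0, spec768, seed = 1), "witness_rate")
})

test_that("witness tile count follows the requested rate", {
  g <- generate_slide(1, 0.3, synthetic_spec(), seed = 5)
  n_tissue <- sum(g$truth$tiles$tissue_fraction >= 0.05)
  expect_lte(abs(sum(g$truth$tiles$witness) - 0.3 * n_tissue), 1)
  ## witness tiles are tissue tiles
  wt <- g$truth$tiles[g$truth$tiles$witness == 1, ]
  expect_true(all(wt$tissue_fraction >= 0.05))
})

test_that("slide generation is byte-identical under a fixed seed", {
  g1 <- generate_slide(1, 0.4, spec768, seed = 7)
  g2 <- generate_slide(1, 0.4, spec768, seed = 7)
  expect_identical(g1$slide$pixels, g2$slide$pixels)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_slide(1, 0.4, spec768, seed = 8)
  expect_false(identical(g1$slide$pixels, g3$slide$pixels))
})

test_that("expression values respect the label-side constraint", {
  withr::with_seed(3, {
    pos <- replicate(50, generate_expression(1, 10))
    neg <- replicate(50, generate_expression(0, 10))
  })
  expect_true(all(pos > 10))
  expect_true(all(neg >= 0 & neg <= 10))
  expect_error(generate_expression(1, 0), "cutoff")
})

test_that("dichotomization at matched prevalence recovers planted labels", {
  co <- generate_cohort(synthetic_spec(n_patients = 40, seed = 12))
  m <- co$manifest
  d <- dichotomize_expression(m, "median")   # 50/50 cohort: median matches
  recovered <- unname(d$labels[m$slide_id])
  expect_gte(mean(recovered == m$label), 0.95)
})

test_that("cohort structure: counts, labels per patient, MIL assumption", {
  co <- generate_cohort(synthetic_spec(n_patients = 20,
                                       slides_per_patient = 2, seed = 4))
  m <- co$manifest
  expect_equal(nrow(m), 40L)
  expect_equal(sum(m$label), 20L)            # balanced by construction
  per_patient <- tapply(m$label, m$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1L))
  ## every positive slide has >= 1 witness tile, negatives none;
  ## the bag-level oracle reproduces the slide label exactly
  for (i in c(1, 2, nrow(m))) {
    g <- cohort_slide(co, i)
    expect_identical(bag_label_oracle(g$truth$tiles$witness), m$label[i])
  }
})

test_that("witness and background tiles separate by mean darkness", {
  aucs <- c()
  for (sd in 1:2) {
    g <- generate_slide(1, 0.35, synthetic_spec(), seed = sd * 100)
    m <- compute_tissue_mask(g$slide)
    tiles <- extract_tiles(g$slide, m)
    key <- paste(g$truth$tiles$x, g$truth$tiles$y)
    wit <- vapply(tiles, function(t)
      g$truth$tiles$witness[match(paste(t$x, t$y), key)], 0L)
    dark <- vapply(tiles, function(t) 1 - mean(t$patch), 0)
    aucs <- c(aucs, roc_auc(dark, wit))
  }
  expect_gte(mean(aucs), 0.95)
})

test_that("cohort export writes images, manifest and ground truth", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  co <- generate_cohort(synthetic_spec(n_patients = 4, image_size = 512L,
                                       seed = 2), out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  gt <- read.csv(file.path(out, "ground_truth.csv"))
  expect_equal(nrow(gt), 4 * 4)              # 2x2 tile grid per slide
  pngs <- list.files(out, pattern = "\\.png$")
  expect_length(pngs, 4L)
  ## reading a written slide back preserves the raster to 8-bit depth
  sl <- read_slide_image(file.path(out, pngs[1]))
  g <- cohort_slide(co, match(tools::file_path_sans_ext(pngs[1]),
                              co$manifest$slide_id))
  expect_lt(max(abs(sl$pixels - g$slide$pixels)), 1 / 255)
  expect_error(generate_cohort(synthetic_spec(n_patients = 4, seed = 2),
                               out_dir = out), "already exists")
})
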