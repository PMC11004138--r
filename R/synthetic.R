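## Synthetic cohort generator: textured tissue images with planted
## witness tiles, expression values consistent with slide labels, and
## full tile-level ground truth.  The data realize the multiple-instance
## assumption exactly: negative slides contain no witness tiles,
## positive slides a contiguous witness region at a controlled rate.

#' Specification of a synthetic cohort
#'
#' Slides are white rasters carrying an irregular pink/purple tissue
#' region textured with scattered dark nuclei; positive slides
#' additionally carry a spatially contiguous region of "witness" tiles
#' with a much denser, darker nucleus motif (emulating hyperchromatic
#' tumor areas).  Per-slide base intensity, stain strength and
#' background nucleus density vary so that slides differ globally in
#' ways unrelated to the label.
#'
#' @param n_patients number of patients (>= 4).
#' @param slides_per_patient slides per patient (all share the
#'   patient's label).
#' @param image_size slide side in pixels (multiple of 256; 1536 gives
#'   a 6 x 6 tile grid).
#' @param witness_rate_range `(lo, hi)` fraction of a positive slide's
#'   tissue tiles carrying the witness motif.
#' @param tissue_coverage target fraction of the image that is tissue.
#' @param nucleus_density background nuclei per 256-px tile.
#' @param witness_density nuclei per witness tile.
#' @param expression_cutoff the value separating low from high
#'   expression in the generated FPKM-UQ-like values.
#' @param mpp declared microns per pixel (0.5 = 20x).
#' @param seed master seed; every slide derives its own stream.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 20L, slides_per_patient = 1L,
                           image_size = 1536L,
                           witness_rate_range = c(0.2, 0.5),
                           tissue_coverage = 0.7,
                           nucleus_density = 40,
                           witness_density = 260,
                           expression_cutoff = 10,
                           mpp = 0.5, seed = 1L) {
  if (image_size %% 256L != 0L)
    stopf("image_size must be a multiple of 256")
  wr <- witness_rate_range
  if (wr[1] <= 0 || wr[1] > wr[2] || wr[2] > 1)
    stopf("witness_rate_range must satisfy 0 < lo <= hi <= 1")
  if (n_patients < 4L) stopf("need at least 4 patients")
  structure(list(n_patients = as.integer(n_patients),
                 slides_per_patient = as.integer(slides_per_patient),
                 image_size = as.integer(image_size),
                 witness_rate_range = wr,
                 tissue_coverage = tissue_coverage,
                 nucleus_density = nucleus_density,
                 witness_density = witness_density,
                 expression_cutoff = expression_cutoff,
                 mpp = mpp, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic slide with tile-level ground truth
#'
#' Deterministic given `seed`.  For `label = 1` a contiguous region of
#' `round(witness_rate * n_tissue_tiles)` tissue tiles receives the
#' witness motif; for `label = 0` no tile does.
#'
#' @param label slide label in `{0, 1}`.
#' @param witness_rate witness-tile fraction for positive slides
#'   (ignored, may be `NA`, for negative slides).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed for this slide.
#' @param slide_id identifier.
#' @return List with `slide` (a [slide_image()]) and `truth`: per-tile
#'   data.frame (`x`, `y`, `tissue_fraction`, `witness`), the slide
#'   `label`, `witness_rate`, and the exact tissue mask downsampled by
#'   32 (`mask_grid`).
#' @export
generate_slide <- function(label, witness_rate = NA, spec = synthetic_spec(),
                           seed = 1L, slide_id = "SYN-1") {
  if (label == 1 && (is.na(witness_rate) || witness_rate <= 0))
    stopf("positive slides need witness_rate > 0")
  s <- spec$image_size
  nt <- s %/% 256L
  with_seed(seed, {
    ## irregular tissue region from thresholded smooth noise
    tissue <- smooth_noise_field(s, 12L)
    tissue <- tissue >= quantile(tissue, 1 - spec$tissue_coverage)
    ## base stain: per-slide intensity and stain-strength variation
    base_int <- runif(1, 0.78, 0.88)
    stain <- 1 + rnorm(1, 0, 0.08)
    shade <- smooth_noise_field(s, 8L)
    shade <- 1 + 0.05 * (shade - mean(shade)) / (sd(shade) + 1e-9)
    base_col <- c(base_int, base_int - 0.12, base_int - 0.05)
    chans <- lapply(1:3, function(c) {
      ch <- matrix(1, s, s)
      ch[tissue] <- (base_col[c] * shade)[tissue]
      ch
    })
    ## per-tile exact tissue fractions
    fr <- matrix(0, nt, nt)
    for (j in 1:nt) for (i in 1:nt)
      fr[i, j] <- mean(tissue[((i - 1) * 256 + 1):(i * 256),
                              ((j - 1) * 256 + 1):(j * 256)])
    tissue_tile <- fr >= 0.05
    ## witness region: contiguous growth, preferring interior tiles
    ## (high tissue fraction) so the motif is not diluted by background
    witness <- matrix(FALSE, nt, nt)
    wr <- if (label == 1) witness_rate else 0
    if (label == 1) {
      k <- max(1L, round(wr * sum(tissue_tile)))
      interior <- fr >= 0.7
      avail <- if (sum(interior) >= k) interior else tissue_tile
      witness <- grow_tile_region(avail, k)
    }
    ## background nuclei over the tissue
    dens <- runif(1, 0.75, 1.5) * spec$nucleus_density
    n_bg <- round(dens * sum(tissue) / 256^2)
    chans <- blend_nuclei(chans, nucleus_shade(s, tissue, n_bg, c(2.5, 5)),
                          base_col = c(0.38, 0.24, 0.48))
    ## witness motif: dense dark nuclei within witness tiles
    if (any(witness)) {
      wmask <- matrix(FALSE, s, s)
      for (j in 1:nt) for (i in 1:nt) if (witness[i, j])
        wmask[((i - 1) * 256 + 1):(i * 256),
              ((j - 1) * 256 + 1):(j * 256)] <- TRUE
      wmask <- wmask & tissue
      n_w <- round(spec$witness_density * sum(witness))
      chans <- blend_nuclei(chans, nucleus_shade(s, wmask, n_w, c(3, 6)),
                            base_col = c(0.22, 0.10, 0.32))
    }
    ## per-slide stain strength applied to the darkness
    img <- array(0, dim = c(s, s, 3L))
    for (c in 1:3) {
      dk <- (1 - chans[[c]]) * stain
      dk[dk < 0] <- 0; dk[dk > 1] <- 1
      img[, , c] <- 1 - dk
    }
    truth <- data.frame(
      x = rep((0:(nt - 1)) * 256L, each = nt),
      y = rep((0:(nt - 1)) * 256L, times = nt),
      tissue_fraction = as.vector(fr),
      witness = as.integer(as.vector(witness)))
    ## exact tissue mask at the standard working downsample
    mg <- block_reduce_mean(tissue, 32L) >= 0.5
    list(slide = slide_image(img, slide_id, mpp = spec$mpp),
         truth = list(tiles = truth, label = as.integer(label),
                      witness_rate = wr, mask_grid = mg))
  })
}

## Smooth random field: coarse gaussian grid bilinearly upsampled.
smooth_noise_field <- function(size, grid) {
  coarse <- array(rnorm(grid * grid), dim = c(grid, grid, 1L))
  resize_bilinear(coarse, size, size)[, , 1]
}

## Mean over non-overlapping b x b blocks of a logical/numeric matrix.
block_reduce_mean <- function(m, b) {
  n <- nrow(m) %/% b
  k <- ncol(m) %/% b
  out <- matrix(0, n, k)
  for (j in 1:k) for (i in 1:n)
    out[i, j] <- mean(m[((i - 1) * b + 1):(i * b),
                        ((j - 1) * b + 1):(j * b)])
  out
}

## Grow a 4-connected region of target size k over available tiles,
## jumping to a new random seed tile if a component is exhausted.
grow_tile_region <- function(avail, k) {
  sel <- matrix(FALSE, nrow(avail), ncol(avail))
  cand <- which(avail)
  k <- min(k, length(cand))
  frontier <- integer(0)
  nr <- nrow(avail)
  while (sum(sel) < k) {
    if (length(frontier) == 0L) {
      pool <- setdiff(which(avail & !sel), integer(0))
      frontier <- pool[sample.int(length(pool), 1L)]
    }
    cur <- frontier[1L]; frontier <- frontier[-1L]
    if (sel[cur]) next
    sel[cur] <- TRUE
    i <- (cur - 1L) %% nr + 1L; j <- (cur - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= ncol(avail)) {
        nxt <- (jj - 1L) * nr + ii
        if (avail[nxt] && !sel[nxt]) frontier <- c(frontier, nxt)
      }
    }
  }
  sel
}

## Shade matrix of n dark elliptical nuclei at random positions of
## `support`: 0 where no nucleus, else a per-nucleus shade multiplier.
nucleus_shade <- function(s, support, n, radii) {
  shade_m <- matrix(0, s, s)
  if (n <= 0L || !any(support)) return(shade_m)
  pos <- which(support)
  pick <- pos[sample.int(length(pos), n, replace = TRUE)]
  cy <- (pick - 1L) %% s + 1L
  cx <- (pick - 1L) %/% s + 1L
  a <- runif(n, radii[1], radii[2])
  b <- runif(n, radii[1], radii[2])
  th <- runif(n, 0, pi)
  shade <- runif(n, 0.85, 1.15)
  for (t in seq_len(n)) {
    r <- ceiling(max(a[t], b[t]))
    rows <- max(1L, cy[t] - r):min(s, cy[t] + r)
    cols <- max(1L, cx[t] - r):min(s, cx[t] + r)
    dy <- rows - cy[t]; dx <- cols - cx[t]
    ct <- cos(th[t]); st <- sin(th[t])
    u <- (rep(dx * ct, each = length(dy)) + dy * st) / a[t]
    v <- (rep(dx * -st, each = length(dy)) + dy * ct) / b[t]
    inside <- u * u + v * v <= 1
    if (!any(inside)) next
    patch <- shade_m[rows, cols]
    patch[inside] <- shade[t]
    shade_m[rows, cols] <- patch
  }
  shade_m
}

## Darken the channels to base_col * shade wherever nuclei were stamped.
blend_nuclei <- function(chans, shade_m, base_col) {
  hit <- which(shade_m > 0)
  if (!length(hit)) return(chans)
  sv <- shade_m[hit]
  for (c in 1:3)
    chans[[c]][hit] <- pmin(chans[[c]][hit], base_col[c] * sv)
  chans
}

#' Generate an expression value consistent with a slide label
#'
#' Positive slides draw strictly above the cutoff (shifted lognormal);
#' negative slides draw in `[0, cutoff]` with a small guard band, giving
#' the bimodal structure a percentile dichotomization recovers.
#'
#' @param label 0 or 1.
#' @param cutoff positive threshold value.
#' @return A non-negative value.
#' @export
generate_expression <- function(label, cutoff) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  if (label == 1) cutoff * (1.05 + exp(rnorm(1, -0.7, 0.6)))
  else cutoff * 0.97 * runif(1)^1.3
}

#' Generate a synthetic cohort manifest (slides built on demand)
#'
#' Assigns balanced patient labels, draws witness rates for positive
#' slides and expression values consistent with each label, and derives
#' one RNG stream per slide so images can be regenerated lazily and
#' deterministically via [cohort_slide()].  With `out_dir` set, slide
#' PNGs, `manifest.csv` and `ground_truth.csv` are written.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional output directory.
#' @return An object of class `synthetic_cohort`: the `spec` and a
#'   `manifest` data.frame (`slide_id`, `patient_id`, `cancer_type`,
#'   `fpkm_uq`, `label`, `witness_rate`, `slide_seed`).
#' @export
generate_cohort <- function(spec = synthetic_spec(), out_dir = NULL) {
  n <- spec$n_patients
  manifest <- with_seed(spec$seed, {
    plab <- sample(rep(0:1, length.out = n))
    rows <- list()
    for (p in seq_len(n)) {
      pid <- sprintf("P%03d", p)
      for (sl in seq_len(spec$slides_per_patient)) {
        lab <- plab[p]
        wr <- if (lab == 1)
          runif(1, spec$witness_rate_range[1], spec$witness_rate_range[2])
        else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          slide_id = sprintf("SYN-%s-S%d", pid, sl),
          patient_id = pid, cancer_type = "SYN",
          fpkm_uq = generate_expression(lab, spec$expression_cutoff),
          label = lab, witness_rate = wr)
      }
    }
    do.call(rbind, rows)
  })
  manifest$slide_seed <- derive_seeds(spec$seed + 1L, nrow(manifest))
  cohort <- structure(list(spec = spec, manifest = manifest),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) {
    if (file.exists(file.path(out_dir, "manifest.csv")))
      stopf("output already exists at %s", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gt <- list()
    for (i in seq_len(nrow(manifest))) {
      g <- cohort_slide(cohort, i)
      png::writePNG(g$slide$pixels,
                    file.path(out_dir, paste0(g$slide$slide_id, ".png")))
      t <- g$truth$tiles
      t$slide_id <- g$slide$slide_id
      gt[[i]] <- t
    }
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, gt), file.path(out_dir, "ground_truth.csv"),
              row.names = FALSE)
  }
  cohort
}

#' Materialize one slide of a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param i manifest row index.
#' @return See [generate_slide()].
#' @export
cohort_slide <- function(cohort, i) {
  m <- cohort$manifest[i, ]
  generate_slide(m$label, m$witness_rate, cohort$spec,
                 seed = m$slide_seed, slide_id = m$slide_id)
}
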