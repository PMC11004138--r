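test_that("AUC handles separation, ties, and the hand example", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with pairwise concordance and is rank-invariant", {
  withr::with_seed(37, {
    for (rep in 1:25) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)          # force some ties
      expect_equal(roc_auc(scores, labels), ref_auc(scores, labels))
      ## strictly increasing transform preserves the AUC
      expect_equal(roc_auc(exp(3 * scores), labels),
                   roc_auc(scores, labels))
    }
    ## cross-check against an established ROC implementation
    if (requireNamespace("pROC", quietly = TRUE)) {
      sc <- runif(80); la <- c(0, 1, rbinom(78, 1, plogis(3 * sc[-(1:2)])))
      expect_equal(roc_auc(sc, la),
                   as.numeric(pROC::auc(pROC::roc(la, sc, quiet = TRUE))))
    }
  })
})

test_that("Youden threshold matches exhaustive search", {
  expect_equal(youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)),
               0.8)
  expect_equal(youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               0.35)
  expect_error(youden_threshold(1:4, rep(1, 4)), "both classes")
  withr::with_seed(41, {
    for (rep in 1:25) {
      n <- sample(4:40, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)
      expect_equal(youden_threshold(scores, labels),
                   ref_youden(scores, labels))
    }
  })
})

test_that("Youden threshold maximizes sensitivity + specificity", {
  withr::with_seed(43, {
    scores <- runif(60)
    labels <- rbinom(60, 1, plogis(4 * scores - 2))
    if (length(unique(labels)) == 2) {
      t_star <- youden_threshold(scores, labels)
      m_star <- confusion_metrics(scores, labels, t_star)
      for (t in unique(scores)) {
        m <- confusion_metrics(scores, labels, t)
        expect_lte(m$sensitivity + m$specificity,
                   m_star$sensitivity + m_star$specificity + 1e-12)
      }
    }
  })
})

test_that("confusion metrics match direct formula evaluation", {
  ## TP = 3, FP = 1, FN = 1, TN = 5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-4)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, 14 / 24, tolerance = 1e-4)
})

test_that("degenerate confusion tables follow the conventions", {
  perfect <- confusion_metrics(c(0.1, 0.9), c(0, 1), 0.5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  ## everything predicted positive on balanced labels
  allpos <- confusion_metrics(c(0.9, 0.8), c(0, 1), 0.1)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$mcc, 0)
})

test_that("bootstrap interval is degenerate under perfect separation", {
  ci <- bootstrap_ci(c(1, 2, 3, 8, 9, 10), c(0, 0, 0, 1, 1, 1),
                     n_resamples = 200, seed = 2)
  expect_equal(ci, c(1, 1))
})

test_that("bootstrap interval is ordered, bounded, and reproducible", {
  withr::with_seed(47, {
    scores <- c(rnorm(30), rnorm(30, 1))
    labels <- rep(0:1, each = 30)
  })
  ci <- bootstrap_ci(scores, labels, n_resamples = 300, seed = 5)
  expect_lte(ci[1], ci[2])
  expect_true(all(ci >= 0 & ci <= 1))
  expect_identical(ci, bootstrap_ci(scores, labels, 300, seed = 5))
  expect_warning(bootstrap_ci(scores, labels, n_resamples = 50, seed = 1),
                 "resamples")
})

test_that("metrics report brackets the AUC and prints", {
  withr::with_seed(53, {
    scores <- c(rnorm(40), rnorm(40, 1.5))
    labels <- rep(0:1, each = 40)
  })
  rep <- metrics_report(scores, labels, n_resamples = 300, seed = 9)
  expect_lte(rep$ci_low, rep$auc)
  expect_gte(rep$ci_high, rep$auc)
  expect_identical(rep$n, 80L)
  expect_output(print(rep), "AUC")
})

test_that("matched-patch correlation recovers affine relations", {
  withr::with_seed(59, pred <- runif(1000))
  expect_equal(matched_patch_correlation(pred, 2 * pred + 1), 1)
  expect_equal(matched_patch_correlation(pred, -3 * pred + 5), -1)
  ## ceiling arithmetic: 1% of 1000 selects 10 top patches
  sel <- order(pred, decreasing = TRUE)[1:10]
  ref <- rep(0, 1000); ref[sel] <- pred[sel]
  expect_equal(matched_patch_correlation(pred, ref, mode = "top"), 1)
  expect_error(matched_patch_correlation(runif(50), runif(50),
                                         fraction = 0.01, mode = "top"),
               "fewer than 3")
  expect_error(matched_patch_correlation(runif(10), runif(9)), "aligned")
})

test_that("heatmaps fill tile footprints with the colormap endpoints", {
  df <- data.frame(x = c(0, 256), y = c(0, 0), side_px = 256,
                   typicality = c(1, 1))
  img <- render_heatmap(df, c(512, 512), downsample = 32)
  expect_identical(dim(img), c(16L, 16L, 3L))
  ## red endpoint over tiles, white elsewhere
  expect_true(all(img[1:8, 1:16, 1] == 1 & img[1:8, 1:16, 3] == 0))
  expect_true(all(img[9:16, , ] == 1))
  df$typicality <- c(0, 0)
  img2 <- render_heatmap(df, c(512, 512), downsample = 32)
  expect_true(all(img2[1:8, 1:16, 3] == 1 & img2[1:8, 1:16, 1] == 0))
  df$x <- c(0, 400)
  expect_error(render_heatmap(df, c(512, 512)), "outside")
})
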