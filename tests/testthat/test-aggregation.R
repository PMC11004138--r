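test_that("trimmed summary matches direct computation", {
  s <- trimmed_stat_summary(c(0.1, 0.9, 0.5, 0.6))
  ## trim keeps {0.5, 0.6}
  expect_equal(unname(s["positive_fraction"]), 0.5)
  expect_equal(unname(s["median"]), 0.55)
  expect_equal(unname(s["mean"]), 0.55)
  expect_equal(sum(s[paste0("hist", 1:8)]), 1)
  expect_length(s, 11L)
})

test_that("constant probabilities put all mass in one central bin", {
  s <- trimmed_stat_summary(rep(0.5, 10))
  expect_equal(unname(s["positive_fraction"]), 0)
  expect_equal(unname(s["median"]), 0.5)
  expect_equal(unname(s["mean"]), 0.5)
  h <- s[paste0("hist", 1:8)]
  expect_equal(sum(h == 1), 1L)
  expect_equal(sum(h), 1)
})

test_that("summary is permutation invariant and falls back when trimmed empty", {
  withr::with_seed(3, p <- runif(50))
  expect_identical(trimmed_stat_summary(p),
                   trimmed_stat_summary(rev(sample(p))))
  ## all-extreme probabilities: untrimmed fallback over [0, 1]
  s <- trimmed_stat_summary(c(0.05, 0.95, 0.9))
  expect_equal(sum(s[paste0("hist", 1:8)]), 1)
  expect_equal(unname(s["mean"]), mean(c(0.05, 0.95, 0.9)))
  expect_error(trimmed_stat_summary(numeric(0)))
})

test_that("fused token has length d and tolerates a single tile", {
  fu <- init_fusion(32, seed = 2)
  one <- fuse_token(matrix(rnorm(32), 1, 32), fu)
  expect_length(one, 32L)
  expect_true(all(is.finite(one)))
})

test_that("fused token is invariant to tile order", {
  withr::with_seed(17, {
    fu <- init_fusion(32, seed = 4)
    E <- matrix(rnorm(20 * 32), 20, 32)
    t1 <- fuse_token(E, fu)
    t2 <- fuse_token(E[sample(20), ], fu)
    expect_equal(t1, t2, tolerance = 1e-5)
  })
})

test_that("feature dimension mismatches are rejected", {
  fu <- init_fusion(32, seed = 1)
  expect_error(fuse_token(matrix(0, 2, 16), fu), "dimension")
  expect_error(fuse_token(list(rnorm(8), rnorm(9)), fu), "inconsistent")
})

test_that("embedding concatenates token then stats", {
  stats <- trimmed_stat_summary(runif(30))
  tok512 <- rnorm(512)
  e <- build_embedding(tok512, stats)
  expect_length(e, 523L)
  expect_identical(e[1:512], tok512)
  expect_identical(e[513:523], unname(stats))
  expect_length(build_embedding(rnorm(32), stats), 43L)
  expect_error(build_embedding(tok512, stats[1:10]), "length 11")
})

test_that("the slide MLP fits separable embeddings to full accuracy", {
  withr::with_seed(23, {
    n <- 20
    emb <- rbind(matrix(rnorm(n / 2 * 43, -2), n / 2, 43),
                 matrix(rnorm(n / 2 * 43, 2), n / 2, 43))
    labs <- rep(0:1, each = n / 2)
    clf <- train_slide_classifier(emb, labs, lr = 0.05, epochs = 200,
                                  seed = 3)
    pr <- predict_embedding(clf, emb)
    expect_equal(as.integer(pr > 0.5), labs)
    ## class probabilities are complementary (softmax over two classes)
    p_full <- milts:::mlp_forward(clf$mlp,
      (emb[1, ] - clf$center) / clf$scale)$probs
    expect_equal(sum(p_full), 1)
    ## same seed reproduces identical weights
    clf2 <- train_slide_classifier(emb, labs, lr = 0.05, epochs = 200,
                                   seed = 3)
    expect_identical(clf$mlp, clf2$mlp)
    expect_error(train_slide_classifier(emb, rep(1, n)), "both classes")
  })
})

test_that("the joint slide model is deterministic and predicts in [0, 1]", {
  withr::with_seed(29, {
    feats <- lapply(1:10, function(i)
      matrix(rnorm(8 * 16, mean = ifelse(i %% 2 == 0, 0.6, -0.6)), 8, 16))
    stats <- lapply(1:10, function(i)
      trimmed_stat_summary(runif(20, 0.2, 0.8) +
                             ifelse(i %% 2 == 0, 0.05, -0.05)))
    labs <- rep(c(0L, 1L), 5)
    m1 <- train_slide_model(feats, stats, labs, d = 16, lr = 0.01,
                            epochs = 100, seed = 6)
    m2 <- train_slide_model(feats, stats, labs, d = 16, lr = 0.01,
                            epochs = 100, seed = 6)
    expect_identical(m1$mlp, m2$mlp)
    expect_identical(m1$fusion, m2$fusion)
    p <- milts:::predict_slide_model(m1, feats[[1]], stats[[1]])
    expect_true(p >= 0 && p <= 1)
  })
})

test_that("predict_slide returns tile and slide probabilities in range", {
  bags <- tiny_bags()
  cfg <- milts_train_config(epochs = 1, batch_size = 8,
                            encoder = encoder_spec(input_px = 16),
                            labeled_proportion = 0.5, seed = 3)
  fit <- milts(bags, cfg, milts_loss_config(lambda = 10),
               slide_epochs = 20L)
  out <- predict_slide(bags[[1]], fit$state, fit$slide_model)
  expect_length(out$tile_probs, bags[[1]]$n)
  expect_true(all(out$tile_probs >= 0 & out$tile_probs <= 1))
  expect_true(out$slide_prob >= 0 && out$slide_prob <= 1)
  ## repeated inference is identical
  expect_identical(out,
                   predict_slide(bags[[1]], fit$state, fit$slide_model))
  ## predict method agrees
  expect_equal(predict(fit, bags[[1]]), out$slide_prob)
})
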