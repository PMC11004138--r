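test_that("bag label follows the multiple-instance assumption", {
  expect_identical(bag_label_oracle(c(0, 0, 0)), 0L)
  expect_identical(bag_label_oracle(c(0, 1, 0)), 1L)
  expect_identical(bag_label_oracle(integer(0)), 0L)
  expect_error(bag_label_oracle(c(0, 2)), "0 or 1")
})

test_that("representative selection takes extremes with index ties", {
  expect_identical(select_representatives(c(0.1, 0.9, 0.5), 1, 1), 2L)
  expect_identical(select_representatives(c(0.1, 0.9, 0.5), 0, 2),
                   c(1L, 3L))
  expect_identical(select_representatives(rep(0.4, 5), 1, 1), 1L)
  expect_error(select_representatives(c(0.1, 0.2), 1, 3), "M must be")
  expect_error(select_representatives(c(0.1, NaN), 1, 1), "finite")
})

test_that("selection agrees with a full sort and partitions the bag", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(3:40, 1)
      scores <- runif(n)
      M <- sample(n, 1)
      top <- select_representatives(scores, 1, M)
      expect_identical(top, sort(order(scores, decreasing = TRUE)[1:M]))
      if (M < n) {
        bot <- select_representatives(scores, 0, n - M)
        expect_identical(sort(c(top, bot)), seq_len(n))
      }
    }
  })
})

test_that("pseudo-labels cover round(proportion * n) tiles with the bag label", {
  bag <- milts_bag("b", array(0.5, c(8, 8, 3, 100)), 1L)
  pl <- assign_pseudo_labels(bag, runif(100), 0.35)
  expect_identical(pl$M, 35L)
  expect_length(pl$labeled, 35L)
  expect_identical(sort(c(pl$labeled, pl$unlabeled)), 1:100)
  expect_identical(pl$pseudo_label, 1L)
  ## at least one tile is always labeled
  small <- milts_bag("s", array(0.5, c(8, 8, 3, 3)), 0L)
  expect_identical(assign_pseudo_labels(small, c(0.2, 0.1, 0.9), 0.1)$M, 1L)
})

test_that("EMA update matches closed-form arithmetic", {
  st <- list(student = list(w = 1), teacher = list(w = 0),
             ema_decay = 0.99, global_step = 0L)
  out <- ema_update(st)
  expect_equal(out$teacher$w, 0.01)
  expect_identical(out$global_step, 1L)
  st$ema_decay <- 1
  expect_equal(ema_update(st)$teacher$w, 0)
  st$ema_decay <- 0
  expect_equal(ema_update(st)$teacher$w, 1)
  st$teacher <- list(w = c(0, 0))
  expect_error(ema_update(st), "shapes differ")
})

test_that("the loss matches its closed form and degenerate limits", {
  ## one labeled (y = 1, f = 0.5) plus one unlabeled with gap 0.2
  expect_equal(milts_loss(0.5, 1, c(1, 1), 0.6, 0.8, lambda = 100),
               -log(0.5) + 100 * 0.2^2, tolerance = 1e-12)
  ## identical teacher and student: consistency vanishes for any lambda
  expect_equal(milts_loss(0.7, 1, c(1, 1), c(0.3, 0.9), c(0.3, 0.9),
                          lambda = 1e6),
               -log(0.7))
  ## perfect labeled predictions, lambda 0: loss at the clipping floor
  expect_lt(milts_loss(c(1, 0), c(1, 0), c(1, 1), lambda = 0), 1e-5)
  expect_error(milts_loss(0.5, 1, c(1, 1), lambda = -1), "lambda")
  expect_error(milts_loss(c(0.5, 0.6), 1), "lengths differ")
})

test_that("cosine schedule anneals from base to trough and restarts", {
  cfg <- milts_train_config(epochs = 30, lr_cycles = 2)
  spe <- 7L                              # cycle of 105 steps
  expect_equal(cosine_lr(0L, cfg, spe), 1e-2)
  trough <- 15L * spe - 1L               # last step of the first cycle
  expect_equal(cosine_lr(trough, cfg, spe), 1e-4)
  expect_equal(cosine_lr(trough + 1L, cfg, spe), 1e-2)  # warm restart
  ## half phase sits midway between base and trough
  expect_equal(cosine_lr(trough %/% 2L, cfg, spe), (1e-2 + 1e-4) / 2)
})

test_that("scoring is deterministic, ordered, and in [0, 1]", {
  bags <- tiny_bags()
  p <- milts:::init_encoder(encoder_spec(input_px = 16), seed = 2)
  s1 <- score_instances(p, bags[[1]])
  s2 <- score_instances(p, bags[[1]])
  expect_identical(s1, s2)
  expect_length(s1, bags[[1]]$n)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("training is seed-reproducible and logs its schedule", {
  bags <- tiny_bags()
  cfg <- milts_train_config(epochs = 2, batch_size = 8,
                            encoder = encoder_spec(input_px = 16),
                            labeled_proportion = 0.5, seed = 5)
  lcfg <- milts_loss_config(lambda = 10)
  f1 <- train_teacher_student(bags, cfg, lcfg)
  f2 <- train_teacher_student(bags, cfg, lcfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$teacher, f2$teacher)
  expect_equal(nrow(f1$log), 2L)
  expect_true(all(is.finite(f1$log$wce)))
  expect_error(train_teacher_student(bags[c(2, 4)], cfg, lcfg),
               "each class")
})

test_that("the teacher replays as an EMA of the student trajectory", {
  bags <- tiny_bags(n_bags = 4, n_inst = 4)
  cfg <- milts_train_config(epochs = 1, batch_size = 8, ema_decay = 0.95,
                            encoder = encoder_spec(input_px = 16),
                            labeled_proportion = 0.5, seed = 8)
  fit <- train_teacher_student(bags, cfg, milts_loss_config(lambda = 10),
                               record_trajectory = TRUE)
  ## replay: teacher_t = a teacher_{t-1} + (1 - a) student_t from init
  st0 <- milts:::init_encoder(cfg$encoder,
                              seed = withr::with_seed(cfg$seed,
                                sample.int(.Machine$integer.max, 1)))
  replay <- st0
  for (snap in fit$trajectory)
    replay <- mapply(function(t, s) 0.95 * t + 0.05 * s, replay, snap,
                     SIMPLIFY = FALSE)
  expect_equal(replay, fit$teacher, tolerance = 1e-12)
})

test_that("fully supervised mode labels every tile and learns separably", {
  bags <- tiny_bags(n_bags = 6, n_inst = 6, n_dark = 6)
  cfg <- milts_train_config(epochs = 6, batch_size = 12, base_lr = 0.05,
                            min_lr = 1e-3, lr_cycles = 1,
                            encoder = encoder_spec(input_px = 16),
                            labeled_proportion = 1, seed = 13)
  fit <- train_teacher_student(bags, cfg, milts_loss_config(lambda = 0))
  ## with proportion 1 every instance is pseudo-labeled: churn is 0
  expect_true(all(fit$log$churn[-1] == 0))
  ## student separates all-dark positive bags from light negative bags
  sc <- unlist(lapply(bags, function(b)
    score_instances(fit, b, model = "student")))
  labs <- unlist(lapply(bags, function(b) rep(b$label, b$n)))
  expect_gte(roc_auc(sc, labs), 0.95)
  ## loss decreased over training
  expect_lt(fit$log$wce[6], fit$log$wce[1])
})
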