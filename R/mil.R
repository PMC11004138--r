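## Teacher-student multiple instance learning: class-targeted
## representative selection, dynamic pseudo-labeling, weighted
## cross-entropy plus consistency distillation, EMA teacher.

#' Build a bag (one slide's tiles plus its label)
#'
#' @param slide_id character identifier.
#' @param patches `h x w x 3 x n` array of tile rasters (already resized
#'   to the encoder input), or a list of `tile` objects.
#' @param label bag label in `{0, 1}`.
#' @param witness optional ground-truth per-tile flags (synthetic data).
#' @param coords optional `n x 2` matrix of tile `(x, y)` offsets.
#' @return An object of class `milts_bag`.
#' @export
milts_bag <- function(slide_id, patches, label, witness = NULL,
                      coords = NULL) {
  if (is.list(patches)) {
    coords <- cbind(vapply(patches, `[[`, 0L, "x"),
                    vapply(patches, `[[`, 0L, "y"))
    arrs <- lapply(patches, `[[`, "patch")
    d1 <- dim(arrs[[1]])
    patches <- array(unlist(arrs, use.names = FALSE),
                     dim = c(d1, length(arrs)))
  }
  if (length(dim(patches)) != 4L) stopf("patches must be h x w x 3 x n")
  if (!label %in% c(0, 1)) stopf("bag label must be 0 or 1")
  structure(list(slide_id = as.character(slide_id), patches = patches,
                 n = dim(patches)[4], label = as.integer(label),
                 witness = witness, coords = coords),
            class = "milts_bag")
}

#' Bag label implied by instance labels
#'
#' The multiple-instance assumption: a bag is negative exactly when
#' every instance is negative (an empty bag is negative).
#'
#' @param instance_labels vector of 0/1 instance labels.
#' @return 0 or 1.
#' @export
bag_label_oracle <- function(instance_labels) {
  if (length(instance_labels) == 0L) return(0L)
  if (!all(instance_labels %in% c(0, 1)))
    stopf("instance labels must be 0 or 1")
  as.integer(sum(instance_labels) > 0)
}

#' Select the class-representative instances of a bag
#'
#' The maximum-minimum criterion: for a positive bag the `M` instances
#' with the highest typicality scores; for a negative bag the `M`
#' lowest.  Ties are broken toward the lower index.  Indices are 1-based
#' and returned sorted ascending.
#'
#' @param scores finite numeric typicality scores.
#' @param bag_label 0 or 1.
#' @param M number of representatives, `1 <= M <= length(scores)`.
#' @return Sorted integer indices of the selected instances.
#' @export
select_representatives <- function(scores, bag_label, M) {
  n <- length(scores)
  if (anyNA(scores) || any(!is.finite(scores)))
    stopf("scores must be finite")
  if (M < 1L || M > n) stopf("M must be in [1, %d], got %s", n, M)
  ord <- if (bag_label == 1) order(-scores, seq_len(n))
         else order(scores, seq_len(n))
  sort(ord[seq_len(M)])
}

#' Assign dynamic pseudo-labels within a bag
#'
#' `M = max(1, round(proportion * n))` representatives selected by the
#' teacher's scores inherit the bag label; the rest remain unlabeled and
#' are only subject to the consistency cost.
#'
#' @param bag a [milts_bag()].
#' @param teacher_scores typicality scores, one per instance.
#' @param proportion labeled-instance proportion in `(0, 1]` (see
#'   [labeled_proportion()]).
#' @return List with `labeled` (indices), `unlabeled` (complement), `M`,
#'   and `pseudo_label` (the bag label carried by every labeled
#'   instance).
#' @export
assign_pseudo_labels <- function(bag, teacher_scores, proportion) {
  if (bag$n < 1L) stopf("empty bag '%s'", bag$slide_id)
  if (length(teacher_scores) != bag$n)
    stopf("bag '%s': %d scores for %d instances", bag$slide_id,
          length(teacher_scores), bag$n)
  if (proportion <= 0 || proportion > 1)
    stopf("proportion must be in (0, 1]")
  M <- max(1L, as.integer(round(proportion * bag$n)))
  labeled <- select_representatives(teacher_scores, bag$label, M)
  list(labeled = labeled,
       unlabeled = setdiff(seq_len(bag$n), labeled),
       M = M, pseudo_label = bag$label)
}

#' Exponential-moving-average update of the teacher
#'
#' After each optimizer step the teacher parameters move toward the
#' student: `theta' <- alpha * theta' + (1 - alpha) * theta`,
#' elementwise, and the step counter is incremented.
#'
#' @param state list with `student`, `teacher` (parameter lists of
#'   identical shapes), `ema_decay`, `global_step`.
#' @return The updated state.
#' @export
ema_update <- function(state) {
  a <- state$ema_decay
  shape <- function(p) dim(p) %||% length(p)
  if (!identical(lapply(state$student, shape),
                 lapply(state$teacher, shape)))
    stopf("student/teacher parameter shapes differ")
  state$teacher <- mapply(function(t, s) a * t + (1 - a) * s,
                          state$teacher, state$student, SIMPLIFY = FALSE)
  state$global_step <- state$global_step + 1L
  state
}

#' Training loss: weighted cross-entropy plus consistency cost
#'
#' `L = WCE(labeled) + lambda * sum((teacher - student)^2)` over the
#' unlabeled instances, where `WCE = -sum(w_pos * y * log f + w_neg *
#' (1 - y) * log(1 - f))` on probabilities clipped at `1e-7`.  With
#' `reduction = "batch_mean"` both terms are divided by `batch_size`
#' (the per-batch normalization used by the trainer).
#'
#' @param labeled_probs student probabilities on pseudo-labeled tiles.
#' @param pseudo_labels their 0/1 pseudo-labels.
#' @param weights `c(w_pos, w_neg)`, positive class-balancing weights.
#' @param student_unlabeled_probs,teacher_unlabeled_probs probabilities
#'   of the two models on the identically transformed unlabeled tiles.
#' @param lambda non-negative consistency weight (default 100).
#' @param reduction `"sum"` (the loss as written) or `"batch_mean"`.
#' @param batch_size divisor for `"batch_mean"`.
#' @return Non-negative scalar loss.
#' @export
milts_loss <- function(labeled_probs, pseudo_labels, weights = c(1, 1),
                       student_unlabeled_probs = numeric(0),
                       teacher_unlabeled_probs = numeric(0),
                       lambda = 100,
                       reduction = c("sum", "batch_mean"),
                       batch_size = NULL) {
  reduction <- match.arg(reduction)
  if (lambda < 0) stopf("lambda must be >= 0")
  if (length(labeled_probs) != length(pseudo_labels))
    stopf("labeled_probs and pseudo_labels lengths differ")
  if (length(student_unlabeled_probs) != length(teacher_unlabeled_probs))
    stopf("student and teacher unlabeled lengths differ")
  if (any(weights <= 0)) stopf("class weights must be positive")
  f <- clip01(labeled_probs)
  y <- pseudo_labels
  wce <- -sum(weights[1] * y * log(f) + weights[2] * (1 - y) * log(1 - f))
  cons <- sum((teacher_unlabeled_probs - student_unlabeled_probs)^2)
  L <- wce + lambda * cons
  if (reduction == "batch_mean") {
    if (is.null(batch_size))
      batch_size <- length(labeled_probs) + length(student_unlabeled_probs)
    L <- L / batch_size
  }
  L
}

#' Cosine-annealed learning rate with warm restarts
#'
#' The rate starts at `base_lr`, decays along a half cosine to `min_lr`
#' at the end of each cycle, and restarts; the default 30-epoch run
#' completes two cycles.  Evaluated per optimizer iteration.
#'
#' @param step 0-based global iteration counter.
#' @param config a [milts_train_config()].
#' @param steps_per_epoch iterations per epoch (default 1).
#' @return The learning rate.
#' @export
cosine_lr <- function(step, config, steps_per_epoch = 1L) {
  cycle_steps <- max(1L, as.integer(config$epochs / config$lr_cycles *
                                      steps_per_epoch))
  pos <- step %% cycle_steps
  t <- if (cycle_steps > 1L) pos / (cycle_steps - 1L) else 0
  config$min_lr + 0.5 * (config$base_lr - config$min_lr) *
    (1 + cos(pi * t))
}

#' Training configuration for the teacher-student engine
#'
#' Defaults follow the full-scale recipe: SGD from `1e-2` cosine-annealed
#' to `1e-4` over 30 epochs in two cycles, batch 512.  Desk-scale runs
#' shrink `epochs`, `batch_size` and the encoder.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param base_lr,min_lr initial and trough learning rates.
#' @param lr_cycles cosine cycles completed over `epochs`.
#' @param momentum SGD momentum.
#' @param labeled_proportion per-slide labeled-instance proportion (see
#'   [labeled_proportion()]).
#' @param ema_decay teacher EMA decay `alpha` in `[0, 1]` (default 0.99),
#'   fixed throughout a run.
#' @param encoder an [encoder_spec()].
#' @param seed integer seed controlling init, shuffling and augmentation.
#' @return An object of class `milts_train_config`.
#' @export
milts_train_config <- function(epochs = 30L, batch_size = 512L,
                               base_lr = 1e-2, min_lr = 1e-4,
                               lr_cycles = 2L, momentum = 0.9,
                               labeled_proportion = 0.35,
                               ema_decay = 0.99,
                               encoder = encoder_spec(), seed = 1L) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (!(base_lr > min_lr && min_lr > 0))
    stopf("need base_lr > min_lr > 0")
  if (ema_decay < 0 || ema_decay > 1) stopf("ema_decay must be in [0, 1]")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr, min_lr = min_lr,
                 lr_cycles = as.integer(lr_cycles), momentum = momentum,
                 labeled_proportion = labeled_proportion,
                 ema_decay = ema_decay,
                 encoder = encoder, seed = as.integer(seed)),
            class = "milts_train_config")
}

#' Loss configuration for the teacher-student engine
#'
#' @param class_weights `c(w_pos, w_neg)` or `NULL` to use inverse slide
#'   label frequencies normalized to mean 1.
#' @param lambda consistency weight (default 100).
#' @param augment the stochastic transform applied to training tiles;
#'   one draw is shared by the student and teacher branches of each
#'   instance.
#' @return An object of class `milts_loss_config`.
#' @export
milts_loss_config <- function(class_weights = NULL, lambda = 100,
                              augment = augment_params()) {
  if (lambda < 0) stopf("lambda must be >= 0")
  structure(list(class_weights = class_weights, lambda = lambda,
                 augment = augment),
            class = "milts_loss_config")
}

#' Score tiles with a trained instance model
#'
#' Deterministic evaluation-mode forward pass (no augmentation);
#' returns one typicality in `[0, 1]` per tile, in input order.
#'
#' @param params a parameter list, or a teacher-student `state` (the
#'   teacher is used by default).
#' @param tiles a `h x w x 3 x n` array, a [milts_bag()], or a list of
#'   `tile` objects; patches are resized to the encoder input if needed.
#' @param input_px encoder input side (required when `params` is a bare
#'   parameter list and resizing is needed).
#' @param model `"teacher"` or `"student"` when given a state.
#' @return Numeric vector of typicalities.
#' @export
score_instances <- function(params, tiles, input_px = NULL,
                            model = c("teacher", "student")) {
  model <- match.arg(model)
  if (!is.null(params$student)) {
    input_px <- input_px %||% params$config$encoder$input_px
    params <- params[[model]]
  }
  X <- as_patch_stack(tiles, input_px)
  encoder_score_stack(params, X)$prob
}

as_patch_stack <- function(tiles, input_px = NULL) {
  if (inherits(tiles, "milts_bag")) tiles <- tiles$patches
  if (is.list(tiles)) {
    arrs <- lapply(tiles, function(t) {
      p <- if (inherits(t, "tile")) t$patch else t
      if (is.null(p)) stopf("tile without pixel patch")
      if (!is.null(input_px) && dim(p)[1] != input_px)
        p <- resize_bilinear(p, input_px, input_px)
      p
    })
    tiles <- array(unlist(arrs, use.names = FALSE),
                   dim = c(dim(arrs[[1]]), length(arrs)))
  }
  if (length(dim(tiles)) != 4L) stopf("expected a h x w x 3 x n stack")
  if (!is.null(input_px) && dim(tiles)[1] != input_px) {
    n <- dim(tiles)[4]
    out <- array(0, c(input_px, input_px, 3L, n))
    for (i in seq_len(n))
      out[, , , i] <- resize_bilinear(
        array(tiles[, , , i], dim(tiles)[1:3]), input_px, input_px)
    tiles <- out
  }
  tiles
}

#' Train the teacher-student instance scorer
#'
#' Each epoch the teacher scores every tile, pseudo-labels are
#' re-assigned per bag by the maximum-minimum criterion, and the student
#' is optimized by SGD over shuffled mini-batches on the weighted
#' cross-entropy (pseudo-labeled tiles) plus `lambda` times the
#' consistency cost (unlabeled tiles, identical transform fed to both
#' models).  The teacher tracks the student by EMA after every step.
#'
#' @param bags list of [milts_bag()] with labels; both classes must be
#'   present.
#' @param train_cfg a [milts_train_config()].
#' @param loss_cfg a [milts_loss_config()].
#' @param record_trajectory keep a snapshot of the student parameters
#'   after every optimizer step (for audit/replay; memory-heavy, only
#'   for small runs).
#' @param verbose print one line per epoch.
#' @return A teacher-student `milts_state`: `student`, `teacher`,
#'   `ema_decay`, `global_step`, `config`, `class_weights`, and a
#'   per-epoch `log` (epoch, lr, wce, cons, churn).
#' @export
train_teacher_student <- function(bags, train_cfg = milts_train_config(),
                                  loss_cfg = milts_loss_config(),
                                  record_trajectory = FALSE,
                                  verbose = FALSE) {
  labels <- vapply(bags, `[[`, 0L, "label")
  if (length(unique(labels)) < 2L)
    stopf("training requires at least one bag of each class")
  spec <- train_cfg$encoder
  ## pool instances
  stacks <- lapply(bags, function(b) as_patch_stack(b, spec$input_px))
  ns <- vapply(stacks, function(s) dim(s)[4], 0L)
  N <- sum(ns)
  X <- array(unlist(stacks, use.names = FALSE),
             dim = c(spec$input_px, spec$input_px, 3L, N))
  rm(stacks)
  bag_of <- rep(seq_along(bags), ns)
  bag_idx <- split(seq_len(N), bag_of)
  ## class weights: inverse slide-label frequency, mean 1
  w <- loss_cfg$class_weights
  if (is.null(w)) {
    fp <- mean(labels == 1); fn <- 1 - fp
    u <- c(1 / fp, 1 / fn)
    w <- u / mean(u)
  }
  lambda <- loss_cfg$lambda
  prop <- train_cfg$labeled_proportion
  B <- train_cfg$batch_size
  steps_per_epoch <- max(1L, ceiling(N / B))
  state <- with_seed(train_cfg$seed, {
    student <- init_encoder(spec, seed = sample.int(.Machine$integer.max, 1))
    list(student = student, teacher = student,
         ema_decay = train_cfg$ema_decay, global_step = 0L,
         config = train_cfg, class_weights = w)
  })
  velocity <- zero_like(state$student)
  log <- data.frame(epoch = integer(0), lr = numeric(0), wce = numeric(0),
                    cons = numeric(0), churn = numeric(0))
  prev_labeled <- NULL
  trajectory <- if (record_trajectory) list() else NULL
  set.seed(derive_seeds(train_cfg$seed, 2L)[2])
  for (epoch in seq_len(train_cfg$epochs)) {
    ## (1) teacher scores every instance, (2) pseudo-labels per bag
    scores <- encoder_score_stack(state$teacher, X)$prob
    labeled_global <- logical(N)
    y_global <- integer(N)
    for (k in seq_along(bags)) {
      idx <- bag_idx[[k]]
      pl <- assign_pseudo_labels(bags[[k]], scores[idx], prop)
      labeled_global[idx[pl$labeled]] <- TRUE
      y_global[idx[pl$labeled]] <- pl$pseudo_label
    }
    churn <- if (is.null(prev_labeled)) NA_real_ else
      mean(!(which(labeled_global) %in% prev_labeled))
    prev_labeled <- which(labeled_global)
    ## (3) student SGD over shuffled mini-batches
    perm <- sample.int(N)
    ep_wce <- 0; ep_cons <- 0; n_lab <- 0; n_unl <- 0; lr <- NA_real_
    for (s in seq.int(1L, N, by = B)) {
      bi <- perm[s:min(s + B - 1L, N)]
      nb <- length(bi)
      xb <- array(0, c(spec$input_px, spec$input_px, 3L, nb))
      for (i in seq_len(nb))
        xb[, , , i] <- augment_patch(X[, , , bi[i]], loss_cfg$augment)
      fw <- encoder_forward(state$student, xb, keep = TRUE)
      tw_prob <- encoder_forward(state$teacher, xb)$prob
      lab <- labeled_global[bi]
      y <- y_global[bi]
      p <- clip01(fw$prob)
      dlogit <- numeric(nb)
      ## weighted BCE on pseudo-labeled tiles (grad through sigmoid)
      wy <- ifelse(y == 1, w[1], w[2])
      dlogit[lab] <- (wy * (p - y))[lab] / nb
      ## consistency on unlabeled tiles: lambda (t - s)^2, d/dlogit
      if (any(!lab) && lambda > 0) {
        sm <- fw$prob[!lab]; tm <- tw_prob[!lab]
        dlogit[!lab] <- lambda * 2 * (sm - tm) * sm * (1 - sm) / nb
      }
      grads <- encoder_backward(state$student, fw$cache, dlogit)
      lr <- cosine_lr(state$global_step, train_cfg, steps_per_epoch)
      up <- sgd_step(state$student, grads, velocity, lr,
                     train_cfg$momentum)
      state$student <- up$params; velocity <- up$velocity
      state <- ema_update(state)
      if (record_trajectory)
        trajectory[[length(trajectory) + 1L]] <- state$student
      wce_b <- -sum(ifelse(y[lab] == 1, w[1] * log(p[lab]),
                           w[2] * log(1 - p[lab])))
      cons_b <- sum((tw_prob[!lab] - fw$prob[!lab])^2)
      if (!is.finite(wce_b + cons_b))
        stopf("non-finite loss at epoch %d (wce %.3g, cons %.3g)",
              epoch, wce_b, cons_b)
      ep_wce <- ep_wce + wce_b; ep_cons <- ep_cons + cons_b
      n_lab <- n_lab + sum(lab); n_unl <- n_unl + sum(!lab)
    }
    log <- rbind(log, data.frame(
      epoch = epoch, lr = lr,
      wce = ep_wce / max(1L, n_lab),
      cons = ep_cons / max(1L, n_unl), churn = churn))
    if (verbose)
      message(sprintf("epoch %d  lr %.2e  wce %.4f  cons %.2e  churn %s",
                      epoch, lr, log$wce[epoch], log$cons[epoch],
                      format(churn, digits = 3)))
  }
  state$log <- log
  if (record_trajectory) state$trajectory <- trajectory
  class(state) <- "milts_state"
  state
}
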