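## The fitted-model interface: milts() trains the full two-stage model
## on a set of labeled bags and returns a classed object with the usual
## print / summary / predict / plot methods.

#' Fit the teacher-student MIL model and slide-level classifier
#'
#' Stage one trains the teacher-student instance scorer on the bags
#' ([train_teacher_student()]); stage two extracts teacher features and
#' trimmed statistical summaries for every bag and jointly trains the
#' attention fusion block and MLP slide classifier
#' ([train_slide_model()]).
#'
#' @param bags list of [milts_bag()] with labels (both classes present).
#' @param train_cfg a [milts_train_config()].
#' @param loss_cfg a [milts_loss_config()].
#' @param slide_lr,slide_epochs learning rate and epoch cap for the
#'   slide-level stage (defaults `2e-4`, 500).
#' @param verbose print per-epoch progress.
#' @return An object of class `milts`: the teacher-student `state`, the
#'   `slide_model`, the training `log`, and the configurations.
#' @export
milts <- function(bags, train_cfg = milts_train_config(),
                  loss_cfg = milts_loss_config(),
                  slide_lr = 2e-4, slide_epochs = 500L,
                  verbose = FALSE) {
  state <- train_teacher_student(bags, train_cfg, loss_cfg,
                                 verbose = verbose)
  feats <- vector("list", length(bags))
  stats <- vector("list", length(bags))
  for (k in seq_along(bags)) {
    sc <- encoder_score_stack(state$teacher,
                              as_patch_stack(bags[[k]],
                                             train_cfg$encoder$input_px))
    feats[[k]] <- sc$feat
    stats[[k]] <- trimmed_stat_summary(sc$prob)
  }
  labels <- vapply(bags, `[[`, 0L, "label")
  slide_model <- train_slide_model(
    feats, stats, labels, d = train_cfg$encoder$d,
    lr = slide_lr, epochs = slide_epochs,
    seed = derive_seeds(train_cfg$seed + 7L, 1L))
  structure(list(state = state, slide_model = slide_model,
                 log = state$log, train_cfg = train_cfg,
                 loss_cfg = loss_cfg, n_bags = length(bags),
                 label_table = table(labels), call = match.call()),
            class = "milts")
}

#' @export
print.milts <- function(x, ...) {
  enc <- x$train_cfg$encoder
  cat("Teacher-student MIL model\n")
  cat(sprintf("  bags: %d (%s)\n", x$n_bags,
              paste(sprintf("%s: %d", names(x$label_table),
                            as.integer(x$label_table)), collapse = ", ")))
  cat(sprintf("  encoder: %s, d = %d, input %d px\n",
              enc$name, enc$d, enc$input_px))
  cat(sprintf("  epochs: %d, lambda = %g, labeled proportion = %g\n",
              x$train_cfg$epochs, x$loss_cfg$lambda,
              x$train_cfg$labeled_proportion))
  n <- nrow(x$log)
  cat(sprintf("  final epoch: wce %.4f, consistency %.3g, churn %s\n",
              x$log$wce[n], x$log$cons[n],
              format(x$log$churn[n], digits = 3)))
  invisible(x)
}

#' @export
summary.milts <- function(object, ...) {
  print(object)
  cat("\nTraining log (last 5 epochs):\n")
  print(utils::tail(object$log, 5L), row.names = FALSE)
  invisible(object)
}

#' Predict slide and tile probabilities from a fitted model
#'
#' @param object a fitted [milts()] model.
#' @param newdata a single bag/tile stack or a list of them.
#' @param type `"slide"` for slide-level probabilities, `"tile"` for
#'   per-tile typicalities, `"both"` for both.
#' @param ... unused.
#' @return For `"slide"`, a numeric vector; for `"tile"`, a list of
#'   numeric vectors; for `"both"`, a list of [predict_slide()] results.
#' @export
predict.milts <- function(object, newdata, type = c("slide", "tile", "both"),
                          ...) {
  type <- match.arg(type)
  if (inherits(newdata, "milts_bag") || !is.list(newdata) ||
      inherits(newdata, "tile"))
    newdata <- list(newdata)
  if (all(vapply(newdata, inherits, TRUE, "tile")))
    newdata <- list(newdata)
  res <- lapply(newdata, predict_slide, state = object$state,
                slide_model = object$slide_model)
  switch(type,
         slide = vapply(res, `[[`, 0, "slide_prob"),
         tile = lapply(res, `[[`, "tile_probs"),
         both = res)
}

#' Plot training diagnostics of a fitted model
#'
#' Four panels: weighted cross-entropy, consistency cost, learning rate
#' and pseudo-label churn per epoch.
#'
#' @param x a fitted [milts()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.milts <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(log$epoch, log$wce, type = "b", xlab = "epoch",
                 ylab = "weighted CE", main = "classification cost", ...)
  graphics::plot(log$epoch, log$cons, type = "b", xlab = "epoch",
                 ylab = "consistency", main = "consistency cost", ...)
  graphics::plot(log$epoch, log$lr, type = "l", xlab = "epoch",
                 ylab = "learning rate", main = "cosine schedule", ...)
  graphics::plot(log$epoch, log$churn, type = "b", xlab = "epoch",
                 ylab = "churn", main = "pseudo-label churn", ...)
  invisible(x)
}
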