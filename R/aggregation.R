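## Slide-level aggregation: trimmed statistical summary of tile
## probabilities, self-attention fusion of tile features into a class
## token, and the MLP slide classifier.

#' Trimmed statistical summary of tile probabilities
#'
#' Tiles with typicality above 0.8 or below 0.2 are removed before
#' summarizing, so the features reflect the central tendency of the
#' ambiguous tiles; if nothing survives the trim, the untrimmed list is
#' used.  The 11 features are: the fraction of (trimmed) tiles with
#' probability above 0.5, an 8-bin normalized histogram over the trimmed
#' support `[0.2, 0.8]` (over `[0, 1]` in the fallback), and the median
#' and mean.
#'
#' @param probs non-empty numeric vector of probabilities in `[0, 1]`.
#' @return Named numeric vector of length 11 (`positive_fraction`,
#'   `hist1`..`hist8`, `median`, `mean`).
#' @export
trimmed_stat_summary <- function(probs) {
  if (length(probs) == 0L) stopf("no probabilities supplied")
  keep <- probs >= 0.2 & probs <= 0.8
  if (any(keep)) {
    s <- probs[keep]
    support <- c(0.2, 0.8)
  } else {
    s <- probs
    support <- c(0, 1)
  }
  breaks <- seq(support[1], support[2], length.out = 9L)
  cnt <- tabulate(cut(pmin(pmax(s, support[1]), support[2]), breaks,
                      include.lowest = TRUE, labels = FALSE), nbins = 8L)
  h <- cnt / sum(cnt)
  setNames(c(mean(s > 0.5), h, median(s), mean(s)),
           c("positive_fraction", paste0("hist", 1:8), "median", "mean"))
}

#' Initialize the self-attention fusion block
#'
#' One multi-head self-attention layer with a learnable class token and
#' layer normalization, the minimal structure producing a slide token
#' from a set of tile features.  No positional encoding is used, so the
#' fused token is invariant to tile order.
#'
#' @param d feature dimension.
#' @param n_heads number of attention heads (must divide `d`); defaults
#'   to 8 for `d >= 512` and 2 otherwise.
#' @param seed RNG seed for the initialization.
#' @return An object of class `milts_fusion` (parameter list).
#' @export
init_fusion <- function(d, n_heads = if (d >= 512L) 8L else 2L,
                        seed = 1L) {
  d <- as.integer(d)
  if (d %% n_heads != 0L) stopf("n_heads must divide d")
  with_seed(seed, {
    mat <- function() matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d)
    structure(list(Wq = mat(), Wk = mat(), Wv = mat(), Wo = mat(),
                   bo = numeric(d), g = rep(1, d), b = numeric(d),
                   cls = rnorm(d, sd = 0.02),
                   d = d, n_heads = as.integer(n_heads)),
              class = "milts_fusion")
  })
}

#' Fuse tile features into a slide token
#'
#' Prepends the learnable class token to the tile feature sequence,
#' applies one multi-head self-attention block followed by layer
#' normalization, and returns the first output row (the class token).
#'
#' @param features `m x d` matrix of tile features (rows are tiles), or
#'   a list of equal-length numeric vectors.
#' @param fusion an [init_fusion()] parameter set.
#' @return Numeric vector of length `d`.
#' @export
fuse_token <- function(features, fusion) {
  fusion_forward(fusion, as_feature_matrix(features, fusion$d))$token
}

as_feature_matrix <- function(features, d) {
  if (is.list(features)) {
    len <- vapply(features, length, 0L)
    if (length(unique(len)) != 1L)
      stopf("tile features have inconsistent lengths")
    features <- do.call(rbind, features)
  }
  if (ncol(features) != d)
    stopf("feature dimension %d does not match fusion d = %d",
          ncol(features), d)
  if (nrow(features) < 1L) stopf("need at least one tile feature")
  features
}

## Forward pass; only the class-token row of the attention output is
## needed downstream, so the per-head computation is restricted to the
## first query row.
fusion_forward <- function(fu, E) {
  d <- fu$d; nh <- fu$n_heads; dh <- d %/% nh
  Z <- rbind(fu$cls, E)
  q1 <- drop(fu$cls %*% fu$Wq)
  K <- Z %*% fu$Wk
  V <- Z %*% fu$Wv
  o <- numeric(d); att <- vector("list", nh)
  for (j in seq_len(nh)) {
    cols <- ((j - 1L) * dh + 1L):(j * dh)
    sc <- drop(K[, cols] %*% q1[cols]) / sqrt(dh)
    sc <- sc - max(sc)
    a <- exp(sc); a <- a / sum(a)
    o[cols] <- drop(a %*% V[, cols])
    att[[j]] <- a
  }
  u <- drop(o %*% fu$Wo) + fu$bo
  mu <- mean(u); v <- mean((u - mu)^2); sdv <- sqrt(v + 1e-5)
  xhat <- (u - mu) / sdv
  token <- fu$g * xhat + fu$b
  list(token = token,
       cache = list(Z = Z, q1 = q1, K = K, V = V, o = o, att = att,
                    u = u, xhat = xhat, sdv = sdv))
}

## Backward pass: gradient of a scalar loss wrt the fusion parameters,
## given d(loss)/d(token).  Tile features are treated as fixed inputs.
fusion_backward <- function(fu, cache, dtoken) {
  d <- fu$d; nh <- fu$n_heads; dh <- d %/% nh
  g <- list()
  g$g <- dtoken * cache$xhat
  g$b <- dtoken
  dxhat <- dtoken * fu$g
  du <- (dxhat - mean(dxhat) - cache$xhat * mean(dxhat * cache$xhat)) /
    cache$sdv
  g$Wo <- outer(cache$o, du)
  g$bo <- du
  do <- drop(fu$Wo %*% du)
  Z <- cache$Z
  dWq <- matrix(0, d, d); dWk <- matrix(0, d, d); dWv <- matrix(0, d, d)
  dcls <- numeric(d)
  dq1 <- numeric(d)
  for (j in seq_len(nh)) {
    cols <- ((j - 1L) * dh + 1L):(j * dh)
    a <- cache$att[[j]]
    doj <- do[cols]
    da <- drop(cache$V[, cols] %*% doj)
    ds <- a * (da - sum(da * a))
    ds <- ds / sqrt(dh)
    dq1[cols] <- drop(ds %*% cache$K[, cols])
    dK <- outer(ds, cache$q1[cols])        # (m+1) x dh
    dV <- outer(a, doj)
    dWk[, cols] <- dWk[, cols] + t(Z) %*% dK
    dWv[, cols] <- dWv[, cols] + t(Z) %*% dV
    dcls <- dcls + drop(fu$Wk[, cols] %*% dK[1, ]) +
      drop(fu$Wv[, cols] %*% dV[1, ])
  }
  g$Wq <- outer(fu$cls, dq1)
  dcls <- dcls + drop(fu$Wq %*% dq1)
  g$Wk <- dWk; g$Wv <- dWv; g$cls <- dcls
  g
}

#' Concatenate the fused token and statistical summary
#'
#' The slide embedding is `[token || stats]`: the first `d` entries are
#' the class token, the last 11 the trimmed statistical summary (523
#' total for the full-scale `d = 512` encoder).
#'
#' @param token numeric vector of length `d`.
#' @param stats length-11 summary from [trimmed_stat_summary()].
#' @return Numeric vector of length `d + 11`.
#' @export
build_embedding <- function(token, stats) {
  if (length(stats) != 11L)
    stopf("stats must have length 11, got %d", length(stats))
  c(unname(token), unname(stats))
}

## ---- MLP classifier -------------------------------------------------

init_mlp <- function(in_dim, hidden = c(256L, 64L), seed = 1L) {
  dims <- c(in_dim, hidden, 2L)
  with_seed(seed, {
    p <- list()
    for (l in seq_len(length(dims) - 1L)) {
      p[[paste0("W", l)]] <- matrix(
        rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
        dims[l], dims[l + 1])
      p[[paste0("b", l)]] <- numeric(dims[l + 1])
    }
    p$n_layers <- length(dims) - 1L
    p
  })
}

mlp_forward <- function(p, v, keep = FALSE) {
  h <- list(matrix(v, nrow = 1L))
  for (l in seq_len(p$n_layers)) {
    z <- h[[l]] %*% p[[paste0("W", l)]]
    z <- sweep(z, 2L, p[[paste0("b", l)]], `+`)
    h[[l + 1L]] <- if (l < p$n_layers) z * (z > 0) else z
  }
  logits <- drop(h[[p$n_layers + 1L]])
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  out <- list(probs = probs, logits = logits)
  if (keep) out$h <- h
  out
}

## Backward from d(loss)/d(logits); returns grads and d(loss)/d(input).
mlp_backward <- function(p, h, dlogits) {
  g <- list()
  delta <- matrix(dlogits, nrow = 1L)
  for (l in rev(seq_len(p$n_layers))) {
    g[[paste0("W", l)]] <- t(h[[l]]) %*% delta
    g[[paste0("b", l)]] <- drop(delta)
    dprev <- delta %*% t(p[[paste0("W", l)]])
    if (l > 1L) delta <- dprev * (h[[l]] > 0)
  }
  list(grads = g, dinput = drop(dprev))
}

#' Train the slide-level MLP classifier on fixed embeddings
#'
#' A two-hidden-layer perceptron (`(d+11) -> 256 -> 64 -> 2`, ReLU)
#' trained with full-batch SGD on the cross-entropy.  Embedding columns
#' are standardized (the scaler is stored for prediction).
#'
#' @param embeddings `n x (d+11)` matrix (rows are slides) or a list of
#'   [build_embedding()] vectors.
#' @param labels 0/1 slide labels; both classes required.
#' @param lr learning rate (default `2e-4`).
#' @param epochs epoch cap (default 500).
#' @param momentum SGD momentum.
#' @param seed initialization seed.
#' @return An object of class `milts_classifier` with a
#'   [predict_embedding()] method.
#' @export
train_slide_classifier <- function(embeddings, labels, lr = 2e-4,
                                   epochs = 500L, momentum = 0.9,
                                   seed = 1L) {
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("slide classifier needs both classes in training data")
  ctr <- colMeans(embeddings)
  scl <- apply(embeddings, 2L, sd); scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(embeddings, 2L, ctr), 2L, scl, `/`)
  p <- init_mlp(ncol(Xs), seed = seed)
  vel <- zero_like(p[names(p) != "n_layers"])
  n <- nrow(Xs)
  for (ep in seq_len(epochs)) {
    acc <- NULL
    for (i in seq_len(n)) {
      fw <- mlp_forward(p, Xs[i, ], keep = TRUE)
      dlogits <- fw$probs; dlogits[labels[i] + 1L] <-
        dlogits[labels[i] + 1L] - 1
      bk <- mlp_backward(p, fw$h, dlogits / n)
      acc <- if (is.null(acc)) bk$grads else
        mapply(`+`, acc, bk$grads, SIMPLIFY = FALSE)
    }
    up <- sgd_step(p[names(acc)], acc, vel, lr, momentum)
    p[names(acc)] <- up$params; vel <- up$velocity
  }
  structure(list(mlp = p, center = ctr, scale = scl),
            class = "milts_classifier")
}

#' Class-1 probability of embeddings under a trained classifier
#'
#' @param clf a [train_slide_classifier()] result.
#' @param embeddings matrix or single embedding vector.
#' @return Numeric vector of probabilities.
#' @export
predict_embedding <- function(clf, embeddings) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  Xs <- sweep(sweep(embeddings, 2L, clf$center), 2L, clf$scale, `/`)
  vapply(seq_len(nrow(Xs)),
         function(i) mlp_forward(clf$mlp, Xs[i, ])$probs[2L], 0)
}

#' Jointly train the fusion block and slide classifier
#'
#' The class token, attention weights, layer norm and MLP are optimized
#' together by full-batch SGD on the cross-entropy over slides, with the
#' tile features and statistical summaries held fixed.  The 11
#' statistical features are standardized; the token passes through layer
#' normalization and is used as-is.
#'
#' @param features_by_slide list of `m_i x d` tile-feature matrices.
#' @param stats_by_slide list (or `n x 11` matrix) of summaries from
#'   [trimmed_stat_summary()].
#' @param labels 0/1 slide labels.
#' @param d feature dimension.
#' @param lr learning rate (default `2e-4`).
#' @param epochs epoch cap (default 500).
#' @param momentum SGD momentum.
#' @param seed initialization seed.
#' @return An object of class `milts_slide_model` (fusion + MLP +
#'   stat scaler).
#' @export
train_slide_model <- function(features_by_slide, stats_by_slide, labels,
                              d, lr = 2e-4, epochs = 500L,
                              momentum = 0.9, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("slide model needs both classes in training data")
  if (is.list(stats_by_slide))
    stats_by_slide <- do.call(rbind, stats_by_slide)
  ctr <- colMeans(stats_by_slide)
  scl <- apply(stats_by_slide, 2L, sd); scl[scl < 1e-8] <- 1
  S <- sweep(sweep(stats_by_slide, 2L, ctr), 2L, scl, `/`)
  seeds <- derive_seeds(seed, 2L)
  fu <- init_fusion(d, seed = seeds[1])
  mlp <- init_mlp(d + 11L, seed = seeds[2])
  fu_names <- c("Wq", "Wk", "Wv", "Wo", "bo", "g", "b", "cls")
  vel_fu <- zero_like(fu[fu_names])
  vel_mlp <- zero_like(mlp[names(mlp) != "n_layers"])
  n <- length(features_by_slide)
  for (ep in seq_len(epochs)) {
    acc_fu <- NULL; acc_mlp <- NULL
    for (i in seq_len(n)) {
      fw_f <- fusion_forward(fu, features_by_slide[[i]])
      v <- c(fw_f$token, S[i, ])
      fw_m <- mlp_forward(mlp, v, keep = TRUE)
      dlogits <- fw_m$probs
      dlogits[labels[i] + 1L] <- dlogits[labels[i] + 1L] - 1
      bk_m <- mlp_backward(mlp, fw_m$h, dlogits / n)
      bk_f <- fusion_backward(fu, fw_f$cache, bk_m$dinput[seq_len(d)])
      acc_mlp <- if (is.null(acc_mlp)) bk_m$grads else
        mapply(`+`, acc_mlp, bk_m$grads, SIMPLIFY = FALSE)
      acc_fu <- if (is.null(acc_fu)) bk_f[fu_names] else
        mapply(`+`, acc_fu, bk_f[fu_names], SIMPLIFY = FALSE)
    }
    up <- sgd_step(mlp[names(acc_mlp)], acc_mlp, vel_mlp, lr, momentum)
    mlp[names(acc_mlp)] <- up$params; vel_mlp <- up$velocity
    up <- sgd_step(fu[fu_names], acc_fu, vel_fu, lr, momentum)
    fu[fu_names] <- up$params; vel_fu <- up$velocity
  }
  structure(list(fusion = fu, mlp = mlp, stat_center = ctr,
                 stat_scale = scl, d = d),
            class = "milts_slide_model")
}

predict_slide_model <- function(model, features, stats) {
  token <- fuse_token(features, model$fusion)
  s <- (unname(stats) - model$stat_center) / model$stat_scale
  mlp_forward(model$mlp, c(token, s))$probs[2L]
}

#' Slide-level prediction from tiles
#'
#' Scores every tile with the (teacher) instance model, fuses the tile
#' features into a slide token, summarizes the tile probabilities, and
#' classifies the resulting embedding.
#'
#' @param tiles tile stack, bag, or list of tiles with patches.
#' @param state a trained `milts_state` from [train_teacher_student()].
#' @param slide_model a [train_slide_model()] result.
#' @return List with `slide_prob` (scalar) and `tile_probs`.
#' @export
predict_slide <- function(tiles, state, slide_model) {
  X <- as_patch_stack(tiles, state$config$encoder$input_px)
  if (dim(X)[4] < 1L) stopf("no tiles to predict from")
  sc <- encoder_score_stack(state$teacher, X)
  stats <- trimmed_stat_summary(sc$prob)
  list(slide_prob = predict_slide_model(slide_model, sc$feat, stats),
       tile_probs = sc$prob)
}
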