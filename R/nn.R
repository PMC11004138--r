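## Tile encoder: a compact 3-block convolutional network.  Each block is
## a 3x3 same-padded convolution, ReLU, and 2x2 average pooling; global
## average pooling yields the d-dimensional tile feature and a linear
## head with a sigmoid yields the typicality score in [0, 1].

#' Describe the tile encoder architecture
#'
#' A three-block convolutional encoder whose feature dimension `d`
#' equals the width of the last block.  Tiles are bilinearly resized to
#' `input_px` before entering the network; with three 2x2 poolings the
#' spatial footprint at the head is `input_px / 8`.  The compact default
#' (`d = 32`, 32-px input) trains in minutes on one CPU; wider settings
#' (e.g. `d = 512`) reproduce the full-scale embedding dimension.
#'
#' @param d feature dimension (>= 8); equals the last block width.
#' @param input_px side of the resized input fed to the network
#'   (multiple of 8).
#' @param channels widths of the three blocks; the last must equal `d`.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(d = 32L, input_px = 32L,
                         channels = c(16L, 32L, d)) {
  d <- as.integer(d); input_px <- as.integer(input_px)
  channels <- as.integer(channels)
  if (d < 8L) stopf("encoder feature dimension d must be >= 8")
  if (length(channels) != 3L || channels[3] != d)
    stopf("channels must be three block widths ending in d")
  if (input_px %% 8L != 0L) stopf("input_px must be a multiple of 8")
  structure(list(name = "cnn3", d = d, input_px = input_px,
                 channels = channels),
            class = "encoder_spec")
}

## He-normal initialization of all encoder parameters.
init_encoder <- function(spec, seed = 1L) {
  ch <- c(3L, spec$channels)
  with_seed(seed, {
    params <- list()
    for (b in 1:3) {
      fan_in <- 9 * ch[b]
      params[[paste0("W", b)]] <- array(
        rnorm(9 * ch[b] * ch[b + 1], sd = sqrt(2 / fan_in)),
        dim = c(3L, 3L, ch[b], ch[b + 1]))
      params[[paste0("b", b)]] <- numeric(ch[b + 1])
    }
    ## The typicality head starts at zero so every tile scores exactly
    ## 0.5 before training: the first max-min selection is then
    ## uninformative instead of following an arbitrary random
    ## projection, which can otherwise lock the teacher-student loop
    ## into a polarity-inverted scorer.
    params$head_w <- matrix(0, spec$d, 1L)
    params$head_b <- 0
    params
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## One same-padded 3x3 convolution through im2col + BLAS GEMM.  The
## column matrix row order is (ho, wo, n); reshaping the GEMM result to
## (Ho, Wo, N, Co) and permuting recovers the (H, W, C, N) layout.
conv_gemm_fwd <- function(X, K, b) {
  dk <- dim(K)
  dx <- dim(X)
  Xcol <- im2col(X, dk[1], dk[2], 1L)
  Y <- Xcol %*% matrix(K, dk[1] * dk[2] * dk[3], dk[4])
  Y <- Y + rep(b, each = nrow(Y))
  out <- aperm(array(Y, c(dx[1], dx[2], dx[4], dk[4])), c(1, 2, 4, 3))
  list(out = out, Xcol = Xcol)
}

conv_gemm_bwd <- function(Xcol, K, dY) {
  dk <- dim(K)
  dm <- dim(dY)
  dYmat <- matrix(aperm(dY, c(1, 2, 4, 3)), dm[1] * dm[2] * dm[4], dm[3])
  list(dW = array(crossprod(Xcol, dYmat), dk),
       db = colSums(dYmat),
       dX = col2im_add(
         tcrossprod(dYmat, matrix(K, dk[1] * dk[2] * dk[3], dk[4])),
         dm[1], dm[2], dk[3], dm[4], dk[1], dk[2], 1L))
}

## Forward pass over a batch X (h, w, 3, N).  Returns features (N x d),
## probabilities (N) and, when keep = TRUE, the cache for backprop.
encoder_forward <- function(params, X, keep = FALSE) {
  c1 <- conv_gemm_fwd(X, params$W1, params$b1)
  a1 <- c1$out * (c1$out > 0)
  p1 <- avgpool2_fwd(a1)
  c2 <- conv_gemm_fwd(p1, params$W2, params$b2)
  a2 <- c2$out * (c2$out > 0)
  p2 <- avgpool2_fwd(a2)
  c3 <- conv_gemm_fwd(p2, params$W3, params$b3)
  a3 <- c3$out * (c3$out > 0)
  p3 <- avgpool2_fwd(a3)
  dm <- dim(p3)                      # (s, s, d, N)
  feat <- t(matrix(colMeans(matrix(p3, dm[1] * dm[2], dm[3] * dm[4])),
                   dm[3], dm[4]))    # N x d
  logit <- drop(feat %*% params$head_w) + params$head_b
  prob <- sigmoid(logit)
  out <- list(feat = feat, prob = prob, logit = logit)
  if (keep)
    out$cache <- list(z1 = c1$out, x1 = c1$Xcol, z2 = c2$out,
                      x2 = c2$Xcol, z3 = c3$out, x3 = c3$Xcol,
                      p3dim = dm, feat = feat)
  out
}

## Backward pass given d(loss)/d(logit) per instance (length N).
## Returns gradients with the same shapes as params.
encoder_backward <- function(params, cache, dlogit) {
  feat <- cache$feat
  g <- list()
  g$head_w <- t(feat) %*% matrix(dlogit, ncol = 1L)
  g$head_b <- sum(dlogit)
  dfeat <- matrix(dlogit, ncol = 1L) %*% t(params$head_w)  # N x d
  dm <- cache$p3dim
  ## spread the global-average-pool gradient over the spatial footprint
  dp3 <- array(rep(t(dfeat) / (dm[1] * dm[2]),
                   each = dm[1] * dm[2]), dim = dm)
  da3 <- avgpool2_bwd(dp3, dm[1] * 2L, dm[2] * 2L)
  dz3 <- da3 * (cache$z3 > 0)
  b3 <- conv_gemm_bwd(cache$x3, params$W3, dz3)
  g$W3 <- b3$dW; g$b3 <- b3$db
  da2 <- avgpool2_bwd(b3$dX, dim(cache$z2)[1], dim(cache$z2)[2])
  dz2 <- da2 * (cache$z2 > 0)
  b2 <- conv_gemm_bwd(cache$x2, params$W2, dz2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- avgpool2_bwd(b2$dX, dim(cache$z1)[1], dim(cache$z1)[2])
  dz1 <- da1 * (cache$z1 > 0)
  b1 <- conv_gemm_bwd(cache$x1, params$W1, dz1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

## SGD with classical momentum: v <- mu v - lr g; theta <- theta + v.
sgd_step <- function(params, grads, velocity, lr, momentum = 0.9) {
  for (nm in names(grads)) {
    velocity[[nm]] <- momentum * velocity[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + velocity[[nm]]
  }
  list(params = params, velocity = velocity)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

## Batched scoring of a (h, w, 3, N) stack; returns features and probs.
encoder_score_stack <- function(params, X, batch = 256L) {
  N <- dim(X)[4]
  feats <- NULL; probs <- numeric(N)
  for (s in seq.int(1L, N, by = batch)) {
    e <- min(s + batch - 1L, N)
    fw <- encoder_forward(params, X[, , , s:e, drop = FALSE])
    if (is.null(feats)) feats <- matrix(0, N, ncol(fw$feat))
    feats[s:e, ] <- fw$feat
    probs[s:e] <- fw$prob
  }
  list(feat = feats, prob = probs)
}
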