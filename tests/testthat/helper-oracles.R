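# Independent reference implementations used as oracles, plus small
# fixture builders.  These deliberately use the dumbest correct
# algorithm (flood fill, O(n^2) pair counting, exhaustive search) and
# share no code with the package internals.

# Queue-based flood fill hysteresis on a response matrix.
ref_hysteresis <- function(resp, low, high) {
  out <- matrix(FALSE, nrow(resp), ncol(resp))
  queue <- which(resp >= high)
  out[queue] <- TRUE
  nr <- nrow(resp)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    i <- (cur - 1) %% nr + 1; j <- (cur - 1) %/% nr + 1
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > ncol(resp)) next
      nb <- (jj - 1) * nr + ii
      if (!out[nb] && resp[nb] >= low) {
        out[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  out
}

# Pairwise concordance AUC (ties count one half).
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden search returning the smallest maximizer.
ref_youden <- function(scores, labels) {
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  best_t
}

# A flat-colored test patch.
flat_patch <- function(side = 32, col = c(0.8, 0.6, 0.7)) {
  array(rep(col, each = side * side), dim = c(side, side, 3))
}

# Tiny bags with a plantable dark-tile signal: positive bags carry
# `n_dark` dark instances, all others are light with mild noise.
tiny_bags <- function(n_bags = 4, n_inst = 6, side = 16, n_dark = 2,
                      seed = 99) {
  withr::with_seed(seed, {
    lapply(seq_len(n_bags), function(k) {
      lab <- as.integer(k %% 2 == 0)
      patches <- array(0, c(side, side, 3, n_inst))
      for (i in seq_len(n_inst)) {
        base <- if (lab == 1 && i <= n_dark) 0.25 else 0.8
        patches[, , , i] <- base + runif(side * side * 3, -0.05, 0.05)
      }
      milts_bag(sprintf("bag%d", k), patches, lab)
    })
  })
}
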