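# Minimal convolutional network, implemented directly on matrices.
#
# Feature maps are stored as matrices of shape (H*W, C*N): pixel index
# (column-major within the H x W map) varies fastest, then channel, then
# sample.  Convolutions use an im2col lowering with zero padding of one
# pixel ('same' 3x3 convolution); 2x2 max pooling and global average
# pooling complete the blocks.  Training is plain SGD with momentum.
# Everything is deterministic given the seed.

# --- plans -----------------------------------------------------------------

# im2col plan for a 'same' 3x3 convolution on H x W maps with C channels
conv_plan <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  # linear indices (within one sample) of original pixels in the padded array
  grid <- expand.grid(i = seq_len(H), j = seq_len(W), c = seq_len(C))
  pad_pos <- (grid$c - 1L) * Hp * Wp + (grid$j) * Hp + (grid$i + 1L)
  # rows of the lowered matrix: offset (da, db) fastest, then channel
  offs <- expand.grid(da = -1:1, db = -1:1)
  K <- 9L * C
  out <- expand.grid(i = seq_len(H), j = seq_len(W))
  idx <- matrix(0L, K, H * W)
  r <- 0L
  for (c in seq_len(C)) {
    for (k in seq_len(9L)) {
      r <- r + 1L
      ii <- out$i + offs$da[k] + 1L   # padded row coord
      jj <- out$j + offs$db[k] + 1L   # padded col coord
      idx[r, ] <- (c - 1L) * Hp * Wp + (jj - 1L) * Hp + ii
    }
  }
  list(H = H, W = W, C = C, Hp = Hp, Wp = Wp, K = K,
       pad_pos = pad_pos, idx = idx, idx_vec = as.vector(idx))
}

# 2x2 max-pooling plan on H x W maps (H, W even)
pool_plan <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  out <- expand.grid(io = seq_len(Ho), jo = seq_len(Wo))
  lin <- function(i, j) (j - 1L) * H + i
  list(Ho = Ho, Wo = Wo,
       i1 = lin(2L * out$io - 1L, 2L * out$jo - 1L),
       i2 = lin(2L * out$io,      2L * out$jo - 1L),
       i3 = lin(2L * out$io - 1L, 2L * out$jo),
       i4 = lin(2L * out$io,      2L * out$jo))
}

# --- layers ----------------------------------------------------------------

# X: (H*W*C, N) -> list(out = (HW, F*N) pre-activation, cols cache)
conv_forward <- function(X, Wt, b, plan, N) {
  Xp <- matrix(0, plan$Hp * plan$Wp * plan$C, N)
  Xp[plan$pad_pos, ] <- X
  cols <- Xp[plan$idx_vec, , drop = FALSE]
  dim(cols) <- c(plan$K, plan$H * plan$W * N)
  Z <- Wt %*% cols + b
  Zarr <- array(Z, c(nrow(Wt), plan$H * plan$W, N))
  out <- aperm(Zarr, c(2L, 1L, 3L))
  dim(out) <- c(plan$H * plan$W, nrow(Wt) * N)
  list(out = out, cols = cols)
}

# dOut: (HW, F*N) -> gradients and dX (H*W*C, N)
conv_backward <- function(dOut, cols, Wt, plan, N) {
  F_ <- nrow(Wt)
  dZ <- array(dOut, c(plan$H * plan$W, F_, N))
  dZ <- aperm(dZ, c(2L, 1L, 3L))
  dim(dZ) <- c(F_, plan$H * plan$W * N)
  dW <- dZ %*% t(cols)
  db <- rowSums(dZ)
  dcols <- crossprod(Wt, dZ)            # (K, HW*N)
  dim(dcols) <- c(plan$K, plan$H * plan$W, N)
  dXp <- matrix(0, plan$Hp * plan$Wp * plan$C, N)
  for (r in seq_len(plan$K)) {
    tgt <- plan$idx[r, ]
    dXp[tgt, ] <- dXp[tgt, ] + matrix(dcols[r, , ], plan$H * plan$W, N)
  }
  list(dW = dW, db = db, dX = dXp[plan$pad_pos, , drop = FALSE])
}

maxpool_forward <- function(Y, plan) {
  A1 <- Y[plan$i1, , drop = FALSE]
  A2 <- Y[plan$i2, , drop = FALSE]
  A3 <- Y[plan$i3, , drop = FALSE]
  A4 <- Y[plan$i4, , drop = FALSE]
  P <- pmax(A1, A2, A3, A4)
  list(out = P, A = list(A1, A2, A3, A4))
}

maxpool_backward <- function(dP, fw, plan, nrow_in) {
  dY <- matrix(0, nrow_in, ncol(dP))
  rem <- dP
  idx <- list(plan$i1, plan$i2, plan$i3, plan$i4)
  P <- fw$out
  for (k in 1:4) {
    # route gradient to the first argmax only
    g <- rem * (fw$A[[k]] == P)
    dY[idx[[k]], ] <- dY[idx[[k]], ] + g
    rem <- rem - g
  }
  dY
}

softmax_cols <- function(L) {
  L <- sweep(L, 2L, apply(L, 2L, max))
  E <- exp(L)
  sweep(E, 2L, colSums(E), "/")
}

# --- network ---------------------------------------------------------------

init_small_cnn <- function(filters = c(8L, 16L, 32L), n_classes = 3L,
                           input_side = 32L) {
  stopifnot(input_side %% 8L == 0L)
  F1 <- filters[1]; F2 <- filters[2]; F3 <- filters[3]
  he <- function(nr, nc, fanin) matrix(stats::rnorm(nr * nc, 0,
                                                    sqrt(2 / fanin)), nr, nc)
  s <- input_side
  list(params = list(W1 = he(F1, 9L, 9L), b1 = rep(0, F1),
                     W2 = he(F2, 9L * F1, 9L * F1), b2 = rep(0, F2),
                     W3 = he(F3, 9L * F2, 9L * F2), b3 = rep(0, F3),
                     V = he(n_classes, F3, F3), cv = rep(0, n_classes)),
       plans = list(c1 = conv_plan(s, s, 1L),
                    p1 = pool_plan(s, s),
                    c2 = conv_plan(s %/% 2L, s %/% 2L, F1),
                    p2 = pool_plan(s %/% 2L, s %/% 2L),
                    c3 = conv_plan(s %/% 4L, s %/% 4L, F2),
                    p3 = pool_plan(s %/% 4L, s %/% 4L)),
       filters = c(F1, F2, F3), n_classes = n_classes, input_side = s)
}

# forward pass; X: (side^2, N).  Returns probabilities and, if `cache`,
# the intermediates needed for backprop.
cnn_forward <- function(net, X, cache = FALSE) {
  p <- net$params; pl <- net$plans
  N <- ncol(X)
  c1 <- conv_forward(X, p$W1, p$b1, pl$c1, N)
  a1 <- pmax(c1$out, 0)
  m1 <- maxpool_forward(a1, pl$p1)
  x2 <- m1$out; dim(x2) <- c(pl$p1$Ho * pl$p1$Wo * net$filters[1], N)
  c2 <- conv_forward(x2, p$W2, p$b2, pl$c2, N)
  a2 <- pmax(c2$out, 0)
  m2 <- maxpool_forward(a2, pl$p2)
  x3 <- m2$out; dim(x3) <- c(pl$p2$Ho * pl$p2$Wo * net$filters[2], N)
  c3 <- conv_forward(x3, p$W3, p$b3, pl$c3, N)
  a3 <- pmax(c3$out, 0)
  m3 <- maxpool_forward(a3, pl$p3)
  hw3 <- pl$p3$Ho * pl$p3$Wo
  G <- matrix(colMeans(m3$out), net$filters[3], N)
  L <- p$V %*% G + p$cv
  probs <- softmax_cols(L)
  if (!cache) return(list(probs = probs))
  list(probs = probs, G = G, m3 = m3, a3 = a3, c3 = c3, x3 = x3,
       m2 = m2, a2 = a2, c2 = c2, x2 = x2, m1 = m1, a1 = a1, c1 = c1,
       hw3 = hw3, N = N)
}

# cross-entropy gradient for one mini-batch; Y: one-hot (K, N)
cnn_backward <- function(net, fw, Y) {
  p <- net$params; pl <- net$plans
  N <- fw$N
  dL <- (fw$probs - Y) / N
  dV <- dL %*% t(fw$G)
  dcv <- rowSums(dL)
  dG <- crossprod(p$V, dL)
  dP3 <- matrix(as.vector(dG), fw$hw3, net$filters[3] * N,
                byrow = TRUE) / fw$hw3
  dA3 <- maxpool_backward(dP3, fw$m3, pl$p3, nrow(fw$a3))
  dC3 <- dA3 * (fw$c3$out > 0)
  g3 <- conv_backward(dC3, fw$c3$cols, p$W3, pl$c3, N)
  dX3 <- g3$dX; dim(dX3) <- c(pl$p2$Ho * pl$p2$Wo, net$filters[2] * N)
  dA2 <- maxpool_backward(dX3, fw$m2, pl$p2, nrow(fw$a2))
  dC2 <- dA2 * (fw$c2$out > 0)
  g2 <- conv_backward(dC2, fw$c2$cols, p$W2, pl$c2, N)
  dX2 <- g2$dX; dim(dX2) <- c(pl$p1$Ho * pl$p1$Wo, net$filters[1] * N)
  dA1 <- maxpool_backward(dX2, fw$m1, pl$p1, nrow(fw$a1))
  dC1 <- dA1 * (fw$c1$out > 0)
  g1 <- conv_backward(dC1, fw$c1$cols, p$W1, pl$c1, N)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, V = dV, cv = dcv)
}

cnn_loss <- function(net, X, Y) {
  probs <- cnn_forward(net, X)$probs
  -mean(colSums(Y * log(pmax(probs, 1e-12))))
}

# SGD with momentum; X: (side^2, N), y: integer labels 1..K
cnn_train <- function(net, X, y, epochs = 30L, batch_size = 32L,
                      learning_rate = 0.05, momentum = 0.9,
                      weight_decay = 1e-4) {
  K <- net$n_classes
  N <- ncol(X)
  Y <- matrix(0, K, N)
  Y[cbind(y, seq_len(N))] <- 1
  vel <- lapply(net$params, function(w) w * 0)
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(N)
    tot <- 0
    for (start in seq(1L, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, N)]
      fw <- cnn_forward(net, X[, idx, drop = FALSE], cache = TRUE)
      gr <- cnn_backward(net, fw, Y[, idx, drop = FALSE])
      for (nm in names(net$params)) {
        g <- gr[[nm]]
        if (is.matrix(net$params[[nm]]))
          g <- g + weight_decay * net$params[[nm]]
        vel[[nm]] <- momentum * vel[[nm]] - learning_rate * g
        net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
      }
      tot <- tot - sum(log(pmax(fw$probs[cbind(y[idx],
                                               seq_along(idx))], 1e-12)))
    }
    losses[e] <- tot / N
    if (!is.finite(losses[e]))
      stop("non-finite training loss at epoch ", e,
           " (learning rate too high?)")
  }
  net$losses <- losses
  net
}
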