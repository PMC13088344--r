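# Compact convolutional regressor for spectrogram inputs.
#
# Architecture (per input channel, trunks not shared): two 3x3 "same"
# convolution blocks (16 then 32 filters, ReLU, 2x2 average pooling) -> flatten
# -> concatenate channels -> dense 64 (ReLU) -> dense 1 with softplus output
# so predictions are non-negative. Trained with Adam on mean squared error.
#
# Convolutions are evaluated as im2col matrix products. Activations are kept
# as (N * n_positions) x n_filters matrices with row index
# (position - 1) * N + sample; all gather/scatter index vectors are
# precomputed once per grid and batch size.

# --- geometry ------------------------------------------------------------

# Position maps for a H x W grid with 1-pixel zero padding: `interior` maps
# grid positions into the padded grid, `offsets[[j]]` maps each output
# position to the padded position of the j-th 3x3 patch element.
conv_geom <- function(H, W) {
  Hp <- H + 2L
  h <- rep(seq_len(H), W)
  w <- rep(seq_len(W), each = H)
  interior <- w * Hp + h + 1L # (w+1-1)*Hp + (h+1)
  offsets <- list()
  j <- 0L
  for (dw in -1:1) for (dh in -1:1) {
    j <- j + 1L
    offsets[[j]] <- (w + dw) * Hp + (h + dh) + 1L
  }
  list(H = H, W = W, Hp = Hp, Wp = W + 2L, interior = interior,
       offsets = offsets)
}

# 2x2 max-pool corner position maps (floor semantics: trailing odd row/col
# dropped).
pool_geom <- function(H, W) {
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  h2 <- rep(seq_len(H2), W2)
  w2 <- rep(seq_len(W2), each = H2)
  corners <- list()
  j <- 0L
  for (dw in 0:1) for (dh in 0:1) {
    j <- j + 1L
    corners[[j]] <- (2L * w2 - 2L + dw) * H + (2L * h2 - 1L + dh)
  }
  list(H2 = H2, W2 = W2, corners = corners)
}

# Expand a position map into row indices of the (N * n_pos) x C layout.
pos_rows <- function(posmap, N) {
  rep((posmap - 1L) * N, each = N) + rep.int(seq_len(N), length(posmap))
}

# All index vectors for one batch size N.
make_rowcache <- function(geom, N) {
  g1 <- geom$conv1; p1 <- geom$pool1; g2 <- geom$conv2; p2 <- geom$pool2
  list(
    N = N,
    int1 = pos_rows(g1$interior, N),
    off1 = lapply(g1$offsets, pos_rows, N = N),
    pool1 = lapply(p1$corners, pos_rows, N = N),
    int2 = pos_rows(g2$interior, N),
    off2 = lapply(g2$offsets, pos_rows, N = N),
    pool2 = lapply(p2$corners, pos_rows, N = N)
  )
}

# --- network -------------------------------------------------------------

cnn_init <- function(input_dim = c(101L, 9L), n_channels = 3L,
                     filters = c(16L, 32L), dense = 64L, seed = 1L,
                     y_mean = 1) {
  H <- input_dim[1L]; W <- input_dim[2L]
  g1 <- conv_geom(H, W)
  p1 <- pool_geom(H, W)
  g2 <- conv_geom(p1$H2, p1$W2)
  p2 <- pool_geom(p1$H2, p1$W2)
  flat <- p2$H2 * p2$W2 * filters[2L]
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  params <- with_seed(seed, {
    p <- list()
    for (ch in seq_len(n_channels)) {
      p[[paste0("W1_", ch)]] <- he(9L, filters[1L], 9L)
      p[[paste0("b1_", ch)]] <- numeric(filters[1L])
      p[[paste0("W2_", ch)]] <- he(9L * filters[1L], filters[2L],
                                   9L * filters[1L])
      p[[paste0("b2_", ch)]] <- numeric(filters[2L])
    }
    # dense layers use Xavier-scale init: spectrogram activations compound
    # through the conv trunks and a conservative scale keeps the softplus
    # output in its responsive range at the start of training
    p$Wd1 <- he(n_channels * flat, dense, 2L * n_channels * flat)
    p$bd1 <- numeric(dense)
    p$Wd2 <- he(dense, 1L, 2L * dense)
    p$bd2 <- matrix(log(expm1(max(y_mean, 1e-3))), 1L, 1L)
    p
  })
  list(params = params,
       geom = list(conv1 = g1, pool1 = p1, conv2 = g2, pool2 = p2,
                   flat = flat),
       n_channels = n_channels, filters = filters, dense = dense,
       input_dim = input_dim)
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# Forward pass. x: list of per-channel column matrices ((N * H * W) x 1).
# Returns yhat and, when keep = TRUE, the cache needed for backprop.
cnn_forward <- function(net, x, rc, keep = FALSE) {
  p <- net$params
  g <- net$geom
  N <- rc$N
  F1 <- net$filters[1L]; F2 <- net$filters[2L]
  n1 <- g$conv1$Hp * g$conv1$Wp
  n2 <- g$conv2$Hp * g$conv2$Wp
  flats <- vector("list", net$n_channels)
  caches <- if (keep) vector("list", net$n_channels) else NULL
  for (ch in seq_len(net$n_channels)) {
    W1 <- p[[paste0("W1_", ch)]]; b1 <- p[[paste0("b1_", ch)]]
    W2 <- p[[paste0("W2_", ch)]]; b2 <- p[[paste0("b2_", ch)]]
    Pp1 <- numeric(N * n1)
    Pp1[rc$int1] <- x[[ch]]
    M1 <- matrix(0, N * g$conv1$H * g$conv1$W, 9L)
    for (j in 1:9) M1[, j] <- Pp1[rc$off1[[j]]]
    Z1 <- M1 %*% W1
    Z1 <- Z1 + rep(b1, each = nrow(Z1))
    A1 <- pmax(Z1, 0)
    Mx1 <- (A1[rc$pool1[[1L]], , drop = FALSE] + A1[rc$pool1[[2L]], , drop = FALSE] +
              A1[rc$pool1[[3L]], , drop = FALSE] + A1[rc$pool1[[4L]], , drop = FALSE]) / 4
    Pp2 <- matrix(0, N * n2, F1)
    Pp2[rc$int2, ] <- Mx1
    M2 <- matrix(0, N * g$conv2$H * g$conv2$W, 9L * F1)
    for (j in 1:9) M2[, ((j - 1L) * F1 + 1L):(j * F1)] <- Pp2[rc$off2[[j]], ]
    Z2 <- M2 %*% W2
    Z2 <- Z2 + rep(b2, each = nrow(Z2))
    A2 <- pmax(Z2, 0)
    Mx2 <- (A2[rc$pool2[[1L]], , drop = FALSE] + A2[rc$pool2[[2L]], , drop = FALSE] +
              A2[rc$pool2[[3L]], , drop = FALSE] + A2[rc$pool2[[4L]], , drop = FALSE]) / 4
    fl <- Mx2
    dim(fl) <- c(N, g$flat)
    flats[[ch]] <- fl
    if (keep) {
      caches[[ch]] <- list(M1 = M1, Z1 = Z1, M2 = M2, Z2 = Z2)
    }
  }
  Fl <- do.call(cbind, flats)
  Zd1 <- Fl %*% p$Wd1
  Zd1 <- Zd1 + rep(p$bd1, each = nrow(Zd1))
  H1 <- pmax(Zd1, 0)
  z <- as.numeric(H1 %*% p$Wd2) + p$bd2[1L, 1L]
  yhat <- softplus(z)
  out <- list(yhat = yhat, z = z)
  if (keep) {
    out$cache <- list(channels = caches, Fl = Fl, Zd1 = Zd1, H1 = H1)
  }
  out
}

# Backward pass for MSE loss; returns gradient list matching net$params.
cnn_backward <- function(net, x, y, fwd, rc) {
  p <- net$params
  g <- net$geom
  N <- rc$N
  F1 <- net$filters[1L]; F2 <- net$filters[2L]
  n2 <- g$conv2$Hp * g$conv2$Wp
  cache <- fwd$cache
  grads <- list()
  dyhat <- 2 * (fwd$yhat - y) / N
  dz <- dyhat * stats::plogis(fwd$z) # d softplus
  grads$Wd2 <- crossprod(cache$H1, matrix(dz, ncol = 1L))
  grads$bd2 <- matrix(sum(dz), 1L, 1L)
  dH1 <- matrix(dz, ncol = 1L) %*% t(p$Wd2)
  dZd1 <- dH1 * (cache$Zd1 > 0)
  grads$Wd1 <- crossprod(cache$Fl, dZd1)
  grads$bd1 <- colSums(dZd1)
  dFl <- dZd1 %*% t(p$Wd1)
  for (ch in seq_len(net$n_channels)) {
    cc <- cache$channels[[ch]]
    cols <- ((ch - 1L) * g$flat + 1L):(ch * g$flat)
    dMx2 <- dFl[, cols, drop = FALSE]
    dim(dMx2) <- c(N * g$pool2$H2 * g$pool2$W2, F2)
    # average pooling spreads the gradient uniformly over the 2x2 window
    dMx2 <- dMx2 / 4
    dA2 <- matrix(0, nrow(cc$Z2), F2)
    for (cix in 1:4) {
      r <- rc$pool2[[cix]]
      dA2[r, ] <- dA2[r, ] + dMx2
    }
    dZ2 <- dA2 * (cc$Z2 > 0)
    grads[[paste0("W2_", ch)]] <- crossprod(cc$M2, dZ2)
    grads[[paste0("b2_", ch)]] <- colSums(dZ2)
    dM2 <- dZ2 %*% t(p[[paste0("W2_", ch)]])
    dPp2 <- matrix(0, N * n2, F1)
    for (j in 1:9) {
      r <- rc$off2[[j]]
      dPp2[r, ] <- dPp2[r, ] + dM2[, ((j - 1L) * F1 + 1L):(j * F1)]
    }
    dMx1 <- dPp2[rc$int2, , drop = FALSE] / 4
    dA1 <- matrix(0, nrow(cc$Z1), F1)
    for (cix in 1:4) {
      r <- rc$pool1[[cix]]
      dA1[r, ] <- dA1[r, ] + dMx1
    }
    dZ1 <- dA1 * (cc$Z1 > 0)
    grads[[paste0("W1_", ch)]] <- crossprod(cc$M1, dZ1)
    grads[[paste0("b1_", ch)]] <- colSums(dZ1)
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1)))
  if (is.finite(gnorm) && gnorm > clip) {
    grads <- lapply(grads, function(g) g * (clip / gnorm))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Convert a features array (N x C x H x W) into the per-channel column
# layout expected by cnn_forward, applying per-channel normalization.
features_to_columns <- function(features, channel_idx, norm) {
  N <- dim(features)[1L]
  lapply(seq_along(channel_idx), function(k) {
    ch <- channel_idx[k]
    a <- (features[, ch, , , drop = FALSE] - norm$mean[k]) / norm$sd[k]
    matrix(as.numeric(a), ncol = 1L) # order: n fastest, then h, then w
  })
}
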