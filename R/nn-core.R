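# Minimal deterministic deep-learning core used by the segmentation model.
#
# Batched feature tensors are numeric arrays with dim (nx, ny, nz, B, C)
# (channels last, so `matrix(x, ncol = C)` exposes the per-channel columns
# over all voxels and batch elements). Every forward function returns the
# output plus the cache its matching backward function needs; backward
# functions return the input gradient and parameter gradients. All heavy
# convolution/pooling arithmetic lives in the C++ kernels.

as_mat5 <- function(x) {
  d <- dim(x)
  matrix(x, nrow = prod(d[1:4]), ncol = d[5])
}

arr5 <- function(M, sp, B) array(M, dim = c(sp, B, ncol(M)))

## ---- 3D convolution (kernel k, same padding) ----

conv3d_fw <- function(x, W, b, k) {
  d <- dim(x)
  y <- cpp_conv3d_fw(x, as.integer(d), W, as.numeric(b), as.integer(k))
  array(y, dim = c(d[1:4], nrow(W)))
}

conv3d_bw <- function(x, W, gy, k) {
  d <- dim(x)
  r <- cpp_conv3d_bw(x, as.integer(d), W, gy, as.integer(k))
  list(gx = array(r$gx, dim = d), gW = r$gw, gb = as.numeric(r$gb))
}

## ---- batch normalization (statistics over batch x space, per channel) ----

bn_fw <- function(x, gamma, beta, state, key, train, eps = 1e-5, momentum = 0.1) {
  M <- as_mat5(x)
  if (train) {
    mu <- colMeans(M)
    v <- colMeans(M * M) - mu^2
    v <- pmax(v, 0)
    rm_key <- paste0(key, ".rm"); rv_key <- paste0(key, ".rv")
    state[[rm_key]] <- (1 - momentum) * state[[rm_key]] + momentum * mu
    state[[rv_key]] <- (1 - momentum) * state[[rv_key]] + momentum * v
  } else {
    mu <- state[[paste0(key, ".rm")]]
    v <- state[[paste0(key, ".rv")]]
  }
  s <- sqrt(v + eps)
  a <- gamma / s
  b0 <- beta - mu * a
  Y <- M
  for (cc in seq_len(ncol(M))) Y[, cc] <- M[, cc] * a[cc] + b0[cc]
  d <- dim(x)
  list(y = array(Y, dim = d), mu = mu, v = v, eps = eps)
}

bn_bw <- function(x, gy, gamma, cache) {
  M <- as_mat5(x)
  GY <- as_mat5(gy)
  N <- nrow(M)
  s <- sqrt(cache$v + cache$eps)
  dX <- M
  ggamma <- numeric(ncol(M))
  gbeta <- numeric(ncol(M))
  for (cc in seq_len(ncol(M))) {
    xc <- M[, cc] - cache$mu[cc]
    gc_ <- GY[, cc]
    dxhat <- gc_ * gamma[cc]
    dv <- sum(dxhat * xc) * (-0.5) / s[cc]^3
    dmu <- -sum(dxhat) / s[cc]
    dX[, cc] <- dxhat / s[cc] + xc * (2 * dv / N) + dmu / N
    ggamma[cc] <- sum(gc_ * xc) / s[cc]
    gbeta[cc] <- sum(gc_)
  }
  list(gx = array(dX, dim = dim(x)), ggamma = ggamma, gbeta = gbeta)
}

## ---- ReLU / max pooling ----

relu_fw <- function(x) pmax(x, 0)

relu_bw <- function(y, gy) gy * (y > 0)

maxpool_fw <- function(x, f) {
  d <- dim(x)
  r <- cpp_maxpool3d_fw(x, as.integer(d), as.integer(f))
  od <- c(d[1:3] %/% f, d[4], d[5])
  list(y = array(r$y, dim = od), idx = r$idx, n_x = prod(d))
}

maxpool_bw <- function(cache, gy, xdim) {
  array(cpp_maxpool3d_bw(cache$idx, gy, cache$n_x), dim = xdim)
}

## ---- transposed convolution, stride = kernel = pool factors ----

tconv_fw <- function(x, Wlist, b, f) {
  d <- dim(x)
  sp <- d[1:3]; B <- d[4]
  Cout <- ncol(Wlist[[1]])
  M <- as_mat5(x)
  out <- array(0, dim = c(sp * f, B, Cout))
  o <- 0L
  for (dz in seq_len(f[3])) for (dy in seq_len(f[2])) for (dx in seq_len(f[1])) {
    o <- o + 1L
    Y <- sweep(M %*% Wlist[[o]], 2L, b, "+")
    out[seq(dx, by = f[1], length.out = sp[1]),
        seq(dy, by = f[2], length.out = sp[2]),
        seq(dz, by = f[3], length.out = sp[3]), , ] <- array(Y, c(sp, B, Cout))
  }
  out
}

tconv_bw <- function(x, Wlist, gy, f) {
  d <- dim(x)
  sp <- d[1:3]; B <- d[4]
  M <- as_mat5(x)
  gX <- matrix(0, nrow(M), d[5])
  gW <- vector("list", length(Wlist))
  gb <- 0
  o <- 0L
  for (dz in seq_len(f[3])) for (dy in seq_len(f[2])) for (dx in seq_len(f[1])) {
    o <- o + 1L
    G <- gy[seq(dx, by = f[1], length.out = sp[1]),
            seq(dy, by = f[2], length.out = sp[2]),
            seq(dz, by = f[3], length.out = sp[3]), , , drop = FALSE]
    Gm <- matrix(G, nrow = nrow(M))
    gW[[o]] <- crossprod(M, Gm)
    gX <- gX + Gm %*% t(Wlist[[o]])
    gb <- gb + colSums(Gm)
  }
  list(gx = array(gX, dim = d), gW = gW, gb = gb)
}

## ---- pointwise (1x1x1) convolution ----

conv1_fw <- function(x, W, b) {
  M <- as_mat5(x)
  Y <- sweep(M %*% W, 2L, b, "+")
  array(Y, dim = c(dim(x)[1:4], ncol(W)))
}

conv1_bw <- function(x, W, gy) {
  M <- as_mat5(x)
  G <- as_mat5(gy)
  list(gx = array(G %*% t(W), dim = dim(x)),
       gW = crossprod(M, G), gb = colSums(G))
}

## ---- token-level layers (n_tokens x embed matrices, one sample) ----

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

ln_fw <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans(x * x) - mu^2
  s <- sqrt(v + eps)
  xhat <- (x - mu) / s
  list(y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"), xhat = xhat, s = s)
}

ln_bw <- function(cache, g, gy) {
  xhat <- cache$xhat
  dxhat <- sweep(gy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  gx <- (dxhat - m1 - xhat * m2) / cache$s
  list(gx = gx, gg = colSums(gy * xhat), gb = colSums(gy))
}

mhsa_fw <- function(x, Wq, Wk, Wv, Wo, bo, n_heads) {
  E <- ncol(x)
  dh <- E %/% n_heads
  Q <- x %*% Wq; K <- x %*% Wk; V <- x %*% Wv
  O <- matrix(0, nrow(x), E)
  P <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    P[[h]] <- softmax_rows(S)
    O[, cols] <- P[[h]] %*% V[, cols, drop = FALSE]
  }
  y <- sweep(O %*% Wo, 2L, bo, "+")
  list(y = y, Q = Q, K = K, V = V, P = P, O = O)
}

mhsa_bw <- function(x, Wq, Wk, Wv, Wo, n_heads, cache, gy) {
  E <- ncol(x)
  dh <- E %/% n_heads
  gO <- gy %*% t(Wo)
  gWo <- crossprod(cache$O, gy)
  gbo <- colSums(gy)
  gQ <- matrix(0, nrow(x), E); gK <- gQ; gV <- gQ
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    P <- cache$P[[h]]
    gOh <- gO[, cols, drop = FALSE]
    gP <- tcrossprod(gOh, cache$V[, cols, drop = FALSE])
    gV[, cols] <- crossprod(P, gOh)
    gS <- P * (gP - rowSums(gP * P))
    gQ[, cols] <- gS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    gK[, cols] <- crossprod(gS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  list(gx = gQ %*% t(Wq) + gK %*% t(Wk) + gV %*% t(Wv),
       gWq = crossprod(x, gQ), gWk = crossprod(x, gK),
       gWv = crossprod(x, gV), gWo = gWo, gbo = gbo)
}

gelu <- function(x) x * pnorm(x)

gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

mlp_fw <- function(x, W1, b1, W2, b2) {
  h <- sweep(x %*% W1, 2L, b1, "+")
  a <- gelu(h)
  list(y = sweep(a %*% W2, 2L, b2, "+"), h = h, a = a)
}

mlp_bw <- function(x, W1, W2, cache, gy) {
  ga <- gy %*% t(W2)
  gh <- ga * gelu_grad(cache$h)
  list(gx = gh %*% t(W1),
       gW1 = crossprod(x, gh), gb1 = colSums(gh),
       gW2 = crossprod(cache$a, gy), gb2 = colSums(gy))
}

## ---- patch partitioning (one sample: (nx, ny, nz, C) array) ----

# Split a (possibly zero-padded) feature map into non-overlapping 3D patches;
# returns the n_tokens x (prod(patch) * C) patch matrix plus the grid.
patchify <- function(f, patch) {
  d <- dim(f)
  sp <- d[1:3]; C <- d[4]
  grid <- as.integer(ceiling(sp / patch))
  pd <- grid * patch
  p <- if (all(pd == sp)) f else {
    tmp <- array(0, dim = c(pd, C))
    tmp[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), ] <- f
    tmp
  }
  dim(p) <- c(patch[1], grid[1], patch[2], grid[2], patch[3], grid[3], C)
  p <- aperm(p, c(1, 3, 5, 7, 2, 4, 6))
  L <- prod(patch) * C
  list(tokens_raw = t(matrix(p, nrow = L)), grid = grid, padded = pd,
       spatial = sp, C = C)
}

unpatchify <- function(T_raw, patch, grid, spatial, C) {
  p <- array(t(T_raw), dim = c(patch, C, grid))
  p <- aperm(p, c(1, 5, 2, 6, 3, 7, 4))
  dim(p) <- c(grid * patch, C)
  p[seq_len(spatial[1]), seq_len(spatial[2]), seq_len(spatial[3]), , drop = FALSE]
}
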