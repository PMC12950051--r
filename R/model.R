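#' Model configuration
#'
#' Architecture hyperparameters of the hybrid CNN-transformer segmentation
#' network and its ablation variants. The published description fixes the
#' structure (three conv-BN-ReLU-maxpool encoder blocks with in-plane /8
#' downsampling, 8x8x8 patch tokenisation, pre-norm transformer blocks, a
#' transposed-convolution U-Net decoder with skip connections) but not the
#' layer widths; widths default to values that shrink cleanly for CPU-scale
#' experiments and are all exposed here.
#'
#' @param variant one of `"baseline"` (single encoder, 3-channel input),
#'   `"single_enc_attention"` (baseline plus voxel-level self-attention after
#'   the encoder), `"dual_enc_no_attention"` (two encoders, channel
#'   concatenation + 1x1x1 projection), `"dual_enc_temporal_attention"`
#'   (two encoders fused by the parameter-free temporal attention gate
#'   `F_early + F_early * F_diff`; the proposed model).
#' @param enc_channels integer length-3 encoder widths; the last entry is the
#'   feature dimension C entering the fusion stage.
#' @param pool_factors integer length-3 max-pool factors per block (default
#'   2, 2, 1: in-plane halving, through-plane preserved).
#' @param conv_kernel convolution kernel size (odd).
#' @param patch_size integer length-3 transformer patch size.
#' @param embed_dim transformer token width (divisible by `n_heads`).
#' @param transformer_depth number of pre-norm transformer blocks.
#' @param n_heads attention heads.
#' @param mlp_ratio MLP hidden width as a multiple of `embed_dim`.
#' @param dec_channels integer length-3 decoder widths (coarse to fine).
#' @param input_shape integer length-3 model input volume shape; in-plane
#'   extents must be divisible by the cubed in-plane pool factor (8 by
#'   default). Violations are config errors at construction time.
#' @param skip_source `"early"` (skip connections from the early-phase /
#'   main encoder) or `"fused"` (element-wise sum of both encoders'
#'   pre-pooling activations).
#' @param normalize per-volume min-max scaling of each input channel to
#'   `[0, 1]` before the network.
#' @param final_bias initial bias of the output head (logit scale); negative
#'   values encode the sparse-foreground prior.
#' @param pretrained_init optional path to externally supplied transformer
#'   weights (hook only; `NULL` keeps random initialisation).
#' @return A `model_config` object.
#' @export
model_config <- function(variant = c("dual_enc_temporal_attention", "baseline",
                                     "single_enc_attention",
                                     "dual_enc_no_attention"),
                         enc_channels = c(32L, 64L, 128L),
                         pool_factors = c(2L, 2L, 1L),
                         conv_kernel = 3L,
                         patch_size = c(8L, 8L, 8L),
                         embed_dim = 256L,
                         transformer_depth = 4L,
                         n_heads = 8L,
                         mlp_ratio = 4,
                         dec_channels = c(64L, 32L, 16L),
                         input_shape = c(176L, 176L, 144L),
                         skip_source = c("early", "fused"),
                         normalize = TRUE,
                         final_bias = -2,
                         pretrained_init = NULL) {
  variant <- match.arg(variant)
  skip_source <- match.arg(skip_source)
  enc_channels <- as.integer(enc_channels)
  pool_factors <- as.integer(pool_factors)
  patch_size <- as.integer(rep_len(patch_size, 3L))
  input_shape <- as.integer(input_shape)
  if (embed_dim %% n_heads != 0L)
    stop("config error: embed_dim must be divisible by n_heads")
  if (conv_kernel %% 2L != 1L)
    stop("config error: conv_kernel must be odd")
  total_pool <- pool_factors^3L
  if (any(input_shape %% total_pool != 0L))
    stop(sprintf(
      "config error: input_shape must be divisible by the cubed pool factors (%s)",
      paste(total_pool, collapse = " x ")))
  structure(list(variant = variant,
                 enc_channels = enc_channels,
                 pool_factors = pool_factors,
                 conv_kernel = as.integer(conv_kernel),
                 patch_size = patch_size,
                 embed_dim = as.integer(embed_dim),
                 transformer_depth = as.integer(transformer_depth),
                 n_heads = as.integer(n_heads),
                 mlp_ratio = mlp_ratio,
                 dec_channels = as.integer(dec_channels),
                 input_shape = input_shape,
                 skip_source = skip_source,
                 normalize = isTRUE(normalize),
                 final_bias = final_bias,
                 pretrained_init = pretrained_init),
            class = "model_config")
}

# Derived shape bookkeeping shared by init / forward.
model_dims <- function(cfg) {
  ds <- cfg$pool_factors^3L
  enc_out <- cfg$input_shape %/% ds
  grid <- as.integer(ceiling(enc_out / cfg$patch_size))
  list(enc_out = enc_out, grid = grid, n_tokens = prod(grid),
       token_len = prod(cfg$patch_size) * cfg$enc_channels[3])
}

is_dual <- function(cfg) cfg$variant %in% c("dual_enc_no_attention",
                                            "dual_enc_temporal_attention")

#' Instantiate a model
#'
#' Builds randomly initialised weights for the selected variant (He
#' initialisation for convolutions, scaled-Gaussian for projections, unit
#' batch-norm) and the batch-norm running statistics.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return An `nme_model` list with `config`, `params` (flat named list of
#'   trainable arrays) and `state` (running statistics).
#' @export
nme_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  cfg <- config
  md <- model_dims(cfg)
  k <- cfg$conv_kernel
  P <- list()
  state <- list()

  add_enc <- function(P, state, prefix, in_ch) {
    ch <- c(in_ch, cfg$enc_channels)
    for (i in 1:3) {
      key <- paste0(prefix, ".b", i)
      fan_in <- ch[i] * k^3
      P[[paste0(key, ".convW")]] <-
        matrix(rnorm(ch[i + 1] * fan_in, sd = sqrt(2 / fan_in)),
               nrow = ch[i + 1])
      P[[paste0(key, ".convB")]] <- rep(0, ch[i + 1])
      P[[paste0(key, ".bnG")]] <- rep(1, ch[i + 1])
      P[[paste0(key, ".bnB")]] <- rep(0, ch[i + 1])
      state[[paste0(key, ".rm")]] <- rep(0, ch[i + 1])
      state[[paste0(key, ".rv")]] <- rep(1, ch[i + 1])
    }
    list(P = P, state = state)
  }

  C <- cfg$enc_channels[3]
  if (is_dual(cfg)) {
    r <- add_enc(P, state, "enc_early", 1L); P <- r$P; state <- r$state
    r <- add_enc(P, state, "enc_diff", 1L); P <- r$P; state <- r$state
  } else {
    r <- add_enc(P, state, "enc_main", 3L); P <- r$P; state <- r$state
  }

  if (cfg$variant == "single_enc_attention") {
    P$att.Wq <- matrix(rnorm(C * C, sd = sqrt(1 / C)), C, C)
    P$att.Wk <- matrix(rnorm(C * C, sd = sqrt(1 / C)), C, C)
    P$att.Wv <- matrix(rnorm(C * C, sd = sqrt(1 / C)), C, C)
    P$att.Wo <- matrix(rnorm(C * C, sd = 0.02), C, C)
    P$att.bo <- rep(0, C)
  }
  if (cfg$variant == "dual_enc_no_attention") {
    P$fuse.W <- matrix(rnorm(2 * C * C, sd = sqrt(1 / (2 * C))), 2 * C, C)
    P$fuse.b <- rep(0, C)
  }

  E <- cfg$embed_dim
  L <- md$token_len
  P$patch.We <- matrix(rnorm(L * E, sd = sqrt(1 / L)), L, E)
  P$patch.be <- rep(0, E)
  P$patch.pos <- matrix(rnorm(md$n_tokens * E, sd = 0.02), md$n_tokens, E)

  mE <- round(cfg$mlp_ratio * E)
  for (l in seq_len(cfg$transformer_depth)) {
    key <- paste0("tr", l)
    P[[paste0(key, ".ln1G")]] <- rep(1, E)
    P[[paste0(key, ".ln1B")]] <- rep(0, E)
    P[[paste0(key, ".Wq")]] <- matrix(rnorm(E * E, sd = sqrt(1 / E)), E, E)
    P[[paste0(key, ".Wk")]] <- matrix(rnorm(E * E, sd = sqrt(1 / E)), E, E)
    P[[paste0(key, ".Wv")]] <- matrix(rnorm(E * E, sd = sqrt(1 / E)), E, E)
    P[[paste0(key, ".Wo")]] <- matrix(rnorm(E * E, sd = sqrt(1 / E)), E, E)
    P[[paste0(key, ".bo")]] <- rep(0, E)
    P[[paste0(key, ".ln2G")]] <- rep(1, E)
    P[[paste0(key, ".ln2B")]] <- rep(0, E)
    P[[paste0(key, ".W1")]] <- matrix(rnorm(E * mE, sd = sqrt(1 / E)), E, mE)
    P[[paste0(key, ".b1")]] <- rep(0, mE)
    P[[paste0(key, ".W2")]] <- matrix(rnorm(mE * E, sd = sqrt(1 / mE)), mE, E)
    P[[paste0(key, ".b2")]] <- rep(0, E)
  }
  P$unpatch.Wu <- matrix(rnorm(E * L, sd = sqrt(1 / E)), E, L)
  P$unpatch.bu <- rep(0, L)

  dch <- cfg$dec_channels
  skip_ch <- rev(cfg$enc_channels)     # decoder stage s concatenates skip 4-s
  in_ch <- c(C, dch[1], dch[2])
  fo <- prod(cfg$pool_factors)
  for (s in 1:3) {
    key <- paste0("dec", s)
    for (o in seq_len(fo))
      P[[paste0(key, ".tcW", o)]] <-
        matrix(rnorm(in_ch[s] * dch[s], sd = sqrt(2 / in_ch[s])),
               in_ch[s], dch[s])
    P[[paste0(key, ".tcB")]] <- rep(0, dch[s])
    cin <- dch[s] + skip_ch[s]
    fan_in <- cin * k^3
    P[[paste0(key, ".convW")]] <-
      matrix(rnorm(dch[s] * fan_in, sd = sqrt(2 / fan_in)), nrow = dch[s])
    P[[paste0(key, ".convB")]] <- rep(0, dch[s])
    P[[paste0(key, ".bnG")]] <- rep(1, dch[s])
    P[[paste0(key, ".bnB")]] <- rep(0, dch[s])
    state[[paste0(key, ".rm")]] <- rep(0, dch[s])
    state[[paste0(key, ".rv")]] <- rep(1, dch[s])
  }
  P$head.W <- matrix(rnorm(dch[3], sd = sqrt(2 / dch[3])), dch[3], 1)
  P$head.b <- cfg$final_bias

  structure(list(config = cfg, params = P, state = state),
            class = "nme_model")
}

#' Count trainable parameters
#' @param model an `nme_model`.
#' @return Named integer: total scalar parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

## ---------------------------------------------------------------------------
## Architecture operations (public, test-addressable)
## ---------------------------------------------------------------------------

#' Difference-driven temporal attention gate
#'
#' The parameter-free fusion `F_att = F_early + F_early * F_diff`
#' (element-wise product): voxels where both the early-phase feature and the
#' temporal-difference feature are large are multiplicatively amplified, while
#' the residual term preserves the early-phase representation. Output shape
#' equals input shape.
#'
#' @param f_early,f_diff numeric arrays of identical shape.
#' @return Array of the same shape.
#' @export
temporal_attention <- function(f_early, f_diff) {
  if (!identical(dim(f_early), dim(f_diff)))
    stop("temporal attention inputs must have identical shapes")
  f_early + f_early * f_diff
}

#' Concatenation fusion with pointwise projection
#'
#' Channel-axis concatenation of the two encoder outputs (2C channels)
#' followed by a 1x1x1 linear projection back to C channels, so the shared
#' transformer input width is variant-independent.
#'
#' @param f_early,f_diff arrays with channels on the last axis, equal shapes.
#' @param W projection matrix (2C x C).
#' @param b projection bias (length C).
#' @return Array shaped like `f_early`.
#' @export
fuse_concat <- function(f_early, f_diff, W, b = rep(0, ncol(W))) {
  if (!identical(dim(f_early), dim(f_diff)))
    stop("fusion inputs must have identical shapes")
  d <- dim(f_early)
  C <- d[length(d)]
  if (nrow(W) != 2 * C) stop("projection must map 2C -> C channels")
  M <- cbind(matrix(f_early, ncol = C), matrix(f_diff, ncol = C))
  Y <- sweep(M %*% W, 2L, b, "+")
  array(Y, dim = c(d[-length(d)], ncol(W)))
}

#' Voxel-level self-attention over an encoder feature map
#'
#' Used by the single-encoder ablation: the encoder output constructs
#' query/key/value via learned channel projections, scaled dot-product
#' attention runs over all spatial positions, and the attended features are
#' added residually to the input.
#'
#' @param f array (nx, ny, nz, C), one sample.
#' @param Wq,Wk,Wv,Wo C x C projection matrices.
#' @param bo output bias (length C).
#' @return Array shaped like `f`.
#' @export
single_encoder_attention <- function(f, Wq, Wk, Wv, Wo, bo = rep(0, ncol(Wo))) {
  d <- dim(f)
  C <- d[length(d)]
  X <- matrix(f, ncol = C)
  att <- mhsa_fw(X, Wq, Wk, Wv, Wo, bo, n_heads = 1L)
  array(X + att$y, dim = d)
}

#' Patch embedding of a feature map
#'
#' Zero-pads the spatial extent up to the next multiple of `patch_size` per
#' axis, flattens each non-overlapping 3D patch, projects it linearly to the
#' embedding width, and adds the learned positional embedding.
#'
#' @param f array (nx, ny, nz, C), one sample.
#' @param We patch projection (`prod(patch_size) * C` x embed_dim).
#' @param be embedding bias.
#' @param pos positional embedding (n_tokens x embed_dim).
#' @param patch_size integer length-3.
#' @return List with `tokens` (n_tokens x embed_dim), `grid`, `padded`,
#'   `spatial`, `C`.
#' @export
patchify_embed <- function(f, We, be, pos, patch_size) {
  pf <- patchify(f, patch_size)
  if (nrow(pos) != nrow(pf$tokens_raw))
    stop("positional embedding size does not match the token grid")
  tokens <- sweep(pf$tokens_raw %*% We, 2L, be, "+") + pos
  list(tokens = tokens, grid = pf$grid, padded = pf$padded,
       spatial = pf$spatial, C = pf$C)
}

#' Transformer encoder forward pass
#'
#' `transformer_depth` pre-norm blocks: `x <- x + MHSA(LN(x))` then
#' `x <- x + MLP(LN(x))`, with multi-head scaled dot-product attention.
#'
#' @param tokens n_tokens x embed_dim matrix.
#' @param model an `nme_model` supplying the block weights.
#' @return Matrix of the same shape.
#' @export
transformer_forward <- function(tokens, model) {
  cfg <- model$config; P <- model$params
  x <- tokens
  for (l in seq_len(cfg$transformer_depth)) {
    key <- paste0("tr", l)
    n1 <- ln_fw(x, P[[paste0(key, ".ln1G")]], P[[paste0(key, ".ln1B")]])
    at <- mhsa_fw(n1$y, P[[paste0(key, ".Wq")]], P[[paste0(key, ".Wk")]],
                  P[[paste0(key, ".Wv")]], P[[paste0(key, ".Wo")]],
                  P[[paste0(key, ".bo")]], cfg$n_heads)
    x <- x + at$y
    n2 <- ln_fw(x, P[[paste0(key, ".ln2G")]], P[[paste0(key, ".ln2B")]])
    ml <- mlp_fw(n2$y, P[[paste0(key, ".W1")]], P[[paste0(key, ".b1")]],
                 P[[paste0(key, ".W2")]], P[[paste0(key, ".b2")]])
    x <- x + ml$y
  }
  x
}

#' Encoder forward pass
#'
#' Runs one CNN encoder branch (three conv-BN-ReLU-maxpool blocks) in
#' inference mode. With default pooling the output spatial shape is
#' (nx/8, ny/8, nz); a 176 x 176 x 144 input yields 22 x 22 x 144.
#'
#' @param model an `nme_model`.
#' @param volume 3D array (single channel) or 4D array (nx, ny, nz, C_in).
#' @param branch `"early"`, `"diff"` or `"main"`; defaults to the branch the
#'   variant owns.
#' @return Feature array (nx', ny', nz', C) with the per-block pre-pooling
#'   activations attached as attribute `"skips"`.
#' @export
encoder_forward <- function(model, volume, branch = NULL) {
  cfg <- model$config
  if (is.null(branch)) branch <- if (is_dual(cfg)) "early" else "main"
  prefix <- if (is_dual(cfg)) paste0("enc_", branch) else "enc_main"
  if (length(dim(volume)) == 3L) dim(volume) <- c(dim(volume), 1L)
  d <- dim(volume)
  x <- array(volume, dim = c(d[1:3], 1L, d[4]))   # batch of one
  r <- enc_fw(prefix, x, cfg, model$params, model$state, train = FALSE)
  out <- r$out
  od <- dim(out)
  skips <- lapply(r$skips, function(s) array(s, dim = dim(s)[-4]))
  res <- array(out, dim = od[-4])
  attr(res, "skips") <- skips
  res
}

#' Decoder forward pass
#'
#' Reshapes transformer tokens back onto the (padded) feature grid, removes
#' the padding, and applies three transposed-convolution upsampling stages
#' with skip concatenation, ending in a pointwise projection and logistic
#' map. Output spatial shape equals the model input shape.
#'
#' @param model an `nme_model`.
#' @param tokens n_tokens x embed_dim matrix (one sample).
#' @param skips list of three pre-pooling encoder activations (fine to
#'   coarse), as attached by [encoder_forward()].
#' @return 3D array of per-voxel probabilities in `[0, 1]`.
#' @export
decoder_forward <- function(model, tokens, skips) {
  cfg <- model$config; P <- model$params
  md <- model_dims(cfg)
  U <- sweep(tokens %*% P$unpatch.Wu, 2L, P$unpatch.bu, "+")
  fmap <- unpatchify(U, cfg$patch_size, md$grid, md$enc_out,
                     cfg$enc_channels[3])
  x <- array(fmap, dim = c(md$enc_out, 1L, cfg$enc_channels[3]))
  skips5 <- lapply(skips, function(s) {
    ds <- dim(s)
    if (length(ds) == 4L) array(s, dim = c(ds[1:3], 1L, ds[4])) else s
  })
  r <- dec_fw(x, skips5, cfg, P, model$state, train = FALSE)
  array(r$prob, dim = dim(r$prob)[1:3])
}

#' Binarize a probability map
#' @param prob numeric array of probabilities.
#' @param threshold decision threshold in (0, 1).
#' @return Logical array `prob >= threshold`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  vg_values(prob) >= threshold
}

## ---------------------------------------------------------------------------
## Full forward / backward over a mini-batch (internal)
## ---------------------------------------------------------------------------

enc_fw <- function(prefix, x, cfg, P, state, train) {
  blocks <- vector("list", 3L)
  skips <- vector("list", 3L)
  cur <- x
  for (i in 1:3) {
    key <- paste0(prefix, ".b", i)
    z <- conv3d_fw(cur, P[[paste0(key, ".convW")]], P[[paste0(key, ".convB")]],
                   cfg$conv_kernel)
    bn <- bn_fw(z, P[[paste0(key, ".bnG")]], P[[paste0(key, ".bnB")]],
                state, key, train)
    a <- relu_fw(bn$y)
    mp <- maxpool_fw(a, cfg$pool_factors)
    blocks[[i]] <- list(x_in = cur, z = z, bn = bn[c("mu", "v", "eps")],
                        a = a, mp = mp[c("idx", "n_x")], adim = dim(a))
    skips[[i]] <- a
    cur <- mp$y
  }
  list(out = cur, skips = skips, blocks = blocks)
}

enc_bw <- function(prefix, blocks, gout, gskips, cfg, P, G) {
  g <- gout
  for (i in 3:1) {
    key <- paste0(prefix, ".b", i)
    blk <- blocks[[i]]
    g <- maxpool_bw(blk$mp, g, blk$adim)
    if (!is.null(gskips[[i]])) g <- g + gskips[[i]]
    g <- relu_bw(blk$a, g)
    bnb <- bn_bw(blk$z, g, P[[paste0(key, ".bnG")]], blk$bn)
    gadd(G, paste0(key, ".bnG"), bnb$ggamma)
    gadd(G, paste0(key, ".bnB"), bnb$gbeta)
    g <- bnb$gx
    cb <- conv3d_bw(blk$x_in, P[[paste0(key, ".convW")]], g, cfg$conv_kernel)
    gadd(G, paste0(key, ".convW"), cb$gW)
    gadd(G, paste0(key, ".convB"), cb$gb)
    g <- cb$gx
  }
  invisible(g)
}

dec_fw <- function(x, skips, cfg, P, state, train) {
  stages <- vector("list", 3L)
  cur <- x
  for (s in 1:3) {
    key <- paste0("dec", s)
    skip <- skips[[4L - s]]
    Wl <- lapply(seq_len(prod(cfg$pool_factors)),
                 function(o) P[[paste0(key, ".tcW", o)]])
    tc <- tconv_fw(cur, Wl, P[[paste0(key, ".tcB")]], cfg$pool_factors)
    ds <- dim(tc)
    cat5 <- array(c(tc, skip), dim = c(ds[1:4], ds[5] + dim(skip)[5]))
    z <- conv3d_fw(cat5, P[[paste0(key, ".convW")]], P[[paste0(key, ".convB")]],
                   cfg$conv_kernel)
    bn <- bn_fw(z, P[[paste0(key, ".bnG")]], P[[paste0(key, ".bnB")]],
                state, key, train)
    a <- relu_fw(bn$y)
    stages[[s]] <- list(x_in = cur, tc_dim = ds, cat5 = cat5, z = z,
                        bn = bn[c("mu", "v", "eps")], a = a)
    cur <- a
  }
  logits <- conv1_fw(cur, P$head.W, P$head.b)
  prob <- 1 / (1 + exp(-logits))
  list(prob = array(prob, dim = dim(prob)[1:4]), stages = stages,
       last = cur)
}

dec_bw <- function(fwd, glogits, cfg, P, G) {
  hb <- conv1_bw(fwd$last, P$head.W,
                 array(glogits, dim = c(dim(glogits), 1L)))
  gadd(G, "head.W", hb$gW)
  gadd(G, "head.b", hb$gb)
  g <- hb$gx
  gskips <- vector("list", 3L)
  for (s in 3:1) {
    key <- paste0("dec", s)
    st <- fwd$stages[[s]]
    g <- relu_bw(st$a, g)
    bnb <- bn_bw(st$z, g, P[[paste0(key, ".bnG")]], st$bn)
    gadd(G, paste0(key, ".bnG"), bnb$ggamma)
    gadd(G, paste0(key, ".bnB"), bnb$gbeta)
    cb <- conv3d_bw(st$cat5, P[[paste0(key, ".convW")]], bnb$gx,
                    cfg$conv_kernel)
    gadd(G, paste0(key, ".convW"), cb$gW)
    gadd(G, paste0(key, ".convB"), cb$gb)
    ct <- st$tc_dim[5]
    gcat <- cb$gx
    gt <- gcat[, , , , seq_len(ct), drop = FALSE]
    gskips[[4L - s]] <- gcat[, , , , (ct + 1L):dim(gcat)[5], drop = FALSE]
    Wl <- lapply(seq_len(prod(cfg$pool_factors)),
                 function(o) P[[paste0(key, ".tcW", o)]])
    tb <- tconv_bw(st$x_in, Wl, gt, cfg$pool_factors)
    for (o in seq_along(Wl)) gadd(G, paste0(key, ".tcW", o), tb$gW[[o]])
    gadd(G, paste0(key, ".tcB"), tb$gb)
    g <- tb$gx
  }
  list(gx = g, gskips = gskips)
}

# Transformer stage for one sample (patchify -> blocks -> unpatchify).
trans_fw <- function(fmap, cfg, P) {
  pf <- patchify(fmap, cfg$patch_size)
  x <- sweep(pf$tokens_raw %*% P$patch.We, 2L, P$patch.be, "+") + P$patch.pos
  blocks <- vector("list", cfg$transformer_depth)
  for (l in seq_len(cfg$transformer_depth)) {
    key <- paste0("tr", l)
    x_in1 <- x
    n1 <- ln_fw(x, P[[paste0(key, ".ln1G")]], P[[paste0(key, ".ln1B")]])
    at <- mhsa_fw(n1$y, P[[paste0(key, ".Wq")]], P[[paste0(key, ".Wk")]],
                  P[[paste0(key, ".Wv")]], P[[paste0(key, ".Wo")]],
                  P[[paste0(key, ".bo")]], cfg$n_heads)
    x <- x + at$y
    x_in2 <- x
    n2 <- ln_fw(x, P[[paste0(key, ".ln2G")]], P[[paste0(key, ".ln2B")]])
    ml <- mlp_fw(n2$y, P[[paste0(key, ".W1")]], P[[paste0(key, ".b1")]],
                 P[[paste0(key, ".W2")]], P[[paste0(key, ".b2")]])
    x <- x + ml$y
    blocks[[l]] <- list(x_in1 = x_in1, n1 = n1, at = at,
                        x_in2 = x_in2, n2 = n2, ml = ml)
  }
  x_out <- x
  U <- sweep(x_out %*% P$unpatch.Wu, 2L, P$unpatch.bu, "+")
  fout <- unpatchify(U, cfg$patch_size, pf$grid, pf$spatial, pf$C)
  list(fout = fout, pf = pf, blocks = blocks, x_out = x_out)
}

trans_bw <- function(cache, gfout, cfg, P, G) {
  pf <- cache$pf
  # backward of unpatchify: pad gradient with zeros, then re-patchify
  gpad <- array(0, dim = c(pf$padded, pf$C))
  gpad[seq_len(pf$spatial[1]), seq_len(pf$spatial[2]),
       seq_len(pf$spatial[3]), ] <- gfout
  gU <- patchify(gpad, cfg$patch_size)$tokens_raw
  gadd(G, "unpatch.Wu", crossprod(cache$x_out, gU))
  gadd(G, "unpatch.bu", colSums(gU))
  gx <- gU %*% t(P$unpatch.Wu)
  for (l in rev(seq_len(cfg$transformer_depth))) {
    key <- paste0("tr", l)
    blk <- cache$blocks[[l]]
    mb <- mlp_bw(blk$n2$y, P[[paste0(key, ".W1")]], P[[paste0(key, ".W2")]],
                 blk$ml, gx)
    gadd(G, paste0(key, ".W1"), mb$gW1); gadd(G, paste0(key, ".b1"), mb$gb1)
    gadd(G, paste0(key, ".W2"), mb$gW2); gadd(G, paste0(key, ".b2"), mb$gb2)
    lb <- ln_bw(blk$n2, P[[paste0(key, ".ln2G")]], mb$gx)
    gadd(G, paste0(key, ".ln2G"), lb$gg); gadd(G, paste0(key, ".ln2B"), lb$gb)
    gx <- gx + lb$gx
    ab <- mhsa_bw(blk$n1$y, P[[paste0(key, ".Wq")]], P[[paste0(key, ".Wk")]],
                  P[[paste0(key, ".Wv")]], P[[paste0(key, ".Wo")]],
                  cfg$n_heads, blk$at, gx)
    gadd(G, paste0(key, ".Wq"), ab$gWq); gadd(G, paste0(key, ".Wk"), ab$gWk)
    gadd(G, paste0(key, ".Wv"), ab$gWv); gadd(G, paste0(key, ".Wo"), ab$gWo)
    gadd(G, paste0(key, ".bo"), ab$gbo)
    lb1 <- ln_bw(blk$n1, P[[paste0(key, ".ln1G")]], ab$gx)
    gadd(G, paste0(key, ".ln1G"), lb1$gg); gadd(G, paste0(key, ".ln1B"), lb1$gb)
    gx <- gx + lb1$gx
  }
  gadd(G, "patch.pos", gx)
  gadd(G, "patch.We", crossprod(pf$tokens_raw, gx))
  gadd(G, "patch.be", colSums(gx))
  gT <- gx %*% t(P$patch.We)
  gmap <- unpatchify(gT, cfg$patch_size, pf$grid, pf$spatial, pf$C)
  gmap
}

gadd <- function(G, name, val) {
  if (is.null(G[[name]])) G[[name]] <- val else G[[name]] <- G[[name]] + val
  invisible(NULL)
}

# Assemble the (nx, ny, nz, B, C) input tensors for a batch of prepared
# studies (each a list with pre/early/diff 3D arrays).
assemble_inputs <- function(batch, cfg) {
  sp <- cfg$input_shape
  B <- length(batch)
  for (s in batch)
    if (!identical(as.integer(dim(s$early)), sp))
      stop("input volume shape does not match model input_shape")
  if (is_dual(cfg)) {
    xe <- array(0, dim = c(sp, B, 1L)); xd <- xe
    for (b in seq_len(B)) {
      xe[, , , b, 1L] <- batch[[b]]$early
      xd[, , , b, 1L] <- batch[[b]]$diff
    }
    list(xe = xe, xd = xd)
  } else {
    x <- array(0, dim = c(sp, B, 3L))
    for (b in seq_len(B)) {
      x[, , , b, 1L] <- batch[[b]]$pre
      x[, , , b, 2L] <- batch[[b]]$early
      x[, , , b, 3L] <- batch[[b]]$diff
    }
    list(x = x)
  }
}

nn_forward <- function(model, batch, train = FALSE) {
  cfg <- model$config; P <- model$params
  state <- model$state
  st_env <- list2env(state)
  ins <- assemble_inputs(batch, cfg)
  B <- length(batch)
  cache <- list(ins = ins)

  if (is_dual(cfg)) {
    ee <- enc_fw("enc_early", ins$xe, cfg, P, st_env, train)
    ed <- enc_fw("enc_diff", ins$xd, cfg, P, st_env, train)
    cache$enc_early <- ee; cache$enc_diff <- ed
    if (cfg$variant == "dual_enc_temporal_attention") {
      fused <- ee$out + ee$out * ed$out
    } else {
      d5 <- dim(ee$out)
      catm <- cbind(as_mat5(ee$out), as_mat5(ed$out))
      fused <- array(sweep(catm %*% P$fuse.W, 2L, P$fuse.b, "+"),
                     dim = c(d5[1:4], ncol(P$fuse.W)))
      cache$fuse_in <- catm
    }
    skips_raw <- list(early = ee$skips, diff = ed$skips)
  } else {
    em <- enc_fw("enc_main", ins$x, cfg, P, st_env, train)
    cache$enc_main <- em
    if (cfg$variant == "single_enc_attention") {
      d5 <- dim(em$out)
      fused <- array(0, dim = d5)
      att_caches <- vector("list", B)
      for (b in seq_len(B)) {
        Xb <- matrix(em$out[, , , b, , drop = FALSE], ncol = d5[5])
        at <- mhsa_fw(Xb, P$att.Wq, P$att.Wk, P$att.Wv, P$att.Wo, P$att.bo,
                      n_heads = 1L)
        fused[, , , b, ] <- array(Xb + at$y, dim = c(d5[1:3], 1L, d5[5]))
        att_caches[[b]] <- at
      }
      cache$att <- att_caches
    } else {
      fused <- em$out
    }
    skips_raw <- list(early = em$skips, diff = NULL)
  }
  cache$fused <- fused

  skips <- if (cfg$skip_source == "fused" && is_dual(cfg)) {
    Map(`+`, skips_raw$early, skips_raw$diff)
  } else skips_raw$early

  # transformer per sample
  d5 <- dim(fused)
  tout <- array(0, dim = d5)
  tcaches <- vector("list", B)
  for (b in seq_len(B)) {
    fb <- array(fused[, , , b, , drop = FALSE], dim = c(d5[1:3], d5[5]))
    tc <- trans_fw(fb, cfg, P)
    tout[, , , b, ] <- array(tc$fout, dim = c(d5[1:3], 1L, d5[5]))
    tcaches[[b]] <- tc
  }
  cache$trans <- tcaches

  dec <- dec_fw(tout, skips, cfg, P, st_env, train)
  cache$dec <- dec
  cache$tout_dim <- dim(tout)

  prob <- array(dec$prob, dim = c(cfg$input_shape, B))
  new_state <- as.list(st_env)
  list(prob = prob, cache = cache, state = new_state)
}

nn_backward <- function(model, cache, gprob, prob) {
  cfg <- model$config; P <- model$params
  B <- dim(gprob)[4]
  glogits <- gprob * prob * (1 - prob)
  G <- new.env(parent = emptyenv())

  db <- dec_bw(cache$dec, glogits, cfg, P, G)
  gtout <- db$gx
  gskips <- db$gskips          # fine -> coarse (indices 1..3 match encoder blocks)

  d5 <- dim(gtout)
  gfused <- array(0, dim = d5)
  for (b in seq_len(B)) {
    gfb <- array(gtout[, , , b, , drop = FALSE], dim = c(d5[1:3], d5[5]))
    gmap <- trans_bw(cache$trans[[b]], gfb, cfg, P, G)
    gfused[, , , b, ] <- array(gmap, dim = c(d5[1:3], 1L, d5[5]))
  }

  if (is_dual(cfg)) {
    ee <- cache$enc_early; ed <- cache$enc_diff
    if (cfg$variant == "dual_enc_temporal_attention") {
      ge <- gfused * (1 + ed$out)
      gd <- gfused * ee$out
    } else {
      gcat <- as_mat5(gfused) %*% t(P$fuse.W)
      gadd(G, "fuse.W", crossprod(cache$fuse_in, as_mat5(gfused)))
      gadd(G, "fuse.b", colSums(as_mat5(gfused)))
      C <- d5[5]
      ge <- array(gcat[, seq_len(C)], dim = dim(ee$out))
      gd <- array(gcat[, C + seq_len(C)], dim = dim(ed$out))
    }
    if (cfg$skip_source == "fused") {
      enc_bw("enc_early", ee$blocks, ge, gskips, cfg, P, G)
      enc_bw("enc_diff", ed$blocks, gd, gskips, cfg, P, G)
    } else {
      enc_bw("enc_early", ee$blocks, ge, gskips, cfg, P, G)
      enc_bw("enc_diff", ed$blocks, gd, vector("list", 3L), cfg, P, G)
    }
  } else {
    em <- cache$enc_main
    if (cfg$variant == "single_enc_attention") {
      gout <- array(0, dim = d5)
      for (b in seq_len(B)) {
        Xb <- matrix(em$out[, , , b, , drop = FALSE], ncol = d5[5])
        gyb <- matrix(gfused[, , , b, , drop = FALSE], ncol = d5[5])
        ab <- mhsa_bw(Xb, P$att.Wq, P$att.Wk, P$att.Wv, P$att.Wo,
                      1L, cache$att[[b]], gyb)
        gadd(G, "att.Wq", ab$gWq); gadd(G, "att.Wk", ab$gWk)
        gadd(G, "att.Wv", ab$gWv); gadd(G, "att.Wo", ab$gWo)
        gadd(G, "att.bo", ab$gbo)
        gout[, , , b, ] <- array(gyb + ab$gx, dim = c(d5[1:3], 1L, d5[5]))
      }
      enc_bw("enc_main", em$blocks, gout, gskips, cfg, P, G)
    } else {
      enc_bw("enc_main", em$blocks, gfused, gskips, cfg, P, G)
    }
  }
  as.list(G)
}

#' Model forward pass on one study
#'
#' Routes the study through the variant-appropriate path: encoder(s), fusion
#' (none / voxel self-attention / concatenation projection / temporal
#' attention gate), patch embedding, transformer, and decoder. Inputs are
#' min-max normalised per volume when the config requests it. Deterministic
#' given weights and input.
#'
#' @param model an `nme_model`.
#' @param study list with 3D arrays or `volume_grid`s `pre`, `early`, `diff`
#'   (all required for the single-encoder variants; `early` and `diff` for
#'   the dual-encoder ones).
#' @return 3D array of per-voxel probabilities, same shape as the input.
#' @export
model_forward <- function(model, study) {
  cfg <- model$config
  s <- prepare_model_inputs(study, cfg)
  res <- nn_forward(model, list(s), train = FALSE)
  array(res$prob, dim = cfg$input_shape)
}

prepare_model_inputs <- function(study, cfg) {
  need <- if (is_dual(cfg)) c("early", "diff") else c("pre", "early", "diff")
  out <- list()
  for (nm in need) {
    if (is.null(study[[nm]]))
      stop(sprintf("variant '%s' requires input '%s'", cfg$variant, nm))
    v <- vg_values(study[[nm]])
    out[[nm]] <- if (cfg$normalize) normalize_minmax(v) else v
  }
  if (!is_dual(cfg)) out else c(out, list(pre = NULL))
}
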