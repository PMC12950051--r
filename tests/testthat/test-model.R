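test_that("configuration contracts are enforced at construction", {
  expect_error(model_config(embed_dim = 30L, n_heads = 8L), "divisible")
  expect_error(model_config(input_shape = c(100L, 176L, 144L)),
               "config error")
  expect_error(model_config(conv_kernel = 4L), "odd")
  expect_s3_class(tiny_model_config(), "model_config")
})

test_that("encoder halves the in-plane extent three times and is ReLU-bounded", {
  cfg <- tiny_model_config(input_shape = c(16L, 16L, 8L))
  model <- nme_model(cfg, seed = 2)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  f <- encoder_forward(model, x, branch = "early")
  expect_identical(dim(f), c(2L, 2L, 8L, 3L))
  expect_true(all(f >= 0))
  skips <- attr(f, "skips")
  expect_identical(dim(skips[[1]])[1:3], c(16L, 16L, 8L))
  expect_identical(dim(skips[[2]])[1:3], c(8L, 8L, 8L))
  expect_identical(dim(skips[[3]])[1:3], c(4L, 4L, 8L))
  # shape arithmetic at a second size
  cfg2 <- tiny_model_config(input_shape = c(24L, 24L, 8L))
  f2 <- encoder_forward(nme_model(cfg2, 2),
                        array(0, c(24, 24, 8)), branch = "early")
  expect_identical(dim(f2)[1:3], c(3L, 3L, 8L))
})

test_that("temporal attention gate matches its closed forms and a loop oracle", {
  set.seed(8)
  fe <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  fd <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  expect_identical(temporal_attention(fe, array(0, dim(fe))), fe)
  expect_equal(temporal_attention(fe, array(1, dim(fe))), 2 * fe)
  want <- array(0, dim(fe))
  for (i in seq_along(fe)) want[i] <- fe[i] + fe[i] * fd[i]
  expect_identical(max(abs(temporal_attention(fe, fd) - want)), 0)
  expect_error(temporal_attention(fe, array(0, c(2, 2, 2, 3))), "shape")
  # gate monotonicity for nonnegative early features
  fe_pos <- abs(fe)
  fd2 <- fd; fd2[1] <- fd2[1] + 0.5
  expect_gte(temporal_attention(fe_pos, fd2)[1],
             temporal_attention(fe_pos, fd)[1])
})

test_that("concatenation fusion projects 2C channels back to C", {
  set.seed(9)
  C <- 3
  fe <- array(rnorm(4 * 4 * 2 * C), c(4, 4, 2, C))
  fd <- array(rnorm(4 * 4 * 2 * C), c(4, 4, 2, C))
  W_id <- rbind(diag(C), matrix(0, C, C))
  expect_equal(fuse_concat(fe, fd, W_id), fe)
  W_avg <- rbind(diag(C) / 2, diag(C) / 2)
  expect_equal(fuse_concat(fe, fd, W_avg), (fe + fd) / 2)
  expect_identical(dim(fuse_concat(fe, fd, W_avg)), dim(fe))
  expect_error(fuse_concat(fe, fd, diag(C)), "2C")
})

test_that("voxel self-attention is a residual map with exact small-case form", {
  set.seed(10)
  C <- 4
  f <- array(rnorm(2 * 2 * 1 * C), c(2, 2, 1, C))
  zero <- matrix(0, C, C)
  W <- matrix(rnorm(C * C, sd = 0.3), C, C)
  # zero Q/K/V makes attention output the (uniform) mean of V = 0 rows
  expect_equal(single_encoder_attention(f, zero, zero, zero, W), f)
  # single-voxel extent: softmax over one element is exactly 1
  f1 <- array(rnorm(C), c(1, 1, 1, C))
  Wq <- matrix(rnorm(C * C), C, C); Wk <- matrix(rnorm(C * C), C, C)
  Wv <- matrix(rnorm(C * C), C, C); Wo <- matrix(rnorm(C * C), C, C)
  X <- matrix(f1, ncol = C)
  expect_equal(as.numeric(single_encoder_attention(f1, Wq, Wk, Wv, Wo)),
               as.numeric(X + (X %*% Wv) %*% Wo))
  # 2x2x1 map against a direct softmax(Q K^T / sqrt(d)) V computation
  got <- single_encoder_attention(f, Wq, Wk, Wv, Wo)
  Xm <- matrix(f, ncol = C)
  S <- (Xm %*% Wq) %*% t(Xm %*% Wk) / sqrt(C)
  P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
  want <- Xm + (P %*% (Xm %*% Wv)) %*% Wo
  expect_lt(max(abs(matrix(got, ncol = C) - want)), 1e-6)
})

test_that("patch partitioning counts tokens and round-trips", {
  f <- array(rnorm(22 * 22 * 144), c(22, 22, 144, 1))
  pf <- nmeseg:::patchify(f, c(8L, 8L, 8L))
  expect_identical(pf$grid, c(3L, 3L, 18L))
  expect_identical(pf$padded, c(24L, 24L, 144L))
  expect_identical(nrow(pf$tokens_raw), 162L)
  f2 <- array(rnorm(16 * 16 * 16 * 2), c(16, 16, 16, 2))
  pf2 <- nmeseg:::patchify(f2, c(8L, 8L, 8L))
  expect_identical(nrow(pf2$tokens_raw), 8L)
  expect_identical(pf2$padded, dim(f2)[1:3])
  # round trip recovers the original map on the unpadded region
  back <- nmeseg:::unpatchify(pf$tokens_raw, c(8L, 8L, 8L), pf$grid,
                              pf$spatial, pf$C)
  expect_identical(back, f)
  back2 <- nmeseg:::unpatchify(pf2$tokens_raw, c(8L, 8L, 8L), pf2$grid,
                               pf2$spatial, pf2$C)
  expect_identical(back2, f2)
})

test_that("patch embedding applies projection plus positional offsets", {
  cfg <- tiny_model_config()
  model <- nme_model(cfg, seed = 4)
  md <- nmeseg:::model_dims(cfg)
  f <- array(rnorm(prod(md$enc_out) * cfg$enc_channels[3]),
             c(md$enc_out, cfg$enc_channels[3]))
  pe <- patchify_embed(f, model$params$patch.We, model$params$patch.be,
                       model$params$patch.pos, cfg$patch_size)
  expect_identical(dim(pe$tokens), c(as.integer(md$n_tokens), cfg$embed_dim))
  expect_identical(nrow(pe$tokens), as.integer(prod(pe$grid)))
  expect_error(patchify_embed(f, model$params$patch.We, model$params$patch.be,
                              model$params$patch.pos[-1, , drop = FALSE],
                              cfg$patch_size),
               "positional")
})

test_that("transformer blocks are residual-consistent and row-normalised", {
  cfg <- tiny_model_config()
  model <- nme_model(cfg, seed = 5)
  md <- nmeseg:::model_dims(cfg)
  x <- matrix(rnorm(md$n_tokens * cfg$embed_dim), md$n_tokens)
  # zeroing the residual-branch output weights gives the identity
  m0 <- model
  m0$params$tr1.Wo <- m0$params$tr1.Wo * 0
  m0$params$tr1.bo <- m0$params$tr1.bo * 0
  m0$params$tr1.W2 <- m0$params$tr1.W2 * 0
  m0$params$tr1.b2 <- m0$params$tr1.b2 * 0
  expect_equal(transformer_forward(x, m0), x)
  # attention rows sum to one for every head
  at <- nmeseg:::mhsa_fw(x, model$params$tr1.Wq, model$params$tr1.Wk,
                         model$params$tr1.Wv, model$params$tr1.Wo,
                         model$params$tr1.bo, cfg$n_heads)
  for (P in at$P) expect_equal(rowSums(P), rep(1, md$n_tokens))
  # depth-1, 1-head, 2-token, 4-dim block against a hand-rolled computation
  cfg1 <- model_config(variant = "baseline", enc_channels = c(2L, 2L, 2L),
                       patch_size = c(1L, 1L, 1L), embed_dim = 4L,
                       transformer_depth = 1L, n_heads = 1L, mlp_ratio = 2,
                       dec_channels = c(2L, 2L, 2L),
                       input_shape = c(8L, 8L, 1L))
  m1 <- nme_model(cfg1, seed = 6)
  P <- m1$params
  x1 <- matrix(rnorm(8), 2, 4)
  lnorm <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-6)
  h <- x1
  n1 <- t(apply(h, 1, lnorm))
  n1 <- sweep(sweep(n1, 2, P$tr1.ln1G, "*"), 2, P$tr1.ln1B, "+")
  Q <- n1 %*% P$tr1.Wq; K <- n1 %*% P$tr1.Wk; V <- n1 %*% P$tr1.Wv
  S <- Q %*% t(K) / 2
  Pm <- exp(S - apply(S, 1, max)); Pm <- Pm / rowSums(Pm)
  h <- h + sweep((Pm %*% V) %*% P$tr1.Wo, 2, P$tr1.bo, "+")
  n2 <- t(apply(h, 1, lnorm))
  n2 <- sweep(sweep(n2, 2, P$tr1.ln2G, "*"), 2, P$tr1.ln2B, "+")
  a <- sweep(n2 %*% P$tr1.W1, 2, P$tr1.b1, "+")
  a <- a * pnorm(a)
  h <- h + sweep(a %*% P$tr1.W2, 2, P$tr1.b2, "+")
  expect_lt(max(abs(transformer_forward(x1, m1) - h)), 1e-5)
})

test_that("decoder restores the input resolution with probabilities", {
  cfg <- tiny_model_config(input_shape = c(16L, 16L, 8L))
  model <- nme_model(cfg, seed = 11)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  f <- encoder_forward(model, x, branch = "early")
  pe <- patchify_embed(f, model$params$patch.We, model$params$patch.be,
                       model$params$patch.pos, cfg$patch_size)
  tok <- transformer_forward(pe$tokens, model)
  prob <- decoder_forward(model, tok, attr(f, "skips"))
  expect_identical(dim(prob), c(16L, 16L, 8L))
  expect_true(all(prob >= 0 & prob <= 1))
})

test_that("all variants share the output contract and stay finite", {
  s <- random_study(c(16, 16, 8), seed = 3)
  for (v in c("baseline", "single_enc_attention", "dual_enc_no_attention",
              "dual_enc_temporal_attention")) {
    model <- nme_model(tiny_model_config(v), seed = 12)
    prob <- model_forward(model, s)
    expect_identical(dim(prob), c(16L, 16L, 8L))
    expect_true(all(is.finite(prob)))
    expect_true(all(prob >= 0 & prob <= 1))
  }
})

test_that("the temporal gate is parameter-free and collapses when diff is zero", {
  m3 <- nme_model(tiny_model_config("dual_enc_no_attention"), seed = 13)
  m4 <- nme_model(tiny_model_config("dual_enc_temporal_attention"), seed = 13)
  extra <- setdiff(names(m3$params), names(m4$params))
  expect_identical(sort(extra), c("fuse.W", "fuse.b"))
  expect_identical(setdiff(names(m4$params), names(m3$params)), character(0))
  for (nm in names(m4$params))
    expect_identical(dim(m4$params[[nm]]), dim(m3$params[[nm]]))
  # diff identically zero: the fused map equals the raw early encoder output
  s <- random_study(c(16, 16, 8), seed = 5)
  s$diff <- array(0, c(16, 16, 8))
  model <- nme_model(tiny_model_config("dual_enc_temporal_attention"), 14)
  model$config$normalize <- FALSE
  fwd <- nmeseg:::nn_forward(model,
                             list(list(early = s$early, diff = s$diff)),
                             train = FALSE)
  expect_identical(fwd$cache$fused, fwd$cache$enc_early$out)
})

test_that("every trainable parameter receives gradient in every variant", {
  for (v in c("baseline", "single_enc_attention", "dual_enc_no_attention",
              "dual_enc_temporal_attention")) {
    model <- nme_model(tiny_model_config(v), seed = 15)
    batch <- list(random_study(c(16, 16, 8), seed = 6),
                  random_study(c(16, 16, 8), seed = 7))
    batch <- lapply(batch, function(s) nmeseg:::prepare_model_inputs(s, model$config))
    fwd <- nmeseg:::nn_forward(model, batch, train = TRUE)
    gprob <- array(rnorm(length(fwd$prob)), dim = dim(fwd$prob))
    grads <- nmeseg:::nn_backward(model, fwd$cache, gprob, fwd$prob)
    for (nm in names(model$params)) {
      expect_false(is.null(grads[[nm]]), info = paste(v, nm))
      expect_gt(max(abs(grads[[nm]])), 0)
    }
  }
})

test_that("binarize follows the threshold rule exactly", {
  expect_true(all(binarize(array(1, c(2, 2, 2)), 0.5)))
  expect_false(any(binarize(array(0, c(2, 2, 2)), 0.5)))
  set.seed(16)
  p <- array(runif(24), c(4, 3, 2))
  got <- binarize(p, 0.3)
  want <- array(FALSE, dim(p))
  for (i in seq_along(p)) want[i] <- p[i] >= 0.3
  expect_identical(got, want)
  expect_error(binarize(p, 1.5), "threshold")
})
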