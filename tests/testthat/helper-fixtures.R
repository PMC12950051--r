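# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small phantom study chain on a 48 x 48 x 16 grid.
small_phantom <- function(seed = 7, noise_sigma = 2) {
  cached(sprintf("phantom_%d_%g", seed, noise_sigma), {
    cfg <- phantom_config(grid_shape = c(48L, 48L, 16L),
                          noise_sigma = noise_sigma, rng_seed = seed)
    bg <- generate_breast_background(cfg)
    lesion <- place_nme_lesion(bg, bg$breast_mask, cfg)
    early <- apply_enhancement(bg$volume, lesion, bg$breast_mask, cfg)
    list(cfg = cfg, bg = bg, lesion = lesion, early = early)
  })
}

# A tiny model configuration whose forward/backward runs in milliseconds.
tiny_model_config <- function(variant = "dual_enc_temporal_attention",
                              input_shape = c(16L, 16L, 8L)) {
  model_config(variant = variant,
               enc_channels = c(2L, 2L, 3L),
               patch_size = c(2L, 2L, 2L),
               embed_dim = 8L,
               transformer_depth = 1L,
               n_heads = 2L,
               mlp_ratio = 2,
               dec_channels = c(3L, 3L, 2L),
               input_shape = input_shape,
               final_bias = 0)
}

# Random prepared study matching a model input shape.
random_study <- function(shape, seed = 1, mask_frac = 0.02) {
  set.seed(seed)
  list(pre = array(runif(prod(shape)), shape),
       early = array(runif(prod(shape)), shape),
       diff = array(runif(prod(shape)), shape),
       mask = array(runif(prod(shape)) < mask_frac, shape))
}

# Stub trainer whose predictor returns the ground-truth mask.
oracle_trainer <- function(variant, train_studies, seed) {
  function(study) array(as.numeric(study$mask), dim = dim(study$mask))
}
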