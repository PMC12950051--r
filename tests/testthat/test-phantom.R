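test_that("background generation is deterministic and seed-sensitive", {
  cfg <- phantom_config(grid_shape = c(48, 48, 16), noise_sigma = 0,
                        rng_seed = 3)
  a <- generate_breast_background(cfg)
  b <- generate_breast_background(cfg)
  expect_identical(a$volume$values, b$volume$values)
  cfg2 <- cfg; cfg2$rng_seed <- 4L
  c3 <- generate_breast_background(cfg2)
  expect_gt(sum(a$volume$values != c3$volume$values), 0)
})

test_that("background carries two anterior mounds with recorded apices", {
  ph <- small_phantom()
  bg <- ph$bg
  ny <- dim(bg$breast_mask)[2]
  anterior <- bg$breast_mask[, (ny %/% 2 + 1):ny, , drop = FALSE]
  lab <- nmeseg:::label_components(anterior)
  expect_identical(lab$n, 2L)
  # recorded apices are the unique most-anterior voxels of their mound
  for (s in 1:2) {
    m <- bg$mound_masks[[s]]
    ap <- bg$apices[s, ]
    expect_true(m[ap[1], ap[2], ap[3]])
    expect_identical(sum(m[, ap[2], ]), 1L)   # unique at that y level
  }
})

test_that("grids too small for two mounds are rejected", {
  expect_error(phantom_config(grid_shape = c(8, 8, 8)), "invalid config")
  cfg <- phantom_config(grid_shape = c(16, 48, 16))
  expect_error(generate_breast_background(cfg), "two breast mounds")
  expect_error(phantom_config(grid_shape = c(48, 48, 17)), "even")
})

test_that("lesion is confined to the breast and hits its target volume", {
  ph <- small_phantom()
  expect_true(all(ph$bg$breast_mask[ph$lesion]))
  expect_identical(sum(ph$lesion), ph$cfg$lesion_volume_voxels)
  # configurable volume range: a 500-voxel target lands within +/- 20%
  cfg <- phantom_config(grid_shape = c(64, 64, 24),
                        lesion_volume_voxels = 500, rng_seed = 11)
  bg <- generate_breast_background(cfg)
  les <- place_nme_lesion(bg, bg$breast_mask, cfg)
  expect_gte(sum(les), 400)
  expect_lte(sum(les), 600)
})

test_that("lesion is less spherical than a ball of the same volume", {
  ph <- small_phantom()
  lesion <- ph$lesion
  v <- sum(lesion)
  # digital ball with the same voxel count
  d <- dim(lesion)
  r <- (3 * v / (4 * pi))^(1 / 3) + 1
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  ctr <- d / 2
  dist2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
                 (zs - ctr[3])^2, "+")
  thr <- sort(as.numeric(dist2))[v]
  ball <- dist2 <= thr
  surf <- function(m) nmeseg:::cpp_surface_faces(as.logical(m),
                                                 as.integer(dim(m)))
  sphericity <- function(m) (pi^(1 / 3)) * (6 * sum(m))^(2 / 3) / surf(m)
  expect_lt(sphericity(lesion), sphericity(ball))
})

test_that("enhancement follows the two-phase amplitude model", {
  ph <- small_phantom()
  cfg <- ph$cfg
  # zero uptake everywhere: early == pre exactly
  cfg0 <- cfg
  cfg0$uptake_amplitude <- 0; cfg0$n_vessels <- 0L
  cfg0$parenchymal_uptake <- 0
  e0 <- apply_enhancement(ph$bg$volume, ph$lesion, ph$bg$breast_mask, cfg0)
  expect_equal(e0$values, ph$bg$volume$values)
  # malignant defaults enhance more than benign under the same seed
  cfg_m <- cfg; cfg_m$uptake_amplitude <- 0.8; cfg_m$uptake_heterogeneity <- 0.5
  cfg_b <- cfg; cfg_b$uptake_amplitude <- 0.25; cfg_b$uptake_heterogeneity <- 0.1
  em <- apply_enhancement(ph$bg$volume, ph$lesion, ph$bg$breast_mask, cfg_m)
  eb <- apply_enhancement(ph$bg$volume, ph$lesion, ph$bg$breast_mask, cfg_b)
  up_m <- em$values - ph$bg$volume$values
  up_b <- eb$values - ph$bg$volume$values
  expect_gt(mean(up_m[ph$lesion]), mean(up_b[ph$lesion]))
  # heterogeneity raises the within-lesion uptake dispersion
  cfg_h0 <- cfg_m; cfg_h0$uptake_heterogeneity <- 0
  eh0 <- apply_enhancement(ph$bg$volume, ph$lesion, ph$bg$breast_mask, cfg_h0)
  expect_gt(sd(up_m[ph$lesion]),
            sd((eh0$values - ph$bg$volume$values)[ph$lesion]))
})

test_that("cohorts respect label counts, determinism and separation", {
  tmpl <- phantom_config(grid_shape = c(48, 48, 16))
  res <- generate_cohort(10, 0.5, tmpl, seed = 5)
  expect_identical(sum(res$manifest$label == "benign"), 5L)
  expect_identical(sum(res$manifest$label == "malignant"), 5L)
  res2 <- generate_cohort(10, 0.5, tmpl, seed = 5)
  expect_identical(res$manifest, res2$manifest)
  expect_identical(res$studies[[3]]$early_volume$values,
                   res2$studies[[3]]$early_volume$values)
  # documented rounding rule (half away from zero) at the full cohort size
  expect_identical(nmeseg:::round_half_away(151 * 0.4), 60)
  expect_identical(nmeseg:::round_half_away(7 * 0.5), 4)
  # lesion enhancement exceeds background enhancement once motion is undone
  for (st in res$studies[1:4]) {
    sep <- enhancement_separation(st)
    expect_gt(sep$lesion, sep$background)
    expect_true(all(st$breast_mask[st$lesion_mask]))
  }
})

test_that("cohort writes NIfTI volumes and a readable manifest", {
  out <- withr::local_tempdir()
  tmpl <- phantom_config(grid_shape = c(48, 48, 16))
  res <- generate_cohort(2, 0.5, tmpl, seed = 2, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  man <- read.csv(file.path(out, "manifest.csv"), stringsAsFactors = FALSE)
  expect_identical(names(man),
                   c("patient_id", "label", "pre_path", "early_path",
                     "mask_path"))
  rt <- read_volume(man$pre_path[1])
  expect_equal(rt$values, res$studies[[1]]$pre_volume$values,
               tolerance = 1e-6)
  expect_equal(rt$spacing_mm, res$studies[[1]]$pre_volume$spacing_mm,
               tolerance = 1e-6)
})

test_that("structure counts are preserved across grid scales", {
  for (gs in list(c(48, 48, 16), c(64, 64, 24))) {
    cfg <- phantom_config(grid_shape = gs, rng_seed = 13)
    bg <- generate_breast_background(cfg)
    ny <- gs[2]
    anterior <- bg$breast_mask[, (ny %/% 2 + 1):ny, , drop = FALSE]
    expect_identical(nmeseg:::label_components(anterior)$n, 2L)
    les <- place_nme_lesion(bg, bg$breast_mask, cfg)
    expect_gt(sum(les), 0)
    expect_true(all(bg$breast_mask[les]))
  }
})
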