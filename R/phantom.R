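#' Configuration for the synthetic two-phase breast DCE-MRI phantom
#'
#' The phantom emulates the geometry of a bilateral axial breast acquisition:
#' a dark posterior chest-wall slab, a thin subcutaneous tissue layer on its
#' anterior surface, and two anterior breast mounds with protruding nipple
#' apices, filled with smoothed fibroglandular texture. Contrast kinetics are
#' reduced to a two-phase amplitude model: the early post-contrast volume is
#' the pre-contrast volume plus an uptake field concentrated in a diffuse
#' multi-focal lesion, in curvilinear vessels, and mildly in parenchyma.
#' Malignant lesions default to strong, heterogeneous uptake and benign
#' lesions to weak, homogeneous uptake, qualitatively encoding the kinetic
#' contrast between the two lesion classes; the magnitudes are package
#' choices, not measured values.
#'
#' @param grid_shape integer length-3 (nx, ny, nz): in-plane x, in-plane y
#'   (posterior to anterior), slices. All components >= 16 and nz even.
#' @param voxel_spacing_mm numeric length-3 voxel size in mm.
#' @param lesion_label `"benign"` or `"malignant"`; sets kinetic defaults.
#' @param uptake_amplitude mean lesion enhancement as a fraction of the mean
#'   breast pre-contrast intensity. Default 0.8 (malignant) / 0.25 (benign).
#' @param uptake_heterogeneity spatial coefficient of variation of lesion
#'   uptake in `[0, 1]`. Default 0.5 (malignant) / 0.1 (benign).
#' @param parenchymal_uptake mild global background parenchymal enhancement
#'   (same fractional units); a false-positive source.
#' @param n_vessels number of enhancing curvilinear vessels (false-positive
#'   sources).
#' @param vessel_uptake vessel enhancement fraction.
#' @param vessel_radius_vox vessel tube radius in voxels.
#' @param lesion_volume_voxels target lesion voxel count; default 0.25% of the
#'   grid volume.
#' @param n_lesion_blobs number of overlapping smoothed blobs forming the
#'   diffuse lesion (>= 3).
#' @param motion_translation_mm maximum absolute inter-phase rigid shift per
#'   axis (mm); the applied shift is drawn uniformly within the bound.
#' @param noise_sigma additive Gaussian noise SD in intensity units.
#' @param rng_seed integer seed controlling every random field of the phantom.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(352L, 352L, 144L),
                           voxel_spacing_mm = c(0.91, 0.91, 1.0),
                           lesion_label = c("malignant", "benign"),
                           uptake_amplitude = NULL,
                           uptake_heterogeneity = NULL,
                           parenchymal_uptake = 0.06,
                           n_vessels = 3L,
                           vessel_uptake = 0.6,
                           vessel_radius_vox = 2L,
                           lesion_volume_voxels = NULL,
                           n_lesion_blobs = 5L,
                           motion_translation_mm = c(2, 2, 2),
                           noise_sigma = 2,
                           rng_seed = 1L) {
  lesion_label <- match.arg(lesion_label)
  grid_shape <- as.integer(round(grid_shape))
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("invalid config: grid_shape components must all be >= 16")
  if (grid_shape[3] %% 2L != 0L)
    stop("invalid config: slice count must be even")
  if (is.null(uptake_amplitude))
    uptake_amplitude <- if (lesion_label == "malignant") 0.8 else 0.25
  if (is.null(uptake_heterogeneity))
    uptake_heterogeneity <- if (lesion_label == "malignant") 0.5 else 0.1
  if (uptake_amplitude < 0) stop("invalid config: uptake_amplitude must be >= 0")
  if (uptake_heterogeneity < 0 || uptake_heterogeneity > 1)
    stop("invalid config: uptake_heterogeneity must be in [0, 1]")
  if (n_vessels < 0) stop("invalid config: n_vessels must be >= 0")
  if (vessel_uptake < 0) stop("invalid config: vessel_uptake must be >= 0")
  if (noise_sigma < 0) stop("invalid config: noise_sigma must be >= 0")
  if (is.null(lesion_volume_voxels))
    lesion_volume_voxels <- max(150L, round(0.0025 * prod(grid_shape)))
  if (n_lesion_blobs < 3L) stop("invalid config: need >= 3 lesion blobs")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 lesion_label = lesion_label,
                 uptake_amplitude = uptake_amplitude,
                 uptake_heterogeneity = uptake_heterogeneity,
                 parenchymal_uptake = parenchymal_uptake,
                 n_vessels = as.integer(n_vessels),
                 vessel_uptake = vessel_uptake,
                 vessel_radius_vox = as.integer(vessel_radius_vox),
                 lesion_volume_voxels = as.integer(lesion_volume_voxels),
                 n_lesion_blobs = as.integer(n_lesion_blobs),
                 motion_translation_mm = as.numeric(motion_translation_mm),
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

# Geometry of the two mounds for a given grid; shared by background, lesion
# placement and apex bookkeeping. Fractions of the grid, chosen so that the
# mound cores stay inside the central half of the x extent (the in-plane crop
# window) while the mounds still read as two separate anterior structures.
phantom_geometry <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  y_chest <- round(0.20 * ny)
  layer_th <- max(2L, round(0.025 * ny))
  list(y_chest = y_chest,
       layer_top = y_chest + layer_th,
       centers_x = c(round(0.32 * nx), round(0.68 * nx)),
       center_z = round(0.5 * nz),
       semi = c(0.13 * nx, 0.36 * ny, 0.33 * nz))
}

#' Generate the pre-contrast breast background volume
#'
#' Builds the anatomical scaffold: low-intensity anterior air, a dark
#' posterior chest-wall slab, a thin bright subcutaneous layer along the
#' chest surface, and two half-ellipsoidal breast mounds with single-voxel
#' nipple apices and smoothed random fibroglandular texture. Additive
#' Gaussian noise with `noise_sigma` is applied to the whole volume.
#'
#' @param config a [phantom_config()].
#' @return A list with `volume` (pre-contrast `volume_grid`), `breast_mask`
#'   (binary array marking breast tissue: mounds plus subcutaneous layer),
#'   `mound_masks` (list of two binary arrays), and `apices` (2 x 3 matrix of
#'   the recorded nipple apex voxels, 1-based).
#' @export
generate_breast_background <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  if (nx < 32L || ny < 32L)
    stop("invalid config: grid too small to contain two breast mounds")
  geom <- phantom_geometry(gs)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$rng_seed)

  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  X <- array(rep(xs, times = ny * nz), dim = gs)
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = gs)
  Z <- array(rep(zs, each = nx * ny), dim = gs)

  mound_masks <- vector("list", 2L)
  apices <- matrix(0L, 2L, 3L)
  for (s in 1:2) {
    cx <- geom$centers_x[s] + round(runif(1, -0.01, 0.01) * nx)
    cz <- geom$center_z + round(runif(1, -0.02, 0.02) * nz)
    a <- geom$semi * exp(runif(3, -0.05, 0.05))
    m <- ((X - cx) / a[1])^2 + ((Y - geom$y_chest) / a[2])^2 +
      ((Z - cz) / a[3])^2 <= 1 & Y > geom$layer_top
    # nipple papilla: a small protrusion with a unique most-anterior voxel
    apex_y <- max(Y[m])
    tip_y <- min(apex_y + 2L, ny)
    m[cx + c(-1L, 0L, 1L), min(apex_y + 1L, ny), cz] <- TRUE
    m[cx, tip_y, cz] <- TRUE
    mound_masks[[s]] <- m
    apices[s, ] <- as.integer(c(cx, tip_y, cz))
  }
  layer <- Y > geom$y_chest & Y <= geom$layer_top
  chest <- Y <= geom$y_chest
  breast_mask <- mound_masks[[1]] | mound_masks[[2]] | layer

  fibro <- gauss_smooth(array(rnorm(prod(gs)), dim = gs),
                        pmax(1, 0.012 * gs))
  fibro <- fibro / stats::sd(fibro)

  vol <- array(0, dim = gs)
  vol[chest] <- 12
  vol[layer] <- 95
  in_mound <- mound_masks[[1]] | mound_masks[[2]]
  vol[in_mound] <- pmax(40, 100 * (1 + 0.25 * fibro[in_mound]))
  if (config$noise_sigma > 0)
    vol <- vol + array(rnorm(prod(gs), sd = config$noise_sigma), dim = gs)

  list(volume = volume_grid(vol, config$voxel_spacing_mm),
       breast_mask = breast_mask,
       mound_masks = mound_masks,
       apices = apices,
       fibro = fibro,
       geometry = geom)
}

#' Place a diffuse non-mass lesion inside one breast
#'
#' The lesion is the union of several overlapping, anisotropically smoothed
#' blobs confined to the fibroglandular core of one mound, thresholded so the
#' voxel count matches `lesion_volume_voxels` exactly. The multi-focal,
#' smoothed construction yields an irregular, non-spherical region emulating
#' diffuse non-mass enhancement rather than a well-defined mass.
#'
#' @param background result of [generate_breast_background()].
#' @param breast_mask binary breast tissue mask.
#' @param config a [phantom_config()].
#' @return Binary 3D array (lesion mask), a strict subset of `breast_mask`.
#' @export
place_nme_lesion <- function(background, breast_mask, config) {
  gs <- config$grid_shape
  geom <- background$geometry
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$rng_seed + 1000L)

  side <- sample(1:2, 1L)
  mound <- background$mound_masks[[side]]
  idx <- which(mound)
  if (length(idx) < 4L * config$lesion_volume_voxels)
    stop("lesion placement failed: selected mound too small for target volume")
  co <- arrayInd(idx, gs)
  ctr <- colMeans(co)
  # allowed region: interior of the mound, away from skin
  eroded <- array(cpp_box_morph(as.logical(mound), as.integer(gs), 2L, FALSE), dim = gs)
  core <- if (sum(eroded) > 2L * config$lesion_volume_voxels) eroded else mound

  sig <- pmax(1.5, c(0.035, 0.05, 0.05) * gs)
  field <- array(0, dim = gs)
  first <- ctr + c(0.2, 0.1, 0) * sig * rnorm(3)
  pts <- matrix(rep(first, config$n_lesion_blobs), ncol = 3, byrow = TRUE)
  if (config$n_lesion_blobs > 1L)
    for (j in 2:config$n_lesion_blobs)
      pts[j, ] <- first + rnorm(3, sd = 1.6 * sig)
  xs <- seq_len(gs[1]); ys <- seq_len(gs[2]); zs <- seq_len(gs[3])
  for (j in seq_len(config$n_lesion_blobs)) {
    r <- sig * exp(runif(3, -0.4, 0.4))
    dx2 <- ((xs - pts[j, 1]) / r[1])^2
    dy2 <- ((ys - pts[j, 2]) / r[2])^2
    dz2 <- ((zs - pts[j, 3]) / r[3])^2
    field <- field + exp(-0.5 * outer(outer(dx2, dy2, "+"), dz2, "+"))
  }
  field <- gauss_smooth(field, c(1, 1, 1))
  field[!core] <- -Inf

  v <- config$lesion_volume_voxels
  avail <- sum(is.finite(field) & field > 0)
  if (avail < v)
    stop("lesion placement failed: not enough fibroglandular voxels in budget")
  thr <- sort(field[is.finite(field)], decreasing = TRUE)[v]
  lesion <- field >= thr & is.finite(field)
  lesion & breast_mask
}

#' Apply two-phase contrast enhancement
#'
#' Builds the early post-contrast volume as `pre + uptake`, where the uptake
#' field carries (a) lesion uptake `amplitude * (1 + heterogeneity * texture)`
#' relative to the mean breast pre-contrast intensity, clipped at zero,
#' (b) bright curvilinear vessel tubes, and (c) mild global parenchymal
#' enhancement across the remaining breast tissue.
#'
#' @param pre pre-contrast `volume_grid` (or array).
#' @param lesion_mask,breast_mask binary arrays on the same grid.
#' @param config a [phantom_config()].
#' @return Early post-contrast `volume_grid`; the rasterized vessel mask is
#'   attached as attribute `"vessel_mask"`.
#' @export
apply_enhancement <- function(pre, lesion_mask, breast_mask, config) {
  prev <- vg_values(pre)
  gs <- dim(prev)
  check_same_grid(prev, lesion_mask); check_same_grid(prev, breast_mask)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$rng_seed + 2000L)

  i_ref <- mean(prev[breast_mask])
  uptake <- array(0, dim = gs)

  if (any(lesion_mask) && config$uptake_amplitude > 0) {
    tex <- gauss_smooth(array(rnorm(prod(gs)), dim = gs), pmax(1, 0.008 * gs))
    tl <- tex[lesion_mask]
    tl <- (tl - mean(tl)) / max(stats::sd(tl), 1e-12)
    u <- config$uptake_amplitude * i_ref *
      (1 + config$uptake_heterogeneity * tl)
    uptake[lesion_mask] <- pmax(u, 0)
  }

  vessel_mask <- array(FALSE, dim = gs)
  if (config$n_vessels > 0L) {
    vessel_mask <- rasterize_vessels(breast_mask, config)
    vm <- vessel_mask & !lesion_mask
    uptake[vm] <- uptake[vm] + config$vessel_uptake * i_ref
  }

  if (config$parenchymal_uptake > 0) {
    par <- breast_mask & !lesion_mask & !vessel_mask
    tex2 <- gauss_smooth(array(rnorm(prod(gs)), dim = gs), pmax(1, 0.012 * gs))
    tex2 <- normalize_minmax(tex2)
    uptake[par] <- uptake[par] + config$parenchymal_uptake * i_ref *
      (0.5 + tex2[par])
  }

  early <- volume_grid(prev + uptake,
                       if (inherits(pre, "volume_grid")) pre$spacing_mm
                       else config$voxel_spacing_mm)
  attr(early, "vessel_mask") <- vessel_mask
  early
}

# Curvilinear enhancing vessels: smooth 3D curves through the breast tissue,
# stamped as tubes of the configured radius.
rasterize_vessels <- function(breast_mask, config) {
  gs <- dim(breast_mask)
  vm <- array(FALSE, dim = gs)
  idx <- which(breast_mask)
  if (length(idx) == 0L) return(vm)
  co <- arrayInd(idx, gs)
  rv <- config$vessel_radius_vox
  ball <- as.matrix(expand.grid(dx = -rv:rv, dy = -rv:rv, dz = -rv:rv))
  ball <- ball[sqrt(rowSums(ball^2)) <= rv + 0.25, , drop = FALSE]
  for (v in seq_len(config$n_vessels)) {
    # control points ordered posterior -> anterior within the tissue
    qs <- stats::quantile(co[, 2], c(0.05, 0.35, 0.65, 0.92))
    ctrl <- t(vapply(seq_along(qs), function(j) {
      band <- which(abs(co[, 2] - qs[j]) <= max(2, 0.05 * gs[2]))
      if (length(band) == 0L) band <- seq_len(nrow(co))
      co[band[sample.int(length(band), 1L)], ]
    }, numeric(3)))
    tt <- seq(0, 1, length.out = nrow(ctrl))
    dense <- seq(0, 1, length.out = max(60L, 2L * max(gs)))
    path <- cbind(stats::spline(tt, ctrl[, 1], xout = dense)$y,
                  stats::spline(tt, ctrl[, 2], xout = dense)$y,
                  stats::spline(tt, ctrl[, 3], xout = dense)$y)
    path <- round(path)
    keep <- path[, 1] >= 1 & path[, 1] <= gs[1] &
      path[, 2] >= 1 & path[, 2] <= gs[2] &
      path[, 3] >= 1 & path[, 3] <= gs[3]
    path <- unique(path[keep, , drop = FALSE])
    for (p in seq_len(nrow(path))) {
      pts <- sweep(ball, 2L, path[p, ], "+")
      ok <- pts[, 1] >= 1 & pts[, 1] <= gs[1] &
        pts[, 2] >= 1 & pts[, 2] <= gs[2] &
        pts[, 3] >= 1 & pts[, 3] <= gs[3]
      vm[pts[ok, , drop = FALSE]] <- TRUE
    }
  }
  vm & breast_mask
}

#' Generate a synthetic patient cohort
#'
#' Emulates a two-phase DCE-MRI cohort: per-patient seeds are derived
#' deterministically from the master seed, each study gets an independent
#' phantom with its own lesion, and the early phase receives a small rigid
#' motion (drawn within `motion_translation_mm`) followed by fresh additive
#' noise, both applied after enhancement. Benign label counts follow
#' round-half-away-from-zero of `n_patients * benign_fraction`.
#'
#' @param n_patients number of studies (>= 1).
#' @param benign_fraction fraction of benign lesions in `[0, 1]`.
#' @param config_template a [phantom_config()] supplying everything except
#'   the per-patient label and seed.
#' @param seed master seed.
#' @param out_dir optional directory; when given, pre/early/mask volumes are
#'   written as NIfTI-1 (`.nii.gz`) and a `manifest.csv` with columns
#'   `patient_id,label,pre_path,early_path,mask_path` is created.
#' @return List with `studies` (list of `synthetic_study`) and `manifest`
#'   (data frame).
#' @export
generate_cohort <- function(n_patients, benign_fraction = 0.5,
                            config_template = phantom_config(),
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_patients >= 1)
  n_benign <- round_half_away(n_patients * benign_fraction)
  labels <- c(rep("benign", n_benign),
              rep("malignant", n_patients - n_benign))
  seeds <- derive_seeds(seed, n_patients + 1L)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seeds[n_patients + 1L])
  labels <- sample(labels)

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir)
  }

  studies <- vector("list", n_patients)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    cfg <- config_template
    cfg$lesion_label <- labels[i]
    cfg$uptake_amplitude <- if (labels[i] == "malignant") 0.8 else 0.25
    cfg$uptake_heterogeneity <- if (labels[i] == "malignant") 0.5 else 0.1
    cfg$rng_seed <- seeds[i]

    bg <- generate_breast_background(cfg)
    lesion <- place_nme_lesion(bg, bg$breast_mask, cfg)
    early0 <- apply_enhancement(bg$volume, lesion, bg$breast_mask, cfg)
    vessel_mask <- attr(early0, "vessel_mask")

    set.seed(cfg$rng_seed + 3000L)
    motion <- runif(3, -1, 1) * cfg$motion_translation_mm
    moved <- shift_volume(early0, motion)
    if (cfg$noise_sigma > 0)
      moved$values <- moved$values +
        array(rnorm(prod(cfg$grid_shape), sd = cfg$noise_sigma),
              dim = cfg$grid_shape)

    st <- structure(list(patient_id = pid,
                         pre_volume = bg$volume,
                         early_volume = moved,
                         lesion_mask = lesion,
                         vessel_mask = vessel_mask,
                         breast_mask = bg$breast_mask,
                         apices = bg$apices,
                         lesion_label = labels[i],
                         applied_motion = motion),
                    class = "synthetic_study")
    studies[[i]] <- st

    if (!is.null(out_dir)) {
      pp <- file.path(out_dir, paste0(pid, "_pre.nii.gz"))
      ep <- file.path(out_dir, paste0(pid, "_early.nii.gz"))
      mp <- file.path(out_dir, paste0(pid, "_mask.nii.gz"))
      write_volume(bg$volume, pp)
      write_volume(moved, ep)
      write_volume(volume_grid(array(as.numeric(lesion), dim = cfg$grid_shape),
                               cfg$voxel_spacing_mm), mp)
      rows[[i]] <- data.frame(patient_id = pid, label = labels[i],
                              pre_path = pp, early_path = ep, mask_path = mp,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(patient_id = pid, label = labels[i],
                              pre_path = NA_character_,
                              early_path = NA_character_,
                              mask_path = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(studies = studies, manifest = manifest)
}

# round() half-away-from-zero (R's round() rounds half to even).
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

# Translate a volume's content by `shift_mm` (rigid, no rotation); linear
# interpolation, zero outside the field of view.
shift_volume <- function(vol, shift_mm) {
  vol <- as_volume_grid(vol)
  res <- cpp_resample_rigid(as.numeric(vol$values), as.integer(vol$shape),
                            vol$spacing_mm, diag(3), -as.numeric(shift_mm),
                            c(0, 0, 0))
  vg_like(res$values, vol)
}

#' Enhancement separation of a synthetic study
#'
#' Undoes the applied inter-phase motion and contrasts the mean early-minus-
#' pre difference inside the lesion with the mean over the remaining breast
#' tissue (vessels excluded).
#'
#' @param study a `synthetic_study`.
#' @return Named list with `lesion` and `background` mean enhancement.
#' @export
enhancement_separation <- function(study) {
  early_undone <- shift_volume(study$early_volume, -study$applied_motion)
  d <- early_undone$values - study$pre_volume$values
  bg <- study$breast_mask & !study$lesion_mask & !study$vessel_mask
  list(lesion = mean(d[study$lesion_mask]), background = mean(d[bg]))
}
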