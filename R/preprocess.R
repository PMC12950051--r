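#' Rigid transform
#'
#' A 6-DOF rigid map acting on world (mm) coordinates:
#' `q = R (p - center) + center + translation`, with `R` composed from
#' extrinsic x-y-z Euler angles (`R = Rz Ry Rx`).
#'
#' @param translation_mm numeric length-3 translation in mm.
#' @param rotation_rad numeric length-3 extrinsic x-y-z Euler angles.
#' @param center_mm rotation centre in mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_rad = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_rad = as.numeric(rotation_rad),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

rt_rotmat <- function(rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Invert a rigid transform
#'
#' The inverse has rotation matrix `t(R)`; composing a transform with its
#' inverse is the identity map.
#' @param tf a [rigid_transform()].
#' @return A `rigid_transform` whose action undoes `tf` (expressed with the
#'   same rotation centre; the inverse of an Euler triple is returned as the
#'   negated angles applied in reverse order, folded into the matrix).
#' @export
rt_invert <- function(tf) {
  R <- rt_rotmat(tf$rotation_rad)
  # inverse rotation as extrinsic x-y-z angles of t(R)
  Ri <- t(R)
  ang <- c(atan2(Ri[3, 2], Ri[3, 3]),
           asin(pmin(1, pmax(-1, -Ri[3, 1]))),
           atan2(Ri[2, 1], Ri[1, 1]))
  rigid_transform(-as.numeric(Ri %*% tf$translation_mm), ang, tf$center_mm)
}

#' Resample a volume under a rigid transform
#'
#' Maps each output voxel centre `p` to `q = R (p - c) + c + t` and samples
#' the input there with trilinear interpolation; points outside the field of
#' view are set to zero.
#'
#' @param vol `volume_grid` to resample.
#' @param tf a [rigid_transform()].
#' @param with_mask when `TRUE`, also return the in-field indicator.
#' @return A `volume_grid` (or a list with `volume` and `inside`).
#' @export
resample_volume <- function(vol, tf, with_mask = FALSE) {
  vol <- as_volume_grid(vol)
  res <- cpp_resample_rigid(as.numeric(vol$values), as.integer(vol$shape),
                            vol$spacing_mm, rt_rotmat(tf$rotation_rad),
                            tf$translation_mm, tf$center_mm)
  out <- vg_like(res$values, vol)
  if (with_mask) list(volume = out, inside = array(res$inside, vol$shape)) else out
}

#' Registration settings
#'
#' @param mode `"rigid"` (6 DOF) or `"translation"` (3 DOF).
#' @param levels number of multi-resolution levels (coarse-to-fine).
#' @param max_iter Nelder-Mead iteration budget per level.
#' @param smooth_sigma Gaussian sigma (voxels) applied before downsampling.
#' @return A settings list.
#' @export
register_settings <- function(mode = c("rigid", "translation"),
                              levels = 3L, max_iter = 300L,
                              smooth_sigma = 1) {
  list(mode = match.arg(mode), levels = as.integer(levels),
       max_iter = as.integer(max_iter), smooth_sigma = smooth_sigma)
}

downsample2 <- function(vol) {
  v <- gauss_smooth(vol$values, c(1, 1, 1))
  d <- dim(v)
  ix <- seq(1L, d[1], by = 2L); iy <- seq(1L, d[2], by = 2L)
  iz <- seq(1L, d[3], by = 2L)
  volume_grid(v[ix, iy, iz, drop = FALSE], vol$spacing_mm * 2)
}

#' Rigid intensity-based registration
#'
#' Aligns `moving` onto the grid of `fixed` by minimising the mean squared
#' intensity difference over a multi-resolution schedule (Nelder-Mead over
#' the rigid parameters, coarse-to-fine, rotation centre at the volume
#' centre). Deterministic: no randomness is involved.
#'
#' @param fixed,moving `volume_grid`s sharing voxel spacing.
#' @param settings a [register_settings()].
#' @return List with `transform` (the recovered [rigid_transform()]; applying
#'   it to `moving` via [resample_volume()] aligns it with `fixed`),
#'   `resampled` (moving resampled into the fixed grid), `cost_trace`.
#' @export
register_rigid <- function(fixed, moving, settings = register_settings()) {
  fixed <- as_volume_grid(fixed); moving <- as_volume_grid(moving)
  if (!isTRUE(all.equal(fixed$spacing_mm, moving$spacing_mm)))
    stop("fixed and moving volumes must share voxel spacing")
  check_same_grid(fixed, moving)

  pyr_f <- list(fixed); pyr_m <- list(moving)
  lv <- settings$levels
  while (length(pyr_f) < lv && all(dim(pyr_f[[length(pyr_f)]]$values) >= 32)) {
    pyr_f[[length(pyr_f) + 1L]] <- downsample2(pyr_f[[length(pyr_f)]])
    pyr_m[[length(pyr_m) + 1L]] <- downsample2(pyr_m[[length(pyr_m)]])
  }

  n_par <- if (settings$mode == "translation") 3L else 6L
  par <- rep(0, n_par)
  center <- (fixed$shape - 1) * fixed$spacing_mm / 2
  trace <- numeric(0)

  cost_fn <- function(par, fvol, mvol) {
    tf <- par_to_tf(par, center)
    res <- cpp_resample_rigid(as.numeric(mvol$values), as.integer(mvol$shape),
                              mvol$spacing_mm, rt_rotmat(tf$rotation_rad),
                              tf$translation_mm, tf$center_mm)
    inside <- res$inside
    if (!any(inside)) return(Inf)
    mean((res$values[inside] - fvol$values[inside])^2)
  }

  for (l in rev(seq_along(pyr_f))) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    parscale <- c(rep(1, 3), rep(0.02, n_par - 3L))[seq_len(n_par)]
    opt <- stats::optim(par, function(p) cost_fn(p, f, m),
                        method = "Nelder-Mead",
                        control = list(maxit = settings$max_iter,
                                       parscale = parscale,
                                       reltol = 1e-10))
    par <- opt$par
    trace <- c(trace, opt$value)
  }

  initial_cost <- cost_fn(rep(0, n_par), fixed, moving)
  final_cost <- cost_fn(par, fixed, moving)
  if (final_cost > initial_cost) {
    e <- simpleError(sprintf(
      "registration failure: cost increased (%.4g -> %.4g)",
      initial_cost, final_cost))
    e$cost_trace <- c(initial = initial_cost, trace, final = final_cost)
    stop(e)
  }
  tf <- par_to_tf(par, center)
  list(transform = tf, resampled = resample_volume(moving, tf),
       cost_trace = c(initial = initial_cost, trace, final = final_cost))
}

par_to_tf <- function(par, center) {
  if (length(par) == 3L) rigid_transform(par, c(0, 0, 0), center)
  else rigid_transform(par[1:3], par[4:6], center)
}

#' Positive-clamped subtraction image
#'
#' Voxel-wise `max(early_aligned - pre, 0)`: regions of increased signal due
#' to contrast uptake are preserved while negative differences, typically
#' noise or minor registration inaccuracy, are set to zero.
#'
#' @param early_aligned,pre `volume_grid`s (or arrays) on the same grid.
#' @return A `volume_grid` (or array, matching the input type).
#' @export
subtract_clamp <- function(early_aligned, pre) {
  check_same_grid(early_aligned, pre, "subtraction inputs")
  d <- pmax(vg_values(early_aligned) - vg_values(pre), 0)
  if (inherits(early_aligned, "volume_grid")) vg_like(d, early_aligned) else d
}

#' Gray-level breast foreground segmentation
#'
#' Otsu-thresholds the intensity histogram, picks as foreground the side of
#' the threshold that is (proportionally) absent from the most anterior
#' image border (so the operation is invariant to global contrast
#' inversion), retains connected components reaching the anterior half of
#' the volume, and applies a morphological closing.
#'
#' @param early `volume_grid` or 3D array (early post-contrast image).
#' @param close_radius box closing radius in voxels.
#' @return Binary 3D array marking the breast foreground.
#' @export
segment_breast_foreground <- function(early, close_radius = 1L) {
  x <- vg_values(early)
  thr <- otsu_threshold(x)
  hi <- x > thr
  ny <- dim(x)[2]
  border_hi <- mean(hi[, ny, ])
  fg <- if (border_hi <= 0.5) hi else !hi
  lab <- label_components(fg)
  if (lab$n == 0L) return(array(FALSE, dim(x)))
  anterior <- lab$labels[, (floor(ny / 2) + 1L):ny, , drop = FALSE]
  keep <- setdiff(unique(as.integer(anterior)), 0L)
  fg <- array(lab$labels %in% keep, dim(x))
  morph_close(fg, close_radius)
}

#' Detect nipple and sternum landmarks
#'
#' Per lateral half of the image the nipple is the foreground voxel with the
#' maximal anterior (y) coordinate, ties resolved toward that half's
#' foreground centroid; the midpoint is the rounded mean of the two nipples;
#' the sternum point is the most anterior foreground voxel on the midline
#' column strictly posterior to the midpoint.
#'
#' @param foreground binary 3D array.
#' @return List with `left_nipple`, `right_nipple`, `midpoint`,
#'   `sternum_point`: integer (x, y, z) voxel coordinates, 1-based.
#' @export
detect_landmarks <- function(foreground) {
  d <- dim(foreground)
  nx <- d[1]; ny <- d[2]
  mid_x <- floor(nx / 2)
  half_apex <- function(xs, side) {
    sub <- foreground[xs, , , drop = FALSE]
    idx <- which(sub)
    if (length(idx) == 0L)
      stop(sprintf("landmark failure: no foreground in the %s half", side))
    co <- arrayInd(idx, dim(sub))
    anterior <- co[co[, 2] > floor(ny / 2), , drop = FALSE]
    if (nrow(anterior) == 0L)
      stop(sprintf("landmark failure: no anterior breast mound in the %s half",
                   side))
    ymax <- max(co[, 2])
    cand <- co[co[, 2] == ymax, , drop = FALSE]
    ctr <- colMeans(co)
    best <- which.min((cand[, 1] - ctr[1])^2 + (cand[, 3] - ctr[3])^2)
    p <- cand[best, ]
    p[1] <- p[1] + xs[1] - 1L
    as.integer(p)
  }
  left <- half_apex(1:mid_x, "left")
  right <- half_apex((mid_x + 1L):nx, "right")
  midpoint <- as.integer(round((left + right) / 2))
  col_mask <- foreground[midpoint[1], , , drop = FALSE]
  idx <- which(col_mask)
  if (length(idx) > 0L) {
    co <- arrayInd(idx, dim(col_mask))
    co <- co[co[, 2] < midpoint[2], , drop = FALSE]
  } else co <- matrix(numeric(0), 0, 3)
  if (nrow(co) == 0L)
    stop("landmark failure: no midline foreground posterior to the nipple midpoint")
  ymax <- max(co[, 2])
  cand <- co[co[, 2] == ymax, , drop = FALSE]
  best <- which.min(abs(cand[, 3] - midpoint[3]))
  sternum <- as.integer(c(midpoint[1], ymax, cand[best, 3]))
  list(left_nipple = left, right_nipple = right,
       midpoint = midpoint, sternum_point = sternum)
}

#' Landmark-driven breast ROI extraction
#'
#' Forms the rectangle spanning the full left-right extent and the anterior-
#' posterior interval between the sternum landmark and the nipple level
#' (the more anterior of the two nipples), then centrally crops it -- or
#' symmetrically zero-pads when smaller -- to `target_inplane` square
#' in-plane. All slices are retained and the identical integer window is
#' applied to every volume passed in.
#'
#' @param volumes named list of `volume_grid`s / 3D arrays on one grid
#'   (e.g. pre, early, diff, mask).
#' @param landmarks result of [detect_landmarks()].
#' @param target_inplane output in-plane edge length (default 176).
#' @param pad allow symmetric zero-padding when the rectangle is smaller
#'   than the target; when `FALSE` such inputs raise a crop error.
#' @return List with `volumes` (cropped, same names/types) and `roi_spec`
#'   (windows in input coordinates, JSON-serialisable).
#' @export
extract_roi <- function(volumes, landmarks, target_inplane = 176L, pad = TRUE) {
  stopifnot(length(volumes) >= 1L)
  d <- dim(vg_values(volumes[[1]]))
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  t <- as.integer(target_inplane)
  if (t > nx && !pad)
    stop("crop error: target_inplane exceeds the grid and padding is disabled")
  y0 <- landmarks$sternum_point[2]
  y1 <- max(landmarks$left_nipple[2], landmarks$right_nipple[2])
  if (y1 < y0) stop("crop error: nipple level posterior to sternum landmark")
  x_start <- 1L + floor((nx - t) / 2)           # may be <= 0 when padding
  h <- y1 - y0 + 1L
  y_start <- y0 + floor((h - t) / 2)
  if (h < t && !pad)
    stop("crop error: landmark rectangle smaller than target and padding disabled")
  spec <- list(x_start = x_start, y_start = y_start, z_start = 1L,
               target_inplane = t, n_slices = nz, input_shape = d,
               y_rect = c(y0, y1))
  out <- lapply(volumes, function(v) crop_window(v, spec))
  list(volumes = out, roi_spec = spec)
}

crop_window <- function(v, spec) {
  arr <- vg_values(v)
  d <- dim(arr)
  t <- spec$target_inplane
  is_log <- is.logical(arr)
  out <- array(if (is_log) FALSE else 0, dim = c(t, t, d[3]))
  xs <- spec$x_start:(spec$x_start + t - 1L)
  ys <- spec$y_start:(spec$y_start + t - 1L)
  ok_x <- xs >= 1L & xs <= d[1]
  ok_y <- ys >= 1L & ys <= d[2]
  out[which(ok_x), which(ok_y), ] <- arr[xs[ok_x], ys[ok_y], , drop = FALSE]
  if (inherits(v, "volume_grid")) volume_grid(out, v$spacing_mm) else out
}

#' Serialize an ROI specification to JSON
#' @param roi_spec the `roi_spec` element returned by [extract_roi()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_spec <- function(roi_spec, path) {
  jsonlite::write_json(roi_spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Full image preparation for one study
#'
#' Chains the preparation pipeline: rigid registration of the early phase
#' onto the pre-contrast grid (the pre-contrast image is the fixed image),
#' positive-clamped subtraction, gray-level foreground segmentation,
#' landmark detection, and the fixed-size ROI crop applied identically to
#' the pre, aligned early, difference and annotation volumes.
#'
#' @param pre,early `volume_grid`s.
#' @param mask optional binary ground-truth mask on the pre-contrast grid.
#' @param target_inplane ROI edge length.
#' @param register apply rigid registration (set `FALSE` for already-aligned
#'   inputs).
#' @param settings registration settings.
#' @return List with cropped `pre`, `early`, `diff`, `mask`, plus
#'   `roi_spec`, `transform` and `landmarks`.
#' @export
preprocess_study <- function(pre, early, mask = NULL, target_inplane = 176L,
                             register = TRUE,
                             settings = register_settings("translation")) {
  pre <- as_volume_grid(pre); early <- as_volume_grid(early)
  tf <- NULL
  early_aligned <- early
  if (register) {
    reg <- register_rigid(pre, early, settings)
    tf <- reg$transform
    early_aligned <- reg$resampled
  }
  diff <- subtract_clamp(early_aligned, pre)
  fg <- segment_breast_foreground(early_aligned)
  lm <- detect_landmarks(fg)
  vols <- list(pre = pre, early = early_aligned, diff = diff)
  if (!is.null(mask)) vols$mask <- vg_values(mask)
  roi <- extract_roi(vols, lm, target_inplane = target_inplane)
  c(roi$volumes,
    list(roi_spec = roi$roi_spec, transform = tf, landmarks = lm))
}
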