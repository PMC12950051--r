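#' Construct a voxel grid volume
#'
#' The universal image carrier: a 3D scalar field with voxel spacing. The axis
#' convention used throughout the package is x = left-right, y = posterior to
#' anterior (increasing y is more anterior), z = inferior to superior;
#' indices are voxel-centred.
#'
#' @param values 3D numeric array (nx, ny, nz).
#' @param spacing_mm numeric length-3, voxel spacing in mm (all > 0).
#' @return An object of class `volume_grid` with fields `values`, `spacing_mm`
#'   and `shape`.
#' @export
volume_grid <- function(values, spacing_mm = c(1, 1, 1)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive numbers")
  if (!all(is.finite(values)))
    stop("volume values must be finite")
  structure(list(values = values, spacing_mm = spacing_mm,
                 shape = dim(values)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %d x %d x %d, spacing %.3g x %.3g x %.3g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

as_volume_grid <- function(x, spacing_mm = c(1, 1, 1)) {
  if (inherits(x, "volume_grid")) x else volume_grid(x, spacing_mm)
}

vg_values <- function(x) if (inherits(x, "volume_grid")) x$values else x

vg_like <- function(values, template) {
  volume_grid(array(values, dim = template$shape), template$spacing_mm)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(vg_values(a)), dim(vg_values(b))))
    stop(sprintf("%s must share the same grid shape", what))
  invisible(TRUE)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the package's spacing convention.
#' @param path file path, typically ending in `.nii.gz`.
#' @param vol a `volume_grid` (for writing).
#' @return `read_volume` returns a `volume_grid`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]), sp)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume_grid(vol)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Global Otsu threshold on a 3D intensity histogram (256 bins).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("degenerate input: constant intensity volume has no threshold")
  h <- tabulate(pmin(n_bins, 1L + as.integer((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

# Connected components (6-connectivity); returns integer array of labels.
label_components <- function(mask) {
  d <- dim(mask)
  res <- cpp_label3d(as.logical(mask), as.integer(d))
  list(labels = array(res$labels, dim = d), n = res$n)
}

morph_close <- function(mask, r = 1L) {
  d <- dim(mask)
  m <- cpp_box_morph(as.logical(mask), as.integer(d), as.integer(r), TRUE)
  m <- cpp_box_morph(m, as.integer(d), as.integer(r), FALSE)
  array(m, dim = d)
}

morph_dilate <- function(mask, r = 1L) {
  d <- dim(mask)
  array(cpp_box_morph(as.logical(mask), as.integer(d), as.integer(r), TRUE), dim = d)
}

gauss_smooth <- function(x, sigma_vox) {
  d <- dim(x)
  sigma_vox <- rep_len(as.numeric(sigma_vox), 3L)
  array(cpp_gauss_blur3(as.numeric(x), as.integer(d), sigma_vox), dim = d)
}

# Per-volume min-max scaling to [0, 1]; constant volumes map to all zeros.
normalize_minmax <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(array(0, dim = dim(x)))
  (x - rng[1]) / diff(rng)
}

# Deterministic fan-out of one master seed into per-entity seeds (< 2^31).
derive_seeds <- function(master_seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
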