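#' Augmentation configuration
#'
#' The seven on-the-fly training augmentations — intensity scaling,
#' contrast (gamma) adjustment, Gaussian smoothing, Gaussian sharpening,
#' flipping, rotation and elastic 3D deformation — each applied
#' independently with probability `probability` (default 0.3). The flip
#' axis is drawn uniformly from `flip_axes` (one axis per draw), the
#' rotation angle uniformly from `[-rotation_range, +rotation_range]`
#' radians about the axial axis, and the remaining transform parameters
#' uniformly from their ranges. One shared random stream drives all draws,
#' so a single seed reproduces the whole augmentation.
#'
#' @param probability per-transform application chance in \[0, 1\].
#' @param rotation_range maximum rotation magnitude in radians (default
#'   0.4).
#' @param flip_axes subset of `c(1, 2, 3)` the flip axis is drawn from.
#' @param intensity_scale_range multiplicative intensity factor range.
#' @param contrast_gamma_range gamma range for contrast adjustment.
#' @param gaussian_smooth_sigma_range smoothing sigma range in voxels.
#' @param gaussian_sharpen_range unsharp-mask amount range.
#' @param elastic_magnitude displacement magnitude range in voxels.
#' @param elastic_grid_spacing control-grid spacing in voxels for the
#'   elastic field.
#' @param seed default seed used by [apply_augmentations()].
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(probability = 0.3, rotation_range = 0.4,
                           flip_axes = c(1, 2, 3),
                           intensity_scale_range = c(0.9, 1.1),
                           contrast_gamma_range = c(0.7, 1.4),
                           gaussian_smooth_sigma_range = c(0.25, 1),
                           gaussian_sharpen_range = c(0.1, 0.5),
                           elastic_magnitude = c(1, 4),
                           elastic_grid_spacing = 8,
                           seed = NULL) {
  stopifnot(probability >= 0, probability <= 1, rotation_range >= 0,
            all(flip_axes %in% 1:3), elastic_grid_spacing >= 2)
  for (rg in list(intensity_scale_range, contrast_gamma_range,
                  gaussian_smooth_sigma_range, gaussian_sharpen_range,
                  elastic_magnitude))
    if (length(rg) != 2 || rg[1] > rg[2] || any(rg < 0))
      stop("augmentation ranges must be ordered pairs of non-negative values",
           call. = FALSE)
  structure(list(probability = probability, rotation_range = rotation_range,
                 flip_axes = as.integer(flip_axes),
                 intensity_scale_range = intensity_scale_range,
                 contrast_gamma_range = contrast_gamma_range,
                 gaussian_smooth_sigma_range = gaussian_smooth_sigma_range,
                 gaussian_sharpen_range = gaussian_sharpen_range,
                 elastic_magnitude = elastic_magnitude,
                 elastic_grid_spacing = elastic_grid_spacing,
                 seed = seed),
            class = "augment_config")
}

#' Apply seeded augmentations to an image/mask pair
#'
#' Draws and applies the seven transforms of [augment_config()] in a fixed
#' order (intensity scale, gamma, smooth, sharpen, flip, rotation,
#' elastic). Spatial transforms are applied identically to image and mask,
#' with the mask resampled nearest-neighbour so it stays exactly binary;
#' intensity-only transforms never touch the mask. Deterministic for a
#' fixed seed.
#'
#' @param v a `volume`.
#' @param m a `binary_mask` of the same shape.
#' @param cfg an [augment_config()].
#' @param seed seed for this draw; defaults to `cfg$seed`.
#' @return `list(volume =, mask =)`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(16, 16, 8), seed = 0))
#' out <- apply_augmentations(ph$volume, ph$gt, augment_config(seed = 1))
#' @export
apply_augmentations <- function(v, m, cfg = augment_config(),
                                seed = cfg$seed) {
  check_same_shape(v, m)
  arr <- grid_of(v)
  mk <- grid_of(m)
  with_local_seed(seed, {
    p <- cfg$probability
    apply_flags <- stats::runif(7) < p

    if (apply_flags[1]) {  # intensity scaling
      f <- stats::runif(1, cfg$intensity_scale_range[1], cfg$intensity_scale_range[2])
      arr <- arr * f
    }
    if (apply_flags[2]) {  # contrast (gamma on the normalized range)
      gma <- stats::runif(1, cfg$contrast_gamma_range[1], cfg$contrast_gamma_range[2])
      rng <- range(arr)
      if (gma != 1 && rng[2] > rng[1])
        arr <- ((arr - rng[1]) / (rng[2] - rng[1]))^gma * (rng[2] - rng[1]) + rng[1]
    }
    if (apply_flags[3]) {  # Gaussian smoothing
      sg <- stats::runif(1, cfg$gaussian_smooth_sigma_range[1],
                         cfg$gaussian_smooth_sigma_range[2])
      arr <- gaussian_smooth3(arr, sg)
    }
    if (apply_flags[4]) {  # Gaussian sharpening (unsharp mask)
      amt <- stats::runif(1, cfg$gaussian_sharpen_range[1],
                          cfg$gaussian_sharpen_range[2])
      arr <- arr + amt * (arr - gaussian_smooth3(arr, 1))
    }
    if (apply_flags[5]) {  # flip along one random axis
      ax <- cfg$flip_axes[sample.int(length(cfg$flip_axes), 1)]
      arr <- flip_axis(arr, ax)
      mk <- flip_axis(mk, ax)
    }
    if (apply_flags[6]) {  # rotation about the axial axis
      th <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
      arr <- rotate_axial(arr, th, nearest = FALSE)
      mk <- rotate_axial(mk, th, nearest = TRUE)
    }
    if (apply_flags[7]) {  # elastic 3D deformation
      mag <- stats::runif(1, cfg$elastic_magnitude[1], cfg$elastic_magnitude[2])
      disp <- elastic_field(dim(arr), mag, cfg$elastic_grid_spacing)
      arr <- warp_volume(arr, disp, nearest = FALSE)
      mk <- warp_volume(mk, disp, nearest = TRUE)
    }
    list(volume = as_volume(arr, spacing_of(v)),
         mask = as_mask(array(as.integer(mk), dim(mk)), spacing_of(m)))
  })
}

flip_axis <- function(arr, ax) {
  d <- dim(arr)
  idx <- rev(seq_len(d[ax]))
  if (ax == 1) arr[idx, , , drop = FALSE]
  else if (ax == 2) arr[, idx, , drop = FALSE]
  else arr[, , idx, drop = FALSE]
}

gaussian_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    n <- d[ax]
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- if (ax == 1) arr[idx, , , drop = FALSE]
                 else if (ax == 2) arr[, idx, , drop = FALSE]
                 else arr[, , idx, drop = FALSE]
      out <- out + k[o + r + 1L] * shifted
    }
    arr <- out
  }
  arr
}

# Rotate every axial slice by theta about the slice centre; source sampled
# bilinearly (or nearest for masks) with replicate clamping at the borders.
rotate_axial <- function(arr, theta, nearest = FALSE) {
  d <- dim(arr)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  xs <- seq_len(d[1]) - cx
  ys <- seq_len(d[2]) - cy
  X <- matrix(xs, d[1], d[2])
  Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  # inverse mapping: source = R(-theta) * target
  sx <- cos(theta) * X + sin(theta) * Y + cx
  sy <- -sin(theta) * X + cos(theta) * Y + cy
  out <- array(0, d)
  for (k in seq_len(d[3]))
    out[, , k] <- sample_plane(arr[, , k], sx, sy, nearest)
  out
}

sample_plane <- function(sl, sx, sy, nearest) {
  d <- dim(sl)
  if (nearest) {
    ix <- pmin(pmax(round(sx), 1L), d[1])
    iy <- pmin(pmax(round(sy), 1L), d[2])
    return(matrix(sl[cbind(as.vector(ix), as.vector(iy))], d[1], d[2]))
  }
  sx <- pmin(pmax(sx, 1), d[1]); sy <- pmin(pmax(sy, 1), d[2])
  x0 <- pmin(floor(sx), d[1] - 1L); y0 <- pmin(floor(sy), d[2] - 1L)
  wx <- sx - x0; wy <- sy - y0
  g <- function(ix, iy) matrix(sl[cbind(as.vector(ix), as.vector(iy))], d[1], d[2])
  g(x0, y0) * (1 - wx) * (1 - wy) + g(x0 + 1, y0) * wx * (1 - wy) +
    g(x0, y0 + 1) * (1 - wx) * wy + g(x0 + 1, y0 + 1) * wx * wy
}

# Smooth random displacement field: per-axis coarse-grid components drawn
# uniform(-mag, mag) voxels, upsampled trilinearly to the full grid.
elastic_field <- function(d, mag, grid_spacing) {
  coarse <- pmax(2L, ceiling(d / grid_spacing) + 1L)
  co <- lapply(1:3, function(a) seq(1, coarse[a], length.out = d[a]))
  lapply(1:3, function(a) {
    cg <- array(stats::runif(prod(coarse), -mag, mag), coarse)
    sample_trilinear(cg, co[[1]], co[[2]], co[[3]])
  })
}

warp_volume <- function(arr, disp, nearest = FALSE) {
  d <- dim(arr)
  out <- array(0, d)
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  sx <- pmin(pmax(X + disp[[1]], 1), d[1])
  sy <- pmin(pmax(Y + disp[[2]], 1), d[2])
  sz <- pmin(pmax(Z + disp[[3]], 1), d[3])
  if (nearest) {
    idx <- cbind(as.vector(round(sx)), as.vector(round(sy)), as.vector(round(sz)))
    return(array(arr[idx], d))
  }
  x0 <- pmin(floor(sx), d[1] - 1L); y0 <- pmin(floor(sy), d[2] - 1L)
  z0 <- pmin(floor(sz), d[3] - 1L)
  wx <- sx - x0; wy <- sy - y0; wz <- sz - z0
  g <- function(ix, iy, iz)
    array(arr[cbind(as.vector(ix), as.vector(iy), as.vector(iz))], d)
  g(x0, y0, z0) * (1 - wx) * (1 - wy) * (1 - wz) +
    g(x0 + 1, y0, z0) * wx * (1 - wy) * (1 - wz) +
    g(x0, y0 + 1, z0) * (1 - wx) * wy * (1 - wz) +
    g(x0, y0, z0 + 1) * (1 - wx) * (1 - wy) * wz +
    g(x0 + 1, y0 + 1, z0) * wx * wy * (1 - wz) +
    g(x0 + 1, y0, z0 + 1) * wx * (1 - wy) * wz +
    g(x0, y0 + 1, z0 + 1) * (1 - wx) * wy * wz +
    g(x0 + 1, y0 + 1, z0 + 1) * wx * wy * wz
}
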