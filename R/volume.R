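#' 3D image volumes and binary masks
#'
#' A `volume` is a 3D array of scalar intensities plus a physical voxel
#' spacing in mm. A `binary_mask` is the same container restricted to values
#' in \{0, 1\}. The axis convention used throughout the package is fixed:
#' axis 1 indexes the sagittal direction, axis 2 the coronal direction and
#' axis 3 the axial slice, so `v$data[, , k]` is an axial slice.
#'
#' @param data a numeric 3D array; for masks every element must be 0 or 1.
#' @param spacing numeric length-3 voxel spacing in mm, all strictly positive
#'   and finite.
#' @return An object of class `volume` (or `binary_mask`) with elements
#'   `data` and `spacing`.
#' @examples
#' v <- as_volume(array(runif(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 2))
#' m <- as_mask(array(0L, c(8, 8, 4)), spacing = c(1, 1, 2))
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  check_grid(data, spacing)
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "volume")
}

#' @rdname as_volume
#' @export
as_mask <- function(data, spacing = c(1, 1, 1)) {
  check_grid(data, spacing, allow_nonfinite = FALSE)
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1)))
    stop("mask values must all be 0 or 1", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

check_grid <- function(data, spacing, allow_nonfinite = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array", call. = FALSE)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)",
         call. = FALSE)
  if (!allow_nonfinite && any(!is.finite(data)))
    stop("data contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

is_volume <- function(x) inherits(x, "volume")
is_mask <- function(x) inherits(x, "binary_mask")

# Accept volume/binary_mask or bare array; return the 3D array.
grid_of <- function(x) {
  if (is_volume(x) || is_mask(x)) x$data else x
}

spacing_of <- function(x, default = c(1, 1, 1)) {
  if (is_volume(x) || is_mask(x)) x$spacing else default
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, intensity [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d foreground (%.1f%%)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(grid_of(a)), dim(grid_of(b))))
    stop("grids have different shapes: ",
         paste(dim(grid_of(a)), collapse = "x"), " vs ",
         paste(dim(grid_of(b)), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI volume or binary mask
#'
#' Volumes are read with their native intensity scale and the voxel spacing
#' taken from the file header; when the file carries a spatial transform the
#' data are reoriented to the closest-to-RAS canonical orientation so that
#' the axial plane is always the third axis. `read_mask()` additionally
#' binarizes the data: voxels above 0.5 map to 1, all others to 0.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [as_volume()] `volume` (or `binary_mask`).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  img <- try_reorient(img)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
    pd <- RNifti::pixdim(img)[1:3]
    return(finish_read(img2, pd, path))
  }
  if (length(d) != 3L)
    stop("not a 3D image (", length(d), " dimensions): ", path, call. = FALSE)
  finish_read(array(as.numeric(img), d), RNifti::pixdim(img)[1:3], path)
}

finish_read <- function(arr, pd, path) {
  if (any(!is.finite(arr)))
    stop("image contains NaN/Inf voxels: ", path, call. = FALSE)
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("invalid voxel spacing in header of ", path, call. = FALSE)
  as_volume(arr, pd)
}

try_reorient <- function(img) {
  # images written without qform/sform (e.g. the package's own output) are
  # used as-is; RNifti warns about the missing transform, which is expected
  out <- try(
    suppressWarnings({
      if (!is.na(RNifti::orientation(img))) RNifti::orientation(img) <- "RAS"
      img
    }),
    silent = TRUE
  )
  if (inherits(out, "try-error")) img else out
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  as_mask(array(as.integer(v$data > 0.5), dim(v$data)), v$spacing)
}

#' Write a volume or mask to NIfTI
#'
#' Writes the grid and spacing such that [read_volume()] reproduces both
#' exactly. Masks are stored as unsigned 8-bit integers; volumes as 64-bit
#' floats.
#'
#' @param v a `volume` or `binary_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  arr <- grid_of(v)
  storage.mode(arr) <- if (is_mask(v)) "integer" else "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_of(v)
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask(v)) "uint8" else "double")
  invisible(path)
}

#' Resample a volume or mask to a target grid shape
#'
#' Resampling preserves the physical extent: the output spacing is the input
#' spacing scaled by the shape ratio, so `shape * spacing` is unchanged.
#' Intensity volumes use trilinear interpolation, masks nearest-neighbour
#' (so they stay binary); passing `mode = "linear"` for a mask is an error.
#'
#' @param v a `volume` or `binary_mask`.
#' @param target_shape integer length-3, each component at least 2.
#' @param mode `"auto"` (linear for volumes, nearest for masks), `"linear"`
#'   or `"nearest"`.
#' @return An object of the same class as `v` with `dim(v$data) ==
#'   target_shape`.
#' @export
resample_to_shape <- function(v, target_shape,
                              mode = c("auto", "linear", "nearest")) {
  mode <- match.arg(mode)
  if (length(target_shape) != 3L || any(target_shape < 2))
    stop("target_shape must have three components >= 2", call. = FALSE)
  target_shape <- as.integer(target_shape)
  if (is_mask(v)) {
    if (mode == "linear")
      stop("linear interpolation would break the binary mask; use nearest",
           call. = FALSE)
    mode <- "nearest"
  } else if (mode == "auto") mode <- "linear"

  src <- grid_of(v)
  d <- dim(src)
  sp_out <- spacing_of(v) * d / target_shape
  if (identical(d, target_shape)) {
    out <- src
  } else {
    # voxel-centre aligned source coordinates per output index
    co <- lapply(1:3, function(a)
      (seq_len(target_shape[a]) - 0.5) * d[a] / target_shape[a] + 0.5)
    out <- if (mode == "nearest") sample_nearest(src, co[[1]], co[[2]], co[[3]])
           else sample_trilinear(src, co[[1]], co[[2]], co[[3]])
  }
  if (is_mask(v)) as_mask(array(as.integer(out), target_shape), sp_out)
  else as_volume(out, sp_out)
}

# Separable grid sampling: xs, ys, zs are per-axis source coordinates
# (1-based, voxel centres); returns array length(xs) x length(ys) x length(zs).
sample_nearest <- function(src, xs, ys, zs) {
  d <- dim(src)
  ix <- pmin(pmax(round(xs), 1L), d[1])
  iy <- pmin(pmax(round(ys), 1L), d[2])
  iz <- pmin(pmax(round(zs), 1L), d[3])
  src[ix, iy, iz, drop = FALSE]
}

sample_trilinear <- function(src, xs, ys, zs) {
  d <- dim(src)
  ax <- lin_weights(xs, d[1]); ay <- lin_weights(ys, d[2]); az <- lin_weights(zs, d[3])
  out <- array(0, c(length(xs), length(ys), length(zs)))
  for (k in seq_along(zs)) {
    s0 <- src[, , az$i0[k]]; s1 <- src[, , az$i1[k]]
    sl <- s0 * (1 - az$w[k]) + s1 * az$w[k]
    # bilinear in-plane via two matrix gathers per axis
    m <- sl[ax$i0, , drop = FALSE] * (1 - ax$w) + sl[ax$i1, , drop = FALSE] * ax$w
    out[, , k] <- sweep(m[, ay$i0, drop = FALSE], 2, 1 - ay$w, "*") +
                  sweep(m[, ay$i1, drop = FALSE], 2, ay$w, "*")
  }
  out
}

lin_weights <- function(coord, n) {
  c0 <- pmin(pmax(coord, 1), n)
  i0 <- pmin(floor(c0), n - 1L)
  list(i0 = as.integer(i0), i1 = as.integer(i0 + 1L), w = c0 - i0)
}

#' Min-max intensity normalization
#'
#' Affinely rescales a volume's intensities to span \[0, 1\], the same
#' normalization applied to network inputs. A constant volume (no intensity
#' range) maps to all zeros with a warning.
#'
#' @param v a `volume`.
#' @return A `volume` with `min(data) == 0` and `max(data) == 1` (all zeros
#'   in the degenerate constant case); spacing unchanged.
#' @export
minmax_normalize <- function(v) {
  arr <- grid_of(v)
  rng <- range(arr)
  if (rng[1] == rng[2]) {
    warning("constant volume: min-max normalization returns all zeros")
    return(as_volume(array(0, dim(arr)), spacing_of(v)))
  }
  as_volume((arr - rng[1]) / (rng[2] - rng[1]), spacing_of(v))
}
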