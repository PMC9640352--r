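#' Voxel-wise confusion counts between two binary masks
#'
#' Counts true positives, false positives, false negatives and true
#' negatives over the full grid, with the first argument taken as ground
#' truth.
#'
#' @param gt,pred `binary_mask` objects (or bare \{0,1\} arrays) of equal
#'   shape.
#' @return A list of class `confusion_counts` with integer elements `tp`,
#'   `fp`, `fn`, `tn` summing to the voxel count.
#' @export
confusion_counts <- function(gt, pred) {
  check_same_shape(gt, pred)
  g <- grid_of(gt); p <- grid_of(pred)
  tp <- sum(g == 1 & p == 1)
  fp <- sum(g == 0 & p == 1)
  fn <- sum(g == 1 & p == 0)
  tn <- length(g) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

as_counts <- function(x) {
  if (inherits(x, "confusion_counts")) x
  else stop("expected confusion_counts", call. = FALSE)
}

#' Overlap metrics from confusion counts
#'
#' The clinical overlap suite: Dice similarity coefficient
#' \eqn{2TP/(2TP+FP+FN)}, Jaccard index \eqn{TP/(TP+FP+FN)},
#' over-segmentation \eqn{OS = 2FP/(|GT|+|Pred|)} and under-segmentation
#' \eqn{US = 2FN/(|GT|+|Pred|)} with \eqn{|GT| = TP+FN},
#' \eqn{|Pred| = TP+FP}. These satisfy the identities
#' `os + us == 2 * (1 - dice)` and `jaccard == dice / (2 - dice)`.
#' When both masks are empty the pair is defined as a perfect match:
#' Dice = Jaccard = 1 and OS = US = 0. Note US reaches 2 when the
#' prediction is empty but the ground truth is not.
#'
#' @param c a `confusion_counts` object from [confusion_counts()].
#' @return A single numeric value.
#' @examples
#' cc <- structure(list(tp = 6, fp = 2, fn = 2, tn = 54),
#'                 class = "confusion_counts")
#' dice(cc); jaccard(cc); over_seg(cc); under_seg(cc)
#' @export
dice <- function(c) {
  c <- as_counts(c)
  if (c$tp + c$fp + c$fn == 0) return(1)
  2 * c$tp / (2 * c$tp + c$fp + c$fn)
}

#' @rdname dice
#' @export
jaccard <- function(c) {
  c <- as_counts(c)
  if (c$tp + c$fp + c$fn == 0) return(1)
  c$tp / (c$tp + c$fp + c$fn)
}

#' @rdname dice
#' @export
over_seg <- function(c) {
  c <- as_counts(c)
  den <- 2 * c$tp + c$fp + c$fn   # |GT| + |Pred|
  if (den == 0) return(0)
  2 * c$fp / den
}

#' @rdname dice
#' @export
under_seg <- function(c) {
  c <- as_counts(c)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(0)
  2 * c$fn / den
}

# Boundary voxels: foreground with at least one face-adjacent background
# neighbour; the outside of the grid counts as background. Returns an
# n x 3 matrix of 1-based voxel indices.
boundary_voxels <- function(mask) {
  m <- grid_of(mask)
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_min <- pmin(
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)],
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)],
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)],
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)],
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]],
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  which(core == 1L & nb_min == 0L, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance between mask surfaces
#'
#' Symmetric HD95 in millimetres: boundary voxels (foreground voxels with a
#' face-adjacent background neighbour) of each mask are converted to
#' physical coordinates with the voxel spacing, the two directed nearest-
#' surface distance sets are reduced to their 95th percentiles (linear
#' interpolation between order statistics) and the larger of the two is
#' returned. Robust to a small fraction of outlier boundary voxels compared
#' with the exact Hausdorff distance.
#'
#' @param gt,pred nonempty `binary_mask` objects (or \{0,1\} arrays) of
#'   equal shape.
#' @param spacing voxel spacing in mm; defaults to the masks' spacing (or
#'   isotropic 1 mm for bare arrays).
#' @param percentile distance percentile in (0, 100\]; 100 gives the exact
#'   Hausdorff distance.
#' @return Distance in mm.
#' @export
hd95 <- function(gt, pred, spacing = NULL, percentile = 95) {
  check_same_shape(gt, pred)
  if (is.null(spacing)) spacing <- spacing_of(gt)
  a <- boundary_voxels(gt)
  b <- boundary_voxels(pred)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("HD95 undefined: one of the masks is empty", call. = FALSE)
  A <- sweep(a, 2, spacing, "*")
  B <- sweep(b, 2, spacing, "*")
  d_ab <- directed_min_dist(A, B)
  d_ba <- directed_min_dist(B, A)
  max(stats::quantile(d_ab, percentile / 100, names = FALSE, type = 7),
      stats::quantile(d_ba, percentile / 100, names = FALSE, type = 7))
}

# For each row of A (physical coords), the distance to the nearest row of B.
# Chunked |A|x|B| computation using the expanded-square identity.
directed_min_dist <- function(A, B) {
  b2 <- rowSums(B^2)
  n <- nrow(A)
  out <- numeric(n)
  step <- max(1L, floor(2e6 / nrow(B)))
  for (s in seq(1L, n, by = step)) {
    idx <- s:min(s + step - 1L, n)
    Ak <- A[idx, , drop = FALSE]
    d2 <- outer(rowSums(Ak^2), b2, "+") - 2 * Ak %*% t(B)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Strip a border shell from a mask
#'
#' Morphological erosion by a cube structuring element of odd edge length,
#' used to remove the boundary shell of a segmentation so that metrics can
#' be recomputed on the inner region only (edge lengths 3 and 5 remove 1-
#' and 2-voxel shells). Voxels outside the grid count as background.
#'
#' @param m a `binary_mask` (or \{0,1\} array).
#' @param cube_edge odd positive integer edge of the cube; 1 is the
#'   identity.
#' @return A `binary_mask` contained in `m`.
#' @export
border_strip <- function(m, cube_edge) {
  if (length(cube_edge) != 1 || cube_edge < 1 || cube_edge %% 2 != 1)
    stop("cube_edge must be an odd positive integer", call. = FALSE)
  arr <- grid_of(m)
  r <- (cube_edge - 1) / 2
  out <- erode_cube(arr, r)
  as_mask(out, spacing_of(m))
}

# Erosion by a (2r+1)-cube = r successive erosions by the 3-cube, itself
# separable into per-axis length-3 running minima with zero padding.
erode_cube <- function(arr, r) {
  storage.mode(arr) <- "integer"
  if (r == 0) return(arr)
  d <- dim(arr)
  for (i in seq_len(r)) {
    for (ax in 1:3) arr <- erode_axis3(arr, ax)
  }
  arr
}

erode_axis3 <- function(arr, ax) {
  d <- dim(arr)
  lo <- shift_axis(arr, ax, 1L)
  hi <- shift_axis(arr, ax, -1L)
  out <- arr
  out[lo == 0L | hi == 0L] <- 0L
  out
}

dilate_axis3 <- function(arr, ax) {
  lo <- shift_axis(arr, ax, 1L)
  hi <- shift_axis(arr, ax, -1L)
  out <- arr
  out[lo == 1L | hi == 1L] <- 1L
  out
}

# Shift a 3D array by `by` voxels along axis ax, filling with 0.
shift_axis <- function(arr, ax, by) {
  d <- dim(arr)
  out <- array(0L, d)
  n <- d[ax]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (ax == 1) { out[dst, , ] <- arr[src, , ] }
  else if (ax == 2) { out[, dst, ] <- arr[, src, ] }
  else { out[, , dst] <- arr[, , src] }
  out
}

# 6-connected binary dilation (cross structuring element), used by the
# phantom perturbations.
dilate_cross <- function(arr, iterations = 1L) {
  storage.mode(arr) <- "integer"
  for (i in seq_len(iterations)) {
    acc <- arr
    for (ax in 1:3) acc <- pmax(acc, shift_axis(arr, ax, 1L), shift_axis(arr, ax, -1L))
    arr <- acc
  }
  arr
}

#' Combine two masks voxel-wise
#'
#' `union` is the element-wise logical OR of the two masks; `intersection`
#' is their element-wise (Hadamard) product.
#'
#' @param a,b `binary_mask` objects (or \{0,1\} arrays) of equal shape.
#' @param op `"union"` or `"intersection"`.
#' @return A `binary_mask`.
#' @export
combine_masks <- function(a, b, op = c("union", "intersection")) {
  op <- match.arg(op)
  check_same_shape(a, b)
  ga <- grid_of(a); gb <- grid_of(b)
  out <- if (op == "union") pmax(ga, gb) else ga * gb
  as_mask(array(as.integer(out), dim(ga)), spacing_of(a))
}

#' Evaluate a predicted mask against ground truth
#'
#' Computes the full per-volume metric row: Dice, Jaccard, over- and
#' under-segmentation, and HD95 in mm (`NA` when either mask is empty,
#' and 0 when both are empty, i.e. a perfect degenerate match).
#'
#' @param gt,pred `binary_mask` objects of equal shape.
#' @param spacing voxel spacing in mm (default: taken from `gt`).
#' @param volume_id optional label for the report row.
#' @return A one-row tibble with columns `volume_id`, `dice`, `jaccard`,
#'   `os`, `us`, `hd95_mm`.
#' @examples
#' m <- as_mask(array(c(rep(1L, 32), rep(0L, 480)), c(8, 8, 8)))
#' evaluate_pair(m, m)
#' @export
evaluate_pair <- function(gt, pred, spacing = NULL, volume_id = NA_character_) {
  check_same_shape(gt, pred)
  if (is.null(spacing)) spacing <- spacing_of(gt)
  cc <- confusion_counts(gt, pred)
  n_gt <- cc$tp + cc$fn
  n_pred <- cc$tp + cc$fp
  hd <- if (n_gt == 0 && n_pred == 0) 0
        else if (n_gt == 0 || n_pred == 0) NA_real_
        else hd95(gt, pred, spacing = spacing)
  tibble::tibble(volume_id = as.character(volume_id),
                 dice = dice(cc), jaccard = jaccard(cc),
                 os = over_seg(cc), us = under_seg(cc),
                 hd95_mm = hd)
}

#' Aggregate per-volume metric reports
#'
#' @param reports a tibble/data frame of rows from [evaluate_pair()] (any
#'   set of numeric metric columns).
#' @return A tibble with one row per metric: `mean`, `sd` (sample, n-1;
#'   0 with a warning for a single report), `median`, `q25`, `q75`, `n`.
#'   `NA` metric values (e.g. undefined HD95) are dropped per metric.
#' @export
summarize_metrics <- function(reports) {
  if (is.null(nrow(reports)) || nrow(reports) == 0)
    stop("no reports to summarize", call. = FALSE)
  num_cols <- names(reports)[vapply(reports, is.numeric, logical(1))]
  rows <- lapply(num_cols, function(cl) {
    x <- reports[[cl]]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(tibble::tibble(metric = cl, mean = NA_real_, sd = NA_real_,
                            median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                            n = 0L))
    s <- if (length(x) == 1) {
      warning("single report: standard deviation undefined, reporting 0")
      0
    } else stats::sd(x)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(metric = cl, mean = mean(x), sd = s,
                   median = q[2], q25 = q[1], q75 = q[3], n = length(x))
  })
  do.call(rbind, rows)
}
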