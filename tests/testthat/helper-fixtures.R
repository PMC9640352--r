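# Shared fixtures built in code.

# Random {0,1} array of the given shape.
rand_mask_array <- function(shape, p = 0.3, seed = 1) {
  set.seed(seed)
  array(as.integer(stats::runif(prod(shape)) < p), shape)
}

rand_mask <- function(shape, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  as_mask(rand_mask_array(shape, p, seed), spacing)
}

# Small phantom reused across tests (memoized per session).
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_spec(shape = c(32, 32, 16), seed = 0))
    cache
  }
})

# Default-sized phantom (the standard study configuration), memoized.
std_phantom <- local({
  cache <- list()
  function(seed = 0) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_phantom(phantom_spec(seed = seed))
    cache[[key]]
  }
})

# Brute-force directed distances between boundary voxel sets, written as an
# explicit per-voxel loop, independent of the package's chunked-matrix path.
brute_surface_distances <- function(from, to, spacing) {
  vapply(seq_len(nrow(from)), function(i) {
    d2 <- (spacing[1] * (from[i, 1] - to[, 1]))^2 +
          (spacing[2] * (from[i, 2] - to[, 2]))^2 +
          (spacing[3] * (from[i, 3] - to[, 3]))^2
    sqrt(min(d2))
  }, numeric(1))
}

# Brute-force boundary extraction with an explicit neighbour loop.
brute_boundary <- function(arr) {
  d <- dim(arr)
  res <- NULL
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(arr == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    on_bd <- FALSE
    for (o in seq_len(6)) {
      nb <- v + offs[o, ]
      if (any(nb < 1) || any(nb > d) || arr[nb[1], nb[2], nb[3]] == 0L) {
        on_bd <- TRUE
        break
      }
    }
    if (on_bd) res <- rbind(res, v)
  }
  res
}

brute_hd95 <- function(gt, pred, spacing, percentile = 95) {
  a <- brute_boundary(grid_of_arr(gt))
  b <- brute_boundary(grid_of_arr(pred))
  d_ab <- brute_surface_distances(a, b, spacing)
  d_ba <- brute_surface_distances(b, a, spacing)
  max(stats::quantile(d_ab, percentile / 100, names = FALSE, type = 7),
      stats::quantile(d_ba, percentile / 100, names = FALSE, type = 7))
}

grid_of_arr <- function(x) if (is.list(x) && !is.null(x$data)) x$data else x

# 2D 4-neighbour binary erosion (r iterations), for boundary/interior bands.
erode_slice <- function(m, r) {
  for (i in seq_len(r)) {
    d <- dim(m)
    up <- rbind(m[-1, , drop = FALSE], 0)
    dn <- rbind(0, m[-d[1], , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], 0)
    rt <- cbind(0, m[, -d[2], drop = FALSE])
    m <- m * (up & dn & lf & rt)
  }
  m
}
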