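#' Specification for a synthetic liver phantom
#'
#' Describes a contrast-enhanced-T1-like test volume: a hyper-intense,
#' smoothly deformed superellipsoidal "liver" over a dark background, an
#' adjacent confounder organ whose intensity sits within `edge_weakness` of
#' the liver's (manufacturing the weak-edge contact through which contour
#' leakage happens in real data), hypo-intense internal lesions, and
#' additive Gaussian noise. All randomness (deformation, lesion placement,
#' noise) is driven by `seed`, so a spec generates its phantom
#' reproducibly.
#'
#' @param shape grid shape (default 64 x 64 x 32).
#' @param spacing voxel spacing in mm (default 1 x 1 x 2, liver-MR-like
#'   anisotropy).
#' @param center liver centre in voxels (default: grid centre, shifted so
#'   the confounder fits).
#' @param radii liver semi-axes in voxels.
#' @param exponent superellipsoid exponent (2 = ellipsoid; larger values
#'   flatten the faces slightly, closer to a liver's blunt profile).
#' @param deform_amplitude amplitude (in voxels, measured radially) of the
#'   smooth random boundary deformation.
#' @param n_lesions number of spherical hypo-intense lesions placed inside
#'   the liver.
#' @param lesion_radius range (voxels) lesion radii are drawn from.
#' @param lesion_drop intensity drop of lesions below liver level.
#' @param confounder_radii semi-axes of the adjacent confounder organ
#'   (ellipsoid placed in contact with the liver's +x side).
#' @param intensities named list with `background`, `liver` and
#'   `confounder` levels in \[0, 1\].
#' @param edge_weakness maximum allowed liver-confounder intensity gap;
#'   the spec is rejected if `|liver - confounder|` exceeds it.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed making the phantom deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 32), spacing = c(1, 1, 2),
                         center = NULL, radii = NULL, exponent = 2.5,
                         deform_amplitude = 1.5,
                         n_lesions = 2, lesion_radius = c(2, 4),
                         lesion_drop = 0.3,
                         confounder_radii = NULL,
                         intensities = list(background = 0.15, liver = 0.75,
                                            confounder = 0.65),
                         edge_weakness = 0.15, noise_sd = 0.02, seed = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 8), all(spacing > 0),
            exponent > 0, deform_amplitude >= 0, n_lesions >= 0,
            noise_sd >= 0)
  if (is.null(radii)) radii <- pmax(2, round(shape * c(0.33, 0.28, 0.34)))
  if (is.null(center)) center <- (shape + 1) / 2 - c(0.08, 0, 0) * shape
  if (is.null(confounder_radii)) confounder_radii <- pmax(2, round(shape * c(0.10, 0.14, 0.17)))
  if (abs(intensities$liver - intensities$confounder) > edge_weakness)
    stop("confounder intensity must lie within edge_weakness of the liver intensity",
         call. = FALSE)
  structure(list(shape = shape, spacing = spacing, center = center,
                 radii = radii, exponent = exponent,
                 deform_amplitude = deform_amplitude,
                 n_lesions = n_lesions, lesion_radius = lesion_radius,
                 lesion_drop = lesion_drop,
                 confounder_radii = confounder_radii,
                 intensities = intensities, edge_weakness = edge_weakness,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# Smooth random field in [-1, 1]: coarse uniform grid upsampled trilinearly.
smooth_noise_field <- function(shape, coarse = c(5, 5, 4)) {
  cg <- array(stats::runif(prod(coarse), -1, 1), coarse)
  co <- lapply(1:3, function(a)
    seq(1, coarse[a], length.out = shape[a]))
  sample_trilinear(cg, co[[1]], co[[2]], co[[3]])
}

#' Generate a synthetic liver phantom
#'
#' Builds the noisy intensity volume and the exact ground-truth liver mask
#' described by a [phantom_spec()]. The ground truth is a single
#' 6-connected component with at least a 2-voxel margin to the grid
#' boundary; lesions are hypo-intense but belong to the liver mask (the
#' parenchyma is segmented as a whole organ, lesions included). Lesion
#' geometry is recorded in `attr(gt, "lesions")` for use by
#' [perturb_mask()].
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a `volume` with intensities in
#'   \[0, 1\]) and `gt` (a `binary_mask`).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 16), seed = 0))
#' ph$gt
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    d <- spec$shape
    x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
    dx <- abs(x - spec$center[1]) / spec$radii[1]
    dy <- abs(y - spec$center[2]) / spec$radii[2]
    dz <- abs(z - spec$center[3]) / spec$radii[3]
    e <- spec$exponent
    # superellipsoid implicit function, radially deformed by a smooth field
    rad <- (outer(outer(dx^e, dy^e, "+"), dz^e, "+"))^(1 / e)
    if (spec$deform_amplitude > 0) {
      f <- smooth_noise_field(d)
      rad <- rad + f * spec$deform_amplitude / mean(spec$radii)
    }
    liver <- array(as.integer(rad <= 1), d)
    liver <- largest_component6(liver)
    if (margin_to_edge(liver) < 2)
      stop("phantom spec leaves less than a 2-voxel margin to the grid boundary",
           call. = FALSE)

    # confounder organ touching the liver's +x side
    cx <- max(which(apply(liver == 1L, 1, any)))  # rightmost liver extent
    ccen <- c(min(cx + spec$confounder_radii[1] - 1, d[1] - 1),
              spec$center[2], spec$center[3])
    ex <- abs(x - ccen[1]) / spec$confounder_radii[1]
    ey <- abs(y - ccen[2]) / spec$confounder_radii[2]
    ez <- abs(z - ccen[3]) / spec$confounder_radii[3]
    conf <- (outer(outer(ex^2, ey^2, "+"), ez^2, "+")) <= 1
    conf <- conf & liver == 0L

    img <- array(spec$intensities$background, d)
    img[conf] <- spec$intensities$confounder
    img[liver == 1L] <- spec$intensities$liver

    # lesions: hypo-intense spheres fully inside the liver
    lesions <- list()
    if (spec$n_lesions > 0) {
      interior <- erode_cube(liver, 1L)
      for (i in seq_len(spec$n_lesions)) {
        r <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
        core <- erode_cube(liver, ceiling(r) + 1L)
        cand <- which(core == 1L, arr.ind = TRUE)
        if (nrow(cand) == 0) break
        cen <- cand[sample.int(nrow(cand), 1), ]
        sph <- sphere_voxels(d, cen, r)
        sph <- sph & interior == 1L
        img[sph] <- img[sph] - spec$lesion_drop
        lesions[[length(lesions) + 1L]] <- list(center = as.numeric(cen), radius = r)
      }
    }

    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    img <- pmin(pmax(img, 0), 1)

    gt <- as_mask(liver, spec$spacing)
    attr(gt$data, "lesions") <- NULL
    attr(gt, "lesions") <- lesions
    list(volume = as_volume(array(img, d), spec$spacing), gt = gt)
  })
}

sphere_voxels <- function(d, center, radius) {
  x <- seq_len(d[1]) - center[1]
  y <- seq_len(d[2]) - center[2]
  z <- seq_len(d[3]) - center[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= radius^2
}

margin_to_edge <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(Inf)
  d <- dim(mask)
  min(c(idx[, 1] - 1, d[1] - idx[, 1],
        idx[, 2] - 1, d[2] - idx[, 2],
        idx[, 3] - 1, d[3] - idx[, 3]))
}

# Largest 6-connected foreground component (iterative flood fill).
largest_component6 <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lab <- integer(n)
  m <- as.integer(mask)
  strides <- c(1L, d[1], d[1] * d[2])
  cur <- 0L
  best_lab <- 0L; best_size <- 0L
  for (start in which(m == 1L & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    size <- 0L
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      size <- size + length(v)
      # decode subscripts for boundary checks
      i0 <- (v - 1L) %% d[1]
      j0 <- ((v - 1L) %/% d[1]) %% d[2]
      k0 <- (v - 1L) %/% (d[1] * d[2])
      nb <- c(v[i0 > 0L] - 1L, v[i0 < d[1] - 1L] + 1L,
              v[j0 > 0L] - strides[2], v[j0 < d[2] - 1L] + strides[2],
              v[k0 > 0L] - strides[3], v[k0 < d[3] - 1L] + strides[3])
      nb <- unique(nb[m[nb] == 1L & lab[nb] == 0L])
      lab[nb] <- cur
      queue <- nb
    }
    if (size > best_size) { best_size <- size; best_lab <- cur }
  }
  out <- array(0L, d)
  if (best_lab > 0L) out[lab == best_lab] <- 1L
  out
}

#' Systematically flaw a ground-truth mask
#'
#' Produces the "predicted"-mask failure modes seen in automated liver
#' segmentation: `erode_boundary` (uniform boundary under-segmentation by
#' `magnitude` voxels), `dilate_leak` (localized leakage: dilation by
#' `magnitude` voxels restricted to a random boundary patch, emulating
#' spill into an adjacent organ), `drop_lesion` (removes the sphere around
#' a recorded lesion site, requiring the lesion metadata attached by
#' [generate_phantom()]), and `punch_holes` (removes `magnitude` random
#' interior spheres). Each mode moves the mask in one direction only:
#' erosion/lesions/holes create no false positives, leakage creates no
#' false negatives. Deterministic for a fixed `seed`.
#'
#' @param gt nonempty `binary_mask`.
#' @param mode one of `"erode_boundary"`, `"dilate_leak"`, `"drop_lesion"`,
#'   `"punch_holes"`.
#' @param magnitude voxels (erode/dilate), or count of holes; `drop_lesion`
#'   interprets it as the 1-based lesion index (out of range picks a random
#'   lesion).
#' @param seed integer seed for the random patch/hole placement.
#' @return A perturbed `binary_mask`.
#' @export
perturb_mask <- function(gt, mode = c("erode_boundary", "dilate_leak",
                                      "drop_lesion", "punch_holes"),
                         magnitude = 2, seed = 0) {
  mode <- match.arg(mode)
  m <- grid_of(gt)
  if (sum(m) == 0) stop("ground-truth mask is empty", call. = FALSE)
  if (magnitude == 0 && mode != "drop_lesion")
    return(as_mask(m, spacing_of(gt)))
  d <- dim(m)
  out <- with_local_seed(seed, {
    switch(mode,
      erode_boundary = erode_cube(m, as.integer(magnitude)),
      dilate_leak = {
        bd <- boundary_voxels(m)
        cen <- bd[sample.int(nrow(bd), 1), ]
        patch <- sphere_voxels(d, cen, 3 * magnitude)
        grown <- dilate_cross(m, as.integer(magnitude))
        res <- m
        res[patch & grown == 1L] <- 1L
        res
      },
      drop_lesion = {
        les <- attr(gt, "lesions")
        if (is.null(les) || length(les) == 0)
          stop("no lesion metadata on this mask (need a phantom ground truth with lesions)",
               call. = FALSE)
        pick <- if (magnitude >= 1 && magnitude <= length(les)) magnitude
                else sample.int(length(les), 1)
        l <- les[[pick]]
        res <- m
        res[sphere_voxels(d, l$center, l$radius + 1)] <- 0L
        res
      },
      punch_holes = {
        interior <- erode_cube(m, 3L)
        cand <- which(interior == 1L, arr.ind = TRUE)
        res <- m
        if (nrow(cand) > 0) {
          for (i in seq_len(magnitude)) {
            cen <- cand[sample.int(nrow(cand), 1), ]
            res[sphere_voxels(d, cen, 2)] <- 0L
          }
        }
        res
      })
  })
  if (sum(out) == 0)
    warning("perturbation removed the entire mask")
  res <- as_mask(out, spacing_of(gt))
  attr(res, "lesions") <- attr(gt, "lesions")
  res
}

#' Generate a suite of phantom cases
#'
#' Each case couples a phantom (varied deformation and lesions via its
#' seed) with a flawed initial mask from one perturbation mode. When
#' `modes` is `NULL` a mode is drawn per case from the four failure modes;
#' passing a single mode (e.g. `"erode_boundary"`) applies it to every
#' case. With `dir` set, the volumes and masks are written as NIfTI files
#' together with a `manifest.csv` (columns `volume_id`, `image`, `gt`,
#' `init`) for command-line batch evaluation.
#'
#' @param n number of cases; must equal `length(seeds)`.
#' @param base_spec the [phantom_spec()] each case's spec is derived from
#'   (its seed is replaced per case).
#' @param seeds integer seeds, one per case.
#' @param modes `NULL`, a single mode, or a vector of `n` modes.
#' @param magnitude perturbation magnitude passed to [perturb_mask()].
#' @param dir optional output directory for NIfTI files + manifest.
#' @return A list of `n` cases: `list(volume, gt, init, seed, mode)`.
#' @export
make_suite <- function(n = 5, base_spec = phantom_spec(),
                       seeds = seq_len(n) - 1L, modes = NULL,
                       magnitude = 2, dir = NULL) {
  if (n != length(seeds)) stop("n must equal length(seeds)", call. = FALSE)
  all_modes <- c("erode_boundary", "dilate_leak", "drop_lesion", "punch_holes")
  draw_modes <- is.null(modes)
  if (!draw_modes) {
    if (length(modes) == 1) modes <- rep(modes, n)
    stopifnot(length(modes) == n, all(modes %in% all_modes))
  }

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$seed <- seeds[i]
    ph <- generate_phantom(sp)
    mode_i <- if (draw_modes) {
      # drop_lesion is only offered when the phantom actually has lesions
      avail <- all_modes
      if (length(attr(ph$gt, "lesions")) == 0)
        avail <- setdiff(avail, "drop_lesion")
      with_local_seed(seeds[i] + 1000L, sample(avail, 1))
    } else modes[i]
    init <- perturb_mask(ph$gt, mode_i, magnitude = magnitude,
                         seed = seeds[i])
    cases[[i]] <- list(volume = ph$volume, gt = ph$gt, init = init,
                       seed = seeds[i], mode = mode_i)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rows <- lapply(seq_len(n), function(i) {
      id <- sprintf("case%03d", i)
      paths <- file.path(dir, paste0(c("image_", "gt_", "init_"), id, ".nii.gz"))
      write_volume(cases[[i]]$volume, paths[1])
      write_volume(cases[[i]]$gt, paths[2])
      write_volume(cases[[i]]$init, paths[3])
      data.frame(volume_id = id, image = paths[1], gt = paths[2],
                 init = paths[3], stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  cases
}
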