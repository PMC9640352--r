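test_that("edge indicator is 1 on constant slices and dips on edges", {
  expect_equal(edge_indicator(matrix(0.3, 7, 7)), matrix(1, 7, 7))

  # vertical unit step across column 3 of a 5x5 slice: central differences
  # give |grad| = 0.5 on the two columns flanking the step and on it
  step <- matrix(0, 5, 5)
  step[, 3:5] <- 1
  g <- edge_indicator(step, sigma = 0)
  # by hand: d/dy at column 2 = (0-0)/2... column 2: (step[,3]-step[,1])/2 = 0.5
  expect_equal(g[3, 2], 1 / (1 + 0.25))
  expect_equal(g[3, 3], 1 / (1 + 0.25))
  expect_equal(g[3, 1], 1)
  expect_equal(which.min(g[3, ]), 2)  # first minimum adjacent to the step
  expect_true(all(g > 0 & g <= 1))

  # halving the intensity scale raises g everywhere
  ph <- small_phantom()
  sl <- ph$volume$data[, , 8]
  g1 <- edge_indicator(sl, 0.2)
  g2 <- edge_indicator(0.5 * sl, 0.2)
  expect_true(all(g2 >= g1 - 1e-12))
})

test_that("binary level-set initialization follows the sign convention", {
  empty <- matrix(0L, 6, 6)
  expect_equal(init_phi_from_mask(empty, 2), matrix(2, 6, 6))
  expect_equal(init_phi_from_mask(1 - empty, 2), matrix(-2, 6, 6))
  one <- empty; one[3, 4] <- 1L
  phi <- init_phi_from_mask(one, 2)
  expect_equal(phi[3, 4], -2)
  expect_equal(sum(phi == -2), 1)
  expect_equal(sum(phi == 2), 35)
  expect_error(init_phi_from_mask(one, -1), "positive")
})

test_that("the regularized Dirac integrates to ~1 across the zero level set", {
  eps <- 0.2
  dirac <- function(x) ifelse(abs(x) <= eps, (1 + cos(pi * x / eps)) / (2 * eps), 0)
  x <- seq(-1, 1, by = 1e-4)   # transect with unit slope through 0
  expect_equal(sum(dirac(x)) * 1e-4, 1, tolerance = 0.05)
})

test_that("regularization-only evolution approximately preserves the contour", {
  ph <- std_phantom(0)
  sl <- ph$volume$data[, , 16]
  ms <- ph$gt$data[, , 16]
  p <- drlse_params(alpha = 0, lam = 0, inner_iters = 10, outer_iters = 1)
  phi <- evolve_slice(sl, init_phi_from_mask(ms, p$c0), p)
  changed <- sum((phi < 0) != (ms == 1))
  expect_lte(changed, 0.02 * sum(ms))
})

test_that("an empty initialization stays empty under a negative area term", {
  sl <- std_phantom(0)$volume$data[, , 16]
  p <- drlse_params(inner_iters = 10, outer_iters = 3)
  phi <- evolve_slice(sl, matrix(p$c0, nrow(sl), ncol(sl)), p)
  expect_equal(sum(phi < 0), 0)
})

test_that("evolution is deterministic and translation-equivariant", {
  ph <- std_phantom(0)
  sl <- ph$volume$data[, , 16]
  ms <- ph$gt$data[, , 16]
  p <- drlse_params(inner_iters = 15, outer_iters = 3)
  phi1 <- evolve_slice(sl, init_phi_from_mask(ms, 2), p)
  phi2 <- evolve_slice(sl, init_phi_from_mask(ms, 2), p)
  expect_identical(unclass(phi1), unclass(phi2))

  # whole-voxel shift of image and init shifts the output mask identically
  sh <- 3
  d <- dim(sl)
  sl_s <- sl; sl_s[] <- sl[c((d[1] - sh + 1):d[1], 1:(d[1] - sh)), ]
  ms_s <- ms; ms_s[] <- ms[c((d[1] - sh + 1):d[1], 1:(d[1] - sh)), ]
  phi_s <- evolve_slice(sl_s, init_phi_from_mask(ms_s, 2), p)
  seg <- (phi1 < 0)[10:50, 10:50]
  seg_s <- (phi_s < 0)[10:50 + sh, 10:50]
  expect_identical(seg, seg_s)
})

test_that("the area term's sign controls monotone growth or shrinkage", {
  cim <- matrix(0.5, 48, 48)
  ms <- matrix(0L, 48, 48)
  ms[18:30, 18:30] <- 1L
  for (al in c(-5, 5)) {
    p <- drlse_params(alpha = al, lam = 0, inner_iters = 5, outer_iters = 8)
    phi <- evolve_slice(cim, init_phi_from_mask(ms, 2), p)
    counts <- attr(phi, "foreground_counts")
    if (al < 0) expect_true(all(diff(counts) >= 0))
    else expect_true(all(diff(counts) <= 0))
  }
})

test_that("refinement recovers eroded boundaries and keeps correct masks", {
  ph <- std_phantom(0)
  init <- perturb_mask(ph$gt, "erode_boundary", magnitude = 2)
  d_init <- evaluate_pair(ph$gt, init)$dice
  ref <- refine_volume(ph$volume, init)
  d_ref <- evaluate_pair(ph$gt, ref)$dice
  # regression values for the standard phantom, seed 0
  expect_equal(d_init, 0.7128352, tolerance = 1e-6)
  expect_gt(d_ref, d_init)
  expect_gt(d_ref, 0.74)

  ref_gt <- refine_volume(ph$volume, ph$gt)
  expect_gte(evaluate_pair(ph$gt, ref_gt)$dice, 0.95)

  # an all-empty initialization passes through empty
  empty <- as_mask(array(0L, dim(ph$gt$data)), ph$gt$spacing)
  out <- refine_volume(ph$volume, empty)
  expect_equal(sum(out$data), 0)
})

test_that("parameter sweep ranks grid points consistently and deterministically", {
  ph <- std_phantom(0)
  init <- perturb_mask(ph$gt, "erode_boundary", magnitude = 2)
  cases <- list(list(volume = ph$volume, init = init, gt = ph$gt))
  fixed <- drlse_params(inner_iters = 10, outer_iters = 5)

  one <- parameter_sweep(cases, alphas = -5, lambdas = 5,
                         iter_pairs = list(c(10, 5)), fixed = fixed)
  expect_equal(nrow(one), 1L)
  direct <- evaluate_pair(ph$gt,
                          refine_volume(ph$volume, init,
                                        drlse_params(alpha = -5, lam = 5,
                                                     inner_iters = 10,
                                                     outer_iters = 5)))
  expect_equal(one$mean_dice, direct$dice, tolerance = 1e-12)
  expect_equal(one$mean_hd95, direct$hd95_mm, tolerance = 1e-12)

  # duplicated grid point: identical metrics, first row wins the tie
  two <- parameter_sweep(cases, alphas = c(-5, -5), lambdas = 5,
                         iter_pairs = list(c(10, 5)), fixed = fixed)
  expect_equal(two$mean_dice[1], two$mean_dice[2])
  expect_identical(which.max(two$mean_dice), 1L)

  expect_error(parameter_sweep(list(), alphas = -5, lambdas = 5,
                               iter_pairs = list(c(5, 5))), "no cases")
})

test_that("stability guard rejects excessive mu * dt", {
  expect_error(drlse_params(mu = 0.3, dt = 1), "0.25")
  expect_s3_class(drlse_params(mu = 0.3, dt = 1, allow_unstable = TRUE),
                  "drlse_params")
})
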