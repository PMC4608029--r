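# Closed-loop polygon tracer: preprocessing, scoring, refinement,
# subdivision, alignment and full traces on clean phantoms.

test_that("preprocess normalizes and strips disconnected noise", {
  cv <- make_curve(shape_spec("open_circle"), seed = 1)
  vol <- rasterize(cv, margin = 35)
  cfg <- tracer_config()
  pv <- preprocess(vol, cfg)
  # zero mean, unit sd before component removal: check on the filtered
  # volume directly with lowpass only
  cfg0 <- tracer_config(lowpass_sigma = 0)
  raw <- vol$data
  z <- (raw - mean(raw)) / sd(raw)
  pv0 <- preprocess(vol, cfg0)
  # largest component kept; with a clean single tube nothing is removed,
  # so the normalization contract is exact
  expect_lt(abs(mean(pv0$data) - mean(z)), 1e-6)
  expect_lt(abs(sd(pv0$data) - sd(z)), 1e-6)
  expect_error(preprocess(density_volume(array(1, c(8, 8, 8)), 1)),
               "no density")

  # a distant smaller blob is zeroed, the tube survives
  noisy <- vol
  blob_idx <- 3:6
  noisy$data[blob_idx, blob_idx, blob_idx] <- 1
  pn <- preprocess(noisy, cfg0)
  expect_true(all(pn$data[blob_idx, blob_idx, blob_idx] == 0))
  expect_gt(max(pn$data), 1) # tube z-scores remain
})

test_that("a regular polygon of target size scores zero penalties", {
  cfg <- tracer_config(contour_length = 20 * 40) # Lbar = 40 per edge at n=20
  n <- 20
  r <- 40 / (2 * sin(pi / n))
  t <- 2 * pi * (0:(n - 1)) / n
  poly <- tibble::tibble(x = 145 + r * cos(t), y = 145 + r * sin(t), z = 145)
  zero_vol <- density_volume(array(0, c(60, 60, 60)), 5)
  sc <- score_polygon(poly, zero_vol, cfg)
  expect_lt(abs(sc$length), 1e-9)
  expect_lt(abs(sc$angle), 1e-9)
  expect_identical(sc$density, 0)
  # displacing one vertex makes both penalties strictly positive
  poly2 <- poly
  poly2$x[3] <- poly2$x[3] + 15
  sc2 <- score_polygon(poly2, zero_vol, cfg)
  expect_lt(sc2$length, -1e-6)
  expect_lt(sc2$angle, -1e-6)
  # a vertex outside the volume is reported by index
  poly3 <- poly
  poly3$x[7] <- 1e5
  expect_error(score_polygon(poly3, zero_vol, cfg), "7")
})

test_that("a polygon on the axis of a clean circle collects peak density", {
  # finer sampling keeps the trilinear interpolation error within 1%
  cv <- make_curve(shape_spec("open_circle", contour_length = 500), seed = 4)
  vol <- rasterize(cv, voxel_size = 2, margin = 30)
  cfg <- tracer_config(w_density = 1, contour_length = 500)
  poly <- resample_closed(cv, 20)
  sc <- score_polygon(poly, vol, cfg)
  expect_gt(sc$density, 20 * 0.99)
})

test_that("subdivision doubles vertices with exact midpoints", {
  sq <- tibble::tibble(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10), z = 0)
  oct <- subdivide(sq)
  expect_equal(nrow(oct), 8)
  expect_equal(closed_arc_length(oct), closed_arc_length(sq))
  expect_equal(oct$x[2], 5) # midpoint of the first edge
  expect_equal(as.data.frame(oct[seq(1, 8, 2), ]), as.data.frame(sq),
               ignore_attr = TRUE)
  p5 <- resample_closed(sq, 5)
  expect_equal(nrow(subdivide(p5)), 10)
  expect_equal(nrow(subdivide(subdivide(p5))), 20)
})

test_that("refinement is monotone and leaves optima in place", {
  cv <- make_curve(shape_spec("open_circle"), seed = 4)
  vol <- rasterize(cv, margin = 35)
  cfg <- tracer_config()
  pv <- preprocess(vol, cfg)
  pv$data <- pv$data / max(pv$data)
  on_axis <- resample_closed(cv, 20)
  ref <- refine(on_axis, pv, cfg)
  move <- max(sqrt(rowSums((as.matrix(ref[, 1:3]) -
                              as.matrix(on_axis[, 1:3]))^2)))
  expect_lt(move, 2.5)                     # near fixed point (about half a voxel)
  traj <- attr(ref, "trajectory")
  expect_true(all(diff(traj) >= -1e-9))    # monotone score

  # displaced polygon approaches the axis
  off <- dplyr::mutate(on_axis, x = x + 20)
  ref2 <- refine(off, pv, cfg)
  expect_lt(curve_rmsd(ref2, cv), curve_rmsd(off, cv))
  expect_gte(attr(ref2, "score")$total, score_polygon(off, pv, cfg)$total)
})

test_that("with no density only the restoring forces act", {
  zero_vol <- density_volume(array(0, c(60, 60, 60)), 5)
  set.seed(2)
  t <- 2 * pi * (0:9) / 10
  irregular <- tibble::tibble(
    x = 150 + 60 * cos(t) + rnorm(10, sd = 12),
    y = 150 + 60 * sin(t) + rnorm(10, sd = 12),
    z = 150 + rnorm(10, sd = 12))
  cfg <- tracer_config(contour_length = 600, max_iters = 150)
  ref <- refine(irregular, zero_vol, cfg)
  elen <- function(cv) {
    m <- as.matrix(cv[, 1:3]); n <- nrow(m)
    sqrt(rowSums((m[c(2:n, 1), ] - m)^2))
  }
  expect_lt(var(elen(ref)), var(elen(irregular)))
  ang <- function(cv) minicircle:::interior_angles(as.matrix(cv[, 1:3]))
  expect_lt(var(ang(ref)), var(ang(irregular)))
})

test_that("closed-curve alignment is cyclic- and orientation-invariant", {
  cv <- make_curve(shape_spec("racquet"), seed = 3)
  m <- as.matrix(cv[, 1:3])
  expect_equal(align_closed_curves(m, m)$distance, 0)
  rot7 <- m[c(8:nrow(m), 1:7), ]
  expect_equal(align_closed_curves(m, rot7)$distance, 0)
  expect_equal(align_closed_curves(m, m[nrow(m):1, ])$distance, 0)
  expect_error(align_closed_curves(m, m[-1, ]), "equal vertex counts")
})

test_that("clean circle phantoms are traced to sub-voxel accuracy", {
  cv <- make_curve(shape_spec("open_circle"), seed = 8)
  vol <- rasterize(cv, margin = 40)
  tr <- trace(vol, tracer_config(seed = 21))
  expect_lt(curve_rmsd(tr$curve, cv), 5)
  expect_true(tr$converged)
  expect_lt(abs(closed_arc_length(tr$curve) / 1142.4 - 1), 0.05)
  expect_equal(nrow(tr$curve), 20)
  # tidy/glance accessors
  td <- tidy(tr)
  expect_identical(names(td), c("vertex", "x", "y", "z"))
  gl <- glance(tr)
  expect_true(gl$converged)
  expect_equal(gl$n_vertices, 20)
})

test_that("double-length phantoms recover the 672-bp contour", {
  cv <- make_curve(shape_spec("open_circle", contour_length = 672 * 3.4),
                   seed = 9)
  vol <- rasterize(cv, margin = 40)
  tr <- trace(vol, tracer_config(contour_length = 672 * 3.4, seed = 22,
                                 n_starts = 2))
  expect_lt(abs(closed_arc_length(tr$curve) / 2284.8 - 1), 0.02)
  expect_lt(curve_rmsd(tr$curve, cv), 5)
})
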