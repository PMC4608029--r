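# Tube-density rasterization and the blur/noise corruption model.

test_that("density profile is a unit-peak Gaussian of distance to the axis", {
  # straight-through: a long flat rectangle whose top edge passes exactly
  # through voxel centres
  cv <- make_curve(shape_spec("open_circle"), seed = 1)
  vol <- rasterize(cv, voxel_size = 2, tube_radius = 10, margin = 25)
  # voxel-centre values follow exp(-d^2 / (2 r^2)) of the exact distance
  # to the polyline, with peak 1 on the axis
  m <- as.matrix(cv[, c("x", "y", "z")])
  nseg <- nrow(m)
  seg_dist <- function(p) {
    d <- Inf
    for (i in seq_len(nseg)) {
      a <- m[i, ]; b <- m[(i %% nseg) + 1, ]
      e <- b - a; t <- min(max(sum((p - a) * e) / sum(e^2), 0), 1)
      d <- min(d, sqrt(sum((p - a - t * e)^2)))
    }
    d
  }
  set.seed(2)
  idx <- cbind(sample(dim(vol)[1], 60, TRUE), sample(dim(vol)[2], 60, TRUE),
               sample(dim(vol)[3], 60, TRUE))
  for (r in seq_len(nrow(idx))) {
    p <- vol$origin + (idx[r, ] - 1) * vol$voxel_size
    d <- seg_dist(p)
    expected <- if (d <= 30) exp(-d^2 / 200) else 0
    expect_equal(vol$data[idx[r, 1], idx[r, 2], idx[r, 3]], expected,
                 tolerance = 1e-6)
  }
  expect_lte(max(vol$data), 1)
  rho_axis <- interp_density(vol, cv)
  expect_gt(max(rho_axis), 0.99)
  # sample at exactly tube_radius from a curve point, along the local
  # outward normal within the curve plane
  m <- as.matrix(cv[, c("x", "y", "z")])
  ctr <- colMeans(m)
  p <- m[1, ]
  nrm <- (p - ctr) / sqrt(sum((p - ctr)^2))
  q <- p + 10 * nrm
  expect_equal(interp_density(vol, matrix(q, 1)), exp(-0.5), tolerance = 0.02)
  # exactly zero beyond 3 tube radii
  q_far <- p + 40 * nrm
  expect_identical(interp_density(vol, matrix(q_far, 1)), 0)
})

test_that("integrated density scales linearly with contour length", {
  c336 <- make_curve(shape_spec("open_circle"), seed = 1)
  c672 <- make_curve(shape_spec("open_circle", contour_length = 672 * 3.4),
                     seed = 1)
  v336 <- rasterize(c336, margin = 35)
  v672 <- rasterize(c672, margin = 35)
  ratio <- sum(v672$data) / sum(v336$data)
  expect_lt(abs(ratio - 2), 0.04)
})

test_that("rasterization is additive over disjoint curves", {
  a <- make_curve(shape_spec("open_circle", contour_length = 400), seed = 1)
  b <- make_curve(shape_spec("open_circle", contour_length = 400), seed = 2)
  b$x <- b$x + 250 # move well clear of a
  box <- 140
  org <- c(-270, -270, -270)
  va <- rasterize(a, box_edge = box, origin = org, margin = 30)
  vb <- rasterize(b, box_edge = box, origin = org, margin = 30)
  # with disjoint supports the pointwise combination of the two tubes is
  # exactly their voxelwise sum (no cross-talk between the curves)
  expect_lt(max(abs(pmax(va$data, vb$data) - (va$data + vb$data))), 1e-9)
  expect_gt(sum(va$data * vb$data), -1) # sanity: grids share the frame
  expect_identical(va$origin, vb$origin)
})

test_that("the box must fit the curve plus margin", {
  cv <- make_curve(shape_spec("open_circle"), seed = 1)
  expect_error(rasterize(cv, box_edge = 40, margin = 30), "box")
})

test_that("corrupt is deterministic, honest about its noise level", {
  cv <- make_curve(shape_spec("open_circle"), seed = 1)
  vol <- rasterize(cv, margin = 30)
  expect_identical(corrupt(vol, 0, 0, seed = 1), vol)
  n1 <- corrupt(vol, 0.3, 0, seed = 5)
  n2 <- corrupt(vol, 0.3, 0, seed = 5)
  n3 <- corrupt(vol, 0.3, 0, seed = 6)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, n3$data))
  # empirical sd of the added noise within 5%
  expect_lt(abs(sd(n1$data - vol$data) / 0.3 - 1), 0.05)
  expect_lt(abs(sd(n3$data - vol$data) / sd(n1$data - vol$data) - 1), 0.1)
  # blur then noise: blur-only output is smooth and conserves mass
  bl <- corrupt(vol, 0, 8, seed = 1)
  expect_lt(abs(sum(bl$data) / sum(vol$data) - 1), 0.01)
  expect_lt(max(bl$data), max(vol$data))
})
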