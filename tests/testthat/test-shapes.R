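# Ground-truth curve generators: geometry, determinism, feasibility.

ALL_CLASSES <- c("open_circle", "open_figure8", "figure8", "racquet",
                 "handcuffs", "needle", "rod")

test_that("generated curves conserve arc length and close properly", {
  for (cls in ALL_CLASSES) {
    cv <- make_curve(shape_spec(cls), seed = 3)
    len <- closed_arc_length(cv)
    expect_lt(abs(len - 1142.4) / 1142.4, 0.01, label = cls)
    m <- as.matrix(cv[, c("x", "y", "z")])
    # closed: first and last vertices are neighbours, not duplicates
    expect_gt(sqrt(sum((m[1, ] - m[nrow(m), ])^2)), 1)
    expect_lt(sqrt(sum((m[1, ] - m[nrow(m), ])^2)), 2 * 1142.4 / nrow(m))
  }
})

test_that("contour length scales with construct size", {
  cv672 <- make_curve(shape_spec("open_circle", contour_length = 672 * 3.4),
                      seed = 1)
  expect_lt(abs(closed_arc_length(cv672) - 2284.8) / 2284.8, 0.01)
})

test_that("planar circle has the analytic radius L / (2 pi)", {
  cv <- make_curve(shape_spec("open_circle"), seed = 2)
  m <- as.matrix(cv[, c("x", "y", "z")])
  r <- sqrt(rowSums(sweep(m, 2, colMeans(m))^2))
  expect_lt(max(abs(r - 1142.4 / (2 * pi))), 1142.4 / (2 * pi) * 0.01)
})

test_that("curve generation is deterministic in the seed", {
  a <- make_curve(shape_spec("racquet"), seed = 7)
  b <- make_curve(shape_spec("racquet"), seed = 7)
  c <- make_curve(shape_spec("racquet"), seed = 8)
  expect_identical(a$x, b$x)
  expect_identical(a$z, b$z)
  expect_false(isTRUE(all.equal(a$x, c$x)))
})

test_that("figure-8 curves carry close to one signed crossing of writhe", {
  cv <- make_curve(shape_spec("figure8"), seed = 4)
  wr <- writhe(cv)
  expect_gte(abs(wr), 0.8)
  expect_lte(abs(wr), 1.0)
  expect_lt(wr, 0) # right-handed crossover convention: negative writhe
})

test_that("non-adjacent points keep at least the strand gap", {
  for (cls in c("figure8", "racquet", "handcuffs", "needle", "rod")) {
    cv <- make_curve(shape_spec(cls), seed = 5)
    m <- as.matrix(cv[, c("x", "y", "z")])
    n <- nrow(m)
    gap <- attr(cv, "spec")$handle_gap
    s <- cumsum(c(0, sqrt(rowSums((m[c(2:n, 1), ] - m)^2))))[1:n]
    L <- closed_arc_length(cv)
    d_arc <- abs(outer(s, s, "-"))
    d_arc <- pmin(d_arc, L - d_arc)
    d <- as.matrix(dist(m))
    far <- d_arc > pi * gap
    expect_gte(min(d[far]), 0.85 * gap)
  }
})

test_that("infeasible shape parameters are rejected with a diagnostic", {
  expect_error(shape_spec("racquet", loop_fraction = 0), "loop_fraction")
  expect_error(make_curve(shape_spec("needle", loop_fraction = 0.02)),
               "tube radius")
  expect_error(make_curve(shape_spec("rod", loop_fraction = 1e-3)),
               "tube radius")
  expect_error(shape_spec("open_circle", ellipticity_param = 7),
               "ellipticity")
  expect_error(make_curve(shape_spec("rod", contour_length = 80)),
               "infeasible|too short")
})

test_that("population generation is a reproducible labelled manifest", {
  pop <- population_spec(c(open_circle = 3, rod = 2), noise_sd = 0.1,
                         blur_sigma = 5, margin = 30, seed = 9,
                         box_edge = 140)
  recs <- generate_population(pop)
  expect_equal(nrow(recs), 5)
  expect_equal(sort(table(recs$shape_class), decreasing = TRUE),
               sort(table(c(rep("open_circle", 3), rep("rod", 2))),
                    decreasing = TRUE))
  # all ground-truth lengths within 1%
  lens <- vapply(recs$curve, closed_arc_length, numeric(1))
  expect_true(all(abs(lens - 1142.4) / 1142.4 < 0.01))
  # identical manifests and volumes on regeneration
  recs2 <- generate_population(pop)
  expect_identical(recs$seed, recs2$seed)
  expect_identical(recs$curve[[1]], recs2$curve[[1]])
  expect_identical(recs$volume[[2]]$data, recs2$volume[[2]]$data)
  expect_error(generate_population(
    population_spec(c(open_circle = 0))), "empty")
})
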