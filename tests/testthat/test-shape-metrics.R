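# Axis lengths, ellipticity, density radius of gyration, descriptors,
# classification and population statistics.

test_that("axis lengths reproduce closed forms for rings and ellipses", {
  t <- 2 * pi * (0:63) / 64
  circ <- tibble::tibble(x = 150 * cos(t), y = 150 * sin(t), z = 0)
  a <- axis_lengths(circ)
  expect_equal(unname(a[1]), 150 / sqrt(2), tolerance = 0.01)
  expect_equal(unname(a[2]), 150 / sqrt(2), tolerance = 0.01)
  expect_lt(a[3], 1e-9)
  # parameter-uniform 2:1 ellipse: axis ratio equals the semi-axis ratio
  ell <- tibble::tibble(x = 2 * 150 * cos(t), y = 150 * sin(t), z = 0)
  expect_equal(ellipticity(ell), 2, tolerance = 0.02)
})

test_that("axis lengths match an independent SVD oracle on random polygons", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rnorm(3 * 30, sd = 50), ncol = 3)
    a <- axis_lengths(m)
    sv <- svd(sweep(m, 2, colMeans(m)))$d / sqrt(nrow(m))
    expect_equal(unname(a), sv, tolerance = 1e-9)
  }
})

test_that("ellipticity is rotation invariant and unit for circles", {
  cv <- make_curve(shape_spec("open_circle"), seed = 2)
  expect_equal(ellipticity(cv), 1, tolerance = 0.01)
  m <- as.matrix(cv[, c("x", "y", "z")])
  rot <- minicircle:::rotation_about_axis(c(2, -1, 1), 0.8)
  expect_lt(abs(ellipticity(m %*% t(rot)) - ellipticity(cv)), 1e-9)
  # generator calibration: requested ratio is the measured ratio
  for (e in c(1.5, 2.6)) {
    cve <- make_curve(shape_spec("open_circle", ellipticity_param = e),
                      seed = 1)
    expect_equal(ellipticity(cve), e, tolerance = 0.01)
  }
})

test_that("density radius of gyration equals the direct-summation oracle", {
  cv <- make_curve(shape_spec("open_circle", contour_length = 500), seed = 2)
  vol <- rasterize(cv, voxel_size = 6, margin = 100)
  rg <- radius_of_gyration(vol, cv, r_in = 45, r_out = 90)
  rg_o <- rg_direct_oracle(vol, cv, r_in = 45, r_out = 90)
  expect_equal(rg, rg_o, tolerance = 1e-6)
})

test_that("thin rings and solid balls give their analytic Rg", {
  cv <- make_curve(shape_spec("open_circle"), seed = 1)
  vol <- rasterize(cv, margin = 185)
  rg <- radius_of_gyration(vol, cv)
  expect_lt(abs(rg - 1142.4 / (2 * pi)) / (1142.4 / (2 * pi)), 0.02)
  # uniform ball of radius a fully inside r_in: Rg = a sqrt(3/5)
  a <- 35; h <- 2; n <- 81
  ax <- ((1:n) - (n + 1) / 2) * h
  arr <- array(0, c(n, n, n))
  for (k in 1:n) {
    arr[, , k] <- outer(ax, ax, function(x, y) as.numeric(x^2 + y^2 + ax[k]^2 <= a^2))
  }
  ball <- density_volume(arr, h, origin = -((n - 1) / 2) * h * c(1, 1, 1))
  t6 <- 2 * pi * (0:15) / 16
  path <- tibble::tibble(x = 6 * cos(t6), y = 6 * sin(t6), z = 0)
  expect_lt(abs(radius_of_gyration(ball, path) / (a * sqrt(3 / 5)) - 1), 0.01)
  # all-negative density is rejected
  neg <- density_volume(-arr - 0.1, h, ball$origin)
  expect_error(radius_of_gyration(neg, path), "no positive density")
})

test_that("Rg and axis metrics are invariant under rigid motion", {
  cv <- make_curve(shape_spec("figure8"), seed = 2)
  vol <- rasterize(cv, margin = 50)
  rg1 <- radius_of_gyration(vol, cv, r_out = 50)
  # translate curve and volume together by a whole number of voxels
  shift <- c(3, -2, 5) * vol$voxel_size
  vol2 <- density_volume(vol$data, vol$voxel_size, vol$origin + shift)
  cv2 <- dplyr::mutate(cv, x = x + shift[1], y = y + shift[2], z = z + shift[3])
  rg2 <- radius_of_gyration(vol2, cv2, r_out = 50)
  expect_lt(abs(rg1 - rg2) / rg1, 1e-6)
})

test_that("descriptors capture the defining features of each class", {
  d_circ <- compute_descriptors(make_curve(shape_spec("open_circle"), seed = 1))
  expect_equal(d_circ$n_crossings, 0)
  expect_lt(d_circ$contact_fraction, 0.01)
  expect_equal(d_circ$loop_count, 1)

  d_rod <- compute_descriptors(make_curve(shape_spec("rod"), seed = 1))
  expect_gt(d_rod$contact_fraction, 0.6)
  expect_equal(d_rod$loop_count, 0)

  d_hc <- compute_descriptors(make_curve(shape_spec("handcuffs"), seed = 1))
  expect_equal(d_hc$loop_count, 2)

  d_f8 <- compute_descriptors(make_curve(shape_spec("figure8"), seed = 1))
  expect_equal(d_f8$n_crossings, 1)
  expect_lte(d_f8$crossing_separation, 60)
})

test_that("classification recovers the generating labels on clean curves", {
  hits <- 0; total <- 0
  for (cls in c("open_circle", "open_figure8", "figure8", "racquet",
                "handcuffs", "needle", "rod")) {
    for (sd in 1:3) {
      d <- compute_descriptors(make_curve(shape_spec(cls), seed = sd))
      total <- total + 1
      if (classify_shape(d) == cls) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
  # degenerate all-zero descriptors fall through to "other"
  d0 <- tibble::tibble(writhe = 0, n_crossings = 0, crossing_separation = NA,
                       a1 = 0, a2 = 0, a3 = 0, ellipticity = 1, planarity = 0,
                       contact_fraction = 1, loop_count = 3, loop_arc1 = NA,
                       loop_arc2 = NA, handle_contact_fraction = 0,
                       rg_density = NA)
  expect_equal(classify_shape(d0), "other")
})

test_that("weighted compactness follows the 1..7 weighting scheme", {
  expect_equal(weighted_compactness(rep("open_circle", 10)), 1)
  expect_equal(weighted_compactness(rep("rod", 5)), 7)
  expect_equal(weighted_compactness(c(rep("open_circle", 5), rep("rod", 5))), 4)
  # 'other' molecules are excluded from the average
  expect_equal(weighted_compactness(c(rep("figure8", 4), rep("other", 6))), 3)
  expect_error(weighted_compactness(rep("other", 3)), "named shape classes")
  # monotone: moving mass to a more compact class increases the score
  w1 <- weighted_compactness(c(racquet = 5, needle = 5))
  w2 <- weighted_compactness(c(racquet = 4, needle = 6))
  expect_gt(w2, w1)
  dist <- shape_distribution(c(rep("open_circle", 2), rep("rod", 2), "other"))
  expect_equal(attr(dist, "weighted_compactness"), 4)
  expect_equal(attr(dist, "n_total"), 5)
  expect_equal(sum(dist$fraction[1:7]), 1)
})

test_that("population summaries aggregate groups independently", {
  rec <- tibble::tibble(
    group = c("a", "a", "b"),
    shape_class = c("open_circle", "rod", "figure8"),
    rg_density = c(100, 80, 95))
  s <- population_summary(rec)
  expect_equal(nrow(s), 2)
  a <- s[s$group == "a", ]
  expect_equal(a$n, 2)
  expect_equal(a$weighted_compactness, 4)
  expect_equal(a$rg_mean, 90)
  expect_equal(a$rg_sd, sd(c(100, 80)))
  b <- s[s$group == "b", ]
  expect_equal(b$rg_sd, 0)        # singleton group: sd reported as 0
  expect_true(b$single_record)    # ... and flagged
  # identical groups give identical summaries
  rec2 <- dplyr::bind_rows(dplyr::mutate(rec[1:2, ], group = "c"),
                           dplyr::mutate(rec[1:2, ], group = "d"))
  s2 <- population_summary(rec2)
  expect_equal(unname(as.list(s2[1, -1])), unname(as.list(s2[2, -1])))
})
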