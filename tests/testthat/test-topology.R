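# Linking-number arithmetic, writhe, crossing signs, relaxation parity,
# and circular cleavage mapping.

test_that("relaxed linking numbers match the helical repeat arithmetic", {
  expect_identical(relaxed_lk(336, 10.5), 32L)
  expect_identical(relaxed_lk(672, 10.5), 64L)
  expect_identical(relaxed_lk(105, 10.5), 10L)
  expect_error(relaxed_lk(-10), "> 0")
})

test_that("topoisomer bookkeeping is internally consistent", {
  tp <- topoisomer(336, 30)
  expect_equal(tp$Lk0, 32L)
  expect_equal(tp$dLk, -2L)
  expect_equal(tp$sigma, -0.0625)
  expect_equal(tp$sigma * tp$Lk0, tp$dLk) # sigma reconstructs dLk exactly
  # the 672-bp circle at the same superhelical density has twice the dLk
  expect_equal(superhelical_density(-4, relaxed_lk(672)),
               superhelical_density(-2, relaxed_lk(336)))
  expect_error(superhelical_density(1, 0), "non-zero")
})

test_that("twist follows from Lk = Tw + Wr", {
  expect_equal(twist_of(32, 0), 32)
  expect_equal(twist_of(26, -4), 30)
  set.seed(1)
  for (i in 1:20) {
    lk <- sample(20:40, 1)
    wr <- rnorm(1)
    expect_equal(twist_of(lk, wr) + wr, lk)
  }
  expect_equal(twist_of(topoisomer(336, 32), 0), 32)
})

test_that("type-II relaxation terminals depend only on Lk parity", {
  expect_identical(relax_steps_of_two(28, 32), 0L)
  expect_identical(relax_steps_of_two(32, 32), 0L)
  expect_identical(relax_steps_of_two(31, 32), c(-1L, 1L))
  for (lk in 26:35) {
    term <- relax_steps_of_two(lk, 32)
    expect_true(all((lk - (32 + term)) %% 2 == 0))
    if ((lk - 32) %% 2 == 0) expect_identical(term, 0L)
    else expect_identical(term, c(-1L, 1L))
  }
})

test_that("planar curves have zero writhe and mirrors flip its sign", {
  t <- 2 * pi * (0:63) / 64
  circ <- tibble::tibble(x = 100 * cos(t), y = 100 * sin(t), z = 0)
  expect_lt(abs(writhe(circ)), 1e-9)
  for (cls in c("racquet", "needle", "rod", "handcuffs")) {
    cv <- make_curve(shape_spec(cls), seed = 6)
    expect_lt(abs(writhe(cv)), 1e-9, label = cls)
  }
  f8 <- make_curve(shape_spec("figure8"), seed = 2)
  mir <- dplyr::mutate(f8, z = -z)
  expect_lt(abs(writhe(mir) + writhe(f8)), 1e-9)
})

test_that("writhe matches a brute-force Gauss integral oracle", {
  f8 <- make_curve(shape_spec("figure8", n_points = 64), seed = 3)
  expect_lt(abs(writhe(f8) - brute_force_writhe(f8, factor = 10)), 1e-3)
  of8 <- make_curve(shape_spec("open_figure8", n_points = 64), seed = 3)
  expect_lt(abs(writhe(of8) - brute_force_writhe(of8, factor = 10)), 1e-3)
})

test_that("writhe is invariant under rigid motion and uniform scaling", {
  cv <- make_curve(shape_spec("figure8"), seed = 5)
  wr <- writhe(cv)
  m <- as.matrix(cv[, c("x", "y", "z")])
  rot <- minicircle:::rotation_about_axis(c(1, 2, 3), 1.1)
  moved <- m %*% t(rot)
  moved <- sweep(moved, 2, c(50, -20, 7), "+")
  expect_lt(abs(writhe(moved) - wr), 1e-9)
  expect_lt(abs(writhe(m * 3.7) - wr), 1e-9)
})

test_that("writhe is stable under subdivision of smooth curves", {
  cv <- make_curve(shape_spec("figure8", n_points = 64), seed = 1)
  expect_lt(abs(writhe(subdivide(cv)) - writhe(cv)), 1e-3)
})

test_that("degenerate segments are reported by index", {
  m <- as.matrix(make_curve(shape_spec("open_circle"), seed = 1))
  m[5, ] <- m[4, ]
  expect_error(writhe(m), "4")
})

test_that("projected crossings carry the chirality of the curve", {
  t <- 2 * pi * (0:63) / 64
  circ <- tibble::tibble(x = 100 * cos(t), y = 100 * sin(t), z = 0)
  expect_equal(nrow(crossing_signs(circ, c(0, 0, 1))), 0)
  f8 <- make_curve(shape_spec("figure8", n_points = 64), seed = 2)
  m <- as.matrix(f8[, c("x", "y", "z")])
  ax <- eigen(crossprod(sweep(m, 2, colMeans(m))), symmetric = TRUE)$vectors[, 3]
  cr <- crossing_signs(f8, ax)
  cr <- cr[!cr$ambiguous, ]
  expect_equal(nrow(cr), 1)
  expect_equal(cr$sign, as.integer(sign(writhe(f8))))
})

test_that("directional average of signed crossings recovers the writhe", {
  f8 <- make_curve(shape_spec("figure8", n_points = 64), seed = 3)
  set.seed(42)
  axes <- matrix(rnorm(3 * 500), ncol = 3)
  pw <- apply(axes, 1, function(a) projected_writhe(f8, a))
  expect_lt(abs(mean(pw) - writhe(f8)), 0.05)
})

test_that("gel calibration interpolates fragment sizes log-linearly", {
  ladder <- tibble::tibble(bp = c(100, 1000), distance = c(50, 10))
  expect_equal(fragment_length_from_migration(ladder, 30), sqrt(1e5),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fragment_length_from_migration(ladder, 50), 100,
               tolerance = 1e-9, ignore_attr = TRUE)
  # synthetic 5-point log-linear ladder: recovery is analytic
  slope <- -0.04; icpt <- 3.5
  d5 <- c(5, 15, 25, 35, 45)
  lad5 <- tibble::tibble(bp = 10^(icpt + slope * d5), distance = d5)
  q <- c(8, 22, 41)
  expect_equal(fragment_length_from_migration(lad5, q),
               10^(icpt + slope * q), tolerance = 1e-6, ignore_attr = TRUE)
  expect_warning(out <- fragment_length_from_migration(lad5, 60),
                 "extrapolat")
  expect_true(attr(out, "extrapolated"))
})

test_that("cleavage sites map onto the circle from double digests", {
  one <- map_cleavage_site(
    336, tibble::tibble(enzyme = "A", site = 0, frag1 = 100, frag2 = 236))
  expect_true(attr(one, "ambiguous"))
  expect_setequal(round(one$center), c(100, 236))
  two <- map_cleavage_site(
    336, tibble::tibble(enzyme = c("A", "B"), site = c(0, 50),
                        frag1 = c(100, 50), frag2 = c(236, 286)))
  expect_false(attr(two, "ambiguous"))
  expect_equal(two$center, 100, tolerance = 1e-9)
  expect_error(map_cleavage_site(
    336, tibble::tibble(enzyme = "A", site = 0, frag1 = 100, frag2 = 150)),
    "inconsistent")
})

test_that("mapped intervals agree with a brute-force position scan", {
  scan_oracle <- function(N, digests, tol) {
    ok <- logical(N)
    for (p in 0:(N - 1)) {
      good <- TRUE
      for (i in seq_len(nrow(digests))) {
        s <- digests$site[i]
        circ <- function(a, b) pmin((a - b) %% N, (b - a) %% N)
        d1 <- min(circ(p, (s + digests$frag1[i]) %% N),
                  circ(p, (s - digests$frag1[i]) %% N))
        if (d1 > tol) good <- FALSE
      }
      ok[p + 1] <- good
    }
    which(ok) - 1
  }
  set.seed(11)
  for (rep in 1:5) {
    p_true <- sample(0:335, 1)
    sites <- sort(sample(0:335, 3))
    digests <- tibble::tibble(
      enzyme = c("A", "B", "C"), site = sites,
      frag1 = (p_true - sites) %% 336 + sample(-5:5, 3, replace = TRUE))
    digests$frag2 <- 336 - digests$frag1
    tol <- 10
    res <- map_cleavage_site(336, digests, tol = tol)
    oracle <- scan_oracle(336, digests, tol)
    # every integer position in the returned interval(s) is accepted by the
    # scan and vice versa
    in_interval <- function(p) any(
      ((p - res$start) %% 336) <= res$width + 1e-9)
    member <- vapply(0:335, in_interval, logical(1))
    expect_identical(which(member) - 1L, as.integer(oracle))
    expect_true(in_interval(p_true))
  }
})
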