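# Ground-truth curve generators for the seven empirical minicircle shape
# classes: open circle, open figure-8, figure-8, racquet, handcuffs, needle,
# rod. Each generator builds a minimal piecewise-analytic skeleton with the
# class's defining features, smooths the junctions, rescales to the exact
# contour length, resamples to uniform arc spacing and applies a seeded
# random rigid rotation.

#' Specification of a single minicircle shape
#'
#' Parameters of one ground-truth conformer. Class-specific defaults:
#' `loop_fraction` is 0.45 for racquet, 0.2 for needle and 0.7 (both loops
#' combined) for handcuffs; `crossing_offset` is 30 A for figure-8 and 80 A
#' for open figure-8.
#'
#' @param shape_class One of `r paste(SHAPE_CLASSES, collapse = ", ")`.
#' @param contour_length Total contour length in Angstroms. Default
#'   336 bp x 3.4 A/bp = 1142.4 A, the 336 bp minicircle.
#' @param ellipticity_param Target principal-axis ratio a1/a2 for open
#'   circles, in `[1, 5]`. The ellipse semi-axis ratio is calibrated so the
#'   generated curve *measures* this value via [axis_lengths()].
#' @param loop_fraction Fraction of the contour in the loop (racquet,
#'   needle) or in both loops combined (handcuffs).
#' @param handle_gap Centre-to-centre distance (A) between juxtaposed
#'   duplex strands (handles, rod sides). Default 30 A.
#' @param crossing_offset Strand separation (A) at the crossing for the
#'   figure-8 family.
#' @param n_points Number of vertices of the generated curve.
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(shape_class,
                       contour_length = 336 * 3.4,
                       ellipticity_param = 1,
                       loop_fraction = NULL,
                       handle_gap = 30,
                       crossing_offset = NULL,
                       n_points = 200) {
  shape_class <- match.arg(shape_class, SHAPE_CLASSES)
  if (is.null(loop_fraction)) {
    loop_fraction <- switch(shape_class, racquet = 0.45, needle = 0.2,
                            handcuffs = 0.7, NA_real_)
  }
  if (is.null(crossing_offset)) {
    crossing_offset <- switch(shape_class, figure8 = 30, open_figure8 = 80,
                              NA_real_)
  }
  spec <- structure(list(shape_class = shape_class,
                         contour_length = contour_length,
                         ellipticity_param = ellipticity_param,
                         loop_fraction = loop_fraction,
                         handle_gap = handle_gap,
                         crossing_offset = crossing_offset,
                         n_points = as.integer(n_points)),
                    class = "shape_spec")
  validate_shape_spec(spec)
  spec
}

validate_shape_spec <- function(spec) {
  with(spec, {
    if (!is.numeric(contour_length) || contour_length <= 0) {
      stop("invalid shape_spec: contour_length must be > 0")
    }
    if (shape_class == "open_circle" &&
        (ellipticity_param < 1 || ellipticity_param > 5)) {
      stop("invalid shape_spec: ellipticity_param must lie in [1, 5]")
    }
    if (!is.na(loop_fraction) && (loop_fraction <= 0 || loop_fraction >= 1)) {
      stop("invalid shape_spec: loop_fraction must lie in (0, 1)")
    }
    if (handle_gap <= 0) stop("invalid shape_spec: handle_gap must be > 0")
    if (n_points < 8) stop("invalid shape_spec: n_points must be >= 8")
  })
  invisible(spec)
}

#' Generate a ground-truth closed curve for one shape class
#'
#' Returns a closed curve (first and last vertices are neighbours, not
#' duplicates) whose total polygon arc length is within 1% of
#' `spec$contour_length`, centred at the origin and rotated by a random
#' rigid rotation drawn deterministically from `seed`.
#'
#' @param spec A [shape_spec()].
#' @param seed Integer seed controlling the random orientation.
#' @return A tibble with columns `x`, `y`, `z` (Angstroms) and attributes
#'   `shape_class` and `spec`.
#' @export
#' @examples
#' circ <- make_curve(shape_spec("open_circle"), seed = 1)
#' closed_arc_length(circ) / (336 * 3.4) # ~1
make_curve <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "shape_spec"))
  validate_shape_spec(spec)
  L <- spec$contour_length
  skel <- switch(spec$shape_class,
    open_circle  = skeleton_ellipse(L, spec$ellipticity_param),
    open_figure8 = skeleton_figure8(L, spec$crossing_offset),
    figure8      = skeleton_figure8(L, spec$crossing_offset),
    racquet      = skeleton_racquet(L, spec$loop_fraction, spec$handle_gap),
    needle       = skeleton_racquet(L, spec$loop_fraction, spec$handle_gap),
    handcuffs    = skeleton_handcuffs(L, spec$loop_fraction, spec$handle_gap),
    rod          = {
      # a rod has no loop, but a requested loop_fraction that implies a
      # loop tighter than the duplex radius is still a spec violation
      if (!is.na(spec$loop_fraction) &&
          spec$loop_fraction * L / (2 * pi) < DNA_TUBE_RADIUS) {
        stop(sprintf(paste0("infeasible shape parameters: loop_fraction ",
                            "%.3g gives loop radius %.1f A < DNA tube ",
                            "radius %.0f A"),
                     spec$loop_fraction,
                     spec$loop_fraction * L / (2 * pi), DNA_TUBE_RADIUS))
      }
      skeleton_rod(L, spec$handle_gap)
    })

  ds <- mean(sqrt(rowSums((rbind(skel[-1, ], skel[1, ]) - skel)^2)))
  m <- smooth_closed(skel, window = max(3, 2 * floor(6 / ds) + 1))
  m <- as_curve_matrix(resample_closed(m, spec$n_points))
  # exact perimeter: isotropic rescale about the centroid
  ctr <- colMeans(m)
  m <- sweep(m, 2, ctr)
  m <- m * (L / closed_arc_length(m))
  rot <- with_seed(seed, random_rotation_matrix())
  m <- m %*% t(rot)
  check_self_clearance(m, spec)
  out <- curve_tibble(m)
  attr(out, "shape_class") <- spec$shape_class
  attr(out, "spec") <- spec
  out
}

# Reject curves whose non-adjacent points approach closer than the strand
# gap (would merge into one tube at the density level).
check_self_clearance <- function(m, spec) {
  gap <- min(spec$handle_gap,
             if (!is.na(spec$crossing_offset)) spec$crossing_offset else Inf)
  n <- nrow(m)
  L <- closed_arc_length(m)
  s <- vertex_arc_positions(m)
  d_arc <- abs(outer(s, s, "-"))
  d_arc <- pmin(d_arc, L - d_arc)
  d2 <- as.matrix(stats::dist(m))
  excl <- d_arc <= pi * gap  # neighbours along the contour
  cand <- d2[!excl]
  if (length(cand) && min(cand) < 0.85 * gap) {
    stop(sprintf(paste0("infeasible shape parameters: non-adjacent points ",
                        "approach %.1f A (< strand gap %.1f A)"),
                 min(cand), gap))
  }
  invisible(m)
}

# --- skeletons (canonical frame, dense sampling, approximate size; the ---
# --- caller rescales to the exact contour length)                      ---

dense_t <- function(n = 2400) 2 * pi * (seq_len(n) - 1) / n

# Planar ellipse. For ellipticity > 1 the semi-axis ratio is calibrated so
# the *measured* a1/a2 of the arc-length-resampled curve equals the target
# (uniform arc sampling weights the flatter sides more, so the measured
# ratio is slightly below the semi-axis ratio).
skeleton_ellipse <- function(L, ellipticity) {
  measured <- function(rho) {
    t <- dense_t(1024)
    m <- cbind(rho * cos(t), sin(t), 0)
    m <- as_curve_matrix(resample_closed(m, 512))
    a <- principal_axis_lengths(m)
    a[1] / a[2]
  }
  rho <- if (ellipticity <= 1 + 1e-9) 1 else {
    stats::uniroot(function(r) measured(r) - ellipticity,
                   lower = ellipticity, upper = 2 * ellipticity,
                   extendInt = "upX", tol = 1e-5)$root
  }
  t <- dense_t()
  m <- cbind(rho * cos(t), sin(t), 0)
  m * (L / closed_arc_length(m))
}

# Figure-8: planar lemniscate (one transversal crossing in projection) with
# the two strand passes separated by `offset` along z at the crossing. The
# orientation is chosen so the default curve has negative writhe, matching
# a right-handed crossover of negatively supercoiled DNA.
skeleton_figure8 <- function(L, offset) {
  t <- dense_t()
  mk <- function(A) cbind(A * cos(t), A * sin(t) * cos(t),
                          -offset / 2 * sin(t))
  A <- stats::uniroot(function(A) closed_arc_length(mk(A)) - L,
                      lower = L / 20, upper = L / 2, tol = 1e-8)$root
  mk(A)
}

# Racquet / needle: a loop of radius r joined to a doubled-back handle of
# two parallel strands `gap` apart, closed by a U-turn.
skeleton_racquet <- function(L, loop_fraction, gap) {
  f <- loop_fraction
  r <- f * L / (2 * pi)
  for (i in 1:80) r <- f * L / (2 * pi - 2 * asin(min(1, gap / (2 * r))))
  if (r < DNA_TUBE_RADIUS) {
    stop(sprintf(paste0("infeasible shape parameters: loop_fraction %.3g ",
                        "gives loop radius %.1f A < DNA tube radius %.0f A"),
                 f, r, DNA_TUBE_RADIUS))
  }
  if (gap / (2 * r) >= 1) {
    stop("infeasible shape parameters: handle_gap exceeds loop diameter")
  }
  h <- (L - f * L - pi * gap / 2) / 2
  if (h <= gap) {
    stop(sprintf(paste0("infeasible shape parameters: loop_fraction %.3g ",
                        "leaves no handle (h = %.1f A)"), f, h))
  }
  y0 <- -sqrt(r^2 - gap^2 / 4)
  alpha <- asin(gap / (2 * r))
  th1 <- atan2(y0, gap / 2)              # right junction, ~ -pi/2 + alpha
  arc <- seq(th1, th1 + (2 * pi - 2 * alpha), length.out = 1600)
  loop <- cbind(r * cos(arc), r * sin(arc), 0)
  nseg <- function(len) max(8, round(len / 1.5))
  left_dn <- cbind(-gap / 2, seq(y0, y0 - h, length.out = nseg(h)), 0)
  phi <- seq(pi, 2 * pi, length.out = nseg(pi * gap / 2))
  uturn <- cbind(gap / 2 * cos(phi), y0 - h + gap / 2 * sin(phi), 0)
  right_up <- cbind(gap / 2, seq(y0 - h, y0, length.out = nseg(h)), 0)
  drop_last <- function(m) m[-nrow(m), , drop = FALSE]
  rbind(drop_last(loop), drop_last(left_dn), drop_last(uturn),
        drop_last(right_up))
}

# Handcuffs: two loops of radius r joined by two parallel strands `gap`
# apart; `loop_fraction` is the contour fraction in both loops combined.
skeleton_handcuffs <- function(L, loop_fraction, gap) {
  f <- loop_fraction
  r <- f * L / (4 * pi)
  for (i in 1:80) {
    s <- sqrt(max(r^2 - gap^2 / 4, 1e-9))
    gam <- atan2(gap / 2, s)
    r <- f * L / (2 * (2 * pi - 2 * gam))
  }
  if (r < DNA_TUBE_RADIUS) {
    stop(sprintf(paste0("infeasible shape parameters: loop_fraction %.3g ",
                        "gives loop radius %.1f A < DNA tube radius %.0f A"),
                 f, r, DNA_TUBE_RADIUS))
  }
  s <- sqrt(r^2 - gap^2 / 4)
  gam <- atan2(gap / 2, s)
  d <- (1 - f) * L / 2                   # straight length per strand
  if (d <= gap) {
    stop("infeasible shape parameters: handcuffs handle shorter than the gap")
  }
  cx <- d / 2 + s                        # loop centres at (+-cx, 0)
  nseg <- function(len) max(8, round(len / 1.5))
  arcn <- 1200
  a1 <- seq(pi - gam, -(pi - gam), length.out = arcn)   # right loop, long way
  right_loop <- cbind(cx + r * cos(a1), r * sin(a1), 0)
  bottom <- cbind(seq(d / 2, -d / 2, length.out = nseg(d)), -gap / 2, 0)
  a2 <- seq(-gam, -(2 * pi - gam), length.out = arcn)   # left loop, long way
  left_loop <- cbind(-cx + r * cos(a2), r * sin(a2), 0)
  top <- cbind(seq(-d / 2, d / 2, length.out = nseg(d)), gap / 2, 0)
  drop_last <- function(m) m[-nrow(m), , drop = FALSE]
  rbind(drop_last(right_loop), drop_last(bottom), drop_last(left_loop),
        drop_last(top))
}

# Rod: a stadium — two long juxtaposed strands capped by two apical bends.
skeleton_rod <- function(L, gap) {
  slen <- (L - pi * gap) / 2
  if (slen <= gap) {
    stop("infeasible shape parameters: contour too short for a rod at this handle_gap")
  }
  nseg <- function(len) max(8, round(len / 1.5))
  top <- cbind(seq(-slen / 2, slen / 2, length.out = nseg(slen)), gap / 2, 0)
  a1 <- seq(pi / 2, -pi / 2, length.out = nseg(pi * gap / 2))
  right_cap <- cbind(slen / 2 + gap / 2 * cos(a1), gap / 2 * sin(a1), 0)
  bottom <- cbind(seq(slen / 2, -slen / 2, length.out = nseg(slen)), -gap / 2, 0)
  a2 <- seq(-pi / 2, -3 * pi / 2, length.out = nseg(pi * gap / 2))
  left_cap <- cbind(-slen / 2 + gap / 2 * cos(a2), gap / 2 * sin(a2), 0)
  drop_last <- function(m) m[-nrow(m), , drop = FALSE]
  rbind(drop_last(top), drop_last(right_cap), drop_last(bottom),
        drop_last(left_cap))
}
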