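# Closed-loop polygon tracing of a minicircle backbone in a density volume.
#
# The tracer places a small closed polygon around the density, scores it by
# interpolated density at the vertices minus quadratic penalties on edge
# lengths and interior angles (restoring forces toward a regular polygon of
# the expected contour length), follows the score gradient, then doubles the
# vertex count and repeats: 5 -> 10 -> 20 vertices by default. Convergence
# is verified by running multiple random starts and measuring their mutual
# agreement after cyclic/orientation alignment.

#' Tracer configuration
#'
#' @param n_init Initial vertex count (>= 3). Default 5.
#' @param n_final Final vertex count; must equal `n_init * 2^k`. Default 20.
#' @param w_density Weight of the density term. Default 20 (density is
#'   rescaled to unit peak internally by [trace()], so the default weight
#'   ratio is volume-size invariant). Tuned on clean phantoms so the
#'   density attraction dominates the restoring forces wherever density is
#'   present.
#' @param w_length Weight (1/A^2) of the squared edge-length deviation from
#'   the regular-polygon target. Default 0.02.
#' @param w_angle Weight (1/rad^2) of the squared interior-angle deviation.
#'   Default 0.2.
#' @param step_size Vertex move per iteration in A (with backtracking
#'   halving when a step would lower the score). Default 2.
#' @param max_iters Maximum gradient iterations per refinement stage.
#' @param convergence_tol Relative score improvement below which a stage
#'   stops.
#' @param n_starts Number of independent starts. Default 6.
#' @param agreement_tol Aligned vertex distance (A) below which an
#'   independent start counts as reproducing the best one. Default 15
#'   (half the strand gap of an interwound superhelix).
#' @param lowpass_sigma Preprocessing Gaussian low-pass sigma in A.
#' @param contour_length Expected backbone contour length in A (construct
#'   length in bp times 3.4 A/bp); sets the target edge length. Default
#'   1142.4 A (336 bp).
#' @param w_overlap Weight (1/A^2) of the excluded-volume penalty: pairs
#'   of non-adjacent vertices closer than `overlap_dist` are penalized by
#'   the squared shortfall. Prevents degenerate traces that cover the same
#'   stretch of density twice. Default 0.2.
#' @param overlap_dist Excluded-volume distance in A; 15 by default, below
#'   the centre-to-centre gap of genuinely juxtaposed duplex strands
#'   (~30 A) but above tracing jitter.
#' @param length_soften Multiplier further softening the edge-length weight
#'   during the staged refinement (the final polish pass always uses the
#'   full weight). Default 0.25.
#' @param edge_samples Extra density samples per edge included in the score
#'   (0 = density at vertices only, the default; the variant exists for
#'   diagnostics and does not alter the refinement gradient).
#' @param seed Integer seed for start orientations.
#' @return A `tracer_config` list.
#' @export
tracer_config <- function(n_init = 5, n_final = 20,
                          w_density = 20, w_length = 0.02, w_angle = 0.2,
                          step_size = 2, max_iters = 250,
                          convergence_tol = 1e-6,
                          n_starts = 6, agreement_tol = 15,
                          lowpass_sigma = 5,
                          contour_length = 336 * 3.4,
                          w_overlap = 0.2, overlap_dist = 15,
                          edge_samples = 0, length_soften = 0.25, seed = 1L) {
  if (n_init < 3) stop("n_init must be >= 3")
  k <- log2(n_final / n_init)
  if (abs(k - round(k)) > 1e-9 || k < 0) {
    stop("n_final must equal n_init * 2^k for integer k >= 0")
  }
  if (any(c(w_density, w_length, w_angle) < 0)) stop("weights must be >= 0")
  if (n_starts < 1) stop("n_starts must be >= 1")
  structure(list(n_init = as.integer(n_init), n_final = as.integer(n_final),
                 w_density = w_density, w_length = w_length,
                 w_angle = w_angle, step_size = step_size,
                 max_iters = as.integer(max_iters),
                 convergence_tol = convergence_tol,
                 n_starts = as.integer(n_starts),
                 agreement_tol = agreement_tol,
                 lowpass_sigma = lowpass_sigma,
                 contour_length = contour_length,
                 w_overlap = w_overlap, overlap_dist = overlap_dist,
                 edge_samples = as.integer(edge_samples),
                 length_soften = length_soften,
                 seed = as.integer(seed)),
            class = "tracer_config")
}

#' Preprocess a density volume for tracing
#'
#' Gaussian low-pass filter (identity when `lowpass_sigma = 0`), then
#' normalization to zero mean and unit standard deviation, then removal of
#' disconnected noise: all above-threshold connected components
#' (threshold = mean + 1 sd of the filtered volume, 26-connectivity) except
#' the largest are zeroed.
#'
#' @param volume A [density_volume].
#' @param config A [tracer_config()].
#' @return A preprocessed [density_volume] with attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess <- function(volume, config = tracer_config()) {
  stopifnot(inherits(volume, "density_volume"))
  dat <- as.numeric(volume$data)
  if (stats::sd(dat) < 1e-12) stop("no density: volume is constant")
  d3 <- dim(volume$data)
  if (config$lowpass_sigma > 0) {
    dat <- cpp_gaussian_blur(dat, d3, config$lowpass_sigma / volume$voxel_size)
  }
  dat <- (dat - mean(dat)) / stats::sd(dat)
  # zero every above-threshold component except the largest (by voxel count)
  mask <- dat > 1
  if (any(mask)) {
    lab <- cpp_label_components(mask, d3)
    counts <- tabulate(lab[lab > 0])
    keep <- which.max(counts)
    dat[lab > 0 & lab != keep] <- 0
  }
  out <- density_volume(array(dat, d3), volume$voxel_size, volume$origin)
  attr(out, "preprocessed") <- TRUE
  out
}

# target edge length and interior angle for an n-gon of given contour length
polygon_targets <- function(n, contour_length) {
  list(edge = contour_length / n, angle = pi - 2 * pi / n)
}

# interior angles at each vertex of a closed polygon
interior_angles <- function(m) {
  n <- nrow(m)
  prv <- m[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- m[c(2:n, 1), , drop = FALSE]
  u <- prv - m
  w <- nxt - m
  cu <- sqrt(rowSums(u^2)); cw <- sqrt(rowSums(w^2))
  cosang <- pmin(pmax(rowSums(u * w) / pmax(cu * cw, 1e-300), -1), 1)
  acos(cosang)
}

#' Score a closed polygon against a density volume
#'
#' Score = `w_density * sum(rho(v_i)) - w_length * sum((|e_i| - Lbar)^2)
#' - w_angle * sum((theta_i - thetabar)^2) - w_overlap * P_ev`, with `rho`
#' trilinearly interpolated density, `Lbar` the target edge length
#' (`contour_length / n`), `thetabar` the regular-polygon interior angle
#' `pi - 2*pi/n`, and `P_ev` the excluded-volume penalty (squared shortfall
#' below `overlap_dist` over non-adjacent vertex pairs), which keeps the
#' polygon from covering the same stretch of density twice.
#'
#' @inheritParams as_curve_matrix
#' @param volume A [density_volume] (typically preprocessed).
#' @param config A [tracer_config()].
#' @return A list with `total`, `density`, `length`, `angle`, `overlap`
#'   components (penalty entries are the already-weighted, signed
#'   contributions).
#' @export
score_polygon <- function(curve, volume, config = tracer_config()) {
  m <- as_curve_matrix(curve)
  n <- nrow(m)
  rho <- interp_density(volume, m)
  if (any(is.na(rho))) {
    stop("vertex outside volume: index ",
         paste(which(is.na(rho)), collapse = ", "))
  }
  dens_sum <- sum(rho)
  if (config$edge_samples > 0) {
    es <- config$edge_samples
    nxt <- m[c(2:n, 1), , drop = FALSE]
    pts <- do.call(rbind, lapply(seq_len(es), function(k) {
      f <- k / (es + 1)
      m + f * (nxt - m)
    }))
    rho_e <- interp_density(volume, pts)
    rho_e[is.na(rho_e)] <- 0
    dens_sum <- n * mean(c(rho, rho_e))
  }
  tg <- polygon_targets(n, config$contour_length)
  e <- m[c(2:n, 1), , drop = FALSE] - m
  elen <- sqrt(rowSums(e^2))
  pen_len <- sum((elen - tg$edge)^2)
  ang <- interior_angles(m)
  pen_ang <- sum((ang - tg$angle)^2)
  dens <- config$w_density * dens_sum
  lenp <- -config$w_length * pen_len
  angp <- -config$w_angle * pen_ang
  ovl <- if (config$w_overlap > 0) {
    -config$w_overlap * cpp_overlap(m, config$overlap_dist)$penalty
  } else 0
  list(total = dens + lenp + angp + ovl, density = dens, length = lenp,
       angle = angp, overlap = ovl)
}

# gradient of the total score with respect to every vertex (n x 3).
# Density gradient by central finite differences of the interpolated field
# (delta = half a voxel); length and angle penalty gradients analytic.
score_gradient <- function(m, volume, config) {
  n <- nrow(m)
  tg <- polygon_targets(n, config$contour_length)
  delta <- volume$voxel_size / 2
  g <- matrix(0, n, 3)
  for (d in 1:3) {
    mp <- m; mp[, d] <- mp[, d] + delta
    mm <- m; mm[, d] <- mm[, d] - delta
    fp <- interp_density(volume, mp)
    fm <- interp_density(volume, mm)
    fp[is.na(fp)] <- 0; fm[is.na(fm)] <- 0
    g[, d] <- config$w_density * (fp - fm) / (2 * delta)
  }
  # length penalty: score term is -w_length * sum((|e_i| - Lbar)^2);
  # d/dv_j P_L = coef_{j-1} ehat_{j-1} - coef_j ehat_j with coef = 2(|e|-Lbar)
  nxt_i <- c(2:n, 1)
  prv_i <- c(n, 1:(n - 1))
  e <- m[nxt_i, , drop = FALSE] - m
  elen <- pmax(sqrt(rowSums(e^2)), 1e-12)
  ehat <- e / elen
  coef <- 2 * (elen - tg$edge)
  g_len <- (coef * ehat)[prv_i, , drop = FALSE] - coef * ehat
  # angle penalty
  u <- m[prv_i, , drop = FALSE] - m
  w <- m[nxt_i, , drop = FALSE] - m
  cu <- pmax(sqrt(rowSums(u^2)), 1e-12)
  cw <- pmax(sqrt(rowSums(w^2)), 1e-12)
  uh <- u / cu; wh <- w / cw
  cosang <- pmin(pmax(rowSums(uh * wh), -1), 1)
  sinang <- sqrt(pmax(1 - cosang^2, 1e-12))
  theta <- acos(cosang)
  ccoef <- 2 * (theta - tg$angle)
  dth_du <- -(wh - cosang * uh) / (cu * sinang)
  dth_dw <- -(uh - cosang * wh) / (cw * sinang)
  g_ang <- matrix(0, n, 3)
  # angle at j contributes to vertices j-1 (via u), j (via -u-w), j+1 (via w)
  contrib_u <- ccoef * dth_du
  contrib_w <- ccoef * dth_dw
  g_ang <- g_ang - contrib_u - contrib_w           # vertex j itself
  g_ang[prv_i, ] <- g_ang[prv_i, ] + contrib_u     # vertex j-1
  g_ang[nxt_i, ] <- g_ang[nxt_i, ] + contrib_w     # vertex j+1
  g <- g - config$w_length * g_len - config$w_angle * g_ang
  # excluded-volume repulsion (gradient of the score term
  # -w_overlap * penalty, so minus the penalty gradient)
  if (config$w_overlap > 0) {
    ov <- cpp_overlap(m, config$overlap_dist)
    g <- g - config$w_overlap * ov$gradient
  }
  g
}

#' Refine a closed polygon by score gradient ascent
#'
#' Each iteration moves every vertex by `step_size` along the (normalized)
#' gradient of the total score at that vertex; a step that would lower the
#' score is retried with halved step sizes (backtracking). Stops when the
#' relative score improvement falls below `convergence_tol` or `max_iters`
#' is reached. The returned polygon never scores below the input.
#'
#' Vertices whose update would leave the volume are clamped to the boundary;
#' if more than half the vertices end up clamped the result carries a
#' non-convergence flag.
#'
#' @inheritParams score_polygon
#' @return The refined curve tibble with attributes `score` (final score
#'   list), `iterations`, `converged`, `clamped_fraction`.
#' @export
refine <- function(curve, volume, config = tracer_config(),
                   .basin_hop = TRUE) {
  m <- as_curve_matrix(curve)
  m <- clamp_to_volume(m, volume)
  sc <- score_polygon(m, volume, config)
  trajectory <- sc$total
  clamped_frac <- 0
  iters <- 0
  for (it in seq_len(config$max_iters)) {
    iters <- it
    g <- score_gradient(m, volume, config)
    gn <- sqrt(rowSums(g^2))
    # proportional step: the steepest vertex moves by step_size, the rest
    # in proportion, so settled vertices are not jostled off their optima
    dir <- g / max(max(gn), 1e-12)
    step <- config$step_size
    improved <- FALSE
    for (try in 1:12) {
      prop <- clamp_to_volume(m + step * dir, volume)
      sp <- score_polygon(prop, volume, config)
      if (sp$total > sc$total) {
        clamped_frac <- mean(rowSums(prop != m + step * dir) > 0)
        m <- prop; scold <- sc; sc <- sp
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    # score-guarded arc-length reparameterization: redistributing the
    # vertices uniformly along the current contour is attempted whenever
    # gradient steps stall (and periodically); it is only accepted if the
    # total score improves, preserving monotonicity
    if (!improved || it %% 20 == 0) {
      prop <- clamp_to_volume(as_curve_matrix(resample_closed(m, nrow(m))),
                              volume)
      sp <- score_polygon(prop, volume, config)
      if (sp$total > sc$total) {
        scold <- sc
        m <- prop; sc <- sp
        improved <- TRUE
      }
    }
    # score-guarded crankshaft moves: when gradient steps stall, rotate
    # contiguous vertex arcs by 180 degrees about the chord through their
    # endpoints. This discrete move escapes draping defects (an arc settled
    # on the wrong side of the density) that no continuous gradient path
    # can fix. The most promising rotated candidates are briefly re-refined
    # before deciding; a move is accepted only if it ends above the current
    # score, preserving monotonicity.
    if (!improved && .basin_hop) {
      cs <- crankshaft_hop(m, volume, config, sc$total)
      if (!is.null(cs)) {
        scold <- sc
        m <- cs$m; sc <- cs$score
        improved <- TRUE
      }
    }
    # void-vertex reseating: a vertex stranded beyond the density support
    # feels no density gradient at all; propose re-seating it on a coarse
    # grid around its neighbours' midpoint and accept the best candidate
    # that improves the total score
    if (!improved) {
      rs <- reseat_void_vertices(m, volume, config, sc$total)
      if (!is.null(rs)) {
        scold <- sc
        m <- rs$m; sc <- rs$score
        improved <- TRUE
      }
    }
    if (!improved) break
    trajectory <- c(trajectory, sc$total)
    rel <- (sc$total - scold$total) / max(abs(sc$total), 1e-12)
    if (rel < config$convergence_tol) break
  }
  out <- curve_tibble(m)
  attr(out, "score") <- sc
  attr(out, "iterations") <- iters
  attr(out, "trajectory") <- trajectory
  attr(out, "clamped_fraction") <- clamped_frac
  attr(out, "converged") <- clamped_frac <= 0.5
  out
}

# crankshaft basin hop: enumerate 180-degree rotations of every contiguous
# vertex arc about the chord through its endpoints, briefly re-refine the
# most promising candidates, and return the best result if it beats the
# current score (NULL otherwise)
crankshaft_hop <- function(m, volume, config, current_total,
                           n_candidates = 8, polish_iters = 80) {
  n <- nrow(m)
  if (n < 8) return(NULL)
  props <- list()
  totals <- numeric(0)
  for (i in seq_len(n)) {
    for (len in seq(3, n - 4)) {
      j <- ((i + len - 1) %% n) + 1
      a <- m[i, ]; b <- m[j, ]
      ax <- b - a
      if (sum(ax^2) < 1e-12) next
      rot <- rotation_about_axis(ax, pi)
      idx <- ((i:(i + len - 2)) %% n) + 1   # interior vertices of the arc
      prop <- m
      prop[idx, ] <- t(a + rot %*% (t(prop[idx, , drop = FALSE]) - a))
      prop <- clamp_to_volume(prop, volume)
      sp <- score_polygon(prop, volume, config)
      props[[length(props) + 1]] <- prop
      totals <- c(totals, sp$total)
    }
  }
  if (!length(props)) return(NULL)
  ord <- order(totals, decreasing = TRUE)[seq_len(min(n_candidates,
                                                      length(props)))]
  cfg_mini <- config
  cfg_mini$max_iters <- polish_iters
  best <- NULL
  best_total <- current_total
  for (o in ord) {
    ref <- refine(curve_tibble(props[[o]]), volume, cfg_mini,
                  .basin_hop = FALSE)
    st <- attr(ref, "score")
    if (st$total > best_total + 1e-9) {
      best_total <- st$total
      best <- list(m = as_curve_matrix(ref), score = st)
    }
  }
  best
}

# re-seat vertices with (near) zero interpolated density by grid search
# around the midpoint of their neighbours; returns the improved polygon or
# NULL
reseat_void_vertices <- function(m, volume, config, current_total,
                                 reach = 60, spacing = 12) {
  rho <- interp_density(volume, m)
  rho[is.na(rho)] <- 0
  void <- which(rho < 0.05 * max(rho, na.rm = TRUE))
  if (!length(void)) return(NULL)
  n <- nrow(m)
  g1 <- seq(-reach, reach, by = spacing)
  grid <- as.matrix(expand.grid(x = g1, y = g1, z = g1))
  best <- NULL
  best_total <- current_total
  cur <- m
  for (i in void) {
    mid <- (cur[((i - 2) %% n) + 1, ] + cur[(i %% n) + 1, ]) / 2
    cand <- sweep(grid, 2, mid, "+")
    cand_rho <- interp_density(volume, cand)
    cand <- cand[!is.na(cand_rho) & cand_rho > 0.2, , drop = FALSE]
    if (!nrow(cand)) next
    for (ci in seq_len(nrow(cand))) {
      prop <- cur
      prop[i, ] <- cand[ci, ]
      sp <- score_polygon(prop, volume, config)
      if (sp$total > best_total + 1e-9) {
        best_total <- sp$total
        best <- list(m = prop, score = sp)
      }
    }
    if (!is.null(best)) cur <- best$m
  }
  best
}

clamp_to_volume <- function(m, volume) {
  lo <- volume$origin + 1e-6
  hi <- volume$origin + (dim(volume$data) - 1) * volume$voxel_size - 1e-6
  for (d in 1:3) m[, d] <- pmin(pmax(m[, d], lo[d]), hi[d])
  m
}

#' Double the vertex count of a closed polygon
#'
#' Inserts the midpoint of every edge: output vertices at odd positions
#' (1-based: 2, 4, ...) are exact edge midpoints, vertices at even input
#' positions are the input vertices. The polyline is unchanged as a set.
#'
#' @inheritParams as_curve_matrix
#' @return A curve tibble with `2 n` vertices.
#' @export
subdivide <- function(curve) {
  m <- as_curve_matrix(curve)
  n <- nrow(m)
  mid <- (m + m[c(2:n, 1), , drop = FALSE]) / 2
  out <- matrix(0, 2 * n, 3)
  out[seq(1, 2 * n, by = 2), ] <- m
  out[seq(2, 2 * n, by = 2), ] <- mid
  curve_tibble(out)
}

#' Optimal cyclic alignment distance between two closed curves
#'
#' Minimum over all cyclic index shifts and both orientations of the mean
#' pairwise vertex distance. No rigid-body superposition is performed: the
#' curves are assumed to share a volume frame.
#'
#' @param a,b Closed curves with equal vertex counts.
#' @return A list: `distance` (mean vertex distance, A), `shift`,
#'   `reversed`, and `matched` (b reindexed to match a).
#' @export
align_closed_curves <- function(a, b) {
  ma <- as_curve_matrix(a)
  mb <- as_curve_matrix(b)
  n <- nrow(ma)
  if (nrow(mb) != n) stop("curves must have equal vertex counts")
  best <- list(distance = Inf, shift = 0L, reversed = FALSE, matched = mb)
  for (rev in c(FALSE, TRUE)) {
    mbo <- if (rev) mb[n:1, , drop = FALSE] else mb
    for (s in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      d <- mean(sqrt(rowSums((ma - mbo[idx, , drop = FALSE])^2)))
      if (d < best$distance) {
        best <- list(distance = d, shift = s, reversed = rev,
                     matched = curve_tibble(mbo[idx, , drop = FALSE]))
      }
    }
  }
  best
}

#' Trace a closed DNA backbone in a density volume
#'
#' Full tracing pipeline: (optionally) preprocess, then for each start
#' place a regular `n_init`-gon at the density centroid (radius from the
#' density's spatial extent; the first start lies in the density's
#' principal plane, further starts are randomly oriented), refine, double
#' the vertices, refine, double, refine (5 -> 10 -> 20 by default). The
#' best-scoring start is returned; agreement is the mean aligned vertex
#' distance between the best start and the others.
#'
#' @param volume A [density_volume]; preprocessed automatically unless it
#'   carries the `preprocessed` attribute or `preprocess = FALSE`.
#' @param config A [tracer_config()].
#' @param preprocess Whether to run [preprocess()] first when needed.
#' @return A `trace_result`: list with `curve` (tibble of `n_final`
#'   vertices), `score` (component breakdown), `agreement` (A),
#'   `converged`, `iterations` (per stage, best start), and `starts` (per-
#'   start summary tibble). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
trace <- function(volume, config = tracer_config(), preprocess = TRUE) {
  stopifnot(inherits(volume, "density_volume"))
  if (preprocess && !isTRUE(attr(volume, "preprocessed"))) {
    volume <- minicircle::preprocess(volume, config)
  }
  # unit-peak copy for scoring so the default weights are box-size invariant
  vol <- volume
  mx <- max(vol$data)
  if (mx <= 0) stop("no above-threshold density to trace")
  vol$data <- vol$data / mx

  mask <- vol$data > 1 / mx  # z-score threshold (mean + 1 sd) on the rescaled copy
  if (!any(mask)) stop("no above-threshold density to trace")
  wts <- vol$data[mask]
  coords <- voxel_coords(vol, which(mask))
  ctr <- colSums(coords * wts) / sum(wts)
  cc <- sweep(coords, 2, ctr)
  cov <- crossprod(cc * sqrt(wts / sum(wts)))
  eg <- eigen(cov, symmetric = TRUE)
  r_circle <- config$contour_length / (2 * pi)
  # anisotropic initial radii from the density's principal spatial extent
  r1 <- max(min(1.5 * r_circle, sqrt(2 * max(eg$values[1], 0))),
            5 * vol$voxel_size)
  r2 <- max(min(1.5 * r_circle, sqrt(2 * max(eg$values[2], 0))),
            5 * vol$voxel_size)

  # coarse-to-fine: early stages see an extra-blurred copy of the density
  # so the small polygon is captured from far away; the final stage sees
  # the preprocessed volume itself
  n_stages <- round(log2(config$n_final / config$n_init)) + 1
  extra_blur <- if (n_stages >= 4) c(rep(40, n_stages - 3), 24, 8, 0) else
    utils::tail(c(24, 8, 0), n_stages)
  stage_vols <- lapply(extra_blur, function(sg) {
    if (sg <= 0) return(vol)
    v <- vol
    v$data <- array(cpp_gaussian_blur(vol$data, dim(vol$data),
                                      sg / vol$voxel_size), dim(vol$data))
    v$data <- v$data / max(v$data)
    v
  })

  # start diversity: start 1 lies in the density's principal plane at the
  # measured extent; further starts tilt that plane by a random axis and
  # angle (bounded so the polygon stays within the blurred tube's capture
  # range) and rescale the initial radii, so the starts explore both
  # shrink-wrap (outside-in) and inflate (inside-out) basins
  radius_scales <- c(1.0, 1.35, 0.7, 1.15, 0.85, 1.25)
  starts <- vector("list", config$n_starts)
  for (k in seq_len(config$n_starts)) {
    basis <- if (k <= 3) eg$vectors[, 1:2] else {
      with_seed(config$seed + 977L * k, {
        ax <- stats::rnorm(3)
        ang <- stats::runif(1, 0, 50 * pi / 180)
        rotation_about_axis(ax, ang) %*% eg$vectors[, 1:2]
      })
    }
    sc <- radius_scales[((k - 1) %% length(radius_scales)) + 1]
    phi <- 2 * pi * (seq_len(config$n_init) - 1) / config$n_init
    init <- t(ctr + t(cos(phi) %o% (sc * r1 * basis[, 1]) +
                        sin(phi) %o% (sc * r2 * basis[, 2])))
    cur <- curve_tibble(clamp_to_volume(init, vol))
    iters <- integer(0)
    flags <- logical(0)
    stage <- 1
    repeat {
      # the edge-length penalty is quadratic around a target that scales as
      # 1/n, so at sparse vertex counts it would dominate the density term
      # and deform the polygon before it has settled on the tube; keep it
      # soft while the topology forms (scaled by (n/n_final)^2 / 4) ...
      cfg_s <- config
      cfg_s$w_length <- config$w_length * (nrow(cur) / config$n_final)^2 *
        config$length_soften
      cur <- refine(cur, stage_vols[[stage]], cfg_s,
                    .basin_hop = nrow(cur) >= config$n_final)
      iters <- c(iters, attr(cur, "iterations"))
      flags <- c(flags, attr(cur, "converged"))
      if (nrow(cur) >= config$n_final) break
      cur <- subdivide(cur)
      stage <- stage + 1
    }
    # ... then polish at the final vertex count with the full length weight
    # so the polygon extends to the expected contour length
    cur <- refine(cur, vol, config)
    iters <- c(iters, attr(cur, "iterations"))
    flags <- c(flags, attr(cur, "converged"))
    # adaptive extension: if the polygon still misses the known construct
    # length, escalate the length weight to push it over the dynamical
    # barrier (typically vertex allocation around apical bends), then
    # re-settle under the normal weights; keep the best-scoring state
    best_state <- cur
    best_total <- attr(cur, "score")$total
    attempt <- 0
    while (abs(closed_arc_length(cur) / config$contour_length - 1) > 0.03 &&
           attempt < 3) {
      attempt <- attempt + 1
      cfg_hi <- config
      cfg_hi$w_length <- config$w_length * 4^attempt
      pushed <- refine(cur, vol, cfg_hi)
      cur <- refine(pushed, vol, config)
      iters <- c(iters, attr(cur, "iterations"))
      tot <- attr(cur, "score")$total
      if (tot > best_total) {
        best_total <- tot
        best_state <- cur
      }
    }
    if (attr(best_state, "score")$total >= attr(cur, "score")$total) {
      cur <- best_state
    }
    # final score on the common (unblurred) volume for comparability
    final_score <- score_polygon(cur, vol, config)
    starts[[k]] <- list(curve = cur, score = final_score,
                        iterations = iters, converged = all(flags))
  }
  scores <- vapply(starts, function(s) s$score$total, numeric(1))
  best_i <- which.max(scores)
  best <- starts[[best_i]]
  # agreement between starts: aligned (cyclic shift + reversal) mean vertex
  # distance, computed on finely resampled copies so the arbitrary vertex
  # phase of a closed polygon does not dominate the distance
  # symmetric mean curve-to-curve distance: insensitive to vertex phase
  # and to the strand-pairing degeneracy of juxtaposed-strand shapes
  # (handcuffs, figure-8), where two traces can cover the same density
  # tube with different connectivity
  start_dists <- vapply(seq_len(config$n_starts), function(k) {
    if (k == best_i) return(0)
    (curve_rmsd(best$curve, starts[[k]]$curve) +
       curve_rmsd(starts[[k]]$curve, best$curve)) / 2
  }, numeric(1))
  agreement <- if (config$n_starts > 1) {
    mean(start_dists[-best_i])
  } else NA_real_
  any_ok <- any(vapply(starts, function(s) s$converged, logical(1)))
  # converged: the best start is internally converged and at least one
  # independent start reproduces its curve
  converged <- best$converged &&
    (config$n_starts == 1 ||
       min(start_dists[-best_i]) < config$agreement_tol)
  if (!any_ok) converged <- FALSE

  start_tbl <- tibble::tibble(
    start = seq_len(config$n_starts),
    score = scores,
    converged = vapply(starts, function(s) s$converged, logical(1)),
    iterations = vapply(starts, function(s) sum(s$iterations), numeric(1)))

  structure(list(curve = curve_tibble(as_curve_matrix(best$curve)),
                 score = best$score,
                 iterations = best$iterations,
                 agreement = agreement,
                 converged = converged,
                 starts = start_tbl,
                 config = config),
            class = "trace_result")
}

voxel_coords <- function(volume, lin_idx) {
  d <- dim(volume$data)
  i <- (lin_idx - 1) %% d[1]
  j <- ((lin_idx - 1) %/% d[1]) %% d[2]
  k <- (lin_idx - 1) %/% (d[1] * d[2])
  cbind(volume$origin[1] + i * volume$voxel_size,
        volume$origin[2] + j * volume$voxel_size,
        volume$origin[3] + k * volume$voxel_size)
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("<trace_result> %d vertices, perimeter %.1f A\n",
              nrow(x$curve), closed_arc_length(x$curve)))
  cat(sprintf("  score %.3f (density %.3f, length %.3f, angle %.3f)\n",
              x$score$total, x$score$density, x$score$length, x$score$angle))
  cat(sprintf("  multi-start agreement %.2f A, converged: %s\n",
              x$agreement, x$converged))
  invisible(x)
}

#' Tidy a trace result into a vertex table
#'
#' @param x A `trace_result`.
#' @param ... Unused.
#' @return Tibble with `vertex`, `x`, `y`, `z`.
#' @export
tidy.trace_result <- function(x, ...) {
  dplyr::mutate(x$curve, vertex = dplyr::row_number(), .before = 1)
}

#' One-row summary of a trace result
#'
#' @inheritParams tidy.trace_result
#' @return Tibble with score components, perimeter, agreement, convergence.
#' @export
glance.trace_result <- function(x, ...) {
  tibble::tibble(n_vertices = nrow(x$curve),
                 perimeter = closed_arc_length(x$curve),
                 score = x$score$total,
                 score_density = x$score$density,
                 score_length = x$score$length,
                 score_angle = x$score$angle,
                 agreement = x$agreement,
                 converged = x$converged)
}
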