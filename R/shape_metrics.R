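# Per-molecule shape quantification and rule-based classification into the
# empirical minicircle shape taxonomy, plus population-level statistics
# (shape frequency distributions and the weighted compactness average).

# principal axis lengths: square roots of the eigenvalues of the vertex
# coordinate covariance (population covariance, centred), descending
principal_axis_lengths <- function(m) {
  cc <- sweep(m, 2, colMeans(m))
  ev <- eigen(crossprod(cc) / nrow(m), symmetric = TRUE)$values
  sqrt(pmax(ev, 0))
}

#' Principal axis lengths of a traced polygon
#'
#' The three relative axis lengths a1 >= a2 >= a3 of a closed curve,
#' computed as the square roots of the eigenvalues of the vertex-coordinate
#' covariance (equivalently the singular values of the centred coordinate
#' array divided by sqrt(n)).
#'
#' @inheritParams as_curve_matrix
#' @return Named numeric vector `c(a1, a2, a3)` in Angstroms.
#' @export
#' @examples
#' t <- 2 * pi * (0:63) / 64
#' axis_lengths(tibble::tibble(x = cos(t), y = sin(t), z = 0))
#' # a1 = a2 = 1/sqrt(2), a3 = 0
axis_lengths <- function(curve) {
  a <- principal_axis_lengths(as_curve_matrix(curve))
  stats::setNames(a, c("a1", "a2", "a3"))
}

#' Ellipticity of an open-circle trace
#'
#' Ratio a1/a2 of the two largest principal axis lengths: the in-plane
#' aspect ratio of the traced polygon. Meaningful for open circles; other
#' shapes yield a value but it no longer measures deviation from a circle.
#'
#' @inheritParams as_curve_matrix
#' @return Ellipticity >= 1.
#' @export
ellipticity <- function(curve) {
  a <- axis_lengths(curve)
  if (a[["a2"]] < 1e-9) stop("degenerate curve: second axis length is zero")
  unname(a[["a1"]] / a[["a2"]])
}

#' Density-weighted radius of gyration around a traced path
#'
#' The raw density is masked around the fitted path: voxels within `r_in`
#' of the path carry weight 1, beyond that the weight is damped by a
#' Gaussian decay reaching 0.01 at `r_out` and is zero past `r_out`.
#' Rg^2 = sum(w * rho * |r - rbar|^2) / sum(w * rho) with rho clamped at
#' >= 0 and rbar the (w * rho)-weighted centroid.
#'
#' @param volume A [density_volume] (raw, not preprocessed).
#' @inheritParams as_curve_matrix
#' @param r_in Direct-inclusion radius in A. Default 45.
#' @param r_out Outer mask extent in A. Default 180.
#' @return Radius of gyration in Angstroms.
#' @export
radius_of_gyration <- function(volume, curve, r_in = 45, r_out = 180) {
  stopifnot(inherits(volume, "density_volume"), r_out > r_in, r_in > 0)
  m <- as_curve_matrix(curve)
  d3 <- dim(volume$data)
  d <- cpp_dist_field(d3, volume$voxel_size, volume$origin, m, cutoff = r_out)
  s <- (r_out - r_in) / sqrt(2 * log(100))  # w(r_out) = 0.01
  w <- numeric(length(d))
  inner <- is.finite(d) & d <= r_in
  decay <- is.finite(d) & d > r_in & d <= r_out
  w[inner] <- 1
  w[decay] <- exp(-(d[decay] - r_in)^2 / (2 * s^2))
  rho <- pmax(as.numeric(volume$data), 0)
  wr <- w * rho
  idx <- which(wr > 0)
  tot <- sum(wr[idx])
  if (tot <= 0) stop("no positive density in mask")
  pos <- voxel_coords(volume, idx)
  ctr <- colSums(pos * wr[idx]) / tot
  sqrt(sum(wr[idx] * rowSums(sweep(pos, 2, ctr)^2)) / tot)
}

#' Shape descriptor thresholds
#'
#' Defaults for the descriptor computation and the classification decision
#' list. All distances in Angstroms, arcs as fractions of the contour.
#'
#' @param contact_distance Two vertices closer than this (and non-adjacent
#'   along the contour) are in contact. Default 60.
#' @param min_arc Minimum arc separation for a vertex pair to count as
#'   non-adjacent. Default 120.
#' @param min_loop_frac Minimum contour fraction for a non-contact run to
#'   count as a loop. Default 0.12.
#' @param wr_open Max |writhe| for an open circle. Default 0.35.
#' @param contact_open Max contact fraction for an open circle. Default 0.1.
#' @param loop_arc_racquet Min loop arc fraction separating racquet from
#'   needle. Default 0.35.
#' @param loop_arc_fig8 Min arc fraction of *each* loop for a figure-8.
#'   Default 0.25.
#' @param handle_contact Min contact fraction over handle (non-loop)
#'   vertices for handcuffs. Default 0.5.
#' @param contact_rod Min overall contact fraction for a rod. Default 0.5.
#' @return A named list of thresholds.
#' @export
shape_thresholds <- function(contact_distance = 60, min_arc = 120,
                             min_loop_frac = 0.12, wr_open = 0.35,
                             contact_open = 0.1, loop_arc_racquet = 0.35,
                             loop_arc_fig8 = 0.25, handle_contact = 0.5,
                             contact_rod = 0.5) {
  list(contact_distance = contact_distance, min_arc = min_arc,
       min_loop_frac = min_loop_frac, wr_open = wr_open,
       contact_open = contact_open, loop_arc_racquet = loop_arc_racquet,
       loop_arc_fig8 = loop_arc_fig8, handle_contact = handle_contact,
       contact_rod = contact_rod)
}

#' Compute the shape descriptor vector of a traced curve
#'
#' Aggregates writhe, projected crossings (projection along the smallest
#' principal axis), principal axis lengths, ellipticity and planarity,
#' strand-contact statistics and loop structure, and — when a volume is
#' supplied — the density-weighted radius of gyration.
#'
#' Contact: a vertex is "in contact" if some vertex more than `min_arc`
#' away along the contour lies within `contact_distance` in space. Loops
#' are circular runs of non-contact vertices spanning at least
#' `min_loop_frac` of the contour; a fully contact-free curve counts as a
#' single loop (the open circle).
#'
#' @inheritParams as_curve_matrix
#' @param volume Optional [density_volume] for the Rg computation.
#' @param thresholds A [shape_thresholds()] list.
#' @param r_in,r_out Mask radii passed to [radius_of_gyration()].
#' @return A one-row tibble of descriptors.
#' @export
compute_descriptors <- function(curve, volume = NULL,
                                thresholds = shape_thresholds(),
                                r_in = 45, r_out = 180) {
  m <- as_curve_matrix(curve)
  n <- nrow(m)
  th <- thresholds
  L <- closed_arc_length(m)
  wr <- writhe(m)
  a <- principal_axis_lengths(m)
  cc <- sweep(m, 2, colMeans(m))
  axis3 <- eigen(crossprod(cc) / n, symmetric = TRUE)$vectors[, 3]
  cr <- crossing_signs(m, axis3)
  cr_ok <- cr[!cr$ambiguous, , drop = FALSE]
  n_crossings <- nrow(cr_ok)
  crossing_sep <- if (n_crossings > 0) min(cr_ok$separation) else NA_real_

  s <- vertex_arc_positions(m)
  d_arc <- abs(outer(s, s, "-"))
  d_arc <- pmin(d_arc, L - d_arc)
  d_eu <- as.matrix(stats::dist(m))
  contact_mat <- d_eu < th$contact_distance & d_arc > th$min_arc
  contact <- rowSums(contact_mat) > 0
  contact_fraction <- mean(contact)

  loops <- circular_runs(!contact)
  loop_arcs <- vapply(loops, function(run) run_arc_length(run, s, L),
                      numeric(1))
  is_loop <- loop_arcs >= th$min_loop_frac * L
  loop_count <- sum(is_loop)
  loop_fracs <- sort(loop_arcs[is_loop], decreasing = TRUE) / L
  loop_arc1 <- if (loop_count >= 1) loop_fracs[1] else NA_real_
  loop_arc2 <- if (loop_count >= 2) loop_fracs[2] else NA_real_
  in_loop <- rep(FALSE, n)
  for (k in which(is_loop)) in_loop[loops[[k]]] <- TRUE
  handle_contact_fraction <- if (all(in_loop)) NA_real_ else
    mean(contact[!in_loop])

  rg <- if (!is.null(volume)) {
    radius_of_gyration(volume, m, r_in = r_in, r_out = r_out)
  } else NA_real_

  tibble::tibble(writhe = wr, n_crossings = n_crossings,
                 crossing_separation = crossing_sep,
                 a1 = a[1], a2 = a[2], a3 = a[3],
                 ellipticity = a[1] / max(a[2], 1e-12),
                 planarity = a[3] / max(a[2], 1e-12),
                 contact_fraction = contact_fraction,
                 loop_count = loop_count,
                 loop_arc1 = loop_arc1, loop_arc2 = loop_arc2,
                 handle_contact_fraction = handle_contact_fraction,
                 rg_density = rg)
}

# circular runs of TRUE values; returns list of index vectors
circular_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(list(seq_len(n)))   # contact-free: one whole-curve run
  if (!any(flag)) return(list())
  # rotate so position 1 is FALSE, then ordinary run-length encoding
  off <- which(!flag)[1] - 1
  rot <- flag[((seq_len(n) - 1 + off) %% n) + 1]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  runs <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      idx <- ((starts[k]:ends[k] - 1 + off) %% n) + 1
      runs[[length(runs) + 1]] <- idx
    }
  }
  runs
}

# arc length spanned by a contiguous (circularly contiguous) vertex run
run_arc_length <- function(run, s, L) {
  if (length(run) == length(s)) return(L)
  first <- run[1]; last <- run[length(run)]
  d <- s[last] - s[first]
  if (d < 0) d <- d + L
  d + L / length(s)  # include one edge spacing so single-vertex runs count
}

#' Classify a shape descriptor vector
#'
#' Deterministic first-match decision list over the descriptor vector,
#' mirroring the visual taxonomy: open circle, open figure-8, figure-8,
#' racquet, needle, handcuffs, rod, with `other` as fallback. All
#' thresholds come from [shape_thresholds()].
#'
#' @param descriptors One-row tibble from [compute_descriptors()] (or a
#'   multi-row tibble, classified rowwise).
#' @param thresholds A [shape_thresholds()] list.
#' @return Character vector of class labels.
#' @export
classify_shape <- function(descriptors, thresholds = shape_thresholds()) {
  th <- thresholds
  one <- function(d) {
    if (abs(d$writhe) < th$wr_open && d$n_crossings == 0 &&
        d$contact_fraction < th$contact_open) return("open_circle")
    if (d$n_crossings == 1 && !is.na(d$crossing_separation) &&
        d$crossing_separation > th$contact_distance) return("open_figure8")
    if (d$n_crossings == 1 && !is.na(d$crossing_separation) &&
        d$crossing_separation <= th$contact_distance &&
        d$loop_count == 2 && !is.na(d$loop_arc2) &&
        d$loop_arc2 >= th$loop_arc_fig8) return("figure8")
    if (d$loop_count == 1 && d$loop_arc1 >= th$loop_arc_racquet)
      return("racquet")
    if (d$loop_count == 1 && d$loop_arc1 < th$loop_arc_racquet)
      return("needle")
    if (d$loop_count == 2 && !is.na(d$handle_contact_fraction) &&
        d$handle_contact_fraction > th$handle_contact) return("handcuffs")
    if (d$loop_count == 0 && d$contact_fraction > th$contact_rod)
      return("rod")
    "other"
  }
  vapply(seq_len(nrow(descriptors)),
         function(i) one(descriptors[i, , drop = FALSE]), character(1))
}

COMPACTNESS_WEIGHTS <- stats::setNames(1:7, SHAPE_CLASSES)

#' Shape frequency distribution of a population
#'
#' @param labels Character vector of per-molecule class labels.
#' @return A tibble with one row per class (`shape_class`, `count`,
#'   `fraction` over the seven named classes, `weight`), attributes
#'   `n_total` and `weighted_compactness`.
#' @export
shape_distribution <- function(labels) {
  lv <- c(SHAPE_CLASSES, "other")
  counts <- table(factor(labels, levels = lv))
  named <- counts[SHAPE_CLASSES]
  denom <- sum(named)
  out <- tibble::tibble(
    shape_class = lv,
    count = as.integer(counts),
    fraction = ifelse(lv %in% SHAPE_CLASSES,
                      if (denom > 0) as.integer(counts) / denom else NA_real_,
                      NA_real_),
    weight = c(COMPACTNESS_WEIGHTS, NA_real_))
  attr(out, "n_total") <- length(labels)
  attr(out, "weighted_compactness") <-
    if (denom > 0) sum(out$fraction[1:7] * 1:7) else NA_real_
  out
}

#' Weighted compactness of a shape distribution
#'
#' The weighted average of class weights 1 (open circle) through 7 (rod)
#' under the class fractions, renormalized over the seven named classes
#' ('other' is excluded). Ranges from 1 (all open circles) to 7 (all rods).
#'
#' @param x A [shape_distribution()] tibble, a character vector of labels,
#'   or a named count vector.
#' @return The weighted compactness in `[1, 7]`.
#' @export
#' @examples
#' weighted_compactness(c(open_circle = 50, rod = 50)) # 4
weighted_compactness <- function(x) {
  if (is.data.frame(x)) {
    counts <- stats::setNames(x$count, x$shape_class)[SHAPE_CLASSES]
  } else if (is.character(x)) {
    counts <- table(factor(x, levels = SHAPE_CLASSES))
  } else if (!is.null(names(x))) {
    counts <- stats::setNames(rep(0, 7), SHAPE_CLASSES)
    keep <- intersect(names(x), SHAPE_CLASSES)
    counts[keep] <- x[keep]
  } else stop("cannot interpret `x` as a shape distribution")
  counts[is.na(counts)] <- 0
  tot <- sum(counts)
  if (tot == 0) stop("no molecules in the seven named shape classes")
  sum(counts / tot * COMPACTNESS_WEIGHTS)
}

#' Per-group population summary
#'
#' Summarizes a per-molecule table into per-group rows: number of
#' molecules, class fractions, weighted compactness and the mean and sd of
#' the density radius of gyration.
#'
#' @param records Data frame with columns `group`, `shape_class` and
#'   optionally `rg_density`.
#' @return A tibble with one row per group: `n`, `weighted_compactness`,
#'   `rg_mean`, `rg_sd` (0 for singleton groups, flagged by
#'   `single_record`), and one `frac_<class>` column per named class.
#' @export
population_summary <- function(records) {
  stopifnot(all(c("group", "shape_class") %in% names(records)))
  if (!"rg_density" %in% names(records)) records$rg_density <- NA_real_
  records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      fr <- as.numeric(table(factor(d$shape_class, levels = SHAPE_CLASSES)))
      fr <- if (sum(fr) > 0) fr / sum(fr) else rep(NA_real_, 7)
      wc <- tryCatch(weighted_compactness(d$shape_class),
                     error = function(e) NA_real_)
      rg <- d$rg_density[!is.na(d$rg_density)]
      tibble::tibble(
        n = nrow(d),
        weighted_compactness = wc,
        rg_mean = if (length(rg)) mean(rg) else NA_real_,
        rg_sd = if (length(rg) > 1) stats::sd(rg) else
          if (length(rg) == 1) 0 else NA_real_,
        single_record = nrow(d) == 1) |>
        dplyr::bind_cols(stats::setNames(as.list(fr),
                                         paste0("frac_", SHAPE_CLASSES)))
    }) |>
    dplyr::ungroup()
}
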