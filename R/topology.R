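# Topological bookkeeping for covalently closed DNA circles: linking number
# arithmetic (Lk, Lk0, dLk, superhelical density), writhe of closed curves by
# the Gauss double integral, projected crossing signs, the steps-of-two
# relaxation parity of type-II topoisomerases, and circular cleavage-site
# mapping from restriction fragment sizes.

#' Linking number of the relaxed topoisomer
#'
#' The relaxed linking number Lk0 is the nearest integer to
#' `n_bp / helical_repeat`. Exact half-integer ties round away from zero
#' (never reached for canonical helical repeats and the constructs studied
#' here).
#'
#' @param n_bp Number of base pairs (> 0).
#' @param helical_repeat Helical repeat in bp/turn. Default 10.5 for B-DNA.
#' @return Integer Lk0.
#' @export
#' @examples
#' relaxed_lk(336) # 32
#' relaxed_lk(672) # 64
relaxed_lk <- function(n_bp, helical_repeat = 10.5) {
  if (any(n_bp <= 0) || helical_repeat <= 0) {
    stop("n_bp and helical_repeat must be > 0")
  }
  x <- n_bp / helical_repeat
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Topoisomer bookkeeping record
#'
#' @param n_bp Base pairs of the circle.
#' @param Lk Integer linking number of this topoisomer.
#' @param helical_repeat Helical repeat in bp/turn.
#' @return A one-row tibble: `n_bp`, `helical_repeat`, `Lk`, `Lk0`, `dLk`,
#'   `sigma` (superhelical density dLk/Lk0).
#' @export
#' @examples
#' topoisomer(336, 30) # dLk = -2, sigma = -0.0625
topoisomer <- function(n_bp, Lk, helical_repeat = 10.5) {
  Lk0 <- relaxed_lk(n_bp, helical_repeat)
  dLk <- as.integer(Lk) - Lk0
  tibble::tibble(n_bp = as.integer(n_bp), helical_repeat = helical_repeat,
                 Lk = as.integer(Lk), Lk0 = Lk0, dLk = dLk,
                 sigma = superhelical_density(dLk, Lk0))
}

#' Superhelical density
#'
#' @param dLk Linking difference Lk - Lk0.
#' @param Lk0 Relaxed linking number (non-zero).
#' @return dLk / Lk0.
#' @export
superhelical_density <- function(dLk, Lk0) {
  if (any(Lk0 == 0)) stop("Lk0 must be non-zero")
  dLk / Lk0
}

#' Writhe of a closed curve
#'
#' Discrete Gauss double integral over all non-adjacent segment pairs, each
#' pair evaluated by the exact closed-form solid angle of the quadrilateral
#' spanned by the two segments. Adjacent segments contribute exactly zero.
#'
#' @inheritParams as_curve_matrix
#' @return The writhe Wr (dimensionless, signed).
#' @export
#' @examples
#' t <- 2 * pi * (0:63) / 64
#' writhe(tibble::tibble(x = cos(t), y = sin(t), z = 0)) # 0: planar curve
writhe <- function(curve) {
  m <- as_curve_matrix(curve)
  if (nrow(m) < 4) stop("writhe needs a closed curve with >= 4 vertices")
  e <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE]) - m
  len <- sqrt(rowSums(e^2))
  bad <- which(len < 1e-9)
  if (length(bad)) {
    stop("degenerate zero-length segment(s) at vertex index: ",
         paste(bad, collapse = ", "))
  }
  cpp_writhe(m)
}

#' Twist from the conservation Lk = Tw + Wr
#'
#' @param topo A topoisomer row from [topoisomer()], or a numeric Lk.
#' @param wr Writhe.
#' @return Tw = Lk - Wr.
#' @export
twist_of <- function(topo, wr) {
  Lk <- if (is.data.frame(topo)) topo$Lk else topo
  Lk - wr
}

#' Terminal linking differences after type-II relaxation in steps of two
#'
#' Type-II topoisomerases change Lk in steps of +-2 until |dLk| is minimal.
#' The terminal set depends only on the parity of Lk - Lk0: equal parity
#' relaxes uniquely to dLk = 0; opposite parity ends in a mixture of
#' dLk = -1 and +1.
#'
#' @param Lk,Lk0 Integers.
#' @return Sorted integer vector of terminal dLk values.
#' @export
#' @examples
#' relax_steps_of_two(28, 32) # 0
#' relax_steps_of_two(31, 32) # -1 +1
relax_steps_of_two <- function(Lk, Lk0) {
  stopifnot(Lk == round(Lk), Lk0 == round(Lk0))
  if ((Lk - Lk0) %% 2 == 0) 0L else c(-1L, 1L)
}

#' Signed self-crossings of a curve's planar projection
#'
#' Projects the closed curve along `axis` and finds all transversal
#' self-crossings of the projected polygon. Each crossing is signed by the
#' standard chirality rule: with `t_over` and `t_under` the 3D tangents of
#' the strand nearer/farther along the projection axis, the sign is
#' `sign((t_over x t_under) . axis)`. A right-handed crossover (negatively
#' supercoiled DNA) carries a negative sign. Crossings that are tangential
#' within tolerance are flagged ambiguous and excluded from the projected
#' writhe sum.
#'
#' @inheritParams as_curve_matrix
#' @param axis Length-3 projection direction (normalized internally).
#' @param tol Relative tolerance below which a crossing counts as
#'   tangential.
#' @return A tibble with one row per crossing: segment indices `seg_a`,
#'   `seg_b`, arc-length positions `arc_a`, `arc_b`, 3D strand `separation`
#'   at the crossing, `sign`, `ambiguous`. The attribute
#'   `projected_writhe` holds the sum of unambiguous signs.
#' @export
crossing_signs <- function(curve, axis = c(0, 0, 1), tol = 1e-9) {
  m <- as_curve_matrix(curve)
  n <- nrow(m)
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal in-plane basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  p2 <- cbind(m %*% u, m %*% v)
  hgt <- as.numeric(m %*% axis)
  nxt <- c(2:n, 1)
  e2 <- p2[nxt, ] - p2
  arc <- vertex_arc_positions(m)
  elen3 <- sqrt(rowSums((m[nxt, ] - m)^2))
  scale2 <- sqrt(rowSums(e2^2))

  rows <- list()
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) break
      det <- e2[i, 1] * e2[j, 2] - e2[i, 2] * e2[j, 1]
      dp <- p2[j, ] - p2[i, ]
      denom_scale <- max(scale2[i] * scale2[j], 1e-300)
      if (abs(det) <= tol * denom_scale) {
        # parallel in projection; could still overlap, flag only if they
        # actually touch — skip (tangential crossings handled below)
        next
      }
      t_i <- (dp[1] * e2[j, 2] - dp[2] * e2[j, 1]) / det
      t_j <- (dp[1] * e2[i, 2] - dp[2] * e2[i, 1]) / det
      if (t_i <= 0 || t_i >= 1 || t_j <= 0 || t_j >= 1) next
      h_i <- hgt[i] + t_i * (hgt[nxt[i]] - hgt[i])
      h_j <- hgt[j] + t_j * (hgt[nxt[j]] - hgt[j])
      pt_i <- m[i, ] + t_i * (m[nxt[i], ] - m[i, ])
      pt_j <- m[j, ] + t_j * (m[nxt[j], ] - m[j, ])
      sep <- sqrt(sum((pt_i - pt_j)^2))
      ambiguous <- abs(det) < 1e-6 * denom_scale || abs(h_i - h_j) < 1e-9
      if (h_i >= h_j) { t_over <- m[nxt[i], ] - m[i, ]; t_under <- m[nxt[j], ] - m[j, ] }
      else           { t_over <- m[nxt[j], ] - m[j, ]; t_under <- m[nxt[i], ] - m[i, ] }
      cr <- c(t_over[2] * t_under[3] - t_over[3] * t_under[2],
              t_over[3] * t_under[1] - t_over[1] * t_under[3],
              t_over[1] * t_under[2] - t_over[2] * t_under[1])
      sgn <- sign(sum(cr * axis))
      rows[[length(rows) + 1]] <- tibble::tibble(
        seg_a = i, seg_b = j,
        arc_a = arc[i] + t_i * elen3[i], arc_b = arc[j] + t_j * elen3[j],
        separation = sep, sign = as.integer(sgn), ambiguous = ambiguous)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(seg_a = integer(), seg_b = integer(), arc_a = numeric(),
                   arc_b = numeric(), separation = numeric(),
                   sign = integer(), ambiguous = logical())
  }
  attr(out, "projected_writhe") <- sum(out$sign[!out$ambiguous])
  out
}

#' Projected writhe along one direction
#'
#' Sum of signed transversal crossings of the projection along `axis`.
#' Averaged over uniformly random directions this converges to the writhe.
#'
#' @inheritParams crossing_signs
#' @return Signed integer crossing sum.
#' @export
projected_writhe <- function(curve, axis = c(0, 0, 1)) {
  attr(crossing_signs(curve, axis), "projected_writhe")
}

# ---------------------------------------------------------------------------
# Gel-based fragment sizing and circular cleavage mapping

#' Fragment length from gel migration distance
#'
#' Fits the standard semi-log calibration (least squares of log10(bp)
#' against migration distance) to a ladder and interpolates query
#' distances. Queries outside the ladder's distance span are extrapolated
#' and flagged.
#'
#' @param ladder Data frame with columns `bp` and `distance`.
#' @param distance Numeric vector of query migration distances.
#' @return Numeric vector of estimated fragment sizes (bp), with attribute
#'   `extrapolated` (logical vector). A warning is issued on extrapolation.
#' @export
#' @examples
#' ladder <- tibble::tibble(bp = c(100, 1000), distance = c(50, 10))
#' fragment_length_from_migration(ladder, 30) # ~316 bp
fragment_length_from_migration <- function(ladder, distance) {
  stopifnot(is.data.frame(ladder), all(c("bp", "distance") %in% names(ladder)))
  if (nrow(ladder) < 2) stop("need at least 2 ladder points")
  fit <- stats::lm(log10(bp) ~ distance, data = ladder)
  est <- 10^stats::predict(fit, newdata = data.frame(distance = distance))
  outside <- distance < min(ladder$distance) | distance > max(ladder$distance)
  if (any(outside)) {
    warning(sprintf("%d quer%s outside the ladder span: extrapolated",
                    sum(outside), if (sum(outside) == 1) "y lies" else "ies lie"))
  }
  est <- unname(est)
  attr(est, "extrapolated") <- outside
  est
}

#' Map a cleavage site on a circle from double-digest fragment sizes
#'
#' A single unknown cut plus one known restriction site splits the circle
#' into two fragments; the unknown cut therefore lies at `site + f` or
#' `site - f` (mod circle size) for the smaller fragment size `f`. Each
#' enzyme contributes two candidate positions (widened to intervals by the
#' fragment-size tolerance); the cut site is the circular intersection
#' across enzymes.
#'
#' @param circle_bp Circle size in bp.
#' @param digests Data frame with columns `enzyme`, `site` (known cut
#'   position, bp), `frag1`, `frag2` (observed fragment sizes, bp;
#'   `frag1 + frag2` must equal `circle_bp` within `2 * tol`).
#' @param tol Fragment-size tolerance in bp (half-width of each candidate
#'   interval). Default 10.
#' @return A tibble of circular candidate intervals with columns `start`,
#'   `end`, `width`, `center` (bp, mod `circle_bp`) and attribute
#'   `ambiguous` (TRUE when more than one disjoint interval remains, e.g.
#'   with a single enzyme).
#' @export
map_cleavage_site <- function(circle_bp, digests, tol = 10) {
  stopifnot(is.data.frame(digests),
            all(c("enzyme", "site", "frag1", "frag2") %in% names(digests)))
  N <- circle_bp
  bad <- abs(digests$frag1 + digests$frag2 - N) > 2 * tol
  if (any(bad)) {
    stop("inconsistent fragments: sizes for ",
         paste(digests$enzyme[bad], collapse = ", "),
         " do not sum to the circle size within tolerance")
  }
  # per-enzyme allowed set: union of two circular intervals (start, width)
  enz_sets <- lapply(seq_len(nrow(digests)), function(i) {
    s <- digests$site[i]; f <- digests$frag1[i]
    cand <- c((s + f) %% N, (s - f) %% N)
    lapply(unique(cand), function(cc) c(start = (cc - tol) %% N, width = 2 * tol))
  })
  acc <- enz_sets[[1]]
  if (length(enz_sets) > 1) {
    for (k in 2:length(enz_sets)) {
      acc <- intersect_circular(acc, enz_sets[[k]], N)
      if (length(acc) == 0) {
        stop("inconsistent fragments: no circle position fits all digests")
      }
    }
  }
  acc <- merge_circular(acc, N)
  out <- tibble::tibble(
    start = vapply(acc, function(a) a[["start"]] %% N, numeric(1)),
    width = vapply(acc, function(a) a[["width"]], numeric(1)))
  out$end <- (out$start + out$width) %% N
  out$center <- (out$start + out$width / 2) %% N
  out <- out[, c("start", "end", "width", "center")]
  attr(out, "ambiguous") <- nrow(out) > 1
  if (nrow(digests) == 1) attr(out, "ambiguous") <- TRUE
  out
}

# intersect two unions of circular intervals; intervals are c(start, width)
intersect_circular <- function(A, B, N) {
  out <- list()
  for (a in A) for (b in B) for (shift in c(-N, 0, N)) {
    lo <- max(a[["start"]], b[["start"]] + shift)
    hi <- min(a[["start"]] + a[["width"]], b[["start"]] + b[["width"]] + shift)
    if (hi >= lo) out[[length(out) + 1]] <- c(start = lo, width = hi - lo)
  }
  out
}

# merge overlapping members of a union of circular intervals
merge_circular <- function(A, N) {
  if (length(A) <= 1) return(A)
  iv <- do.call(rbind, lapply(A, function(a) c(a[["start"]] %% N, a[["width"]])))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list()
  cur <- iv[1, ]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= cur[1] + cur[2] + 1e-9) {
        cur[2] <- max(cur[1] + cur[2], iv[i, 1] + iv[i, 2]) - cur[1]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- iv[i, ]
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  # wrap-around join of first and last
  if (length(merged) > 1) {
    first <- merged[[1]]; last <- merged[[length(merged)]]
    if (last[1] + last[2] >= N + first[1] - 1e-9) {
      merged[[1]] <- c(last[1], first[1] + first[2] + N - last[1])
      merged[[length(merged)]] <- NULL
    }
  }
  lapply(merged, function(x) c(start = x[[1]], width = x[[2]]))
}
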