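# Shared geometry helpers for closed curves.
#
# Curves are ordered cyclic vertex lists in Angstroms. User-facing functions
# accept any data frame with columns x, y, z (or a plain n x 3 matrix) and
# return tibbles, so results chain with the pipe.

#' Coerce a curve to an n x 3 coordinate matrix
#'
#' @param curve A data frame with numeric columns `x`, `y`, `z`, or an
#'   n x 3 numeric matrix. Coordinates are in Angstroms.
#' @return An n x 3 numeric matrix.
#' @keywords internal
as_curve_matrix <- function(curve) {
  if (is.matrix(curve)) {
    if (ncol(curve) != 3) stop("curve matrix must have 3 columns (x, y, z)")
    m <- curve
  } else if (is.data.frame(curve)) {
    if (!all(c("x", "y", "z") %in% names(curve))) {
      stop("curve data frame must have columns x, y, z")
    }
    m <- cbind(curve$x, curve$y, curve$z)
  } else {
    stop("curve must be a data frame with x/y/z or an n x 3 matrix")
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 3) stop("a closed curve needs at least 3 vertices")
  if (any(!is.finite(m))) stop("curve coordinates must be finite")
  dimnames(m) <- NULL
  m
}

#' Build a curve tibble from a coordinate matrix
#' @keywords internal
curve_tibble <- function(m) {
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Arc length of a closed polygon
#'
#' Sum of all edge lengths including the closing edge from the last vertex
#' back to the first.
#'
#' @inheritParams as_curve_matrix
#' @return Total perimeter in Angstroms.
#' @export
#' @examples
#' sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
#' closed_arc_length(sq) # 4
closed_arc_length <- function(curve) {
  m <- as_curve_matrix(curve)
  e <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE]) - m
  sum(sqrt(rowSums(e^2)))
}

# Cumulative arc position of each vertex (first vertex at 0).
vertex_arc_positions <- function(m) {
  e <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE]) - m
  c(0, cumsum(sqrt(rowSums(e^2)))[-nrow(m)])
}

#' Resample a closed curve to uniform arc-length spacing
#'
#' Linear interpolation along the closed polyline at `n` equally spaced arc
#' positions, starting from the first vertex.
#'
#' @inheritParams as_curve_matrix
#' @param n Number of output vertices.
#' @return A tibble with columns x, y, z.
#' @export
resample_closed <- function(curve, n) {
  m <- as_curve_matrix(curve)
  stopifnot(n >= 3)
  s <- vertex_arc_positions(m)
  total <- closed_arc_length(m)
  # closed parameterization: append the first vertex at arc position `total`
  sm <- c(s, total)
  mm <- rbind(m, m[1, , drop = FALSE])
  target <- total * (seq_len(n) - 1) / n
  out <- vapply(1:3, function(d) stats::approx(sm, mm[, d], xout = target,
                                               rule = 2)$y,
                numeric(n))
  curve_tibble(out)
}

# Circular moving-average smoothing of a closed vertex list.
smooth_closed <- function(m, window) {
  if (window <= 1) return(m)
  n <- nrow(m)
  half <- floor(window / 2)
  idx <- outer(seq_len(n), -half:half, function(i, o) ((i - 1 + o) %% n) + 1)
  out <- m
  for (d in 1:3) {
    v <- m[, d]
    out[, d] <- rowMeans(matrix(v[idx], nrow = n))
  }
  out
}

# Uniformly random rotation matrix (det +1) from the current RNG stream.
random_rotation_matrix <- function() {
  repeat {
    a <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(a)
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-8) return(q)
  }
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Root-mean-square distance from one curve's vertices to another curve
#'
#' Each vertex of `curve` is matched to its nearest point on the closed
#' polyline `reference` (not just its nearest vertex), and the RMS of those
#' distances is returned. Used to compare a traced polygon against the dense
#' ground-truth backbone it was traced from; no superposition is performed
#' because both live in the same volume frame.
#'
#' @param curve,reference Data frames with columns x, y, z (or n x 3 matrices).
#' @return RMS point-to-curve distance in Angstroms.
#' @export
curve_rmsd <- function(curve, reference) {
  p <- as_curve_matrix(curve)
  q <- as_curve_matrix(reference)
  n <- nrow(q)
  a <- q
  b <- rbind(q[-1, , drop = FALSE], q[1, , drop = FALSE])
  e <- b - a
  ee <- rowSums(e^2)
  d2 <- vapply(seq_len(nrow(p)), function(i) {
    w <- sweep(a, 2, p[i, ], "-")
    t <- pmin(pmax(-rowSums(w * e) / pmax(ee, 1e-300), 0), 1)
    dd <- w + e * t
    min(rowSums(dd^2))
  }, numeric(1))
  sqrt(mean(d2))
}

# Rodrigues rotation matrix about a unit axis
rotation_about_axis <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
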