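# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force Gauss double integral for the writhe of a closed polygon,
# midpoint rule over all ordered segment pairs at `factor`-times vertex
# density.
brute_force_writhe <- function(curve, factor = 10) {
  m <- as.matrix(resample_closed(curve, factor * nrow(as.data.frame(curve))))
  n <- nrow(m)
  nxt <- c(2:n, 1)
  tang <- m[nxt, ] - m
  mid <- (m + m[nxt, ]) / 2
  s <- 0
  for (i in seq_len(n)) {
    r <- sweep(-mid, 2, -mid[i, ])          # mid_i - mid_j for all j
    cr <- cbind(tang[i, 2] * tang[, 3] - tang[i, 3] * tang[, 2],
                tang[i, 3] * tang[, 1] - tang[i, 1] * tang[, 3],
                tang[i, 1] * tang[, 2] - tang[i, 2] * tang[, 1])
    num <- rowSums(cr * r)
    den <- rowSums(r^2)^1.5
    keep <- seq_len(n) != i
    s <- s + sum(num[keep] / den[keep])
  }
  s / (4 * pi)
}

# Direct-summation radius of gyration: plain R loop over segments for the
# distance field, explicit weighted sums.
rg_direct_oracle <- function(volume, curve, r_in = 45, r_out = 180) {
  m <- as.matrix(as.data.frame(curve)[, c("x", "y", "z")])
  d3 <- dim(volume$data)
  ax <- lapply(1:3, function(a) volume$origin[a] + (seq_len(d3[a]) - 1) * volume$voxel_size)
  pos <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  # min distance to each closed-curve segment
  n <- nrow(m)
  dmin <- rep(Inf, nrow(pos))
  for (i in seq_len(n)) {
    a <- m[i, ]; b <- m[(i %% n) + 1, ]
    e <- b - a
    ee <- sum(e^2)
    w <- sweep(pos, 2, a)
    t <- pmin(pmax(as.numeric(w %*% e) / max(ee, 1e-300), 0), 1)
    dd <- w - outer(t, e)
    dmin <- pmin(dmin, sqrt(rowSums(dd^2)))
  }
  s <- (r_out - r_in) / sqrt(2 * log(100))
  wgt <- ifelse(dmin <= r_in, 1,
                ifelse(dmin <= r_out, exp(-(dmin - r_in)^2 / (2 * s^2)), 0))
  # note: expand.grid runs x fastest, matching R array linearization
  rho <- pmax(as.numeric(volume$data), 0)
  wr <- wgt * rho
  tot <- sum(wr)
  ctr <- colSums(pos * wr) / tot
  sqrt(sum(wr * rowSums(sweep(pos, 2, ctr)^2)) / tot)
}

# quick clean phantom of one class
phantom <- function(cls, seed = 1, margin = 40, ...) {
  cv <- make_curve(shape_spec(cls, ...), seed = seed)
  list(curve = cv, volume = rasterize(cv, margin = margin))
}
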