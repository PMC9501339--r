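# Independent brute-force oracles: naive loop implementations kept separate
# from the package's vectorized code paths, used to pin down expected values.

rand_mask <- function(seed, d = c(16, 16, 16), p = 0.5,
                      dx = 0.4, dy = 0.6, dz = 0.8) {
  withr::with_seed(seed, {
    m <- array(runif(prod(d)) < p, d)
    binary_grid(m, dx, dy, dz)
  })
}

bf_biovolume <- function(bg) {
  m <- bg$mask; d <- dim(m); n <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (m[z, y, x]) n <- n + 1L
  n * bg$dx * bg$dy * bg$dz
}

bf_coverage_slice <- function(bg, z) {
  m <- bg$mask; d <- dim(m); n <- 0L
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) if (m[z, y, x]) n <- n + 1L
  n / (d[2] * d[3])
}

bf_coverage_substratum <- function(bg) {
  m <- bg$mask; d <- dim(m); n <- 0L
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    hit <- FALSE
    for (z in seq_len(d[1])) if (m[z, y, x]) { hit <- TRUE; break }
    if (hit) n <- n + 1L
  }
  n / (d[2] * d[3])
}

# count of foreground voxels with a background / out-of-bounds face neighbour
bf_area_to_volume <- function(bg) {
  m <- bg$mask; d <- dim(m)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(m, arr.ind = TRUE)
  nb_exposed <- 0L
  for (i in seq_len(nrow(idx))) {
    for (k in 1:6) {
      z <- idx[i, 1] + offs[k, 1]; y <- idx[i, 2] + offs[k, 2]
      x <- idx[i, 3] + offs[k, 3]
      out <- z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]
      if (out || !m[z, y, x]) { nb_exposed <- nb_exposed + 1L; break }
    }
  }
  (nb_exposed * bg$dx * bg$dy) / bf_biovolume(bg)
}

bf_top_height <- function(bg) {
  m <- bg$mask; d <- dim(m)
  h <- matrix(0, d[2], d[3])
  for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    for (z in rev(seq_len(d[1]))) if (m[z, y, x]) { h[y, x] <- z * bg$dz; break }
  h
}

bf_mean_sd <- function(h) {
  n <- length(h); s <- 0
  for (v in h) s <- s + v
  mu <- s / n
  ss <- 0
  for (v in h) ss <- ss + (v - mu)^2
  c(mean = mu, sd = sqrt(ss / n))
}

bf_rms <- function(h) {
  ms <- bf_mean_sd(h)
  unname(ms["sd"])
}

# average ranks by counting, then the Pearson product-moment formula
bf_spearman <- function(x, y) {
  rk <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- rk(x); ry <- rk(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# 26-connected component count by breadth-first flood fill
bf_component_count <- function(bg) {
  m <- bg$mask; d <- dim(m)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ncomp <- 0L
  idx <- which(m, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    if (seen[idx[i, 1], idx[i, 2], idx[i, 3]]) next
    ncomp <- ncomp + 1L
    queue <- list(idx[i, ])
    seen[idx[i, 1], idx[i, 2], idx[i, 3]] <- TRUE
    while (length(queue)) {
      v <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        z <- v[1] + offs[k, 1]; y <- v[2] + offs[k, 2]; x <- v[3] + offs[k, 3]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        if (m[z, y, x] && !seen[z, y, x]) {
          seen[z, y, x] <- TRUE
          queue[[length(queue) + 1L]] <- c(z, y, x)
        }
      }
    }
  }
  ncomp
}

# independent box counting: explicit grid scan instead of unique boxes,
# slope by the closed-form least-squares formula
bf_box_dimension <- function(slice) {
  d <- dim(slice)
  bnd <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!slice[i, j]) next
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && !slice[ii, jj]) {
        bnd[i, j] <- TRUE; break
      }
    }
  }
  eps <- 1L; sizes <- integer(0)
  while (eps <= min(d) / 4) { sizes <- c(sizes, eps); eps <- eps * 2L }
  counts <- numeric(length(sizes))
  for (s in seq_along(sizes)) {
    e <- sizes[s]; cnt <- 0L
    for (bi in seq_len(ceiling(d[1] / e))) for (bj in seq_len(ceiling(d[2] / e))) {
      rows <- ((bi - 1L) * e + 1L):min(bi * e, d[1])
      cols <- ((bj - 1L) * e + 1L):min(bj * e, d[2])
      if (any(bnd[rows, cols])) cnt <- cnt + 1L
    }
    counts[s] <- cnt
  }
  lx <- log(1 / sizes); ly <- log(counts)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

# analytic spherical-cap volume
cap_vol <- function(r, h) pi * h^2 * (3 * r - h) / 3

# flat-substrate height map built directly from a matrix
make_height_map <- function(h, dx = 1, dy = 1) {
  structure(list(h = h, covered = h > 0, dx = dx, dy = dy),
            class = "height_map")
}
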