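# Shared fixtures: coordinate grids, analytic shapes, overlap metrics, and
# independent oracles used across the suite. Everything is generated in code.

coord_grids <- function(n, center = (n + 1) / 2) {
  d <- c(n, n, n)
  list(
    X = array(rep(seq_len(n), times = n * n), d),
    Y = array(rep(rep(seq_len(n), each = n), times = n), d),
    Z = array(rep(seq_len(n), each = n * n), d),
    center = rep_len(center, 3L), dim = d)
}

radius_field <- function(g, center = g$center) {
  sqrt((g$X - center[1])^2 + (g$Y - center[2])^2 + (g$Z - center[3])^2)
}

ball_volume <- function(n, radius, center = (n + 1) / 2) {
  g <- coord_grids(n, center)
  volume((radius_field(g) < radius) * 1, dtype_tag = "mask")
}

vol_like2 <- function(vol, data) {
  v <- vol
  v$data <- array(data, dim(vol$data))
  v$dtype_tag <- "float"
  v
}

dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

# a random star-shaped smooth blob whose curvature radius stays safely
# beyond the default 5-voxel narrow band (no medial sheet inside the band)
random_smooth_proba <- function(n = 48) {
  g <- coord_grids(n)
  ax <- runif(3, 0.95, 1.1)
  A <- runif(1, 0.3, 0.5)
  R <- runif(1, 11, 13)
  xr <- (g$X - g$center[1]) / ax[1]
  yr <- (g$Y - g$center[2]) / ax[2]
  zr <- (g$Z - g$center[3]) / ax[3]
  r <- sqrt(xr^2 + yr^2 + zr^2)
  r0 <- pmax(r, 1e-9)
  Rv <- R + A * sin(pi * xr / r0) * sin(pi * yr / r0) +
    0.8 * A * sin(pi * zr / r0)
  volume(1 / (1 + exp((r - Rv) * 1.5)))
}

# central-difference Eikonal residual of a level set within its band
eikonal_residual <- function(ls, band = 5) {
  phi <- ls$phi$data
  h <- ls$phi$voxel_size
  g <- cortexr:::central_gradients(phi, h)
  gn <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  abs(gn - 1)[abs(phi) <= band * mean(h)]
}

# solid torus mask: ring of radius ring_r around the z-axis, tube tube_r
torus_mask <- function(n = 41, ring_r = 10, tube_r = 4) {
  g <- coord_grids(n)
  rho <- sqrt((sqrt((g$X - g$center[1])^2 + (g$Y - g$center[2])^2) - ring_r)^2 +
                (g$Z - g$center[3])^2)
  rho < tube_r
}

# --- independent digital-topology oracles -------------------------------

# Euler characteristic by explicit cell enumeration of the cubical complex
# (unique vertices / edges / faces keyed by their lexicographic corner).
# Only intended for small grids.
euler_oracle <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  corners <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  vkeys <- character(0)
  for (r in seq_len(nrow(corners)))
    vkeys <- c(vkeys, paste(idx[, 1] + corners$dx[r], idx[, 2] + corners$dy[r],
                            idx[, 3] + corners$dz[r]))
  V <- length(unique(vkeys))
  ekeys <- character(0)
  for (axis in 1:3) {
    oth <- setdiff(1:3, axis)
    off <- expand.grid(a = 0:1, b = 0:1)
    for (r in seq_len(nrow(off))) {
      c1 <- idx
      c1[, oth[1]] <- c1[, oth[1]] + off$a[r]
      c1[, oth[2]] <- c1[, oth[2]] + off$b[r]
      ekeys <- c(ekeys, paste(axis, c1[, 1], c1[, 2], c1[, 3]))
    }
  }
  E <- length(unique(ekeys))
  fkeys <- character(0)
  for (axis in 1:3) {
    for (o in 0:1) {
      c1 <- idx
      c1[, axis] <- c1[, axis] + o
      fkeys <- c(fkeys, paste(axis, c1[, 1], c1[, 2], c1[, 3]))
    }
  }
  F <- length(unique(fkeys))
  as.integer(V - E + F - nrow(idx))
}

# Simple-point oracle: topological numbers by vectorized component labeling
# over a batch of 3x3x3 neighborhoods (n x 27 matrix, center column 14
# ignored). Label propagation over precomputed adjacency, independent of
# the package's C++ implementation.
topo_adjacency <- function(conn) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  city0 <- rowSums(abs(off))
  domain <- if (conn == 6) city0 <= 2 & city0 > 0 else city0 > 0
  cadj <- switch(as.character(conn),
                 "6" = city0 == 1,
                 "18" = city0 > 0 & city0 <= 2 & apply(abs(off), 1, max) == 1,
                 "26" = city0 > 0)
  adj <- matrix(FALSE, 27, 27)
  for (p in 1:27) for (q in 1:27) {
    if (p == q || p == 14 || q == 14) next
    dd <- abs(off[p, ] - off[q, ])
    a <- switch(as.character(conn),
                "6" = sum(dd) == 1,
                "18" = max(dd) == 1 && sum(dd) <= 2,
                "26" = max(dd) == 1)
    adj[p, q] <- a
  }
  list(domain = domain, cadj = cadj, adj = adj)
}

topo_number_batch <- function(occ, conn) {
  tt <- topo_adjacency(conn)
  n <- nrow(occ)
  occ <- occ & matrix(tt$domain, n, 27, byrow = TRUE)
  lab <- matrix(rep(1:27, each = n), n, 27)
  lab[!occ] <- Inf
  pairs <- which(tt$adj, arr.ind = TRUE)
  repeat {
    old <- lab
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, 1]; q <- pairs[r, 2]
      ok <- occ[, p] & occ[, q]
      if (any(ok)) lab[ok, p] <- pmin(lab[ok, p], lab[ok, q])
    }
    if (identical(old, lab)) break
  }
  sub <- lab[, tt$cadj, drop = FALSE]
  apply(sub, 1L, function(l) length(unique(l[is.finite(l)])))
}

oracle_simple_point <- function(occ, pair = c(6, 26)) {
  occ <- matrix(occ != 0, ncol = 27)
  topo_number_batch(occ, pair[1]) == 1L &
    topo_number_batch(!occ, pair[2]) == 1L
}
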