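# Independent brute-force oracles used to check the optimized implementations.
# All of these are written as plain scalar loops over definitions, not as
# calls into the package's own code paths.

# per-pixel rotation + max MIP: for every output pixel, rotate its center
# back into the source frame, sample the z-column (bilinear, or nearest at
# multiples of 90 degrees), and reduce by max along the rotated y axis
oracle_mip <- function(vol, angle) {
  v <- vol$values
  d <- dim(v); nx <- d[1]; ny <- d[2]; nz <- d[3]
  P <- as.integer(ceiling(sqrt(nx^2 + ny^2)))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cp <- (P + 1) / 2
  th <- angle * pi / 180
  nearest <- isTRUE(all.equal(angle %% 90, 0)) || isTRUE(all.equal(angle %% 90, 90))
  out <- matrix(0, nz, P)
  for (xp in 1:P) for (yp in 1:P) {
    xs <- cx + (xp - cp) * cos(th) + (yp - cp) * sin(th)
    ys <- cy - (xp - cp) * sin(th) + (yp - cp) * cos(th)
    if (nearest) {
      ix <- floor(xs + 0.5); iy <- floor(ys + 0.5)
      col <- if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny) v[ix, iy, ] else rep(0, nz)
    } else {
      x0 <- floor(xs); y0 <- floor(ys); fx <- xs - x0; fy <- ys - y0
      gv <- function(ix, iy)
        if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny) v[ix, iy, ] else rep(0, nz)
      col <- (1 - fx) * (1 - fy) * gv(x0, y0) + fx * (1 - fy) * gv(x0 + 1, y0) +
             (1 - fx) * fy * gv(x0, y0 + 1) + fx * fy * gv(x0 + 1, y0 + 1)
    }
    out[, xp] <- pmax(out[, xp], col)
  }
  out
}

# flood-fill count of 27-connected components (stack-based BFS)
oracle_component_count <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, dim = d)
  n <- 0L
  for (start in which(mask > 0)) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        x <- co[1] + dx; y <- co[2] + dy; z <- co[3] + dz
        if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3]) next
        if (mask[x, y, z] > 0 && !seen[x, y, z]) {
          seen[x, y, z] <- TRUE
          queue <- c(queue, (z - 1L) * d[1] * d[2] + (y - 1L) * d[1] + x)
        }
      }
    }
  }
  n
}

# O(n^2) surface-distance oracle: surfaces by explicit 6-neighbor scan,
# distances by looping over all voxel pairs
oracle_surface_points <- function(mask, spacing) {
  d <- dim(mask)
  pts <- NULL
  for (ix in which(mask > 0)) {
    co <- arrayInd(ix, d)
    on_surface <- FALSE
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      x <- co[1] + o[1]; y <- co[2] + o[2]; z <- co[3] + o[3]
      if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3] ||
          mask[x, y, z] == 0) { on_surface <- TRUE; break }
    }
    if (on_surface) pts <- rbind(pts, co * spacing)
  }
  pts
}

oracle_distance_sets <- function(a, b, spacing) {
  pa <- oracle_surface_points(a, spacing)
  pb <- oracle_surface_points(b, spacing)
  if (is.null(pa) || is.null(pb)) return(NULL)
  d_ab <- apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))
  d_ba <- apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  list(a2b = d_ab, b2a = d_ba)
}

# random binary blob mask: union of a few balls, guaranteed non-empty
random_blob_mask <- function(d, n_blobs = 2, r_range = c(1.5, 3.5)) {
  m <- array(0, dim = d)
  for (b in seq_len(n_blobs)) {
    cen <- sapply(d, function(n) runif(1, 1.5, n - 0.5))
    r <- runif(1, r_range[1], r_range[2])
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3])
      if (sum(((c(x, y, z) - cen))^2) <= r^2) m[x, y, z] <- 1
  }
  if (sum(m) == 0) m[ceiling(d[1]/2), ceiling(d[2]/2), ceiling(d[3]/2)] <- 1
  m
}

# small smooth random volume (sum of gaussian bumps) for interpolation tests
smooth_random_volume <- function(d, n_bumps = 4) {
  v <- array(0, dim = d)
  grid <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  for (b in seq_len(n_bumps)) {
    cen <- sapply(d, function(n) runif(1, 2, n - 1))
    amp <- runif(1, 0.5, 2)
    sig <- runif(1, 1.5, 3)
    v <- v + amp * array(exp(-((grid$x - cen[1])^2 + (grid$y - cen[2])^2 +
                               (grid$z - cen[3])^2) / (2 * sig^2)), dim = d)
  }
  v
}
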