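# Independent oracles and shared fixtures for the test suite.

# Plain-R flood-fill labelling oracle (frontier BFS over voxel
# coordinates), independent of the compiled labeller. Seeds are taken in
# linear-index order, so labels are first-encounter canonical and can be
# compared to the implementation's output directly.
flood_fill_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   `6` = 1, `18` = 2, `26` = 3), ,
               drop = FALSE]
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    frontier <- arrayInd(seed, d)
    lab[seed] <- nxt
    while (nrow(frontier) > 0L) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                       drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1) * d[1] +
                      (cand[, 3] - 1) * d[1] * d[2])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nxt
      frontier <- arrayInd(lin, d)
    }
  }
  lab
}

# scipy.spatial.ConvexHull volume of a 3D point cloud (python oracle)
scipy_hull_volume <- function(pts) {
  f_in <- tempfile(fileext = ".csv")
  utils::write.table(pts, f_in, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from scipy.spatial import ConvexHull; ",
    "print(repr(ConvexHull(np.loadtxt('", f_in, "', delimiter=',')).volume))"
  ))), stdout = TRUE)
  unlink(f_in)
  as.numeric(out[length(out)])
}

# Monte-Carlo slab-intersection oracle for the orientation correction:
# drop uniformly oriented segments of length L with centres uniform over
# a slab much thicker than the section and count those intersecting a
# section of thickness T. Returns the estimated O_c and its standard
# error.
mc_orientation_oracle <- function(L, T, n = 2e5, seed = 42) {
  withr::with_seed(seed, {
    M <- L  # margin beyond the section on both sides
    z <- runif(n, -M, T + M)
    u <- abs(runif(n, -1, 1))         # |cos(theta)|, uniform orientations
    hit <- (z + L / 2 * u > 0) & (z - L / 2 * u < T)
    p <- mean(hit)
    scale <- (T + 2 * M) / T
    list(oc = p * scale, se = sqrt(p * (1 - p) / n) * scale)
  })
}

# small fibre-only phantom used by several detection tests
mini_phantom <- function(n_fibres = 10, extents = c(96, 96, 96), seed = 7,
                         ...) {
  spec <- phantom_spec(extents = extents, n_fibres = n_fibres, seed = seed,
                       ...)
  records <- sample_fibre_population(spec)
  vol <- render_phantom(records, spec)
  list(spec = spec, records = records, vol = vol,
       truth = vol$meta$ground_truth)
}

# digitized ball voxel set, radius in voxels
ball_voxels <- function(r, n = 2 * r + 7) {
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  c0 <- (n + 1) / 2
  g[rowSums((g - c0)^2) <= r^2, , drop = FALSE]
}
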