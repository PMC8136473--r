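# Synthetic AB-laden lung phantoms with exact per-fibre ground truth.

# run expr with a temporary RNG seed, restoring caller state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic lung-tissue phantom
#'
#' Describes the content of a synthetic micro-CT volume: coated-fibre
#' (asbestos body) count and morphometry distributions, air voids
#' (alveoli/bronchioles), particulate distractors, grey-level model and
#' additive noise. Defaults emulate the morphometry reported for real
#' tissue: log-normal lengths with population mean near 21 um in a narrow
#' range, transversal widths near 3.3-3.6 um, beaded coatings, and AB as
#' the brightest phase. Grey levels live on a nominal `[0, 1]` scale; the AB
#' grey must exceed the tissue mean by at least 5 noise standard
#' deviations so that segmentation of the phantom is well posed.
#'
#' @param extents voxel counts per axis (length 3 or scalar).
#' @param voxel_size isotropic voxel size in micrometres.
#' @param n_fibres number of asbestos bodies to place.
#' @param length_meanlog,length_sdlog log-normal parameters of fibre
#'   length in micrometres.
#' @param width_mean,width_sd normal parameters of fibre width
#'   (micrometres), truncated to positive values below the fibre length.
#' @param beading_amplitude relative sinusoidal radius modulation in
#'   `[0, 1)` mimicking beaded/segmented coatings; beads dip inward from
#'   the width envelope so that the ground-truth width is the true outer
#'   width of the rendered body.
#' @param beading_period_um beading period along the fibre axis.
#' @param grey_tissue,grey_void,grey_ab,grey_distractor grey levels of the
#'   four phases; AB must be the brightest together with distractors.
#' @param noise_sd standard deviation of additive Gaussian grey noise.
#' @param n_voids number of dark spherical voids.
#' @param void_radius_um radius range (min, max) of voids, micrometres.
#' @param n_small_distractors number of near-spherical bright blobs below
#'   the AB size range (particulate matter).
#' @param small_distractor_radius_um radius range of small distractors.
#' @param n_large_distractors number of large bright spherical regions
#'   outside the AB shape range (e.g. pleural-thickening-like structures).
#' @param large_distractor_radius_um radius range of large distractors.
#' @param placement `"uniform"` or `"clustered"` fibre centroids;
#'   clustered placement gathers fibres around a few foci the way AB
#'   accumulate on alveolar walls.
#' @param seed integer RNG seed; identical spec and seed give bit-identical
#'   phantoms.
#' @return An object of class `ab_phantom_spec`.
#' @export
phantom_spec <- function(extents = c(256L, 256L, 256L),
                         voxel_size = 0.332,
                         n_fibres = 120L,
                         length_meanlog = log(20),
                         length_sdlog = 0.3,
                         width_mean = 3.1,
                         width_sd = 0.25,
                         beading_amplitude = 0.25,
                         beading_period_um = 3,
                         grey_tissue = 0.30,
                         grey_void = 0.05,
                         grey_ab = 0.90,
                         grey_distractor = 0.90,
                         noise_sd = 0.05,
                         n_voids = 3L,
                         void_radius_um = c(10, 25),
                         n_small_distractors = 20L,
                         small_distractor_radius_um = c(0.5, 1.0),
                         n_large_distractors = 2L,
                         large_distractor_radius_um = c(6, 10),
                         placement = c("uniform", "clustered"),
                         seed = 1L) {
  if (length(extents) == 1L) extents <- rep(extents, 3L)
  stopifnot(length(extents) == 3L, all(extents >= 1))
  if (voxel_size <= 0 || !is.finite(voxel_size))
    stop("voxel_size must be positive and finite")
  counts <- c(n_fibres, n_voids, n_small_distractors, n_large_distractors)
  if (any(counts < 0)) stop("all object counts must be >= 0")
  if (length_sdlog < 0) stop("length_sdlog must be >= 0")
  if (width_mean <= 0 || width_sd < 0)
    stop("width distribution must have positive mean and sd >= 0")
  if (beading_amplitude < 0 || beading_amplitude >= 1)
    stop("beading_amplitude must lie in [0, 1)")
  if (beading_period_um <= 0) stop("beading_period_um must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (grey_ab <= grey_tissue + 5 * noise_sd)
    stop("detectability contract violated: grey_ab must exceed ",
         "grey_tissue + 5 * noise_sd")
  stopifnot(length(void_radius_um) == 2L, all(void_radius_um > 0),
            length(small_distractor_radius_um) == 2L,
            length(large_distractor_radius_um) == 2L)
  placement <- match.arg(placement)
  structure(
    list(extents = as.integer(extents), voxel_size = voxel_size,
         n_fibres = as.integer(n_fibres),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         width_mean = width_mean, width_sd = width_sd,
         beading_amplitude = beading_amplitude,
         beading_period_um = beading_period_um,
         grey_tissue = grey_tissue, grey_void = grey_void,
         grey_ab = grey_ab, grey_distractor = grey_distractor,
         noise_sd = noise_sd,
         n_voids = as.integer(n_voids), void_radius_um = void_radius_um,
         n_small_distractors = as.integer(n_small_distractors),
         small_distractor_radius_um = small_distractor_radius_um,
         n_large_distractors = as.integer(n_large_distractors),
         large_distractor_radius_um = large_distractor_radius_um,
         placement = placement, seed = as.integer(seed)),
    class = "ab_phantom_spec"
  )
}

# shortest distance between segments c1 +/- h1*u1 and c2 +/- h2*u2
.segment_distance <- function(c1, u1, h1, c2, u2, h2) {
  a0 <- c1 - h1 * u1; d1 <- 2 * h1 * u1
  b0 <- c2 - h2 * u2; d2 <- 2 * h2 * u2
  r <- a0 - b0
  a <- sum(d1 * d1); e <- sum(d2 * d2)
  f <- sum(d2 * r); cc <- sum(d1 * r); b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-12) min(max((b * f - cc * e) / denom, 0), 1) else 0
  t <- if (e > 1e-12) (b * s + f) / e else 0
  if (t < 0) { t <- 0; s <- if (a > 1e-12) min(max(-cc / a, 0), 1) else 0 }
  if (t > 1) { t <- 1; s <- if (a > 1e-12) min(max((b - cc) / a, 0), 1) else 0 }
  sqrt(sum((a0 + s * d1 - (b0 + t * d2))^2))
}

# analytic capsule volume: cylinder of length L - 2r plus two hemispheres
.capsule_volume <- function(length_um, width_um) {
  r <- width_um / 2
  h <- max(length_um - 2 * r, 0)
  pi * r^2 * h + 4 / 3 * pi * r^3
}

#' Sample a ground-truth fibre population
#'
#' Draws fibre lengths (log-normal), widths (truncated normal) and
#' orientations (uniform on the sphere), and places centroids by rejection
#' sampling so that every fibre capsule fits entirely inside the volume
#' and clears every other fibre by at least 2 voxels. The clearance
#' guarantees that each rendered fibre forms exactly one 26-connected
#' component, so ground-truth count equals component count.
#'
#' @param spec an [phantom_spec()] object.
#' @return A data.frame of ground-truth records with columns `id`,
#'   `cx_um`, `cy_um`, `cz_um` (centroid in volume coordinates), `ox`,
#'   `oy`, `oz` (unit orientation), `length_um`, `width_um`, and
#'   `volume_um3` (analytic capsule volume until rendered).
#' @export
sample_fibre_population <- function(spec) {
  stopifnot(inherits(spec, "ab_phantom_spec"))
  n <- spec$n_fibres
  empty <- data.frame(id = integer(0), cx_um = numeric(0),
                      cy_um = numeric(0), cz_um = numeric(0),
                      ox = numeric(0), oy = numeric(0), oz = numeric(0),
                      length_um = numeric(0), width_um = numeric(0),
                      volume_um3 = numeric(0))
  if (n == 0L) return(empty)
  size_um <- spec$extents * spec$voxel_size
  vs <- spec$voxel_size
  .with_seed(spec$seed, {
    cluster_centres <- NULL
    if (spec$placement == "clustered") {
      k <- max(1L, min(3L, n))
      cluster_centres <- cbind(runif(k, 0.25, 0.75) * size_um[1],
                               runif(k, 0.25, 0.75) * size_um[2],
                               runif(k, 0.25, 0.75) * size_um[3])
    }
    recs <- vector("list", n)
    p_ctr <- matrix(0, n, 3)      # placed-fibre geometry, rows 1..(i-1)
    p_u <- matrix(0, n, 3)
    p_h <- numeric(n)
    p_r <- numeric(n)
    attempts <- 0L
    max_attempts <- 2000L * n
    i <- 1L
    while (i <= n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n, " fibres in a ",
             paste(spec$extents, collapse = "x"),
             "-voxel volume after ", max_attempts, " attempts; ",
             "volume too small or too crowded")
      L <- rlnorm(1, spec$length_meanlog, spec$length_sdlog)
      W <- rnorm(1, spec$width_mean, spec$width_sd)
      if (W <= 0 || W >= L) next
      z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
      u <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      r_eff <- W / 2
      h <- max(L / 2 - W / 2, 0)
      ext <- h * abs(u) + r_eff + vs  # capsule half-extent + 1 voxel margin
      if (any(2 * ext >= size_um)) next
      ctr <- if (spec$placement == "clustered") {
        cc <- cluster_centres[sample.int(nrow(cluster_centres), 1L), ]
        cand <- cc + rnorm(3, 0, 15)
        if (any(cand < ext) || any(cand > size_um - ext)) next
        cand
      } else {
        runif(3, ext, size_um - ext)
      }
      clear <- TRUE
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        dc <- sqrt((p_ctr[prev, 1] - ctr[1])^2 +
                     (p_ctr[prev, 2] - ctr[2])^2 +
                     (p_ctr[prev, 3] - ctr[3])^2)
        # segment distance >= centroid distance - h_i - h_j: only pairs
        # failing that bound need the exact segment-segment distance
        need <- prev[dc - h - p_h[prev] < r_eff + p_r[prev] + 2 * vs]
        for (p in need) {
          dmin <- .segment_distance(ctr, u, h, p_ctr[p, ], p_u[p, ],
                                    p_h[p])
          if (dmin < r_eff + p_r[p] + 2 * vs) { clear <- FALSE; break }
        }
      }
      if (!clear) next
      p_ctr[i, ] <- ctr; p_u[i, ] <- u; p_h[i] <- h; p_r[i] <- r_eff
      recs[[i]] <- data.frame(
        id = i, cx_um = ctr[1], cy_um = ctr[2], cz_um = ctr[3],
        ox = u[1], oy = u[2], oz = u[3],
        length_um = L, width_um = W,
        volume_um3 = .capsule_volume(L, W)
      )
      i <- i + 1L
    }
    do.call(rbind, recs)
  })
}

# paint a solid ball into arr; returns the modified array
.paint_ball <- function(arr, centre_um, radius_um, vs, value) {
  d <- dim(arr)
  lo <- pmax(1L, ceiling(centre_um / vs + 0.5 - radius_um / vs))
  hi <- pmin(d, floor(centre_um / vs + 0.5 + radius_um / vs))
  if (any(lo > hi)) return(arr)
  dx2 <- (((lo[1]:hi[1]) - 0.5) * vs - centre_um[1])^2
  dy2 <- (((lo[2]:hi[2]) - 0.5) * vs - centre_um[2])^2
  dz2 <- (((lo[3]:hi[3]) - 0.5) * vs - centre_um[3])^2
  mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_um^2
  blk <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  blk[mask] <- value
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
  arr
}

# paint one capsule fibre; returns list(arr, n_voxels)
.paint_capsule <- function(arr, rec, spec) {
  vs <- spec$voxel_size
  d <- dim(arr)
  ctr <- c(rec$cx_um, rec$cy_um, rec$cz_um)
  u <- c(rec$ox, rec$oy, rec$oz)
  r <- rec$width_um / 2
  h <- max(rec$length_um / 2 - r, 0)
  ext <- h * abs(u) + r + vs
  lo <- pmax(1L, ceiling((ctr - ext) / vs + 0.5))
  hi <- pmin(d, floor((ctr + ext) / vs + 0.5))
  if (any(lo > hi)) return(list(arr = arr, n_voxels = 0L))
  x <- ((lo[1]:hi[1]) - 0.5) * vs - ctr[1]
  y <- ((lo[2]:hi[2]) - 0.5) * vs - ctr[2]
  z <- ((lo[3]:hi[3]) - 0.5) * vs - ctr[3]
  tax <- outer(outer(x * u[1], y * u[2], "+"), z * u[3], "+")
  p2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  tc <- pmin(pmax(tax, -h), h)
  d2 <- p2 - 2 * tc * tax + tc^2
  # beads dip inward from the width envelope, so the recorded width is the
  # true outer width of the rendered body
  rt <- r * (1 - spec$beading_amplitude *
               (1 + sin(2 * pi * tc / spec$beading_period_um)) / 2)
  mask <- d2 <= rt^2
  blk <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  blk[mask] <- spec$grey_ab
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
  list(arr = arr, n_voxels = sum(mask))
}

#' Render a phantom volume from ground-truth records
#'
#' Paints, onto a uniform tissue background: dark spherical voids
#' (alveoli/bronchioles), bright near-spherical distractors (small
#' particulate and large diffuse structures), and finally each fibre as a
#' capsule (cylinder with hemispherical caps) along its orientation with
#' optional sinusoidal radius modulation (beading). Gaussian grey noise is
#' added last. Deterministic for a fixed spec seed.
#'
#' @param records ground-truth data.frame from [sample_fibre_population()].
#' @param spec the [phantom_spec()] the records were drawn from.
#' @return An [volume()] object; `meta$ground_truth` holds the records
#'   with `volume_um3` replaced by the rendered voxel volume of each
#'   fibre.
#' @export
render_phantom <- function(records, spec) {
  stopifnot(inherits(spec, "ab_phantom_spec"))
  d <- spec$extents
  vs <- spec$voxel_size
  size_um <- d * vs
  arr <- array(spec$grey_tissue, dim = d)
  # fibre capsules, for distractor clearance (a bright distractor fused to
  # a fibre would corrupt both the count and the morphometry)
  fib <- if (nrow(records) > 0) lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    list(ctr = c(r$cx_um, r$cy_um, r$cz_um), u = c(r$ox, r$oy, r$oz),
         h = max(r$length_um / 2 - r$width_um / 2, 0),
         r_eff = r$width_um / 2)
  }) else list()
  clear_of_fibres <- function(ctr, rad) {
    for (f in fib) {
      if (.segment_distance(ctr, c(1, 0, 0), 0, f$ctr, f$u, f$h) <
          rad + f$r_eff + 2 * vs) return(FALSE)
    }
    TRUE
  }
  draw_ball <- function(r_lo, r_hi, need_clearance) {
    for (att in 1:100) {
      ctr <- runif(3) * size_um
      rad <- runif(1, r_lo, r_hi)
      if (!need_clearance || clear_of_fibres(ctr, rad))
        return(list(ctr = ctr, rad = rad))
    }
    NULL
  }
  .with_seed(spec$seed + 1000003L, {
    for (k in seq_len(spec$n_voids)) {
      b <- draw_ball(spec$void_radius_um[1], spec$void_radius_um[2], FALSE)
      arr <- .paint_ball(arr, b$ctr, b$rad, vs, spec$grey_void)
    }
    for (k in seq_len(spec$n_small_distractors)) {
      b <- draw_ball(spec$small_distractor_radius_um[1],
                     spec$small_distractor_radius_um[2], TRUE)
      if (!is.null(b))
        arr <- .paint_ball(arr, b$ctr, b$rad, vs, spec$grey_distractor)
    }
    for (k in seq_len(spec$n_large_distractors)) {
      b <- draw_ball(spec$large_distractor_radius_um[1],
                     spec$large_distractor_radius_um[2], TRUE)
      if (!is.null(b))
        arr <- .paint_ball(arr, b$ctr, b$rad, vs, spec$grey_distractor)
    }
    if (nrow(records) > 0) {
      nvox <- integer(nrow(records))
      for (i in seq_len(nrow(records))) {
        res <- .paint_capsule(arr, records[i, ], spec)
        arr <- res$arr
        nvox[i] <- res$n_voxels
      }
      records$volume_um3 <- nvox * vs^3
    }
    if (spec$noise_sd > 0)
      arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), dim = d)
  })
  volume(arr, vs, meta = list(phantom = TRUE, seed = spec$seed,
                              ground_truth = records))
}

#' True fibre number density of a phantom
#'
#' Ground-truth count divided by the physical volume, in counts per cm^3.
#'
#' @param records ground-truth data.frame.
#' @param volume the rendered [volume()].
#' @return Number density in cm^-3.
#' @export
true_density <- function(records, volume) {
  vc <- physical_volume_cm3(volume)
  if (vc <= 0) stop("volume has zero physical size")
  nrow(records) / vc
}

#' Write or read a ground-truth table as CSV
#'
#' @param records ground-truth data.frame.
#' @param path CSV path.
#' @return `path` (write) or the records data.frame (read).
#' @export
write_ground_truth <- function(records, path) {
  cols <- c("id", "cx_um", "cy_um", "cz_um", "ox", "oy", "oz",
            "length_um", "width_um", "volume_um3")
  write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read.csv(path)
}
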