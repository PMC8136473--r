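# Volume container, TIFF stack round trips, chunking and projections.

test_that("volume constructor enforces its invariants", {
  a <- array(0.5, c(4, 4, 4))
  expect_s3_class(volume(a, 0.332), "ab_volume")
  expect_error(volume(matrix(1, 3, 3), 0.332), "3D")
  expect_error(volume(a, 0), "voxel_size")
  expect_error(volume(a, -1), "voxel_size")
  expect_error(volume(a, Inf), "voxel_size")
  b <- a; b[1] <- NA
  expect_error(volume(b, 0.332), "finite")
  expect_gt(physical_volume_cm3(volume(a, 0.332)), 0)
  # V_c formula: n_voxels * voxel^3 * 1e-12
  expect_equal(physical_volume_cm3(volume(a, 10)), 64 * 1000 * 1e-12)
})

test_that("acquisition geometry arithmetic matches the instrument setup", {
  expect_identical(effective_voxel_size(6.5, 20), 0.325)
  ext <- physical_extents_um(c(2560, 2560, 2160), 0.325)
  expect_equal(ext, c(832, 832, 702))
})

test_that("write/read round-trips are exact for float and integer grids", {
  dir <- withr::local_tempdir()
  # 32-bit float, values outside [0,1] preserved exactly
  v <- volume(array(3.5, c(8, 8, 8)), 0.332)
  p <- file.path(dir, "v.tif")
  write_volume(v, p)
  expect_identical(read_volume(p, 0.332)$data, v$data)
  # float32 storage of arbitrary reals (float precision)
  a <- array(runif(6 * 5 * 4) * 7 - 2, c(6, 5, 4))
  write_volume(volume(a, 1), p)
  expect_equal(read_volume(p, 1)$data, a, tolerance = 1e-6)
  # integer formats are bit-exact
  a8 <- array(sample(0:255, 60, TRUE), c(5, 4, 3))
  write_volume(volume(a8, 1), p, bits = 8)
  expect_identical(read_volume(p, 1)$data, a8 + 0)
  a16 <- array(sample(0:65535, 60, TRUE), c(5, 4, 3))
  write_volume(volume(a16, 1), p, bits = 16)
  expect_identical(read_volume(p, 1)$data, a16 + 0)
  # degenerate 1x1x1 volume is a valid single-page stack
  v1 <- volume(array(2.25, c(1, 1, 1)), 0.5)
  write_volume(v1, p)
  expect_identical(read_volume(p, 0.5)$data, v1$data)
})

test_that("read/write errors are distinct and informative", {
  dir <- withr::local_tempdir()
  expect_error(read_volume(file.path(dir, "absent.tif"), 1), "exist")
  p <- file.path(dir, "v.tif")
  write_volume(volume(array(1, c(2, 2, 2)), 1), p)
  expect_error(read_volume(p, 0), "voxel_size")
  expect_error(read_volume(p, -2), "voxel_size")
  expect_error(write_volume(volume(array(1, c(2, 2, 2)), 1),
                            file.path(dir, "nodir", "v.tif")),
               "directory")
  expect_error(write_volume(volume(array(0.5, c(2, 2, 2)), 1), p,
                            bits = 8), "integer")
  expect_error(write_volume(volume(array(1, c(2, 2, 2)), 1), p,
                            bits = 12), "bits")
  # not a TIFF at all
  bad <- file.path(dir, "bad.tif")
  writeLines("not a tiff", bad)
  expect_error(read_volume(bad, 1), "TIFF")
})

test_that("codec interoperates with an independent TIFF implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  dir <- withr::local_tempdir()
  tif <- file.path(dir, "py.tif"); csv <- file.path(dir, "py.csv")
  # python/tifffile writes a float32 stack with values outside [0,1]
  status <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np, tifffile\n",
    "rng = np.random.default_rng(3)\n",
    "a = (rng.random((4, 6, 5)) * 10 - 3).astype(np.float32)\n",
    "tifffile.imwrite('", tif, "', a, photometric='minisblack')\n",
    "np.savetxt('", csv, "', a.reshape(4, -1), delimiter=',')\n"
  ))))
  skip_if(status != 0, "python/tifffile unavailable")
  ref <- as.matrix(utils::read.csv(csv, header = FALSE))
  v <- read_volume(tif, 1)
  expect_equal(dim(v$data), c(6, 5, 4))
  for (p in 1:4) {
    page <- matrix(ref[p, ], nrow = 6, byrow = TRUE)
    expect_equal(v$data[, , p], page, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # and tifffile reads ours back with identical values
  ours <- file.path(dir, "ours.tif"); back <- file.path(dir, "back.csv")
  a <- array(seq(-1, 5, length.out = 24), c(2, 3, 4))
  write_volume(volume(a, 1), ours)
  status <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np, tifffile\n",
    "b = tifffile.imread('", ours, "')\n",
    "np.savetxt('", back, "', b.reshape(b.shape[0], -1), delimiter=',')\n"
  ))))
  skip_if(status != 0, "python/tifffile unavailable")
  got <- as.matrix(utils::read.csv(back, header = FALSE))
  for (p in 1:4)
    expect_equal(matrix(got[p, ], nrow = 2, byrow = TRUE), a[, , p],
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("split_volume covers the grid with the stated overlap", {
  v <- volume(array(seq_len(3 * 3 * 10), c(3, 3, 10)), 1)
  ch <- split_volume(v, c(3, 3, 4), overlap = 2)
  expect_length(ch, 4)
  expect_equal(vapply(ch, function(c) c$offset[3], integer(1)),
               c(0L, 2L, 4L, 6L))
  # union of chunk plane sets covers all 10 planes
  planes <- sort(unique(unlist(lapply(ch, function(c)
    c$offset[3] + seq_len(dim(c$data)[3])))))
  expect_identical(planes, 1:10)
  # chunk data equals the corresponding slab of the parent
  for (c in ch)
    expect_identical(c$data,
                     v$data[, , c$offset[3] + seq_len(4), drop = FALSE])
  # identity split
  one <- split_volume(v, dim(v$data), overlap = 0)
  expect_length(one, 1)
  expect_identical(one[[1]]$data, v$data)
  expect_error(split_volume(v, c(3, 3, 11), 0), "exceeds")
  expect_error(split_volume(v, c(3, 3, 4), -1), "overlap")
})

test_that("split coverage holds on randomized sizes; overlap 0 partitions", {
  withr::with_seed(5, {
    for (rep in 1:8) {
      d <- sample(4:12, 3, replace = TRUE)
      v <- volume(array(0, d), 1)
      ce <- pmin(d, sample(2:8, 3, replace = TRUE))
      ov <- sample(0:(min(ce) - 1), 1)
      ch <- split_volume(v, ce, overlap = ov)
      cover <- array(0L, d)
      for (c in ch) {
        i <- lapply(1:3, function(a) c$offset[a] + seq_len(dim(c$data)[a]))
        cover[i[[1]], i[[2]], i[[3]]] <- cover[i[[1]], i[[2]], i[[3]]] + 1L
      }
      expect_true(all(cover >= 1L))
      if (ov == 0 && all(d %% ce == 0)) expect_true(all(cover == 1L))
    }
  })
})

test_that("projections collapse slabs as stated", {
  a <- array(0.2, c(6, 7, 8))
  v <- volume(a, 0.332)
  for (m in c("max", "mean", "sum")) {
    p <- project_volume(v, 3, mode = m)
    expect_equal(dim(p), c(6, 7))
    expect_true(all(abs(p - if (m == "sum") 0.2 * 8 else 0.2) < 1e-12))
  }
  # single bright voxel appears at its in-plane position under max
  a[3, 5, 2] <- 9
  p <- project_volume(volume(a, 1), 3, mode = "max")
  expect_equal(p[3, 5], 9)
  expect_equal(sum(p > 0.2), 1)
  expect_error(project_volume(v, 4), "axis")
  expect_error(project_volume(v, 3, slab = integer(0)), "slab")
  expect_error(project_volume(v, 3, slab = 9), "bounds")
})

test_that("max projection of a union is the elementwise max of projections", {
  withr::with_seed(9, {
    a <- array(runif(5 * 5 * 5), c(5, 5, 5))
    b <- array(runif(5 * 5 * 5), c(5, 5, 5))
    pu <- project_volume(volume(pmax(a, b), 1), 2, mode = "max")
    pa <- project_volume(volume(a, 1), 2, mode = "max")
    pb <- project_volume(volume(b, 1), 2, mode = "max")
    expect_equal(pu, pmax(pa, pb))
  })
})

test_that("chunk manifests serialize to JSON", {
  v <- volume(array(0, c(4, 4, 8)), 1)
  ch <- split_volume(v, c(4, 4, 4), overlap = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_chunk_manifest(ch, p)
  m <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(m), length(ch))
  expect_equal(m$overlap[1], 1)
})
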