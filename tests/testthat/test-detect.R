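# Segmentation, labelling, morphometry and the filter cascade.

test_that("segmentation selects exactly the voxels in the grey band", {
  a <- array(0.2, c(10, 10, 10))
  v <- volume(a, 1)
  expect_equal(sum(segment(v, segmentation_params(0.5, 1))), 0)
  idx <- sample(length(a), 100)
  a[idx] <- 0.9
  v <- volume(a, 1)
  m <- segment(v, segmentation_params(0.5, 1))
  expect_equal(which(m), sort(idx))
  # elementwise oracle on a noisy phantom
  ph <- mini_phantom(n_fibres = 6, extents = c(64, 64, 64), seed = 4)
  m <- segment(ph$vol, segmentation_params(0.6, 2))
  expect_identical(m, ph$vol$data >= 0.6 & ph$vol$data <= 2)
  expect_error(segmentation_params(1, 0.5), "grey_lo")
})

test_that("connectivity semantics follow the 6/18/26 definitions", {
  m <- array(FALSE, c(5, 5, 5))
  # two 2x2x2 cubes with a 1-voxel gap -> always two components
  m[1:2, 1:2, 1:2] <- TRUE
  m[4:5, 4:5, 1:2] <- TRUE
  expect_equal(attr(label_components(m, 26), "n_components"), 2)
  # corner contact: one component at 26, two at 6 and 18
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(attr(label_components(m, 26), "n_components"), 1)
  expect_equal(attr(label_components(m, 18), "n_components"), 2)
  expect_equal(attr(label_components(m, 6), "n_components"), 2)
  # edge contact: joined at 18 and 26, split at 6
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  expect_equal(attr(label_components(m, 26), "n_components"), 1)
  expect_equal(attr(label_components(m, 18), "n_components"), 1)
  expect_equal(attr(label_components(m, 6), "n_components"), 2)
  expect_error(label_components(m, 4), "connectivity")
})

test_that("labelling equals the flood-fill oracle on random masks", {
  withr::with_seed(11, {
    for (conn in c(6L, 18L, 26L)) {
      d <- sample(8:20, 3, replace = TRUE)
      m <- array(runif(prod(d)) < 0.12, d)
      expect_identical(label_components(m, conn),
                       flood_fill_oracle(m, conn),
                       ignore_attr = TRUE)
    }
  })
})

test_that("box morphometry is exact under the extent convention", {
  b <- as.matrix(expand.grid(1:90, 1:9, 1:9))
  f <- measure_object(b, 0.332)
  expect_equal(f$length_um, 90 * 0.332)
  expect_equal(f$width_um, 9 * 0.332)
  expect_equal(f$aspect_ratio, 10)
  expect_equal(f$sphericity, 0.1)
  expect_equal(f$solidity, 1)
  expect_equal(f$volume_um3, 90 * 81 * 0.332^3)
  # orientation must not matter for an axis-permuted box
  f2 <- measure_object(b[, c(3, 1, 2)], 0.332)
  expect_equal(f2$length_um, f$length_um)
  expect_equal(f2$width_um, f$width_um)
})

test_that("a single voxel has one-voxel extents and solidity 1", {
  f <- measure_object(matrix(c(5, 7, 2), 1), 0.332)
  expect_equal(f$length_um, 0.332)
  expect_equal(f$width_um, 0.332)
  expect_equal(f$aspect_ratio, 1)
  expect_equal(f$solidity, 1)
  expect_error(measure_object(matrix(numeric(0), ncol = 3), 1),
               "non-empty")
})

test_that("a digitized ball is near-spherical with corner-hull solidity", {
  f <- measure_object(ball_voxels(12), 1)
  expect_gte(f$sphericity, 0.9)
  expect_lte(f$aspect_ratio, 1.15)
  # corner-convention hull circumscribes the ball by a surface term,
  # so solidity sits below 1 but well above the filter floor
  expect_gte(f$solidity, 0.85)
  expect_lte(f$solidity, 1)
})

test_that("hull volumes agree with an independent qhull implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  withr::with_seed(23, {
    # random point clouds
    for (rep in 1:3) {
      pts <- matrix(rnorm(60), ncol = 3)
      ours <- abct:::.hull_volume_cpp(pts)
      ref <- scipy_hull_volume(pts)
      skip_if(is.na(ref), "scipy unavailable")
      expect_equal(ours, ref, tolerance = 1e-9)
    }
    # reduced corner cloud of a digitized ball, exactly as solidity uses it
    corners <- abct:::.hull_corner_points(ball_voxels(9))
    expect_equal(abct:::.hull_volume_cpp(corners),
                 scipy_hull_volume(corners), tolerance = 1e-9)
  })
})

test_that("solidity never exceeds 1 on random digitized blobs", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      d <- c(14, 14, 14)
      m <- array(FALSE, d)
      # random walk blob
      p <- c(7, 7, 7)
      for (s in 1:120) {
        m[p[1], p[2], p[3]] <- TRUE
        p <- pmin(pmax(p + sample(c(-1, 0, 1), 3, TRUE), 1), d)
      }
      vox <- which(m, arr.ind = TRUE)
      f <- measure_object(vox, 0.5)
      expect_lte(f$solidity, 1)
      expect_gt(f$solidity, 0)
      expect_gte(f$aspect_ratio, 1)
      expect_true(f$sphericity > 0 && f$sphericity <= 1)
    }
  })
})

test_that("the filter cascade applies rules in a fixed order", {
  fp <- filter_params(min_size_vox = 20)
  fibre <- measure_object(as.matrix(expand.grid(1:60, 1:6, 1:6)), 0.332)
  expect_equal(classify_object(fibre, fp)$status, "accepted")
  ball <- measure_object(ball_voxels(8), 0.332)
  # with default shape thresholds a ball trips the sphericity rule first
  cl <- classify_object(ball, fp)
  expect_equal(cl$status, "rejected")
  expect_equal(cl$reason, "sphericity")
  # with permissive sphericity/solidity the aspect-ratio rule (> 3)
  # still rejects it
  cl2 <- classify_object(ball, filter_params(min_size_vox = 20,
                                             max_sphericity = 1,
                                             min_solidity = 0.01))
  expect_equal(cl2$reason, "aspect_ratio")
  # a 2-voxel speck fails the size rule
  speck <- measure_object(matrix(c(1, 1, 1, 2, 1, 1), 2, byrow = TRUE), 1)
  expect_equal(classify_object(speck, fp)$reason, "size")
  # border policy
  bf <- fibre; bf$touches_border <- TRUE
  expect_equal(classify_object(bf, fp)$status, "accepted")
  fpx <- filter_params(min_size_vox = 20, border_policy = "exclude")
  expect_equal(classify_object(bf, fpx)$reason, "border")
  expect_error(filter_params(min_size_vox = 0), "min_size")
  expect_error(filter_params(min_size_vox = 10, max_size_vox = 5),
               "exceed")
})

test_that("aspect-ratio acceptance is strict at the threshold", {
  f <- measure_object(as.matrix(expand.grid(1:9, 1:3, 1:3)), 1)
  # extents 9 and 3 -> aspect ratio exactly 3: not accepted under "> 3"
  expect_equal(f$aspect_ratio, 3)
  cl <- classify_object(f, filter_params(min_size_vox = 1,
                                         max_sphericity = 1,
                                         min_solidity = 0.01))
  expect_equal(cl$reason, "aspect_ratio")
})

test_that("detect_ab recovers a clean phantom exactly", {
  # 25 well-separated fibres, no noise, distractors below min size
  sp <- phantom_spec(extents = c(160, 160, 160), n_fibres = 25,
                     length_meanlog = log(22), length_sdlog = 0.12,
                     noise_sd = 0, n_voids = 2,
                     n_small_distractors = 10, n_large_distractors = 0,
                     seed = 31)
  rec <- sample_fibre_population(sp)
  vol <- render_phantom(rec, sp)
  tab <- detect_ab(vol, segmentation_params(0.6, 2), filter_params())
  expect_equal(nrow(tab$accepted), 25)
  expect_true(all(tab$objects$reason[tab$objects$status == "rejected"]
                  == "size"))
  m <- match_truth(tab, rec)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$fdr, 0)
  # accepted objects satisfy every threshold they were filtered on
  acc <- tab$accepted
  expect_true(all(acc$voxel_count >= 200 & acc$voxel_count <= 2e5))
  expect_true(all(acc$sphericity <= 0.5))
  expect_true(all(acc$solidity >= 0.5 & acc$solidity <= 1))
  expect_true(all(acc$aspect_ratio > 3))
})

test_that("an empty phantom yields an empty table", {
  sp <- phantom_spec(extents = c(48, 48, 48), n_fibres = 0,
                     n_small_distractors = 0, n_large_distractors = 0,
                     seed = 1)
  vol <- render_phantom(sample_fibre_population(sp), sp)
  tab <- detect_ab(vol, segmentation_params(0.6, 2), filter_params())
  expect_equal(nrow(tab$accepted), 0)
  expect_equal(nrow(tab$objects), 0)
  expect_gt(tab$V_c_cm3, 0)
})

test_that("widening the grey band never loses foreground", {
  ph <- mini_phantom(n_fibres = 5, extents = c(64, 64, 64), seed = 8)
  n1 <- sum(segment(ph$vol, segmentation_params(0.7, 1.0)))
  n2 <- sum(segment(ph$vol, segmentation_params(0.6, 1.5)))
  n3 <- sum(segment(ph$vol, segmentation_params(0.5, 2.0)))
  expect_true(n1 <= n2 && n2 <= n3)
})

test_that("raising the aspect-ratio floor never gains acceptances", {
  ph <- mini_phantom(n_fibres = 8, seed = 15)
  seg <- segmentation_params(0.6, 2)
  prev <- Inf
  for (ar in c(1, 2, 3, 5, 8)) {
    n <- nrow(detect_ab(ph$vol, seg,
                        filter_params(min_aspect_ratio = ar))$accepted)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("3D counting beats counting on a projection", {
  # a crowded phantom: the 2D max projection fuses overlapping bodies
  sp <- phantom_spec(extents = c(128, 128, 128), n_fibres = 30, seed = 19)
  rec <- sample_fibre_population(sp)
  vol <- render_phantom(rec, sp)
  tab <- detect_ab(vol, segmentation_params(0.6, 2), filter_params())
  proj <- project_volume(vol, 3, mode = "max")
  pm <- array(proj >= 0.6 & proj <= 2, dim = c(dim(proj), 1))
  n2d <- attr(label_components(pm, 26), "n_components")
  expect_lte(n2d, nrow(tab$accepted))
})

test_that("chunked and whole-volume detection agree exactly", {
  sp <- phantom_spec(extents = c(96, 96, 240), n_fibres = 25, seed = 23)
  rec <- sample_fibre_population(sp)
  vol <- render_phantom(rec, sp)
  seg <- segmentation_params(0.6, 2)
  whole <- detect_ab(vol, seg, filter_params())
  chunked <- detect_ab(vol, seg, filter_params(), n_chunks = 5)
  expect_equal(nrow(chunked$accepted), nrow(whole$accepted))
  ow <- whole$accepted[order(whole$accepted$cz_um, whole$accepted$cy_um), ]
  oc <- chunked$accepted[order(chunked$accepted$cz_um,
                               chunked$accepted$cy_um), ]
  for (col in c("voxel_count", "length_um", "width_um", "aspect_ratio",
                "sphericity", "solidity", "cx_um", "cy_um", "cz_um"))
    expect_equal(oc[[col]], ow[[col]], tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("morphometry CSV mirrors the object table", {
  ph <- mini_phantom(n_fibres = 6, seed = 27)
  tab <- detect_ab(ph$vol, segmentation_params(0.6, 2), filter_params())
  p <- withr::local_tempfile(fileext = ".csv")
  write_morphometry_csv(tab, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), nrow(tab$objects))
  acc <- back[back$status == "accepted", ]
  expect_equal(mean(acc$length_um),
               mean(tab$accepted$length_um))
})
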