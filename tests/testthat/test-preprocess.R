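# CT I/O and the preprocessing chain: HU clipping, lung masking, isotropic
# resampling, normalisation, world/voxel conversion, ROI cropping.

test_that("MetaImage volumes round-trip bit-exactly", {
  case <- tiny_phantom(seed = 1)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "case.mhd")
  write_mhd(case$volume, path)
  back <- load_volume(path)
  expect_identical(back$voxels, case$volume$voxels)
  expect_identical(back$spacing, case$volume$spacing)
  expect_identical(back$origin, case$volume$origin)
})

test_that("MetaImage header metadata is honoured", {
  dir <- withr::local_tempdir()
  vol <- ct_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                   spacing = c(2.5, 0.7, 0.7), origin = c(-1, 2, 3))
  path <- file.path(dir, "v.mhd")
  write_mhd(vol, path)
  back <- load_volume(path)
  expect_equal(back$spacing, c(2.5, 0.7, 0.7))
  expect_equal(back$origin, c(-1, 2, 3))
  # corrupt header: missing spacing
  hdr <- readLines(path)
  writeLines(hdr[!grepl("ElementSpacing", hdr)], path)
  expect_error(load_volume(path), "ElementSpacing")
  # 2D data refused
  writeLines(sub("NDims = 3", "NDims = 2", hdr), path)
  expect_error(load_volume(path), "3D|NDims")
})

test_that("annotations CSV parses, validates and round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "annotations.csv")
  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "s1,10.0,-20.0,30.0,6.0"), path)
  anns <- load_annotations(path)
  expect_length(anns, 1)
  expect_equal(anns[[1]]$series_id, "s1")
  expect_equal(anns[[1]]$center_world, c(10, -20, 30))
  expect_equal(anns[[1]]$diameter_mm, 6)
  # empty file with header
  writeLines("seriesuid,coordX,coordY,coordZ,diameter_mm", path)
  expect_length(load_annotations(path), 0)
  # missing column
  writeLines(c("seriesuid,coordX,coordY,diameter_mm", "s1,1,2,3"), path)
  expect_error(load_annotations(path), "coordZ")
  # non-positive diameter names the row
  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "s1,1,2,3,-1"), path)
  expect_error(load_annotations(path), "row 1")
  # write then read
  path2 <- file.path(dir, "ann2.csv")
  write_annotations(nodule_annotation("s2", c(1, 2, 3), 8), path2)
  expect_equal(load_annotations(path2)[[1]]$diameter_mm, 8)
})

test_that("HU clipping enforces the retained window", {
  vol <- ct_volume(array(c(-2000, -1000, 0, 600, 3000, 100), c(1, 2, 3)))
  out <- clip_hu(vol)
  expect_equal(sort(unique(as.vector(out$voxels))), c(-1000, 0, 100, 600))
  expect_equal(range(out$voxels), c(-1000, 600))
  # identity inside the window
  z <- ct_volume(array(0, c(2, 2, 2)))
  expect_identical(clip_hu(z)$voxels, z$voxels)
  expect_error(clip_hu(z, 0, 0), "lo < hi")
})

test_that("lung mask recovers the phantom lung fields", {
  case <- tiny_phantom(seed = 3)
  vol <- clip_hu(case$volume)
  mask <- extract_lung_mask(vol)
  lab <- case$lung_label
  expect_gte(dsc(mask * 1L, lab * 1L), 0.95)
  # morphological containment: eroded label within dilated extraction
  er <- nodseg:::binary_erode(lab, 1)
  di <- nodseg:::binary_dilate(mask, 2)
  expect_true(all(di[er]))
  # degenerate input fails open with a warning
  flat <- ct_volume(array(-1000, c(6, 6, 6)))
  expect_warning(m <- extract_lung_mask(flat), "all-true")
  expect_true(all(m))
})

test_that("isotropic resampling preserves geometry and constants", {
  vol <- ct_volume(array(rnorm(100 * 50 * 50), c(100, 50, 50)),
                   spacing = c(2, 0.5, 0.5))
  out <- resample_isotropic(vol)
  expect_equal(dim(out$voxels), c(200, 25, 25))
  expect_equal(out$spacing, c(1, 1, 1))
  # identity at unit spacing
  v1 <- ct_volume(array(rnorm(10 * 10 * 10), c(10, 10, 10)))
  expect_equal(resample_isotropic(v1)$voxels, v1$voxels, tolerance = 1e-6)
  # constants stay constant
  vc <- ct_volume(array(7, c(9, 11, 13)), spacing = c(1.7, 0.8, 0.6))
  expect_equal(range(resample_isotropic(vc)$voxels), c(7, 7))
  expect_error(resample_isotropic(v1, 0), "target_spacing")
})

test_that("normalisation maps the window to [0,1] and de-averages", {
  two <- ct_volume(array(c(-1000, 600), c(1, 1, 2)))
  expect_equal(as.vector(normalize_volume(two)$voxels), c(-0.5, 0.5))
  flat <- normalize_volume(ct_volume(array(-1000, c(3, 3, 3))))
  expect_equal(max(abs(flat$voxels)), 0)
  set.seed(5)
  v <- normalize_volume(clip_hu(ct_volume(array(rnorm(1000, 0, 800), c(10, 10, 10)))))
  expect_lt(abs(mean(v$voxels)), 1e-6)
  expect_true(all(v$voxels >= -1 & v$voxels <= 1))
  expect_equal(v$intensity_domain, "normalized")
  expect_error(normalize_volume(v), "already normalized")
})

test_that("world/voxel conversion reorders axes and bounds-checks", {
  vol <- ct_volume(array(0, c(40, 40, 40)))
  ann <- nodule_annotation("s", c(10, 20, 30), 5)
  expect_equal(world_to_voxel(ann, vol), c(30, 20, 10))
  vol2 <- ct_volume(array(0, c(10, 10, 10)), origin = c(-5, -5, -5))
  expect_equal(world_to_voxel(nodule_annotation("s", c(0, 0, 0), 5), vol2),
               c(5, 5, 5))
  expect_error(world_to_voxel(nodule_annotation("far", c(500, 0, 0), 5), vol),
               "outside")
})

test_that("ROI cropping centres, pads and preserves shape", {
  set.seed(6)
  v <- array(rnorm(64 * 128 * 128), c(64, 128, 128))
  vol <- ct_volume(v, intensity_domain = "HU")
  vol$intensity_domain <- "normalized"
  ctr <- c(32L, 64L, 64L)
  roi <- crop_roi(vol, NULL, ctr)
  expect_equal(dim(roi$image), c(11, 64, 64))
  # interior crop equals the direct subarray
  expect_equal(roi$image, v[28:38, 33:96, 33:96])
  # centring contract: patch centre voxel equals vol[center]
  expect_equal(roi$image[6, 33, 33], v[33, 65, 65])
  # border crop: zero halo, interior matches (direct slicing oracle)
  expect_warning(roi0 <- crop_roi(vol, NULL, c(0L, 0L, 0L)), "padding")
  expect_equal(dim(roi0$image), c(11, 64, 64))
  expect_equal(roi0$image[1:5, , ], array(0, c(5, 64, 64)))  # z < 0 padded
  expect_equal(roi0$image[6:11, 33:64, 33:64], v[1:6, 1:32, 1:32])
  # random centres always give exact shape and centred value
  for (i in 1:10) {
    ctr <- c(sample(0:63, 1), sample(0:127, 1), sample(0:127, 1))
    r <- suppressWarnings(crop_roi(vol, NULL, ctr))
    expect_equal(dim(r$image), c(11, 64, 64))
    expect_equal(r$image[6, 33, 33], v[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1])
  }
})

test_that("sphere proxy masks have the right volume and symmetry", {
  vol <- ct_volume(array(0, c(30, 30, 30)))
  ann <- nodule_annotation("s", c(15, 15, 15), 6)
  m <- sphere_mask_from_annotation(ann, vol)
  expect_lt(abs(sum(m) - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.15)
  # reflection symmetry through the centre voxel
  cv <- world_to_voxel(ann, vol) + 1L
  sub <- m[(cv[1] - 4):(cv[1] + 4), (cv[2] - 4):(cv[2] + 4),
           (cv[3] - 4):(cv[3] + 4)]
  expect_identical(sub, sub[9:1, 9:1, 9:1])
  # sub-voxel nodule still marks the centre voxel
  tiny <- sphere_mask_from_annotation(nodule_annotation("s", c(15, 15, 15), 0.4), vol)
  expect_equal(sum(tiny), 1)
  expect_equal(tiny[cv[1], cv[2], cv[3]], 1L)
})

test_that("the full pipeline is deterministic and nodule-centred", {
  case <- tiny_phantom("wall_adherent", seed = 9)
  r1 <- preprocess_case(case$volume, case$annotation, gt_mask = case$mask)
  r2 <- preprocess_case(case$volume, case$annotation, gt_mask = case$mask)
  expect_identical(r1[[1]]$image, r2[[1]]$image)
  expect_identical(r1[[1]]$mask, r2[[1]]$mask)
  expect_equal(dim(r1[[1]]$image), c(11, 64, 64))
  expect_gt(sum(r1[[1]]$mask), 0)
  expect_equal(r1[[1]]$mask[6, 33, 33], 1)   # centre voxel inside the nodule
  expect_lt(abs(mean(r1[[1]]$image)), 0.5)   # normalised intensities
})
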