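test_that("image2d validates its invariants", {
  expect_error(image2d(matrix(0, 10, 10)), "32x32")
  expect_error(image2d(matrix(c(NA, rep(1, 32 * 32 - 1)), 32, 32)), "finite")
  expect_error(image2d(matrix(-1, 32, 32)), "non-negative")
  im <- image2d(matrix(runif(40 * 40), 40, 40))
  expect_equal(im$pixel_spacing, 0.39)
  expect_equal(im$slice_thickness, 3.0)
})

test_that("mask round-trips are bit-exact and carry the label", {
  dir <- withr::local_tempdir()
  m0 <- seg_mask(matrix(0L, 40, 30))
  p <- file.path(dir, "zero.png")
  write_mask(m0, p)
  expect_identical(read_mask(p)$pixels, m0$pixels)

  ph <- test_phantom(n_bodies = 2, noise_sigma = 0)
  m1 <- seg_mask(ph$truth$masks[[1]], label = 3L)
  p1 <- file.path(dir, "body.png")
  write_mask(m1, p1)
  back <- read_mask(p1)
  expect_identical(back$pixels, m1$pixels)
  expect_identical(back$label, 3L)

  p2 <- file.path(dir, "body.nii")
  write_mask(m1, p2)
  expect_identical(read_mask(p2)$pixels, m1$pixels)
})

test_that("phantom image round-trips pixel-identically through NIfTI", {
  dir <- withr::local_tempdir()
  ph <- test_phantom(n_bodies = 2)
  im <- image2d(vertseg:::normalize01(ph$image$pixels))
  p <- file.path(dir, "ph.nii")
  write_image(im, p)
  back <- read_image(p)
  expect_equal(back$pixels, im$pixels, tolerance = 1e-7)
  expect_equal(dim(back$pixels), dim(im$pixels))
})

test_that("PNG/TIFF readers return the raster at the written size", {
  dir <- withr::local_tempdir()
  x <- matrix(round(runif(64 * 48) * 255) / 255, 64, 48)
  pp <- file.path(dir, "x.png"); tp <- file.path(dir, "x.tif")
  write_image(x, pp); write_image(x, tp)
  expect_equal(dim(read_image(pp)$pixels), c(64, 48))
  expect_equal(dim(read_image(tp)$pixels), c(64, 48))
  expect_equal(read_image(pp)$pixels, vertseg:::normalize01(x),
               tolerance = 2e-4)
})

test_that("minimal DICOM reader recovers pixels and PixelSpacing", {
  dir <- withr::local_tempdir()
  set.seed(7)
  px <- matrix(sample.int(4000, 48 * 40, replace = TRUE), 48, 40)
  p <- file.path(dir, "x.dcm")
  write_test_dicom(p, px, spacing = 0.39, thickness = 3)
  im <- read_image(p)
  expect_equal(im$pixel_spacing, 0.39)
  expect_equal(im$slice_thickness, 3)
  expect_equal(im$pixels, vertseg:::normalize01(px), tolerance = 1e-12)
  expect_error(read_image(file.path(dir, "nope.dcm")), "no such file")
})

test_that("ROI and contour JSON round-trip", {
  dir <- withr::local_tempdir()
  roi <- roi_box(c(120.5, 64), 40, 30, angle = 12)
  p <- file.path(dir, "roi.json")
  write_roi_json(roi, p)
  back <- read_roi_json(p)
  expect_equal(back$center, roi$center)
  expect_equal(back$lx, roi$lx)
  expect_equal(back$angle, roi$angle)

  ct <- boundary_contour(upper = cbind(1:5, 1:5), right = cbind(5:9, 5:1),
                         lower = cbind(2:6, 3:7), left = cbind(1:4, 2:5))
  pc <- file.path(dir, "ct.json")
  write_contour_json(ct, pc)
  back <- read_contour_json(pc)
  expect_equal(back$upper, ct$upper, ignore_attr = TRUE)
  expect_true(back$closed)
})

test_that("pipeline decisions are invariant to intensity scaling", {
  ph <- test_phantom(n_bodies = 3, seed = 4)
  roi <- default_user_roi(ph)
  r1 <- run_pipeline(ph$image, roi)
  scaled <- image2d(ph$image$pixels * 7.3)
  r2 <- run_pipeline(scaled, roi)
  expect_identical(lapply(r1$masks, function(m) m$pixels),
                   lapply(r2$masks, function(m) m$pixels))
})

test_that("extract_roi presents a rotated box axis-aligned", {
  ph <- test_phantom(n_bodies = 3, rotations = 15, noise_sigma = 0, seed = 2)
  roi <- roi_box(ph$truth$centers[2, ], 96, 66, angle = 15)
  crop <- extract_roi(ph$image, roi)
  expect_equal(dim(crop), c(66, 96))
  # the derotated body should produce an axis-aligned edge map
  expect_equal(estimate_rotation(detect_edges(crop)), 0, tolerance = 2)
})
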