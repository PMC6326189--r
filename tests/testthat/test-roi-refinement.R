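test_that("edge detection handles flat and step inputs canonically", {
  expect_equal(sum(detect_edges(matrix(0.5, 30, 30))), 0)
  # vertical step at column 15
  step <- cbind(matrix(0.2, 40, 14), matrix(0.8, 40, 26))
  e <- detect_edges(step)
  cols <- which(colSums(e) > 0)
  expect_true(all(abs(cols - 14.5) <= 1.5))
  expect_gt(sum(e), 20)
  expect_error(detect_edges(matrix(0.5, 10, 10)), "16x16")
})

test_that("edges of a noiseless vertebra crop trace the cortical rim", {
  ph <- test_phantom(n_bodies = 3, noise_sigma = 0, seed = 2)
  ctr <- ph$truth$centers[2, ]
  roi <- roi_box(ctr, 96, 66)
  crop <- extract_roi(ph$image, roi)
  e <- detect_edges(crop)
  pts <- which(e == 1, arr.ind = TRUE)
  expect_gt(nrow(pts), 100)
  # distance of each edge pixel to the rounded-rect rim band
  hx <- ph$truth$sizes[2, 1] / 2; hy <- ph$truth$sizes[2, 2] / 2
  u <- pts[, 2] - (96 + 1) / 2
  v <- pts[, 1] - (66 + 1) / 2
  sdf <- vertseg:::rounded_rect_sdf(u, v, hx, hy, 0.25 * min(hx, hy))
  inband <- sdf > -4 & sdf < 2.5
  expect_gt(mean(inband), 0.9)
  # edge evidence on all four sides
  expect_true(any(pts[, 2] < 20) && any(pts[, 2] > 76))
  expect_true(any(pts[, 1] < 15) && any(pts[, 1] > 51))
})

test_that("rotation is estimated within 2 degrees across the tested range", {
  for (ang in c(-30, -20, -10, 0, 10, 20, 30)) {
    e <- rect_edge_map(80, 52, ang)
    expect_equal(estimate_rotation(e), ang, tolerance = 2)
  }
  # a nearly square body too
  expect_equal(estimate_rotation(rect_edge_map(60, 55, 20)), 20, tolerance = 2)
  expect_error(estimate_rotation(matrix(0L, 30, 30)), "insufficient edges")
})

test_that("derotation reaches a fixed point and contracts", {
  ph <- test_phantom(n_bodies = 3, rotations = 10, noise_sigma = 0, seed = 4)
  roi <- roi_box(ph$truth$centers[2, ], 96, 66)
  est <- estimate_rotation(detect_edges(extract_roi(ph$image, roi)))
  roi1 <- derotate_roi(roi, est)
  resid1 <- estimate_rotation(detect_edges(extract_roi(ph$image, roi1)))
  expect_lte(abs(resid1), 2)
  # applying a second pass never increases the residual
  roi2 <- derotate_roi(roi1, resid1)
  resid2 <- estimate_rotation(detect_edges(extract_roi(ph$image, roi2)))
  expect_lte(abs(resid2), abs(resid1) + 1e-9)
  # identity case
  r0 <- derotate_roi(roi, 0)
  expect_equal(r0$angle, roi$angle)
})

test_that("boundary adjustment extends only cropped sides and is idempotent", {
  ph <- test_phantom(n_bodies = 3, noise_sigma = 0, seed = 4)
  ctr <- ph$truth$centers[2, ]
  full <- roi_box(ctr, 96, 66)
  out <- adjust_boundaries(ph$image, full)
  expect_equal(out$lx, full$lx)
  expect_equal(out$ly, full$ly)

  lx_t <- ph$truth$sizes[2, 1]
  # shift the ROI right so ~15% of the body sticks out to the left
  shifted <- roi_box(ctr + c(0, 0.35 * lx_t), 96, 66)
  ext <- adjust_boundaries(ph$image, shifted)
  expect_gt(ext$lx, shifted$lx)
  expect_lt(ext$center[2] - ext$lx / 2, ctr[2] - lx_t / 2)  # rim inside

  # too-short ROI: both vertical sides extended
  short <- roi_box(ctr, 96, max(8, round(0.7 * ph$truth$sizes[2, 2])))
  ext2 <- adjust_boundaries(ph$image, short)
  expect_gt(ext2$ly, short$ly)
  # top and bottom rims end up inside the ROI (sub-pixel slack)
  expect_lt(ext2$center[1] - ext2$ly / 2,
            ctr[1] - ph$truth$sizes[2, 2] / 2 + 1)
  expect_gt(ext2$center[1] + ext2$ly / 2,
            ctr[1] + ph$truth$sizes[2, 2] / 2 - 1)

  # idempotence
  again <- adjust_boundaries(ph$image, ext2)
  expect_equal(again$lx, ext2$lx)
  expect_equal(again$ly, ext2$ly)
  expect_equal(again$center, ext2$center)
})

test_that("after refinement every ground-truth rim pixel is inside the ROI", {
  ph <- test_phantom(n_bodies = 4, rotations = c(5, -10, 15, 0), seed = 8)
  for (i in 1:4) {
    roi <- refine_roi(ph$image, roi_box(ph$truth$centers[i, ], 96, 66))
    poly <- ph$truth$rim_polygons[[i]]
    # transform rim points into the ROI's local frame and check the bounds
    a <- roi$angle * pi / 180
    dr <- poly[, 1] - roi$center[1]; dc <- poly[, 2] - roi$center[2]
    u <- dc * cos(a) - dr * sin(a)
    v <- dc * sin(a) + dr * cos(a)
    expect_true(all(abs(u) <= roi$lx / 2 + 1e-6),
                label = paste("body", i, "horizontal containment"))
    expect_true(all(abs(v) <= roi$ly / 2 + 1e-6),
                label = paste("body", i, "vertical containment"))
  }
})

test_that("projection profiles account for every edge pixel", {
  e <- rect_edge_map(40, 26, 7, 80)
  pr <- projection_profiles(e)
  expect_equal(sum(pr$Px), sum(e))
  expect_equal(sum(pr$Py), sum(e))
  expect_equal(length(pr$Px), 80)
})
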