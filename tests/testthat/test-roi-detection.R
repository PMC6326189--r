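test_that("correlation map matches the brute-force oracle", {
  set.seed(11)
  img <- matrix(runif(80 * 70), 80, 70)
  tpl <- img[20:36, 25:39]
  cm <- compute_correlation_map(img, tpl)
  oracle <- brute_force_ncc(img, tpl)
  ok <- !cm$suppressed
  expect_lt(max(abs(cm$scores[ok] - oracle[ok])), 1e-9)
  # self-match at the cut position
  expect_equal(max(cm$scores), 1.0, tolerance = 1e-9)
  expect_true(all(cm$scores >= -1 & cm$scores <= 1))
  expect_error(compute_correlation_map(img, matrix(0.5, 9, 9)), "constant")
  expect_error(compute_correlation_map(img, matrix(runif(80 * 70), 80, 70)),
               "smaller")
})

test_that("template against independent noise stays below 0.5", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    img <- matrix(runif(60 * 60), 60, 60)
    tpl <- matrix(runif(15 * 15), 15, 15)
    cm <- compute_correlation_map(img, tpl)
    worst <- max(worst, max(abs(cm$scores[!cm$suppressed])))
  }
  expect_lt(worst, 0.5)
})

test_that("identical vertebrae yield one >0.99 peak per body", {
  ph <- generate_phantom(phantom_spec(n_bodies = 5, size_jitter = 0,
                                      noise_sigma = 0, img_width = 255L,
                                      seed = 1))
  roi <- roi_box(ph$truth$centers[3, ], 96, 66)
  tpl <- vertseg:::crop_roi_pixels(ph$image, roi)
  cm <- compute_correlation_map(ph$image, tpl)
  sc <- cm$scores
  # local maxima over a 3x3 neighborhood with score > 0.99
  H <- nrow(sc); W <- ncol(sc)
  loc <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    loc <- loc & (sc >= vertseg:::shift_mat(sc, dr, dc, fill = -Inf))
  }
  peaks <- which(loc & sc > 0.99 & !cm$suppressed, arr.ind = TRUE)
  expect_equal(nrow(peaks), 5)
  ord <- peaks[order(peaks[, 1]), , drop = FALSE]
  expect_equal(ord[, 1], ph$truth$centers[, 1], tolerance = 1.01,
               ignore_attr = TRUE)
})

test_that("detection recovers all centers regardless of the starting body", {
  ph <- generate_phantom(phantom_spec(n_bodies = 5, size_jitter = 0,
                                      noise_sigma = 0, seed = 6))
  for (start in c(1, 3)) {
    roi <- default_user_roi(ph, start)
    det <- detect_vertebrae(ph$image, roi)
    expect_equal(nrow(det$vb_centers), 5)
    err <- sqrt(rowSums((det$vb_centers - ph$truth$centers)^2))
    expect_lt(max(err), 2)
    expect_true(all(diff(det$vb_centers[, 1]) > 0))     # monotone ordering
    expect_gt(det$d, 98)
    expect_lt(det$d, 112 + 4)
    # stacking invariant: consecutive vertical separations within [2/3, 3/2] d
    dv <- diff(det$vb_centers[, 1])
    expect_true(all(dv >= 2 / 3 * det$d & dv <= 3 / 2 * det$d))
  }
})

test_that("an image with a single vertebra raises the dedicated error", {
  ph <- test_phantom(n_bodies = 2, pitch = 200, margin = 80, noise_sigma = 0,
                     seed = 3)
  # crop a sub-image holding only the first body
  sub <- ph$image$pixels[1:160, ]
  roi <- roi_box(c(80, ph$truth$centers[1, 2]), 96, 66)
  tpl <- vertseg:::crop_roi_pixels(sub, roi)
  cm <- compute_correlation_map(sub, tpl)
  expect_error(find_vertebra_centers(cm, roi), "single vertebra")
})

test_that("suppression neighborhoods are excluded from later queries", {
  ph <- test_phantom(n_bodies = 4, noise_sigma = 0, seed = 5)
  roi <- default_user_roi(ph)
  tpl <- vertseg:::crop_roi_pixels(ph$image, roi)
  cm <- compute_correlation_map(ph$image, tpl)
  det <- find_vertebra_centers(cm, roi)
  # no two found centers may lie within each other's lx/3 x ly/3 window
  ctr <- det$vb_centers
  for (i in 1:(nrow(ctr) - 1)) for (j in (i + 1):nrow(ctr)) {
    expect_false(abs(ctr[i, 1] - ctr[j, 1]) <= floor(66 / 6) &&
                 abs(ctr[i, 2] - ctr[j, 2]) <= floor(96 / 6))
  }
})

test_that("disc refinement leaves aligned phantoms unchanged", {
  ph <- test_phantom(n_bodies = 5, noise_sigma = 0, seed = 6)
  roi <- default_user_roi(ph, 3)
  det <- detect_vertebrae(ph$image, roi,
                          config = pipeline_config(disc_refine = FALSE))
  det2 <- refine_with_discs(ph$image, det, roi)
  expect_equal(det2$vb_centers, det$vb_centers)
  expect_false(any(det2$corrected))
  expect_gt(nrow(det2$disc_centers), 2)
})

test_that("disc refinement corrects only above-threshold displacements", {
  ph <- test_phantom(n_bodies = 5, noise_sigma = 0, seed = 6)
  roi <- default_user_roi(ph, 3)
  det <- detect_vertebrae(ph$image, roi,
                          config = pipeline_config(disc_refine = FALSE))
  ly <- roi$ly
  # inject a 0.2*ly horizontal displacement on body 2: snapped back
  det_bad <- det
  det_bad$vb_centers[2, 2] <- det$vb_centers[2, 2] + 0.2 * ly
  fixed <- refine_with_discs(ph$image, det_bad, roi)
  expect_true(fixed$corrected[2])
  expect_lt(abs(fixed$vb_centers[2, 2] - ph$truth$centers[2, 2]), 3)
  # a 0.05*ly displacement stays below the 10% rule and is kept
  det_ok <- det
  det_ok$vb_centers[2, 2] <- det$vb_centers[2, 2] + 0.05 * ly
  kept <- refine_with_discs(ph$image, det_ok, roi)
  expect_false(kept$corrected[2])
  expect_equal(kept$vb_centers[2, 2], det_ok$vb_centers[2, 2])
})

test_that("disc refinement is skipped with a warning at the image border", {
  ph <- test_phantom(n_bodies = 3, noise_sigma = 0, seed = 2)
  roi <- default_user_roi(ph, 1)  # top body: disc template exits above
  det <- detect_vertebrae(ph$image, roi,
                          config = pipeline_config(disc_refine = FALSE))
  # move the user index to the top body whose template would exit
  expect_true(nrow(det$vb_centers) == 3)
  ph_short <- image2d(ph$image$pixels[30:nrow(ph$image$pixels), ])
  det_s <- det
  det_s$vb_centers[, 1] <- det_s$vb_centers[, 1] - 29
  det_s$user_index <- 1L
  expect_warning(out <- refine_with_discs(ph_short, det_s,
                                          roi_box(det_s$vb_centers[1, ], 96, 66)),
                 "skipped")
  expect_equal(out$vb_centers, det_s$vb_centers)
})
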