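test_that("vertices are located at the projection maxima", {
  # centered rectangle of width 40, height 26 in an 80x60 ROI
  e <- matrix(0L, 60, 80)
  e[18:43, 21] <- 1L; e[18:43, 60] <- 1L
  e[18, 21:60] <- 1L; e[43, 21:60] <- 1L
  v <- locate_vertices(projection_profiles(e))
  expect_equal(v$bL, 21); expect_equal(v$bR, 60)
  expect_equal(v$bU, 18); expect_equal(v$bD, 43)
  # symmetry about the ROI center
  expect_equal(v$bR - 40, 40 - v$bL, tolerance = 1.01)
  expect_error(locate_vertices(list(Px = c(0, 0, 0, 0, 1, 1, 0, 0),
                                    Py = rep(1, 8))), "no edge evidence")
})

test_that("vertices of a phantom crop land on the rim lines", {
  ph <- test_phantom(n_bodies = 3, noise_sigma = 0, seed = 2)
  crop <- extract_roi(ph$image, roi_box(ph$truth$centers[2, ], 96, 66))
  v <- locate_vertices(projection_profiles(detect_edges(crop)))
  hx <- as.numeric(ph$truth$sizes[2, 1]) / 2
  hy <- as.numeric(ph$truth$sizes[2, 2]) / 2
  expect_lt(abs(v$bL - ((96 + 1) / 2 - hx)), 3)
  expect_lt(abs(v$bR - ((96 + 1) / 2 + hx)), 3)
  expect_lt(abs(v$bU - ((66 + 1) / 2 - hy)), 3)
  expect_lt(abs(v$bD - ((66 + 1) / 2 + hy)), 3)
})

test_that("area partition is disjoint, covering, and sized as expected", {
  v <- list(bL = 21, bR = 60, bU = 18, bD = 43)
  s <- 4
  part <- partition_areas(v, s, 80, 60)
  lab <- matrix(0L, 60, 80)
  paint <- function(rows, cols, mask = NULL) {
    sub <- lab[rows, cols]
    if (is.null(mask)) sub <- sub + 1L else sub[mask] <- sub[mask] + 1L
    lab[rows, cols] <<- sub
  }
  for (b in part$bands) paint(b$rows, b$cols)
  for (cn in part$corners) {
    paint(cn$rows, cn$cols, cn$tri1)
    paint(cn$rows, cn$cols, cn$tri2)
  }
  expect_true(all(lab <= 1L))                      # pairwise disjoint
  ann <- lab[(v$bU - s):(v$bD + s - 1), (v$bL - s):(v$bR + s - 1)]
  inner <- ann[(2 * s + 1):(nrow(ann) - 2 * s), (2 * s + 1):(ncol(ann) - 2 * s)]
  expect_true(all(inner == 0L))
  ann[(2 * s + 1):(nrow(ann) - 2 * s), (2 * s + 1):(ncol(ann) - 2 * s)] <- 1L
  expect_true(all(ann == 1L))                      # annulus fully covered
  # band U pixel count = (bR - bL - 2s) * 2s
  U <- part$bands$U
  expect_equal(length(U$rows) * length(U$cols), (v$bR - v$bL - 2 * s) * 2 * s)
  # left-right mirror symmetry of the partition widths
  expect_equal(length(part$bands$L$rows), length(part$bands$R$rows))
  expect_error(partition_areas(list(bL = 30, bR = 40, bU = 25, bD = 35), 4,
                               80, 60), "too small")
})

test_that("graph path finds the dark ridge and matches exhaustive search", {
  # unique zero-cost row
  band <- matrix(1, 7, 20); band[4, ] <- 0
  expect_equal(segment_band_graph(band)$path, rep(4L, 20))
  # dark sinusoidal ridge
  w <- 40
  ridge <- round(8 + 4 * sin(seq(0, 2 * pi, length.out = w)))
  band2 <- matrix(1, 16, w)
  for (j in 1:w) band2[ridge[j], j] <- 0.01
  expect_true(all(abs(segment_band_graph(band2)$path - ridge) <= 1))
  # optimality against full enumeration on random small bands
  set.seed(42)
  for (trial in 1:100) {
    h <- sample(2:5, 1); w <- sample(3:8, 1)
    b <- matrix(runif(h * w), h, w)
    expect_equal(segment_band_graph(b)$cost, brute_force_min_path_cost(b),
                 tolerance = 1e-12)
  }
  # vertical orientation is the transposed problem
  bv <- t(band)
  expect_equal(segment_band_graph(bv, "vertical")$path, rep(4L, 20))
})

test_that("intensity clustering is deterministic with ordered ranks", {
  two <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  cl <- suppressMessages(cluster_roi(two, k = 10))
  expect_equal(cl$k, 2)
  expect_identical(cl$ranks, matrix(rep(c(1L, 2L), each = 50), 10, 10))

  ph <- test_phantom(n_bodies = 3, noise_sigma = 0, seed = 2)
  crop <- extract_roi(ph$image, roi_box(ph$truth$centers[2, ], 96, 66))
  c1 <- suppressMessages(cluster_roi(crop))
  c2 <- suppressMessages(cluster_roi(crop))
  expect_identical(c1$ranks, c2$ranks)
  expect_true(all(diff(c1$centers) > 0))
  # noiseless tissue classes map to constant ranks
  hx <- ph$truth$sizes[2, 1] / 2
  interior <- c1$ranks[30:36, 45:52]     # deep body interior
  expect_equal(length(unique(as.vector(interior))), 1)
})

test_that("line rules reproduce the hand-traced cases", {
  # deep valley at index 4, bright plateau far from the base: Case 1
  r <- segment_line(c(8, 8, 8, 2, 7, 7, 7), side = "left")
  expect_equal(r$case, 1)
  expect_equal(r$e, 4)
  expect_equal(r$b, 7)
  expect_equal(r$rref, 4)
  # monotone decreasing, no valley: Case 3 at the ceil(Y(B)/3) level
  r2 <- segment_line(c(9, 7, 5, 3, 2, 1), side = "right")
  expect_equal(r2$case, 3)
  expect_equal(r2$e, which(c(9, 7, 5, 3, 2, 1) == ceiling(9 / 3))[1])
  # flat line: Case 3, falls back to the far end
  r3 <- segment_line(rep(5, 6), side = "left")
  expect_equal(r3$case, 3)
  expect_true(r3$fallback)
  expect_equal(r3$e, 1)   # far end for a left-side line
  expect_error(segment_line(c(0, 1, 2), "left"), "positive integer")
})

test_that("case classification is total and exclusive (scaled sweep)", {
  res <- vertseg:::.check_line_rules_cpp(4L, 10L)
  expect_equal(res$n_violations, 0)
  expect_equal(res$n_checked, 10 + 100 + 1000 + 10000)
  expect_equal(res$case1 + res$case2 + res$case3, res$n_checked)
  # all three cases occur
  expect_true(all(c(res$case1, res$case2, res$case3) > 0))
})

test_that("triangle padding yields full lines and in-triangle boundaries", {
  sq <- matrix(7, 8, 8)
  tri <- outer(1:8, 1:8, function(i, j) j >= i)
  expect_equal(triangles_to_parallelograms(sq, tri, "cols"),
               matrix(7, 8, 8))
  set.seed(3)
  sq2 <- matrix(runif(64), 8, 8)
  pad <- triangles_to_parallelograms(sq2, tri, "cols")
  expect_equal(dim(pad), c(8, 8))
  expect_false(anyNA(pad))
  expect_equal(pad[tri], sq2[tri])       # original values preserved
  pts <- vertseg:::corner_graph_points(sq2, tri)
  for (k in seq_len(nrow(pts))) {
    expect_true(tri[pts[k, 1], pts[k, 2]])
  }
})

test_that("cubic smoothing replaces only outliers", {
  x <- 1:20
  y <- 0.002 * x^3 - 0.05 * x^2 + x + 3
  sides <- list(upper = cbind(y, x), right = cbind(x, y + 1),
                lower = cbind(y + 5, x), left = cbind(x, y))
  sm <- smooth_contour(sides, delta = 3)
  expect_equal(sm$upper[, 1], y, tolerance = 1e-8)
  # one 10-px outlier on a linear side is pulled onto the curve
  y2 <- x * 0.5 + 2; y2[10] <- y2[10] + 10
  sm2 <- smooth_contour(list(upper = cbind(y2, x), right = cbind(x, y2),
                             lower = cbind(y2, x), left = cbind(x, y2)),
                        delta = 3)
  resid <- sm2$upper[, 1] - (x * 0.5 + 2)
  expect_lt(abs(resid[10]), 3.5)
  expect_true(all(abs(resid) <= 3.5))
})

test_that("single-vertebra segmentation meets the phantom accuracy bar", {
  ph <- test_phantom(n_bodies = 3, seed = 2)    # default mild noise
  roi <- refine_roi(ph$image, roi_box(ph$truth$centers[2, ], 96, 66))
  seg <- suppressMessages(segment_vertebra(ph$image, roi))
  d_clean <- dice(seg$mask, seg_mask(ph$truth$masks[[2]]))
  expect_gte(d_clean, 0.95)
  # mask is one piece inside the ROI polygon and simple as a polygon
  fg <- which(seg$mask$pixels == 1, arr.ind = TRUE)
  a <- seg$roi$angle * pi / 180
  dr <- fg[, 1] - seg$roi$center[1]; dc <- fg[, 2] - seg$roi$center[2]
  u <- dc * cos(a) - dr * sin(a); v <- dc * sin(a) + dr * cos(a)
  expect_true(all(abs(u) <= seg$roi$lx / 2 + 1))
  expect_true(all(abs(v) <= seg$roi$ly / 2 + 1))
  expect_true(polygon_is_simple(contour_polygon(seg$contour)))

  # heavier noise: 5% of the dynamic range
  ph5 <- test_phantom(n_bodies = 3, noise_sigma = 0.05, seed = 2)
  roi5 <- refine_roi(ph5$image, roi_box(ph5$truth$centers[2, ], 96, 66))
  seg5 <- suppressMessages(segment_vertebra(ph5$image, roi5))
  expect_gte(dice(seg5$mask, seg_mask(ph5$truth$masks[[2]])), 0.85)

  # 10-degree rotation (after refinement) costs at most 2 DSC points
  phr <- test_phantom(n_bodies = 3, rotations = 10, seed = 2)
  roir <- refine_roi(phr$image, roi_box(phr$truth$centers[2, ], 96, 66))
  segr <- suppressMessages(segment_vertebra(phr$image, roir))
  d_rot <- dice(segr$mask, seg_mask(phr$truth$masks[[2]]))
  expect_gte(d_rot, d_clean - 0.02)
})

test_that("segmentation contours stay simple across random phantoms", {
  set.seed(10)
  for (k in 1:6) {
    ph <- test_phantom(n_bodies = 3, rotations = runif(3, -15, 15),
                       seed = 100 + k)
    roi <- refine_roi(ph$image, roi_box(ph$truth$centers[2, ], 96, 66))
    seg <- suppressMessages(segment_vertebra(ph$image, roi))
    expect_true(polygon_is_simple(contour_polygon(seg$contour)),
                label = paste("phantom", k))
  }
})
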