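# Segmentation of one refined ROI: approximate vertices from edge projection
# profiles, partition into four bands + four corner squares (each split into
# two triangles), minimum-cost graph paths on the superior/inferior bands,
# cluster-rank line rules on the lateral bands, cubic smoothing, polygon fill.

#' Locate approximate vertebra vertices from projection profiles
#'
#' The left/right vertex columns are the argmax of the column edge profile on
#' its outer half-interval, the upper/lower vertex rows the argmax of the row
#' profile likewise; `(bL, bU)`, `(bR, bU)`, `(bL, bD)`, `(bR, bD)` are the
#' approximate corners of the vertebral body. Ties are broken toward the ROI
#' border.
#'
#' @param profiles a [projection_profiles()] list (`Px`, `Py`).
#' @return list with integer `bL`, `bR` (columns) and `bU`, `bD` (rows).
#' @export
locate_vertices <- function(profiles) {
  Px <- profiles$Px; Py <- profiles$Py
  lx <- length(Px); ly <- length(Py)
  half_argmax <- function(p, lo, hi, prefer_low, side) {
    seg <- p[lo:hi]
    if (max(seg) == 0) stop("no edge evidence for side: ", side)
    idx <- which(seg == max(seg))
    lo - 1L + if (prefer_low) min(idx) else max(idx)
  }
  hx <- floor(lx / 2); hy <- floor(ly / 2)
  list(bL = half_argmax(Px, 2L, hx - 1L, TRUE, "left"),
       bR = half_argmax(Px, hx + 1L, lx, FALSE, "right"),
       bU = half_argmax(Py, 2L, hy - 1L, TRUE, "upper"),
       bD = half_argmax(Py, hy + 1L, ly, FALSE, "lower"))
}

#' Partition an ROI into segmentation areas
#'
#' The ROI is divided into an annular band around the vertex rectangle:
#' four rectangular bands of half-width `s` straddling the rectangle sides
#' (`U`, `D`, `L`, `R`) and four `2s x 2s` corner squares, each split along
#' its outer-to-inner diagonal into two triangles — suffix 1 adjoining the
#' horizontal bands (segmented like `U`/`D`), suffix 2 adjoining the vertical
#' bands (segmented like `L`/`R`). All areas are pairwise disjoint and cover
#' the annulus.
#'
#' @param vertices a [locate_vertices()] result.
#' @param spacing the in/out spacing `s` in pixels (at least 2); clamped
#'   (with a warning) when the annulus would exit the crop.
#' @param lx,ly crop width and height in pixels.
#' @return a `vertseg_partition` list: `s`, `bands` (each with `rows`,
#'   `cols` index vectors) and `corners` (each with `rows`, `cols`, logical
#'   `tri1`/`tri2` masks).
#' @export
partition_areas <- function(vertices, spacing, lx, ly) {
  bL <- vertices$bL; bR <- vertices$bR; bU <- vertices$bU; bD <- vertices$bD
  s <- as.integer(spacing)
  if (s < 2L) stop("spacing must be at least 2 px")
  if (bR - bL < 4L * s || bD - bU < 4L * s)
    stop("vertex rectangle too small for spacing s = ", s,
         " (needs width and height >= 4s)")
  s_fit <- min(bL - 1L, lx - bR + 1L, bU - 1L, ly - bD + 1L)
  if (s_fit < s) {
    if (s_fit < 2L) stop("vertex rectangle too close to the crop border")
    warning("partition spacing clamped from ", s, " to ", s_fit,
            " to stay inside the crop")
    s <- s_fit
  }
  CL <- (bL - s):(bL + s - 1L); CM <- (bL + s):(bR - s - 1L)
  CR <- (bR - s):(bR + s - 1L)
  RU <- (bU - s):(bU + s - 1L); RM <- (bU + s):(bD - s - 1L)
  RD <- (bD - s):(bD + s - 1L)
  n2 <- 2L * s
  ii <- matrix(seq_len(n2), n2, n2)          # local row index
  jj <- t(ii)                                # local col index
  corners <- list(
    UL = list(rows = RU, cols = CL, tri1 = jj >= ii),
    UR = list(rows = RU, cols = CR, tri1 = ii + jj <= n2 + 1L),
    DL = list(rows = RD, cols = CL, tri1 = ii + jj >= n2 + 1L),
    DR = list(rows = RD, cols = CR, tri1 = jj <= ii))
  for (nm in names(corners)) corners[[nm]]$tri2 <- !corners[[nm]]$tri1
  structure(list(
    s = s, vertices = vertices,
    bands = list(U = list(rows = RU, cols = CM),
                 D = list(rows = RD, cols = CM),
                 L = list(rows = RM, cols = CL),
                 R = list(rows = RM, cols = CR)),
    corners = corners), class = "vertseg_partition")
}

#' Minimum-cost boundary path across a band
#'
#' Finds the minimum-cost monotone path across the band (one pixel per
#' column for horizontal orientation), where the step cost is the intensity
#' of the traversed pixel and steps connect 8-neighbors, so the path is
#' attracted to the dark cortical rim and divides the band into a top and a
#' bottom part. This dynamic program computes the s/t minimum cut of the
#' chain graph whose nodes are the inter-pixel intervals along the
#' transverse axis and whose edge weights are the pixel intensities, and is
#' deterministic (ties resolved toward the smallest row index).
#'
#' @param band_pixels numeric matrix (intensities or cluster ranks).
#' @param orientation `"horizontal"` (one row value per column, default) or
#'   `"vertical"` (one column value per row; the transposed problem).
#' @return list with `path` (integer positions, one per line), `cost`
#'   (total path cost) and `orientation`.
#' @export
segment_band_graph <- function(band_pixels,
                               orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  b <- as.matrix(band_pixels)
  if (orientation == "vertical") b <- t(b)
  h <- nrow(b); w <- ncol(b)
  if (h < 2L || w < 2L) stop("band too small for a boundary path")
  C <- matrix(0, h, w)
  move <- matrix(0L, h, w)
  C[, 1] <- b[, 1]
  for (j in 2:w) {
    up <- c(Inf, C[-h, j - 1L])        # from row r-1
    same <- C[, j - 1L]
    down <- c(C[-1, j - 1L], Inf)      # from row r+1
    vals <- cbind(up, same, down)
    pick <- max.col(-vals, ties.method = "first")   # tie -> smallest source row
    C[, j] <- b[, j] + vals[cbind(seq_len(h), pick)]
    move[, j] <- pick - 2L
  }
  r <- which.min(C[, w])               # tie -> smallest row
  path <- integer(w)
  path[w] <- r
  for (j in w:2) {
    r <- r + move[r, j]
    path[j - 1L] <- r
  }
  list(path = path, cost = C[path[w], w], orientation = orientation)
}

#' Intensity clustering of an ROI into ordered ranks
#'
#' K-means clustering of the crop intensities into (up to) `k` clusters; each
#' pixel gets the rank of its cluster, 1..k ordered by ascending cluster
#' center. Centers are initialized deterministically at intensity quantiles
#' (1-D k-means needs no random restarts for stability), so the rank raster
#' is fully reproducible. When the patch has fewer than `k` distinct
#' intensities, `k` is reduced to that count.
#'
#' @param roi_pixels numeric matrix.
#' @param k number of clusters (default 10).
#' @return a `vertseg_clusters` list: `ranks` (integer matrix in 1..k),
#'   `k` (effective count), `centers` (ascending).
#' @export
cluster_roi <- function(roi_pixels, k = 10L) {
  patch <- as.matrix(roi_pixels)
  vals <- as.numeric(patch)
  uq <- sort(unique(vals))
  k_eff <- min(as.integer(k), length(uq))
  if (k_eff < as.integer(k))
    message("cluster_roi: only ", length(uq),
            " distinct intensities; k reduced to ", k_eff)
  if (k_eff == length(uq)) {
    assign <- match(vals, uq)
    centers <- uq
  } else {
    centers0 <- stats::quantile(uq, probs = seq(0, 1, length.out = k_eff),
                                names = FALSE)
    km <- stats::kmeans(vals, centers = matrix(centers0, ncol = 1),
                        iter.max = 100L)
    ord <- order(km$centers[, 1])
    rank_of <- integer(k_eff); rank_of[ord] <- seq_len(k_eff)
    assign <- rank_of[km$cluster]
    centers <- sort(km$centers[, 1])
  }
  ranks <- matrix(as.integer(assign), nrow(patch), ncol(patch))
  structure(list(ranks = ranks, k = k_eff, centers = centers),
            class = "vertseg_clusters")
}

#' Per-line boundary point from cluster ranks
#'
#' Classifies one band line of cluster ranks into Case 1/2/3 and returns the
#' boundary point. The base point `B` is the line end on the vertebra side
#' (the last index for the left band, the first for the right) or the
#' nearest intensity peak to it; the reference value is `ceil(Y(B)/2)`.
#' Case 1 (a deep valley followed by a peak exceeding the reference):
#' the boundary is the deepest point between that peak and the base-side
#' line end. Cases 2 (peaks below the reference) and 3 (no valley): the
#' boundary is the point nearest `B` whose rank equals `ceil(Y(B)/3)`; if no
#' point attains it, the far line end is used and flagged as a fallback.
#'
#' @param y integer vector of cluster ranks (values in 1..k).
#' @param side `"left"` or `"right"` band; determines the base end and scan
#'   direction.
#' @return list with `case` (1/2/3), `e` (boundary index into `y`), `b`
#'   (base index), `rref`, `fallback`.
#' @export
segment_line <- function(y, side = c("left", "right")) {
  side <- match.arg(side)
  y <- as.integer(y)
  if (length(y) < 1L || anyNA(y) || any(y < 1L))
    stop("line profile must be positive integer cluster ranks")
  res <- .classify_line_cpp(y, side == "left")
  names(res)[names(res) == "case"] <- "case"
  res
}

#' Pad a triangular corner area to a parallelogram
#'
#' Each short line of the triangle is padded to full length by replicating
#' its terminal pixel value, yielding a rectangular array on which the band
#' segmentation methods can operate; lines with no triangle pixel are copied
#' from the nearest non-empty line. Boundary points later found in padded
#' cells are projected back onto the triangle's hypotenuse (see
#' [segment_vertebra()]).
#'
#' @param square_vals the `2s x 2s` corner square of pixel values (or
#'   cluster ranks).
#' @param tri_mask logical matrix, `TRUE` on the triangle.
#' @param line_dir `"cols"` (lines are columns; for the graph method) or
#'   `"rows"` (lines are rows; for the line-rule method).
#' @return matrix of the same shape with every line fully populated.
#' @export
triangles_to_parallelograms <- function(square_vals, tri_mask,
                                        line_dir = c("cols", "rows")) {
  line_dir <- match.arg(line_dir)
  v <- as.matrix(square_vals); m <- tri_mask
  if (!any(m)) stop("empty triangular area")
  if (line_dir == "rows") { v <- t(v); m <- t(m) }
  out <- v
  empty <- integer(0)
  for (j in seq_len(ncol(v))) {
    idx <- which(m[, j])
    if (length(idx) == 0L) { empty <- c(empty, j); next }
    lo <- min(idx); hi <- max(idx)
    if (lo > 1L) out[seq_len(lo - 1L), j] <- v[lo, j]
    if (hi < nrow(v)) out[(hi + 1L):nrow(v), j] <- v[hi, j]
  }
  for (j in empty) {
    nonempty <- setdiff(seq_len(ncol(v)), empty)
    out[, j] <- out[, nonempty[which.min(abs(nonempty - j))]]
  }
  if (line_dir == "rows") out <- t(out)
  out
}

# cubic least-squares fit of one contour side; points with residual > delta
# are replaced by the curve value
fit_side_cubic <- function(x, y, delta) {
  if (length(x) < 4L || length(unique(x)) < 4L) return(y)  # kept raw
  fit <- stats::lm(y ~ stats::poly(x, 3))
  yy <- stats::fitted(fit)
  out <- y
  repl <- abs(y - yy) > delta
  out[repl] <- yy[repl]
  out
}

#' Smooth raw boundary points into a closed contour
#'
#' Per side, a cubic polynomial is fitted by least squares (row as a function
#' of column for the upper/lower sides, column as a function of row for
#' left/right); points deviating from the curve by more than `delta` px are
#' replaced with the curve value. Sides with fewer than 4 points (or fewer
#' than 4 distinct abscissae) are kept raw.
#'
#' @param raw_sides list with `upper`, `right`, `lower`, `left`, each an
#'   n x 2 `(row, col)` matrix ordered along the side.
#' @param delta replacement tolerance in px (default 3).
#' @return a [boundary_contour()].
#' @export
smooth_contour <- function(raw_sides, delta = 3) {
  up <- raw_sides$upper; lo <- raw_sides$lower
  le <- raw_sides$left; ri <- raw_sides$right
  up[, 1] <- fit_side_cubic(up[, 2], up[, 1], delta)
  lo[, 1] <- fit_side_cubic(lo[, 2], lo[, 1], delta)
  le[, 2] <- fit_side_cubic(le[, 1], le[, 2], delta)
  ri[, 2] <- fit_side_cubic(ri[, 1], ri[, 2], delta)
  boundary_contour(upper = up, right = ri, lower = lo, left = le)
}

# even-odd scanline polygon fill; pixel centers at integer coordinates
fill_polygon <- function(poly, dim) {
  r <- poly[, 1]; cc <- poly[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(cc[-1], cc[1])
  mask <- matrix(FALSE, dim[1], dim[2])
  ylo <- max(1L, ceiling(min(r))); yhi <- min(dim[1], floor(max(r)))
  if (yhi < ylo) return(mask)
  for (y in ylo:yhi) {
    cross <- (r <= y & r2 > y) | (r2 <= y & r > y)
    if (!any(cross)) next
    xs <- sort(cc[cross] + (y - r[cross]) * (c2[cross] - cc[cross]) /
                 (r2[cross] - r[cross]))
    nseg <- floor(length(xs) / 2)
    for (i in seq_len(nseg)) {
      a <- ceiling(xs[2 * i - 1] - 1e-9); b <- floor(xs[2 * i] + 1e-9)
      if (b >= a) mask[y, max(1L, a):min(dim[2], b)] <- TRUE
    }
  }
  mask
}

# collect the per-column boundary rows of a *1 triangle via the padded graph
# path, projecting padded hits back onto the triangle
corner_graph_points <- function(crop_square, tri_mask) {
  padded <- triangles_to_parallelograms(crop_square, tri_mask, "cols")
  gp <- segment_band_graph(padded, "horizontal")
  pts <- NULL
  for (j in seq_len(ncol(crop_square))) {
    idx <- which(tri_mask[, j])
    if (length(idx) == 0L) next
    rr <- min(max(gp$path[j], min(idx)), max(idx))
    pts <- rbind(pts, c(rr, j))
  }
  pts
}

# per-row boundary cols of a *2 triangle via padded line rules
corner_line_points <- function(rank_square, tri_mask, side) {
  padded <- triangles_to_parallelograms(rank_square, tri_mask, "rows")
  pts <- NULL
  for (i in seq_len(nrow(rank_square))) {
    idx <- which(tri_mask[i, ])
    if (length(idx) == 0L) next
    e <- segment_line(padded[i, ], side)$e
    ccol <- min(max(e, min(idx)), max(idx))
    pts <- rbind(pts, c(i, ccol))
  }
  pts
}

#' Segment one vertebral body inside a refined ROI
#'
#' Full single-vertebra segmentation: Canny edges and projection profiles of
#' the crop, approximate vertices ([locate_vertices()]), area partition
#' ([partition_areas()]), minimum-cost graph paths on the superior/inferior
#' bands and corner triangles 1, cluster-rank line rules
#' ([segment_line()]) on the lateral bands and corner triangles 2, cubic
#' smoothing ([smooth_contour()]) and polygon fill. The returned mask is in
#' full-image coordinates.
#'
#' @param image the [image2d()].
#' @param refined_roi a refined [roi_box()] (see [refine_roi()]).
#' @param config a [pipeline_config()].
#' @param label vertebra index stored in the mask.
#' @return list with `mask` (a [seg_mask()]), `contour` (image-frame
#'   [boundary_contour()]), `contour_crop` (crop-frame), `vertices`,
#'   `partition`, and `roi` (the box actually segmented; it may be slightly
#'   larger than the input when the vertex rectangle touched the crop
#'   border and the crop was retried enlarged).
#' @export
segment_vertebra <- function(image, refined_roi, config = pipeline_config(),
                             label = 1L) {
  img <- if (inherits(image, "vertseg_image")) image$pixels else as.matrix(image)
  roi <- refined_roi
  # when the located vertex rectangle touches the crop border the annular
  # partition cannot be placed; one retry on a slightly enlarged crop
  res <- tryCatch(segment_vertebra_crop(img, roi, config),
                  error = function(e) e)
  if (inherits(res, "error")) {
    if (!grepl("crop border|small for spacing|no edge evidence",
               conditionMessage(res)))
      stop(res)
    roi <- roi_box(roi$center, roi$lx * 1.2, roi$ly * 1.2, angle = roi$angle)
    res <- segment_vertebra_crop(img, roi, config)
  }
  contour <- res$contour
  poly <- contour_polygon(contour)
  mask <- fill_polygon(poly, dim(img))
  list(mask = seg_mask(mask, label = label), contour = contour,
       contour_crop = res$contour_crop, vertices = res$vertices,
       partition = res$partition, roi = roi)
}

segment_vertebra_crop <- function(img, roi, config) {
  crop <- extract_roi(img, roi)
  ly <- nrow(crop); lx <- ncol(crop)
  edges <- detect_edges(crop, sigma = config$canny_sigma)
  prof <- projection_profiles(edges)
  vert <- locate_vertices(prof)
  s <- max(3L, ceiling(config$spacing_frac * min(lx, ly)))
  part <- partition_areas(vert, s, lx, ly)
  bands <- part$bands; corners <- part$corners

  ranks <- cluster_roi(crop, k = config$k_clusters)$ranks

  band_path_pts <- function(bd) {
    sub <- crop[bd$rows, bd$cols, drop = FALSE]
    gp <- segment_band_graph(sub, "horizontal")
    cbind(bd$rows[1] - 1L + gp$path, bd$cols)
  }
  line_pts <- function(bd, side) {
    pts <- NULL
    for (i in seq_along(bd$rows)) {
      y <- ranks[bd$rows[i], bd$cols]
      e <- segment_line(y, side)$e
      pts <- rbind(pts, c(bd$rows[i], bd$cols[1] - 1L + e))
    }
    pts
  }
  corner_pts <- function(cn, which_tri, side = NULL) {
    rows <- cn$rows; cols <- cn$cols
    if (which_tri == 1L) {
      p <- corner_graph_points(crop[rows, cols, drop = FALSE], cn$tri1)
    } else {
      p <- corner_line_points(ranks[rows, cols, drop = FALSE], cn$tri2, side)
    }
    if (is.null(p)) return(NULL)
    cbind(rows[1] - 1L + p[, 1], cols[1] - 1L + p[, 2])
  }

  upper <- rbind(corner_pts(corners$UL, 1L), band_path_pts(bands$U),
                 corner_pts(corners$UR, 1L))
  lower <- rbind(corner_pts(corners$DL, 1L), band_path_pts(bands$D),
                 corner_pts(corners$DR, 1L))
  left <- rbind(corner_pts(corners$UL, 2L, "left"), line_pts(bands$L, "left"),
                corner_pts(corners$DL, 2L, "left"))
  right <- rbind(corner_pts(corners$UR, 2L, "right"),
                 line_pts(bands$R, "right"),
                 corner_pts(corners$DR, 2L, "right"))
  upper <- upper[order(upper[, 2]), , drop = FALSE]
  lower <- lower[order(lower[, 2]), , drop = FALSE]
  left <- left[order(left[, 1]), , drop = FALSE]
  right <- right[order(right[, 1]), , drop = FALSE]

  contour_crop <- smooth_contour(
    list(upper = upper, right = right, lower = lower, left = left),
    delta = config$delta)

  # map crop-frame contour to image frame
  to_image <- function(pts) {
    u <- pts[, 2] - (lx + 1) / 2
    v <- pts[, 1] - (ly + 1) / 2
    off <- roi_local_to_image(u, v, roi$angle)
    cbind(roi$center[1] + off[, 1], roi$center[2] + off[, 2])
  }
  contour <- boundary_contour(upper = to_image(contour_crop$upper),
                              right = to_image(contour_crop$right),
                              lower = to_image(contour_crop$lower),
                              left = to_image(contour_crop$left))
  list(contour = contour, contour_crop = contour_crop, vertices = vert,
       partition = part)
}
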