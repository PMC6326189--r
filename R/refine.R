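# Per-ROI fine tuning: Canny edges, Hough-based rotation estimation and
# counter-rotation, projection-profile boundary extension.

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with edge replication
conv_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2
  H <- nrow(img); W <- ncol(img)
  ridx <- pmin(pmax(seq_len(H + 2 * r) - r, 1L), H)
  cidx <- pmin(pmax(seq_len(W + 2 * r) - r, 1L), W)
  pad <- img[ridx, cidx, drop = FALSE]
  # rows
  out <- matrix(0, H + 2 * r, W)
  for (i in seq_along(k))
    out <- out + k[i] * pad[, i:(i + W - 1L), drop = FALSE]
  res <- matrix(0, H, W)
  for (i in seq_along(k))
    res <- res + k[i] * out[i:(i + H - 1L), , drop = FALSE]
  res
}

conv3 <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  ridx <- pmin(pmax(0:(H + 1L), 1L), H)
  cidx <- pmin(pmax(0:(W + 1L), 1L), W)
  pad <- img[ridx, cidx, drop = FALSE]
  out <- matrix(0, H, W)
  for (a in 1:3) for (b in 1:3)
    out <- out + kern[a, b] * pad[a:(a + H - 1L), b:(b + W - 1L), drop = FALSE]
  out
}

shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Canny edge detection on an ROI crop
#'
#' Classical Canny: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding. Hysteresis thresholds are taken from percentiles of the
#' positive gradient magnitudes, which keeps the rule intensity-scale free.
#'
#' @param roi_pixels numeric matrix, at least 16 x 16.
#' @param sigma Gaussian smoothing standard deviation in px (default 1.4).
#' @param low_q,high_q magnitude percentiles for the weak/strong hysteresis
#'   thresholds (defaults 0.70 and 0.90).
#' @return binary (0/1) edge matrix, same shape as the input. A constant
#'   patch yields an all-zero map.
#' @export
detect_edges <- function(roi_pixels, sigma = 1.4, low_q = 0.70, high_q = 0.90) {
  img <- as.matrix(roi_pixels)
  if (nrow(img) < 16L || ncol(img) < 16L)
    stop("edge detection needs a patch of at least 16x16")
  rng <- diff(range(img))
  if (rng == 0) return(matrix(0L, nrow(img), ncol(img)))
  sm <- conv_sep(img, gaussian_kernel1d(sigma))
  sob_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)          # d/dcol
  sob_y <- t(sob_x)                                               # d/drow
  gx <- conv3(sm, sob_x)
  gy <- conv3(sm, sob_y)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) <= 1e-10 * rng) return(matrix(0L, nrow(img), ncol(img)))

  # non-maximum suppression along quantized gradient direction
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4  # 0:E,1:SE,2:S,3:SW
  nmax <- matrix(FALSE, nrow(img), ncol(img))
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    n1 <- shift_mat(mag, o[1], o[2])
    n2 <- shift_mat(mag, -o[1], -o[2])
    sel <- sector == s & mag >= n1 & mag >= n2
    nmax <- nmax | sel
  }
  mags <- mag[mag > 0]
  hi <- stats::quantile(mags, high_q, names = FALSE)
  lo <- stats::quantile(mags, low_q, names = FALSE)
  strong <- nmax & mag >= hi
  weak <- nmax & mag >= lo

  # hysteresis: grow strong edges through weak pixels (8-connectivity)
  cur <- strong
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) grown <- grown | shift_mat(cur, dr, dc, FALSE)
    grown <- grown & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  mode(cur) <- "integer"
  cur
}

# Hough accumulator extents: for each candidate angle, the length of the
# nonzero area along rho, i.e. the distance from the first to the last
# occupied distance cell of the edge set projected on that direction.
# (The occupied-cell span is used rather than the occupied-cell count: a
# closed outline projects onto its whole span, and the count version
# suffers from strong rasterization aliasing at low-order rational angles.)
hough_extents <- function(edges, thetas, rho_step = 1) {
  pts <- which(edges != 0, arr.ind = TRUE)
  r <- pts[, 1]; c <- pts[, 2]
  th <- thetas * pi / 180
  # projection p(theta) = col*cos(theta) - row*sin(theta): for an object
  # rotated CCW-on-screen by A, the projected span is minimized at
  # theta = A (the projection aligns with the object's own x-axis).
  proj <- outer(c, cos(th)) - outer(r, sin(th))
  vapply(seq_along(thetas),
         function(j) diff(range(proj[, j])) / rho_step,
         numeric(1))
}

#' Hough transform accumulator of an edge map
#'
#' Accumulator over (angle theta, distance rho from origin), vote = edge
#' pixel count per cell. Exposed mostly for inspection/plotting; rotation
#' estimation uses the per-angle occupied extent of this accumulator.
#'
#' @param edges binary edge matrix.
#' @param thetas candidate angles in degrees (default -45..45 step 1).
#' @param rho_step distance bin width in px (default 1).
#' @return a list with `H` (rho x theta count matrix), `thetas`, `rhos`.
#' @export
hough_image <- function(edges, thetas = seq(-45, 45, by = 1), rho_step = 1) {
  pts <- which(edges != 0, arr.ind = TRUE)
  th <- thetas * pi / 180
  proj <- outer(pts[, 2], cos(th)) - outer(pts[, 1], sin(th))
  bins <- floor(proj / rho_step)
  rng <- range(bins)
  rhos <- rng[1]:rng[2]
  H <- vapply(seq_along(thetas), function(j)
    tabulate(bins[, j] - rng[1] + 1L, nbins = length(rhos)),
    integer(length(rhos)))
  list(H = H, thetas = thetas, rhos = rhos * rho_step)
}

#' Estimate the rotation angle of a rectangle-like edge map
#'
#' For each candidate angle the extent (count of occupied distance bins) of
#' the Hough accumulator at that angle is computed. A rectangle-like object
#' has its smallest extent at the object's own axis orientation, where the
#' extent curve `w |cos(theta - A)| + h |sin(theta - A)|` forms a sharp
#' V-shaped cusp. Within a +/-45 degree window that cusp is the only
#' interior local minimum (the competing minimum along the short axis lies
#' 90 degrees away), so the estimate is the interior local minimum of the
#' extent curve; the raw window argmin is used only as a fallback when no
#' interior minimum exists. Ties are broken toward the smallest magnitude
#' angle. The estimate is only reliable when the whole body lies inside the
#' edge map; [refine_roi()] therefore estimates on an enlarged crop.
#'
#' @param edges binary edge matrix with at least 20 edge pixels.
#' @param theta_range search range in degrees (default c(-45, 45)).
#' @param theta_step angle step in degrees (default 1).
#' @param rho_step distance bin width in px (default 1).
#' @return estimated angle in degrees (positive = counter-clockwise on
#'   screen).
#' @export
estimate_rotation <- function(edges, theta_range = c(-45, 45), theta_step = 1,
                              rho_step = 1) {
  if (sum(edges != 0) < 20L)
    stop("insufficient edges for rotation estimate (need >= 20 edge pixels)")
  thetas <- seq(theta_range[1], theta_range[2], by = theta_step)
  ext <- hough_extents(edges, thetas, rho_step)
  n <- length(ext)
  i <- 2:(n - 1)
  loc <- i[ext[i] <= ext[i - 1] & ext[i] <= ext[i + 1]]
  cand <- if (length(loc)) loc[ext[loc] == min(ext[loc])] else
    which(ext == min(ext))
  cand <- cand[order(abs(thetas[cand]), thetas[cand])]
  thetas[cand[1]]
}

#' Counter-rotate an ROI by an estimated angle
#'
#' Adds the estimated rotation to the box angle so that re-extracted pixels
#' ([extract_roi()]) present the vertebral body axis-aligned.
#'
#' @param roi a [roi_box()].
#' @param angle estimated rotation in degrees (|angle| <= 45).
#' @return the adjusted [roi_box()].
#' @export
derotate_roi <- function(roi, angle) {
  stopifnot(abs(angle) <= 45)
  roi_box(roi$center, roi$lx, roi$ly, angle = roi$angle + angle)
}

#' Edge projection profiles of an ROI crop
#'
#' @param edges binary edge matrix (the crop's edge map).
#' @return list with `Px` (edge counts per column, length `lx`) and `Py`
#'   (edge counts per row, length `ly`).
#' @export
projection_profiles <- function(edges) {
  list(Px = colSums(edges != 0), Py = rowSums(edges != 0))
}

# one side test: does the profile max over the interior-to-border interval
# exceed alpha times the central value? (interval excludes 1 border pixel)
side_contains_edge <- function(p, side, alpha) {
  n <- length(p)
  ctr <- max(2L, round(n / 2))
  idx <- if (side == "low") 2:(ctr - 1L) else (ctr + 1L):(n - 1L)
  max(p[idx]) >= alpha * max(p[ctr], 1)
}

#' Extend an ROI until it contains all four vertebral-body edges
#'
#' Builds edge projection profiles of the current crop and tests each side:
#' a rectangle-like body projects strong side edges near the profile ends,
#' considerably larger than the central profile value, so a side whose
#' interior-to-border maximum stays below `alpha` times the central value is
#' deemed to have the body edge outside the ROI, and the ROI is extended
#' outward on that side by a step of `step_frac` of the original size. The
#' test repeats on the re-cropped region up to a maximum total extension of
#' `max_extend` per side. The operation is idempotent: applied to its own
#' output it makes no further change.
#'
#' @param image the source [image2d()] (re-cropping after each extension
#'   needs the image, not just one edge map).
#' @param roi a [roi_box()] (extension happens along its rotated axes).
#' @param alpha side-test multiplier, > 1 (default 1.5).
#' @param step_frac extension step as a fraction of the original `lx`/`ly`
#'   (default 0.1).
#' @param max_extend maximum total extension per side as a fraction of the
#'   original size (default 0.5).
#' @param sigma Canny smoothing passed to [detect_edges()].
#' @return the adjusted [roi_box()]; extensions that would exceed the image
#'   bounds are clamped with a warning.
#' @export
adjust_boundaries <- function(image, roi, alpha = 1.5, step_frac = 0.1,
                              max_extend = 0.5, sigma = 1.4) {
  stopifnot(alpha > 1)
  img <- if (inherits(image, "vertseg_image")) image$pixels else as.matrix(image)
  lx0 <- roi$lx; ly0 <- roi$ly
  dx <- ceiling(step_frac * lx0); dy <- ceiling(step_frac * ly0)
  ext <- c(left = 0, right = 0, up = 0, down = 0)
  clamped <- FALSE
  for (iter in 1:25) {
    crop <- extract_roi(img, roi)
    edges <- detect_edges(crop, sigma = sigma)
    pr <- projection_profiles(edges)
    ok <- c(left  = side_contains_edge(pr$Px, "low", alpha),
            right = side_contains_edge(pr$Px, "high", alpha),
            up    = side_contains_edge(pr$Py, "low", alpha),
            down  = side_contains_edge(pr$Py, "high", alpha))
    grow <- c(left  = !ok["left"]  && ext["left"]  + dx <= max_extend * lx0,
              right = !ok["right"] && ext["right"] + dx <= max_extend * lx0,
              up    = !ok["up"]    && ext["up"]    + dy <= max_extend * ly0,
              down  = !ok["down"]  && ext["down"]  + dy <= max_extend * ly0)
    names(grow) <- c("left", "right", "up", "down")
    if (!any(grow)) break
    ax <- roi_axes(roi$angle)
    add_x <- (grow["left"] + grow["right"]) * dx
    add_y <- (grow["up"] + grow["down"]) * dy
    shift <- (grow["right"] - grow["left"]) * dx / 2 * ax$x +
             (grow["down"] - grow["up"]) * dy / 2 * ax$y
    cand <- roi_box(roi$center + shift, roi$lx + add_x, roi$ly + add_y,
                    angle = roi$angle)
    # clamp: keep the (rotated) box inside the image
    pg <- roi_polygon(cand)
    if (min(pg[, 1]) < 1 || min(pg[, 2]) < 1 ||
        max(pg[, 1]) > nrow(img) || max(pg[, 2]) > ncol(img)) {
      clamped <- TRUE
      break
    }
    roi <- cand
    ext <- ext + c(grow["left"], grow["right"], grow["up"], grow["down"]) *
      c(dx, dx, dy, dy)
  }
  if (clamped)
    warning("ROI extension clamped at the image bounds")
  attr(roi, "extension") <- ext
  roi
}

#' Full per-ROI refinement: rotation estimate, counter-rotation, extension
#'
#' Runs [detect_edges()] + [estimate_rotation()] on the crop, counter-rotates
#' the box ([derotate_roi()]), then extends it with [adjust_boundaries()]
#' (rotation first: the rectangle assumption behind the projection tests
#' requires axis alignment).
#'
#' @param image the [image2d()].
#' @param roi a [roi_box()].
#' @param alpha,step_frac,max_extend see [adjust_boundaries()].
#' @param sigma Canny smoothing in px.
#' @param expand factor by which the crop used for rotation estimation is
#'   enlarged (default 1.3), so that a body rotated up to ~30 degrees still
#'   fits inside the estimation window.
#' @return the refined [roi_box()] (with an `"extension"` attribute). If
#'   rotation estimation fails for lack of edges, the angle is kept and a
#'   warning is issued.
#' @export
refine_roi <- function(image, roi, alpha = 1.5, step_frac = 0.1,
                       max_extend = 0.5, sigma = 1.4, expand = 1.3) {
  est_roi <- roi_box(roi$center, roi$lx * expand, roi$ly * expand,
                     angle = roi$angle)
  crop <- extract_roi(image, est_roi)
  ang <- tryCatch(estimate_rotation(detect_edges(crop, sigma = sigma)),
                  error = function(e) {
                    warning("rotation estimate skipped: ", conditionMessage(e))
                    0
                  })
  roi <- derotate_roi(roi, ang)
  adjust_boundaries(image, roi, alpha = alpha, step_frac = step_frac,
                    max_extend = max_extend, sigma = sigma)
}
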