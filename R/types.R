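#' @useDynLib vertseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd kmeans lm median
NULL

# Coordinate convention used throughout the package: (row, col), 1-based in R,
# row increases downward (superior -> inferior). Angles are in degrees,
# positive = counter-clockwise on screen (top of the object tilts left).

#' 2-D grayscale image
#'
#' Container for a single sagittal slice: a non-negative intensity raster plus
#' optional physical metadata. All downstream decisions are made on relative
#' intensities, so images are typically normalized to `[0, 1]` on load.
#'
#' @param pixels numeric matrix, at least 32 x 32, finite and non-negative.
#' @param pixel_spacing in-plane pixel size in mm (default 0.39).
#' @param slice_thickness slice thickness in mm (default 3).
#' @param normalize rescale intensities to `[0, 1]` (default `FALSE`; readers
#'   normalize on load).
#' @return an object of class `vertseg_image`.
#' @export
image2d <- function(pixels, pixel_spacing = 0.39, slice_thickness = 3.0,
                    normalize = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 32L || ncol(pixels) < 32L)
    stop("image must be at least 32x32, got ", nrow(pixels), "x", ncol(pixels))
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values")
  if (min(pixels) < 0)
    stop("image intensities must be non-negative")
  if (normalize) pixels <- normalize01(pixels)
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness),
    class = "vertseg_image")
}

normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

#' @export
print.vertseg_image <- function(x, ...) {
  cat(sprintf("<vertseg_image> %d x %d px, spacing %.3g mm, thickness %.3g mm\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing,
              x$slice_thickness))
  invisible(x)
}

as_image2d <- function(x, ...) {
  if (inherits(x, "vertseg_image")) x else image2d(x, ...)
}

#' Rectangular region of interest
#'
#' An axis-aligned-then-rotatable rectangle locating one vertebral body. The
#' box is stored unrotated (center, width `lx`, height `ly`) plus an angle;
#' pixel extraction resamples the rotated rectangle by bilinear interpolation
#' (see [extract_roi()]).
#'
#' @param center numeric `(row, col)` center, may be fractional.
#' @param lx,ly width and height in pixels (each at least 8).
#' @param angle rotation in degrees, counter-clockwise on screen, in
#'   `(-90, 90]`.
#' @return an object of class `vertseg_roi`.
#' @export
roi_box <- function(center, lx, ly, angle = 0) {
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center)))
    stop("center must be a finite (row, col) pair")
  if (lx < 8 || ly < 8) stop("ROI must be at least 8x8 (lx >= 8, ly >= 8)")
  if (angle <= -90 || angle > 90) stop("angle must lie in (-90, 90]")
  structure(list(center = center, lx = as.numeric(lx), ly = as.numeric(ly),
                 angle = as.numeric(angle)),
            class = "vertseg_roi")
}

#' @export
print.vertseg_roi <- function(x, ...) {
  cat(sprintf("<vertseg_roi> center (%.1f, %.1f), %g x %g px, angle %.1f deg\n",
              x$center[1], x$center[2], x$lx, x$ly, x$angle))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param pixels 0/1 (or logical) matrix, same shape as the source image.
#' @param label vertebra index, 1 = most superior detected body.
#' @return an object of class `vertseg_mask`.
#' @export
seg_mask <- function(pixels, label = 1L) {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) pixels <- pixels * 1L
  storage.mode(pixels) <- "integer"
  if (!all(pixels %in% c(0L, 1L))) stop("mask values must be 0/1")
  structure(list(pixels = pixels, label = as.integer(label)),
            class = "vertseg_mask")
}

#' @export
print.vertseg_mask <- function(x, ...) {
  cat(sprintf("<vertseg_mask> %d x %d px, label %d, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$label, sum(x$pixels)))
  invisible(x)
}

#' Four-sided vertebra boundary contour
#'
#' Ordered per-side point lists (each an n x 2 matrix of subpixel
#' `(row, col)`). Concatenating upper (left to right), right (top to bottom),
#' lower (right to left) and left (bottom to top) yields a closed polygon.
#'
#' @param upper,right,lower,left n x 2 point matrices in traversal order.
#' @param closed logical closure flag.
#' @return an object of class `vertseg_contour`.
#' @export
boundary_contour <- function(upper, right, lower, left, closed = TRUE) {
  sides <- list(upper = upper, right = right, lower = lower, left = left)
  for (nm in names(sides)) {
    s <- as.matrix(sides[[nm]])
    if (ncol(s) != 2L) stop("side '", nm, "' must be an n x 2 (row, col) matrix")
    sides[[nm]] <- s
  }
  structure(c(sides, list(closed = closed)), class = "vertseg_contour")
}

#' Closed polygon of a contour
#'
#' @param contour a [boundary_contour()].
#' @return an n x 2 matrix of `(row, col)` vertices traversed clockwise on
#'   screen (upper, right, lower reversed, left reversed).
#' @export
contour_polygon <- function(contour) {
  stopifnot(inherits(contour, "vertseg_contour"))
  lower <- contour$lower[rev(seq_len(nrow(contour$lower))), , drop = FALSE]
  left  <- contour$left[rev(seq_len(nrow(contour$left))), , drop = FALSE]
  poly <- rbind(contour$upper, contour$right, lower, left)
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-9)
  poly[keep, , drop = FALSE]
}

# round half away from zero (rasterization convention)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Unit vectors (as (row, col) deltas) of the local x- and y-axes of a box
# rotated by `angle` degrees CCW-on-screen.
roi_axes <- function(angle) {
  a <- angle * pi / 180
  list(x = c(-sin(a), cos(a)), y = c(cos(a), sin(a)))
}

# Map ROI-local offsets (u right, v down, in the rotated frame) to image
# (row, col) offsets.
roi_local_to_image <- function(u, v, angle) {
  a <- angle * pi / 180
  cbind(row = -u * sin(a) + v * cos(a), col = u * cos(a) + v * sin(a))
}

# Bilinear sampling of matrix `img` at fractional (r, c); coordinates are
# clamped to the image border.
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H)
  c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1)
  i10 <- cbind(r0 + 1, c0); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i01] * (1 - fr) * fc +
    img[i10] * fr * (1 - fc) + img[i11] * fr * fc
}

#' Extract ROI pixels
#'
#' Resamples the (possibly rotated) rectangle of a [roi_box()] from an image
#' by bilinear interpolation. The returned crop has `ly` rows and `lx` cols
#' (rounded) and presents the box contents axis-aligned: if the imaged object
#' is rotated by the box angle, the crop shows it upright.
#'
#' @param image a [image2d()] (or plain matrix).
#' @param roi a [roi_box()].
#' @return numeric matrix of size `round(ly) x round(lx)`.
#' @export
extract_roi <- function(image, roi) {
  img <- if (inherits(image, "vertseg_image")) image$pixels else as.matrix(image)
  lx <- max(2L, as.integer(round(roi$lx)))
  ly <- max(2L, as.integer(round(roi$ly)))
  u <- seq_len(lx) - (lx + 1) / 2
  v <- seq_len(ly) - (ly + 1) / 2
  uu <- rep(u, each = ly)
  vv <- rep(v, times = lx)
  off <- roi_local_to_image(uu, vv, roi$angle)
  vals <- bilinear_sample(img, roi$center[1] + off[, 1], roi$center[2] + off[, 2])
  matrix(vals, nrow = ly, ncol = lx)
}

# Integer-grid crop (no interpolation) of an axis-aligned ROI; used for
# correlation templates where exact pixel values matter.
crop_roi_pixels <- function(image, roi) {
  img <- if (inherits(image, "vertseg_image")) image$pixels else as.matrix(image)
  lx <- as.integer(round(roi$lx)); ly <- as.integer(round(roi$ly))
  r0 <- as.integer(round_half_up(roi$center[1])) - floor(ly / 2)
  c0 <- as.integer(round_half_up(roi$center[2])) - floor(lx / 2)
  rows <- r0:(r0 + ly - 1L); cols <- c0:(c0 + lx - 1L)
  if (rows[1] < 1L || cols[1] < 1L || rows[ly] > nrow(img) || cols[lx] > ncol(img))
    stop("ROI crop exits the image")
  img[rows, cols, drop = FALSE]
}

# polygon corner points of a rotated roi, clockwise
roi_polygon <- function(roi) {
  hx <- roi$lx / 2; hy <- roi$ly / 2
  u <- c(-hx, hx, hx, -hx); v <- c(-hy, -hy, hy, hy)
  off <- roi_local_to_image(u, v, roi$angle)
  cbind(row = roi$center[1] + off[, 1], col = roi$center[2] + off[, 2])
}
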