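# ROI detection: one user box on one vertebral body -> all vertebral bodies.
#
# The match score is zero-mean normalized cross-correlation (ZNCC): at every
# position the template (the user crop) is compared with the equally sized
# patch centered there; scores lie in [-1, 1] and are invariant to affine
# intensity changes of either operand. Cross products are computed by FFT,
# local patch moments by integral images, so the map is exact up to floating
# round-off.

# cyclic 2-D cross products of image with a zero-mean template, "valid" part
fft_cross_valid <- function(img, t0) {
  H <- nrow(img); W <- ncol(img); m <- nrow(t0); n <- ncol(t0)
  P <- stats::nextn(H + m - 1L); Q <- stats::nextn(W + n - 1L)
  A <- matrix(0, P, Q); A[1:H, 1:W] <- img
  B <- matrix(0, P, Q); B[m:1, n:1] <- t0  # flipped kernel -> correlation
  C <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P * Q)
  C[m:(H), n:(W), drop = FALSE][seq_len(H - m + 1L), seq_len(W - n + 1L), drop = FALSE]
}

# sliding-window sums over m x n windows via integral image; result indexed by
# window top-left corner
window_sums <- function(img, m, n) {
  cs <- apply(apply(img, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0, H + 1L, W + 1L)
  pad[2:(H + 1L), 2:(W + 1L)] <- cs
  i2 <- (m + 1L):(H + 1L); i1 <- i2 - m
  j2 <- (n + 1L):(W + 1L); j1 <- j2 - n
  pad[i2, j2] - pad[i1, j2] - pad[i2, j1] + pad[i1, j1]
}

#' Correlation map between a template and every image position
#'
#' Computes the zero-mean normalized cross-correlation between `template` and
#' the equally sized patch centered at each pixel. Border positions where the
#' patch would exit the image are marked suppressed and excluded from all
#' peak queries, as are near-constant patches (undefined correlation, score
#' set to 0).
#'
#' @param image an [image2d()] or matrix.
#' @param template numeric matrix strictly smaller than the image, with
#'   nonzero intensity variance.
#' @return a `vertseg_cmap`: list with `scores` (same shape as the image,
#'   values in `[-1, 1]`), `suppressed` (logical raster) and
#'   `template_center` (row, col of the template pixel anchored at each
#'   position).
#' @export
compute_correlation_map <- function(image, template) {
  img <- if (inherits(image, "vertseg_image")) image$pixels else as.matrix(image)
  tpl <- as.matrix(template)
  m <- nrow(tpl); n <- ncol(tpl)
  if (m >= nrow(img) || n >= ncol(img))
    stop("template must be strictly smaller than the image")
  t0 <- tpl - mean(tpl)
  sst <- sum(t0^2)
  if (sst <= .Machine$double.eps * length(tpl))
    stop("constant template: correlation is undefined")
  N <- m * n
  cross <- fft_cross_valid(img, t0)
  s1 <- window_sums(img, m, n)
  s2 <- window_sums(img * img, m, n)
  varp <- pmax(s2 - s1^2 / N, 0)
  denom <- sqrt(varp * sst)
  ok <- denom > 1e-12 * N
  sc <- matrix(0, nrow(cross), ncol(cross))
  sc[ok] <- cross[ok] / denom[ok]
  sc <- pmin(pmax(sc, -1), 1)

  H <- nrow(img); W <- ncol(img)
  cr <- floor(m / 2) + 1L; cc <- floor(n / 2) + 1L
  scores <- matrix(0, H, W)
  suppressed <- matrix(TRUE, H, W)
  rows <- cr:(cr + H - m); cols <- cc:(cc + W - n)
  scores[rows, cols] <- sc
  suppressed[rows, cols] <- !ok
  structure(list(scores = scores, suppressed = suppressed,
                 template_center = c(cr, cc), template_dim = c(m, n)),
            class = "vertseg_cmap")
}

# argmax over unsuppressed scores; ties broken by smallest row, then smallest
# column. Optional window restricts the query. Returns NULL if empty.
cmap_argmax <- function(scores, suppressed, window = NULL) {
  if (!is.null(window)) {
    rows <- window$rows; cols <- window$cols
    sub <- scores[rows, cols, drop = FALSE]
    subsup <- suppressed[rows, cols, drop = FALSE]
  } else {
    rows <- seq_len(nrow(scores)); cols <- seq_len(ncol(scores))
    sub <- scores; subsup <- suppressed
  }
  if (all(subsup)) return(NULL)
  sub[subsup] <- -Inf
  mx <- max(sub)
  idx <- which(sub == mx, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(pos = c(rows[idx[1, 1]], cols[idx[1, 2]]), score = mx)
}

# suppress the lx/3 x ly/3 neighborhood (side length reading) around a peak
suppress_neighborhood <- function(suppressed, pos, lx, ly) {
  hh <- max(1L, floor(ly / 6)); hw <- max(1L, floor(lx / 6))
  r <- as.integer(round_half_up(pos[1])); c <- as.integer(round_half_up(pos[2]))
  rows <- max(1L, r - hh):min(nrow(suppressed), r + hh)
  cols <- max(1L, c - hw):min(ncol(suppressed), c + hw)
  suppressed[rows, cols] <- TRUE
  suppressed
}

#' Find all vertebral-body centers from a correlation map
#'
#' Iterative peak search with neighborhood suppression. The global peak `p1`
#' is the user's vertebra; after suppressing its `lx/3 x ly/3` neighborhood
#' the next closest vertebral body `p2` (the nearest of the strongest
#' remaining peaks) gives the reference distance `d = |p1 - p2|`.
#' Subsequent centers are searched inside `lx x ly` windows centered at the
#' last-found center offset by the `p1 -> p2` displacement (of magnitude `d`,
#' vertical on an upright spine), alternating outward in both directions.
#' Search in a direction stops when the window leaves the image or the window
#' peak falls below `beta` times the score of `p2`.
#'
#' @param cmap a [compute_correlation_map()] result.
#' @param roi the user [roi_box()].
#' @param max_bodies maximum number of bodies to accept (default 8).
#' @param beta acceptance threshold as a fraction of `score(p2)`
#'   (default 0.6).
#' @param min_second minimum absolute score for `p2`; below it the image is
#'   declared to contain a single detectable vertebra (default 0.6).
#' @return a `vertseg_detection`: list with `vb_centers` (n x 2 matrix,
#'   superior to inferior), `d`, `user_index`, `scores`, `disc_centers`
#'   (NULL until [refine_with_discs()]), `step` (the inter-body displacement
#'   vector used).
#' @export
find_vertebra_centers <- function(cmap, roi, max_bodies = 8L, beta = 0.6,
                                  min_second = 0.6) {
  stopifnot(inherits(cmap, "vertseg_cmap"))
  scores <- cmap$scores
  sup <- cmap$suppressed
  lx <- roi$lx; ly <- roi$ly
  H <- nrow(scores); W <- ncol(scores)

  p1 <- cmap_argmax(scores, sup)
  if (is.null(p1)) stop("correlation map is fully suppressed")
  sup <- suppress_neighborhood(sup, p1$pos, lx, ly)
  # p2 is the next *closest* vertebral body: among the strongest remaining
  # correlation peaks (iterative argmax + suppression on a scratch mask),
  # take the nearest non-degenerate one. On a stack of identical bodies this
  # is simply the second-highest peak; when bodies differ slightly (relative
  # rotation, size jitter) a more distant body can outscore the adjacent
  # one, which would corrupt the reference distance.
  cand <- list()
  scratch <- sup
  for (j in 1:6) {
    pk <- cmap_argmax(scores, scratch)
    if (is.null(pk)) break
    if (length(cand) > 0L && pk$score < max(0.6 * cand[[1]]$score, min_second))
      break
    if (pk$score < min_second) break
    cand[[length(cand) + 1L]] <- pk
    scratch <- suppress_neighborhood(scratch, pk$pos, lx, ly)
  }
  dmin <- max(lx, ly) / 2
  dists <- vapply(cand, function(p) sqrt(sum((p1$pos - p$pos)^2)), numeric(1))
  valid <- which(dists >= dmin)
  if (length(cand) == 0L || length(valid) == 0L) {
    if (length(cand) == 0L)
      stop("single vertebra detected: no second correlation peak above ",
           min_second)
    stop("degenerate reference distance: d = ", round(min(dists), 2), " < ",
         dmin)
  }
  p2 <- cand[[valid[which.min(dists[valid])]]]
  d <- sqrt(sum((p1$pos - p2$pos)^2))
  sup <- suppress_neighborhood(sup, p2$pos, lx, ly)

  # spine-axis step vector, oriented downward (rows increase)
  step <- p2$pos - p1$pos
  if (step[1] < 0) step <- -step

  centers <- rbind(p1$pos, p2$pos)
  cscores <- c(p1$score, p2$score)
  thresh <- beta * p2$score
  hw <- floor(lx / 2); hh <- floor(ly / 2)

  for (dir in c(1, -1)) {
    repeat {
      if (nrow(centers) >= max_bodies) break
      last <- if (dir > 0) centers[which.max(centers[, 1]), ]
              else centers[which.min(centers[, 1]), ]
      target <- last + dir * step
      r0 <- round_half_up(target[1]); c0 <- round_half_up(target[2])
      rows <- (r0 - hh):(r0 + hh); cols <- (c0 - hw):(c0 + hw)
      if (rows[1] < 1 || cols[1] < 1 || rows[length(rows)] > H ||
          cols[length(cols)] > W)
        break  # window leaves the image
      pk <- cmap_argmax(scores, sup, window = list(rows = rows, cols = cols))
      if (is.null(pk) || pk$score < thresh) break
      centers <- rbind(centers, pk$pos)
      cscores <- c(cscores, pk$score)
      sup <- suppress_neighborhood(sup, pk$pos, lx, ly)
    }
  }

  ord <- order(centers[, 1], centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  cscores <- cscores[ord]
  dimnames(centers) <- list(NULL, c("row", "col"))
  user_index <- which(centers[, 1] == p1$pos[1] & centers[, 2] == p1$pos[2])[1]
  structure(list(vb_centers = centers, disc_centers = NULL, d = d,
                 user_index = user_index, scores = cscores, step = step),
            class = "vertseg_detection")
}

#' @export
print.vertseg_detection <- function(x, ...) {
  cat(sprintf("<vertseg_detection> %d vertebral bodies, d = %.1f px, user body #%d\n",
              nrow(x$vb_centers), x$d, x$user_index))
  invisible(x)
}

#' Refine horizontal body positions with intervertebral-disc correlation
#'
#' A disc template (width `lx`, height `disc_height_frac * ly`) is cut
#' immediately above the user's vertebra ROI, and disc centers are detected
#' by the same correlation peak search. For each vertebral body, if its
#' column differs from the column of the surrounding discs (mean of the
#' adjacent discs found within `0.75 d`) by more than 10% of `ly`, the body
#' column is replaced by the disc column; rows are unchanged.
#'
#' @param image the [image2d()].
#' @param result a `vertseg_detection` with at least two bodies.
#' @param roi the user [roi_box()].
#' @param disc_height_frac disc template height as a fraction of `ly`
#'   (default 0.5).
#' @param threshold_frac correction threshold as a fraction of `ly`
#'   (default 0.1).
#' @param beta,min_second,max_bodies passed to the disc peak search.
#' @return the detection result with corrected `vb_centers`, populated
#'   `disc_centers` and a `corrected` logical vector. If the disc template
#'   would exit the image (or disc detection fails), the input is returned
#'   unchanged with a warning.
#' @export
refine_with_discs <- function(image, result, roi, disc_height_frac = 0.5,
                              threshold_frac = 0.1, beta = 0.6,
                              min_second = 0.6, max_bodies = 16L) {
  stopifnot(inherits(result, "vertseg_detection"))
  if (nrow(result$vb_centers) < 2L)
    stop("disc refinement needs at least two detected bodies")
  img <- if (inherits(image, "vertseg_image")) image$pixels else as.matrix(image)
  lx <- roi$lx; ly <- roi$ly
  h <- max(4L, as.integer(round(disc_height_frac * ly)))
  user <- result$vb_centers[result$user_index, ]
  disc_center <- c(user[1] - round(ly / 2) - h / 2, user[2])
  disc_roi <- roi_box(disc_center, lx = lx, ly = h)
  tpl <- try(crop_roi_pixels(img, disc_roi), silent = TRUE)
  if (inherits(tpl, "try-error")) {
    warning("disc template exits the image; disc refinement skipped")
    return(result)
  }
  discs <- try({
    dmap <- compute_correlation_map(img, tpl)
    find_vertebra_centers(dmap, disc_roi, max_bodies = max_bodies,
                          beta = beta, min_second = min_second)
  }, silent = TRUE)
  if (inherits(discs, "try-error")) {
    warning("disc detection failed; disc refinement skipped: ",
            attr(discs, "condition")$message)
    return(result)
  }
  dc <- discs$vb_centers
  centers <- result$vb_centers
  corrected <- logical(nrow(centers))
  # per-body discrepancy between the surrounding-disc column and the body
  # column; the shared median absorbs any constant offset of the disc chain
  # (e.g. the disc-template cut position on a globally tilted spine), so
  # only relative outliers are corrected. On an upright spine the median is
  # ~0 and this is the plain body-vs-disc column comparison.
  # a body's surrounding-disc column is unbiased (even on a tilted spine)
  # only when discs on both sides are seen; one-sided means are offset by
  # ~(d/2)*sin(tilt) and are not used
  disc_col <- rep(NA_real_, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    near <- which(abs(dc[, 1] - centers[i, 1]) <= 0.75 * result$d)
    above <- near[dc[near, 1] < centers[i, 1]]
    below <- near[dc[near, 1] > centers[i, 1]]
    if (length(above) > 0L && length(below) > 0L)
      disc_col[i] <- mean(c(mean(dc[above, 2]), mean(dc[below, 2])))
  }
  delta <- disc_col - centers[, 2]
  med <- stats::median(delta, na.rm = TRUE)
  if (is.finite(med)) {
    for (i in seq_len(nrow(centers))) {
      if (is.na(delta[i])) next
      if (abs(delta[i] - med) > threshold_frac * ly) {
        centers[i, 2] <- disc_col[i] - med
        corrected[i] <- TRUE
      }
    }
  }
  result$vb_centers <- centers
  result$disc_centers <- dc
  result$corrected <- corrected
  result
}
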