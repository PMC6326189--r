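# Quantitative evaluation: Dice similarity, voxel counts, physical volume,
# detection error.

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined to
#' have DSC 1 (perfect agreement on "nothing to segment").
#'
#' @param a,b [seg_mask()] objects (or 0/1 matrices) of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  pa <- if (inherits(a, "vertseg_mask")) a$pixels else as.matrix(a)
  pb <- if (inherits(b, "vertseg_mask")) b$pixels else as.matrix(b)
  if (!all(dim(pa) == dim(pb)))
    stop("mask shape mismatch: ", paste(dim(pa), collapse = "x"), " vs ",
         paste(dim(pb), collapse = "x"))
  na <- sum(pa != 0); nb <- sum(pb != 0)
  if (na + nb == 0) return(1.0)
  2 * sum(pa != 0 & pb != 0) / (na + nb)
}

#' Physical volume of a mask
#'
#' One slice contributes `foreground voxels * spacing^2 * thickness` mm^3.
#'
#' @param m a [seg_mask()] or 0/1 matrix.
#' @param spacing in-plane pixel spacing in mm (> 0).
#' @param thickness slice thickness in mm (> 0).
#' @return volume in mm^3.
#' @export
mask_volume <- function(m, spacing = 0.39, thickness = 3.0) {
  stopifnot(spacing > 0, thickness > 0)
  px <- if (inherits(m, "vertseg_mask")) m$pixels else as.matrix(m)
  sum(px != 0) * spacing^2 * thickness
}

#' Detection error between predicted and reference centers
#'
#' Centers are matched by vertical rank (the stacking invariant makes
#' bipartite matching unnecessary); the error is the mean Euclidean pixel
#' distance over matched pairs. Surplus centers on either side are counted
#' as failures (misses/spurious detections), not folded into the distance.
#'
#' @param pred_centers,true_centers n x 2 `(row, col)` matrices.
#' @return list with `mean_error` (px, over matched pairs), `n_matched`,
#'   `n_missed` (reference bodies without a prediction), `n_spurious`
#'   (predictions without a reference), `per_pair` distances.
#' @export
detection_error <- function(pred_centers, true_centers) {
  p <- as.matrix(pred_centers); t <- as.matrix(true_centers)
  if (nrow(p) == 0L || nrow(t) == 0L)
    stop("detection_error needs non-empty center lists")
  p <- p[order(p[, 1]), , drop = FALSE]
  t <- t[order(t[, 1]), , drop = FALSE]
  n <- min(nrow(p), nrow(t))
  # align by vertical rank; when counts differ, match the contiguous run of
  # reference bodies closest to the predictions
  if (nrow(t) > n) {
    offs <- 0:(nrow(t) - n)
    costs <- vapply(offs, function(o)
      sum(abs(p[seq_len(n), 1] - t[seq_len(n) + o, 1])), numeric(1))
    t <- t[which.min(costs) - 1L + seq_len(n), , drop = FALSE]
  } else if (nrow(p) > n) {
    offs <- 0:(nrow(p) - n)
    costs <- vapply(offs, function(o)
      sum(abs(p[seq_len(n) + o, 1] - t[seq_len(n), 1])), numeric(1))
    p <- p[which.min(costs) - 1L + seq_len(n), , drop = FALSE]
  }
  d <- sqrt(rowSums((p - t)^2))
  list(mean_error = mean(d), n_matched = n,
       n_missed = nrow(as.matrix(true_centers)) - n,
       n_spurious = nrow(as.matrix(pred_centers)) - n,
       per_pair = d)
}

#' Evaluation report for a set of segmented vertebrae
#'
#' Per-vertebra DSC against reference masks (matched by vertical order of
#' the mask centroids), voxel counts, physical volumes, and (optionally)
#' the center detection error.
#'
#' @param pred_masks,ref_masks lists of [seg_mask()] objects.
#' @param spacing,thickness physical voxel size in mm.
#' @param pred_centers,true_centers optional center lists for
#'   [detection_error()].
#' @return a `vertseg_report` list: `per_vertebra` data frame (label, dsc,
#'   voxels, volumes), `mean_dsc`, `sd_dsc`, and `detection` (or NULL).
#' @export
eval_report <- function(pred_masks, ref_masks, spacing = 0.39, thickness = 3.0,
                        pred_centers = NULL, true_centers = NULL) {
  centroid_row <- function(m) {
    px <- if (inherits(m, "vertseg_mask")) m$pixels else as.matrix(m)
    if (sum(px) == 0) return(NA_real_)
    mean(which(px != 0, arr.ind = TRUE)[, 1])
  }
  pr <- vapply(pred_masks, centroid_row, numeric(1))
  rr <- vapply(ref_masks, centroid_row, numeric(1))
  pred_masks <- pred_masks[order(pr)]; pr <- sort(pr)
  ref_masks <- ref_masks[order(rr)]; rr <- sort(rr)
  n <- min(length(pred_masks), length(ref_masks))
  # align by vertical rank; with unequal counts pick the contiguous
  # reference (or prediction) run closest in centroid rows
  if (length(rr) > n) {
    offs <- 0:(length(rr) - n)
    costs <- vapply(offs, function(o)
      sum(abs(pr[seq_len(n)] - rr[seq_len(n) + o])), numeric(1))
    ref_masks <- ref_masks[which.min(costs) - 1L + seq_len(n)]
  } else if (length(pr) > n) {
    offs <- 0:(length(pr) - n)
    costs <- vapply(offs, function(o)
      sum(abs(pr[seq_len(n) + o] - rr[seq_len(n)])), numeric(1))
    pred_masks <- pred_masks[which.min(costs) - 1L + seq_len(n)]
  }
  rows <- lapply(seq_len(n), function(i) {
    pm <- pred_masks[[i]]; rm <- ref_masks[[i]]
    data.frame(
      vertebra = i,
      dsc = dice(pm, rm),
      voxels_pred = sum((if (inherits(pm, "vertseg_mask")) pm$pixels else pm) != 0),
      voxels_ref = sum((if (inherits(rm, "vertseg_mask")) rm$pixels else rm) != 0),
      volume_pred = mask_volume(pm, spacing, thickness),
      volume_ref = mask_volume(rm, spacing, thickness))
  })
  per <- do.call(rbind, rows)
  det <- if (!is.null(pred_centers) && !is.null(true_centers))
    detection_error(pred_centers, true_centers) else NULL
  structure(list(per_vertebra = per, mean_dsc = mean(per$dsc),
                 sd_dsc = stats::sd(per$dsc), detection = det,
                 spacing = spacing, thickness = thickness),
            class = "vertseg_report")
}

#' @export
print.vertseg_report <- function(x, ...) {
  cat(sprintf("<vertseg_report> %d vertebrae, DSC %.2f%% +/- %.2f%%\n",
              nrow(x$per_vertebra), 100 * x$mean_dsc,
              100 * ifelse(is.na(x$sd_dsc), 0, x$sd_dsc)))
  if (!is.null(x$detection))
    cat(sprintf("  detection: mean error %.2f px, %d matched, %d missed, %d spurious\n",
                x$detection$mean_error, x$detection$n_matched,
                x$detection$n_missed, x$detection$n_spurious))
  invisible(x)
}
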