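# Pipeline orchestration and configuration. One user ROI in, one mask per
# detected vertebral body out.

#' Pipeline configuration
#'
#' All tunable parameters with their defaults. The configuration is echoed
#' verbatim into every pipeline result for auditability.
#'
#' @param alpha projection side-test multiplier for ROI extension (> 1).
#' @param beta correlation-peak acceptance threshold as a fraction of the
#'   second peak's score.
#' @param delta cubic-smoothing replacement tolerance in px.
#' @param spacing_frac partition spacing as a fraction of the smaller ROI
#'   dimension (minimum 3 px applies).
#' @param k_clusters number of intensity clusters for the lateral line rules.
#' @param canny_sigma Gaussian smoothing s.d. for edge detection in px.
#' @param max_bodies maximum number of vertebral bodies to detect.
#' @param seed integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed governs phantom generation in simulation runs).
#' @param disc_refine use intervertebral-disc correlation to correct
#'   horizontal body positions.
#' @param disc_height_frac disc template height as a fraction of `ly`.
#' @param min_second_peak minimum absolute score for the second correlation
#'   peak.
#' @param step_frac,max_extend ROI extension step and cap (fractions of the
#'   original size).
#' @return a `vertseg_config` list.
#' @export
pipeline_config <- function(alpha = 1.5, beta = 0.6, delta = 3,
                            spacing_frac = 0.08, k_clusters = 10L,
                            canny_sigma = 1.4, max_bodies = 8L, seed = 0L,
                            disc_refine = TRUE, disc_height_frac = 0.5,
                            min_second_peak = 0.6, step_frac = 0.1,
                            max_extend = 0.5) {
  stopifnot(alpha > 1, beta > 0, beta < 1, delta > 0, spacing_frac > 0,
            k_clusters >= 2, canny_sigma > 0, max_bodies >= 2)
  structure(list(alpha = alpha, beta = beta, delta = delta,
                 spacing_frac = spacing_frac,
                 k_clusters = as.integer(k_clusters),
                 canny_sigma = canny_sigma, max_bodies = as.integer(max_bodies),
                 seed = as.integer(seed), disc_refine = disc_refine,
                 disc_height_frac = disc_height_frac,
                 min_second_peak = min_second_peak, step_frac = step_frac,
                 max_extend = max_extend),
            class = "vertseg_config")
}

#' Detect all vertebral bodies from one user ROI
#'
#' Convenience wrapper: template crop, correlation map, peak search, and
#' (optionally) disc-based horizontal correction.
#'
#' @param image an [image2d()].
#' @param roi the user [roi_box()].
#' @param config a [pipeline_config()].
#' @return a `vertseg_detection` (see [find_vertebra_centers()]).
#' @export
detect_vertebrae <- function(image, roi, config = pipeline_config()) {
  template <- crop_roi_pixels(image, roi)
  cmap <- compute_correlation_map(image, template)
  det <- find_vertebra_centers(cmap, roi, max_bodies = config$max_bodies,
                               beta = config$beta,
                               min_second = config$min_second_peak)
  if (config$disc_refine)
    det <- refine_with_discs(image, det, roi,
                             disc_height_frac = config$disc_height_frac,
                             beta = config$beta,
                             min_second = config$min_second_peak)
  det
}

#' Run the full segmentation pipeline
#'
#' Executes detection (one user ROI), per-ROI refinement, per-vertebra
#' segmentation, and (when reference masks are given) evaluation. Identical
#' inputs and configuration produce byte-identical masks.
#'
#' @param image an [image2d()] (or a path readable by [read_image()]).
#' @param roi the user [roi_box()] containing exactly one vertebral body.
#' @param config a [pipeline_config()].
#' @param reference optional list of reference [seg_mask()]s (or logical
#'   matrices) for evaluation.
#' @param true_centers optional reference centers for the detection error.
#' @return a `vertseg_result`: `detection`, `rois` (refined per body),
#'   `masks`, `contours`, `failures` (per-vertebra error messages, if any),
#'   `report` (a [eval_report()] or NULL), `config`.
#' @export
run_pipeline <- function(image, roi, config = pipeline_config(),
                         reference = NULL, true_centers = NULL) {
  if (is.character(image)) image <- read_image(image)
  det <- detect_vertebrae(image, roi, config)
  n <- nrow(det$vb_centers)
  rois <- vector("list", n)
  masks <- vector("list", n)
  contours <- vector("list", n)
  failures <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      ri <- roi_box(det$vb_centers[i, ], roi$lx, roi$ly)
      ri <- refine_roi(image, ri, alpha = config$alpha,
                       step_frac = config$step_frac,
                       max_extend = config$max_extend,
                       sigma = config$canny_sigma)
      seg <- segment_vertebra(image, ri, config, label = i)
      list(roi = ri, seg = seg)
    }, error = function(e)
      simpleError(paste0("vertebra ", i, ": ", conditionMessage(e))))
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- conditionMessage(res)
    } else {
      rois[[i]] <- res$roi
      masks[[i]] <- res$seg$mask
      contours[[i]] <- res$seg$contour
    }
  }
  ok <- !vapply(masks, is.null, logical(1))
  report <- NULL
  if (!is.null(reference)) {
    report <- eval_report(masks[ok], reference,
                          spacing = image$pixel_spacing,
                          thickness = image$slice_thickness,
                          pred_centers = det$vb_centers,
                          true_centers = true_centers)
  }
  structure(list(detection = det, rois = rois[ok], masks = masks[ok],
                 contours = contours[ok], failures = failures,
                 report = report, config = config),
            class = "vertseg_result")
}

#' @export
print.vertseg_result <- function(x, ...) {
  cat(sprintf("<vertseg_result> %d vertebrae segmented (%d failures)\n",
              length(x$masks), length(x$failures)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
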