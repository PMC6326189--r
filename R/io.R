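#' Read a 2-D grayscale image
#'
#' Reads PNG, TIFF, NIfTI or single-frame DICOM into an [image2d()].
#' Intensities are normalized to `[0, 1]` on load; every downstream rule in
#' the pipeline is contrast-relative, so this changes no decision.
#' Multi-slice NIfTI volumes yield one slice (default: the mid-sagittal,
#' i.e. middle, slice).
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"png"`, `"tiff"`,
#'   `"dicom"`, `"nifti"`.
#' @param slice slice index for 3-D volumes; `"mid"` (default) selects the
#'   middle slice.
#' @param pixel_spacing,slice_thickness metadata overrides in mm; when `NULL`
#'   they are taken from the file header where available (DICOM PixelSpacing /
#'   SliceThickness, NIfTI pixdim), else the defaults 0.39 / 3.
#' @return an [image2d()].
#' @export
read_image <- function(path, format = c("auto", "png", "tiff", "dicom", "nifti"),
                       slice = "mid", pixel_spacing = NULL,
                       slice_thickness = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  spacing <- pixel_spacing
  thickness <- slice_thickness
  px <- switch(format,
    png = {
      a <- try(png::readPNG(path), silent = TRUE)
      if (inherits(a, "try-error")) stop("failed to parse PNG: ", path)
      to_gray(a)
    },
    tiff = {
      a <- try(tiff::readTIFF(path), silent = TRUE)
      if (inherits(a, "try-error")) stop("failed to parse TIFF: ", path)
      to_gray(a)
    },
    nifti = {
      a <- try(RNifti::readNifti(path), silent = TRUE)
      if (inherits(a, "try-error")) stop("failed to parse NIfTI: ", path)
      pd <- RNifti::pixdim(a)
      if (is.null(spacing) && length(pd) >= 1 && pd[1] > 0) spacing <- pd[1]
      if (is.null(thickness) && length(pd) >= 3 && pd[3] > 0) thickness <- pd[3]
      arr <- as.array(a)
      if (length(dim(arr)) >= 3 && dim(arr)[3] > 1) {
        k <- if (identical(slice, "mid")) ceiling(dim(arr)[3] / 2) else slice
        if (is.null(k) || is.na(k))
          stop("3-D input with ", dim(arr)[3], " slices requires a slice index")
        arr <- arr[, , k]
      } else if (length(dim(arr)) >= 3) arr <- arr[, , 1]
      matrix(as.numeric(arr), nrow(arr), ncol(arr))  # strip NIfTI attributes
    },
    dicom = {
      d <- read_dicom_minimal(path)
      if (is.null(spacing) && !is.null(d$pixel_spacing)) spacing <- d$pixel_spacing
      if (is.null(thickness) && !is.null(d$slice_thickness)) thickness <- d$slice_thickness
      d$pixels
    })
  if (is.null(spacing)) spacing <- 0.39
  if (is.null(thickness)) thickness <- 3.0
  image2d(normalize01(px), pixel_spacing = spacing,
          slice_thickness = thickness)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext,
    png = "png", tif = "tiff", tiff = "tiff",
    dcm = "dicom", dicom = "dicom",
    nii = "nifti",
    stop("cannot guess image format from extension: ", path))
}

to_gray <- function(a) {
  if (length(dim(a)) == 3) {
    nc <- min(dim(a)[3], 3L)
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  as.matrix(a)
}

#' Write a 2-D grayscale image
#'
#' PNG and TIFF are written as 16-bit grayscale (values clamped to
#' `[0, 1]`); NIfTI stores the raster as floating point, so a
#' NIfTI round-trip through [read_image()] is bit-exact for an already
#' normalized image.
#'
#' @param image an [image2d()] or numeric matrix.
#' @param path output path (`.png`, `.tif`/`.tiff` or `.nii`).
#' @return the path, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "vertseg_image")) image$pixels else as.matrix(image)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(px, 0), 1), target = path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(px, 0), 1), path, bits.per.sample = 16L)
  } else if (ext == "nii") {
    nim <- RNifti::asNifti(px)
    if (inherits(image, "vertseg_image"))
      RNifti::pixdim(nim) <- c(image$pixel_spacing, image$pixel_spacing,
                               image$slice_thickness)[1:2]
    RNifti::writeNifti(nim, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Write a segmentation mask
#'
#' Writes a [seg_mask()] losslessly. PNG masks are stored as 0/255 grayscale
#' with the vertebra label in a `label` text chunk; NIfTI masks as 0/1
#' integer volumes. Read-back via [read_mask()] reproduces the raster
#' bit-exactly.
#'
#' @param mask a [seg_mask()].
#' @param path output path (`.png` or `.nii`).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vertseg_mask"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write mask: no such directory: ", dir)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    ok <- try(png::writePNG(mask$pixels * 1.0, target = path,
                            text = c(label = as.character(mask$label))),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write mask to ", path)
  } else if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(mask$pixels * 1L), path)
  } else stop("unsupported mask format: .", ext, " (use .png or .nii)")
  invisible(path)
}

#' Read a segmentation mask
#'
#' @param path a mask written by [write_mask()] (PNG 0/255 or NIfTI 0/1).
#' @return a [seg_mask()]; for PNG the label is recovered from the text chunk.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    label <- 1L
    info <- attr(a, "info")
    if (!is.null(info$text) && !is.null(info$text[["label"]]))
      label <- as.integer(info$text[["label"]])
    seg_mask(to_gray(a) > 0.5, label = label)
  } else if (ext == "nii") {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) > 2) arr <- arr[, , 1]
    seg_mask(arr > 0.5)
  } else stop("unsupported mask format: .", ext)
}

#' Serialize / deserialize an ROI as JSON
#'
#' Interchange format: `{"center": [r, c], "lx": ..., "ly": ..., "angle": ...}`.
#'
#' @param roi a [roi_box()].
#' @param path JSON file path.
#' @return `write_roi_json`: the path, invisibly; `read_roi_json`: a
#'   [roi_box()].
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "vertseg_roi"))
  jsonlite::write_json(list(center = roi$center, lx = roi$lx, ly = roi$ly,
                            angle = roi$angle),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_box(center = x$center, lx = x$lx, ly = x$ly,
          angle = if (is.null(x$angle)) 0 else x$angle)
}

#' Serialize a boundary contour as JSON
#'
#' Per-side point arrays (row, col) plus the closure flag.
#'
#' @param contour a [boundary_contour()].
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_contour_json <- function(contour, path) {
  stopifnot(inherits(contour, "vertseg_contour"))
  jsonlite::write_json(
    list(upper = unname(contour$upper), right = unname(contour$right),
         lower = unname(contour$lower), left = unname(contour$left),
         closed = contour$closed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_json
#' @export
read_contour_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  boundary_contour(x$upper, x$right, x$lower, x$left, closed = isTRUE(x$closed))
}

# ---------------------------------------------------------------------------
# Minimal DICOM reader: single-frame, little-endian, uncompressed pixel data,
# explicit or implicit VR. Parses only the tags the pipeline needs (Rows,
# Columns, BitsAllocated, PixelRepresentation, PixelSpacing, SliceThickness,
# RescaleSlope/Intercept, PixelData).
read_dicom_minimal <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140) stop("failed to parse DICOM (file too short): ", path)
  if (rawToChar(raw[129:132]) != "DICM")
    stop("failed to parse DICOM (no DICM magic): ", path)
  pos <- 133L
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) u16(p) + 65536 * u16(p + 2L)
  two_byte_vrs <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
                    "LT","PN","SH","SL","SS","ST","TM","UI","UL","US")
  fields <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit) {
      if (vr %in% two_byte_vrs) {
        len <- u16(pos + 6L); hdr <- 8L
      } else {
        len <- u32(pos + 8L); hdr <- 12L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("DICOM with undefined-length elements is not supported: ", path)
    dstart <- pos + hdr
    if (dstart + len - 1L > n) stop("failed to parse DICOM (truncated element): ", path)
    data <- raw[dstart:(dstart + len - 1L)]
    key <- sprintf("%04x%04x", group, elem)
    if (key %in% c("00280010", "00280011", "00280100", "00280103")) {
      fields[[key]] <- u16(dstart)
    } else if (key %in% c("00280030", "00180050", "00281052", "00281053")) {
      fields[[key]] <- as.numeric(strsplit(trimws(rawToChar(data)), "\\\\")[[1]])
    } else if (key == "7fe00010") {
      fields[[key]] <- data
      break
    }
    pos <- dstart + len
  }
  need <- c("00280010", "00280011", "7fe00010")
  if (!all(need %in% names(fields)))
    stop("failed to parse DICOM (missing Rows/Columns/PixelData): ", path)
  rows <- fields[["00280010"]]; cols <- fields[["00280011"]]
  bits <- if (!is.null(fields[["00280100"]])) fields[["00280100"]] else 16L
  signed <- isTRUE(fields[["00280103"]] == 1L)
  pd <- fields[["7fe00010"]]
  vals <- if (bits == 8) {
    as.integer(pd[seq_len(rows * cols)])
  } else {
    readBin(pd, "integer", n = rows * cols, size = 2L,
            signed = signed, endian = "little")
  }
  slope <- if (!is.null(fields[["00281053"]])) fields[["00281053"]][1] else 1
  inter <- if (!is.null(fields[["00281052"]])) fields[["00281052"]][1] else 0
  px <- matrix(vals * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  px <- px - min(px)  # keep non-negative; reader normalizes afterwards
  list(pixels = px,
       pixel_spacing = if (!is.null(fields[["00280030"]])) fields[["00280030"]][1] else NULL,
       slice_thickness = if (!is.null(fields[["00180050"]])) fields[["00180050"]][1] else NULL)
}
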