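# Independent oracles and small fixture builders, deliberately written
# without reusing any package internals.

# brute-force zero-mean normalized cross-correlation at every valid center,
# via stats::cor on the flattened patch/template
brute_force_ncc <- function(img, tpl) {
  m <- nrow(tpl); n <- ncol(tpl)
  H <- nrow(img); W <- ncol(img)
  cr <- floor(m / 2) + 1L; cc <- floor(n / 2) + 1L
  out <- matrix(NA_real_, H, W)
  tv <- as.vector(tpl)
  for (k in 1:(H - m + 1)) {
    for (l in 1:(W - n + 1)) {
      pv <- as.vector(img[k:(k + m - 1), l:(l + n - 1)])
      out[k + cr - 1L, l + cc - 1L] <- suppressWarnings(stats::cor(pv, tv))
    }
  }
  out
}

# exhaustive enumeration of all monotone (8-connected, one pixel per column)
# left-to-right paths across a band; returns the minimum total cost
brute_force_min_path_cost <- function(band) {
  h <- nrow(band); w <- ncol(band)
  best <- Inf
  recurse <- function(row, col, cost) {
    cost <- cost + band[row, col]
    if (col == w) {
      best <<- min(best, cost)
      return(invisible())
    }
    for (dr in -1:1) {
      r2 <- row + dr
      if (r2 >= 1 && r2 <= h) recurse(r2, col + 1L, cost)
    }
  }
  for (r in 1:h) recurse(r, 1L, 0)
  best
}

# set-arithmetic Dice oracle on logical vectors
dice_oracle <- function(a, b) {
  A <- which(as.vector(a) != 0); B <- which(as.vector(b) != 0)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# rasterized outline of a rectangle rotated CCW-on-screen, as an edge map
rect_edge_map <- function(w = 80, h = 52, angle = 0, dimn = 160) {
  e <- matrix(0L, dimn, dimn)
  ctr <- (dimn + 1) / 2
  tt <- seq(-1, 1, length.out = 300)
  pu <- c(tt * w / 2, rep(w / 2, 300), rev(tt) * w / 2, rep(-w / 2, 300))
  pv <- c(rep(-h / 2, 300), tt * h / 2, rep(h / 2, 300), rev(tt) * h / 2)
  a <- angle * pi / 180
  r <- round(ctr + (-pu * sin(a) + pv * cos(a)))
  cc <- round(ctr + (pu * cos(a) + pv * sin(a)))
  e[cbind(r, cc)] <- 1L
  e
}

# does a closed polygon self-intersect? O(n^2) segment pair test
polygon_is_simple <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  crosses <- function(p1, p2, p3, p4) {
    d1 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d2 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    d3 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d4 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    (d1 * d2 < -tol) && (d3 * d4 < -tol)
  }
  for (i in 1:(n - 1)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 1):jmax) {
      if (j == i + 1) next   # adjacent segments share a vertex
      if (crosses(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

# small default-geometry phantom for fast tests
test_phantom <- function(n_bodies = 4, rotations = 0, noise_sigma = 0.02,
                         seed = 1, ...) {
  generate_phantom(phantom_spec(n_bodies = n_bodies, rotations = rotations,
                                noise_sigma = noise_sigma, seed = seed, ...))
}

default_user_roi <- function(ph, index = 2, lx = 96, ly = 66) {
  roi_box(ph$truth$centers[index, ], lx, ly)
}

# minimal single-frame explicit-VR little-endian DICOM writer (fixture
# builder for the reader test; intentionally independent of the package)
write_test_dicom <- function(path, pixels, spacing = 0.39, thickness = 3) {
  px <- round(pixels)
  storage.mode(px) <- "integer"
  rows <- nrow(px); cols <- ncol(px)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem_us <- function(group, el, value) {
    u16(group); u16(el); writeBin(charToRaw("US"), con); u16(2); u16(value)
  }
  elem_ds <- function(group, el, txt) {
    if (nchar(txt) %% 2 == 1) txt <- paste0(txt, " ")
    u16(group); u16(el); writeBin(charToRaw("DS"), con); u16(nchar(txt))
    writeBin(charToRaw(txt), con)
  }
  elem_ds(0x0018, 0x0050, format(thickness))
  elem_us(0x0028, 0x0010, rows)
  elem_us(0x0028, 0x0011, cols)
  elem_ds(0x0028, 0x0030, paste0(format(spacing), "\\", format(spacing)))
  elem_us(0x0028, 0x0100, 16)   # BitsAllocated
  elem_us(0x0028, 0x0103, 0)    # unsigned
  npx <- rows * cols
  u16(0x7fe0); u16(0x0010); writeBin(charToRaw("OW"), con); u16(0)
  writeBin(as.integer(2L * npx), con, size = 4, endian = "little")
  writeBin(as.integer(t(px)), con, size = 2, endian = "little")
  invisible(path)
}
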