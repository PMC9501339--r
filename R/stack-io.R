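# Calibrated image-stack containers and I/O.
#
# Axis convention throughout the package: arrays are indexed (z, y, x) with
# z = 1 the substratum plane and z increasing away from the substratum.

#' Calibrated 3D intensity stack
#'
#' Construct a `voxel_grid`, the package's container for a confocal z-stack:
#' a 3D non-negative intensity array indexed `(z, y, x)` together with its
#' voxel calibration in micrometres. Slice `z = 1` is the substratum plane.
#'
#' @param data Numeric 3D array indexed `(z, y, x)`, non-negative. A matrix is
#'   accepted as a single-slice stack.
#' @param dx,dy Lateral pixel size in um (both > 0).
#' @param dz Axial slice spacing in um (> 0).
#'
#' @return An object of class `voxel_grid`: a list with elements `data`,
#'   `dx`, `dy`, `dz`.
#' @examples
#' vg <- voxel_grid(array(runif(5 * 8 * 8, 0, 100), c(5, 8, 8)),
#'                  dx = 0.28, dy = 0.28, dz = 1)
#' dim(vg$data)
#' @export
voxel_grid <- function(data, dx, dy, dz) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array indexed (z, y, x).")
  check_calibration(dx, dy, dz)
  d <- dim(data)
  if (d[1] < 1L || d[2] < 4L || d[3] < 4L)
    abort("stack needs at least 1 slice and 4x4 pixels per slice.")
  if (anyNA(data) || min(data) < 0)
    abort("intensities must be non-negative and free of NA.")
  structure(list(data = data, dx = dx, dy = dy, dz = dz),
            class = "voxel_grid")
}

#' Calibrated 3D foreground mask
#'
#' A `binary_grid` holds the thresholded foreground of a stack: a logical
#' array with the same shape and calibration as its source `voxel_grid`,
#' substratum at `z = 1`.
#'
#' @param mask Logical 3D array indexed `(z, y, x)` (a matrix is promoted to
#'   one slice; numeric input is coerced by `!= 0`).
#' @inheritParams voxel_grid
#'
#' @return An object of class `binary_grid` with elements `mask`, `dx`, `dy`,
#'   `dz`.
#' @export
binary_grid <- function(mask, dx, dy, dz) {
  if (is.matrix(mask)) mask <- array(mask, c(1L, dim(mask)))
  if (!is.array(mask) || length(dim(mask)) != 3L)
    abort("`mask` must be a 3D array indexed (z, y, x).")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "double"
    mask <- mask != 0
  }
  if (anyNA(mask)) abort("mask must not contain NA.")
  check_calibration(dx, dy, dz)
  structure(list(mask = mask, dx = dx, dy = dy, dz = dz),
            class = "binary_grid")
}

check_calibration <- function(dx, dy, dz) {
  for (v in list(dx = dx, dy = dy, dz = dz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort("voxel calibration dx, dy, dz must be positive finite scalars (um).")
  }
  invisible(TRUE)
}

voxel_volume <- function(g) g$dx * g$dy * g$dz

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d slices x %d x %d px | voxel %.3g x %.3g x %.3g um | intensity [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$dx, x$dy, x$dz, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_grid <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_grid> %d slices x %d x %d px | voxel %.3g x %.3g x %.3g um | %d foreground voxels (%.2f%%)\n",
              d[1], d[2], d[3], x$dx, x$dy, x$dz, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Read a calibrated grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into a [voxel_grid()]; page
#' order maps to increasing z (page 1 = substratum). RGB pages are rejected
#' unless `rgb = "luminance"` requests Rec. 709 luminance conversion, because
#' reflection-mode confocal data are single-channel.
#'
#' @param path Path to a TIFF file.
#' @param dx,dy,dz Voxel calibration in um.
#' @param rgb Either `"error"` (default, reject colour input) or
#'   `"luminance"` (convert with 0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @return A [voxel_grid()].
#' @seealso [write_stack()], [binarize()]
#' @export
read_stack <- function(path, dx, dy, dz, rgb = c("error", "luminance")) {
  rgb <- match.arg(rgb)
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file.", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (rgb == "error")
        abort("RGB TIFF pages: pass rgb = \"luminance\" to convert to grayscale.")
      0.2126 * p[, , 1] + 0.7152 * p[, , 2] + 0.0722 * p[, , 3]
    } else p
  })
  d2 <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  voxel_grid(arr, dx = dx, dy = dy, dz = dz)
}

#' Write a stack or mask as a multi-page TIFF
#'
#' `write_stack()` stores integer intensities losslessly at the chosen bit
#' depth; `write_mask()` stores a [binary_grid()] as 8-bit pages with
#' foreground 255 and background 0.
#'
#' @param stack A [voxel_grid()] with integer-valued intensities within the
#'   chosen bit depth.
#' @param path Output TIFF path.
#' @param bits Bits per sample, 8 or 16.
#'
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "voxel_grid"))
  if (!bits %in% c(8L, 16L)) abort("`bits` must be 8 or 16.")
  mx <- 2^bits - 1
  if (max(stack$data) > mx)
    abort(sprintf("intensities exceed %d; use a higher bit depth or rescale.", mx))
  if (any(stack$data != round(stack$data)))
    abort("write_stack() stores integer intensities; round or rescale first.")
  nz <- dim(stack$data)[1]
  pages <- lapply(seq_len(nz), function(z) stack$data[z, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname write_stack
#' @param mask A [binary_grid()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_grid"))
  nz <- dim(mask$mask)[1]
  pages <- lapply(seq_len(nz), function(z) (mask$mask[z, , ] * 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Threshold an intensity stack to a foreground mask
#'
#' Converts a [voxel_grid()] into a [binary_grid()]. Foreground is every voxel
#' with intensity strictly above the threshold, so an all-background stack
#' thresholded at 0 stays exactly empty. The Otsu threshold is computed once
#' over the whole stack by default, keeping metrics comparable across z; set
#' `per_slice = TRUE` for slice-wise thresholds.
#'
#' @param stack A [voxel_grid()].
#' @param method `"otsu"` (histogram-based automatic threshold, the default)
#'   or `"fixed"`.
#' @param threshold Intensity threshold, required for `method = "fixed"`.
#' @param per_slice Compute an Otsu threshold per z-slice instead of globally.
#'
#' @return A [binary_grid()] with the source shape and calibration. The
#'   threshold(s) used are attached as attribute `"threshold"`.
#' @examples
#' vg <- voxel_grid(array(c(0, 100)[1 + (runif(4 * 16 * 16) > 0.7)],
#'                        c(4, 16, 16)), 0.5, 0.5, 1)
#' bg <- binarize(vg)
#' attr(bg, "threshold")
#' @export
binarize <- function(stack, method = c("otsu", "fixed"), threshold = NULL,
                     per_slice = FALSE) {
  stopifnot(inherits(stack, "voxel_grid"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold)) abort("method = \"fixed\" requires `threshold`.")
    thr <- threshold
    mask <- stack$data > thr
  } else if (!per_slice) {
    thr <- otsu_threshold(stack$data)
    mask <- stack$data > thr
  } else {
    nz <- dim(stack$data)[1]
    thr <- vapply(seq_len(nz), function(z) otsu_threshold(stack$data[z, , ]),
                  numeric(1))
    mask <- array(FALSE, dim(stack$data))
    for (z in seq_len(nz)) mask[z, , ] <- stack$data[z, , ] > thr[z]
  }
  out <- binary_grid(mask, dx = stack$dx, dy = stack$dy, dz = stack$dz)
  attr(out, "threshold") <- thr
  out
}

# Otsu threshold on the raw intensity scale; delegates the histogram search
# to EBImage. Errors on constant input, where no threshold separates anything.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2])
    abort("no threshold separable: stack intensity is constant.")
  levels <- if (max(v) <= 255 && all(v == round(v))) 256L else 65536L
  EBImage::otsu(EBImage::Image(matrix(as.numeric(v) / rng[2], ncol = 1L)),
                range = c(rng[1] / rng[2], 1), levels = levels) * rng[2]
}
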