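# Substrate / biofilm top-surface roughness descriptors.

#' 1D roughness height profile
#'
#' A line profile of surface heights at a fixed lateral sampling interval,
#' as produced by profilometry along a scratch-perpendicular line or by
#' [extract_profile()] from a height map.
#'
#' @param heights Numeric vector of surface heights in um (>= 16 samples).
#' @param step Lateral sampling interval in um (> 0).
#' @return An object of class `roughness_profile`; `tidy()` gives a tibble
#'   of `position_um`, `height_um`.
#' @export
roughness_profile <- function(heights, step) {
  if (!is.numeric(heights) || length(heights) < 16L)
    abort("a roughness profile needs at least 16 height samples.")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    abort("`step` must be a positive scalar (um).")
  structure(list(heights = as.numeric(heights), step = step),
            class = "roughness_profile")
}

#' @export
print.roughness_profile <- function(x, ...) {
  cat(sprintf("<roughness_profile> %d samples at %.3g um pitch | R_rms %.3g um\n",
              length(x$heights), x$step, rms_roughness(x)))
  invisible(x)
}

#' @rdname roughness_profile
#' @param x A `roughness_profile`.
#' @param ... Unused.
#' @method tidy roughness_profile
#' @export
tidy.roughness_profile <- function(x, ...) {
  tibble(position_um = (seq_along(x$heights) - 1) * x$step,
         height_um = x$heights)
}

#' Write a roughness profile as two-column CSV
#'
#' @param profile A [roughness_profile()].
#' @param path Output CSV path (columns `position_um`, `height_um`).
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "roughness_profile"))
  utils::write.csv(tidy(profile), path, row.names = FALSE)
  invisible(path)
}

#' Root-mean-square roughness
#'
#' RMS deviation of the surface heights about their mean plane (no tilt
#' removal). Accepts a [height_map()], a [roughness_profile()], or a bare
#' numeric vector/matrix of heights.
#'
#' @param x Heights in one of the accepted forms.
#' @return R_rms in um.
#' @export
rms_roughness <- function(x) {
  h <- if (inherits(x, "height_map")) as.vector(x$h)
       else if (inherits(x, "roughness_profile")) x$heights
       else if (is.numeric(x)) as.vector(x)
       else abort("`x` must be a height_map, roughness_profile, or numeric.")
  if (length(h) == 0L) abort("no height samples.")
  sqrt(mean((h - mean(h))^2))
}

#' Roughness factor (effective / projected area)
#'
#' Ratio of the true (effective) surface area of a height field to its
#' projected (nominal) area. The effective area is computed by splitting each
#' grid cell between four height samples into two planar triangles and
#' summing their 3D areas — exact for piecewise-planar surfaces, so a 45
#' degree sawtooth gives exactly sqrt(2). Always >= 1, with equality only for
#' a constant (flat) field.
#'
#' @param hm A [height_map()], or a numeric height matrix with `dx`, `dy`.
#' @param dx,dy Lateral sample spacing in um (taken from the height map when
#'   one is given).
#' @return Dimensionless R_f >= 1.
#' @export
roughness_factor <- function(hm, dx = NULL, dy = NULL) {
  if (inherits(hm, "height_map")) {
    h <- hm$h; dx <- hm$dx; dy <- hm$dy
  } else if (is.matrix(hm)) {
    h <- hm
    if (is.null(dx) || is.null(dy)) abort("supply `dx` and `dy` for a bare matrix.")
  } else abort("`hm` must be a height_map or a numeric matrix.")
  d <- dim(h)
  if (d[1] < 2L || d[2] < 2L) abort("need at least a 2x2 height field.")
  # cell corners: h11 = h[i, j], h12 = h[i, j+1], h21 = h[i+1, j], h22 = h[i+1, j+1]
  h11 <- h[-d[1], -d[2]]; h12 <- h[-d[1], -1]
  h21 <- h[-1, -d[2]];    h22 <- h[-1, -1]
  # triangle (h11, h12, h22): edges (dx,0,h12-h11) and (dx,dy,h22-h11)
  a1 <- tri_area(dx, 0, h12 - h11, dx, dy, h22 - h11)
  # triangle (h11, h22, h21): edges (dx,dy,h22-h11) and (0,dy,h21-h11)
  a2 <- tri_area(dx, dy, h22 - h11, 0, dy, h21 - h11)
  eff <- sum(a1) + sum(a2)
  proj <- (d[1] - 1) * (d[2] - 1) * dx * dy
  eff / proj
}

# 0.5 * |e1 x e2| for triangles given by two edge vectors (vectorized over
# the z-components).
tri_area <- function(x1, y1, z1, x2, y2, z2) {
  cx <- y1 * z2 - z1 * y2
  cy <- z1 * x2 - x1 * z2
  cz <- x1 * y2 - y1 * x2
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Extract a line profile from a height map
#'
#' Samples surface heights by bilinear interpolation along the segment from
#' `start` to `end` (um coordinates; height sample `h[iy, ix]` sits at
#' `((ix-1) dx, (iy-1) dy)`), at a pitch of `min(dx, dy)`.
#'
#' @param hm A [height_map()].
#' @param start,end Segment endpoints `c(x, y)` in um, inside the map.
#' @return A [roughness_profile()].
#' @export
extract_profile <- function(hm, start, end) {
  stopifnot(inherits(hm, "height_map"))
  d <- dim(hm$h)
  xmax <- (d[2] - 1) * hm$dx
  ymax <- (d[1] - 1) * hm$dy
  for (p in list(start, end)) {
    if (length(p) != 2L || p[1] < 0 || p[1] > xmax || p[2] < 0 || p[2] > ymax)
      abort("profile endpoints must be c(x, y) um inside the height map.")
  }
  len <- sqrt(sum((end - start)^2))
  if (len == 0) abort("profile endpoints coincide.")
  pitch <- min(hm$dx, hm$dy)
  ns <- max(16L, floor(len / pitch) + 1L)
  tt <- seq(0, 1, length.out = ns)
  px <- start[1] + tt * (end[1] - start[1])
  py <- start[2] + tt * (end[2] - start[2])
  heights <- bilinear_sample(hm$h, px / hm$dx + 1, py / hm$dy + 1)
  roughness_profile(heights, step = len / (ns - 1L))
}

# Bilinear interpolation of matrix h at fractional (row = yi, col = xi)
# positions, clamped to the grid.
bilinear_sample <- function(h, xi, yi) {
  d <- dim(h)
  x0 <- pmin(pmax(floor(xi), 1L), d[2] - 1L); x1 <- x0 + 1L
  y0 <- pmin(pmax(floor(yi), 1L), d[1] - 1L); y1 <- y0 + 1L
  fx <- pmin(pmax(xi - x0, 0), 1); fy <- pmin(pmax(yi - y0, 0), 1)
  h00 <- h[cbind(y0, x0)]; h01 <- h[cbind(y0, x1)]
  h10 <- h[cbind(y1, x0)]; h11 <- h[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * h00 + fx * h01) + fy * ((1 - fx) * h10 + fx * h11)
}
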