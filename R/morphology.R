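# Per-stack geometric descriptors of biofilm architecture.

#' Biovolume of a foreground mask
#'
#' Total biomass volume: the number of foreground voxels multiplied by the
#' voxel volume `dx * dy * dz`.
#'
#' @param mask A [binary_grid()].
#' @return Volume in um^3 (0 for an empty mask).
#' @examples
#' m <- array(FALSE, c(2, 4, 4)); m[1, 1:2, 1:2] <- TRUE; m[2, 1:2, 1:2] <- TRUE
#' biovolume(binary_grid(m, 0.5, 0.5, 1))  # 8 voxels x 0.25 um^3
#' @export
biovolume <- function(mask) {
  stopifnot(inherits(mask, "binary_grid"))
  sum(mask$mask) * voxel_volume(mask)
}

#' Coverage fraction
#'
#' With `z` given, the fraction of pixels that are foreground in that
#' cross-section. With `z` omitted, the substratum coverage: the fraction of
#' `(y, x)` columns containing any foreground — the quantity tracked through
#' time in seasonal growth experiments.
#'
#' @param mask A [binary_grid()].
#' @param z Optional 1-based slice index.
#' @return A fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(mask, z = NULL) {
  stopifnot(inherits(mask, "binary_grid"))
  if (is.null(z)) {
    nz <- dim(mask$mask)[1]
    covered <- apply(mask$mask, c(2, 3), any)
    return(mean(covered))
  }
  nz <- dim(mask$mask)[1]
  if (length(z) != 1L || z < 1L || z > nz || z != round(z))
    abort(sprintf("slice index z must be an integer in 1..%d.", nz))
  mean(mask$mask[z, , ])
}

#' Surface area to volume ratio
#'
#' The biofilm surface area `A` is the count of foreground voxels face-adjacent
#' (6-connectivity) to at least one background or out-of-bounds voxel, each
#' weighted by one xy pixel-face area `dx * dy` — a voxel-count measure of the
#' exposed surface. Returned is `A / V` with `V` the [biovolume()].
#' `mode = "faces"` instead counts every exposed face with its own face area,
#' a stricter geometric surface estimate.
#'
#' @param mask A non-empty [binary_grid()].
#' @param mode `"voxels"` (default, pixel-count surface) or `"faces"`
#'   (exposed-face areas).
#' @return Ratio in um^-1.
#' @export
area_to_volume <- function(mask, mode = c("voxels", "faces")) {
  stopifnot(inherits(mask, "binary_grid"))
  mode <- match.arg(mode)
  m <- mask$mask
  if (!any(m)) abort("area/volume ratio undefined for an empty mask.")
  if (mode == "voxels") {
    exposed <- m & !(shift_arr(m, 1, 1L) & shift_arr(m, 1, -1L) &
                     shift_arr(m, 2, 1L) & shift_arr(m, 2, -1L) &
                     shift_arr(m, 3, 1L) & shift_arr(m, 3, -1L))
    a <- sum(exposed) * mask$dx * mask$dy
  } else {
    face_area <- c(mask$dx * mask$dy,   # z faces
                   mask$dx * mask$dz,   # y faces
                   mask$dy * mask$dz)   # x faces
    a <- 0
    for (ax in 1:3) {
      nexp <- sum(m & !shift_arr(m, ax, 1L)) + sum(m & !shift_arr(m, ax, -1L))
      a <- a + nexp * face_area[ax]
    }
  }
  a / biovolume(mask)
}

# Neighbour view of a 3D logical array: out[i] = m[i + by] along axis `ax`
# (1=z, 2=y, 3=x); out-of-bounds neighbours read as FALSE (background).
shift_arr <- function(m, ax, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  if (d[ax] < 2L) return(out)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[ax]] <- 1:(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
  else        { dst[[ax]] <- 2:d[ax];        src[[ax]] <- 1:(d[ax] - 1L) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Per-column biofilm top-height map
#'
#' For every `(y, x)` column the height of the topmost foreground voxel,
#' `h = z_top * dz` um (1-based top slice index times slice spacing), and 0
#' where the column holds no foreground. Internal voids and overhangs are
#' ignored: the map is the biofilm's outer surface as a confocal top-down
#' height field. `mode = "net"` instead returns the column-sum "net volume
#' height" `dz * n_foreground`, which counts occupied voxels regardless of
#' position.
#'
#' @param mask A [binary_grid()].
#' @param mode `"top"` (default) or `"net"`.
#' @return An object of class `height_map`: list with `h` (ny x nx matrix,
#'   um), `covered` (logical matrix), `dx`, `dy`.
#' @export
height_map <- function(mask, mode = c("top", "net")) {
  stopifnot(inherits(mask, "binary_grid"))
  mode <- match.arg(mode)
  d <- dim(mask$mask)
  if (mode == "top") {
    hz <- matrix(0L, d[2], d[3])
    for (z in seq_len(d[1])) {
      sl <- mask$mask[z, , , drop = TRUE]
      if (d[2] == 1L || d[3] == 1L) sl <- matrix(sl, d[2], d[3])
      hz[sl] <- z
    }
    h <- hz * mask$dz
  } else {
    h <- apply(mask$mask, c(2, 3), sum) * mask$dz
  }
  structure(list(h = h, covered = h > 0, dx = mask$dx, dy = mask$dy),
            class = "height_map")
}

#' Mean biofilm thickness
#'
#' Arithmetic mean of the per-column top heights. By default the mean runs
#' over every column of the imaging field (empty columns contribute h = 0);
#' `covered_only = TRUE` averages over biofilm-bearing columns only.
#'
#' @param hm A [height_map()].
#' @param covered_only Restrict to covered columns.
#' @return Mean thickness in um.
#' @export
mean_thickness <- function(hm, covered_only = FALSE) {
  stopifnot(inherits(hm, "height_map"))
  h <- thickness_values(hm, covered_only)
  if (length(h) == 0L) abort("no covered columns: mean thickness undefined.")
  mean(h)
}

thickness_values <- function(hm, covered_only) {
  if (covered_only) hm$h[hm$covered] else as.vector(hm$h)
}

#' Roughness fluctuation coefficient
#'
#' The dimensionless heterogeneity of the thickness distribution: the
#' population standard deviation of the per-column heights divided by their
#' mean, computed over the same column set as [mean_thickness()].
#'
#' @inheritParams mean_thickness
#' @return Dimensionless coefficient (0 for a perfectly flat film).
#' @export
roughness_coefficient <- function(hm, covered_only = FALSE) {
  stopifnot(inherits(hm, "height_map"))
  h <- thickness_values(hm, covered_only)
  m <- mean(h)
  if (length(h) == 0L || m <= 0)
    abort("roughness coefficient undefined: zero mean thickness.")
  sqrt(mean((h - m)^2)) / m
}

#' Box-counting fractal dimension of a 2D boundary
#'
#' Measures the complexity of the biomass/background border in a single
#' cross-section. The boundary set is every foreground pixel 4-adjacent to an
#' in-image background pixel; boxes of dyadic size `eps = 1, 2, 4, ...` up to
#' a quarter of the shorter image side are laid on a grid anchored at the
#' image origin, and the dimension is the least-squares slope of
#' `log N(eps)` against `log(1/eps)`. A smooth straight border gives D near
#' 1; a plane-filling border approaches 2. The reported value is clamped to
#' `[1, 2]`; the raw slope is kept in attribute `"raw"`.
#'
#' @param slice A 2D logical (or 0/1) matrix containing both foreground and
#'   background, at least 8 pixels on the shorter side.
#' @return The clamped dimension, with attributes `raw` (unclamped slope) and
#'   `table` (a tibble of `eps`, `n_boxes`).
#' @export
fractal_dimension_2d <- function(slice) {
  if (inherits(slice, "binary_grid")) {
    if (dim(slice$mask)[1] != 1L)
      abort("pass a single 2D cross-section, e.g. mask$mask[z, , ].")
    slice <- slice$mask[1, , ]
  }
  if (!is.matrix(slice)) abort("`slice` must be a 2D matrix.")
  if (!is.logical(slice)) slice <- slice != 0
  if (!any(slice) || all(slice))
    abort("boundary undefined: cross-section is empty or fully covered.")
  b <- boundary_pixels(slice)
  sides <- dim(slice)
  eps <- 1L
  sizes <- integer(0)
  while (eps <= min(sides) / 4) { sizes <- c(sizes, eps); eps <- eps * 2L }
  if (length(sizes) < 2L)
    abort("cross-section too small for box counting (need >= 8 px per side).")
  idx <- which(b, arr.ind = TRUE)
  n_boxes <- vapply(sizes, function(e) {
    boxes <- (idx - 1L) %/% e
    nrow(unique(boxes))
  }, numeric(1))
  fit <- lm(log(n_boxes) ~ log(1 / sizes))
  d_raw <- unname(coef(fit)[2])
  structure(min(2, max(1, d_raw)), raw = d_raw,
            table = tibble(eps = sizes, n_boxes = n_boxes))
}

# Foreground pixels with at least one in-image 4-adjacent background pixel.
boundary_pixels <- function(sl) {
  d <- dim(sl)
  bg_adj <- matrix(FALSE, d[1], d[2])
  bg <- !sl
  bg_adj[-1, ] <- bg_adj[-1, ] | bg[-d[1], ]
  bg_adj[-d[1], ] <- bg_adj[-d[1], ] | bg[-1, ]
  bg_adj[, -1] <- bg_adj[, -1] | bg[, -d[2]]
  bg_adj[, -d[2]] <- bg_adj[, -d[2]] | bg[, -1]
  sl & bg_adj
}

#' One-row morphology report for a stack
#'
#' Computes the full descriptor set for a foreground mask and returns it as a
#' one-row tibble with fixed column names: `biovolume_um3`, `coverage_pct`
#' (substratum coverage as a percentage), `area_to_volume_per_um`,
#' `mean_thickness_um`, `roughness_coefficient`, `fractal_dimension` (on the
#' cross-section `fractal_z`, NA when undefined), `hopkins_index` (on
#' aggregate centroids, NA when fewer than 10 aggregates) and
#' `aggregation_coefficient`.
#'
#' @param mask A [binary_grid()].
#' @param fractal_z Slice index for the fractal dimension (default 1, the
#'   substratum cross-section).
#' @param v_threshold Aggregate-volume threshold for the aggregation
#'   coefficient, um^3.
#' @param hopkins_m,hopkins_repeats,seed Hopkins sampling size, Monte-Carlo
#'   repeats, and RNG seed (see [hopkins_index()]).
#' @return A one-row tibble.
#' @seealso [write_report()]
#' @export
morphology_report <- function(mask, fractal_z = 1L, v_threshold = 30,
                              hopkins_m = NULL, hopkins_repeats = 99L,
                              seed = 1L) {
  stopifnot(inherits(mask, "binary_grid"))
  hm <- height_map(mask)
  empty <- !any(mask$mask)
  fd <- tryCatch(as.numeric(fractal_dimension_2d(mask$mask[fractal_z, , ])),
                 error = function(e) NA_real_)
  if (empty) {
    return(tibble(
      biovolume_um3 = 0, coverage_pct = 0, area_to_volume_per_um = NA_real_,
      mean_thickness_um = 0, roughness_coefficient = NA_real_,
      fractal_dimension = fd, hopkins_index = NA_real_,
      aggregation_coefficient = NA_real_))
  }
  ags <- label_aggregates(mask)
  cents <- tidy(ags)
  hop <- NA_real_
  if (nrow(cents) >= 10L) {
    d <- dim(mask$mask)
    pp <- point_pattern_2d(cents$centroid_x_um, cents$centroid_y_um,
                           window = c(d[3] * mask$dx, d[2] * mask$dy))
    hop <- hopkins_index(pp, m = hopkins_m, repeats = hopkins_repeats,
                         seed = seed)
  }
  tibble(
    biovolume_um3 = biovolume(mask),
    coverage_pct = 100 * coverage_fraction(mask),
    area_to_volume_per_um = area_to_volume(mask),
    mean_thickness_um = mean_thickness(hm),
    roughness_coefficient = tryCatch(roughness_coefficient(hm),
                                     error = function(e) NA_real_),
    fractal_dimension = fd,
    hopkins_index = hop,
    aggregation_coefficient = aggregation_coefficient(ags,
                                                      v_threshold = v_threshold)
  )
}

#' Write a morphology report to JSON or CSV
#'
#' @param report A tibble from [morphology_report()] (any number of rows).
#' @param path Output path; format chosen by extension `.json` or `.csv`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- if (nrow(report) == 1L) as.list(report) else report
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(report, path, row.names = FALSE)
  } else abort("unsupported report format: use .json or .csv.")
  invisible(path)
}
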