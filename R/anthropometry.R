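## Calliper-style measurements and deformation indexes from the aligned cloud.
##
## The cranial perimeter (CP) is the maximum convex-hull perimeter over a
## family of planes containing the Y direction (tilt about Y within +/-30 deg
## of horizontal, searched on a 1 deg x 2 mm grid with a +/-4 mm point slab).
## Oblique diagonals a and b are chords of that maximal slice through the
## anatomical origin at +/-30 deg azimuth from the X axis, split exactly into
## frontal and back halves by the origin — which makes AI = AAI + PAI an
## identity of this implementation.

SLICE_TILT_RANGE <- c(-30, 30)  # deg about Y
SLICE_TILT_STEP <- 1            # deg
SLICE_OFFSET_STEP <- 2          # mm
SLICE_HALF_WIDTH <- 4           # mm slab half-width
SLICE_MIN_POINTS <- 10L
SLICE_PERIMETER_TOL <- 1e-3     # relative; below this, tilts are tied
OBLIQUE_AZIMUTH <- 30           # deg from the X axis

polygon_perimeter <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - poly)^2)))
}

## TRUE when (0,0) is strictly inside a convex CCW polygon.
origin_inside <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  cr <- (nxt[, 1] - poly[, 1]) * (0 - poly[, 2]) -
        (nxt[, 2] - poly[, 2]) * (0 - poly[, 1])
  all(cr > 0) || all(cr < 0)
}

#' Maximum-perimeter cranial slice
#'
#' Searches planes containing the Y direction (normal `(sin a, 0, cos a)`,
#' tilt `a` on a 1 degree grid in \[-30, 30\], offset on a 2 mm grid spanning
#' the cloud).  Points within a +/-4 mm slab are projected into the plane and
#' wrapped with a 2D convex hull (a tape measure is a convex wrap); the plane
#' maximising the hull perimeter defines the cranial perimeter CP.
#'
#' @param model an aligned [head_model()] with at least 100 points.
#' @return A list with `plane` (`tilt_deg`, `offset_mm`, unit `normal`),
#'   `polygon` (hull vertices, counter-clockwise, in-plane `(u, v)`
#'   coordinates with `u` the in-plane X-like axis and `v = y`, origin at the
#'   projected anatomical origin), `polygon_world` (same vertices in 3D), and
#'   `CP` (mm).
#' @export
max_perimeter_slice <- function(model) {
  pts <- if (inherits(model, "head_model")) model$points else check_num_matrix(model)
  if (nrow(pts) < 100L)
    stop_craniosh("coverage", "slice search needs >= 100 points, got %d", nrow(pts))
  per_tilt <- list()
  for (alpha in seq(SLICE_TILT_RANGE[1], SLICE_TILT_RANGE[2], by = SLICE_TILT_STEP)) {
    ar <- deg2rad(alpha)
    nvec <- c(sin(ar), 0, cos(ar))
    uvec <- c(cos(ar), 0, -sin(ar))
    s <- pts %*% nvec
    best <- NULL
    for (off in seq(min(s), max(s), by = SLICE_OFFSET_STEP)) {
      in_slab <- abs(s - off) <= SLICE_HALF_WIDTH
      if (sum(in_slab) < SLICE_MIN_POINTS) next  # coverage too thin: skip plane
      sub <- pts[in_slab, , drop = FALSE]
      pu <- sub %*% uvec
      pv <- sub[, 2]
      h <- grDevices::chull(pu, pv)           # clockwise
      poly <- cbind(pu[h], pv[h])[rev(seq_along(h)), , drop = FALSE]  # CCW
      per <- polygon_perimeter(poly)
      if (is.null(best) || per > best$CP)
        best <- list(plane = list(tilt_deg = alpha, offset_mm = off, normal = nvec),
                     polygon = poly, CP = per,
                     uvec = uvec)
    }
    if (!is.null(best)) per_tilt[[length(per_tilt) + 1L]] <- best
  }
  if (length(per_tilt) == 0L)
    stop_craniosh("coverage", "no slab contained %d or more points", SLICE_MIN_POINTS)
  # Perimeter differences below the slab-sampling noise do not distinguish
  # planes; among near-maximal tilts take the least-tilted (canonical) one, so
  # rotationally degenerate shapes (a sphere) yield the horizontal slice.
  cps <- vapply(per_tilt, `[[`, double(1), "CP")
  near <- which(cps >= max(cps) * (1 - SLICE_PERIMETER_TOL))
  tilt_of <- vapply(per_tilt, function(b) abs(b$plane$tilt_deg), double(1))
  best <- per_tilt[[near[which.min(tilt_of[near])]]]
  nvec <- best$plane$normal
  best$polygon_world <- best$plane$offset_mm * matrix(nvec, nrow(best$polygon), 3, byrow = TRUE) +
    outer(best$polygon[, 1], best$uvec) + outer(best$polygon[, 2], c(0, 1, 0))
  best$uvec <- NULL
  best
}

## Distance from the in-plane origin to the polygon boundary along `dir`.
ray_boundary_distance <- function(poly, dir) {
  n <- nrow(poly)
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  best <- Inf
  for (i in seq_len(n)) {
    e <- nxt[i, ] - poly[i, ]
    det <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(det) < 1e-14) next
    t <- (poly[i, 1] * (-e[2]) - poly[i, 2] * (-e[1])) / det
    s <- (dir[1] * poly[i, 2] - dir[2] * poly[i, 1]) / det
    if (t > 0 && s >= -1e-12 && s <= 1 + 1e-12) best <- min(best, t)
  }
  if (!is.finite(best)) stop_craniosh("geometry", "ray does not meet the polygon boundary")
  best
}

#' Oblique diagonals of the maximal slice
#'
#' Measures the chords of the maximum-perimeter slice through the anatomical
#' origin at +/-30 degrees azimuth from the X direction: `a` runs front-left
#' to back-right, `b` front-right to back-left.  Each chord is split by the
#' origin into its frontal and back parts, so `a = a_frontal + a_back` holds
#' identically.
#'
#' @param polygon the in-plane hull polygon from [max_perimeter_slice()];
#'   must enclose the in-plane origin.
#' @return Named list `a`, `b`, `a_frontal`, `a_back`, `b_frontal`, `b_back`
#'   (mm).
#' @export
oblique_chords <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (!origin_inside(polygon))
    stop_craniosh("geometry", "anatomical origin lies outside the slice polygon")
  az <- deg2rad(OBLIQUE_AZIMUTH)
  a_frontal <- ray_boundary_distance(polygon, c(cos(az), sin(az)))    # front-left
  a_back    <- ray_boundary_distance(polygon, -c(cos(az), sin(az)))   # back-right
  b_frontal <- ray_boundary_distance(polygon, c(cos(az), -sin(az)))   # front-right
  b_back    <- ray_boundary_distance(polygon, -c(cos(az), -sin(az)))  # back-left
  list(a = a_frontal + a_back, b = b_frontal + b_back,
       a_frontal = a_frontal, a_back = a_back,
       b_frontal = b_frontal, b_back = b_back)
}

#' Head length and width
#'
#' Length `c` is the X extent of the maximum-perimeter slice polygon; width
#' `d` is the Y extent of the full cloud.
#'
#' @param model aligned [head_model()].
#' @param slice result of [max_perimeter_slice()].
#' @return Named list `c`, `d` (mm).
#' @export
head_length_width <- function(model, slice) {
  pts <- if (inherits(model, "head_model")) model$points else check_num_matrix(model)
  if (nrow(pts) == 0L) stop_craniosh("domain", "empty point cloud")
  xw <- slice$polygon_world[, 1]
  list(c = max(xw) - min(xw), d = max(pts[, 2]) - min(pts[, 2]))
}

#' All calliper-style measures of an aligned head
#'
#' Convenience wrapper running [max_perimeter_slice()], [oblique_chords()]
#' and [head_length_width()].
#'
#' @param model aligned [head_model()].
#' @return An `anthropometric_measures` list: `a`, `b`, `c`, `d`, `CP`,
#'   `a_frontal`, `a_back`, `b_frontal`, `b_back`, `perimeter_plane`.
#' @export
cranial_measures <- function(model) {
  slice <- max_perimeter_slice(model)
  ch <- oblique_chords(slice$polygon)
  cd <- head_length_width(model, slice)
  structure(c(ch, cd, list(CP = slice$CP, perimeter_plane = slice$plane,
                           slice = slice)),
            class = "anthropometric_measures")
}

#' Deformation indexes from the measures
#'
#' * `CI = 100 d / c` — cephalic index (width over length), normal 75–95%.
#' * `AI = a - b` — cranial vault asymmetry (CVAI), mm, signed.
#' * `OCLR = 100 a / b`, and `OCLR100 = OCLR - 100`.
#' * `AAI = a_frontal - b_frontal`, `PAI = a_back - b_back` — anterior and
#'   posterior halves of the asymmetry, so `AI = AAI + PAI` exactly.
#' * `f22` — the degree-2 order -2 harmonic coefficient (raw scale);
#'   `f22_x10 = 10 f22` is a display scaling only and never enters any
#'   threshold comparison.
#'
#' @param m an `anthropometric_measures` (or list with the same fields).
#' @param f22 spherical-harmonic asymmetry coefficient.
#' @param lmax degree at which `f22` was fitted.
#' @return An `index_report` list.
#' @export
compute_indexes <- function(m, f22 = NA_real_, lmax = 4L) {
  need <- c("a", "b", "c", "d", "a_frontal", "a_back", "b_frontal", "b_back")
  vals <- unlist(m[need])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_craniosh("domain", "all measures must be positive and finite")
  if (m$b == 0) stop_craniosh("domain", "b is zero; OCLR undefined")
  OCLR <- 100 * m$a / m$b
  structure(list(
    CP = if (!is.null(m$CP)) m$CP else NA_real_,
    CI = 100 * m$d / m$c,
    AI = m$a - m$b,
    AAI = m$a_frontal - m$b_frontal,
    PAI = m$a_back - m$b_back,
    OCLR = OCLR, OCLR100 = OCLR - 100,
    f22 = f22, f22_x10 = 10 * f22,
    lmax_used = as.integer(lmax)
  ), class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat("<index_report>\n")
  cat(sprintf("  CP %.1f mm  CI %.1f%%  AI %+.2f mm  AAI %+.2f  PAI %+.2f  OCLR %.2f%%\n",
              x$CP, x$CI, x$AI, x$AAI, x$PAI, x$OCLR))
  cat(sprintf("  f_2^-2 (lmax %d) = %+.4f  (x10 display: %+.3f)\n",
              x$lmax_used, x$f22, x$f22_x10))
  invisible(x)
}
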