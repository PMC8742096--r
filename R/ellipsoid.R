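## Ideal cranial shape: axis-aligned triaxial ellipsoid fit and orthogonal
## (foot-point) distances from the head surface to it.

#' Construct an ellipsoid
#'
#' Axis-aligned triaxial ellipsoid: `((x-x0)/ax)^2 + ((y-y0)/ay)^2 +
#' ((z-z0)/az)^2 = 1`.  No rotation term — the axes are parallel to the
#' anatomical frame, so the ideal shape is symmetric about the head's
#' longitudinal axis and unaffected by the asymmetry being measured.
#'
#' @param center numeric 3-vector (mm).
#' @param semi_axes numeric 3-vector of positive semi-axis lengths (mm).
#' @return An object of class `cranial_ellipsoid`.
#' @export
ellipsoid_new <- function(center, semi_axes) {
  center <- as.double(center); semi_axes <- as.double(semi_axes)
  if (length(center) != 3L || length(semi_axes) != 3L ||
      !all(is.finite(c(center, semi_axes))))
    stop_craniosh("fit", "ellipsoid needs finite 3-vector center and semi-axes")
  if (any(semi_axes <= 0))
    stop_craniosh("fit", "non-positive semi-axis along %s",
                  paste(c("x", "y", "z")[semi_axes <= 0], collapse = ","))
  structure(list(center = center, semi_axes = semi_axes),
            class = "cranial_ellipsoid")
}

#' @export
print.cranial_ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid center (%.2f, %.2f, %.2f) mm, semi-axes (%.2f, %.2f, %.2f) mm>\n",
              x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

#' Fit the best axis-aligned ellipsoid to a point cloud
#'
#' Linear (algebraic) least squares on `A x^2 + B y^2 + C z^2 + D x + E y +
#' F z = 1`, converted to center and semi-axes by completing the square.
#' Cross terms are never estimated.
#'
#' @param points N x 3 matrix (mm), N >= 9, not all coplanar.
#' @return A `cranial_ellipsoid`.
#' @export
fit_ellipsoid <- function(points) {
  if (inherits(points, "head_model")) points <- points$points
  points <- check_num_matrix(points)
  n <- nrow(points)
  if (n < 9L)
    stop_craniosh("fit", "need at least 9 points to fit an ellipsoid, got %d", n)
  X <- cbind(points^2, points)
  qrX <- qr(X)
  if (qrX$rank < 6L)
    stop_craniosh("fit", "degenerate point cloud (rank %d design); cannot fit an ellipsoid",
                  qrX$rank)
  beta <- qr.coef(qrX, rep(1, n))
  quad <- beta[1:3]; lin <- beta[4:6]
  if (any(quad <= 0))
    stop_craniosh("fit", "non-ellipsoidal fit: non-positive quadratic coefficient along %s",
                  paste(c("x", "y", "z")[quad <= 0], collapse = ","))
  center <- -lin / (2 * quad)
  G <- 1 + sum(lin^2 / (4 * quad))
  if (G <= 0) stop_craniosh("fit", "degenerate fit: negative completed-square constant")
  ellipsoid_new(center, sqrt(G / quad))
}

## Vectorized foot-point solver.  For each point p the nearest surface point is
## q_i = c_i + a_i^2 (p_i - c_i) / (a_i^2 + t) with the Lagrange parameter t the
## root of F(t) = sum_i a_i^2 (p_i - c_i)^2 / (a_i^2 + t)^2 - 1 on
## (-min(a^2), Inf).  F is convex and strictly decreasing there, so a
## bisection-safeguarded Newton iteration is globally convergent.
foot_points_all <- function(points, e, tol = 1e-13, max_iter = 100L) {
  points <- check_num_matrix(points)
  a2 <- e$semi_axes^2
  amin2 <- min(a2)
  d <- sweep(points, 2, e$center)
  n <- nrow(d)
  w <- sweep(d^2, 2, a2, "*")               # a_i^2 d_i^2
  Fval <- function(t) {
    den <- outer(t, a2, "+")
    rowSums(w / den^2) - 1
  }
  dFval <- function(t) {
    den <- outer(t, a2, "+")
    -2 * rowSums(w / den^3)
  }
  r2 <- rowSums(sweep(d^2, 2, a2, "/"))     # ellipsoid level: >1 outside
  at_center <- rowSums(d^2) == 0
  outside <- r2 > 1

  lo <- ifelse(outside, 0, -amin2 * (1 - 1e-12))
  hi <- ifelse(outside, max(e$semi_axes) * sqrt(rowSums(d^2)) + max(a2), 0)
  # expand hi until F(hi) < 0 (only relevant for far-outside points)
  for (k in 1:60) {
    bad <- !at_center & Fval(hi) > 0 & outside
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  ambiguous <- at_center | (!outside & Fval(lo) <= 0)

  t <- ifelse(outside, 0, (lo + hi) / 2)
  active <- !ambiguous
  iters <- integer(n)
  for (k in seq_len(max_iter)) {
    if (!any(active)) break
    Fa <- Fval(t); dFa <- dFval(t)
    pos <- active & Fa > 0
    lo[pos] <- t[pos]
    neg <- active & Fa <= 0
    hi[neg] <- t[neg]
    tn <- t - Fa / dFa
    outb <- active & (tn <= lo | tn >= hi | !is.finite(tn))
    tn[outb] <- (lo[outb] + hi[outb]) / 2
    step <- abs(tn - t)
    conv <- active & step <= tol * (1 + abs(t))
    t[active] <- tn[active]
    iters[active] <- k
    active <- active & !conv
  }
  converged <- !active & !ambiguous

  den <- outer(t, a2, "+")
  q <- sweep(sweep(d, 2, a2, "*") / den, 2, e$center, "+")
  if (any(ambiguous)) {
    # medial-axis / center points: deterministic fallback along the shortest
    # semi-axis (exact at the center; flagged, never converged surface data)
    jmin <- which.min(e$semi_axes)
    for (i in which(ambiguous)) {
      qi <- e$center
      if (at_center[i]) {
        qi[jmin] <- qi[jmin] + e$semi_axes[jmin]
      } else {
        u <- unit(d[i, ] / e$semi_axes)
        qi <- e$center + e$semi_axes * u
      }
      q[i, ] <- qi
    }
  }
  dist <- sqrt(rowSums((points - q)^2)) * ifelse(outside, 1, -1)
  grad <- sweep(q - matrix(e$center, n, 3, byrow = TRUE), 2, a2, "/")
  normal <- grad / sqrt(rowSums(grad^2))
  list(foot = q, normal = normal, signed_distance = dist,
       iterations = iters, converged = converged, ambiguous = ambiguous)
}

#' Orthogonal foot point of a point on an ellipsoid
#'
#' Finds the nearest point `Q_P` on the ellipsoid surface by safeguarded
#' Newton iteration on the Lagrange parameter (tolerance `1e-10` relative on
#' the parameter step, at most 100 iterations).  The signed distance is
#' `+|p - Q_P|` outside the surface and negative inside.  Points on the
#' medial axis (including the exact center) have non-unique foot points; they
#' are resolved deterministically along the shortest semi-axis and flagged
#' `ambiguous`.
#'
#' @param p numeric 3-vector (mm).
#' @param e a `cranial_ellipsoid`.
#' @return A list with `foot_point`, outward unit `normal`, `signed_distance`
#'   (mm), `iterations`, `converged`, `ambiguous`.
#' @export
foot_point <- function(p, e) {
  stopifnot(inherits(e, "cranial_ellipsoid"))
  r <- foot_points_all(matrix(as.double(p), 1, 3), e)
  if (!r$converged[1] && !r$ambiguous[1])
    stop_craniosh("numeric",
                  "foot-point iteration did not converge for point (%g, %g, %g) after %d iterations",
                  p[1], p[2], p[3], r$iterations[1])
  list(foot_point = r$foot[1, ], normal = r$normal[1, ],
       signed_distance = r$signed_distance[1], iterations = r$iterations[1],
       converged = r$converged[1], ambiguous = r$ambiguous[1])
}

#' Signed-distance surface samples on the ellipsoid chart
#'
#' Projects every head point orthogonally onto the fitted ellipsoid and
#' expresses the foot point in geocentric latitude/longitude about the
#' ellipsoid center (Z = pole, longitude measured from +X toward +Y, wrapped
#' to \[0, 360)), paired with the signed orthogonal distance.  The (lat, lon)
#' pair is only an indexing chart for the harmonic expansion.
#'
#' @param model an aligned [head_model()].
#' @param e the `cranial_ellipsoid` fitted to the same points.
#' @return A data.frame with columns `lat`, `lon` (degrees), `distance` (mm),
#'   one row per input point (input order preserved).
#' @export
surface_samples <- function(model, e) {
  stopifnot(inherits(e, "cranial_ellipsoid"))
  pts <- if (inherits(model, "head_model")) model$points else check_num_matrix(model)
  r <- foot_points_all(pts, e)
  bad <- which(!r$converged & !r$ambiguous)
  if (length(bad))
    stop_craniosh("numeric", "foot-point iteration failed for point index %d", bad[1])
  qc <- sweep(r$foot, 2, e$center)
  lat <- rad2deg(atan2(qc[, 3], sqrt(qc[, 1]^2 + qc[, 2]^2)))
  lon <- wrap360(rad2deg(atan2(qc[, 2], qc[, 1])))
  data.frame(lat = lat, lon = lon, distance = r$signed_distance)
}
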