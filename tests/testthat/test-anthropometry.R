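ramanujan_perimeter <- function(a, b) pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))

dense_surface <- function(axes, n = 4000) {
  u <- craniosh:::fibonacci_cap(n, -90)
  head_model(sweep(u, 2, axes, "*"), is_aligned = TRUE)
}

test_that("the maximal slice of a sphere has the great-circle perimeter", {
  m <- dense_surface(c(60, 60, 60))
  s <- max_perimeter_slice(m)
  expect_equal(s$CP, 2 * pi * 60, tolerance = 0.01)
})

test_that("the maximal slice of an ellipsoid matches the Ramanujan ellipse perimeter", {
  m <- dense_surface(c(90, 70, 60))
  s <- max_perimeter_slice(m)
  expect_equal(s$CP, ramanujan_perimeter(90, 70), tolerance = 0.01)
  expect_equal(s$plane$tilt_deg, 0)
  # polygon is counter-clockwise and encloses the origin
  poly <- s$polygon
  nxt <- rbind(poly[-1, ], poly[1, ])
  expect_gt(sum((nxt[, 1] - poly[, 1]) * (nxt[, 2] + poly[, 2])) * -1, 0)
})

test_that("sparse clouds fail the slice search with a coverage error", {
  m <- head_model(matrix(rnorm(150, 0, 50), 50, 3), is_aligned = TRUE)
  expect_error(max_perimeter_slice(m), class = "craniosh_coverage")
})

test_that("chords of a circular slice are symmetric and split equally", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  poly <- cbind(60 * cos(th), 60 * sin(th))
  ch <- oblique_chords(poly)
  expect_equal(ch$a, 120, tolerance = 1e-6)
  expect_equal(ch$b, 120, tolerance = 1e-6)
  expect_equal(ch$a_frontal, 60, tolerance = 1e-6)
  expect_equal(ch$b_back, 60, tolerance = 1e-6)
})

test_that("chords of an elliptical slice match the polar closed form", {
  # half-chord of the (90, 70) ellipse at 30 deg: r = ab / sqrt(b^2 cos^2 + a^2 sin^2)
  r30 <- 90 * 70 / sqrt(70^2 * cos(pi / 6)^2 + 90^2 * sin(pi / 6)^2)
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  poly <- cbind(90 * cos(th), 70 * sin(th))
  ch <- oblique_chords(poly)
  expect_equal(ch$a_frontal, r30, tolerance = 1e-4)
  expect_equal(ch$a, 2 * r30, tolerance = 1e-4)
  expect_equal(ch$b, ch$a, tolerance = 1e-6)
  expect_equal(ch$a, ch$a_frontal + ch$a_back, tolerance = 1e-12)
})

test_that("a polygon not enclosing the origin is a geometry error", {
  th <- seq(0, 2 * pi, length.out = 100)
  poly <- cbind(200 + 60 * cos(th), 60 * sin(th))
  expect_error(oblique_chords(poly), class = "craniosh_geometry")
})

test_that("head length and width read the axis extents", {
  m <- dense_surface(c(90, 70, 60))
  s <- max_perimeter_slice(m)
  cd <- head_length_width(m, s)
  expect_equal(cd$c, 180, tolerance = 0.01)
  expect_equal(cd$d, 140, tolerance = 0.01)

  sph <- dense_surface(c(60, 60, 60))
  cd2 <- head_length_width(sph, max_perimeter_slice(sph))
  expect_equal(cd2$c, 120, tolerance = 0.01)
  expect_equal(cd2$d, 120, tolerance = 0.01)

  # stretching Y doubles the width and leaves the length unchanged
  m2 <- head_model(m$points %*% diag(c(1, 2, 1)), is_aligned = TRUE)
  cd3 <- head_length_width(m2, max_perimeter_slice(m2))
  expect_equal(cd3$d, 280, tolerance = 0.01)
  expect_equal(cd3$c, cd$c, tolerance = 0.01)
})

test_that("index arithmetic follows the definitions", {
  m <- list(a = 100, b = 96, c = 150, d = 120,
            a_frontal = 52, a_back = 48, b_frontal = 50, b_back = 46, CP = 450)
  r <- compute_indexes(m, f22 = -0.3, lmax = 4)
  expect_equal(r$AI, 4)
  expect_equal(r$OCLR, 104.1667, tolerance = 1e-4)
  expect_equal(r$OCLR100, r$OCLR - 100)
  expect_equal(r$CI, 80)
  expect_equal(r$AAI, 2)
  expect_equal(r$PAI, 2)
  expect_equal(r$AI, r$AAI + r$PAI)
  expect_equal(r$f22_x10, -3)

  sym <- list(a = 100, b = 100, c = 150, d = 120,
              a_frontal = 50, a_back = 50, b_frontal = 50, b_back = 50, CP = 450)
  rs <- compute_indexes(sym, f22 = 0)
  expect_equal(rs$AI, 0); expect_equal(rs$AAI, 0); expect_equal(rs$PAI, 0)
  expect_equal(rs$OCLR, 100)

  expect_error(compute_indexes(modifyList(m, list(b = -1))), class = "craniosh_domain")
})

test_that("measures respect mirror and scale symmetries", {
  g <- generate_head(synthetic_spec(
    deformations = list(list(azimuth = 135, lat = 10, amplitude = -7, sd = 45)),
    seed = 21))
  m <- align_head(g$model)
  meas <- cranial_measures(m)
  idx <- compute_indexes(meas, f22 = 0)

  # the slice-plane family is invariant under y -> -y, so the mirror is exact
  mm <- head_model(m$points %*% diag(c(1, -1, 1)), is_aligned = TRUE)
  meas2 <- cranial_measures(mm)
  idx2 <- compute_indexes(meas2, f22 = 0)
  expect_equal(idx2$AI, -idx$AI, tolerance = 1e-6)
  expect_equal(idx2$AAI, -idx$AAI, tolerance = 1e-6)
  expect_equal(idx2$PAI, -idx$PAI, tolerance = 1e-6)
  expect_equal(idx2$OCLR, 10000 / idx$OCLR, tolerance = 1e-6)
  expect_equal(idx2$CP, idx$CP, tolerance = 1e-6)
  expect_equal(idx2$CI, idx$CI, tolerance = 1e-6)

  # uniform scaling: lengths scale, ratios do not (1% slice-grid slack)
  ms <- head_model(m$points * 1.3, is_aligned = TRUE)
  meas3 <- cranial_measures(ms)
  idx3 <- compute_indexes(meas3, f22 = 0)
  expect_equal(meas3$a, 1.3 * meas$a, tolerance = 0.01)
  expect_equal(meas3$CP, 1.3 * meas$CP, tolerance = 0.01)
  expect_equal(idx3$CI, idx$CI, tolerance = 0.01)
  expect_equal(idx3$OCLR, idx$OCLR, tolerance = 0.01)
})
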