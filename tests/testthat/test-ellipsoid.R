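test_that("algebraic fit recovers exact ellipsoid and sphere parameters", {
  pts <- exact_ellipsoid_points(500, c(1, -2, 3), c(90, 70, 60), seed = 7)
  e <- fit_ellipsoid(pts)
  expect_lt(max(abs(e$center - c(1, -2, 3))), 1e-6)
  expect_lt(max(abs(e$semi_axes - c(90, 70, 60))), 1e-6)

  sph <- exact_ellipsoid_points(500, c(0, 0, 0), c(75, 75, 75), seed = 8)
  es <- fit_ellipsoid(sph)
  expect_lt(max(abs(es$semi_axes - 75)), 1e-6)
})

test_that("degenerate clouds are rejected", {
  set.seed(1)
  plane <- cbind(rnorm(200, 0, 40), rnorm(200, 0, 40), 0)
  expect_error(fit_ellipsoid(plane), class = "craniosh_fit")
  expect_error(fit_ellipsoid(matrix(rnorm(24), 8, 3)), class = "craniosh_fit")
})

test_that("fitted parameters sit at a local optimum of the algebraic cost", {
  # sum of squared residuals of A x^2 + B y^2 + C z^2 + D x + E y + F z - 1,
  # re-expressed in (center, axes): residual = (level - 1) / (1 - sum(c^2/a^2))
  algebraic_cost <- function(center, axes, pts) {
    K <- 1 - sum(center^2 / axes^2)
    lvl <- rowSums(sweep(sweep(pts, 2, center), 2, axes, "/")^2)
    sum(((lvl - 1) / K)^2)
  }
  for (s in 1:3) {
    set.seed(s)
    pts <- exact_ellipsoid_points(300, rnorm(3, 0, 3), c(88, 66, 58), seed = s) +
      matrix(rnorm(900, 0, 0.5), ncol = 3)
    e <- fit_ellipsoid(pts)
    c0 <- algebraic_cost(e$center, e$semi_axes, pts)
    for (j in 1:3) {
      for (eps in c(-0.01, 0.01)) {
        ctr <- e$center; ctr[j] <- ctr[j] * (1 + eps) + eps  # shift even if 0
        expect_gte(algebraic_cost(ctr, e$semi_axes, pts), c0 - 1e-9)
        ax <- e$semi_axes; ax[j] <- ax[j] * (1 + eps)
        expect_gte(algebraic_cost(e$center, ax, pts), c0 - 1e-9)
      }
    }
  }
})

test_that("foot points on principal axes match closed forms", {
  e <- ellipsoid_new(c(0, 0, 0), c(90, 70, 60))
  fp <- foot_point(c(100, 0, 0), e)
  expect_equal(fp$foot_point, c(90, 0, 0), tolerance = 1e-9)
  expect_equal(fp$signed_distance, 10, tolerance = 1e-9)

  sph <- ellipsoid_new(c(0, 0, 0), c(60, 60, 60))
  fp2 <- foot_point(c(0, 0, 100), sph)
  expect_equal(fp2$foot_point, c(0, 0, 60), tolerance = 1e-9)
  expect_equal(fp2$signed_distance, 40, tolerance = 1e-9)

  # inside point: negative distance
  fp3 <- foot_point(c(0, 0, 30), sph)
  expect_equal(fp3$signed_distance, -30, tolerance = 1e-9)
})

test_that("foot-point results satisfy their structural invariants", {
  e <- ellipsoid_new(c(2, -1, 3), c(90, 70, 60))
  set.seed(42)
  for (i in 1:50) {
    p <- e$center + rnorm(3, 0, 50)
    fp <- foot_point(p, e)
    lvl <- sum(((fp$foot_point - e$center) / e$semi_axes)^2)
    expect_lt(abs(lvl - 1), 1e-9)
    expect_lt(abs(sqrt(sum(fp$normal^2)) - 1), 1e-12)
    # normal parallel to the gradient at the foot point
    g <- (fp$foot_point - e$center) / e$semi_axes^2
    expect_lt(max(abs(fp$normal - g / sqrt(sum(g^2)))), 1e-9)
  }
  # exact center: deterministic ambiguous fallback along the shortest axis
  fc <- foot_point(e$center, e)
  expect_true(fc$ambiguous)
  expect_equal(fc$foot_point, e$center + c(0, 0, 60), tolerance = 1e-12)
})

test_that("signed distances agree with an independent surface-minimisation oracle", {
  e <- ellipsoid_new(c(0, 0, 0), c(90, 70, 60))
  set.seed(2024)
  n <- 1000
  # shell around the surface: surface points pushed in/out by up to 25 mm
  th <- asin(runif(n, -1, 1)); ph <- runif(n, 0, 2 * pi)
  u <- cbind(cos(th) * cos(ph), cos(th) * sin(ph), sin(th))
  base <- sweep(u, 2, e$semi_axes, "*")
  pts <- base + runif(n, -25, 25) * u
  got <- craniosh:::foot_points_all(pts, e)$signed_distance
  want <- vapply(seq_len(n), function(i) oracle_signed_distance(pts[i, ], e), double(1))
  expect_lt(max(abs(got - want)), 0.05)
})

test_that("moving a point along its foot-point normal shifts the distance exactly", {
  e <- ellipsoid_new(c(0, 0, 0), c(90, 70, 60))
  set.seed(9)
  for (i in 1:20) {
    p <- rnorm(3, 0, 1); p <- p / sqrt(sum(p^2)) * runif(1, 70, 110)
    fp <- foot_point(p, e)
    for (delta in c(0.5, 3, 10)) {
      fp2 <- foot_point(fp$foot_point + (fp$signed_distance + delta) * fp$normal, e)
      expect_lt(abs(fp2$signed_distance - (fp$signed_distance + delta)), 1e-9)
    }
  }
})

test_that("surface samples use the geocentric chart with wrapped longitude", {
  e <- ellipsoid_new(c(0, 0, 0), c(90, 70, 60))
  m <- head_model(rbind(c(100, 0, 0), c(0, -80, 0)), is_aligned = TRUE)
  s <- surface_samples(m, e)
  expect_equal(s$lat, c(0, 0), tolerance = 1e-9)
  expect_equal(s$lon, c(0, 270), tolerance = 1e-9)
  expect_gt(s$distance[1], 0)

  # one sample per point, order preserved, exact surface -> zero distance
  pts <- exact_ellipsoid_points(300, c(0, 0, 0), c(90, 70, 60), seed = 3)
  s2 <- surface_samples(head_model(pts, is_aligned = TRUE), e)
  expect_equal(nrow(s2), 300L)
  expect_lt(max(abs(s2$distance)), 1e-8)
  expect_true(all(s2$lat >= -90 & s2$lat <= 90))
  expect_true(all(s2$lon >= 0 & s2$lon < 360))
})
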