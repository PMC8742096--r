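test_that("the degree-0 harmonic is 1 and invalid orders are rejected", {
  expect_equal(basis_value(0, 0, c(-90, 0, 33, 90), c(0, 120, 240, 359)),
               rep(1, 4))
  expect_error(basis_value(2, 3, 0, 0), class = "craniosh_domain")
  expect_error(basis_value(1, -2, 0, 0), class = "craniosh_domain")
})

test_that("Y_2^-2 alternates sign over the four diagonal quadrants", {
  v <- basis_value(2, -2, 0, c(45, 135, 225, 315))
  expect_equal(sign(v), c(1, -1, 1, -1))
  expect_equal(v[1], -v[2], tolerance = 1e-12)
})

test_that("the basis is 4pi-orthonormal under equal-area quadrature", {
  sites <- spread_sites(20000)
  Y <- craniosh:::sh_design(sites$lat, sites$lon, 4)
  gram <- crossprod(Y) / nrow(Y)       # mean(Y_i Y_j) = delta_ij under 4pi norm
  expect_lt(max(abs(gram - diag(ncol(Y)))), 1e-3)
})

test_that("a constant field loads only the degree-0 coefficient", {
  sites <- spread_sites(500)
  sites$distance <- 2.0
  e <- expand_harmonics(sites, lmax = 4)
  expect_equal(sh_coef(e, 0, 0), 2.0, tolerance = 1e-9)
  others <- e$coefficients$value[!(e$coefficients$l == 0)]
  expect_lt(max(abs(others)), 1e-9)
  expect_equal(nrow(e$coefficients), 25L)
})

test_that("a planted basis function is recovered exactly and reconstructs its samples", {
  sites <- planted_samples(spread_sites(530), 2, -2, 0.7)
  e <- expand_harmonics(sites, lmax = 4)
  expect_equal(sh_coef(e, 2, -2), 0.7, tolerance = 1e-9)
  expect_lt(e$rmse, 1e-9)
  expect_lt(max(abs(reconstruct(e, sites$lat, sites$lon) - sites$distance)), 1e-8)

  # the planted weight is stable across every truncation degree
  sweep <- coefficient_vs_lmax(sites, 2:10)
  expect_equal(sweep$coefficient, rep(0.7, 9), tolerance = 1e-9)

  # trivial expansions
  e0 <- expand_harmonics(data.frame(lat = spread_sites(30)$lat,
                                    lon = spread_sites(30)$lon,
                                    distance = 3), lmax = 0)
  expect_equal(reconstruct(e0, c(-45, 80), c(10, 200)), c(3, 3), tolerance = 1e-9)
})

test_that("underdetermined and degenerate designs are refused", {
  sites <- planted_samples(spread_sites(20), 1, 0, 1)
  expect_error(expand_harmonics(sites, lmax = 4),
               class = "craniosh_insufficient_samples")
  one_spot <- data.frame(lat = rep(10, 50), lon = rep(20, 50), distance = 1)
  expect_error(expand_harmonics(one_spot, lmax = 4),
               class = "craniosh_ill_conditioned")
})

test_that("expansion RMSE is zero on representable fields, permutation-invariant, and bounded by noise", {
  sites <- planted_samples(spread_sites(530), 3, 1, 1.2)
  e <- expand_harmonics(sites, lmax = 4)
  expect_lt(expansion_rmse(e, sites), 1e-9)
  perm <- sites[sample(nrow(sites)), ]
  expect_equal(expansion_rmse(e, perm), expansion_rmse(e, sites), tolerance = 1e-12)
  expect_error(expansion_rmse(e, sites[0, ]), class = "craniosh_domain")

  # fitted residual never exceeds the data noise RMS (15% slack, seeded)
  set.seed(77)
  noisy <- planted_samples(spread_sites(530), 2, -2, 0.5)
  noisy$distance <- noisy$distance + rnorm(530, 0, 1.0)
  en <- expand_harmonics(noisy, lmax = 4)
  expect_lt(en$rmse, 1.0 * 1.15)
})

test_that("training RMSE is non-increasing in lmax (nested least squares)", {
  set.seed(5)
  sites <- spread_sites(530, min_lat = -25)
  sites$distance <- 3 * sin(craniosh:::deg2rad(2 * sites$lon)) *
    cos(craniosh:::deg2rad(sites$lat))^2 + rnorm(530, 0, 0.5)
  sweep <- coefficient_vs_lmax(sites, 2:8)
  expect_true(all(diff(sweep$rmse) <= 1e-12))
})

test_that("mirroring the chart negates sin-type coefficients and preserves cos-type ones", {
  set.seed(6)
  sites <- spread_sites(530, min_lat = -25)
  sites$distance <- rnorm(530, 0, 2)
  e1 <- expand_harmonics(sites, lmax = 4)
  mirrored <- sites
  mirrored$lon <- craniosh:::wrap360(360 - sites$lon)
  e2 <- expand_harmonics(mirrored, lmax = 4)
  neg <- e1$coefficients$m < 0
  expect_equal(e2$coefficients$value[neg], -e1$coefficients$value[neg],
               tolerance = 1e-9)
  expect_equal(e2$coefficients$value[!neg], e1$coefficients$value[!neg],
               tolerance = 1e-9)
})

test_that("expansion is linear in the distance field", {
  sites <- spread_sites(400, min_lat = -25)
  set.seed(8)
  d1 <- rnorm(400); d2 <- rnorm(400)
  ex <- function(d) { s <- sites; s$distance <- d; expand_harmonics(s, 4)$coefficients$value }
  expect_equal(ex(2.5 * d1 - 1.5 * d2), 2.5 * ex(d1) - 1.5 * ex(d2),
               tolerance = 1e-9)
})

test_that("planted amplitudes are recovered without bias under cap sampling and noise", {
  sites <- spread_sites(530, min_lat = -25)
  for (A in c(0.1, 0.5, 1.0)) {
    est <- vapply(1:200, function(r) {
      set.seed(1000 + r)
      s <- planted_samples(sites, 2, -2, A)
      s$distance <- s$distance + rnorm(530, 0, 0.3)
      sh_coef(expand_harmonics(s, 4), 2, -2)
    }, double(1))
    expect_lt(abs(mean(est) - A), 0.05)
    expect_lt(sd(est), 0.1)
  }
})
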