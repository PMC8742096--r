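## Fixtures generated in code: exact ellipsoid samples, spread chart sites,
## and an independent foot-point oracle.

## Exact samples of an ellipsoid surface (random parametric angles).
exact_ellipsoid_points <- function(n, center, axes, seed = 1) {
  set.seed(seed)
  th <- asin(runif(n, -1, 1))          # area-biased is fine for fitting
  ph <- runif(n, 0, 2 * pi)
  cbind(center[1] + axes[1] * cos(th) * cos(ph),
        center[2] + axes[2] * cos(th) * sin(ph),
        center[3] + axes[3] * sin(th))
}

## Well-spread chart sites (full sphere by default).
spread_sites <- function(n, min_lat = -90) {
  u <- craniosh:::fibonacci_cap(n, min_lat)
  data.frame(lat = 180 / pi * asin(pmin(1, pmax(-1, u[, 3]))),
             lon = craniosh:::wrap360(180 / pi * atan2(u[, 2], u[, 1])))
}

## Independent foot-point oracle: direct minimisation of the distance to the
## parametric surface over (theta, phi), multistart L-BFGS-B.  Shares nothing
## with the Lagrange-parameter Newton iteration under test.
oracle_signed_distance <- function(p, e) {
  c0 <- e$center; a <- e$semi_axes
  obj <- function(par) {
    q <- c0 + a * c(cos(par[1]) * cos(par[2]),
                    cos(par[1]) * sin(par[2]),
                    sin(par[1]))
    sum((p - q)^2)
  }
  d <- p - c0
  th0 <- atan2(d[3], sqrt(d[1]^2 + d[2]^2))
  ph0 <- atan2(d[2], d[1])
  starts <- rbind(c(th0, ph0),
                  c(th0 + 0.3, ph0 - 0.3), c(th0 - 0.3, ph0 + 0.3),
                  c(th0, ph0 + 0.6), c(th0, ph0 - 0.6))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- optim(starts[i, ], obj, method = "L-BFGS-B",
               lower = c(-pi / 2 - 0.1, -2 * pi), upper = c(pi / 2 + 0.1, 4 * pi),
               control = list(factr = 1e4))
    best <- min(best, r$value)
  }
  sqrt(best) * if (sum((d / a)^2) > 1) 1 else -1
}

## Planted-field samples: distances are an exact harmonic field at the sites.
planted_samples <- function(sites, l, m, weight) {
  sites$distance <- weight * basis_value(l, m, sites$lat, sites$lon)
  sites
}
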