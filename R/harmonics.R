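## Real spherical-harmonic expansion of scattered signed distances.
##
## Convention (immutable): 4pi-normalized real harmonics without the
## Condon-Shortley phase — the squared basis functions integrate to 4pi over
## the sphere and Y_0^0 == 1.  For m >= 0 the basis is Pbar_l^m(sin lat)
## cos(m lon); for m < 0 it is Pbar_l^|m|(sin lat) sin(|m| lon).  The 0.42
## screening threshold is defined on this scale only.

## Normalized associated Legendre functions Pbar_l^m(sin lat) for m = 0..l.
## pracma::legendre supplies the unnormalized functions with the
## Condon-Shortley phase, which is removed here.
legendre_norm <- function(l, lat_deg) {
  x <- sin(deg2rad(lat_deg))
  P <- pracma::legendre(l, x)                       # (l+1) x n, rows m = 0..l
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
  m <- 0:l
  norm <- (-1)^m * sqrt((2 - (m == 0)) * (2 * l + 1) *
                          exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  P * norm
}

#' Evaluate a real spherical harmonic
#'
#' 4pi-normalized real harmonic `Y_l^m` at geocentric latitude/longitude in
#' degrees.  `Y_0^0` is identically 1; the basis of degree l has `l - |m|`
#' latitudinal and `2|m|` longitudinal zero crossings.
#'
#' @param l degree, integer >= 0.
#' @param m order, integer with |m| <= l (negative orders carry the
#'   `sin(|m| lon)` factor).
#' @param lat,lon degrees; vectors are recycled to a common length.
#' @return Numeric vector of basis values.
#' @export
basis_value <- function(l, m, lat, lon) {
  l <- as.integer(l); m <- as.integer(m)
  if (l < 0 || abs(m) > l)
    stop_craniosh("domain", "invalid degree/order (l = %d, m = %d)", l, m)
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  P <- legendre_norm(l, lat)[abs(m) + 1L, ]
  lon_r <- deg2rad(lon)
  if (m >= 0) P * cos(m * lon_r) else P * sin(abs(m) * lon_r)
}

## (l, m) table in storage order: l = 0..lmax, m = -l..l.
sh_orders <- function(lmax) {
  l <- rep(0:lmax, times = 2 * (0:lmax) + 1)
  m <- unlist(lapply(0:lmax, function(li) -li:li))
  data.frame(l = l, m = m)
}

## Design matrix of all Y_l^m up to lmax at the sample sites.
sh_design <- function(lat, lon, lmax) {
  n <- length(lat)
  lon_r <- deg2rad(lon)
  cols <- vector("list", lmax + 1L)
  for (l in 0:lmax) {
    P <- legendre_norm(l, lat)
    if (n == 1L) P <- matrix(P, ncol = 1L)
    block <- matrix(0, n, 2 * l + 1)
    j <- 0L
    for (m in (-l):l) {
      j <- j + 1L
      block[, j] <- if (m >= 0) P[m + 1L, ] * cos(m * lon_r)
                    else P[-m + 1L, ] * sin(-m * lon_r)
    }
    cols[[l + 1L]] <- block
  }
  do.call(cbind, cols)
}

#' Expand signed distances in spherical harmonics
#'
#' Ordinary least squares of the scattered samples on all real harmonics up
#' to `lmax` (no weighting; optional ridge penalty, default 0, for
#' partial-coverage clouds — its use is recorded on the expansion).
#'
#' @param samples data.frame with columns `lat`, `lon` (degrees) and
#'   `distance` (mm), e.g. from [surface_samples()].
#' @param lmax maximum degree; the fit has `(lmax+1)^2` coefficients and
#'   needs at least that many samples.
#' @param ridge non-negative ridge penalty added to the normal equations.
#' @return An object of class `sh_expansion` with fields `lmax`,
#'   `coefficients` (data.frame `l`, `m`, `value` in (l, m)-lexicographic
#'   order), `normalization`, `rmse` (mm), `n_samples`, `ridge`.
#' @export
expand_harmonics <- function(samples, lmax = 4L, ridge = 0) {
  lmax <- as.integer(lmax)
  if (lmax < 0) stop_craniosh("domain", "lmax must be >= 0")
  stopifnot(all(c("lat", "lon", "distance") %in% names(samples)))
  n <- nrow(samples)
  k <- (lmax + 1L)^2
  if (n < k)
    stop_craniosh("insufficient_samples",
                  "%d samples cannot determine %d coefficients (lmax = %d)", n, k, lmax)
  Y <- sh_design(samples$lat, samples$lon, lmax)
  sv <- svd(Y, nu = 0, nv = 0)$d
  if (ridge == 0 && (min(sv) == 0 || max(sv) / min(sv) > 1e8))
    stop_craniosh("ill_conditioned",
                  "rank-deficient harmonic design (condition number %.3g): samples do not cover the sphere well enough for lmax = %d",
                  max(sv) / max(min(sv), .Machine$double.xmin), lmax)
  d <- samples$distance
  if (ridge > 0) {
    coefs <- solve(crossprod(Y) + diag(ridge, k), crossprod(Y, d))[, 1]
  } else {
    coefs <- qr.coef(qr(Y), d)
  }
  resid <- d - as.vector(Y %*% coefs)
  tab <- sh_orders(lmax)
  tab$value <- as.double(coefs)
  structure(list(lmax = lmax, coefficients = tab,
                 normalization = SH_NORMALIZATION,
                 rmse = sqrt(mean(resid^2)), n_samples = n, ridge = ridge),
            class = "sh_expansion")
}

#' @export
print.sh_expansion <- function(x, ...) {
  cat(sprintf("<sh_expansion lmax = %d (%d coefficients), rmse = %.4g mm, n = %d>\n",
              x$lmax, nrow(x$coefficients), x$rmse, x$n_samples))
  cat(sprintf("  normalization: %s\n", x$normalization))
  cat(sprintf("  f_2^-2 = %.6g\n", sh_coef(x, 2, -2)))
  invisible(x)
}

#' Extract one coefficient from an expansion
#'
#' @param exp an `sh_expansion`.
#' @param l,m degree and order.
#' @return The coefficient `f_l^m` (0 when `l > lmax` is not allowed; that is
#'   a domain error).
#' @export
sh_coef <- function(exp, l = 2L, m = -2L) {
  stopifnot(inherits(exp, "sh_expansion"))
  i <- which(exp$coefficients$l == l & exp$coefficients$m == m)
  if (length(i) != 1L)
    stop_craniosh("domain", "coefficient (l = %d, m = %d) not in expansion (lmax = %d)",
                  l, m, exp$lmax)
  exp$coefficients$value[i]
}

#' Evaluate an expansion at chart positions
#'
#' @param exp an `sh_expansion`.
#' @param lat,lon degrees (vectors recycled to common length).
#' @return Reconstructed distances (mm).
#' @export
reconstruct <- function(exp, lat, lon) {
  stopifnot(inherits(exp, "sh_expansion"))
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  as.vector(sh_design(lat, lon, exp$lmax) %*% exp$coefficients$value)
}

#' Root-mean-square error of an expansion against samples
#'
#' @param exp an `sh_expansion`.
#' @param samples data.frame with `lat`, `lon`, `distance`.
#' @return RMSE in mm.
#' @export
expansion_rmse <- function(exp, samples) {
  if (nrow(samples) == 0L) stop_craniosh("domain", "no samples")
  sqrt(mean((samples$distance - reconstruct(exp, samples$lat, samples$lon))^2))
}

#' Track one coefficient across maximum degrees
#'
#' Refits the expansion independently at every requested `lmax` and extracts
#' `f_l^m` and the fit RMSE from each — the truncation-degree sweep used to
#' pick the working `lmax` for the asymmetry index.
#'
#' @param samples data.frame with `lat`, `lon`, `distance`.
#' @param lmax_list integer vector of maximum degrees (default 2..10).
#' @param l,m coefficient to track (default degree 2, order -2).
#' @param ridge passed to [expand_harmonics()].
#' @return data.frame with columns `lmax`, `coefficient`, `rmse`.
#' @export
coefficient_vs_lmax <- function(samples, lmax_list = 2:10, l = 2L, m = -2L, ridge = 0) {
  res <- lapply(as.integer(lmax_list), function(lm) {
    e <- expand_harmonics(samples, lmax = lm, ridge = ridge)
    data.frame(lmax = lm, coefficient = sh_coef(e, l, m), rmse = e$rmse)
  })
  do.call(rbind, res)
}
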