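## Synthetic head generator: cap-sampled ellipsoidal heads with smooth
## planted deformations, so every pipeline stage is testable against known
## ground truth without patient data.

#' Specification of a synthetic head
#'
#' The generator emulates a cap-based surface scan: ~530 sites area-uniform
#' on a Fibonacci spiral restricted to latitudes above `cap_min_lat` (the cap
#' does not reach the head base), mapped to a triaxial ellipsoid.  The
#' deformation is a sum of smooth Gaussian bumps in great-circle angle,
#' applied along the outward surface normal (negative amplitude = flattening,
#' the DP phenotype); `compensation` adds the opposite-sign bump at the
#' antipodal azimuth.  Measurement noise is Gaussian along the normal.
#'
#' @param semi_axes mm triple, default `c(85, 65, 60)`.
#' @param n_points sampling sites, default 530.
#' @param cap_min_lat degrees, default -25.
#' @param deformations list of bumps, each
#'   `list(azimuth, lat, amplitude, sd)` (degrees, degrees, signed mm,
#'   angular SD degrees >= 20 so the field stays smooth at low degree).
#' @param compensation logical.
#' @param noise_sd mm, default 0.3.
#' @param landmark_noise_sd mm, default 0 (landmarks are noise-free).
#' @param seed integer; fully determines the head.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(semi_axes = c(85, 65, 60), n_points = 530L,
                           cap_min_lat = -25, deformations = list(),
                           compensation = FALSE, noise_sd = 0.3,
                           landmark_noise_sd = 0, seed = 1L) {
  if (n_points < 25L) stop_craniosh("validation", "n_points must be >= 25")
  if (noise_sd < 0 || landmark_noise_sd < 0)
    stop_craniosh("validation", "noise SDs must be >= 0")
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop_craniosh("validation", "semi_axes must be three positive lengths")
  if (cap_min_lat < -90 || cap_min_lat >= 90)
    stop_craniosh("validation", "cap_min_lat must be in [-90, 90)")
  for (d in deformations) {
    if (!all(c("azimuth", "lat", "amplitude", "sd") %in% names(d)))
      stop_craniosh("validation", "each deformation needs azimuth, lat, amplitude, sd")
    if (d$sd < 20)
      stop_craniosh("validation", "deformation angular SD must be >= 20 degrees")
  }
  structure(list(semi_axes = as.double(semi_axes), n_points = as.integer(n_points),
                 cap_min_lat = cap_min_lat, deformations = deformations,
                 compensation = isTRUE(compensation), noise_sd = noise_sd,
                 landmark_noise_sd = landmark_noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Area-uniform directions on the spherical cap lat >= cap_min_lat
## (Fibonacci spiral in z = sin(lat)).
fibonacci_cap <- function(n, cap_min_lat) {
  zmin <- sin(deg2rad(cap_min_lat))
  i <- seq_len(n)
  z <- 1 - (1 - zmin) * (i - 0.5) / n
  golden <- pi * (3 - sqrt(5))
  lon <- (i * golden) %% (2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(lon), r * sin(lon), z)
}

bump_field <- function(u, deformations, compensation) {
  disp <- numeric(nrow(u))
  bumps <- deformations
  if (compensation) {
    bumps <- c(bumps, lapply(deformations, function(d) {
      d$azimuth <- wrap360(d$azimuth + 180)
      d$amplitude <- -d$amplitude
      d
    }))
  }
  for (d in bumps) {
    laz <- deg2rad(d$azimuth); lla <- deg2rad(d$lat)
    ub <- c(cos(lla) * cos(laz), cos(lla) * sin(laz), sin(lla))
    ang <- acos(pmin(1, pmax(-1, u %*% ub)))
    disp <- disp + d$amplitude * exp(-ang^2 / (2 * deg2rad(d$sd)^2))
  }
  disp
}

#' Generate one synthetic head
#'
#' @param spec a [synthetic_spec()].
#' @param id model identifier.
#' @return A list with `model` (a [head_model()] with landmarks, generated in
#'   the anatomical frame), `truth` (`ellipsoid`, `deformations`, `label`).
#' @export
generate_head <- function(spec, id = sprintf("synth-%d", spec$seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  u <- fibonacci_cap(spec$n_points, spec$cap_min_lat)
  a <- spec$semi_axes
  surf <- sweep(u, 2, a, "*")
  normal <- sweep(u, 2, a, "/")
  normal <- normal / sqrt(rowSums(normal^2))
  disp <- bump_field(u, spec$deformations, spec$compensation)
  if (spec$noise_sd > 0) disp <- disp + rnorm(spec$n_points, 0, spec$noise_sd)
  pts <- surf + disp * normal
  lm_pts <- list(preauricular_left = c(0, a[2], 0),
                 preauricular_right = c(0, -a[2], 0),
                 glabella = c(a[1], 0, 0))
  if (spec$landmark_noise_sd > 0)
    lm_pts <- lapply(lm_pts, function(p) p + rnorm(3, 0, spec$landmark_noise_sd))
  lm <- landmarks_new(lm_pts$preauricular_left, lm_pts$preauricular_right,
                      lm_pts$glabella)
  amps <- vapply(spec$deformations, function(d) abs(d$amplitude), double(1))
  label <- if (length(amps) && any(amps > 0)) "DP" else "Healthy"
  list(model = head_model(pts, id = id, landmarks = lm, is_aligned = FALSE),
       truth = list(ellipsoid = ellipsoid_new(c(0, 0, 0), a),
                    deformations = spec$deformations,
                    compensation = spec$compensation,
                    label = label),
       spec = spec)
}

#' Generate a labelled synthetic cohort
#'
#' Healthy heads are pure noisy ellipsoids; DP heads carry one posterior
#' flattening (negative amplitude drawn uniformly from `severity_range`,
#' azimuth uniform in the back band \[120, 240\] degrees, bump latitude 10
#' degrees, angular SD 45 degrees), half of them with frontal compensation.
#' Per-head semi-axes are jittered +/-10%; each head's RNG sub-seed derives
#' deterministically from the master seed.
#'
#' @param n_healthy,n_dp head counts.
#' @param seed master seed.
#' @param severity_range mm amplitude interval, default `c(5, 10)`.
#' @return A list of entries `list(model, label, amplitude, azimuth,
#'   compensation, seed)`, Healthy heads first (`H1..`, then `P1..`).
#' @export
generate_cohort <- function(n_healthy = 8L, n_dp = 10L, seed = 1L,
                            severity_range = c(5, 10)) {
  if (n_healthy < 0 || n_dp < 0) stop_craniosh("validation", "counts must be >= 0")
  n <- n_healthy + n_dp
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    axes <- c(85, 65, 60) * runif(3, 0.9, 1.1)
    dp <- i > n_healthy
    if (dp) {
      amp <- runif(1, severity_range[1], severity_range[2])
      azim <- runif(1, 120, 240)
      comp <- rbinom(1, 1, 0.5) == 1
      defs <- list(list(azimuth = azim, lat = 10, amplitude = -amp, sd = 45))
    } else {
      amp <- 0; azim <- NA_real_; comp <- FALSE; defs <- list()
    }
    id <- if (dp) sprintf("P%d", i - n_healthy) else sprintf("H%d", i)
    sp <- synthetic_spec(semi_axes = axes, deformations = defs,
                         compensation = comp, seed = subseeds[i])
    g <- generate_head(sp, id = id)
    out[[i]] <- list(model = g$model, label = if (dp) "DP" else "Healthy",
                     amplitude = amp, azimuth = azim, compensation = comp,
                     seed = subseeds[i], truth = g$truth)
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes one PLY point cloud and one landmark JSON per head, plus a manifest
#' CSV (`id`, `label`, `amplitude`, `azimuth`, `compensation`, `seed`).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(h) {
    write_point_cloud(h$model, file.path(dir, paste0(h$model$id, ".ply")))
    write_landmarks(h$model$landmarks, file.path(dir, paste0(h$model$id, "_landmarks.json")))
    data.frame(id = h$model$id, label = h$label, amplitude = h$amplitude,
               azimuth = h$azimuth, compensation = h$compensation,
               seed = h$seed, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
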