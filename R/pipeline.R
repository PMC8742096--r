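## Full analysis orchestration: align -> fit ellipsoid -> orthogonal
## distances -> harmonic expansion -> anthropometry -> screening.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_craniosh("stage", "stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Analyze one head end to end
#'
#' Runs the whole pipeline on a head model: alignment into the anatomical
#' frame (if needed), axis-aligned ellipsoid fit, signed orthogonal
#' distances, spherical-harmonic expansion at `lmax` (plus an optional
#' truncation sweep refit independently per degree), calliper-style measures
#' and deformation indexes, and both screening rules.  Every configuration
#' constant and the normalization tag are recorded in the report; partial
#' reports are never emitted.  The analysis is deterministic — no stage uses
#' random numbers.
#'
#' @param model a [head_model()]; must carry landmarks or already be aligned.
#' @param cfg a [screening_config()].
#' @param lmax working maximum harmonic degree (default 4).
#' @param lmax_sweep optional integer vector of degrees to refit (e.g.
#'   `2:10`).
#' @param initial_label optional external `"Healthy"`/`"DP"` label.
#' @param ridge optional ridge penalty for the harmonic fit (default 0).
#' @return A `cranial_report`.
#' @export
analyze_head <- function(model, cfg = screening_config(), lmax = 4L,
                         lmax_sweep = NULL, initial_label = NULL, ridge = 0) {
  stopifnot(inherits(model, "head_model"))
  if (!model$is_aligned && is.null(model$landmarks))
    stop_craniosh("precondition",
                  "stage 'align': head '%s' is not aligned and has no landmarks", model$id)
  aligned <- if (model$is_aligned) model else run_stage("align", align_head(model))
  check_analysis_size(aligned)

  ell <- run_stage("ellipsoid_fit", fit_ellipsoid(aligned$points))
  samples <- run_stage("orthogonal_distances", surface_samples(aligned, ell))
  exp <- run_stage("harmonic_expansion", expand_harmonics(samples, lmax = lmax, ridge = ridge))
  f22 <- sh_coef(exp, 2, -2)
  sweep_tab <- if (!is.null(lmax_sweep))
    run_stage("lmax_sweep", coefficient_vs_lmax(samples, lmax_sweep, ridge = ridge))
  else data.frame(lmax = integer(), coefficient = double(), rmse = double())

  measures <- run_stage("anthropometry", cranial_measures(aligned))
  indexes <- run_stage("indexes", compute_indexes(measures, f22 = f22, lmax = lmax))
  screening <- run_stage("screening",
                         classify_by_indexes(indexes, cfg, initial_label = initial_label))

  structure(list(
    id = aligned$id,
    n_points = nrow(aligned$points),
    ellipsoid = ell,
    measures = list(a = measures$a, b = measures$b, c = measures$c, d = measures$d,
                    CP = measures$CP,
                    a_frontal = measures$a_frontal, a_back = measures$a_back,
                    b_frontal = measures$b_frontal, b_back = measures$b_back,
                    perimeter_plane = measures$perimeter_plane),
    indexes = unclass(indexes),
    coefficients = exp$coefficients,
    rmse = exp$rmse,
    sweep = sweep_tab,
    screening = list(flags = as.list(screening$flags),
                     classification_indexes = screening$classification_indexes,
                     classification_sh = screening$classification_sh,
                     initial_label = screening$initial_label,
                     reclassified = screening$reclassified),
    config = list(screening = unclass(cfg), lmax = as.integer(lmax),
                  ridge = ridge,
                  normalization = SH_NORMALIZATION,
                  slice_tilt_range_deg = SLICE_TILT_RANGE,
                  slice_tilt_step_deg = SLICE_TILT_STEP,
                  slice_offset_step_mm = SLICE_OFFSET_STEP,
                  slice_half_width_mm = SLICE_HALF_WIDTH,
                  oblique_azimuth_deg = OBLIQUE_AZIMUTH)
  ), class = "cranial_report")
}

#' @export
print.cranial_report <- function(x, ...) {
  cat(sprintf("<cranial_report '%s': %d points>\n", x$id, x$n_points))
  print(x$ellipsoid)
  cat(sprintf("  f_2^-2 (lmax %d) = %+.4f, expansion rmse %.3f mm\n",
              x$config$lmax, x$indexes$f22, x$rmse))
  cat(sprintf("  AI %+.2f  AAI %+.2f  PAI %+.2f  OCLR %.2f  CI %.1f  CP %.1f\n",
              x$indexes$AI, x$indexes$AAI, x$indexes$PAI,
              x$indexes$OCLR, x$indexes$CI, x$indexes$CP))
  cat(sprintf("  classification: %s (indexes), %s (harmonic)\n",
              x$screening$classification_indexes, x$screening$classification_sh))
  invisible(x)
}

#' Analyze a cohort and compare groups
#'
#' Produces a per-head report and, when both label groups have at least two
#' heads, a group-comparison table over `|f_2^-2|` (at the working degree and
#' at every sweep degree), `|AI|`, `|AAI| + |PAI|` and `|OCLR - 100|`, sorted
#' by p value.  Statistics are skipped with a warning when a group is too
#' small; reports are still produced.
#'
#' @param models list of [head_model()]s, or of [generate_cohort()] entries
#'   (whose `label` is then used for the grouping).
#' @param cfg a [screening_config()].
#' @param lmax,lmax_sweep,ridge passed to [analyze_head()].
#' @param labels optional explicit `"Healthy"`/`"DP"` per head; defaults to
#'   cohort entry labels, else to the index-based classification.
#' @return A list with `reports` and `comparison` (data.frame or `NULL`).
#' @export
analyze_cohort <- function(models, cfg = screening_config(), lmax = 4L,
                           lmax_sweep = NULL, labels = NULL, ridge = 0) {
  entries <- lapply(models, function(m)
    if (inherits(m, "head_model")) list(model = m, label = NA_character_) else m)
  reports <- lapply(entries, function(e)
    analyze_head(e$model, cfg = cfg, lmax = lmax, lmax_sweep = lmax_sweep,
                 initial_label = if (is.na(e$label)) NULL else e$label,
                 ridge = ridge))
  if (is.null(labels)) {
    labels <- vapply(entries, function(e) e$label, character(1))
    if (anyNA(labels))
      labels <- vapply(reports, function(r) r$screening$classification_indexes,
                       character(1))
  }
  params <- list()
  key <- sprintf("|f22| lmax=%d", lmax)
  params[[key]] <- vapply(reports, function(r) r$indexes$f22, double(1))
  if (!is.null(lmax_sweep)) {
    for (lm in setdiff(as.integer(lmax_sweep), as.integer(lmax))) {
      params[[sprintf("|f22| lmax=%d", lm)]] <- vapply(reports, function(r)
        r$sweep$coefficient[r$sweep$lmax == lm], double(1))
    }
  }
  params[["|AI|"]] <- vapply(reports, function(r) r$indexes$AI, double(1))
  params[["|AAI|+|PAI|"]] <- vapply(reports, function(r)
    abs(r$indexes$AAI) + abs(r$indexes$PAI), double(1))
  params[["|OCLR-100|"]] <- vapply(reports, function(r) r$indexes$OCLR100, double(1))

  comparison <- tryCatch(compare_groups(params, labels),
                         craniosh_sample_size = function(e) {
                           warning("group statistics skipped: ", conditionMessage(e),
                                   call. = FALSE)
                           NULL
                         })
  list(reports = reports, comparison = comparison)
}
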