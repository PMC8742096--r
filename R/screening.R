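## Threshold screening (Healthy vs DP) and cohort group statistics.

#' Screening configuration
#'
#' Default thresholds: asymmetry indexes (AI, AAI, PAI) abnormal iff
#' `|value|` strictly exceeds 4 mm; OCLR normal inside \[94, 106\]%
#' (inclusive); cephalic index normal inside \[75, 95\]% (outside flags
#' scapho-/brachycephaly but never enters the DP call); the harmonic
#' coefficient abnormal iff `|f22|` strictly exceeds 0.42 at `lmax = 4`
#' under the fixed 4pi real normalization.
#'
#' @param asym_threshold mm, strict.
#' @param oclr_normal percent interval, inclusive bounds normal.
#' @param ci_normal percent interval, inclusive bounds normal.
#' @param f22_threshold dimensionless, strict, raw coefficient scale.
#' @param lmax_default working maximum harmonic degree.
#' @return A `screening_config` list.
#' @export
screening_config <- function(asym_threshold = 4, oclr_normal = c(94, 106),
                             ci_normal = c(75, 95), f22_threshold = 0.42,
                             lmax_default = 4L) {
  if (asym_threshold <= 0 || f22_threshold <= 0 ||
      diff(oclr_normal) < 0 || diff(ci_normal) < 0)
    stop_craniosh("domain", "thresholds must be positive and intervals ordered")
  structure(list(asym_threshold = asym_threshold,
                 oclr_normal = as.double(oclr_normal),
                 ci_normal = as.double(ci_normal),
                 f22_threshold = f22_threshold,
                 lmax_default = as.integer(lmax_default)),
            class = "screening_config")
}

#' Classify a head from its anthropometric indexes
#'
#' A head is called DP when any of the AI/AAI/PAI/OCLR flags is raised.  The
#' CI flag is informational only (brachy-/scaphocephaly, not DP).  When an
#' initial (external) label is supplied, `reclassified` records whether the
#' index-based call changed it.
#'
#' @param r an `index_report` (or list with `AI`, `AAI`, `PAI`, `OCLR`, `CI`,
#'   optionally `f22`).
#' @param cfg a [screening_config()].
#' @param initial_label optional `"Healthy"` or `"DP"`.
#' @return A `screening_result` list: per-index `flags`,
#'   `classification_indexes`, `classification_sh`, `initial_label`,
#'   `reclassified`.
#' @export
classify_by_indexes <- function(r, cfg = screening_config(), initial_label = NULL) {
  flags <- c(
    AI   = abs(r$AI)  > cfg$asym_threshold,
    AAI  = abs(r$AAI) > cfg$asym_threshold,
    PAI  = abs(r$PAI) > cfg$asym_threshold,
    OCLR = r$OCLR < cfg$oclr_normal[1] || r$OCLR > cfg$oclr_normal[2],
    CI   = r$CI < cfg$ci_normal[1] || r$CI > cfg$ci_normal[2],
    f22  = !is.null(r$f22) && is.finite(r$f22) && abs(r$f22) > cfg$f22_threshold
  )
  cls <- if (any(flags[c("AI", "AAI", "PAI", "OCLR")])) "DP" else "Healthy"
  sh_cls <- if (!is.null(r$f22) && is.finite(r$f22))
    classify_by_sh(r$f22, cfg) else NA_character_
  structure(list(flags = flags,
                 classification_indexes = cls,
                 classification_sh = sh_cls,
                 initial_label = if (is.null(initial_label)) NA_character_ else initial_label,
                 reclassified = if (is.null(initial_label)) FALSE
                                else !identical(initial_label, cls)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat(sprintf("<screening: %s by indexes%s%s>\n", x$classification_indexes,
              if (!is.na(x$classification_sh))
                sprintf(", %s by f_2^-2", x$classification_sh) else "",
              if (length(on)) paste0("; flags: ", paste(on, collapse = ", ")) else ""))
  invisible(x)
}

#' Classify a head from the harmonic coefficient alone
#'
#' DP iff `|f22|` strictly exceeds the threshold (default 0.42) on the raw
#' coefficient scale.  The sign only encodes the side (negative right-side,
#' positive left-side plagiocephaly).
#'
#' @param f22 degree-2 order -2 coefficient at `cfg$lmax_default`.
#' @param cfg a [screening_config()].
#' @return `"Healthy"` or `"DP"`.
#' @export
classify_by_sh <- function(f22, cfg = screening_config()) {
  if (abs(f22) > cfg$f22_threshold) "DP" else "Healthy"
}

#' Composite anterior+posterior asymmetry
#'
#' `|AAI| + |PAI|` — a simple 3D-only summary that is immune to
#' front/back compensation and invariant under mirroring of the head.
#'
#' @param r an `index_report`.
#' @return mm.
#' @export
composite_index <- function(r) abs(r$AAI) + abs(r$PAI)

#' Compare parameters between Healthy and DP groups
#'
#' For every parameter the per-head values are taken in absolute value, then
#' Shapiro–Wilk normality is checked per group and Levene homoscedasticity
#' across groups (both reported, neither gating), and a two-sided
#' pooled-variance Student t-test is run.  Rows are returned sorted by
#' ascending p value; no multiple-testing correction is applied (ranking
#' only).
#'
#' @param values_by_head named list: parameter name -> numeric vector of
#'   per-head signed values (one per head, common order).
#' @param labels character vector of `"Healthy"`/`"DP"` per head.
#' @return data.frame with columns `parameter`, `n_healthy`, `n_dp`,
#'   `mean_abs_healthy`, `mean_abs_dp`, `sd_abs_healthy`, `sd_abs_dp`, `t`,
#'   `p`, `shapiro_p_healthy`, `shapiro_p_dp`, `levene_p`.
#' @export
compare_groups <- function(values_by_head, labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("Healthy", "DP")))
    stop_craniosh("domain", "labels must be 'Healthy' or 'DP'")
  nh <- sum(labels == "Healthy"); nd <- sum(labels == "DP")
  if (nh < 2L || nd < 2L)
    stop_craniosh("sample_size", "need at least 2 heads per group (got %d Healthy, %d DP)",
                  nh, nd)
  rows <- lapply(names(values_by_head), function(par) {
    v <- abs(as.double(values_by_head[[par]]))
    if (length(v) != length(labels))
      stop_craniosh("domain", "parameter '%s' has %d values for %d heads",
                    par, length(v), length(labels))
    h <- v[labels == "Healthy"]; d <- v[labels == "DP"]
    pooled_var <- ((nh - 1) * stats::var(h) + (nd - 1) * stats::var(d)) / (nh + nd - 2)
    if (!is.finite(pooled_var) || pooled_var <= 0)
      stop_craniosh("degenerate_data", "zero pooled variance for parameter '%s'", par)
    tt <- stats::t.test(h, d, var.equal = TRUE)
    sw <- function(x) if (length(x) >= 3 && stats::sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
    lev <- tryCatch(
      car::leveneTest(v ~ factor(labels))[1, "Pr(>F)"],
      error = function(e) NA_real_)
    data.frame(parameter = par, n_healthy = nh, n_dp = nd,
               mean_abs_healthy = mean(h), mean_abs_dp = mean(d),
               sd_abs_healthy = stats::sd(h), sd_abs_dp = stats::sd(d),
               t = unname(tt$statistic), p = tt$p.value,
               shapiro_p_healthy = sw(h), shapiro_p_dp = sw(d),
               levene_p = lev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
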