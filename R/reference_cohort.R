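# Bundled reference dataset: per-patient condylar changes from a published
# 12-patient (24-condyle) bimaxillary orthognathic surgery cohort, as printed
# (one year between timepoints). Values are kept exactly as published; see
# validate_reference_changes() for the known internal inconsistencies.

#' Load the bundled reference cohort
#'
#' Returns the per-patient demographic/surgical table and the per-condyle
#' change table of the bundled 12-patient orthognathic-surgery cohort. The
#' change table carries, per patient: ramus height change (mm and, where
#' published, percent) per side, intercondylar angle change, condylar axis
#' change per side, condylar volume change (mm^3 and percent), pre/post mean
#' bone density (HU) with the published percent change per side, and the
#' per-region mean surface change (mm) per side.
#'
#' @return A list with data.frames `demographics` and `changes`.
#' @export
load_reference_cohort <- function() {
  dir <- system.file("extdata", package = "condylometry", mustWork = TRUE)
  demographics <- utils::read.csv(
    file.path(dir, "reference_cohort_demographics.csv"))
  changes <- utils::read.csv(file.path(dir, "reference_cohort_changes.csv"))
  list(demographics = demographics, changes = changes)
}

#' Long-format measurement deltas of the reference cohort
#'
#' Reshapes the reference change table into the long format consumed by
#' [build_cohort_report()]: one row per patient, side and variable, with the
#' signed difference in `delta`. Per-patient variables (intercondylar angle,
#' volume) carry side `"n/a"`. Density uses the HU difference
#' (post - pre); the published percent change is kept in `delta_pct`.
#'
#' @param cohort result of [load_reference_cohort()] (loaded if missing).
#' @return A data.frame with columns `patient`, `side`, `variable`, `delta`,
#'   `delta_pct`.
#' @export
reference_measurements <- function(cohort = load_reference_cohort()) {
  ch <- cohort$changes
  rows <- list()
  add <- function(patient, side, variable, delta, delta_pct = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient = patient, side = side, variable = variable,
      delta = delta, delta_pct = delta_pct)
  }
  for (i in seq_len(nrow(ch))) {
    p <- ch$patient[i]
    add(p, "right", "height_mm", ch$height_right_mm[i], ch$height_right_pct[i])
    add(p, "left", "height_mm", ch$height_left_mm[i], ch$height_left_pct[i])
    add(p, "n/a", "intercondylar_deg", ch$intercondylar_deg[i])
    add(p, "right", "axis_deg", ch$axis_right_deg[i])
    add(p, "left", "axis_deg", ch$axis_left_deg[i])
    add(p, "n/a", "volume_mm3", ch$volume_mm3[i], ch$volume_pct[i])
    add(p, "right", "density_hu",
        ch$density_right_post[i] - ch$density_right_pre[i],
        ch$density_right_pct[i])
    add(p, "left", "density_hu",
        ch$density_left_post[i] - ch$density_left_pre[i],
        ch$density_left_pct[i])
    for (surf in SURFACE_LABELS) {
      add(p, "right", paste0("surface_", surf),
          ch[[paste0(surf, "_right")]][i])
      add(p, "left", paste0("surface_", surf),
          ch[[paste0(surf, "_left")]][i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check the printed percent changes against the printed cells
#'
#' Recomputes each published density percent change from its pre/post HU
#' cells and each published height percent from the mm change where possible,
#' and flags cells where the published percentage disagrees with the
#' recomputation by more than `tol` points. Disagreements are reported, not
#' corrected: the bundled fixture always carries the values as published.
#'
#' @param cohort result of [load_reference_cohort()].
#' @param tol flagging threshold in percentage points.
#' @return A data.frame of flagged cells (`patient`, `cell`, `published`,
#'   `recomputed`), zero rows when everything is consistent.
#' @export
validate_reference_changes <- function(cohort = load_reference_cohort(),
                                       tol = 0.15) {
  ch <- cohort$changes
  flags <- list()
  for (i in seq_len(nrow(ch))) {
    for (s in c("right", "left")) {
      pre <- ch[[paste0("density_", s, "_pre")]][i]
      post <- ch[[paste0("density_", s, "_post")]][i]
      pub <- ch[[paste0("density_", s, "_pct")]][i]
      rec <- density_change(pre, post)
      if (is.finite(pub) && abs(pub - rec) > tol)
        flags[[length(flags) + 1]] <- data.frame(
          patient = ch$patient[i], cell = paste0("density_", s, "_pct"),
          published = pub, recomputed = round(rec, 2))
    }
  }
  if (length(flags) == 0)
    return(data.frame(patient = integer(0), cell = character(0),
                      published = numeric(0), recomputed = numeric(0)))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
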