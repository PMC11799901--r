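#' Mean signed voxel-wise dose error inside a structure
#'
#' `ME = (1/N) * sum(D_eval - D_ref)` over the mask, in Gy, plus the same
#' quantity normalized to the prescription and expressed in %.  Both dose
#' grids must already live on the same geometry (resample first).
#'
#' @param eval_dose,ref_dose `sct_volume` dose grids on one geometry.
#' @param mask nonempty [structure_mask()] on that geometry.
#' @param d_pres prescribed dose in Gy.
#' @return list with `gy` and `percent`.
#' @export
mean_error <- function(eval_dose, ref_dose, mask, d_pres) {
  if (!same_geometry(eval_dose, ref_dose) ||
      !same_geometry(eval_dose, mask$geometry))
    stop("mean_error requires both doses and the mask on one grid")
  if (mask$empty) stop("empty mask: ", mask$name)
  me <- mean(eval_dose$values[mask$mask] - ref_dose$values[mask$mask])
  list(gy = me, percent = 100 * me / d_pres)
}

#' Gamma analysis criteria
#'
#' Local-normalization 3D gamma with a lower dose cutoff: voxels of the
#' reference below `threshold_fraction` of the maximum reference dose are
#' excluded entirely (the cutoff governs both inclusion and the local
#' denominator's safety).  The search is capped at `gamma_cap`; capped
#' voxels count as failures.
#'
#' @param dose_percent local dose criterion in % (default 1).
#' @param distance_mm distance-to-agreement criterion in mm (default 1).
#' @param threshold_fraction lower cutoff as a fraction of max reference
#'   dose (default 0.20).
#' @param gamma_cap search/report ceiling (default 2).
#' @param interp_fraction evaluated-grid sampling step as a fraction of
#'   `distance_mm` (default 1/10).
#' @return A `gamma_criteria` list.
#' @export
gamma_criteria <- function(dose_percent = 1, distance_mm = 1,
                           threshold_fraction = 0.20, gamma_cap = 2,
                           interp_fraction = 0.1) {
  stopifnot(dose_percent > 0, distance_mm > 0, gamma_cap >= 1,
            threshold_fraction > 0, threshold_fraction < 1,
            interp_fraction > 0)
  structure(list(dose_percent = dose_percent, distance_mm = distance_mm,
                 threshold_fraction = threshold_fraction,
                 gamma_cap = gamma_cap, interp_fraction = interp_fraction,
                 normalization = "local"),
            class = "gamma_criteria")
}

#' 3D local gamma map and pass rate
#'
#' For every reference voxel at or above the dose threshold, the gamma index
#' is the minimum over evaluated positions within `gamma_cap * distance_mm`
#' of `sqrt(|e-r|^2/dta^2 + (D_eval(e)-D_ref(r))^2/(pct/100*D_ref(r))^2)`,
#' with the evaluated dose sampled by trilinear interpolation on a lattice
#' of step `interp_fraction * distance_mm`.  `gamma_map()` prunes the search
#' by walking the lattice in increasing spatial distance; `gamma_bruteforce()`
#' evaluates the full lattice exhaustively and serves as the oracle for the
#' pruned route (small grids only).
#'
#' @param ref_dose reference dose `sct_volume` (the comparison image set).
#' @param eval_dose evaluated dose `sct_volume` (the tested sCT's dose).
#' @param criteria a [gamma_criteria()].
#' @return `gamma_map()`: list with `gamma` (an `sct_volume`; `NA` where the
#'   reference is below threshold), `pass_rate` in % and `n_included`.
#' @export
gamma_map <- function(ref_dose, eval_dose, criteria = gamma_criteria()) {
  gamma_run(ref_dose, eval_dose, criteria, prune = TRUE)
}

#' @rdname gamma_map
#' @export
gamma_bruteforce <- function(ref_dose, eval_dose, criteria = gamma_criteria()) {
  gamma_run(ref_dose, eval_dose, criteria, prune = FALSE)
}

gamma_run <- function(ref_dose, eval_dose, criteria, prune) {
  if (!identical(ref_dose$frame_id, eval_dose$frame_id))
    stop("gamma requires both doses in a common frame")
  res <- cpp_gamma(ref_dose$values, ref_dose$origin, ref_dose$spacing,
                   as.numeric(ref_dose$axes), eval_dose$values,
                   eval_dose$origin, eval_dose$spacing,
                   as.numeric(eval_dose$axes), criteria$dose_percent,
                   criteria$distance_mm, criteria$threshold_fraction,
                   criteria$gamma_cap, criteria$interp_fraction, prune)
  if (res$n_included == 0)
    stop("all reference voxels below the gamma dose threshold")
  list(gamma = volume(res$gamma, ref_dose$origin, ref_dose$spacing,
                      ref_dose$axes, ref_dose$frame_id),
       pass_rate = res$pass_rate, n_included = res$n_included)
}

#' Gamma pass rate of an existing gamma map
#'
#' @param gamma an `sct_volume` gamma map (`NA` = excluded).
#' @return Percentage of included voxels with gamma <= 1.
#' @export
gamma_pass_rate <- function(gamma) {
  g <- gamma$values[!is.na(gamma$values)]
  if (length(g) == 0) return(NA_real_)
  100 * mean(g <= 1)
}

#' Per-patient, per-reference metric report
#'
#' Bundles the mean errors (per structure, Gy and %), the PTV DVH deltas and
#' the gamma pass rate of one sCT_clin-versus-reference comparison.
#'
#' @param patient_id patient identifier.
#' @param reference_label e.g. `"CT"`, `"sCT_QA_AI_1"`.
#' @param eval_dose dose computed on the tested sCT (sCT_clin).
#' @param ref_dose dose computed on the reference image set.
#' @param structures named list of masks including `ptv`, `brain`, `skull`.
#' @param d_pres prescription in Gy.
#' @param criteria [gamma_criteria()] (set `NULL` to skip gamma).
#' @return One-row data frame (class `metric_report`).
#' @export
metric_report <- function(patient_id, reference_label, eval_dose, ref_dose,
                          structures, d_pres,
                          criteria = gamma_criteria()) {
  row <- data.frame(patient_id = patient_id, reference = reference_label)
  for (st in c("ptv", "brain", "skull")) {
    me <- mean_error(eval_dose, ref_dose, structures[[st]], d_pres)
    row[[paste0("me_", st, "_gy")]] <- me$gy
    row[[paste0("me_", st, "_pct")]] <- me$percent
  }
  dd <- delta_dx(dvh_metrics(eval_dose, structures$ptv),
                 dvh_metrics(ref_dose, structures$ptv), d_pres)
  row$delta_d2_pct <- dd[["d2"]]
  row$delta_d95_pct <- dd[["d95"]]
  row$delta_d98_pct <- dd[["d98"]]
  row$delta_dmean_pct <- dd[["dmean"]]
  row$gamma_pass_pct <- if (is.null(criteria)) NA_real_
    else gamma_map(ref_dose, eval_dose, criteria)$pass_rate
  class(row) <- c("metric_report", class(row))
  row
}
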