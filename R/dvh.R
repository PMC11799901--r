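#' Brain and skull masks by HU thresholding
#'
#' Brain is the HU window [-100, 100] and skull is HU >= 100, both
#' intersected with the body (the largest connected component of HU > -300)
#' to exclude exterior air and couch.  A voxel at exactly 100 HU belongs to
#' BOTH structures -- the window definitions are kept literally as stated,
#' closed on both ends.
#'
#' @param ct an `sct_volume` in HU.
#' @param body_threshold_hu HU above which a voxel can belong to the body.
#' @return list with `brain` and `skull` [structure_mask()] (source
#'   `"threshold"`), plus `body`.
#' @export
threshold_structures <- function(ct, body_threshold_hu = -300) {
  cand <- ct$values > body_threshold_hu
  if (!any(cand)) {
    q <- quantile(ct$values, c(0, 0.5, 1))
    stop(sprintf("no voxels above %d HU (HU range %.0f / median %.0f / %.0f)",
                 body_threshold_hu, q[1], q[2], q[3]))
  }
  lab <- cpp_label3d(cand)
  tab <- tabulate(lab[lab > 0])
  body <- array(lab == which.max(tab), dim(ct$values))
  brain <- body & ct$values >= -100 & ct$values <= 100
  skull <- body & ct$values >= 100
  g <- volume_geometry(ct)
  if (!any(brain) || !any(skull)) {
    q <- quantile(ct$values[body], c(0, 0.25, 0.5, 0.75, 1))
    stop(sprintf(
      "empty threshold structure; body HU quantiles: %s",
      paste(sprintf("%.0f", q), collapse = " / ")))
  }
  list(brain = structure_mask("Brain", brain, g, "threshold"),
       skull = structure_mask("Skull", skull, g, "threshold"),
       body = structure_mask("Body", body, g, "threshold"))
}

#' Dose-volume histogram of a structure
#'
#' @param dose an `sct_volume` in Gy.
#' @param mask an [structure_mask()] on the same geometry.
#' @return A `dvh` object: descending sorted voxel doses plus voxel volume.
#' @export
dvh <- function(dose, mask) {
  if (!same_geometry(dose, mask$geometry))
    stop("dose and mask must share one geometry")
  if (mask$empty) stop("empty structure: ", mask$name)
  structure(list(structure = mask$name,
                 sorted_doses = sort(dose$values[mask$mask], decreasing = TRUE),
                 voxel_volume_mm3 = prod(dose$spacing)),
            class = "dvh")
}

#' Dose covering x% of the structure volume (Dx%)
#'
#' The dose d such that x% of the structure volume receives at least d.
#' Voxel k (1-based, descending doses) carries cumulative volume fraction
#' k/N; between those points the curve is linearly interpolated, and any x
#' below 100/N returns the maximum voxel dose.
#'
#' @param x a `dvh`.
#' @param pct percentage of volume in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(x, pct) {
  stopifnot(inherits(x, "dvh"))
  if (pct <= 0 || pct > 100) stop("pct must be in (0, 100]")
  d <- x$sorted_doses
  n <- length(d)
  f <- pct / 100
  if (f <= 1 / n) return(d[1])
  approx(seq_len(n) / n, d, xout = f)$y
}

#' @rdname dose_at_volume
#' @export
mean_dose <- function(x) {
  stopifnot(inherits(x, "dvh"))
  mean(x$sorted_doses)
}

#' DVH point metrics D2%, D95%, D98%, Dmean
#'
#' @param dose an `sct_volume` in Gy.
#' @param mask an [structure_mask()].
#' @return Named list `d2`, `d95`, `d98`, `dmean` in Gy.
#' @export
dvh_metrics <- function(dose, mask) {
  h <- dvh(dose, mask)
  list(d2 = dose_at_volume(h, 2), d95 = dose_at_volume(h, 95),
       d98 = dose_at_volume(h, 98), dmean = mean_dose(h))
}

#' DVH metric deltas normalized to the prescription
#'
#' Evaluated-minus-reference differences of each DVH metric, expressed in %
#' of the prescribed dose: `100 * (Dx_eval - Dx_ref) / D_pres`.
#'
#' @param eval_metrics,ref_metrics outputs of [dvh_metrics()].
#' @param d_pres prescribed dose in Gy (> 0).
#' @return Named numeric vector (`d2`, `d95`, `d98`, `dmean`) in %.
#' @export
delta_dx <- function(eval_metrics, ref_metrics, d_pres) {
  stopifnot(d_pres > 0)
  nm <- c("d2", "d95", "d98", "dmean")
  vapply(nm, function(m)
    100 * (eval_metrics[[m]] - ref_metrics[[m]]) / d_pres, numeric(1))
}

#' Export a cumulative DVH curve
#'
#' @param x a `dvh`.
#' @return data frame with `dose_gy` and `volume_fraction` (descending).
#' @export
dvh_curve <- function(x) {
  stopifnot(inherits(x, "dvh"))
  n <- length(x$sorted_doses)
  data.frame(dose_gy = x$sorted_doses, volume_fraction = seq_len(n) / n)
}
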