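# Full study replica: simulate a cohort, compute doses on CT / sCT_clin /
# QA-generator sCTs, compare sCT_clin against every reference, classify
# against tolerances, and emit the report tables (per-patient metrics,
# boxplot summaries with labelled outliers, sensitivity matrix,
# positioning deltas).

#' QA-generator role emulation
#'
#' Describes which planted error mode plays the role of one QA sCT
#' generator.  `auto_reject_artifacts` emulates a generator refusing to
#' produce an sCT for patients with MR artifacts (their clinical mode is
#' METAL_ARTIFACT); such patients are excluded from that generator's
#' confusion counts and logged.  `near_sinus_only` applies the mode only to
#' patients whose PTV is placed near the sinus (others get a faithful sCT),
#' emulating a generator whose failures concentrate in the heterogeneous
#' sinus region.
#'
#' @param mode an [error_mode()].
#' @param auto_reject_artifacts logical.
#' @param near_sinus_only logical.
#' @return A `generator_role` list.
#' @export
generator_role <- function(mode, auto_reject_artifacts = FALSE,
                           near_sinus_only = FALSE) {
  structure(list(mode = mode, auto_reject_artifacts = auto_reject_artifacts,
                 near_sinus_only = near_sinus_only),
            class = "generator_role")
}

#' @rdname generator_role
#' @param bd_soft_shift_hu soft-tissue shift for the bulk-density role
#'   (see [calibrate_bias()]).
#' @export
default_generator_roles <- function(bd_soft_shift_hu = 0) {
  list(
    sCT_QA_AI_1 = generator_role(error_mode("NONE"),
                                 auto_reject_artifacts = TRUE),
    sCT_QA_AI_2 = generator_role(error_mode("SINUS_MISPREDICTION"),
                                 near_sinus_only = TRUE),
    sCT_QA_BD = generator_role(error_mode("BULK_DENSITY",
                                          soft_shift_hu = bd_soft_shift_hu)))
}

#' Study configuration
#'
#' @param n_patients cohort size.
#' @param clin_modes list of [error_mode()] for the clinical sCT, one per
#'   patient (default all `NONE`).
#' @param generators named list of [generator_role()] emulating the QA
#'   generators (may be empty for a CT-only comparison).
#' @param base_spec,spec_overrides phantom-spec arguments shared by the
#'   cohort / per-patient overrides (see [cohort_spec()]).
#' @param prescription_gy,mu_eff_per_mm plan parameters.
#' @param cal a [density_calibration()].
#' @param criteria a [gamma_criteria()] or `NULL` to skip gamma.
#' @param tol a [tolerance_set()].
#' @param positioning list: `enabled`, `n_fractions`, `patients` (ids to
#'   run the positioning study on).
#' @param master_seed master seed for the whole study.
#' @param outdir output directory, or `NULL` to skip writing.
#' @param figures also write PNG boxplots.
#' @return A `study_config` list.
#' @export
study_config <- function(n_patients = 20, clin_modes = NULL,
                         generators = default_generator_roles(),
                         base_spec = list(), spec_overrides = list(),
                         prescription_gy = 60, mu_eff_per_mm = 0.005,
                         cal = density_calibration(),
                         criteria = gamma_criteria(), tol = tolerance_set(),
                         positioning = list(enabled = FALSE, n_fractions = 1,
                                            patients = 1),
                         master_seed = 1L, outdir = NULL, figures = FALSE) {
  if (is.null(clin_modes))
    clin_modes <- rep(list(error_mode("NONE")), n_patients)
  structure(list(n_patients = n_patients, clin_modes = clin_modes,
                 generators = generators, base_spec = base_spec,
                 spec_overrides = spec_overrides,
                 prescription_gy = prescription_gy,
                 mu_eff_per_mm = mu_eff_per_mm, cal = cal,
                 criteria = criteria, tol = tol, positioning = positioning,
                 master_seed = as.integer(master_seed), outdir = outdir,
                 figures = figures),
            class = "study_config")
}

#' Boxplot summary with labelled outliers
#'
#' Median and quartiles by linear-interpolation quantiles (type 7);
#' outliers are values beyond the 1.5 x IQR fences, tagged with their
#' patient id.
#'
#' @param values numeric vector.
#' @param patient_ids ids parallel to `values`.
#' @return list: median, q1, q3, iqr, fences, `outliers` data frame.
#' @export
summarize_boxplot <- function(values, patient_ids = seq_along(values)) {
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values < lo | values > hi
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       lower_fence = lo, upper_fence = hi,
       outliers = data.frame(patient_id = patient_ids[out],
                             value = values[out]))
}

# patient-level decision: accept iff every listed metric accepts
patient_verdicts <- function(verdicts, metrics = unique(verdicts$metric)) {
  v <- verdicts[verdicts$metric %in% metrics, ]
  ids <- sort(unique(v$patient_id))
  dec <- vapply(ids, function(id)
    if (all(v$decision[v$patient_id == id] == "accept")) "accept"
    else "reject", character(1))
  data.frame(patient_id = ids, decision = dec)
}

#' Run the full PSQA study replica
#'
#' Deterministic for a fixed master seed: generates the cohort, computes
#' the CT dose (fixing the per-patient normalization), recalculates on
#' every sCT with the normalization unchanged, compares sCT_clin against
#' the CT and every QA generator, classifies against the tolerance set and
#' assembles the sensitivity matrix.  Patients auto-rejected by a
#' generator are excluded from that generator's counts and logged.
#'
#' @param config a [study_config()].
#' @return A `study_report` list: `reports`, `verdicts`, `truth`,
#'   `summaries`, `sensitivity_matrix`, `confusion`, `excluded`,
#'   `positioning`, `seed`.  Written to `config$outdir` when set (see
#'   [write_study_report()]).
#' @export
run_study <- function(config) {
  cohort <- cohort_spec(config$n_patients, config$clin_modes,
                        config$master_seed, config$spec_overrides,
                        config$base_spec)
  gen <- generate_cohort(cohort)
  report_rows <- list()
  excluded <- lapply(config$generators, function(g) integer(0))
  for (i in seq_along(gen$patients)) {
    pat <- gen$patients[[i]]
    plan <- plan_spec(default_plan(pat$structures$ptv),
                      config$prescription_gy, config$mu_eff_per_mm)
    ct_dose <- compute_plan_dose(pat$ct, plan, config$cal,
                                 pat$structures$ptv)
    clin_dose <- compute_plan_dose(pat$sct, plan, config$cal,
                                   mu_factor = ct_dose$mu_factor)
    refs <- list(CT = ct_dose$dose)
    for (gname in names(config$generators)) {
      role <- config$generators[[gname]]
      if (role$auto_reject_artifacts && pat$truth$mode == "METAL_ARTIFACT") {
        excluded[[gname]] <- c(excluded[[gname]], pat$patient_id)
        next
      }
      mode <- role$mode
      if (role$near_sinus_only && pat$spec$ptv_placement != "near_sinus")
        mode <- error_mode("NONE")
      spec_g <- pat$spec
      spec_g$seed <- derive_seed(config$master_seed,
                                 pat$patient_id * 1000 + match(gname,
                                   names(config$generators)))
      qa_pair <- generate_phantom_pair(spec_g, mode, frame_id = pat$ct$frame_id)
      qa_dose <- compute_plan_dose(qa_pair$sct, plan, config$cal,
                                   mu_factor = ct_dose$mu_factor)
      refs[[gname]] <- qa_dose$dose
    }
    for (rname in names(refs))
      report_rows[[paste(i, rname)]] <- metric_report(
        pat$patient_id, rname, clin_dose$dose, refs[[rname]],
        pat$structures, config$prescription_gy, config$criteria)
  }
  reports <- do.call(rbind, report_rows)
  rownames(reports) <- NULL
  verdicts <- verdict_table(reports, config$tol)
  metrics <- unique(verdicts$metric)
  ct_verd <- verdicts[verdicts$reference == "CT", ]
  sens_rows <- list()
  conf <- list()
  for (gname in names(config$generators)) {
    if (!gname %in% verdicts$reference) next
    gv <- verdicts[verdicts$reference == gname, ]
    for (m in metrics) {
      cc <- confusion(ct_verd[ct_verd$metric == m, ],
                      gv[gv$metric == m, ], excluded[[gname]])
      conf[[paste(gname, m, sep = ".")]] <- cc
      sens_rows[[paste(gname, m)]] <- data.frame(
        generator = gname, metric = m, sensitivity = sensitivity(cc),
        specificity = specificity(cc), tp = cc$tp, fn = cc$fn, fp = cc$fp,
        tn = cc$tn, n = cc$n)
    }
  }
  sens <- if (length(sens_rows)) do.call(rbind, sens_rows) else NULL
  if (!is.null(sens)) rownames(sens) <- NULL
  summaries <- summarize_study(reports)
  positioning <- NULL
  if (isTRUE(config$positioning$enabled)) {
    pos_rows <- list()
    for (pid in config$positioning$patients) {
      pat <- gen$patients[[pid]]
      geom <- projection_geometry()
      tab <- run_positioning_study(pat$ct, pat$sct, geom,
                                   n_fractions = config$positioning$n_fractions,
                                   master_seed = derive_seed(
                                     config$master_seed, 500000 + pid))
      tab$patient_id <- pat$patient_id
      pos_rows[[length(pos_rows) + 1]] <- tab
    }
    positioning <- do.call(rbind, pos_rows)
  }
  report <- structure(list(reports = reports, verdicts = verdicts,
                           truth = gen$truth, summaries = summaries,
                           sensitivity_matrix = sens, confusion = conf,
                           excluded = excluded, positioning = positioning,
                           seed = config$master_seed),
                      class = "study_report")
  if (!is.null(config$outdir))
    write_study_report(report, config$outdir, figures = config$figures)
  report
}

# boxplot summaries + paired Wilcoxon annotation (delegated to the standard
# routine) for every metric column, per reference
summarize_study <- function(reports) {
  metric_cols <- c("me_ptv_pct", "me_brain_pct", "me_skull_pct",
                   "delta_d2_pct", "delta_d95_pct", "delta_d98_pct",
                   "delta_dmean_pct", "gamma_pass_pct")
  rows <- list()
  for (ref in unique(reports$reference)) {
    sub <- reports[reports$reference == ref, ]
    for (mc in metric_cols) {
      if (all(is.na(sub[[mc]]))) next
      s <- summarize_boxplot(sub[[mc]], sub$patient_id)
      p_wilcox <- NA_real_
      if (ref != "CT") {
        ct_sub <- reports[reports$reference == "CT", ]
        common <- intersect(sub$patient_id, ct_sub$patient_id)
        if (length(common) >= 3) {
          a <- sub[[mc]][match(common, sub$patient_id)]
          b <- ct_sub[[mc]][match(common, ct_sub$patient_id)]
          if (any(a != b))
            p_wilcox <- suppressWarnings(
              wilcox.test(a, b, paired = TRUE)$p.value)
        }
      }
      rows[[paste(ref, mc)]] <- data.frame(
        reference = ref, metric = mc, median = s$median, q1 = s$q1,
        q3 = s$q3, lower_fence = s$lower_fence, upper_fence = s$upper_fence,
        n_outliers = nrow(s$outliers),
        outlier_patients = paste(s$outliers$patient_id, collapse = ";"),
        p_wilcoxon_vs_ct = p_wilcox)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a study report to disk
#'
#' Emits `metric_reports.csv`, `verdicts.csv`, `truth.csv`,
#' `summaries.csv`, `sensitivity.csv`, `positioning.csv` (when run) and
#' `study.json` (seed, exclusions, confusion counts).  File content is a
#' pure function of the report, so identical seeds give byte-identical
#' files.
#'
#' @param report a [run_study()] result.
#' @param outdir output directory (created if needed).
#' @param figures also write PNG boxplot figures.
#' @return `outdir`, invisibly.
#' @export
write_study_report <- function(report, outdir, figures = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    if (!is.null(df)) write.csv(df, file.path(outdir, name), row.names = FALSE)
  wr(report$reports, "metric_reports.csv")
  wr(report$verdicts, "verdicts.csv")
  wr(report$truth, "truth.csv")
  wr(report$summaries, "summaries.csv")
  wr(report$sensitivity_matrix, "sensitivity.csv")
  wr(report$positioning, "positioning.csv")
  jsonlite::write_json(
    list(seed = report$seed,
         excluded = report$excluded,
         confusion = lapply(report$confusion, function(cc)
           list(tp = cc$tp, fn = cc$fn, fp = cc$fp, tn = cc$tn))),
    file.path(outdir, "study.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (figures) write_study_figures(report, outdir)
  invisible(outdir)
}

write_study_figures <- function(report, outdir) {
  figs <- list(me_ptv = "me_ptv_pct", delta_d2 = "delta_d2_pct",
               gamma = "gamma_pass_pct")
  for (nm in names(figs)) {
    col <- figs[[nm]]
    if (all(is.na(report$reports[[col]]))) next
    grDevices::png(file.path(outdir, paste0(nm, "_boxplot.png")),
                   width = 800, height = 500)
    graphics::boxplot(report$reports[[col]] ~ report$reports$reference,
                      xlab = "reference", ylab = col, main = nm)
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Read a study configuration from YAML or JSON
#'
#' Scalar fields map directly onto [study_config()] arguments; per-patient
#' clinical modes are given as a list of `{patient, kind}` records.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  n <- cfg$n_patients %||% 20
  modes <- rep(list(error_mode("NONE")), n)
  if (!is.null(cfg$clin_modes))
    for (rec in cfg$clin_modes)
      modes[[rec$patient]] <- error_mode(rec$kind)
  args <- list(n_patients = n, clin_modes = modes)
  for (f in c("prescription_gy", "mu_eff_per_mm", "master_seed", "outdir",
              "figures"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$base_spec)) args$base_spec <- cfg$base_spec
  if (!is.null(cfg$tolerance))
    args$tol <- tolerance_set(cfg$tolerance$point %||% 1,
                              cfg$tolerance$gamma_floor %||% 90)
  if (!is.null(cfg$gamma))
    args$criteria <- gamma_criteria(cfg$gamma$dose_percent %||% 1,
                                    cfg$gamma$distance_mm %||% 1,
                                    cfg$gamma$threshold_fraction %||% 0.2)
  if (!is.null(cfg$positioning)) args$positioning <- cfg$positioning
  if (isTRUE(cfg$ct_only)) args$generators <- list()
  do.call(study_config, args)
}
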