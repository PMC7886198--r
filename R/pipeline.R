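#' Pipeline configuration
#'
#' Validated parameter set for the end-to-end analysis. Every threshold
#' the pipeline applies (lesion SD multiplier, FA and turning-angle
#' stops, GEE gate alpha) lives here and is echoed to the run log, so a
#' reanalysis is auditable. Unknown keys are rejected.
#'
#' @param n_per_group Animals per treatment arm (default 6).
#' @param grid_shape,voxel_size Phantom grid (default 64 x 64 x 16 at
#'   0.156 x 0.156 x 0.75 mm).
#' @param snr Acquisition SNR (default 30; `Inf` = noiseless).
#' @param sd_multiplier Lesion/CSF threshold multiplier k in
#'   mean + k SD (default 2).
#' @param fa_threshold,max_angle_deg,step_size,min_length,max_steps
#'   Tracking parameters (see [tracking_params()]).
#' @param slice_start,n_slices Contiguous slice window for ventricular
#'   volumetry (default 8 slices starting at slice 5).
#' @param gate_alpha GEE interaction gate for post-hoc testing (0.05).
#' @param lesion_free Simulate intact controls instead of stroked arms.
#' @param lesion_scale Multiplier on cohort lesion radii (see
#'   [simulate_cohort()]); keep at 1 for the study-scale grid.
#' @param roi_source `"auto"` (recovery ROI for lesioned animals, the
#'   ipsilesional white-matter bundle for intact ones), `"recovery"`,
#'   or `"bundle"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_group = 6L,
                            grid_shape = c(64L, 64L, 16L),
                            voxel_size = c(0.156, 0.156, 0.75),
                            snr = 30,
                            sd_multiplier = 2,
                            fa_threshold = 0.15,
                            max_angle_deg = 45,
                            step_size = NULL,
                            min_length = NULL,
                            max_steps = 2000L,
                            slice_start = 5L,
                            n_slices = 8L,
                            gate_alpha = 0.05,
                            lesion_free = FALSE,
                            lesion_scale = 1,
                            roi_source = c("auto", "recovery", "bundle")) {
  roi_source <- match.arg(roi_source)
  if (sd_multiplier <= 0) stop("sd_multiplier must be positive")
  if (gate_alpha <= 0 || gate_alpha >= 1) stop("gate_alpha must be in (0, 1)")
  if (n_slices < 1L) stop("n_slices must be >= 1")
  # range checks shared with the module constructors
  tracking_params(fa_threshold = fa_threshold, max_angle_deg = max_angle_deg,
                  step_size = step_size, max_steps = max_steps,
                  min_length = min_length)
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 snr = snr, sd_multiplier = sd_multiplier,
                 fa_threshold = fa_threshold, max_angle_deg = max_angle_deg,
                 step_size = step_size, min_length = min_length,
                 max_steps = as.integer(max_steps),
                 slice_start = as.integer(slice_start),
                 n_slices = as.integer(n_slices),
                 gate_alpha = gate_alpha, lesion_free = lesion_free,
                 lesion_scale = lesion_scale, roi_source = roi_source),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns a validated [pipeline_config()] (unknown keys are an error).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

# Analyse one simulated animal end-to-end; returns tidy metric rows.
# The ROI is defined once from the day-1 and final-timepoint lesion
# segmentations (or the ipsilesional bundle for intact animals) and
# applied to every timepoint.
analyze_subject <- function(spec, config, subject_id, group, log) {
  tps <- spec$timepoints
  nt <- length(tps)
  scheme <- gradient_scheme()
  hemi <- hemisphere_masks(spec$grid_shape, spec$voxel_size)
  params <- tracking_params(fa_threshold = config$fa_threshold,
                            max_angle_deg = config$max_angle_deg,
                            step_size = config$step_size,
                            max_steps = config$max_steps,
                            min_length = config$min_length)
  slices <- seq(config$slice_start, length.out = config$n_slices)

  vols <- vector("list", nt)
  t2s <- vector("list", nt)
  mapsets <- vector("list", nt)
  eigsets <- vector("list", nt)
  lesions <- vector("list", nt)
  vent_vol <- numeric(nt)
  lesion_vol <- numeric(nt)
  for (ti in seq_len(nt)) {
    tissues <- default_tissues(spec$lesion_eigenvalue_factor[ti])
    lv <- build_label_volume(spec, tps[ti])
    t2 <- simulate_t2(lv, tissues, seed = spec$seed + 13L * ti)
    dwi <- simulate_dwi(lv, tissues, scheme, snr = spec$snr,
                        seed = spec$seed + 977L * ti)
    eigs <- eigendecompose(fit_tensor(dwi))
    maps <- scalar_maps(eigs)

    contra_normal <- label_mask(unclass(hemi$contra) &
                                  array(lv$labels %in% c(1L, 2L), dim(lv$labels)),
                                spec$voxel_size, "contra_normal")
    les <- suppressMessages(segment_lesion(t2, contra_normal, hemi$ipsi,
                                           k = config$sd_multiplier))
    log(sprintf("subject=%s tp=%s stage=segment threshold=%.4f", subject_id,
                tps[ti], attr(les, "threshold")))
    vent <- measure_ventricles(t2, lv$masks$csf, slices, contra_normal,
                               k = config$sd_multiplier)
    vols[[ti]] <- lv; t2s[[ti]] <- t2; mapsets[[ti]] <- maps
    eigsets[[ti]] <- eigs; lesions[[ti]] <- les
    vent_vol[ti] <- as.numeric(vent)
    lesion_vol[ti] <- mask_volume(les)
  }

  use_bundle <- config$roi_source == "bundle" ||
    (config$roi_source == "auto" && all(spec$lesion_radius == 0))
  roi_ipsi <- if (use_bundle) {
    label_mask(unclass(vols[[nt]]$masks$white) & unclass(hemi$ipsi),
               spec$voxel_size, "bundle_roi")
  } else {
    recovery_roi(lesions[[1L]], lesions[[nt]])
  }
  if (sum(roi_ipsi) == 0L) {
    warning(sprintf("subject %s: empty analysis ROI; relative metrics skipped",
                    subject_id))
  }
  roi <- if (sum(roi_ipsi) > 0L) roi_pair(roi_ipsi) else NULL
  log(sprintf("subject=%s stage=roi source=%s n_voxels=%d", subject_id,
              if (use_bundle) "bundle" else "recovery", sum(roi_ipsi)))

  rows <- list()
  add <- function(tp, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(subject = subject_id, group = group,
                                             timepoint = tp, metric = metric,
                                             value = value)
  norm_or_na <- function(v) {
    if (v[1] > 0) v / v[1] else { warning("day-1 volume is zero; normalization undefined"); rep(NA_real_, length(v)) }
  }
  lesion_norm <- norm_or_na(lesion_vol)
  vent_norm <- norm_or_na(vent_vol)
  for (ti in seq_len(nt)) {
    add(tps[ti], "lesion_volume_mm3", lesion_vol[ti])
    add(tps[ti], "lesion_volume_norm", lesion_norm[ti])
    add(tps[ti], "ventricle_volume_mm3", vent_vol[ti])
    add(tps[ti], "ventricle_volume_norm", vent_norm[ti])
    if (!is.null(roi)) {
      tr_i <- track(eigsets[[ti]], mapsets[[ti]]$FA, roi$ipsi, params)
      tr_c <- track(eigsets[[ti]], mapsets[[ti]]$FA, roi$contra, params)
      rel <- relative_metrics(roi, mapsets[[ti]])
      fd_i <- fiber_density(tr_i); fd_c <- fiber_density(tr_c)
      rel$rFD <- if (fd_c > 0) fd_i / fd_c else NA_real_
      if (fd_c == 0)
        warning(sprintf("subject %s %s: no contralateral streamlines; rFD undefined",
                        subject_id, tps[ti]))
      log(sprintf("subject=%s tp=%s stage=track fa_stop=%.2f angle_stop=%.0f fd_ipsi=%.3f fd_contra=%.3f",
                  subject_id, tps[ti], params$fa_threshold, params$max_angle_deg,
                  fd_i, fd_c))
      for (m in names(rel)) add(tps[ti], m, rel[[m]])
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates (or reuses) a treated cohort, runs every imaging stage per
#' animal and timepoint — tensor fit, scalar maps, lesion and ventricle
#' volumetry with day-1 normalization, recovery-ROI construction with
#' mirrored controls, ROI-seeded tractography, relative metrics — scores
#' the behavioral records, and runs the inference layer: a GEE
#' group-by-time interaction test per outcome, gating per-timepoint
#' one-way ANOVA + Tukey post-hocs, plus Pearson correlations between
#' final-timepoint morphology and DTI outcomes. Fully deterministic
#' under `seed`.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory; created if missing. `NULL` disables
#'   file output.
#' @return List: `metrics` (tidy metric table), `mnss` (scored records),
#'   `exclusions` (report), `gee` (per-outcome interaction tests),
#'   `posthoc` (gated ANOVA/Tukey rows), `pearson`, `log` (character).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L, out_dir = NULL) {
  log_lines <- character()
  log <- function(msg) log_lines[[length(log_lines) + 1L]] <<- msg
  log(sprintf("stage=config sd_multiplier=%g fa_threshold=%g max_angle_deg=%g gate_alpha=%g snr=%g",
              config$sd_multiplier, config$fa_threshold, config$max_angle_deg,
              config$gate_alpha, config$snr))

  sim <- simulate_cohort(config$n_per_group, seed = seed,
                         grid_shape = config$grid_shape,
                         voxel_size = config$voxel_size,
                         snr = config$snr, lesion_free = config$lesion_free,
                         lesion_scale = config$lesion_scale)
  filt <- apply_exclusions(sim$cohort)
  log(sprintf("stage=exclusions enrolled=%d included=%d",
              filt$report$n_enrolled, filt$report$n_included))

  metric_rows <- list()
  for (i in seq_len(nrow(filt$included))) {
    id <- filt$included$animal[i]
    metric_rows[[id]] <- analyze_subject(sim$specs[[id]], config, id,
                                         filt$included$group[i], log)
  }
  metrics <- do.call(rbind, c(metric_rows, list(make.row.names = FALSE)))

  mnss <- score_mnss(sim$mnss[sim$mnss$animal %in% filt$included$animal, ])
  mnss_rows <- data.frame(subject = mnss$animal, group = mnss$group,
                          timepoint = mnss$timepoint, metric = "mnss_total",
                          value = mnss$mnss_total)
  metrics <- rbind(metrics, mnss_rows)

  outcomes <- c("mnss_total", "lesion_volume_norm", "ventricle_volume_norm",
                "rFA", "rAD", "rRD", "rFD")
  gee_rows <- list(); posthoc_rows <- list()
  for (oc in outcomes) {
    d <- metrics[metrics$metric == oc & is.finite(metrics$value), ]
    if (nrow(d) == 0L || length(unique(d$group)) < 2L ||
        length(unique(d$timepoint)) < 2L) next
    gi <- tryCatch(gee_interaction(d, outcome = "value"),
                   error = function(e) { log(sprintf("stage=gee outcome=%s error=%s", oc, conditionMessage(e))); NULL })
    if (is.null(gi)) next
    gi$outcome <- oc
    gee_rows[[oc]] <- gi
    log(sprintf("stage=gee outcome=%s p=%.4g gate=%s", oc, gi$p,
                ifelse(gi$p < config$gate_alpha, "open", "closed")))
    if (is.finite(gi$p) && gi$p < config$gate_alpha) {
      for (tp in unique(d$timepoint)) {
        dt <- d[d$timepoint == tp, ]
        if (min(table(dt$group)) < 2L) next
        at <- anova_tukey(dt$value, dt$group)
        tuk <- at$tukey
        tuk$outcome <- oc; tuk$timepoint <- tp
        tuk$anova_p <- at$anova$p
        posthoc_rows[[paste(oc, tp)]] <- tuk
      }
    }
  }
  gee <- if (length(gee_rows)) do.call(rbind, c(gee_rows, list(make.row.names = FALSE))) else NULL
  posthoc <- if (length(posthoc_rows)) do.call(rbind, c(posthoc_rows, list(make.row.names = FALSE))) else NULL
  if (!is.null(posthoc))
    posthoc$signif <- cut(posthoc$p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                          labels = c("***", "**", "*", ""))

  # morphology vs microstructure at the final timepoint
  tp_last <- sim$timepoints[length(sim$timepoints)]
  wide <- function(m) {
    d <- metrics[metrics$metric == m & metrics$timepoint == tp_last, ]
    stats::setNames(d$value, d$subject)
  }
  pearson <- NULL
  lesion_last <- wide("lesion_volume_norm")
  for (m in c("rFA", "rFD")) {
    v <- wide(m)
    common <- intersect(names(lesion_last), names(v))
    common <- common[is.finite(lesion_last[common]) & is.finite(v[common])]
    if (length(common) >= 3L) {
      pr <- pearson_cor(lesion_last[common], v[common])
      pr$pair <- sprintf("lesion_volume_norm~%s", m)
      pearson <- rbind(pearson, pr)
      log(sprintf("stage=pearson pair=%s r=%.3f p=%.4g", pr$pair, pr$r, pr$p))
    }
  }

  out <- list(metrics = metrics, mnss = mnss, exclusions = filt$report,
              gee = gee, posthoc = posthoc, pearson = pearson,
              log = log_lines)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metric_table(metrics, file.path(out_dir, "metric_table.tsv"))
    if (!is.null(gee)) write_metric_table(gee, file.path(out_dir, "gee_tests.tsv"))
    if (!is.null(posthoc)) write_metric_table(posthoc, file.path(out_dir, "posthoc.tsv"))
    if (!is.null(pearson)) write_metric_table(pearson, file.path(out_dir, "pearson.tsv"))
    write_config(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(list(exclusions = filt$report[c("n_enrolled", "n_included", "n_excluded")],
                              gate_alpha = config$gate_alpha,
                              gees = if (!is.null(gee)) gee else list()),
                         file.path(out_dir, "summary.json"), auto_unbox = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}
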