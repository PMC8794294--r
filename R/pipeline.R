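#' Pipeline configuration
#'
#' All stage parameters in one validated list. Defaults match the study's
#' stated acquisition and analysis parameters: 25 Hz sampling, 0.01-0.3 Hz
#' band-pass, 60-s epochs, 10-s window with 1-s step, alpha = 0.05.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs = 25,
    baseline_window = c(0, 30),
    despike_k = 3, despike_levels = 5, wavelet = "db4",
    band = c(0.01, 0.3), filter_order = 3,
    dpf = c(6, 6),
    qc_thresholds = c(good = 10, average = 3),
    epoch_s = 60, window_s = 10, step_s = 1,
    corr_keep = seq(0, 50, by = 10),
    alpha = 0.05,
    run_despike = TRUE,
    exclude_poor_channels = TRUE,
    apply_quality_gate = TRUE
  )
  cfg <- utils::modifyList(cfg, list(...))
  if (cfg$band[2] >= cfg$fs / 2)
    stop("band high edge (", cfg$band[2], " Hz) must be below Nyquist (",
         cfg$fs / 2, " Hz)")
  if (cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2])
    stop("need 0 < band low < band high")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full analysis pipeline on a simulated or loaded cohort
#'
#' Stages, in order, for every session: quality classification and the
#' subject inclusion gate; optical density; wavelet motion correction;
#' zero-phase band-pass; modified Beer-Lambert conversion;
#' short-separation regression; polynomial detrending; contralateral /
#' ipsilateral ROI averaging; P0/P1/P2 epoch extraction; standardized
#' rolling curves; absolute-AUC and dynamic-correlation tables; group
#' statistics with BH-FDR. Excluded subjects are reported in the manifest,
#' never silently dropped.
#'
#' @param cohort A cohort as returned by [simulate_cohort()], or a list
#'   with the same shape built from loaded sessions (`sessions` = list of
#'   `list(rec, events)`, `patients` tibble).
#' @param config A [pipeline_config()].
#' @param montage Montage from [load_montage()].
#' @return List with `curves`, `auc`, `dyncorr` (contralateral and
#'   ipsilateral), `stats`, `demographics`, `quality`, and `manifest`
#'   (seed/config hashes, inclusion bookkeeping).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         montage = load_montage()) {
  stopifnot(!is.null(cohort$sessions), !is.null(cohort$patients))
  patients <- cohort$patients
  curves <- list(); epochs_by_patient <- list(); quality <- list()
  excluded <- character(0)
  warnings_log <- character(0)
  for (s in cohort$sessions) {
    pid <- s$rec$patient_id
    pp <- withCallingHandlers(
      preprocess_session(s$rec, montage, config),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(pid, ": ",
                                                conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    quality[[pid]] <- pp$quality
    if (config$apply_quality_gate && !pp$quality$include) {
      excluded <- c(excluded, pid)
      next
    }
    lat <- patients$laterality[match(pid, patients$patient_id)]
    roi <- map_sides(pp$conc, montage, lat,
                     quality = if (config$exclude_poor_channels)
                       pp$quality else NULL)
    eps <- withCallingHandlers(
      extract_epochs(roi, s$events, epoch_s = config$epoch_s),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(pid, ": ",
                                                conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    epochs_by_patient[[pid]] <- eps
    curves[[pid]] <- epoch_curves(eps, fs = config$fs)
  }
  if (length(curves) == 0) stop("all subjects excluded by the quality gate")
  auc <- compute_auc_table(curves, patients)
  dyn_con <- compute_dyncorr_table(epochs_by_patient, patients,
                                   side = "contralateral", fs = config$fs,
                                   keep = config$corr_keep)
  dyn_ips <- compute_dyncorr_table(epochs_by_patient, patients,
                                   side = "ipsilateral", fs = config$fs,
                                   keep = config$corr_keep)
  included <- names(curves)
  stats <- list(
    auc = auc_group_tests(auc, alpha = config$alpha),
    dyncorr = list(
      contralateral = dyncorr_anova(dyn_con, alpha = config$alpha),
      ipsilateral = dyncorr_anova(dyn_ips, alpha = config$alpha)))
  demographics <- demographic_summary(patients)
  manifest <- list(
    package_version = as.character(utils::packageVersion("nirspipe")),
    seed = cohort$seed,
    config_hash = rlang::hash(unclass(config)),
    cohort_hash = rlang::hash(lapply(cohort$sessions, function(s)
      s$rec$intensity)),
    n_subjects = nrow(patients),
    n_included = length(included),
    excluded = excluded,
    warnings = warnings_log,
    timestamp = format(Sys.time(), tz = "UTC"))
  list(curves = curves, auc = auc,
       dyncorr = list(contralateral = dyn_con, ipsilateral = dyn_ips),
       stats = stats, demographics = demographics, quality = quality,
       manifest = manifest)
}

#' Read / write a pipeline configuration file
#'
#' YAML serialization of a [pipeline_config()]; reading re-validates, so a
#' config written and read back is identical (lossless round trip) and an
#' edited file with out-of-range parameters fails before any compute.
#'
#' @param path YAML file path.
#' @param cfg A `pipeline_config`.
#' @return `read_pipeline_config` returns the validated config;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$qc_thresholds))
    raw$qc_thresholds <- unlist(raw$qc_thresholds)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  out$qc_thresholds <- as.list(cfg$qc_thresholds)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Group-effect recovery on one simulated cohort
#'
#' Simulates a cohort, runs the preprocessing chain (compiled fast path),
#' extracts the P0/P1/P2 epochs, computes the absolute AUC of the
#' standardized rolling curves averaged over the contralateral S1 ROIs, and
#' tests the nerve-block group effect with the split-plot mixed ANOVA.
#' Used by simulation studies of detection power (effect configs) and
#' type-I calibration (matched null configs).
#'
#' @param config A [sim_config()] (typically the `brief` profile).
#' @param seed Cohort seed.
#' @param montage Montage.
#' @param rois ROIs whose AUC is averaged into the response.
#' @param side,species Which side / hemoglobin species to analyse.
#' @return One-row tibble: `p` (group-effect p-value), `direction_ok`
#'   (`TRUE` when the no-nerve-block mean AUC exceeds the nerve-block
#'   mean, the injected direction), `n_included`.
#' @export
cohort_group_effect <- function(config = sim_config("brief"), seed = 1,
                                montage = load_montage(),
                                rois = rois_all("S1"),
                                side = "contralateral", species = "hbo2") {
  co <- simulate_cohort(config, seed, montage)
  rows <- list()
  for (i in seq_along(co$sessions)) {
    s <- co$sessions[[i]]
    pp <- preprocess_session(s$rec, montage, engine = "core")
    if (!pp$quality$include) next
    roi <- map_sides(pp$conc, montage, co$patients$laterality[i],
                     pp$quality)
    eps <- extract_epochs(roi, s$events)
    for (k in names(eps)) {
      aucs <- vapply(rois, function(r)
        auc_abs(rolling_curve(eps[[k]]$segments[[side]][[species]][, r],
                              fs = config$fs)), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = s$rec$patient_id,
        group = ifelse(co$patients$nerve_block[i], "NB", "non-NB"),
        epoch = k, auc = mean(aucs))
    }
  }
  d <- do.call(rbind, rows)
  an <- mixed_anova(d, "auc", "patient_id", "group", "epoch")
  means <- tapply(d$auc, d$group, mean)
  tibble::tibble(p = an$p[an$effect == "between"],
                 direction_ok = unname(means["non-NB"] > means["NB"]),
                 n_included = length(unique(d$patient_id)))
}

#' Human-readable summary of pipeline results
#'
#' Prints per-ROI mean curve summaries, the AUC table with t-test and FDR
#' flags, the pair-set correlation effects and the demographics block;
#' sections whose inputs are absent are marked missing rather than omitted.
#'
#' @param results Output of [run_pipeline()] (possibly partial).
#' @param file Optional path; when given, the report is also written there.
#' @return The report lines, invisibly.
#' @export
report <- function(results, file = NULL) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("== nirspipe analysis report ==")
  if (!is.null(results$demographics)) {
    g <- results$demographics$groups
    add("-- demographics --")
    for (i in seq_len(nrow(g)))
      add(sprintf("  %s: n=%d, age %.1f +/- %s, %dF/%dM", g$group[i],
                  g$n[i], g$mean_age[i],
                  ifelse(is.na(g$sd_age[i]), "NA",
                         sprintf("%.2f", g$sd_age[i])),
                  g$n_female[i], g$n_male[i]))
    add(sprintf("  nerve-block fraction: %.0f%%",
                100 * results$demographics$nb_fraction))
  } else add("-- demographics: missing --")
  if (!is.null(results$auc) && nrow(results$auc)) {
    add("-- absolute AUC by group (contralateral HbO2) --")
    sub <- results$auc[results$auc$side == "contralateral" &
                         results$auc$species == "hbo2", ]
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$roi, .data$epoch, .data$group),
      mean_auc = mean(.data$auc), se = stats::sd(.data$auc) /
        sqrt(dplyr::n()), .groups = "drop")
    for (i in seq_len(nrow(agg)))
      add(sprintf("  %-14s %s %-7s mean AUC %6.2f (SE %.2f)", agg$roi[i],
                  agg$epoch[i], agg$group[i], agg$mean_auc[i], agg$se[i]))
  } else add("-- AUC table: missing --")
  if (!is.null(results$stats$auc$ttests) &&
      nrow(results$stats$auc$ttests)) {
    tt <- results$stats$auc$ttests
    sig <- tt[tt$significant_raw, ]
    add(sprintf("-- AUC group t-tests: %d/%d significant at raw p, %d after FDR --",
                nrow(sig), nrow(tt), sum(tt$significant_fdr)))
  } else add("-- AUC statistics: missing --")
  if (!is.null(results$stats$dyncorr$contralateral) &&
      nrow(results$stats$dyncorr$contralateral)) {
    dc <- results$stats$dyncorr$contralateral
    add(sprintf("-- dynamic-correlation effects (contralateral): %d significant raw, %d after FDR --",
                sum(dc$significant_raw, na.rm = TRUE),
                sum(dc$significant_fdr, na.rm = TRUE)))
  } else add("-- dynamic-correlation statistics: missing --")
  if (!is.null(results$manifest)) {
    add(sprintf("-- manifest: %d/%d subjects included; excluded: %s --",
                results$manifest$n_included, results$manifest$n_subjects,
                if (length(results$manifest$excluded))
                  paste(results$manifest$excluded, collapse = ", ")
                else "none"))
  }
  if (!is.null(file)) writeLines(ln, file)
  cat(ln, sep = "\n")
  invisible(ln)
}
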