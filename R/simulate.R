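#' Configuration for the synthetic intraoperative cohort generator
#'
#' Defaults emulate the study conditions: 19 patients with an 11/8
#' nerve-block / no-nerve-block split, 25-65 min sessions sampled at 25 Hz,
#' 2-12 painful procedures per session, an evoked contralateral response
#' peaking ~20 s after painful events (0.41 uM HbO2 in S1 for the
#' no-nerve-block group, attenuated and slower with the block), shared
#' cardiac / respiratory / Mayer-wave systemic physiology in long and short
#' channels, slow polynomial drifts, occasional motion spikes, and
#' measurement noise.
#'
#' The `brief` profile keeps every structural and amplitude default but
#' shortens sessions to ~4 minutes (procedure-free opening, then the
#' painful procedures) so that multi-cohort simulation studies run at desk
#' scale; epoch geometry, sampling rate, amplitudes and noise are untouched.
#'
#' @param profile `"study"` (default) or `"brief"`.
#' @param null_effect If `TRUE`, the nerve-block group receives the same
#'   evoked-response parameters as the no-nerve-block group (no injected
#'   group difference) — the matched null configuration.
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return A `sim_config` list.
#' @export
sim_config <- function(profile = c("study", "brief"), null_effect = FALSE,
                       ...) {
  profile <- match.arg(profile)
  cfg <- list(
    n_patients = 19,
    p_nerve_block = 11 / 19,
    fs = 25,
    duration_range_s = c(1500, 3900),
    events = list(
      n_painful_range = c(2, 12),
      n_nonpainful_range = c(2, 8),
      min_gap_s = 30,
      first_painful_min_s = 180,
      end_margin_s = 150,
      quiet_gap_s = 150
    ),
    hrf = list(
      S1 = list(
        non_nb = list(amp = 0.41, ttp = 20, shape = 4,
                      dip_frac = 0.25, dip_ttp = 4, dip_shape = 6,
                      undershoot_frac = 0.1, undershoot_ttp = 45,
                      undershoot_shape = 5),
        nb = list(amp = 0.1, ttp = 30, shape = 4,
                  dip_frac = 0, dip_ttp = 4, dip_shape = 6,
                  undershoot_frac = 0, undershoot_ttp = 60,
                  undershoot_shape = 5)
      ),
      PreFC = list(
        non_nb = list(amp = 0.05, ttp = 20, shape = 4,
                      dip_frac = 0, dip_ttp = 4, dip_shape = 6,
                      undershoot_frac = 0, undershoot_ttp = 45,
                      undershoot_shape = 5),
        nb = list(amp = 0.05, ttp = 20, shape = 4,
                  dip_frac = 0, dip_ttp = 4, dip_shape = 6,
                  undershoot_frac = 0, undershoot_ttp = 45,
                  undershoot_shape = 5)
      ),
      hbr_ratio = -1 / 3,
      amp_jitter = 0.15,
      ipsi_frac = 0
    ),
    systemic = list(
      cardiac_hz = 1.1, cardiac_amp_uM = 0.25,
      resp_hz = 0.25, resp_amp_uM = 0.12,
      mayer_hz = 0.1, mayer_amp_uM = 0.7,
      phase_jitter = 0.02,
      long_gain_range = c(0.4, 0.9),
      short_gain_range = c(5, 10),
      hbr_gain = 0.3
    ),
    drift = list(amp_od = 0.01),
    motion = list(spike_rate_per_min = 0.5, spike_amp_od = 0.05,
                  spike_width_s = c(0.2, 1)),
    noise = list(od_white_sd = 0.003, ar_coef = 0.98, ar_innov_sd = 4e-5),
    baseline_range = c(5e5, 2e6),
    age_range = c(13, 25)
  )
  if (profile == "brief") {
    cfg$fs <- 10
    cfg$duration_range_s <- c(300, 340)
    cfg$events$n_painful_range <- c(2, 3)
    cfg$events$n_nonpainful_range <- c(1, 2)
    cfg$events$min_gap_s <- 10
    cfg$events$first_painful_min_s <- 140
    cfg$events$nonpainful_min_s <- 140
    cfg$events$end_margin_s <- 110
    cfg$events$quiet_gap_s <- 130
  }
  if (null_effect) cfg$hrf$S1$nb <- cfg$hrf$S1$non_nb
  cfg <- utils::modifyList(cfg, list(...))
  cfg$profile <- profile
  cfg$null_effect <- null_effect
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Hemodynamic response kernel
#'
#' Single-gamma kernel normalized to peak 1 exactly at the configured
#' time-to-peak, with an optional early negative deflection (initial dip)
#' and optional late undershoot, each a gamma kernel of its own. Causal:
#' zero at `t = 0` and for `t < 0`.
#'
#' @param t Time in seconds (vector).
#' @param params List with `ttp` (time-to-peak, s, > 0), `shape`
#'   (dimensionless width parameter), and optional `dip_frac`, `dip_ttp`,
#'   `dip_shape`, `undershoot_frac`, `undershoot_ttp`, `undershoot_shape`,
#'   `amp` (default 1).
#' @return Response weights, same length as `t`.
#' @export
hrf <- function(t, params) {
  p <- utils::modifyList(list(amp = 1, shape = 4,
                              dip_frac = 0, dip_ttp = 4, dip_shape = 6,
                              undershoot_frac = 0, undershoot_ttp = 45,
                              undershoot_shape = 5), params)
  if (is.null(p$ttp) || !is.finite(p$ttp) || p$ttp <= 0)
    stop("time-to-peak must be positive")
  h <- gamma_bump(t, p$ttp, p$shape) -
    p$dip_frac * gamma_bump(t, p$dip_ttp, p$dip_shape) -
    p$undershoot_frac * gamma_bump(t, p$undershoot_ttp, p$undershoot_shape)
  p$amp * h
}

# (t/ttp)^a * exp(a * (1 - t/ttp)); peaks at exactly ttp with value 1
gamma_bump <- function(t, ttp, a) {
  w <- numeric(length(t))
  pos <- t > 0
  r <- t[pos] / ttp
  w[pos] <- r^a * exp(a * (1 - r))
  w
}

#' Simulate a full intraoperative cohort
#'
#' Generates seeded sessions with known ground truth: event-locked
#' hemodynamic responses (long channels only, contralateral to the operated
#' knee, group-dependent in S1), systemic physiology shared between each
#' long channel and its paired short channel, slow drifts, motion spikes and
#' measurement noise, all pushed through the forward modified Beer-Lambert
#' model to raw dual-wavelength intensities.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed; identical config + seed reproduce the
#'   cohort exactly.
#' @param montage Montage the sessions are generated against.
#' @return List with `sessions` (per patient: `rec`, `events`, `truth`) and
#'   `patients` (tibble of patient records including `nerve_block` and
#'   `laterality`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1,
                            montage = load_montage()) {
  set.seed(seed)
  n <- config$n_patients
  n_nb <- round(n * config$p_nerve_block)
  if (min(n_nb, n - n_nb) < 2)
    stop("need at least 2 patients per group (got ", n_nb, " vs ", n - n_nb,
         ")")
  nb <- rep(FALSE, n)
  nb[sample.int(n, n_nb)] <- TRUE
  patients <- tibble::tibble(
    patient_id = sprintf("sim%02d", seq_len(n)),
    age = sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    laterality = sample(c("R", "L"), n, replace = TRUE),
    nerve_block = nb,
    vrs_pre = sample(0:2, n, replace = TRUE)
  )
  patients$vrs_post <- pmin(10L, patients$vrs_pre +
                              sample(0:6, n, replace = TRUE))
  patients$vrs_discharge <- pmax(0L, patients$vrs_post -
                                   sample(0:3, n, replace = TRUE))
  patients$pain_procedures <- NA_integer_
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    s <- simulate_session(config, montage,
                          patient_id = patients$patient_id[i],
                          nerve_block = nb[i],
                          laterality = patients$laterality[i])
    patients$pain_procedures[i] <- sum(s$events$painful)
    sessions[[i]] <- s
  }
  list(sessions = sessions, patients = patients, config = config,
       seed = seed)
}

#' Simulate a single intraoperative session
#'
#' @param config A [sim_config()].
#' @param montage Montage to generate against.
#' @param patient_id,nerve_block,laterality Patient attributes.
#' @return List with `rec` (a `session_recording`), `events` (an
#'   `event_log`) and `truth` (injected ground truth: painful event times,
#'   per-channel-by-event response amplitudes, systemic traces, spike times,
#'   group and laterality).
#' @export
simulate_session <- function(config = sim_config(), montage = load_montage(),
                             patient_id = "sim01", nerve_block = FALSE,
                             laterality = c("R", "L")) {
  laterality <- match.arg(laterality)
  fs <- config$fs
  if (fs <= 2 * config$systemic$cardiac_hz)
    stop("sampling rate must exceed twice the cardiac frequency")
  duration <- round(stats::runif(1, config$duration_range_s[1],
                                 config$duration_range_s[2]))
  n <- duration * fs
  time_s <- seq(0, by = 1 / fs, length.out = n)
  ev <- draw_events(config$events, duration)

  ch <- montage$channels
  n_long <- nrow(ch)
  geo <- channel_geometry(montage)
  contra_hemi <- if (laterality == "R") "left" else "right"
  group <- if (nerve_block) "nb" else "non_nb"

  # evoked responses: long channels, contralateral hemisphere, painful events
  hbo2 <- matrix(0, n, n_long + length(geo$short_ids))
  colnames(hbo2) <- c(geo$long_ids, geo$short_ids)
  hbr <- hbo2
  pain_t <- ev$time_s[ev$painful]
  amp_tab <- matrix(0, n_long, length(pain_t),
                    dimnames = list(geo$long_ids, NULL))
  for (ci in seq_len(n_long)) {
    hp <- config$hrf[[ch$region[ci]]][[group]]
    side_gain <- if (ch$hemisphere[ci] == contra_hemi) 1 else
      config$hrf$ipsi_frac
    if (side_gain == 0 || hp$amp == 0 || length(pain_t) == 0) next
    kern_t <- seq(0, by = 1 / fs,
                  length.out = min(n, round((3 * hp$ttp + 60) * fs)))
    kern <- hrf(kern_t, hp[setdiff(names(hp), "amp")])
    for (ei in seq_along(pain_t)) {
      a <- hp$amp * side_gain * (1 + stats::rnorm(1, 0, config$hrf$amp_jitter))
      amp_tab[ci, ei] <- a
      i0 <- round(pain_t[ei] * fs) + 1
      idx <- i0:min(n, i0 + length(kern) - 1)
      hbo2[idx, ci] <- hbo2[idx, ci] + a * kern[seq_along(idx)]
      hbr[idx, ci] <- hbr[idx, ci] +
        a * config$hrf$hbr_ratio * kern[seq_along(idx)]
    }
  }

  # systemic physiology: shared traces, per-channel gains; each long channel
  # shares its paired short channel's trace (scalp layer) with its own gain
  sys <- config$systemic
  traces <- cbind(
    cardiac = sys$cardiac_amp_uM *
      sin(2 * pi * sys$cardiac_hz * time_s +
            cumsum(stats::rnorm(n, 0, sys$phase_jitter))),
    resp = sys$resp_amp_uM *
      sin(2 * pi * sys$resp_hz * time_s +
            cumsum(stats::rnorm(n, 0, sys$phase_jitter))),
    mayer = sys$mayer_amp_uM *
      sin(2 * pi * sys$mayer_hz * time_s +
            cumsum(stats::rnorm(n, 0, sys$phase_jitter))))
  systemic_sum <- rowSums(traces)
  all_ids <- as.integer(colnames(hbo2))
  gains <- numeric(length(all_ids))
  is_short <- all_ids %in% geo$short_ids
  gains[is_short] <- stats::runif(sum(is_short), sys$short_gain_range[1],
                                  sys$short_gain_range[2])
  gains[!is_short] <- stats::runif(sum(!is_short), sys$long_gain_range[1],
                                   sys$long_gain_range[2])
  for (j in seq_along(all_ids)) {
    hbo2[, j] <- hbo2[, j] + gains[j] * systemic_sum
    hbr[, j] <- hbr[, j] + gains[j] * sys$hbr_gain * systemic_sum
  }

  # forward optics + drift + spikes + noise, then intensities (compiled;
  # the per-channel physics matches forward_mbll exactly)
  spike_t <- draw_spikes(config$motion, duration)
  dists <- channel_distance_cm(montage, all_ids)
  E <- ext_matrix(extinction_table())
  intensity <- .cpp_assemble_intensity(
    hbo2, hbr, dists, c(6, 6), E, config$drift$amp_od,
    spike_t, config$motion$spike_amp_od, config$motion$spike_width_s,
    config$noise$ar_coef, config$noise$ar_innov_sd,
    config$noise$od_white_sd, config$baseline_range, fs, duration)
  dimnames(intensity$w690) <- dimnames(intensity$w830) <-
    list(NULL, all_ids)

  rec <- session_recording(time_s, intensity, fs = fs,
                           patient_id = patient_id)
  truth <- list(
    group = if (nerve_block) "NB" else "non-NB",
    laterality = laterality, contralateral_hemisphere = contra_hemi,
    painful_event_times = pain_t,
    response_amp = amp_tab,
    systemic_traces = traces,
    systemic_gains = stats::setNames(gains, all_ids),
    spike_times = spike_t)
  list(rec = rec, events = ev, truth = truth)
}

# reject-and-retry schedule honoring min gap, margins and a guaranteed
# procedure-free quiet gap so the P0 baseline always exists
draw_events <- function(ecfg, duration) {
  lo <- ecfg$first_painful_min_s
  hi <- duration - ecfg$end_margin_s
  if (hi <= lo) stop("session too short for the configured event margins")
  lo_non <- if (!is.null(ecfg$nonpainful_min_s)) ecfg$nonpainful_min_s else
    lo * 0.5
  rint <- function(a, b) a + sample.int(b - a + 1, 1) - 1
  for (try in 1:500) {
    n_pain <- rint(ecfg$n_painful_range[1], ecfg$n_painful_range[2])
    n_non <- rint(ecfg$n_nonpainful_range[1], ecfg$n_nonpainful_range[2])
    t_pain <- sort(stats::runif(n_pain, lo, hi))
    t_non <- stats::runif(n_non, lo_non, hi)
    times <- c(t_pain, t_non)
    painful <- c(rep(TRUE, n_pain), rep(FALSE, n_non))
    ord <- order(times)
    times <- times[ord]; painful <- painful[ord]
    gaps <- diff(c(0, times, duration))
    if (length(times) > 1 && min(diff(times)) < ecfg$min_gap_s) next
    if (max(gaps) < ecfg$quiet_gap_s) next
    labels <- ifelse(painful, "incision",
                     sample(c("scraping", "drilling", "suturing"),
                            length(times), replace = TRUE))
    return(event_log(round(times, 2), labels, painful, duration))
  }
  stop("could not draw an event schedule satisfying the constraints")
}

draw_spikes <- function(mcfg, duration) {
  n <- stats::rpois(1, mcfg$spike_rate_per_min * duration / 60)
  if (n == 0) return(numeric(0))
  sort(stats::runif(n, 0, duration))
}
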