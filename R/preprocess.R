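#' Convert raw intensities to optical-density changes
#'
#' `dOD = -ln(I / I0)` per channel and wavelength, with `I0` the mean
#' intensity over a baseline window (default: the first 30 s of the
#' recording). Scale-invariant in the intensity units.
#'
#' @param rec A `session_recording`.
#' @param baseline_window Length-2 seconds-from-start window whose mean
#'   defines `I0`, half-open `[t0, t1)`.
#' @return Optical-density set: list of matrices `w690`, `w830` plus
#'   `channel_ids`, `fs`, `time_s`, `baseline_window`, `provenance`.
#' @export
intensity_to_od <- function(rec, baseline_window = c(0, 30)) {
  stopifnot(inherits(rec, "session_recording"),
            length(baseline_window) == 2,
            baseline_window[2] > baseline_window[1])
  t0 <- rec$time_s - rec$time_s[1]
  in_base <- t0 >= baseline_window[1] & t0 < baseline_window[2]
  if (!any(in_base)) stop("baseline window contains no samples")
  od <- lapply(rec$intensity[c("w690", "w830")], function(m) {
    if (any(m <= 0)) stop("non-positive intensity; cannot form optical density")
    i0 <- colMeans(m[in_base, , drop = FALSE])
    -log(sweep(m, 2, i0, "/"))
  })
  list(w690 = od$w690, w830 = od$w830,
       channel_ids = as.integer(colnames(rec$intensity$w690)),
       fs = rec$fs, time_s = rec$time_s,
       baseline_window = baseline_window, provenance = "od")
}

# orthonormal Daubechies filters; h1[m] = (-1)^m h0[L-1-m]
daubechies_filters <- function(wavelet = "db4") {
  h0 <- switch(wavelet,
    db2 = c(0.48296291314469025, 0.836516303737469,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unsupported wavelet: ", wavelet))
  L <- length(h0)
  h1 <- (-1)^(0:(L - 1)) * rev(h0)
  list(h0 = h0, h1 = h1)
}

#' Wavelet-based motion-spike correction
#'
#' Multi-level periodized discrete wavelet transform (Daubechies family) per
#' channel and wavelength; detail coefficients whose magnitude exceeds
#' `k` times a robust per-level scale (1.4826 x median absolute deviation)
#' are zeroed before reconstruction. Transient motion spikes concentrate in
#' few large detail coefficients, while the band-limited (< 0.3 Hz)
#' hemodynamic content lives in the approximation and small-coefficient
#' details and is preserved.
#'
#' @param od Optical-density set (or a bare numeric matrix / vector).
#' @param k Threshold multiplier (> 0); larger is more conservative.
#' @param levels Decomposition depth.
#' @param wavelet `"db4"` (default) or `"db2"`.
#' @return Same shape as the input, despiked; provenance gains
#'   `"wavelet_despike"`.
#' @export
wavelet_despike <- function(od, k = 3, levels = 5, wavelet = "db4") {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("threshold multiplier k must be a positive number")
  if (is.list(od)) {
    out <- od
    out$w690 <- despike_matrix(od$w690, k, levels, wavelet)
    out$w830 <- despike_matrix(od$w830, k, levels, wavelet)
    out$provenance <- c(od$provenance, "wavelet_despike")
    return(out)
  }
  despike_matrix(od, k, levels, wavelet)
}

despike_matrix <- function(x, k, levels, wavelet) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(m)
  block <- 2^levels
  if (n < block)
    stop("series length (", n, ") must be at least 2^levels = ", block)
  f <- daubechies_filters(wavelet)
  pad <- (block - n %% block) %% block
  if (pad > 0) {
    # even reflection keeps the padded series continuous at the seam
    refl <- m[n - seq_len(pad) + 1, , drop = FALSE]
    m <- rbind(m, refl)
  }
  res <- .cpp_dwt_despike(m, f$h0, f$h1, as.integer(levels), k)
  res <- res[seq_len(n), , drop = FALSE]
  dimnames(res) <- dimnames(x)
  if (vec) drop(res) else res
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (default 0.01-0.3 Hz, order 3 per pass) applied
#' forward and backward so that event-locked latencies are untouched.
#' Initial filter states are matched to the signal's end levels and the
#' series is odd-reflection padded, following the standard zero-phase
#' filtering construction.
#'
#' @param x Numeric vector or samples-x-channels matrix, or an
#'   optical-density / concentration set (filtered matrix-wise).
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling frequency in Hz (taken from the set when `x` is one).
#' @param order Butterworth order per pass (the band-pass has `2*order`
#'   poles; applied twice).
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(x, low = 0.01, high = 0.3, fs = NULL, order = 3) {
  if (is.list(x)) {
    fs <- x$fs
    out <- x
    for (f in intersect(c("w690", "w830", "hbo2", "hbr", "hbt"), names(x)))
      out[[f]] <- bandpass_matrix(x[[f]], low, high, fs, order)
    out$provenance <- c(x$provenance, "bandpass")
    return(out)
  }
  bandpass_matrix(x, low, high, fs, order)
}

bandpass_matrix <- function(x, low, high, fs, order) {
  if (is.null(fs)) stop("fs is required")
  if (!(low > 0 && high > low && high < fs / 2))
    stop("need 0 < low < high < fs/2 (got ", low, ", ", high,
         " at fs = ", fs, ")")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  b <- bf$b; a <- bf$a
  n <- max(length(a), length(b))
  padlen <- 3L * (n - 1L)
  len <- if (is.null(dim(x))) length(x) else nrow(x)
  if (len <= 3 * padlen)
    stop("series too short to band-pass filter (", len, " samples)")
  zi <- lfilter_zi(b, a)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  res <- .cpp_filtfilt_mat(b, a, zi, m, padlen)
  dimnames(res) <- dimnames(x)
  if (vec) drop(res) else res
}

# step-matched initial conditions for a direct-form II transposed filter
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))   # companion matrix of a
  IminusA <- diag(n - 1) - t(A)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

#' Short-separation nuisance regression
#'
#' Ordinary least squares of a long-separation hemoglobin series on its
#' nearest short-separation channel's series (with intercept); the residual
#' retains cortical signal while shared superficial/systemic physiology is
#' removed. A zero-variance regressor is degenerate: the series is only
#' mean-centered, with a warning.
#'
#' @param y Long-channel series (dependent).
#' @param x Paired short-channel series (regressor).
#' @return Residual series with attributes `b0`, `b1` (the OLS intercept and
#'   slope).
#' @export
short_sep_regress <- function(y, x) {
  if (length(y) != length(x))
    stop("long and short series must have equal length")
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) {
    warning("short-separation regressor has zero variance; mean-centering only")
    res <- y - mean(y)
    attr(res, "b0") <- mean(y); attr(res, "b1") <- 0
    return(res)
  }
  b1 <- stats::cov(x, y) / vx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - (b0 + b1 * x)
  attr(res, "b0") <- b0; attr(res, "b1") <- b1
  res
}

# per-species regression of every long channel on its nearest short channel;
# HbT is recomputed as the exact sum of the residual species
regress_superficial <- function(conc, montage) {
  ch <- montage$channels
  long_ids <- as.character(ch$channel_id)
  short_ids <- as.character(ch$nearest_short_channel_id)
  if (!all(short_ids %in% colnames(conc$hbo2)))
    stop("concentration set lacks the short channels needed for regression")
  out_hbo2 <- conc$hbo2[, long_ids, drop = FALSE]
  out_hbr <- conc$hbr[, long_ids, drop = FALSE]
  for (i in seq_along(long_ids)) {
    out_hbo2[, i] <- strip_attrs(
      short_sep_regress(conc$hbo2[, long_ids[i]], conc$hbo2[, short_ids[i]]))
    out_hbr[, i] <- strip_attrs(
      short_sep_regress(conc$hbr[, long_ids[i]], conc$hbr[, short_ids[i]]))
  }
  conc_set(out_hbo2, out_hbr, as.integer(long_ids), conc$fs, conc$time_s,
           provenance = c(conc$provenance, "short_sep_regress"))
}

strip_attrs <- function(x) { attributes(x) <- NULL; x }

#' Remove slow drifts by polynomial detrending
#'
#' Subtracts the least-squares third-order polynomial fit, then the
#' least-squares linear fit of the residual, per series. A constant series
#' detrends to zeros.
#'
#' @param x Numeric vector, samples-x-channels matrix, or concentration set.
#' @return Same shape, detrended; for a concentration set, HbT remains the
#'   exact species sum (polynomial projection is linear, so additivity is
#'   preserved).
#' @export
detrend_drift <- function(x) {
  if (is.list(x)) {
    hbo2 <- detrend_matrix(x$hbo2)
    hbr <- detrend_matrix(x$hbr)
    return(conc_set(hbo2, hbr, x$channel_ids, x$fs, x$time_s,
                    provenance = c(x$provenance, "detrend_cubic",
                                   "detrend_linear")))
  }
  detrend_matrix(x)
}

detrend_matrix <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(m)
  if (n < 5) stop("need at least 5 samples to detrend")
  t <- seq_len(n) / n                       # scaled for conditioning
  q3 <- qr(cbind(1, stats::poly(t, degree = 3)))
  m <- qr.resid(q3, m)                      # cubic fit (with intercept)
  q1 <- qr(cbind(1, t))
  m <- qr.resid(q1, m)                      # then the linear pass
  dimnames(m) <- dimnames(x)
  if (vec) drop(m) else m
}

#' Channel / region / subject data-quality classification
#'
#' Rates every channel by the prominence of its cardiac spectral peak in the
#' raw intensity time series: the maximum periodogram power in the cardiac
#' band divided by the median power in that band, taking the weaker of the
#' two wavelengths. A channel is `good` above `thresholds["good"]`,
#' `average` above `thresholds["average"]`, else `poor`. A 4-channel QC
#' region is `good` when at least two member channels are good, `average`
#' when at least two are average or better, else `poor`; a subject is
#' included when at least two QC regions are average or better.
#'
#' @param rec A `session_recording` (>= 60 s of data).
#' @param montage Montage providing the `qc_region` channel grouping.
#' @param cardiac_band Hz range searched for the heart-rate peak.
#' @param thresholds Named prominence cutoffs, defaults `good = 10`,
#'   `average = 3`.
#' @return A `quality_report`: list with `channels` (tibble: channel_id,
#'   cardiac peak frequency, prominence, class), `regions` (tibble:
#'   qc_region, class), `include` (logical).
#' @export
quality_classify <- function(rec, montage, cardiac_band = c(0.7, 2.5),
                             thresholds = c(good = 10, average = 3)) {
  stopifnot(inherits(rec, "session_recording"))
  if (length(rec$time_s) < 60 * rec$fs)
    stop("need at least 60 s of data for quality classification")
  ch <- montage$channels
  ids <- as.character(ch$channel_id)
  if (!all(ids %in% colnames(rec$intensity$w690)))
    stop("recording does not contain all montage long channels")
  if (is.null(ch$qc_region))
    stop("montage lacks the qc_region channel grouping")
  p6 <- column_periodogram(rec$intensity$w690[, ids, drop = FALSE], rec$fs,
                           cardiac_band)
  p8 <- column_periodogram(rec$intensity$w830[, ids, drop = FALSE], rec$fs,
                           cardiac_band)
  prom <- pmin(prominence_of(p6), prominence_of(p8))
  pk <- p8$freq[apply(p8$power, 2, which.max)]
  cls <- ifelse(prom >= thresholds["good"], "good",
                ifelse(prom >= thresholds["average"], "average", "poor"))
  channels <- tibble::tibble(channel_id = ch$channel_id,
                             qc_region = ch$qc_region,
                             cardiac_peak_hz = pk,
                             prominence = prom, class = cls)
  regions <- dplyr::summarise(
    dplyr::group_by(channels, .data$qc_region),
    class = region_class(.data$class), .groups = "drop")
  include <- sum(regions$class %in% c("good", "average")) >= 2
  structure(list(channels = channels, regions = regions, include = include),
            class = "quality_report")
}

region_class <- function(member_classes) {
  n_good <- sum(member_classes == "good")
  n_avg_plus <- sum(member_classes %in% c("good", "average"))
  if (n_good >= 2) "good" else if (n_avg_plus >= 2) "average" else "poor"
}

# max / median periodogram power within the cardiac band, per column
prominence_of <- function(p) {
  apply(p$power, 2, function(v) {
    med <- stats::median(v)
    if (med <= 0) return(0)
    max(v) / med
  })
}

cardiac_prominence <- function(m, fs, band) {
  prominence_of(column_periodogram(m, fs, band))
}

# Welch-style averaged periodogram (non-overlapping ~20-s segments).
# Averaging across segments collapses the heavy tail of single-periodogram
# noise so a genuine oscillatory peak stands far above the band median
# while pure noise stays near it.
column_periodogram <- function(m, fs, band, segment_s = 20) {
  n <- nrow(m)
  L <- min(n, round(segment_s * fs))
  nseg <- n %/% L
  nf <- floor(L / 2)
  freq <- seq_len(nf) * fs / L
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("cardiac band contains no Fourier frequencies")
  acc <- matrix(0, sum(keep), ncol(m))
  for (s in seq_len(nseg)) {
    seg <- m[((s - 1) * L + 1):(s * L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    ft <- stats::mvfft(seg)
    acc <- acc + abs(ft[1 + which(keep), , drop = FALSE])^2 / L
  }
  list(freq = freq[keep], power = acc / nseg)
}

#' Full preprocessing chain for one session
#'
#' Fixed stage order: optical density, wavelet motion correction, 0.01-0.3 Hz
#' zero-phase band-pass, modified Beer-Lambert conversion to micromolar
#' concentrations, short-separation nuisance regression (long channels only),
#' third-order polynomial then linear detrending. The stage order is recorded
#' in the result's `provenance`.
#'
#' @param rec A `session_recording` carrying long and short channels.
#' @param montage Montage from [load_montage()].
#' @param config Optional list overriding defaults: `baseline_window`,
#'   `despike_k`, `despike_levels`, `wavelet`, `band` (length-2 Hz),
#'   `filter_order`, `dpf`, `qc_thresholds`, `run_despike`.
#' @param engine `"r"` runs the documented stage functions one by one;
#'   `"core"` runs the numerically identical single-pass compiled chain
#'   (used for large simulation studies). Both produce the same
#'   concentrations to floating tolerance.
#' @return List with `conc` (final long-channel concentration set, uM) and
#'   `quality` (a `quality_report`).
#' @export
preprocess_session <- function(rec, montage, config = list(),
                               engine = c("r", "core")) {
  engine <- match.arg(engine)
  cfg <- utils::modifyList(list(
    baseline_window = c(0, 30), despike_k = 3, despike_levels = 5,
    wavelet = "db4", band = c(0.01, 0.3), filter_order = 3,
    dpf = c(6, 6), qc_thresholds = c(good = 10, average = 3),
    run_despike = TRUE), config)
  quality <- quality_classify(rec, montage,
                              thresholds = cfg$qc_thresholds)
  if (engine == "core") {
    conc <- session_core(rec, montage, cfg)
    return(list(conc = conc, quality = quality))
  }
  od <- intensity_to_od(rec, cfg$baseline_window)
  if (isTRUE(cfg$run_despike))
    od <- wavelet_despike(od, k = cfg$despike_k,
                          levels = cfg$despike_levels, wavelet = cfg$wavelet)
  od <- bandpass(od, cfg$band[1], cfg$band[2], order = cfg$filter_order)
  conc <- mbll(od, montage, dpf = cfg$dpf)
  conc <- regress_superficial(conc, montage)
  conc <- detrend_drift(conc)
  list(conc = conc, quality = quality)
}

# compiled single-pass version of the full chain
session_core <- function(rec, montage, cfg) {
  t0 <- rec$time_s - rec$time_s[1]
  base_n <- sum(t0 >= cfg$baseline_window[1] & t0 < cfg$baseline_window[2])
  if (base_n == 0) stop("baseline window contains no samples")
  if (any(rec$intensity$w690 <= 0) || any(rec$intensity$w830 <= 0))
    stop("non-positive intensity; cannot form optical density")
  f <- daubechies_filters(cfg$wavelet)
  bf <- signal::butter(cfg$filter_order, cfg$band / (rec$fs / 2),
                       type = "pass")
  nb <- max(length(bf$a), length(bf$b))
  zi <- lfilter_zi(bf$b, bf$a)
  E <- ext_matrix(extinction_table())
  ids <- as.integer(colnames(rec$intensity$w690))
  dists <- channel_distance_cm(montage, ids)
  ch <- montage$channels
  long_cols <- match(ch$channel_id, ids) - 1L
  short_cols <- match(ch$nearest_short_channel_id, ids) - 1L
  if (anyNA(long_cols) || anyNA(short_cols))
    stop("recording lacks channels required by the montage")
  n <- length(t0)
  tt <- seq_len(n) / n
  Q <- qr.Q(qr(cbind(1, stats::poly(tt, degree = 3))))
  res <- .cpp_session_core(rec$intensity$w690, rec$intensity$w830,
                           as.integer(base_n), f$h0, f$h1,
                           as.integer(cfg$despike_levels),
                           cfg$despike_k, isTRUE(cfg$run_despike),
                           bf$b, bf$a, zi, 3L * (nb - 1L),
                           solve(E), dists, cfg$dpf,
                           long_cols, short_cols, Q)
  conc_set(res$hbo2, res$hbr, ch$channel_id, rec$fs, rec$time_s,
           provenance = c("od",
                          if (isTRUE(cfg$run_despike)) "wavelet_despike",
                          "bandpass", "mbll", "short_sep_regress",
                          "detrend_cubic", "detrend_linear"))
}
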