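#' Map long channels to contralateral/ipsilateral ROI-averaged series
#'
#' The hemisphere opposite the operated knee is contralateral: a right knee
#' maps the left-hemisphere channels to the contralateral side and vice
#' versa. Within each (side, ROI) cell the member channel series are
#' averaged, unweighted; channels rated `poor` by the quality report are
#' excluded from their ROI mean, and an ROI with no usable channel is marked
#' missing (all-NA series) so downstream statistics drop it.
#'
#' @param conc Long-channel concentration set (from [preprocess_session()]).
#' @param montage Montage from [load_montage()].
#' @param laterality `"R"` or `"L"` operated knee.
#' @param quality Optional `quality_report`; when given, poor channels are
#'   excluded.
#' @return An `roi_series`: list `sides[[side]][[species]]` of
#'   samples-x-6-ROI matrices plus `fs`, `time_s`, `laterality` and
#'   `missing_rois` bookkeeping.
#' @export
map_sides <- function(conc, montage, laterality = c("R", "L"),
                      quality = NULL) {
  laterality <- match.arg(laterality)
  ch <- montage$channels
  usable <- rep(TRUE, nrow(ch))
  if (!is.null(quality)) {
    cls <- quality$channels$class[match(ch$channel_id,
                                        quality$channels$channel_id)]
    usable <- cls != "poor"
  }
  contra_hemi <- if (laterality == "R") "left" else "right"
  sides <- list(contralateral = contra_hemi,
                ipsilateral = setdiff(c("left", "right"), contra_hemi))
  rois <- rois_all()
  missing <- character(0)
  out <- list()
  for (side in names(sides)) {
    out[[side]] <- list()
    for (sp in c("hbo2", "hbr", "hbt")) {
      m <- matrix(NA_real_, nrow(conc[[sp]]), length(rois),
                  dimnames = list(NULL, rois))
      for (roi in rois) {
        sel <- ch$hemisphere == sides[[side]] & ch$roi == roi & usable
        if (!any(sel)) {
          missing <- union(missing, paste(side, roi, sep = ":"))
          next
        }
        cols <- as.character(ch$channel_id[sel])
        m[, roi] <- rowMeans(conc[[sp]][, cols, drop = FALSE])
      }
      out[[side]][[sp]] <- m
    }
  }
  structure(list(sides = out, fs = conc$fs, time_s = conc$time_s,
                 laterality = laterality, missing_rois = missing),
            class = "roi_series")
}

#' Locate the procedure-free baseline epoch (P0)
#'
#' Considers every gap between consecutive procedures — painful or not —
#' with the recording start and end as boundaries, picks the longest gap
#' (earliest on ties) and centers a 60-s window in it. A valid baseline
#' requires a gap of at least 120 s.
#'
#' @param events An `event_log`.
#' @param duration_s Recording duration (defaults to the log's attribute).
#' @param epoch_s Epoch length in seconds.
#' @param min_gap_s Minimum acceptable gap.
#' @return List `(kind = "P0", start_s, length_s, gap)` where `gap` is the
#'   chosen `(from, to)` interval.
#' @export
find_p0 <- function(events, duration_s = attr(events, "duration_s"),
                    epoch_s = 60, min_gap_s = 120) {
  bounds <- c(0, sort(events$time_s), duration_s)
  from <- bounds[-length(bounds)]
  to <- bounds[-1]
  len <- to - from
  best <- which.max(len)  # first maximum = earliest gap on ties
  if (len[best] < min_gap_s)
    stop("no valid P0: longest procedure-free gap is ",
         round(len[best], 1), " s (< ", min_gap_s, " s)")
  mid <- (from[best] + to[best]) / 2
  list(kind = "P0", start_s = mid - epoch_s / 2, length_s = epoch_s,
       gap = c(from[best], to[best]))
}

#' Extract the P0/P1/P2 60-s epochs from ROI series
#'
#' P1 starts at the first painful event, P2 at the last; the baseline P0
#' comes from [find_p0()]. With a single painful event, P1 and P2 coincide
#' (with a warning). Each extracted segment is normalized to its own mean
#' (mean-subtracted) per series.
#'
#' @param roi An `roi_series`.
#' @param events An `event_log` (at least one painful event).
#' @param epoch_s Epoch length, seconds.
#' @return List of epochs `P0`, `P1`, `P2`; each holds `start_s` and
#'   `segments[[side]][[species]]` matrices (`epoch_s * fs` rows x 6 ROIs).
#' @export
extract_epochs <- function(roi, events, epoch_s = 60) {
  stopifnot(inherits(roi, "roi_series"))
  duration_s <- attr(events, "duration_s")
  pain <- events$time_s[events$painful]
  if (length(pain) == 0)
    stop("no painful events: cannot define P1/P2")
  if (length(pain) == 1)
    warning("only one painful event; P1 and P2 coincide")
  starts <- c(P0 = find_p0(events, duration_s, epoch_s)$start_s,
              P1 = pain[1], P2 = pain[length(pain)])
  n_ep <- round(epoch_s * roi$fs)
  t0 <- roi$time_s[1]
  out <- list()
  for (k in names(starts)) {
    if (starts[[k]] + epoch_s > duration_s + 1e-9)
      stop(k, " epoch at ", starts[[k]],
           " s runs past the end of the recording")
    i0 <- round((starts[[k]] - t0) * roi$fs) + 1
    idx <- i0:(i0 + n_ep - 1)
    segs <- lapply(roi$sides, function(side)
      lapply(side, function(m) {
        seg <- m[idx, , drop = FALSE]
        sweep(seg, 2, colMeans(seg))
      }))
    out[[k]] <- list(kind = k, start_s = unname(starts[[k]]),
                     segments = segs)
  }
  out
}

#' Standardized rolling-average curve for one epoch segment
#'
#' The segment is standardized against its own mean and standard deviation
#' (a constant segment maps to all zeros), then averaged over a 10-s window
#' slid in 1-s increments: windows `[j, j + 10)` s for `j = 0..50`, giving
#' 51 points for a 60-s epoch.
#'
#' @param segment Numeric vector of length `epoch_s * fs`.
#' @param fs Sampling rate, Hz.
#' @param epoch_s,window_s,step_s Epoch, window and step lengths in seconds.
#' @return Numeric vector of `(epoch_s - window_s)/step_s + 1` window means.
#' @export
rolling_curve <- function(segment, fs = 25, epoch_s = 60, window_s = 10,
                          step_s = 1) {
  n <- round(epoch_s * fs)
  if (length(segment) != n)
    stop("segment must contain exactly ", n, " samples (got ",
         length(segment), ")")
  if (anyNA(segment)) return(rep(NA_real_, (epoch_s - window_s) / step_s + 1))
  s <- stats::sd(segment)
  z <- if (s == 0) rep(0, n) else (segment - mean(segment)) / s
  wn <- round(window_s * fs)
  starts <- seq(0, epoch_s - window_s, by = step_s)
  cz <- c(0, cumsum(z))
  i0 <- round(starts * fs)
  (cz[i0 + wn + 1] - cz[i0 + 1]) / wn
}

#' Rolling curves for every (side, ROI, species, epoch) cell
#'
#' @param epochs Output of [extract_epochs()].
#' @param fs Sampling rate, Hz.
#' @return Tibble with columns `side`, `roi`, `species`, `epoch`,
#'   `window_start_s`, `value` (51 rows per cell; missing ROIs are dropped).
#' @export
epoch_curves <- function(epochs, fs = 25) {
  rows <- list()
  for (k in names(epochs)) {
    segs <- epochs[[k]]$segments
    for (side in names(segs)) {
      for (sp in names(segs[[side]])) {
        m <- segs[[side]][[sp]]
        for (roi in colnames(m)) {
          if (anyNA(m[, roi])) next
          cv <- rolling_curve(m[, roi], fs = fs)
          rows[[length(rows) + 1]] <- tibble::tibble(
            side = side, roi = roi, species = sp, epoch = k,
            window_start_s = seq_along(cv) - 1, value = cv)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
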