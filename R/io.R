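#' Load a surgical event log
#'
#' Events are timestamped surgical annotations ("incision", "scraping", ...)
#' with a painful flag; painful events anchor the P1 (first incision) and P2
#' (last incision) epochs, and all events — painful or not — bound the
#' procedure-free P0 baseline search.
#'
#' @param path TSV with columns `time_s`, `label`, `painful` (logical or Y/N).
#' @param duration_s Recording duration in seconds; events must lie within
#'   `[0, duration_s]`.
#' @return An `event_log`: tibble of sorted events with attribute
#'   `duration_s`.
#' @export
load_events <- function(path, duration_s) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("time_s", "label", "painful")
  if (!all(required %in% names(ev)))
    stop("event file needs columns: ", paste(required, collapse = ", "))
  event_log(ev$time_s, ev$label, as_flag(ev$painful), duration_s)
}

#' Construct an event log
#'
#' @param time_s Event times, seconds from recording start.
#' @param label Free-text procedure labels.
#' @param painful Logical painful flags.
#' @param duration_s Recording duration in seconds.
#' @return Sorted `event_log` tibble with a `duration_s` attribute.
#' @export
event_log <- function(time_s, label, painful, duration_s) {
  stopifnot(length(time_s) == length(label),
            length(time_s) == length(painful),
            is.numeric(duration_s), duration_s > 0)
  if (length(time_s) && any(time_s < 0))
    stop("negative event times are not allowed")
  if (length(time_s) && any(time_s > duration_s))
    stop("event time beyond the recording duration (",
         max(time_s), " > ", duration_s, " s)")
  if (is.unsorted(time_s)) {
    warning("event times were not sorted; sorting ascending")
    ord <- order(time_s)
    time_s <- time_s[ord]; label <- label[ord]; painful <- painful[ord]
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        label = as.character(label),
                        painful = as.logical(painful))
  attr(out, "duration_s") <- as.numeric(duration_s)
  class(out) <- c("event_log", class(out))
  out
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  up <- toupper(as.character(x))
  out <- up %in% c("Y", "YES", "TRUE", "T", "1")
  bad <- !up %in% c("Y", "YES", "TRUE", "T", "1", "N", "NO", "FALSE", "F", "0")
  if (any(bad)) stop("cannot interpret flag value(s): ",
                     paste(unique(up[bad]), collapse = ", "))
  out
}

#' Load a patient table
#'
#' @param path TSV with columns `patient_id`, `age`, `sex` (M/F),
#'   `laterality` (R/L, operated knee), `pain_procedures`, `nerve_block`
#'   (Y/N or logical), and optional `vrs_pre`, `vrs_post`, `vrs_discharge`
#'   (0-10 verbal rating scale, NA when missing).
#' @return Tibble of typed patient records.
#' @export
load_patients <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("patient_id", "age", "sex", "laterality", "nerve_block")
  if (!all(required %in% names(p)))
    stop("patient file needs columns: ", paste(required, collapse = ", "))
  out <- tibble::tibble(
    patient_id = p$patient_id,
    age = as.numeric(p$age),
    sex = toupper(p$sex),
    laterality = toupper(p$laterality),
    pain_procedures = if (is.null(p$pain_procedures)) NA_integer_ else
      as.integer(p$pain_procedures),
    nerve_block = as_flag(p$nerve_block),
    vrs_pre = vrs_col(p$vrs_pre),
    vrs_post = vrs_col(p$vrs_post),
    vrs_discharge = vrs_col(p$vrs_discharge)
  )
  if (!all(out$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(out$laterality %in% c("R", "L"))) stop("laterality must be R or L")
  if (any(!is.na(out$age) & (out$age < 0 | out$age > 120)))
    stop("implausible age")
  out
}

vrs_col <- function(x) {
  if (is.null(x)) return(NA_integer_)
  x <- suppressWarnings(as.integer(x))
  if (any(!is.na(x) & (x < 0 | x > 10)))
    stop("VRS scores must lie in [0, 10]")
  x
}

#' Path to the packaged demographic/clinical patient table
#'
#' The 19-patient arthroscopic knee-surgery cohort (ages, sex, operated-knee
#' laterality, number of painful procedures, nerve-block flag). Per-patient
#' verbal-rating-scale pain scores are not part of the published table and
#' are carried as missing.
#'
#' @return File path.
#' @export
patients_table1_path <- function() {
  system.file("extdata", "patients_table1.tsv", package = "nirspipe",
              mustWork = TRUE)
}

#' Construct a session recording
#'
#' @param time_s Sample time axis (seconds from start, uniform at `fs`).
#' @param intensity Named list with matrices `w690` and `w830`, each
#'   `n_samples x n_channels` of positive raw intensities; columns named by
#'   channel id (long channels first, then short).
#' @param fs Sampling frequency, Hz.
#' @param patient_id Identifier linking to the patient table.
#' @param montage_path Path of the montage the channel columns refer to.
#' @return A `session_recording` list.
#' @export
session_recording <- function(time_s, intensity, fs = 25,
                              patient_id = NA_character_,
                              montage_path = default_montage_path()) {
  stopifnot(is.list(intensity), all(c("w690", "w830") %in% names(intensity)))
  for (w in c("w690", "w830")) {
    m <- intensity[[w]]
    if (!is.matrix(m)) stop("intensity$", w, " must be a matrix")
    if (nrow(m) != length(time_s))
      stop("intensity rows must match the time axis")
    if (anyNA(m) || any(m <= 0))
      stop("intensities must be positive and finite (", w, ")")
  }
  if (!isTRUE(all.equal(colnames(intensity$w690), colnames(intensity$w830))))
    stop("both wavelengths must carry the same channel columns")
  dt <- diff(time_s)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6)
    stop("time axis must be uniformly sampled")
  structure(list(time_s = as.numeric(time_s), intensity = intensity,
                 fs = as.numeric(fs), patient_id = patient_id,
                 montage_path = montage_path),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat("fNIRS session recording: patient", x$patient_id, "-",
      length(x$time_s), "samples at", x$fs, "Hz,",
      ncol(x$intensity$w690), "channels x 2 wavelengths\n")
  invisible(x)
}

#' Write / read a session recording (text + JSON sidecar)
#'
#' One TSV per wavelength (`<stem>_690.tsv`, `<stem>_830.tsv`; columns
#' `ch<id>`) plus `<stem>.json` holding the time axis origin, sampling rate,
#' patient id and montage path. Intensities are written with 17 significant
#' digits so a write-read round trip is lossless.
#'
#' @param rec A `session_recording`.
#' @param stem Output path stem (no extension).
#' @return `write_session` returns `stem` invisibly; `read_session` returns
#'   the `session_recording`.
#' @export
write_session <- function(rec, stem) {
  stopifnot(inherits(rec, "session_recording"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  for (w in c("w690", "w830")) {
    m <- rec$intensity[[w]]
    dt <- data.table::as.data.table(m)
    data.table::setnames(dt, paste0("ch", colnames(m)))
    f <- paste0(stem, "_", sub("^w", "", w), ".tsv")
    # %.17g guarantees bit-exact double round trip through text
    lines <- do.call(sprintf,
                     c(list(paste(rep("%.17g", ncol(m)), collapse = "\t")),
                       lapply(seq_len(ncol(m)), function(j) m[, j])))
    writeLines(c(paste(names(dt), collapse = "\t"), lines),
               f)
  }
  meta <- list(fs = rec$fs, n_samples = length(rec$time_s),
               t0 = rec$time_s[1], patient_id = rec$patient_id,
               montage_path = rec$montage_path,
               channel_ids = as.integer(colnames(rec$intensity$w690)))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_session
#' @param expected_channels Optional integer vector of channel ids that must
#'   all be present (e.g. the montage's long channels); missing channels are
#'   an error naming the absent ids.
#' @export
read_session <- function(stem, expected_channels = NULL) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  intensity <- list()
  for (w in c("690", "830")) {
    dt <- data.table::fread(paste0(stem, "_", w, ".tsv"), sep = "\t")
    m <- as.matrix(dt)
    colnames(m) <- sub("^ch", "", colnames(m))
    intensity[[paste0("w", w)]] <- m
  }
  if (!is.null(expected_channels)) {
    have <- as.integer(colnames(intensity$w690))
    missing <- setdiff(expected_channels, have)
    if (length(missing))
      stop("session is missing channel(s): ", paste(missing, collapse = ", "))
  }
  fs <- meta$fs
  if (!isTRUE(all.equal(fs, 25)))
    warning("session sampled at ", fs, " Hz (study acquisition was 25 Hz); ",
            "carrying the file's rate through")
  time_s <- meta$t0 + seq(0, by = 1 / fs, length.out = meta$n_samples)
  session_recording(time_s, intensity, fs = fs,
                    patient_id = meta$patient_id,
                    montage_path = meta$montage_path)
}
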