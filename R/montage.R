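#' Path to the packaged default montage
#'
#' The default probe is a 2D schematic cap layout with nine sources, 14
#' long-separation detectors (nominal 30 mm source-detector separation) and
#' nine short-separation detectors (8 mm, one per source). Its 24 long
#' channels cover the bilateral prefrontal cortex (channels 1-12) and the
#' bilateral primary somatosensory cortex (channels 13-24), six channels per
#' hemisphere per region, grouped into six analysis ROIs (lateral_FC,
#' lateral_preFC, medial_PFC, superior_S1, central_S1, inferior_S1).
#'
#' @return Path to the montage JSON file shipped with the package.
#' @export
default_montage_path <- function() {
  system.file("extdata", "default_montage.json", package = "nirspipe",
              mustWork = TRUE)
}

#' Load and validate a probe montage
#'
#' Reads a montage JSON file describing optode positions and the long-channel
#' table, validates it against the declared optode counts, and assigns each
#' long channel its nearest short-separation channel (Euclidean distance from
#' the long channel's source-detector midpoint to the short detector's source
#' position; ties broken by the lowest short-channel id).
#'
#' Short channels are numbered `n_long + source_id` so that a session
#' intensity matrix can carry long and short channels in one block
#' (channels 25-33 for the default montage).
#'
#' @param path Montage JSON file. Defaults to the packaged montage.
#' @return A list with elements `layout` (optode tables and nominal
#'   separations) and `channels` (a tibble with one row per long channel:
#'   `channel_id`, `source_id`, `detector_id`, `separation_class`,
#'   `hemisphere`, `region`, `roi`, `qc_region`, `nearest_short_channel_id`).
#' @export
load_montage <- function(path = default_montage_path()) {
  if (!file.exists(path)) stop("montage file does not exist: ", path)
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (fld in c("sources", "long_detectors", "short_detectors", "channels")) {
    if (is.null(m[[fld]])) stop("montage is missing the '", fld, "' array")
  }
  src  <- as.data.frame(m$sources)
  det  <- as.data.frame(m$long_detectors)
  sdet <- as.data.frame(m$short_detectors)
  ch   <- as.data.frame(m$channels)

  if (anyDuplicated(src$id))  stop("duplicate source ids in montage")
  if (anyDuplicated(det$id))  stop("duplicate long-detector ids in montage")
  if (anyDuplicated(sdet$id)) stop("duplicate short-detector ids in montage")
  if (anyDuplicated(ch$channel_id)) stop("duplicate channel ids in montage")
  coords <- c(src$x, src$y, det$x, det$y, sdet$x, sdet$y)
  if (!all(is.finite(coords))) stop("non-finite optode coordinates in montage")
  if (is.null(ch$source_id) || anyNA(ch$source_id))
    stop("montage validation error: channel missing its source id")
  if (is.null(ch$detector_id) || anyNA(ch$detector_id))
    stop("montage validation error: channel missing its detector id")
  if (!all(ch$source_id %in% src$id))
    stop("channel references unknown source id")
  if (!all(ch$detector_id %in% det$id))
    stop("channel references unknown long-detector id")
  if (!all(sdet$source_id %in% src$id))
    stop("short detector references unknown source id")
  if (anyDuplicated(sdet$source_id))
    stop("a source is paired with more than one short detector")

  # declared geometry of the study probe: 9 sources, 14 long detectors,
  # 9 short detectors, 24 long channels split 12/12 across hemispheres
  # and regions
  if (nrow(sdet) != nrow(src))
    stop("montage validation error: every source needs exactly one short detector (",
         nrow(src), " sources vs ", nrow(sdet), " short detectors)")

  ch$separation_class <- "long"
  n_long <- nrow(ch)
  ch$nearest_short_channel_id <-
    nearest_short_channels(src, det, sdet, ch, n_long)

  layout <- list(
    sources = src, long_detectors = det, short_detectors = sdet,
    nominal_separation_mm = m$nominal_separation_mm,
    n_long_channels = n_long,
    short_channel_ids = n_long + sort(sdet$source_id)
  )
  channels <- tibble::as_tibble(ch[order(ch$channel_id), ])
  validate_channel_table(channels)
  list(layout = layout, channels = channels)
}

# midpoint-to-short-source Euclidean assignment, lowest id on ties
nearest_short_channels <- function(src, det, sdet, ch, n_long) {
  sx <- src$x[match(ch$source_id, src$id)]
  sy <- src$y[match(ch$source_id, src$id)]
  dx <- det$x[match(ch$detector_id, det$id)]
  dy <- det$y[match(ch$detector_id, det$id)]
  mx <- (sx + dx) / 2
  my <- (sy + dy) / 2
  ssx <- src$x[match(sdet$source_id, src$id)]
  ssy <- src$y[match(sdet$source_id, src$id)]
  ord <- order(sdet$source_id)  # candidate order = ascending short-channel id
  ssx <- ssx[ord]; ssy <- ssy[ord]
  ids <- n_long + sdet$source_id[ord]
  vapply(seq_len(nrow(ch)), function(i) {
    d2 <- (mx[i] - ssx)^2 + (my[i] - ssy)^2
    ids[which.min(d2)]  # which.min returns the first (lowest-id) minimum
  }, integer(1))
}

validate_channel_table <- function(channels) {
  stopifnot(is.data.frame(channels))
  n <- nrow(channels)
  if (n != 24)
    stop("montage validation error: expected 24 long channels, found ", n)
  if (!setequal(channels$channel_id, 1:24))
    stop("long channel ids must be 1..24")
  hemi <- table(channels$hemisphere)
  if (!all(c("left", "right") %in% names(hemi)) || any(hemi != 12))
    stop("expected 12 channels per hemisphere")
  reg <- table(channels$region)
  if (!all(c("PreFC", "S1") %in% names(reg)) || any(reg != 12))
    stop("expected 12 PreFC and 12 S1 channels")
  cells <- table(channels$hemisphere, channels$roi)
  if (any(cells[, rois_all()] == 0))
    stop("every (hemisphere, roi) cell must contain at least one channel")
  if (anyNA(channels$nearest_short_channel_id))
    stop("nearest-short assignment must cover every long channel")
  invisible(channels)
}

#' The six analysis ROIs
#'
#' @param region Optionally restrict to `"PreFC"` or `"S1"`.
#' @return Character vector of ROI labels.
#' @export
rois_all <- function(region = c("all", "PreFC", "S1")) {
  region <- match.arg(region)
  prefc <- c("lateral_FC", "lateral_preFC", "medial_PFC")
  s1 <- c("superior_S1", "central_S1", "inferior_S1")
  switch(region, all = c(prefc, s1), PreFC = prefc, S1 = s1)
}

# channel -> source/detector coordinates and separation (cm) for the MBLL
channel_geometry <- function(montage) {
  src <- montage$layout$sources
  det <- montage$layout$long_detectors
  sdet <- montage$layout$short_detectors
  ch <- montage$channels
  sx <- src$x[match(ch$source_id, src$id)]
  sy <- src$y[match(ch$source_id, src$id)]
  dx <- det$x[match(ch$detector_id, det$id)]
  dy <- det$y[match(ch$detector_id, det$id)]
  long_mm <- sqrt((sx - dx)^2 + (sy - dy)^2)
  ssx <- sdet$x; ssy <- sdet$y
  psx <- src$x[match(sdet$source_id, src$id)]
  psy <- src$y[match(sdet$source_id, src$id)]
  short_mm <- sqrt((ssx - psx)^2 + (ssy - psy)^2)
  list(
    long_ids = ch$channel_id,
    long_cm = long_mm / 10,
    short_ids = montage$layout$n_long_channels + sdet$source_id,
    short_cm = short_mm / 10
  )
}

# separation (cm) for an arbitrary mixed vector of channel ids
channel_distance_cm <- function(montage, channel_ids) {
  geo <- channel_geometry(montage)
  out <- numeric(length(channel_ids))
  il <- match(channel_ids, geo$long_ids)
  is <- match(channel_ids, geo$short_ids)
  out[!is.na(il)] <- geo$long_cm[il[!is.na(il)]]
  out[!is.na(is)] <- geo$short_cm[is[!is.na(is)]]
  if (any(is.na(il) & is.na(is)))
    stop("unknown channel id(s): ",
         paste(channel_ids[is.na(il) & is.na(is)], collapse = ", "))
  out
}
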