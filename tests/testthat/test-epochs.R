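fake_conc <- function(values_by_channel, n = 300, fs = 25) {
  ids <- as.integer(names(values_by_channel))
  hbo2 <- sapply(values_by_channel, function(v) rep(v, n))
  colnames(hbo2) <- ids
  nirspipe:::conc_set(hbo2, hbo2 * -0.3, ids, fs,
                      seq(0, by = 1 / fs, length.out = n), "test")
}

test_that("right knee maps left-hemisphere channels contralaterally", {
  ch <- the_montage$channels
  vals <- ifelse(ch$hemisphere == "left", 1, 2)
  conc <- fake_conc(stats::setNames(as.list(vals), ch$channel_id))
  roi <- map_sides(conc, the_montage, "R")
  for (r in rois_all()) {
    expect_equal(unique(roi$sides$contralateral$hbo2[, r]), 1)
    expect_equal(unique(roi$sides$ipsilateral$hbo2[, r]), 2)
  }
  # flipping laterality swaps the two sides exactly (involution)
  roiL <- map_sides(conc, the_montage, "L")
  expect_identical(roiL$sides$contralateral, roi$sides$ipsilateral)
  expect_identical(roiL$sides$ipsilateral, roi$sides$contralateral)
})

test_that("poor channels are excluded from their ROI mean", {
  ch <- the_montage$channels
  sel <- ch$hemisphere == "left" & ch$roi == "superior_S1"
  ids <- ch$channel_id[sel]
  vals <- stats::setNames(as.list(rep(5, 24)), ch$channel_id)
  vals[[as.character(ids[1])]] <- 100      # the channel to be dropped
  conc <- fake_conc(vals)
  q <- list(channels = tibble::tibble(
    channel_id = ch$channel_id,
    class = ifelse(ch$channel_id == ids[1], "poor", "good")))
  roi <- map_sides(conc, the_montage, "R", quality = q)
  expect_equal(unique(roi$sides$contralateral$hbo2[, "superior_S1"]), 5)
  # without the quality report the poor channel contaminates the mean
  roi2 <- map_sides(conc, the_montage, "R")
  expect_equal(unique(roi2$sides$contralateral$hbo2[, "superior_S1"]),
               52.5)
})

test_that("P0 search matches exhaustive gap enumeration", {
  p0_oracle <- function(times, duration) {
    bounds <- c(0, sort(times), duration)
    gaps <- data.frame(from = bounds[-length(bounds)], to = bounds[-1])
    gaps$len <- gaps$to - gaps$from
    best <- gaps[which.max(gaps$len), ]
    if (best$len < 120) return(NULL)
    (best$from + best$to) / 2 - 30
  }
  set.seed(12)
  for (i in 1:25) {
    duration <- sample(600:2000, 1)
    k <- sample(0:8, 1)
    times <- sort(round(stats::runif(k, 1, duration - 1)))
    ev <- event_log(times, rep("x", k), rep(TRUE, k), duration)
    want <- p0_oracle(times, duration)
    if (is.null(want)) {
      expect_error(find_p0(ev), "no valid P0")
    } else {
      expect_equal(find_p0(ev)$start_s, want)
    }
  }
  # worked cases
  ev1 <- event_log(c(300, 840), c("a", "b"), c(TRUE, TRUE), 1500)
  expect_equal(find_p0(ev1)$start_s, (840 + 1500) / 2 - 30)
  ev2 <- event_log(60, "a", TRUE, 600)
  expect_equal(find_p0(ev2)$start_s, (60 + 600) / 2 - 30)  # [300, 360)
  ev3 <- event_log(seq(90, 810, by = 90), rep("a", 9),
                   rep(TRUE, 9), 900)
  expect_error(find_p0(ev3), "no valid P0")
})

make_roi_series <- function(duration, fs = 25) {
  n <- duration * fs
  rois <- rois_all()
  m <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, rois))
  structure(list(
    sides = list(contralateral = list(hbo2 = m, hbr = -m / 3,
                                      hbt = m * 2 / 3),
                 ipsilateral = list(hbo2 = m + 1, hbr = -m / 3,
                                    hbt = m * 2 / 3 + 1)),
    fs = fs, time_s = seq(0, by = 1 / fs, length.out = n),
    laterality = "R", missing_rois = character(0)), class = "roi_series")
}

test_that("epoch anchors follow painful events only", {
  set.seed(5)
  roi <- make_roi_series(900)
  ev <- event_log(c(150, 300, 420, 500, 700),
                  c("incision", "scraping", "incision", "drill", "incision"),
                  c(TRUE, FALSE, TRUE, FALSE, TRUE), 900)
  eps <- extract_epochs(roi, ev)
  expect_equal(eps$P1$start_s, 150)
  expect_equal(eps$P2$start_s, 700)
  # adding non-painful events does not move P1/P2
  ev2 <- event_log(c(150, 160, 300, 420, 500, 700, 710),
                   rep("x", 7),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE), 900)
  eps2 <- extract_epochs(roi, ev2)
  expect_equal(eps2$P1$start_s, 150)
  expect_equal(eps2$P2$start_s, 700)
  # segments are mean-normalized per series
  expect_lt(max(abs(colMeans(eps$P1$segments$contralateral$hbo2))), 1e-12)

  # eleven painful procedures: P2 anchors to the eleventh
  t11 <- seq(150, 750, by = 60)
  ev11 <- event_log(t11, rep("incision", 11), rep(TRUE, 11), 900)
  expect_equal(extract_epochs(roi, ev11)$P2$start_s, 750)
})

test_that("degenerate event logs are handled loudly", {
  set.seed(6)
  roi <- make_roi_series(700)
  one <- event_log(300, "incision", TRUE, 700)
  expect_warning(eps <- extract_epochs(roi, one), "P1 and P2 coincide")
  expect_equal(eps$P1$start_s, eps$P2$start_s)
  none <- event_log(300, "scraping", FALSE, 700)
  expect_error(extract_epochs(roi, none), "no painful events")
  late <- event_log(c(200, 670), c("a", "b"), c(TRUE, TRUE), 700)
  expect_error(extract_epochs(roi, late), "past the end")
})

test_that("rolling curve equals the brute-force windowed mean", {
  set.seed(7)
  fs <- 25
  seg <- rnorm(60 * fs)
  cv <- rolling_curve(seg, fs = fs)
  expect_length(cv, 51)
  z <- (seg - mean(seg)) / sd(seg)
  oracle <- sapply(0:50, function(j) mean(z[(j * fs + 1):((j + 10) * fs)]))
  expect_equal(cv, oracle, tolerance = 1e-12)

  expect_equal(rolling_curve(rep(4, 1500)), rep(0, 51))
  expect_error(rolling_curve(rnorm(1000), fs = 25), "exactly 1500")

  # standardization invariance: a > 0, any b
  expect_equal(rolling_curve(3.2 * seg + 17), cv, tolerance = 1e-10)

  # linear ramp: curve linear in j; each point is the standardized value
  # at the window's mean sample time j + (10 - 1/fs)/2
  times <- seq_len(60 * fs) / fs
  ramp <- times
  rc <- rolling_curve(ramp, fs = fs)
  expect_lt(max(abs(diff(diff(rc)))), 1e-10)
  zr <- (ramp - mean(ramp)) / sd(ramp)
  for (j in c(0, 25, 50)) {
    win <- (j * fs + 1):((j + 10) * fs)
    expect_equal(rc[j + 1],
                 stats::approx(times, zr, xout = mean(times[win]))$y,
                 tolerance = 1e-10)
  }
})

test_that("epoch curves table covers every cell with 51 points", {
  set.seed(8)
  roi <- make_roi_series(700)
  ev <- event_log(c(150, 400), c("a", "b"), c(TRUE, TRUE), 700)
  eps <- extract_epochs(roi, ev)
  cv <- epoch_curves(eps, fs = 25)
  expect_equal(nrow(cv), 3 * 2 * 3 * 6 * 51)  # epoch x side x species x roi
  expect_true(all(table(cv$epoch, cv$side, cv$species, cv$roi) == 51))
  expect_true(all(is.finite(cv$value)))
})
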