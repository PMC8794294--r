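test_that("wavelet despiking removes spikes but preserves slow signal", {
  fs <- 25
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  smooth <- sin(2 * pi * 0.1 * t)
  # spike-free smooth input passes nearly unchanged
  out <- wavelet_despike(smooth, k = 3)
  expect_lt(sqrt(mean((out - smooth)^2)) / sqrt(mean(smooth^2)), 0.05)

  # a 10x-background spike of width 0.2 s is strongly attenuated
  set.seed(4)
  noise <- rnorm(length(t), 0, 0.1)
  clean <- smooth + noise
  spiked <- clean
  idx <- 1500:1504                        # 0.2 s at 25 Hz
  spiked[idx] <- spiked[idx] + 10 * 0.1 * 10
  ds <- wavelet_despike(spiked, k = 3)
  before <- max(abs(spiked[idx] - clean[idx]))
  after <- max(abs(ds[idx] - clean[idx]))
  expect_lt(after, 0.2 * before)

  expect_equal(wavelet_despike(numeric(256), k = 3), numeric(256))
  expect_error(wavelet_despike(smooth, k = 0), "positive")
  expect_error(wavelet_despike(smooth, k = -1), "positive")
  expect_error(wavelet_despike(rnorm(16), k = 3, levels = 5), "2\\^levels")
})

test_that("band-pass filter honors its passband and stopband contract", {
  fs <- 25
  t <- seq(0, 400, by = 1 / fs)
  core <- 2500:7500                       # away from the edges
  pass <- bandpass(sin(2 * pi * 0.1 * t), fs = fs)
  expect_gte(max(abs(pass[core])), 0.95)
  expect_lte(max(abs(pass[core])), 1.05)
  stopb <- bandpass(sin(2 * pi * 1.2 * t), fs = fs)
  expect_lte(max(abs(stopb[core])), 0.1)
  dc <- bandpass(rep(5, length(t)), fs = fs)
  expect_lt(mean(abs(dc[core])), 0.05)

  expect_error(bandpass(rnorm(30), fs = 25), "too short")
  expect_error(bandpass(rnorm(1000), low = 0.3, high = 0.01, fs = 25),
               "low < high")
  expect_error(bandpass(rnorm(1000), low = 0.01, high = 13, fs = 25),
               "low < high")
})

test_that("short-separation regression matches ordinary least squares", {
  x <- rnorm(500)
  y <- 2 * x + 3
  r <- short_sep_regress(y, x)
  expect_lt(max(abs(r)), 1e-10)

  # orthogonal regressor: slope 0, residual is the centered series
  y2 <- c(1, -1, 2, -2); x2 <- c(1, 1, -1, -1)  # cov = 0
  r2 <- short_sep_regress(y2, x2)
  expect_equal(attr(r2, "b1"), 0)
  expect_equal(as.numeric(r2), y2 - mean(y2))

  # closed-form normal-equation oracle over seeded random series
  set.seed(21)
  for (i in 1:100) {
    n <- sample(50:200, 1)
    x <- rnorm(n); y <- rnorm(n, sd = 2) + 0.5 * x
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    r <- short_sep_regress(y, x)
    expect_equal(attr(r, "b0"), beta[1], tolerance = 1e-10)
    expect_equal(attr(r, "b1"), beta[2], tolerance = 1e-10)
    # OLS never increases variance about the mean
    expect_lte(stats::var(as.numeric(r)), stats::var(y) + 1e-12)
  }

  expect_warning(rz <- short_sep_regress(y2, rep(1, 4)), "zero variance")
  expect_equal(as.numeric(rz), y2 - mean(y2))
  expect_error(short_sep_regress(1:5, 1:4), "equal length")
})

test_that("polynomial detrending removes drifts and keeps oscillations", {
  n <- 7500
  t <- seq_len(n) / 25
  cubic <- 2 + 0.1 * t - 0.004 * t^2 + 5e-5 * t^3
  out <- detrend_drift(cubic)
  expect_lt(max(abs(out)), 1e-8 * max(abs(cubic)))

  wave <- sin(2 * pi * 0.1 * t)
  both <- detrend_drift(cubic + wave)
  expect_lt(sqrt(mean((both - wave)^2)) / sqrt(mean(wave^2)), 0.05)

  expect_equal(detrend_drift(numeric(100)), numeric(100))
  expect_equal(detrend_drift(rep(3.7, 100)), numeric(100))
  expect_error(detrend_drift(1:4), "at least 5")
})

test_that("quality classification gates channels, regions and subjects", {
  s <- cached_session()
  q <- quality_classify(s$rec, the_montage)
  expect_true(all(q$channels$class == "good"))
  expect_true(q$include)
  # the detected cardiac peak sits at the simulated cardiac frequency
  expect_equal(median(q$channels$cardiac_peak_hz), 1.1, tolerance = 0.05)

  # pure white noise: no cardiac peak anywhere, subject excluded
  set.seed(9)
  n <- 120 * 25
  mk <- function() {
    m <- matrix(exp(rnorm(n * 33, 0, 0.01)) * 1e5, n, 33)
    colnames(m) <- as.character(1:33)
    m
  }
  recw <- session_recording(seq(0, by = 0.04, length.out = n),
                            list(w690 = mk(), w830 = mk()), fs = 25)
  qw <- quality_classify(recw, the_montage)
  expect_true(all(qw$channels$class == "poor"))
  expect_false(qw$include)
})

test_that("region rating needs two good channels of its four", {
  rc <- nirspipe:::region_class
  expect_equal(rc(c("good", "good", "poor", "poor")), "good")
  expect_equal(rc(c("good", "average", "poor", "poor")), "average")
  expect_equal(rc(c("average", "average", "poor", "poor")), "average")
  expect_equal(rc(c("good", "poor", "poor", "poor")), "poor")
})

test_that("full chain: provenance order, HbT additivity, engine equality", {
  s <- cached_session()
  pr <- preprocess_session(s$rec, the_montage, engine = "r")
  expect_equal(pr$conc$provenance,
               c("od", "wavelet_despike", "bandpass", "mbll",
                 "short_sep_regress", "detrend_cubic", "detrend_linear"))
  expect_equal(pr$conc$hbt, pr$conc$hbo2 + pr$conc$hbr)
  pc <- preprocess_session(s$rec, the_montage, engine = "core")
  scale <- max(abs(pr$conc$hbo2))
  expect_lt(max(abs(pr$conc$hbo2 - pc$conc$hbo2)) / scale, 1e-4)
  expect_lt(max(abs(pr$conc$hbr - pc$conc$hbr)) / scale, 1e-4)
})

test_that("short-separation regression halves systemic-band power", {
  s <- cached_session()
  cfg <- list(baseline_window = c(0, 30), band = c(0.01, 0.3))
  od <- intensity_to_od(s$rec, cfg$baseline_window)
  od <- wavelet_despike(od)
  od <- bandpass(od, cfg$band[1], cfg$band[2])
  conc <- mbll(od, the_montage)
  res <- nirspipe:::regress_superficial(conc, the_montage)
  band_power <- function(x, fs, lo = 0.05, hi = 0.15) {
    n <- length(x)
    ft <- abs(fft(x - mean(x)))^2 / n
    f <- (seq_len(n) - 1) * fs / n
    sum(ft[f >= lo & f <= hi])
  }
  ids <- as.character(1:24)
  before <- sapply(ids, function(i) band_power(conc$hbo2[, i], conc$fs))
  after <- sapply(ids, function(i) band_power(res$hbo2[, i], res$fs))
  expect_lt(mean(after) / mean(before), 0.5)
})
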