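test_that("absolute AUC follows the trapezoid rule on 50 unit intervals", {
  expect_equal(auc_abs(rep(0, 51)), 0)
  expect_identical(auc_abs(rep(1, 51)), 50)
  expect_equal(auc_abs(rep(c(1, -1), length.out = 51)), 50)
  set.seed(1)
  cv <- rnorm(51)
  expect_equal(auc_abs(3 * cv), 3 * auc_abs(cv))     # positive homogeneity
  expect_equal(auc_abs(-cv), auc_abs(cv))            # sign symmetry
  expect_gte(auc_abs(cv), 0)
  expect_error(auc_abs(c(cv[-51], NaN)), "non-finite")
})

test_that("ROI pairs partition into PreFC, S1 and cross sets", {
  pr <- roi_pairs()
  expect_equal(nrow(pr), 15)
  expect_equal(sort(as.integer(table(pr$pair_set))), c(3L, 3L, 9L))
  expect_equal(sum(pr$pair_set == "PreFC/S1"), 9)
  # disjoint partition covering all pairs
  expect_equal(sum(pr$pair_set %in% c("PreFC", "S1", "PreFC/S1")), 15)
  expect_false(any(duplicated(paste(pr$roi_a, pr$roi_b))))
  expect_equal(nrow(roi_pairs(c("a", "b"), prefc = "a")), 1)
  expect_error(roi_pairs(c("a", "a", "b", "c", "d", "e")), "duplicate")
})

test_that("windowed correlation equals the direct Pearson formula", {
  fs <- 25
  set.seed(2)
  x <- rnorm(60 * fs)
  expect_true(all(abs(windowed_pearson(x, x, fs = fs)$r - 1) < 1e-12))
  wp <- windowed_pearson(x, -2 * x + 5, fs = fs)
  expect_equal(wp$r, rep(-1, 51))
  y <- rnorm(60 * fs)
  wp2 <- windowed_pearson(x, y, fs = fs)
  for (j in c(0, 7, 23, 50)) {
    idx <- (j * fs + 1):((j + 10) * fs)
    xs <- x[idx]; ys <- y[idx]
    r_direct <- sum((xs - mean(xs)) * (ys - mean(ys))) /
      sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
    expect_equal(wp2$r[j + 1], r_direct, tolerance = 1e-12)
  }
  # zero-variance window is reported missing
  xz <- x; xz[1:250] <- 2
  expect_true(is.na(windowed_pearson(xz, y, fs = fs)$r[1]))
  # decimated reporting grid
  keep <- windowed_pearson(x, y, fs = fs, keep = seq(0, 50, 10))
  expect_equal(keep$window_start_s, seq(0, 50, 10))
  expect_error(windowed_pearson(x, y[-1], fs = fs), "equal length")
})

test_that("pair-set means obey the size-weighted total identity", {
  set.seed(3)
  roi <- rois_all()
  m2 <- matrix(rnorm(1500 * 6), 1500, 6, dimnames = list(NULL, roi))
  eps <- list(P0 = list(segments = list(contralateral = list(hbo2 = m2))))
  pats <- tibble::tibble(patient_id = "p1", nerve_block = TRUE)
  tab <- compute_dyncorr_table(list(p1 = eps), pats, fs = 25)
  for (w in unique(tab$window_start_s)) {
    sub <- tab[tab$window_start_s == w, ]
    tot <- sub$r_mean[sub$pair_set == "total"]
    parts <- (3 * sub$r_mean[sub$pair_set == "PreFC"] +
                3 * sub$r_mean[sub$pair_set == "S1"] +
                9 * sub$r_mean[sub$pair_set == "PreFC/S1"]) / 15
    expect_equal(tot, parts, tolerance = 1e-12)
    expect_true(all(abs(sub$r_mean) <= 1))
  }
})

test_that("split-plot ANOVA reduces to one-way ANOVA with one level", {
  set.seed(4)
  d <- data.frame(subject = paste0("s", 1:12),
                  group = rep(c("A", "B"), c(7, 5)),
                  epoch = "P1",
                  dv = c(rnorm(7, 1), rnorm(5, 3)))
  res <- mixed_anova(d, "dv", "subject", "group", "epoch")
  # closed-form one-way F computed from sums of squares
  gm <- mean(d$dv)
  means <- tapply(d$dv, d$group, mean)
  ns <- table(d$group)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((d$dv - means[d$group])^2)
  Fw <- (ssb / 1) / (ssw / 10)
  expect_equal(res$F[res$effect == "between"], Fw, tolerance = 1e-10)
  expect_equal(res$df1[res$effect == "between"], 1)
  expect_equal(res$df2[res$effect == "between"], 10)
  expect_equal(res$p[res$effect == "between"],
               stats::pf(Fw, 1, 10, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("split-plot ANOVA matches hand-computed sums of squares", {
  # balanced 2 groups x 3 within-levels, 4 subjects per group
  dv <- c(3, 5, 4,  6, 7, 8,  2, 4, 3,  5, 6, 9,
          8, 9, 11, 7, 9, 10, 9, 12, 13, 6, 8, 9)
  d <- data.frame(subject = rep(paste0("s", 1:8), each = 3),
                  group = rep(c("A", "B"), each = 12),
                  w = rep(c("w1", "w2", "w3"), 8),
                  dv = dv)
  res <- mixed_anova(d, "dv", "subject", "group", "w")
  # manual split-plot decomposition
  gm <- mean(dv)
  subj_means <- tapply(d$dv, d$subject, mean)
  grp_means <- tapply(d$dv, d$group, mean)
  w_means <- tapply(d$dv, d$w, mean)
  cell_means <- tapply(d$dv, list(d$group, d$w), mean)
  ss_between_subj <- 3 * sum((subj_means - gm)^2)
  ss_group <- 12 * sum((grp_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_w <- 8 * sum((w_means - gm)^2)
  ss_cells <- 4 * sum((cell_means - gm)^2)
  ss_gw <- ss_cells - ss_group - ss_w
  ss_total <- sum((dv - gm)^2)
  ss_resid <- ss_total - ss_between_subj - ss_w - ss_gw
  F_group <- (ss_group / 1) / (ss_subj_within / 6)
  F_w <- (ss_w / 2) / (ss_resid / 12)
  F_gw <- (ss_gw / 2) / (ss_resid / 12)
  expect_equal(res$F, c(F_group, F_w, F_gw), tolerance = 1e-10)
  expect_equal(res$df1, c(1, 2, 2))
  expect_equal(res$df2, c(6, 12, 12))
})

test_that("split-plot ANOVA guards its degenerate inputs", {
  d <- data.frame(subject = rep(paste0("s", 1:6), each = 2),
                  group = rep(c("A", "B"), c(8, 4)),
                  w = rep(c("w1", "w2"), 6), dv = rnorm(12))
  d1 <- d; d1$group <- rep("A", 12)
  expect_error(mixed_anova(d1, "dv", "subject", "group", "w"),
               "at least 2 subjects")
  dc <- d; dc$dv <- 5
  res <- mixed_anova(dc, "dv", "subject", "group", "w")
  expect_true(all(is.na(res$F)))
  expect_true(all(is.na(res$p)))
  # a subject missing a within level is dropped listwise with a warning
  dm <- d[-1, ]
  expect_warning(res2 <- mixed_anova(dm, "dv", "subject", "group", "w"),
                 "dropped listwise")
})

test_that("pooled two-sample t matches its closed form", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  swapped <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)
  expect_error(two_sample_t(c(2, 2), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  # Welch form runs and reports fractional df
  w <- two_sample_t(c(1, 2, 3, 9), c(4, 5, 6), welch = TRUE)
  expect_true(w$df < 5)
})

test_that("BH control matches the exhaustive step-up oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(r$p_fdr, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(r$significant_fdr, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(bh_fdr(rep(0.001, 10))$significant_fdr))

  # oracle: largest k with p_(k) <= k * alpha / m; reject the k smallest
  bh_oracle <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * alpha / m)
    reject <- rep(FALSE, m)
    if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
    reject
  }
  set.seed(5)
  for (i in 1:50) {
    m <- sample(1:10, 1)
    p <- round(stats::runif(m), 3)
    got <- bh_fdr(p, alpha = 0.05)$significant_fdr
    expect_equal(got, bh_oracle(p, 0.05))
  }
  # adjusted p-values are monotone in the raw ranks
  p <- stats::runif(20)
  adj <- bh_fdr(p)$p_fdr
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("demographic summaries reproduce the published group values", {
  pt <- load_patients(patients_table1_path())
  ds <- demographic_summary(pt)
  nb <- ds$groups[ds$groups$group == "NB", ]
  nn <- ds$groups[ds$groups$group == "non-NB", ]
  expect_equal(nb$n, 11)
  expect_equal(round(nb$mean_age, 1), 17.6)
  expect_equal(round(nb$sd_age, 2), 3.59)
  expect_equal(nb$n_female, 6)
  expect_equal(nn$n, 8)
  expect_equal(round(nn$mean_age, 1), 18.9)
  expect_equal(round(nn$sd_age, 2), 2.80)
  expect_equal(nn$n_female, 5)
  expect_equal(ds$nb_fraction, 11 / 19)

  single <- pt[c(1, 2, 3), ]
  single$nerve_block <- c(TRUE, FALSE, FALSE)
  expect_true(is.na(demographic_summary(single)$groups$sd_age[1]))
  expect_error(demographic_summary(pt[0, ]), "empty")
})
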