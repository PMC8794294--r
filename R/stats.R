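#' Absolute area under a standardized rolling curve
#'
#' Trapezoidal integral of the absolute value of the 51-point curve at unit
#' (1-s) spacing: 50 intervals, so a constant curve of 1 integrates to 50.
#'
#' @param curve Numeric curve (51 points for the default epoch geometry).
#' @return Non-negative scalar (dimensionless x seconds).
#' @export
auc_abs <- function(curve) {
  if (anyNA(curve) || !all(is.finite(curve)))
    stop("curve contains non-finite values")
  pracma::trapz(seq_along(curve) - 1, abs(curve))
}

#' The 15 unique ROI-ROI pairs and their pair sets
#'
#' All C(6,2) = 15 unordered pairs of the six ROIs, labelled `PreFC` (both
#' ROIs prefrontal, 3 pairs), `S1` (both somatosensory, 3 pairs) or
#' `PreFC/S1` (one of each, 9 pairs); every pair also belongs to `total`.
#'
#' @param rois ROI labels (first half treated as PreFC, second half as S1
#'   when using custom labels; defaults to the packaged six).
#' @param prefc Which of `rois` are prefrontal.
#' @return Tibble with `roi_a`, `roi_b`, `pair_set`.
#' @export
roi_pairs <- function(rois = rois_all(), prefc = rois_all("PreFC")) {
  if (anyDuplicated(rois)) stop("duplicate ROI labels")
  if (length(rois) < 2) stop("need at least two ROIs")
  cmb <- utils::combn(rois, 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  in_pre <- function(x) x %in% prefc
  pair_set <- ifelse(in_pre(a) & in_pre(b), "PreFC",
                     ifelse(!in_pre(a) & !in_pre(b), "S1", "PreFC/S1"))
  tibble::tibble(roi_a = a, roi_b = b, pair_set = pair_set)
}

#' Sliding-window Pearson correlation between two epoch segments
#'
#' Pearson r over the samples in each 10-s window `[j, j + 10)`,
#' j = 0..50 s. Windows in which either series has zero variance yield a
#' missing r.
#'
#' @param x,y Equal-length epoch segments (60 s at `fs`).
#' @param fs Sampling rate, Hz.
#' @param epoch_s,window_s,step_s Window geometry, seconds.
#' @param keep Window starts to report (`NULL` = all). The decimated grid
#'   `c(0, 10, 20, 30, 40, 50)` matches the reported correlation measures.
#' @return Tibble with `window_start_s`, `r`.
#' @export
windowed_pearson <- function(x, y, fs = 25, epoch_s = 60, window_s = 10,
                             step_s = 1, keep = NULL) {
  if (length(x) != length(y)) stop("segments must have equal length")
  starts <- seq(0, epoch_s - window_s, by = step_s)
  wn <- round(window_s * fs)
  r <- vapply(starts, function(j) {
    idx <- (round(j * fs) + 1):(round(j * fs) + wn)
    xs <- x[idx]; ys <- y[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  out <- tibble::tibble(window_start_s = starts, r = r)
  if (!is.null(keep)) out <- out[out$window_start_s %in% keep, ]
  out
}

#' Split-plot (mixed) ANOVA
#'
#' Classical two-way mixed ANOVA with one between-subject factor (group) and
#' one within-subject factor: the between effect is tested against the
#' subject-within-group mean square, the within and interaction effects
#' against the subject-by-within residual. Subjects missing any within level
#' are dropped listwise with a warning. With a single between and a single
#' within factor the sequential sums of squares coincide with Type II, so
#' the unbalanced 11-vs-8 design needs no further adjustment.
#'
#' @param data Data frame.
#' @param dv,subject,between,within Column names.
#' @return Tibble with one row per effect (`between`, `within`,
#'   `interaction`): `F`, `df1`, `df2`, `p`. Degenerate (constant) responses
#'   give missing F and p.
#' @export
mixed_anova <- function(data, dv, subject, between, within) {
  d <- data.frame(dv = data[[dv]], subject = factor(data[[subject]]),
                  between = factor(data[[between]]),
                  within = factor(data[[within]]))
  d <- d[stats::complete.cases(d), ]
  lv <- nlevels(droplevels(d$within))
  cnt <- table(d$subject)
  complete <- names(cnt)[cnt == lv]
  if (length(complete) < length(cnt))
    warning(length(cnt) - length(complete),
            " subject(s) missing within-levels dropped listwise")
  d <- droplevels(d[d$subject %in% complete, ])
  grp_n <- table(unique(d[c("subject", "between")])$between)
  if (length(grp_n) < 2 || any(grp_n < 2))
    stop("need at least 2 subjects per group")
  empty <- tibble::tibble(effect = c("between", "within", "interaction"),
                          F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                          p = NA_real_)
  if (stats::var(d$dv) == 0) return(empty)
  if (nlevels(d$within) == 1) {
    # single within level: the design collapses to a one-way ANOVA on group
    fit <- stats::aov(dv ~ between, data = d)
    s <- summary(fit)[[1]]
    out <- empty
    out[1, c("F", "df1", "df2", "p")] <-
      list(s$`F value`[1], s$Df[1], s$Df[2], s$`Pr(>F)`[1])
    return(out)
  }
  fit <- stats::aov(dv ~ between * within + Error(subject), data = d)
  s <- summary(fit)
  bt <- s[["Error: subject"]][[1]]
  wt <- s[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  b_i <- match("between", rn(bt)); b_r <- match("Residuals", rn(bt))
  w_i <- match("within", rn(wt)); x_i <- match("between:within", rn(wt))
  w_r <- match("Residuals", rn(wt))
  tibble::tibble(
    effect = c("between", "within", "interaction"),
    F = c(bt$`F value`[b_i], wt$`F value`[w_i], wt$`F value`[x_i]),
    df1 = c(bt$Df[b_i], wt$Df[w_i], wt$Df[x_i]),
    df2 = c(bt$Df[b_r], wt$Df[w_r], wt$Df[w_r]),
    p = c(bt$`Pr(>F)`[b_i], wt$`Pr(>F)`[w_i], wt$`Pr(>F)`[x_i]))
}

#' Two-sample t-test between nerve-block and no-nerve-block values
#'
#' Pooled-variance two-sample t by default (Welch optional).
#'
#' @param nb,non_nb Numeric vectors (>= 2 values each).
#' @param welch Use the Welch unequal-variance form.
#' @return Tibble with `t`, `df`, `p`, `mean_nb`, `mean_non_nb`.
#' @export
two_sample_t <- function(nb, non_nb, welch = FALSE) {
  if (length(nb) < 2 || length(non_nb) < 2)
    stop("need at least 2 values per group")
  if (!welch && stats::var(nb) == 0 && stats::var(non_nb) == 0)
    stop("zero pooled variance; t statistic undefined")
  ht <- stats::t.test(nb, non_nb, var.equal = !welch)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_nb = mean(nb),
                 mean_non_nb = mean(non_nb))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjusted p-values (`p.adjust` method `"BH"`) with a rejection set
#' at level `alpha`.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Tibble with `p_raw`, `p_fdr`, `significant_raw`,
#'   `significant_fdr`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p_raw = p, p_fdr = adj,
                 significant_raw = !is.na(p) & p <= alpha,
                 significant_fdr = !is.na(adj) & adj <= alpha)
}

#' Demographic and clinical group summaries
#'
#' Per-group (nerve block vs none) count, mean and sample SD of age, sex
#' counts, plus the overall nerve-block fraction and the paired pre-to-post
#' verbal-rating-scale change where both scores are present.
#'
#' @param patients Patient tibble (see [load_patients()]).
#' @return List with `groups` (tibble), `nb_fraction`, and `vrs` (tibble of
#'   paired VRS change summaries, possibly empty).
#' @export
demographic_summary <- function(patients) {
  if (nrow(patients) == 0) stop("empty patient table")
  g <- dplyr::summarise(
    dplyr::group_by(patients, group = ifelse(.data$nerve_block,
                                             "NB", "non-NB")),
    n = dplyr::n(),
    mean_age = mean(.data$age),
    sd_age = if (dplyr::n() > 1) stats::sd(.data$age) else NA_real_,
    n_female = sum(.data$sex == "F"),
    n_male = sum(.data$sex == "M"),
    .groups = "drop")
  ok <- !is.na(patients$vrs_pre) & !is.na(patients$vrs_post)
  vrs <- if (any(ok)) {
    diffs <- patients$vrs_post[ok] - patients$vrs_pre[ok]
    tibble::tibble(n = sum(ok), mean_change = mean(diffs),
                   sd_change = if (sum(ok) > 1) stats::sd(diffs) else
                     NA_real_)
  } else tibble::tibble(n = integer(0), mean_change = numeric(0),
                        sd_change = numeric(0))
  list(groups = g, nb_fraction = mean(patients$nerve_block), vrs = vrs)
}

#' Absolute-AUC response table for a cohort
#'
#' One row per (patient, side, ROI, species, epoch): the absolute
#' trapezoidal area of the standardized rolling curve.
#'
#' @param curves_by_patient Named list (by patient id) of [epoch_curves()]
#'   tibbles.
#' @param patients Patient tibble with `patient_id` and `nerve_block`.
#' @return Tibble (`auc_table`): `patient_id`, `group`, `side`, `roi`,
#'   `species`, `epoch`, `auc`.
#' @export
compute_auc_table <- function(curves_by_patient, patients) {
  rows <- lapply(names(curves_by_patient), function(pid) {
    cv <- curves_by_patient[[pid]]
    if (is.null(cv) || nrow(cv) == 0) return(NULL)
    out <- dplyr::summarise(
      dplyr::group_by(cv, .data$side, .data$roi, .data$species,
                      .data$epoch),
      auc = auc_abs(.data$value), .groups = "drop")
    out$patient_id <- pid
    out
  })
  tab <- dplyr::bind_rows(rows)
  tab$group <- ifelse(
    patients$nerve_block[match(tab$patient_id, patients$patient_id)],
    "NB", "non-NB")
  dplyr::select(tab, "patient_id", "group", "side", "roi", "species",
                "epoch", "auc")
}

#' Dynamic ROI-ROI correlation table for a cohort
#'
#' For each patient, epoch and ROI pair, the sliding-window Pearson r is
#' computed on the two ROI epoch segments and decimated to window starts
#' 0, 10, ..., 50 s; r values are then averaged within each pair set
#' (`PreFC`, `S1`, `PreFC/S1`, and `total` over all 15 pairs). Zero-variance
#' windows are missing and excluded from the means.
#'
#' @param epochs_by_patient Named list (by patient id) of [extract_epochs()]
#'   results.
#' @param patients Patient tibble.
#' @param side Which side's ROI series to correlate.
#' @param species Hemoglobin species.
#' @param fs Sampling rate, Hz.
#' @param keep Window starts reported.
#' @return Tibble (`dyncorr_table`): `patient_id`, `group`, `side`,
#'   `pair_set`, `epoch`, `window_start_s`, `r_mean`, `n_pairs`.
#' @export
compute_dyncorr_table <- function(epochs_by_patient, patients,
                                  side = "contralateral", species = "hbo2",
                                  fs = 25,
                                  keep = seq(0, 50, by = 10)) {
  pairs <- roi_pairs()
  rows <- list()
  for (pid in names(epochs_by_patient)) {
    eps <- epochs_by_patient[[pid]]
    for (k in names(eps)) {
      m <- eps[[k]]$segments[[side]][[species]]
      pr <- lapply(seq_len(nrow(pairs)), function(i) {
        a <- m[, pairs$roi_a[i]]; b <- m[, pairs$roi_b[i]]
        if (anyNA(a) || anyNA(b)) return(NULL)
        wp <- windowed_pearson(a, b, fs = fs, keep = keep)
        wp$pair_set <- pairs$pair_set[i]
        wp
      })
      pr <- dplyr::bind_rows(pr)
      if (nrow(pr) == 0) next
      tot <- pr; tot$pair_set <- "total"
      agg <- dplyr::summarise(
        dplyr::group_by(dplyr::bind_rows(pr, tot), .data$pair_set,
                        .data$window_start_s),
        r_mean = mean(.data$r, na.rm = TRUE),
        n_pairs = sum(!is.na(.data$r)), .groups = "drop")
      agg$patient_id <- pid
      agg$epoch <- k
      rows[[length(rows) + 1]] <- agg
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab$group <- ifelse(
    patients$nerve_block[match(tab$patient_id, patients$patient_id)],
    "NB", "non-NB")
  tab$side <- side
  dplyr::select(tab, "patient_id", "group", "side", "pair_set", "epoch",
                "window_start_s", "r_mean", "n_pairs")
}

#' Group statistics over the AUC table
#'
#' Per (side, species, ROI): a split-plot mixed ANOVA of AUC with epoch as
#' the within factor and nerve-block group between. Per (side, species,
#' epoch, ROI): a pooled two-sample t-test between groups. Each analysis
#' table forms one BH-FDR family.
#'
#' @param auc_tbl An `auc_table` from [compute_auc_table()].
#' @param alpha Significance / FDR level.
#' @return List of tibbles `anova` and `ttests`, each with `p_fdr` and
#'   significance flags.
#' @export
auc_group_tests <- function(auc_tbl, alpha = 0.05) {
  an <- dplyr::group_modify(
    dplyr::group_by(auc_tbl, .data$side, .data$species, .data$roi),
    function(d, key) {
      res <- tryCatch(
        mixed_anova(d, "auc", "patient_id", "group", "epoch"),
        error = function(e) NULL)
      if (is.null(res)) return(tibble::tibble())
      res
    })
  an <- dplyr::ungroup(an)
  if (nrow(an)) an <- dplyr::bind_cols(an, bh_fdr(an$p, alpha)[-1])
  tt <- dplyr::group_modify(
    dplyr::group_by(auc_tbl, .data$side, .data$species, .data$epoch,
                    .data$roi),
    function(d, key) {
      nb <- d$auc[d$group == "NB"]; nn <- d$auc[d$group == "non-NB"]
      if (length(nb) < 2 || length(nn) < 2) return(tibble::tibble())
      tryCatch(two_sample_t(nb, nn), error = function(e) tibble::tibble())
    })
  tt <- dplyr::ungroup(tt)
  if (nrow(tt)) tt <- dplyr::bind_cols(tt, bh_fdr(tt$p, alpha)[-1])
  list(anova = an, ttests = tt)
}

#' Group-by-time statistics over the dynamic correlation table
#'
#' Per (side, pair set, epoch): a split-plot mixed ANOVA of the mean
#' windowed correlation with the decimated window start as the within
#' factor and nerve-block group between; all effects in the table form one
#' BH-FDR family.
#'
#' @param dyn_tbl A `dyncorr_table`.
#' @param alpha Significance / FDR level.
#' @return Tibble of effects with `p_fdr` and significance flags.
#' @export
dyncorr_anova <- function(dyn_tbl, alpha = 0.05) {
  res <- dplyr::group_modify(
    dplyr::group_by(dyn_tbl, .data$side, .data$pair_set, .data$epoch),
    function(d, key) {
      out <- tryCatch(
        mixed_anova(d, "r_mean", "patient_id", "group", "window_start_s"),
        error = function(e) NULL)
      if (is.null(out)) return(tibble::tibble())
      out
    })
  res <- dplyr::ungroup(res)
  if (nrow(res)) res <- dplyr::bind_cols(res, bh_fdr(res$p, alpha)[-1])
  res
}
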