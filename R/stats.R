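# Statistical layer: correlations, unbalanced factorial ANOVA, split-plot
# ANOVA, estimated-marginal-mean (EMM) pairwise contrasts with Tukey-Kramer
# adjustment, subgroup regressions with Holm correction, and the
# skewness/kurtosis normality screen.

#' Pearson product-moment correlation
#'
#' Two-sided p-value from the t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-degenerate.
#' @return A tibble with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have equal length.",
                 class = "asragree_type_error")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    rlang::abort("Need at least 3 complete pairs.",
                 class = "asragree_degenerate_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Zero variance in `x` or `y`.",
                 class = "asragree_degenerate_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Unbalanced two-way ANOVA with partial eta squared
#'
#' Fits the full-interaction linear model with sum-to-zero factor coding and
#' reports Type III sums of squares (via [car::Anova()]), so results for
#' unbalanced designs line up with estimated-marginal-means contrasts.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' A design whose error sum of squares is (numerically) zero is returned with
#' `degenerate = TRUE` and `NA` F statistics rather than an error, so
#' simulation sweeps keep running.
#'
#' @param y Numeric response.
#' @param a,b Factors (coerced); every cell of `a x b` must be non-empty.
#' @param labels Names used for the two factors in the output table.
#' @return An object of class `factorial_anova`: a list with `table` (one row
#'   per effect and the error row: `effect`, `ss`, `df`, `f`, `p`,
#'   `partial_eta_sq`), the underlying `fit`, cell statistics `cells`, and
#'   `degenerate`.
#' @export
two_way_anova <- function(y, a, b, labels = c("A", "B")) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    rlang::abort("Both factors need at least 2 levels.",
                 class = "asragree_design_error")
  }
  if (any(table(a, b) == 0L)) {
    rlang::abort("Every factor-combination cell must be non-empty.",
                 class = "asragree_design_error")
  }
  dat <- data.frame(y = y, a = a, b = b)
  fit <- stats::lm(
    y ~ a * b, data = dat,
    contrasts = list(a = "contr.sum", b = "contr.sum")
  )
  ss_error <- sum(stats::residuals(fit)^2)
  df_error <- stats::df.residual(fit)
  degenerate <- ss_error < 1e-12 * max(sum(y^2), 1)

  if (degenerate) {
    eff <- c(labels, paste(labels, collapse = ":"))
    tab <- tibble::tibble(
      effect = c(eff, "error"),
      ss = c(rep(NA_real_, 3L), ss_error),
      df = c(nlevels(a) - 1L, nlevels(b) - 1L,
             (nlevels(a) - 1L) * (nlevels(b) - 1L), df_error),
      f = NA_real_, p = NA_real_, partial_eta_sq = NA_real_
    )
  } else {
    aov3 <- car::Anova(fit, type = 3)
    rows <- c("a", "b", "a:b")
    ss_eff <- aov3[rows, "Sum Sq"]
    df_eff <- aov3[rows, "Df"]
    f_eff <- aov3[rows, "F value"]
    p_eff <- aov3[rows, "Pr(>F)"]
    peta <- ss_eff / (ss_eff + ss_error)
    tab <- tibble::tibble(
      effect = c(labels, paste(labels, collapse = ":"), "error"),
      ss = c(ss_eff, ss_error),
      df = c(df_eff, df_error),
      f = c(f_eff, NA_real_),
      p = c(p_eff, NA_real_),
      partial_eta_sq = c(peta, NA_real_)
    )
  }

  cells <- dplyr::summarise(
    dplyr::group_by(dat, .data$a, .data$b),
    mean = mean(.data$y), sd = stats::sd(.data$y), n = dplyr::n(),
    .groups = "drop"
  )
  names(cells)[1:2] <- labels
  structure(
    list(table = tab, fit = fit, cells = cells, labels = labels,
         mse = ss_error / df_error, df_error = df_error,
         degenerate = degenerate),
    class = "factorial_anova"
  )
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat("<factorial_anova> Type III,", x$df_error, "error df",
      if (x$degenerate) "(degenerate: zero error SS)" else "", "\n")
  print(x$table)
  invisible(x)
}

# Core EMM pairwise-contrast arithmetic on cell summaries. Under a
# full-interaction model the EMM of a cell is its raw mean; a contrast is a
# difference of cell means with SE = sqrt(mse * (1/n_i + 1/n_j)) and a
# Tukey-Kramer adjusted p from the studentized-range distribution with
# k = number of cells.
.emm_contrast_core <- function(labels, means, ns, mse, dfs) {
  k <- length(means)
  idx <- utils::combn(k, 2L)
  est <- means[idx[1L, ]] - means[idx[2L, ]]
  se <- sqrt(mse * (1 / ns[idx[1L, ]] + 1 / ns[idx[2L, ]]))
  tr <- est / se
  dfv <- rep_len(dfs, ncol(idx))
  p_adj <- stats::ptukey(sqrt(2) * abs(tr), nmeans = k, df = dfv,
                         lower.tail = FALSE)
  p_adj[se == 0 & est == 0] <- 1
  tibble::tibble(
    contrast = paste(labels[idx[1L, ]], labels[idx[2L, ]], sep = " - "),
    estimate = est, se = se, df = dfv, t_ratio = tr, p_adj = p_adj
  )
}

#' EMM pairwise contrasts with Tukey-Kramer adjustment
#'
#' For a [two_way_anova()] fit, estimated marginal means of the factor-cell
#' combinations equal the raw cell means (full-interaction model); every
#' pairwise contrast is reported with its pooled-error standard error,
#' `t` ratio on the error degrees of freedom, and Tukey-Kramer adjusted
#' p-value (studentized range, `k` = number of cells, Kramer adjustment for
#' unequal cell sizes). For a [split_plot_anova()] fit, each contrast uses
#' the error stratum it belongs to: within-subject comparisons use the
#' within-subject error; between-subject comparisons pool both strata with
#' Satterthwaite degrees of freedom.
#'
#' @param model A `factorial_anova` or `split_plot_anova` object.
#' @return A tibble of contrasts: `contrast`, `estimate`, `se`, `df`,
#'   `t_ratio`, `p_adj`.
#' @export
emm_pairwise <- function(model) {
  UseMethod("emm_pairwise")
}

#' @export
emm_pairwise.factorial_anova <- function(model) {
  cells <- model$cells
  labels <- paste(as.character(cells[[1L]]), as.character(cells[[2L]]))
  .emm_contrast_core(labels, cells$mean, cells$n, model$mse, model$df_error)
}

#' EMM pairwise contrasts from published cell summaries
#'
#' Reconstructs the full-interaction EMM contrast table from cell means,
#' standard deviations and sizes alone (e.g. the summary table of a published
#' study): the pooled error variance is
#' `sum((n_i - 1) s_i^2) / (N - k)` and contrast standard errors, `t` ratios
#' and Tukey-Kramer p-values follow as in [emm_pairwise()]. With `sds =
#' NULL` only the estimates are returned (`se`, `t_ratio`, `p_adj` = `NA`).
#'
#' @param labels Character vector of cell labels.
#' @param means Cell means.
#' @param ns Cell sizes.
#' @param sds Cell standard deviations, or `NULL`.
#' @return A tibble of pairwise contrasts as in [emm_pairwise()].
#' @examples
#' emm_from_summary(c("DS.He", "TD.He", "DS.En", "TD.En"),
#'                  means = c(0.74, 0.94, 0.91, 0.98),
#'                  ns = c(24, 24, 8, 6),
#'                  sds = c(0.08, 0.06, 0.04, 0.02))
#' @export
emm_from_summary <- function(labels, means, ns, sds = NULL) {
  k <- length(means)
  stopifnot(length(labels) == k, length(ns) == k)
  if (is.null(sds)) {
    out <- .emm_contrast_core(labels, means, ns, mse = 1, dfs = sum(ns) - k)
    out$se <- NA_real_; out$t_ratio <- NA_real_; out$p_adj <- NA_real_
    out$df <- NA_real_
    return(out)
  }
  stopifnot(length(sds) == k)
  df_error <- sum(ns) - k
  mse <- sum((ns - 1) * sds^2) / df_error
  .emm_contrast_core(labels, means, ns, mse, df_error)
}

#' Split-plot (mixed) ANOVA
#'
#' Classical split-plot decomposition for one between-subject factor and one
#' within-subject factor: the between effect is tested against subjects
#' within groups, the within effect and the interaction against the
#' within-by-subject residual. Subjects missing any within level are dropped
#' (complete-case) with a warning. Partial eta squared uses each effect's own
#' error stratum.
#'
#' @param y Numeric response.
#' @param between Between-subject factor (constant within subject).
#' @param within Within-subject factor (2 levels; one observation per subject
#'   per level).
#' @param subject Subject identifier.
#' @return An object of class `split_plot_anova`: `table` (effects and both
#'   error strata), group sizes `n_groups`, and the stratum mean squares.
#' @export
split_plot_anova <- function(y, between, within, subject) {
  dat <- data.frame(
    y = y,
    between = factor(between),
    within = factor(within),
    subject = factor(as.character(subject))
  )
  if (nlevels(dat$within) != 2L) {
    rlang::abort("`within` must have exactly 2 levels.",
                 class = "asragree_design_error")
  }
  per_subj <- table(dat$subject, dat$within)
  complete <- rownames(per_subj)[apply(per_subj == 1L, 1L, all)]
  dropped <- setdiff(levels(dat$subject), complete)
  if (length(dropped) > 0L) {
    rlang::warn(sprintf(
      "Dropping %d subject(s) without both within-level observations: %s",
      length(dropped), paste(utils::head(dropped, 5L), collapse = ", ")
    ), class = "asragree_incomplete_subjects")
    dat <- dat[dat$subject %in% complete, , drop = FALSE]
    dat$subject <- droplevels(dat$subject)
    dat$between <- droplevels(dat$between)
  }

  n_subj <- nlevels(dat$subject)
  n_groups <- nlevels(dat$between)
  grand <- mean(dat$y)

  subj_means <- tapply(dat$y, dat$subject, mean)
  subj_group <- tapply(as.character(dat$between), dat$subject, `[`, 1L)
  group_means <- tapply(dat$y, dat$between, mean)
  group_n <- table(dat$between) / 2L        # subjects per group
  within_means <- tapply(dat$y, dat$within, mean)
  cell_means <- tapply(dat$y, list(dat$between, dat$within), mean)

  # Between-subject stratum (2 observations per subject).
  ss_between <- 2 * sum(table(dat$between)[names(group_means)] / 2 *
                          (group_means - grand)^2)
  ss_subj_total <- 2 * sum((subj_means - grand)^2)
  ss_subj_err <- ss_subj_total - ss_between
  df_between <- n_groups - 1L
  df_subj_err <- n_subj - n_groups

  # Within-subject stratum.
  nw <- nlevels(dat$within)
  ss_within <- n_subj * sum((within_means - grand)^2)
  cm <- cell_means
  gm <- matrix(group_means[rownames(cm)], nrow(cm), ncol(cm))
  wm <- matrix(within_means[colnames(cm)], nrow(cm), ncol(cm), byrow = TRUE)
  ngm <- matrix(as.numeric(group_n[rownames(cm)]), nrow(cm), ncol(cm))
  ss_inter <- sum(ngm * (cm - gm - wm + grand)^2)
  ss_total <- sum((dat$y - grand)^2)
  ss_ws_err <- ss_total - ss_subj_total - ss_within - ss_inter
  df_within <- nw - 1L
  df_inter <- df_between * df_within
  df_ws_err <- df_subj_err * df_within

  ms_subj_err <- ss_subj_err / df_subj_err
  ms_ws_err <- ss_ws_err / df_ws_err

  # a zero effect SS gives F = 0 even when the error stratum is also zero
  safe_f <- function(ms_eff, ms_err) {
    if (ms_eff == 0) 0 else ms_eff / ms_err
  }
  f_between <- safe_f(ss_between / df_between, ms_subj_err)
  f_within <- safe_f(ss_within / df_within, ms_ws_err)
  f_inter <- safe_f(ss_inter / df_inter, ms_ws_err)

  tab <- tibble::tibble(
    effect = c("between", "subject_error", "within", "between:within",
               "within_error"),
    ss = c(ss_between, ss_subj_err, ss_within, ss_inter, ss_ws_err),
    df = c(df_between, df_subj_err, df_within, df_inter, df_ws_err),
    f = c(f_between, NA, f_within, f_inter, NA),
    p = c(stats::pf(f_between, df_between, df_subj_err, lower.tail = FALSE),
          NA,
          stats::pf(f_within, df_within, df_ws_err, lower.tail = FALSE),
          stats::pf(f_inter, df_inter, df_ws_err, lower.tail = FALSE),
          NA),
    partial_eta_sq = c(ss_between / (ss_between + ss_subj_err), NA,
                       ss_within / (ss_within + ss_ws_err),
                       ss_inter / (ss_inter + ss_ws_err), NA)
  )

  cells <- dplyr::summarise(
    dplyr::group_by(dat, .data$between, .data$within),
    mean = mean(.data$y), sd = stats::sd(.data$y), n = dplyr::n(),
    .groups = "drop"
  )

  structure(
    list(table = tab, cells = cells,
         n_subjects = n_subj, n_dropped = length(dropped),
         group_n = as.numeric(group_n), group_levels = names(group_n),
         ms_subj_err = ms_subj_err, df_subj_err = df_subj_err,
         ms_ws_err = ms_ws_err, df_ws_err = df_ws_err,
         data = dat),
    class = "split_plot_anova"
  )
}

#' @export
print.split_plot_anova <- function(x, ...) {
  cat("<split_plot_anova>", x$n_subjects, "complete-case subjects",
      if (x$n_dropped) sprintf("(%d dropped)", x$n_dropped) else "", "\n")
  print(x$table)
  invisible(x)
}

#' @export
emm_pairwise.split_plot_anova <- function(model) {
  cells <- model$cells
  k <- nrow(cells)
  labels <- paste(as.character(cells$between), as.character(cells$within))
  group_of <- as.character(cells$between)
  n_subj_of <- model$group_n[match(group_of, model$group_levels)]

  idx <- utils::combn(k, 2L)
  est <- cells$mean[idx[1L, ]] - cells$mean[idx[2L, ]]
  same_group <- group_of[idx[1L, ]] == group_of[idx[2L, ]]

  se <- df <- numeric(ncol(idx))
  for (c_i in seq_len(ncol(idx))) {
    i <- idx[1L, c_i]; j <- idx[2L, c_i]
    if (same_group[c_i]) {
      # paired within-subject comparison: within error stratum only
      se[c_i] <- sqrt(2 * model$ms_ws_err / n_subj_of[i])
      df[c_i] <- model$df_ws_err
    } else {
      # between-subject comparison: cell-mean variance (sigma_s^2 + sigma_e^2)
      # estimated by the average of the two stratum mean squares
      v <- (model$ms_subj_err + model$ms_ws_err) / 2
      se[c_i] <- sqrt(v * (1 / n_subj_of[i] + 1 / n_subj_of[j]))
      df[c_i] <- (model$ms_subj_err + model$ms_ws_err)^2 /
        (model$ms_subj_err^2 / model$df_subj_err +
           model$ms_ws_err^2 / model$df_ws_err)
    }
  }
  tr <- est / se
  p_adj <- stats::ptukey(sqrt(2) * abs(tr), nmeans = k, df = df,
                         lower.tail = FALSE)
  tibble::tibble(
    contrast = paste(labels[idx[1L, ]], labels[idx[2L, ]], sep = " - "),
    estimate = est, se = se, df = df, t_ratio = tr, p_adj = p_adj
  )
}

#' Per-subgroup linear regressions with Holm correction
#'
#' Ordinary least squares of `y` on `x` within each subgroup; slope p-values
#' are Holm-Bonferroni adjusted across the subgroups supplied (one family per
#' call).
#'
#' @param x Predictor (e.g. listener intelligibility score).
#' @param y Response (e.g. listener-ASR agreement).
#' @param subgroup Subgroup labels.
#' @return A tibble with one row per subgroup: `subgroup`, `n`, `slope`,
#'   `intercept`, `r_sq`, `p_slope`, `p_adj`.
#' @export
subgroup_regressions <- function(x, y, subgroup) {
  dat <- data.frame(x = x, y = y, subgroup = as.character(subgroup))
  out <- lapply(split(dat, dat$subgroup), function(d) {
    if (nrow(d) < 3L) {
      rlang::abort(sprintf("Subgroup '%s' has fewer than 3 points.",
                           d$subgroup[1L]),
                   class = "asragree_degenerate_error")
    }
    if (stats::sd(d$x) == 0) {
      rlang::abort(sprintf("Subgroup '%s' has zero predictor variance.",
                           d$subgroup[1L]),
                   class = "asragree_degenerate_error")
    }
    fit <- stats::lm(y ~ x, data = d)
    sm <- suppressWarnings(summary(fit))  # degenerate cases handled below
    if (stats::sd(d$y) == 0) {
      # flat response: slope 0, no explained variance
      slope <- 0; r_sq <- 0; slope_p <- 1
    } else if (sm$sigma < 1e-12 * stats::sd(d$y)) {
      # perfectly collinear data: slope exact, p degenerate at 0
      slope <- unname(stats::coef(fit)["x"]); r_sq <- 1; slope_p <- 0
    } else {
      slope <- unname(stats::coef(fit)["x"])
      r_sq <- sm$r.squared
      slope_p <- sm$coefficients["x", "Pr(>|t|)"]
    }
    tibble::tibble(
      subgroup = d$subgroup[1L], n = nrow(d),
      slope = slope,
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      r_sq = r_sq,
      p_slope = slope_p
    )
  })
  out <- dplyr::bind_rows(out)
  out$p_adj <- stats::p.adjust(out$p_slope, method = "holm")
  out
}

#' Skewness/kurtosis normality screen
#'
#' Bias-corrected sample skewness and excess kurtosis (the SPSS/SAS `G1` and
#' `G2` estimators, [e1071::skewness()] / [e1071::kurtosis()] type 2), with
#' pass flags against the conventional screening thresholds |skewness| <= 2
#' and |excess kurtosis| <= 7.
#'
#' @param values Numeric vector, `n >= 4`.
#' @param skew_limit,kurt_limit Screening thresholds.
#' @return A tibble with `skewness`, `kurtosis`, `pass_skew`, `pass_kurt`,
#'   `n`.
#' @export
normality_screen <- function(values, skew_limit = 2, kurt_limit = 7) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    rlang::abort("Need at least 4 values for the bias-corrected moments.",
                 class = "asragree_degenerate_error")
  }
  sk <- e1071::skewness(values, type = 2)
  ku <- e1071::kurtosis(values, type = 2)
  tibble::tibble(
    skewness = sk, kurtosis = ku,
    pass_skew = abs(sk) <= skew_limit,
    pass_kurt = abs(ku) <= kurt_limit,
    n = length(values)
  )
}
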