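test_that("pearson correlation matches the direct formula", {
  x <- c(1, 2, 4, 5, 7, 9)
  y <- c(2.2, 2.8, 4.5, 4.9, 8.1, 8.4)
  res <- pearson_cor(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((6 - 2) / (1 - r^2))
  expect_equal(res$r, r)
  expect_equal(res$p, 2 * pt(-abs(tstat), 4))
  expect_equal(res$n, 6L)
})

test_that("pearson is exactly +/-1 on affine data and rejects degenerate input", {
  x <- c(0.1, 0.4, 1.2, 3, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(1, 5)), class = "asragree_degenerate_error")
  expect_error(pearson_cor(1:2, 2:3), class = "asragree_degenerate_error")
})

test_that("balanced two-way ANOVA equals the closed-form decomposition", {
  set.seed(410)
  for (rep in 1:5) {
    a <- rep(c("x", "y"), each = 12)
    b <- rep(rep(c("u", "v"), each = 6), 2)
    y <- rnorm(24) + 0.8 * (a == "x") + 0.5 * (b == "v") +
      0.7 * (a == "x") * (b == "v")
    fit <- two_way_anova(y, a, b)
    want <- balanced_anova_oracle(y, a, b)
    tab <- fit$table
    expect_equal(tab$ss[1], want$ss_a, tolerance = 1e-10)
    expect_equal(tab$ss[2], want$ss_b, tolerance = 1e-10)
    expect_equal(tab$ss[3], want$ss_ab, tolerance = 1e-10)
    expect_equal(tab$ss[4], want$ss_error, tolerance = 1e-10)
    eta <- want$ss_a / (want$ss_a + want$ss_error)
    expect_equal(tab$partial_eta_sq[1], eta, tolerance = 1e-10)
  }
})

test_that("unbalanced design bookkeeping: error df = N - cells", {
  set.seed(411)
  n <- c(24, 24, 8, 6)
  a <- rep(c("DS", "TD", "DS", "TD"), n)
  b <- rep(c("heb", "heb", "eng", "eng"), n)
  fit <- two_way_anova(rnorm(62, sd = 0.1), a, b)
  expect_equal(fit$df_error, 62 - 4)
  expect_equal(fit$table$df[fit$table$effect == "error"], 58)
  expect_error(two_way_anova(rnorm(10), rep("a", 10), rep(c("u", "v"), 5)),
               class = "asragree_design_error")
})

test_that("identical cell values are flagged degenerate, not an error", {
  y <- rep(c(1, 2, 3, 4), each = 3)
  a <- rep(c("x", "x", "y", "y"), each = 3)
  b <- rep(c("u", "v", "u", "v"), each = 3)
  fit <- two_way_anova(y, a, b)
  expect_true(fit$degenerate)
  expect_true(all(is.na(fit$table$f)))
})

test_that("EMM contrasts equal raw cell-mean differences and match emmeans", {
  set.seed(412)
  n <- c(9, 5, 7, 12)
  a <- factor(rep(c("g1", "g2", "g1", "g2"), n))
  b <- factor(rep(c("L1", "L1", "L2", "L2"), n))
  y <- rnorm(sum(n)) + as.numeric(a) + 0.5 * as.numeric(b)
  fit <- two_way_anova(y, a, b)
  got <- emm_pairwise(fit)

  cells <- fit$cells
  for (i in 1:3) for (j in (i + 1):4) {
    lab <- paste(paste(cells[[1]][i], cells[[2]][i]),
                 paste(cells[[1]][j], cells[[2]][j]), sep = " - ")
    row <- got[got$contrast == lab, ]
    expect_equal(row$estimate, cells$mean[i] - cells$mean[j])
    expect_equal(row$se,
                 sqrt(fit$mse * (1 / cells$n[i] + 1 / cells$n[j])))
  }

  lmfit <- lm(y ~ a * b)
  em <- emmeans::emmeans(lmfit, ~ a * b)
  ref <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  expect_equal(sort(abs(got$estimate)), sort(abs(ref$estimate)))
  expect_equal(sort(got$se), sort(ref$SE))
  expect_equal(sort(abs(got$t_ratio)), sort(abs(ref$t.ratio)),
               tolerance = 1e-8)
  expect_equal(sort(got$p_adj), sort(ref$p.value), tolerance = 1e-6)
})

test_that("summary-statistic EMM machinery reproduces the raw-data route", {
  set.seed(413)
  n <- c(11, 6, 9, 8)
  a <- factor(rep(c("g1", "g2", "g1", "g2"), n))
  b <- factor(rep(c("L1", "L1", "L2", "L2"), n))
  y <- rnorm(sum(n), sd = 0.3) + as.numeric(a)
  fit <- two_way_anova(y, a, b)
  raw <- emm_pairwise(fit)
  cells <- fit$cells
  from_sum <- emm_from_summary(
    paste(cells[[1]], cells[[2]]), cells$mean, cells$n, cells$sd
  )
  expect_equal(from_sum$estimate, raw$estimate)
  expect_equal(from_sum$se, raw$se, tolerance = 1e-12)
  expect_equal(from_sum$p_adj, raw$p_adj, tolerance = 1e-12)
})

test_that("Tukey-adjusted p-values are never below the unadjusted p", {
  set.seed(414)
  for (rep in 1:50) {
    tstat <- rt(1, 10) * 2
    df <- sample(5:60, 1)
    k <- sample(3:6, 1)
    p_tukey <- ptukey(sqrt(2) * abs(tstat), k, df, lower.tail = FALSE)
    p_raw <- 2 * pt(-abs(tstat), df)
    expect_gte(p_tukey, p_raw - 1e-12)
  }
})

test_that("split-plot decomposition matches the aov Error-stratum oracle", {
  set.seed(415)
  for (rep in 1:4) {
    n_g <- c(4, 3)
    subj <- rep(sprintf("s%02d", 1:7), each = 2)
    grp <- rep(rep(c("A", "B"), n_g), each = 2)
    wtn <- rep(c("w1", "w2"), 7)
    y <- rnorm(14) + (grp == "A") * 0.5 + (wtn == "w2") * 1.2 +
      rep(rnorm(7, sd = 0.7), each = 2)
    got <- split_plot_anova(y, grp, wtn, subj)

    dat <- data.frame(y, grp = factor(grp), wtn = factor(wtn),
                      subj = factor(subj))
    or <- summary(aov(y ~ grp * wtn + Error(subj), data = dat))
    s1 <- or[["Error: subj"]][[1]]
    s2 <- or[["Error: Within"]][[1]]
    tab <- got$table
    expect_equal(tab$ss[tab$effect == "between"], s1["grp", "Sum Sq"])
    expect_equal(tab$ss[tab$effect == "subject_error"],
                 s1["Residuals", "Sum Sq"])
    expect_equal(tab$ss[tab$effect == "within"], s2["wtn", "Sum Sq"])
    expect_equal(tab$ss[tab$effect == "between:within"],
                 s2["grp:wtn", "Sum Sq"])
    expect_equal(tab$ss[tab$effect == "within_error"],
                 s2["Residuals", "Sum Sq"])
    expect_equal(tab$f[tab$effect == "between"], s1["grp", "F value"])
    expect_equal(tab$f[tab$effect == "within"], s2["wtn", "F value"])
    # SS conservation
    expect_equal(sum(tab$ss), sum((y - mean(y))^2))
  }
})

test_that("split-plot degrees of freedom follow the design sizes", {
  set.seed(416)
  # 42 complete-case subjects in 2 groups -> all F tests on (1, 40)
  subj <- rep(sprintf("s%02d", 1:42), each = 2)
  grp <- rep(rep(c("DS", "TD"), c(20, 22)), each = 2)
  wtn <- rep(c("word", "sentence"), 42)
  y <- rnorm(84)
  got <- split_plot_anova(y, grp, wtn, subj)
  tab <- got$table
  expect_equal(tab$df[tab$effect == "subject_error"], 40)
  expect_equal(tab$df[tab$effect == "within_error"], 40)
  expect_equal(tab$df[tab$effect == "between"], 1)
  expect_equal(tab$df[tab$effect == "within"], 1)

  # subjects missing one within level are dropped with a warning
  keep <- !(subj %in% c("s01", "s41") & wtn == "sentence")
  expect_warning(
    got2 <- split_plot_anova(y[keep], grp[keep], wtn[keep], subj[keep]),
    class = "asragree_incomplete_subjects"
  )
  expect_equal(got2$n_subjects, 40)
  expect_equal(got2$table$df[got2$table$effect == "subject_error"], 38)

  # zero within-subject difference everywhere -> within F = 0
  yflat <- rep(rnorm(42), each = 2)
  gotf <- split_plot_anova(yflat, grp, wtn, subj)
  expect_equal(gotf$table$f[gotf$table$effect == "within"], 0)
})

test_that("split-plot EMM contrasts use the right error strata", {
  set.seed(417)
  n_g <- c(10, 8)
  subj <- rep(sprintf("s%02d", 1:18), each = 2)
  grp <- rep(rep(c("A", "B"), n_g), each = 2)
  wtn <- rep(c("w1", "w2"), 18)
  y <- rnorm(36) + rep(rnorm(18, sd = 0.8), each = 2) + (wtn == "w2") * 0.6
  sp <- split_plot_anova(y, grp, wtn, subj)
  got <- emm_pairwise(sp)

  # within-group paired contrast: SE^2 = 2 * MS_within_error / n_subjects
  row <- got[got$contrast == "A w1 - A w2", ]
  expect_equal(row$se^2, 2 * sp$ms_ws_err / 10)
  expect_equal(row$df, sp$df_ws_err)
  # between-group contrast pools the strata
  row <- got[got$contrast == "A w1 - B w1", ]
  v <- (sp$ms_subj_err + sp$ms_ws_err) / 2
  expect_equal(row$se^2, v * (1 / 10 + 1 / 8))
  # estimates are raw cell-mean differences
  cm <- tapply(y, list(grp, wtn), mean)
  expect_equal(got$estimate[got$contrast == "A w1 - B w1"],
               cm["A", "w1"] - cm["B", "w1"])

  # emmeans on the equivalent aov Error-stratum model agrees on SEs
  dat <- data.frame(y, grp = factor(grp), wtn = factor(wtn),
                    subj = factor(subj))
  # inline the data so emmeans can re-evaluate the aov call in its own scope
  afit <- eval(bquote(aov(y ~ grp * wtn + Error(subj), data = .(dat))))
  em <- suppressMessages(emmeans::emmeans(afit, ~ grp * wtn, data = dat))
  ref <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  key <- function(s) paste(sort(strsplit(s, " - ")[[1]]), collapse = "|")
  ref_key <- vapply(as.character(ref$contrast), key, character(1))
  got_key <- vapply(got$contrast, key, character(1))
  ord <- match(got_key, ref_key)
  expect_false(anyNA(ord))
  expect_equal(got$se, ref$SE[ord], tolerance = 1e-8)
  expect_equal(abs(got$estimate), abs(ref$estimate[ord]), tolerance = 1e-10)
})

test_that("Holm correction follows the step-down formula", {
  praw <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(praw, "holm"), c(0.03, 0.04, 0.04))
  set.seed(418)
  x <- runif(30); g <- rep(c("a", "b", "c"), 10)
  y <- 0.5 * x + rnorm(30, sd = 0.2)
  res <- subgroup_regressions(x, y, g)
  expect_equal(res$p_adj, p.adjust(res$p_slope, "holm"))
  expect_true(all(res$p_adj >= res$p_slope))
})

test_that("subgroup regressions recover exact fits and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  res <- subgroup_regressions(x, 0.5 * x, rep("only", 5))
  expect_equal(res$slope, 0.5)
  expect_equal(res$r_sq, 1)
  res <- subgroup_regressions(x, rep(2, 5), rep("only", 5))
  expect_equal(res$slope, 0)
  expect_equal(res$r_sq, 0)
  expect_error(subgroup_regressions(rep(1, 5), x, rep("only", 5)),
               class = "asragree_degenerate_error")
  expect_error(subgroup_regressions(1:2, 1:2, rep("only", 2)),
               class = "asragree_degenerate_error")
})

test_that("normality screen matches direct moment formulas", {
  x <- c(0.2, 0.5, 0.9, 1.4, 2.0, 2.1, 3.3, 7.8)
  res <- normality_screen(x)
  want <- moment_oracle(x)
  expect_equal(res$skewness, want$skewness)
  expect_equal(res$kurtosis, want$kurtosis)
  # mirrored data have zero skewness
  sym <- c(-3, -1, -0.2, 0.2, 1, 3)
  expect_equal(normality_screen(sym)$skewness, 0)
  set.seed(419)
  big <- rnorm(10000)
  scr <- normality_screen(big)
  expect_true(scr$pass_skew && scr$pass_kurt)
})
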