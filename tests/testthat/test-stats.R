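# direct simulation of a tidy threshold table (bypasses the trial level so
# the statistical layer can be exercised quickly)
simulate_rmt_table <- function(n_subjects = 13,
                               base = c(`30` = 68, `60` = 35, `120` = 18),
                               cbz_shift = c(0, 0, 0),
                               lcs_shift = c(0, 0, 0),
                               subject_sd = 4, resid_sd = 0.8) {
  subj_eff <- rnorm(n_subjects, 0, subject_sd)
  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    condition = c("placebo", "carbamazepine", "lacosamide"),
    pulse_width_us = c(30, 60, 120))
  shift <- function(cond, w) {
    k <- match(w, c(30, 60, 120))
    ifelse(cond == "carbamazepine", cbz_shift[k],
           ifelse(cond == "lacosamide", lcs_shift[k], 0))
  }
  grid$rmt_io <- base[as.character(grid$pulse_width_us)] *
    (1 + subj_eff[as.integer(factor(grid$subject_id))] / 100) +
    shift(grid$condition, grid$pulse_width_us) +
    rnorm(nrow(grid), 0, resid_sd)
  grid
}

test_that("effect size is the estimate over the residual SD", {
  expect_equal(cohen_d(0, 3), 0)
  expect_equal(cohen_d(5.11, 5.11), 1)
  expect_equal(cohen_d(c(1, -2), 2), c(0.5, -1))
  expect_error(cohen_d(1, 0), "positive")
})

test_that("threshold mixed model reports consistent effects and df", {
  set.seed(42)
  tbl <- simulate_rmt_table(cbz_shift = c(8, 5, 3), lcs_shift = c(2, 2, 2))
  res <- fit_lme_rmt(tbl)
  expect_s3_class(res$effects, "tbl_df")
  # residual df rule: 117 observations minus 9 fixed-effect columns
  expect_equal(unique(res$effects$df), 108)
  expect_equal(unique(res$anova$df_den), 108)
  expect_equal(res$anova$effect,
               c("condition", "pulse_width", "condition:pulse_width"))
  expect_equal(res$anova$df_num, c(2L, 2L, 4L))
  # internal consistency of the reporting
  expect_equal(res$effects$t, res$effects$estimate / res$effects$se,
               tolerance = 1e-10)
  expect_true(all(res$effects$p > 0 & res$effects$p <= 1))
  expect_true(all(res$anova$F >= 0))
  expect_true(all(res$anova$p > 0 & res$anova$p <= 1))
  # the strong width effect must dominate
  expect_lt(res$anova$p[res$anova$effect == "pulse_width"], 1e-10)
})

test_that("null cohorts give small drug contrasts and additive ones recover", {
  reps <- 100
  null_ok <- 0
  lcs_est <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(5000 + i)
    tbl <- simulate_rmt_table()
    res <- fit_lme_rmt(tbl)
    within2se <- abs(res$effects$estimate) <= 2 * res$effects$se
    null_ok <- null_ok + all(within2se)

    set.seed(6000 + i)
    tbl2 <- simulate_rmt_table(lcs_shift = c(2, 2, 2))
    res2 <- fit_lme_rmt(tbl2)
    lcs_est[i] <- res2$effects$estimate[grepl("lacosamide", res2$effects$term)]
  }
  expect_gte(null_ok / reps, 0.90)
  expect_lt(abs(median(lcs_est) - 2), 0.5)
})

test_that("scalar mixed model matches the printed-df convention", {
  set.seed(8)
  vals <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:13),
                             condition = c("placebo", "carbamazepine",
                                           "lacosamide"))
  vals$sdtc_us <- 550 + rnorm(13, 0, 80)[as.integer(factor(vals$subject_id))] +
    rnorm(nrow(vals), 0, 40) - 70 * (vals$condition == "lacosamide")
  res <- fit_lme_scalar(vals, "sdtc_us")
  # 39 observations minus 3 fixed-effect columns
  expect_equal(unique(res$effects$df), 36)
  expect_equal(res$anova$df_den, 36)
  lcs <- res$effects[grepl("lacosamide", res$effects$term), ]
  expect_lt(abs(lcs$estimate - (-70)), 3 * lcs$se)
  expect_equal(lcs$cohen_d, lcs$estimate / sigma(res$model), tolerance = 1e-10)
})

test_that("identical values across conditions give null contrasts", {
  vals <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:8),
                             condition = c("placebo", "carbamazepine",
                                           "lacosamide"))
  vals$sdtc_us <- rep(seq(400, 750, by = 50), each = 3)
  res <- fit_lme_scalar(vals, "sdtc_us")
  expect_equal(res$effects$estimate, c(0, 0), tolerance = 1e-8)
  expect_lt(res$anova$F, 1e-8)
})

test_that("contrasts are invariant to condition relabelling up to sign", {
  set.seed(12)
  vals <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:10),
                             condition = c("placebo", "carbamazepine",
                                           "lacosamide"))
  vals$sdtc_us <- 500 + rnorm(nrow(vals), 0, 60)
  res_pla <- fit_lme_scalar(vals, "sdtc_us", reference = "placebo")
  res_cbz <- fit_lme_scalar(vals, "sdtc_us", reference = "carbamazepine")
  cbz_vs_pla <- res_pla$effects$estimate[
    grepl("carbamazepine", res_pla$effects$term)]
  pla_vs_cbz <- res_cbz$effects$estimate[
    grepl("placebo", res_cbz$effects$term)]
  expect_equal(cbz_vs_pla, -pla_vs_cbz, tolerance = 1e-8)
  expect_equal(res_pla$anova$F, res_cbz$anova$F, tolerance = 1e-8)
})

test_that("condition F test holds its nominal size", {
  reps <- 500
  pvals <- vapply(seq_len(reps), function(i) {
    set.seed(9000 + i)
    vals <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:13),
                               condition = c("placebo", "carbamazepine",
                                             "lacosamide"))
    vals$y <- 550 + rnorm(13, 0, 100)[as.integer(factor(vals$subject_id))] +
      rnorm(nrow(vals), 0, 50)
    fit_lme_scalar(vals, "y")$anova$p
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.075)
})

test_that("missing cells are dropped listwise with a warning", {
  vals <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:8),
                             condition = c("placebo", "carbamazepine",
                                           "lacosamide"))
  set.seed(2)
  vals$sdtc_us <- 500 + rnorm(nrow(vals), 0, 50)
  vals$sdtc_us[vals$subject_id == "S03" &
                 vals$condition == "lacosamide"] <- NA
  expect_warning(res <- fit_lme_scalar(vals, "sdtc_us"), "S03")
  expect_equal(unique(res$effects$df), 7 * 3 - 3)
})

test_that("placebo differences expose additive versus multiplicative effects", {
  set.seed(33)
  # multiplicative: +12% of threshold at every width; additive: flat +2
  tbl <- simulate_rmt_table(cbz_shift = 0.12 * c(68, 35, 18),
                            lcs_shift = c(2, 2, 2), resid_sd = 0.5)
  res <- placebo_differences(tbl)
  s <- res$summary
  cbz <- s[s$condition == "carbamazepine", ]
  lcs <- s[s$condition == "lacosamide", ]
  # scaling effect: difference shrinks with width; additive: flat
  expect_gt(cbz$mean_diff[cbz$pulse_width_us == 30],
            cbz$mean_diff[cbz$pulse_width_us == 120] + 2)
  expect_lt(abs(lcs$mean_diff[lcs$pulse_width_us == 30] -
                  lcs$mean_diff[lcs$pulse_width_us == 120]), 1)
  expect_equal(unique(res$anova$df_den), 13 * 2 * 3 - 6)
  inter <- res$anova[res$anova$effect == "condition:pulse_width", ]
  expect_lt(inter$p, 0.05)

  # drug identical to placebo gives all-zero differences
  tbl0 <- tbl
  wide <- tidyr::pivot_wider(tbl0, names_from = "condition",
                             values_from = "rmt_io")
  wide$carbamazepine <- wide$placebo
  wide$lacosamide <- wide$placebo
  tbl0 <- tidyr::pivot_longer(wide, cols = c("placebo", "carbamazepine",
                                             "lacosamide"),
                              names_to = "condition", values_to = "rmt_io")
  res0 <- placebo_differences(tbl0)
  expect_true(all(abs(res0$differences$diff_rmt) < 1e-12))
})

test_that("sdtc-rheobase relationship recovers a collinear input exactly", {
  fits <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:10),
                             condition = c("placebo", "carbamazepine",
                                           "lacosamide"))
  set.seed(4)
  fits$rheobase_pct_mso <- runif(nrow(fits), 3, 8)
  fits$sdtc_us <- 900 - 46 * fits$rheobase_pct_mso
  res <- sdtc_rheobase_relationship(fits)
  expect_equal(res$slopes$slope_us_per_pct, rep(-46, 3), tolerance = 1e-8)
  expect_equal(res$slopes$r_squared, rep(1, 3), tolerance = 1e-8)
  slope_term <- res$effects[res$effects$term == "rheobase_pct_mso", ]
  expect_equal(slope_term$estimate, -46, tolerance = 1e-6)
  # residual-rule df: 30 observations minus 6 fixed-effect columns
  expect_equal(unique(res$effects$df), 24)
})

test_that("condition-specific slope offsets are recovered", {
  set.seed(14)
  ests <- replicate(30, {
    fits <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:13),
                               condition = c("placebo", "carbamazepine",
                                             "lacosamide"))
    fits$rheobase_pct_mso <- runif(nrow(fits), 3, 8)
    slope <- ifelse(fits$condition == "lacosamide", -25, -46)
    fits$sdtc_us <- 800 + slope * fits$rheobase_pct_mso +
      rnorm(nrow(fits), 0, 20)
    res <- sdtc_rheobase_relationship(fits)
    res$effects$estimate[
      res$effects$term == "rheobase_pct_mso:conditionlacosamide"]
  })
  expect_lt(abs(median(ests) - 21), 4)
  # degenerate variance is rejected
  bad <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:6),
                            condition = "placebo")
  bad$rheobase_pct_mso <- 5
  bad$sdtc_us <- 500
  expect_error(sdtc_rheobase_relationship(bad), "variance")
})

test_that("satterthwaite df are available as an option", {
  skip_if_not_installed("lmerTest")
  set.seed(3)
  vals <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:10),
                             condition = c("placebo", "carbamazepine",
                                           "lacosamide"))
  vals$sdtc_us <- 500 + rnorm(10, 0, 80)[as.integer(factor(vals$subject_id))] +
    rnorm(nrow(vals), 0, 40)
  res_r <- fit_lme_scalar(vals, "sdtc_us", df_method = "residual")
  res_s <- fit_lme_scalar(vals, "sdtc_us", df_method = "satterthwaite")
  expect_equal(res_s$effects$estimate, res_r$effects$estimate,
               tolerance = 1e-8)
  expect_false(isTRUE(all.equal(res_s$effects$df, res_r$effects$df)))
})
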