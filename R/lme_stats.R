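#' Effect size as estimate over residual SD
#'
#' Cohen d for a mixed-model fixed effect, defined as the fixed-effect
#' estimate divided by the model's residual standard deviation.
#'
#' @param estimate Fixed-effect estimate (model units).
#' @param residual_sd Residual standard deviation (> 0).
#' @return The standardized effect size.
#' @export
cohen_d <- function(estimate, residual_sd) {
  if (any(residual_sd <= 0)) stop("'residual_sd' must be positive", call. = FALSE)
  estimate / residual_sd
}

# residual-rule denominator df: N_obs - rank of the fixed-effects design
residual_df <- function(model) {
  X <- lme4::getME(model, "X")
  nrow(X) - qr(X)$rank
}

# fixed-effect table (estimate, se, t, df, p, d) for selected coefficients
fixed_effect_table <- function(model, terms = NULL, df_method = "residual") {
  b <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(V))
  if (is.null(terms)) terms <- names(b)
  keep <- match(terms, names(b))
  if (anyNA(keep)) {
    stop("unknown coefficient(s): ", paste(terms[is.na(keep)], collapse = ", "),
         call. = FALSE)
  }
  est <- unname(b[keep])
  se <- unname(se[keep])
  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("df_method = 'satterthwaite' requires the lmerTest package",
           call. = FALSE)
    }
    m2 <- lmerTest::as_lmerModLmerTest(model)
    ct <- stats::coef(summary(m2))
    df <- unname(ct[keep, "df"])
  } else {
    df <- rep(residual_df(model), length(keep))
  }
  tval <- est / se
  sig <- stats::sigma(model)
  tibble::tibble(
    term = terms, estimate = est, se = se, t = tval, df = df,
    p = 2 * stats::pt(-abs(tval), df),
    cohen_d = cohen_d(est, sig)
  )
}

# marginal (Type III) Wald F tests of the fixed-effect terms, computed on a
# refit with sum-to-zero contrasts so each term is tested at the average of
# the others
wald_anova <- function(model, df_method = "residual") {
  X <- lme4::getME(model, "X")
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(model), "term.labels")
  b <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  df_den <- residual_df(model)
  rows <- lapply(seq_along(labels), function(k) {
    idx <- which(asgn == k)
    bb <- b[idx]
    Fval <- drop(t(bb) %*% solve(V[idx, idx, drop = FALSE], bb)) / length(idx)
    tibble::tibble(effect = labels[k], df_num = length(idx), df_den = df_den,
                   F = Fval,
                   p = stats::pf(Fval, length(idx), df_den, lower.tail = FALSE))
  })
  purrr::list_rbind(rows)
}

prepare_rmt_data <- function(table, reference) {
  need <- c("subject_id", "condition", "pulse_width_us", "rmt_io")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("threshold table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(table)
  d$condition <- stats::relevel(factor(d$condition), ref = reference)
  d$pulse_width <- factor(d$pulse_width_us)
  d$subject_id <- factor(d$subject_id)
  d
}

#' Mixed-effects analysis of motor thresholds
#'
#' Fits a linear mixed-effects model of the input-output-derived motor
#' threshold with fixed effects of medication condition, pulse width and
#' their interaction, and subject-level random effects. Two summaries are
#' returned: marginal (Type III) F tests of the fixed-effect terms, computed
#' under sum-to-zero contrasts, and reference-coded contrasts of each drug
#' against the reference condition (with pulse width sum-coded, so the
#' contrasts are averages over pulse widths) with SE, t, df, p and Cohen d.
#'
#' The default denominator degrees of freedom use the residual rule
#' `N_obs - rank(fixed design)`; Satterthwaite approximation is available via
#' `df_method = "satterthwaite"`. The default random-effects structure is a
#' subject random intercept; `random = "slope"` adds a random pulse-width
#' slope and falls back to the intercept-only model (with a note) when that
#' fit is singular.
#'
#' @param table Tidy threshold table (`subject_id`, `condition`,
#'   `pulse_width_us`, `rmt_io`), >= 5 subjects.
#' @param reference Reference condition label (default `"placebo"`).
#' @param random `"intercept"` or `"slope"`.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return A list of class `lme_rmt`: `effects` (contrast tibble), `anova`
#'   (F-test tibble), `model` (the reference-coded `lmerMod`), `notes`.
#' @export
fit_lme_rmt <- function(table, reference = "placebo",
                        random = c("intercept", "slope"),
                        df_method = c("residual", "satterthwaite")) {
  random <- match.arg(random)
  df_method <- match.arg(df_method)
  d <- prepare_rmt_data(table, reference)
  if (nlevels(d$subject_id) < 5L) stop("need at least 5 subjects", call. = FALSE)
  notes <- character()
  re <- if (random == "slope") "(1 + pulse_width | subject_id)" else "(1 | subject_id)"
  fit_with <- function(contrs, re_term) {
    form <- stats::as.formula(paste("rmt_io ~ condition * pulse_width +", re_term))
    lme4::lmer(form, data = d, REML = TRUE,
               contrasts = contrs,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  }
  sum_contr <- list(condition = stats::contr.sum, pulse_width = stats::contr.sum)
  trt_contr <- list(condition = stats::contr.treatment, pulse_width = stats::contr.sum)
  m_sum <- fit_with(sum_contr, re)
  if (random == "slope" && lme4::isSingular(m_sum, tol = 1e-5)) {
    notes <- c(notes, "random-slope fit singular; refit with random intercept only")
    re <- "(1 | subject_id)"
    m_sum <- fit_with(sum_contr, re)
  }
  m_trt <- fit_with(trt_contr, re)
  if (qr(lme4::getME(m_trt, "X"))$rank < ncol(lme4::getME(m_trt, "X"))) {
    stop("rank-deficient fixed-effects design", call. = FALSE)
  }
  anova_tbl <- wald_anova(m_sum, df_method)
  drug_terms <- paste0("condition", setdiff(levels(d$condition), reference))
  effects <- fixed_effect_table(m_trt, drug_terms, df_method)
  effects$term <- paste0(sub("^condition", "", effects$term), " - ", reference)
  structure(list(effects = effects, anova = anova_tbl, model = m_trt,
                 notes = notes), class = "lme_rmt")
}

#' Mixed-effects analysis of a per-subject scalar outcome
#'
#' For one value per subject x condition (e.g. the strength-duration time
#' constant or the rheobase): fits `value ~ condition + (1 | subject)`,
#' returning the omnibus condition F test and the contrasts of each condition
#' against the reference, with Cohen d. Subjects with missing cells are
#' dropped listwise with a warning.
#'
#' @param values Tidy table with columns `subject_id`, `condition`, and the
#'   outcome column named by `value_col`.
#' @param value_col Name of the outcome column.
#' @param reference Reference condition label.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return A list of class `lme_scalar` with `effects`, `anova`, `model`.
#' @export
fit_lme_scalar <- function(values, value_col, reference = "placebo",
                           df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  need <- c("subject_id", "condition", value_col)
  missing <- setdiff(need, names(values))
  if (length(missing)) {
    stop("value table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(values)
  d$value <- d[[value_col]]
  d$condition <- stats::relevel(factor(d$condition), ref = reference)
  d$subject_id <- factor(d$subject_id)
  n_cond <- nlevels(d$condition)
  complete <- tapply(!is.na(d$value), d$subject_id, sum)
  drop <- names(complete)[complete < n_cond]
  if (length(drop)) {
    warning("dropping subject(s) with missing cells: ",
            paste(drop, collapse = ", "), call. = FALSE)
    d <- d[!(as.character(d$subject_id) %in% drop), , drop = FALSE]
    d$subject_id <- droplevels(d$subject_id)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  m_sum <- lme4::lmer(value ~ condition + (1 | subject_id), data = d,
                      contrasts = list(condition = stats::contr.sum),
                      control = ctrl)
  m_trt <- lme4::lmer(value ~ condition + (1 | subject_id), data = d,
                      control = ctrl)
  drug_terms <- paste0("condition", setdiff(levels(d$condition), reference))
  effects <- fixed_effect_table(m_trt, drug_terms, df_method)
  effects$term <- paste0(sub("^condition", "", effects$term), " - ", reference)
  structure(list(effects = effects, anova = wald_anova(m_sum, df_method),
                 model = m_trt), class = "lme_scalar")
}

#' Drug-minus-placebo threshold differences across pulse widths
#'
#' Computes per-subject paired differences in motor threshold between each
#' drug condition and the reference at every pulse width, and tests whether
#' the differences depend on pulse width (condition x pulse width interaction
#' in a mixed model on the differences). A multiplicative (threshold-scaling)
#' drug effect produces differences that grow with the absolute threshold —
#' larger at shorter pulse widths — whereas an additive shift produces flat
#' differences.
#'
#' @inheritParams fit_lme_rmt
#' @return A list of class `placebo_diff`: `differences` (per subject x drug
#'   x width), `summary` (mean and SEM per drug x width), `anova` (F tests on
#'   the difference model), `model`.
#' @export
placebo_differences <- function(table, reference = "placebo",
                                df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  d <- prepare_rmt_data(table, reference)
  ref <- d |>
    dplyr::filter(.data$condition == reference) |>
    dplyr::select("subject_id", "pulse_width_us", ref_rmt = "rmt_io")
  diffs <- d |>
    dplyr::filter(.data$condition != reference) |>
    dplyr::inner_join(ref, by = c("subject_id", "pulse_width_us")) |>
    dplyr::mutate(diff_rmt = .data$rmt_io - .data$ref_rmt) |>
    dplyr::select("subject_id", "condition", "pulse_width_us", "pulse_width",
                  "diff_rmt")
  lost <- setdiff(
    unique(paste(d$subject_id[d$condition != reference],
                 d$pulse_width_us[d$condition != reference])),
    unique(paste(diffs$subject_id, diffs$pulse_width_us)))
  if (length(lost)) {
    warning("subject x width cells without a ", reference,
            " measurement were excluded: ", length(lost), call. = FALSE)
  }
  diffs$condition <- droplevels(diffs$condition)
  if (stats::sd(diffs$diff_rmt) < 1e-10) {
    # drug identical to the reference everywhere: nothing to model
    n_cond <- nlevels(diffs$condition)
    n_w <- nlevels(droplevels(diffs$pulse_width))
    labels <- c("condition", "pulse_width", "condition:pulse_width")
    dfs <- c(n_cond - 1L, n_w - 1L, (n_cond - 1L) * (n_w - 1L))
    anova_tbl <- tibble::tibble(effect = labels, df_num = dfs,
                                df_den = nrow(diffs) - n_cond * n_w,
                                F = 0, p = 1)
    m <- NULL
  } else {
    m <- lme4::lmer(diff_rmt ~ condition * pulse_width + (1 | subject_id),
                    data = diffs,
                    contrasts = list(condition = stats::contr.sum,
                                     pulse_width = stats::contr.sum),
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    anova_tbl <- wald_anova(m, df_method)
  }
  summary_tbl <- diffs |>
    dplyr::group_by(.data$condition, .data$pulse_width_us) |>
    dplyr::summarise(mean_diff = mean(.data$diff_rmt),
                     sem = stats::sd(.data$diff_rmt) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(differences = diffs, summary = summary_tbl,
                 anova = anova_tbl, model = m),
            class = "placebo_diff")
}

#' Relationship between the time constant and the rheobase
#'
#' Within-condition ordinary regressions of the strength-duration time
#' constant on the rheobase, plus a combined mixed model with condition and
#' the condition x rheobase interaction as fixed effects and subject random
#' intercepts. A strong inverse association is expected both physiologically
#' (shared dependence on sodium conductance) and — on noisy estimates — as an
#' estimation-covariance artifact of the two-parameter fit.
#'
#' @param fits Table with columns `subject_id`, `condition`, `sdtc_us`,
#'   `rheobase_pct_mso` (e.g. from [fit_sd_study()]); >= 5 subjects.
#' @param reference Reference condition label.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return A list of class `sdtc_rheobase`: `slopes` (per-condition lm
#'   summaries), `effects` (fixed effects of the combined model), `model`.
#' @export
sdtc_rheobase_relationship <- function(fits, reference = "placebo",
                                       df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  need <- c("subject_id", "condition", "sdtc_us", "rheobase_pct_mso")
  missing <- setdiff(need, names(fits))
  if (length(missing)) {
    stop("fit table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(fits)
  d$condition <- stats::relevel(factor(d$condition), ref = reference)
  d$subject_id <- factor(d$subject_id)
  if (nlevels(d$subject_id) < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (stats::var(d$rheobase_pct_mso) <= 0 || stats::var(d$sdtc_us) <= 0) {
    stop("degenerate variance in sdtc or rheobase", call. = FALSE)
  }
  slopes <- d |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(g, key) {
      m <- stats::lm(sdtc_us ~ rheobase_pct_mso, data = g)
      sm <- summary(m)
      tibble::tibble(
        slope_us_per_pct = stats::coef(m)[["rheobase_pct_mso"]],
        se = sm$coefficients["rheobase_pct_mso", "Std. Error"],
        p = sm$coefficients["rheobase_pct_mso", "Pr(>|t|)"],
        r_squared = sm$r.squared, n = nrow(g))
    }) |>
    dplyr::ungroup()
  m <- lme4::lmer(sdtc_us ~ rheobase_pct_mso * condition + (1 | subject_id),
                  data = d,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  structure(list(slopes = slopes,
                 effects = fixed_effect_table(m, df_method = df_method),
                 model = m),
            class = "sdtc_rheobase")
}
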