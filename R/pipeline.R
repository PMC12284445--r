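#' Run the full excitability analysis pipeline
#'
#' Orchestrates the analysis stages in order — input-output curve fitting and
#' threshold inversion per session, strength-duration (rheobase / time
#' constant) fitting per subject and condition, and the mixed-effects
#' statistical layer (threshold model, scalar models for the time constant
#' and rheobase, drug-minus-placebo differences, time-constant-vs-rheobase
#' relationship). Inputs are either a trial table in the standard schema or,
#' when `trials` is `NULL`, a synthetic study generated from `config`. With
#' `out_dir` set, every stage writes its CSV/JSON artifact so any stage can
#' be re-run from its predecessor's outputs.
#'
#' @param trials Trial table (or path to a trial CSV); `NULL` to simulate.
#' @param config A [sim_config()] used when simulating.
#' @param wfs Named waveform list; defaults to the pseudorectangular family
#'   (or rectangular when `waveform = "rectangular"`).
#' @param waveform `"ctms_pseudorect"` or `"rectangular"`.
#' @param shared_sdtc Also fit the shared-time-constant sensitivity analysis?
#' @param reference Reference condition label.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @param out_dir Optional output directory for stage artifacts.
#' @return A list of class `sd_pipeline` with elements `io_fits`,
#'   `rmt_table`, `sd_fits`, `sd_fits_shared` (or `NULL`), `stats`
#'   (`rmt_model`, `sdtc_model`, `rheobase_model`, `differences`,
#'   `relationship`), `truth` (when simulated) and `config`.
#' @export
run_pipeline <- function(trials = NULL, config = sim_config(), wfs = NULL,
                         waveform = c("ctms_pseudorect", "rectangular"),
                         shared_sdtc = FALSE, reference = "placebo",
                         df_method = c("residual", "satterthwaite"),
                         out_dir = NULL) {
  waveform <- match.arg(waveform)
  df_method <- match.arg(df_method)
  truth <- NULL
  if (is.null(trials)) {
    study <- simulate_study(config)
    trials <- study$trials
    truth <- study$truth
  } else if (is.character(trials)) {
    trials <- read_trial_csv(trials)
  } else {
    check_trial_schema(trials)
  }
  widths <- sort(unique(trials$pulse_width_us))
  if (is.null(wfs)) wfs <- waveform_family(widths, shape = waveform)

  io_fits <- fit_io_study(trials)
  rmt_table <- io_fits[, c("subject_id", "condition", "pulse_width_us", "rmt_io")]
  sd_fits <- fit_sd_study(rmt_table, wfs, shared = FALSE)
  sd_shared <- if (shared_sdtc) fit_sd_study(rmt_table, wfs, shared = TRUE) else NULL

  stats_bundle <- list(
    rmt_model = fit_lme_rmt(rmt_table, reference = reference,
                            df_method = df_method),
    sdtc_model = fit_lme_scalar(sd_fits, "sdtc_us", reference = reference,
                                df_method = df_method),
    rheobase_model = fit_lme_scalar(sd_fits, "rheobase_pct_mso",
                                    reference = reference,
                                    df_method = df_method),
    differences = placebo_differences(rmt_table, reference = reference,
                                      df_method = df_method),
    relationship = sdtc_rheobase_relationship(sd_fits, reference = reference,
                                              df_method = df_method)
  )
  out <- structure(list(
    io_fits = io_fits, rmt_table = rmt_table, sd_fits = sd_fits,
    sd_fits_shared = sd_shared, stats = stats_bundle,
    truth = truth, config = config
  ), class = "sd_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

effects_list <- function(effects) {
  lapply(seq_len(nrow(effects)), function(i) as.list(effects[i, ]))
}

#' Write pipeline artifacts
#'
#' Emits the per-stage outputs (per-curve fits, tidy threshold table,
#' strength-duration fits, machine-readable statistics bundle and a
#' human-readable text report) into a directory.
#'
#' @param pipeline An `sd_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "sd_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_io_fits_json(pipeline$io_fits, file.path(dir, "io_fits.json"))
  write_rmt_csv(pipeline$io_fits, file.path(dir, "rmt_io.csv"))
  write_sd_fits(pipeline$sd_fits, file.path(dir, "sd_fits.csv"))
  if (!is.null(pipeline$sd_fits_shared)) {
    write_sd_fits(pipeline$sd_fits_shared, file.path(dir, "sd_fits_shared.csv"))
  }
  st <- pipeline$stats
  bundle <- list(
    rmt_model = list(effects = effects_list(st$rmt_model$effects),
                     anova = effects_list(st$rmt_model$anova)),
    sdtc_model = list(effects = effects_list(st$sdtc_model$effects),
                      anova = effects_list(st$sdtc_model$anova)),
    rheobase_model = list(effects = effects_list(st$rheobase_model$effects),
                          anova = effects_list(st$rheobase_model$anova)),
    differences = list(summary = effects_list(st$differences$summary),
                       anova = effects_list(st$differences$anova)),
    relationship = list(slopes = effects_list(st$relationship$slopes),
                        effects = effects_list(st$relationship$effects))
  )
  jsonlite::write_json(bundle, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(pipeline_report(pipeline), file.path(dir, "report.txt"))
  invisible(dir)
}

fmt_effect_rows <- function(effects) {
  vapply(seq_len(nrow(effects)), function(i) {
    e <- effects[i, ]
    sprintf("  %-28s estimate = %8.3f, SE = %6.3f, t[%d] = %6.2f, p = %.3g, d = %5.2f",
            e$term, e$estimate, e$se, as.integer(e$df), e$t, e$p, e$cohen_d)
  }, character(1))
}

fmt_anova_rows <- function(anova) {
  vapply(seq_len(nrow(anova)), function(i) {
    a <- anova[i, ]
    sprintf("  %-28s F[%d,%d] = %7.2f, p = %.3g",
            a$effect, a$df_num, a$df_den, a$F, a$p)
  }, character(1))
}

#' Human-readable pipeline report
#'
#' Formats every quantity class of the analysis — per-width thresholds,
#' time-constant and rheobase summaries, contrasts with SE/t/df/p/d, ANOVA
#' rows and the time-constant-vs-rheobase slopes — as text lines.
#'
#' @param pipeline An `sd_pipeline`.
#' @return A character vector of report lines.
#' @export
pipeline_report <- function(pipeline) {
  st <- pipeline$stats
  rmt_means <- pipeline$rmt_table |>
    dplyr::group_by(.data$condition, .data$pulse_width_us) |>
    dplyr::summarise(mean = mean(.data$rmt_io),
                     sem = stats::sd(.data$rmt_io) / sqrt(dplyr::n()),
                     .groups = "drop")
  sd_means <- pipeline$sd_fits |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(sdtc = mean(.data$sdtc_us),
                     sdtc_sem = stats::sd(.data$sdtc_us) / sqrt(dplyr::n()),
                     rheobase = mean(.data$rheobase_pct_mso),
                     rheobase_sem = stats::sd(.data$rheobase_pct_mso) / sqrt(dplyr::n()),
                     .groups = "drop")
  c(
    "== Motor thresholds (RMT_I-O, %MSO) ==",
    vapply(seq_len(nrow(rmt_means)), function(i) {
      r <- rmt_means[i, ]
      sprintf("  %-15s %3g us: %6.2f +/- %.2f", r$condition, r$pulse_width_us,
              r$mean, r$sem)
    }, character(1)),
    "", "== Threshold mixed model: ANOVA on fixed effects ==",
    fmt_anova_rows(st$rmt_model$anova),
    "== Threshold mixed model: drug contrasts (%MSO) ==",
    fmt_effect_rows(st$rmt_model$effects),
    "", "== Strength-duration parameters (mean +/- SEM) ==",
    vapply(seq_len(nrow(sd_means)), function(i) {
      r <- sd_means[i, ]
      sprintf("  %-15s SDTC = %6.1f +/- %5.1f us, rheobase = %5.2f +/- %4.2f %%MSO",
              r$condition, r$sdtc, r$sdtc_sem, r$rheobase, r$rheobase_sem)
    }, character(1)),
    "== SDTC mixed model ==",
    fmt_anova_rows(st$sdtc_model$anova),
    fmt_effect_rows(st$sdtc_model$effects),
    "== Rheobase mixed model ==",
    fmt_anova_rows(st$rheobase_model$anova),
    fmt_effect_rows(st$rheobase_model$effects),
    "", "== Drug-minus-placebo threshold differences (%MSO) ==",
    vapply(seq_len(nrow(st$differences$summary)), function(i) {
      r <- st$differences$summary[i, ]
      sprintf("  %-15s %3g us: %+6.2f +/- %.2f", as.character(r$condition),
              r$pulse_width_us, r$mean_diff, r$sem)
    }, character(1)),
    fmt_anova_rows(st$differences$anova),
    "", "== SDTC vs rheobase ==",
    vapply(seq_len(nrow(st$relationship$slopes)), function(i) {
      r <- st$relationship$slopes[i, ]
      sprintf("  %-15s slope = %7.1f us/%%MSO (SE %5.1f), R^2 = %.3f, p = %.3g",
              as.character(r$condition), r$slope_us_per_pct, r$se, r$r_squared,
              r$p)
    }, character(1)),
    fmt_effect_rows(st$relationship$effects)
  )
}

#' @export
print.sd_pipeline <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
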