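#' Configuration for the synthetic crossover study
#'
#' Describes a simulated pulse-width-varied TMS study with the structure the
#' analysis assumes: a cohort of subjects with latent rheobase and
#' strength-duration time constant (SDTC), three crossover drug conditions,
#' three pulse widths, and an input-output protocol of 10 trials at each of
#' 11 intensities anchored to a preliminary motor threshold.
#'
#' Trial-to-trial MEP variability is Gaussian on the log10 amplitude
#' (lognormal amplitudes), consistent with the log-domain analysis; recorded
#' amplitudes are floored by an independent lognormal background-EMG draw,
#' which is what makes the 10th/90th-percentile asymptote rule meaningful.
#'
#' Default effect patterns: carbamazepine scales all thresholds multiplicatively
#' (`threshold_scale` with unchanged SDTC), producing drug-minus-placebo
#' differences that grow toward shorter pulse widths where absolute thresholds
#' are higher; lacosamide combines a rheobase increase with an SDTC reduction
#' sized to produce a near-flat absolute threshold shift across pulse widths.
#' The lacosamide defaults are proportional (`threshold_scale`, `sdtc_scale`)
#' rather than additive: under the first-order membrane model the width
#' profile of a proportional effect is almost independent of a subject's
#' latent parameters, whereas additive shifts calibrated at the population
#' mean reverse sign within +/- 1 SD of the latent SDTC, so only the
#' proportional form yields a coherent cohort-level pattern.
#'
#' @param n_subjects Number of subjects (default 13).
#' @param conditions Condition labels; the first is the reference (placebo).
#' @param pulse_widths_us Pulse widths in microseconds.
#' @param mean_rheobase_pct_mso,sd_rheobase Population mean/SD of the latent
#'   rheobase, %MSO. The default (3.6 +/- 0.6) places the implied true
#'   thresholds (about 68/35/18 %MSO at 30/60/120 us for the mean SDTC)
#'   inside the per-width device ceilings.
#' @param mean_sdtc_us,sd_sdtc Population mean/SD of the latent SDTC, us.
#' @param rheobase_sdtc_correlation Latent correlation between rheobase and
#'   SDTC, in (-1, 1); default 0.
#' @param drug_effects Named list per condition with elements
#'   `rheobase_additive` (%MSO), `sdtc_additive` (us), `threshold_scale`
#'   (multiplicative on the rheobase, hence on every width's threshold) and
#'   optionally `sdtc_scale` (multiplicative on the SDTC, default 1); the
#'   reference condition must be the identity.
#' @param io_spread_s,io_spread_sd Mean/SD of the subject-level sigmoid
#'   spread, %MSO.
#' @param trial_noise_sd_log10 SD of the trial-level Gaussian noise on log10
#'   MEP amplitude.
#' @param noise_floor_median_mv,noise_floor_gsd Median and geometric SD of
#'   the lognormal background-EMG peak-to-peak amplitude, mV.
#' @param upper_plateau_median_mv,upper_plateau_gsd Median and geometric SD of
#'   the subject-level MEP plateau, mV.
#' @param n_trials_per_intensity Trials per intensity level (default 10).
#' @param nominal_levels Intensity levels as % of the preliminary RMT.
#' @param prelim_jitter_pct_mso Half-width of the uniform jitter of the
#'   preliminary RMT around the true threshold, %MSO.
#' @param intensity_resolution Device intensity resolution, %MSO.
#' @param seed Master seed; all per-session streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 13,
                       conditions = c("placebo", "carbamazepine", "lacosamide"),
                       pulse_widths_us = c(30, 60, 120),
                       mean_rheobase_pct_mso = 3.6, sd_rheobase = 0.6,
                       mean_sdtc_us = 550, sd_sdtc = 120,
                       rheobase_sdtc_correlation = 0,
                       drug_effects = list(
                         placebo = list(rheobase_additive = 0,
                                        sdtc_additive = 0,
                                        threshold_scale = 1,
                                        sdtc_scale = 1),
                         carbamazepine = list(rheobase_additive = 0,
                                              sdtc_additive = 0,
                                              threshold_scale = 1.15,
                                              sdtc_scale = 1),
                         lacosamide = list(rheobase_additive = 0,
                                           sdtc_additive = 0,
                                           threshold_scale = 1.57,
                                           sdtc_scale = 0.65)
                       ),
                       io_spread_s = 5, io_spread_sd = 1,
                       trial_noise_sd_log10 = 0.25,
                       noise_floor_median_mv = 0.01, noise_floor_gsd = 1.3,
                       upper_plateau_median_mv = 2, upper_plateau_gsd = 1.3,
                       n_trials_per_intensity = 10,
                       nominal_levels = c(80, 90, 100, 108, 116, 124, 132,
                                          140, 148, 156, 164),
                       prelim_jitter_pct_mso = 2,
                       intensity_resolution = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  scales <- c(mean_rheobase_pct_mso, sd_rheobase, mean_sdtc_us, sd_sdtc,
              io_spread_s, trial_noise_sd_log10, noise_floor_median_mv,
              noise_floor_gsd, upper_plateau_median_mv, upper_plateau_gsd)
  if (any(!is.finite(scales)) || any(scales[c(1, 3, 5, 7, 8, 9, 10)] <= 0)) {
    stop("simulation scales must be positive", call. = FALSE)
  }
  if (abs(rheobase_sdtc_correlation) >= 1) {
    stop("|rheobase_sdtc_correlation| must be < 1", call. = FALSE)
  }
  if (is.unsorted(nominal_levels, strictly = TRUE)) {
    stop("'nominal_levels' must be sorted ascending", call. = FALSE)
  }
  missing_fx <- setdiff(conditions, names(drug_effects))
  if (length(missing_fx)) {
    stop("no drug effects configured for condition(s): ",
         paste(missing_fx, collapse = ", "), call. = FALSE)
  }
  cfg$drug_effects <- lapply(drug_effects, function(fx) {
    if (is.null(fx$sdtc_scale)) fx$sdtc_scale <- 1
    fx
  })
  ref <- cfg$drug_effects[[conditions[1]]]
  if (ref$rheobase_additive != 0 || ref$sdtc_additive != 0 ||
      ref$threshold_scale != 1 || ref$sdtc_scale != 1) {
    stop("the reference condition ('", conditions[1],
         "') must have identity effects", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed for one subject x condition stream, kept within the
# 32-bit integer range
stream_seed <- function(seed, subject, condition_index) {
  as.integer((as.numeric(seed) * 7919 + subject * 104729 +
                condition_index * 1299709) %% 2147483629)
}

#' Draw the latent cohort
#'
#' Draws per-subject latent parameters: (rheobase, SDTC) from a bivariate
#' normal with the configured means, SDs and correlation, plus the sigmoid
#' spread and the MEP plateau level. Reproducible from the config seed.
#'
#' Draws are rejected and redrawn when non-physiological (rheobase below
#' 0.5 %MSO, SDTC outside `[100, 3000]` us) or when the implied true
#' threshold under any configured condition exceeds 92% of the pulse width's
#' device ceiling — a subject whose threshold cannot be bracketed by the
#' stimulator is not testable by the protocol, mirroring the implicit
#' enrolment constraint of any real pulse-width-varied TMS study. If fewer
#' than 1 in 100 candidate draws are feasible the design itself is declared
#' infeasible and an error is raised.
#'
#' @param config A [sim_config()].
#' @param wfs Optional waveform family used for the feasibility screen.
#' @return A tibble of subject latents (`subject_id`, `rheobase_pct_mso`,
#'   `sdtc_us`, `io_spread_s`, `plateau_mv`).
#' @export
draw_population <- function(config, wfs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(wfs)) wfs <- waveform_family(config$pulse_widths_us)
  set.seed(stream_seed(config$seed, 0L, 0L))
  n <- config$n_subjects
  rho <- config$rheobase_sdtc_correlation
  ceilings <- mso_ceiling(config$pulse_widths_us)
  feasible <- function(rb, sd) {
    for (cond in config$conditions) {
      fx <- config$drug_effects[[cond]]
      rb_c <- (rb + fx$rheobase_additive) * fx$threshold_scale
      sd_c <- sd * fx$sdtc_scale + fx$sdtc_additive
      if (rb_c <= 0 || sd_c <= 0) return(FALSE)
      r <- vapply(as.character(config$pulse_widths_us),
                  function(w) depolarization_factor(sd_c, wfs[[w]]), numeric(1))
      if (any(rb_c / r > 0.92 * ceilings)) return(FALSE)
    }
    TRUE
  }
  attempts <- 0L
  draw_one <- function() {
    repeat {
      attempts <<- attempts + 1L
      if (attempts > 100L * n + 1000L) {
        stop("simulation design infeasible: implied thresholds exceed the ",
             "device ceilings for almost all of the latent population",
             call. = FALSE)
      }
      z <- stats::rnorm(2)
      rb <- config$mean_rheobase_pct_mso + config$sd_rheobase * z[1]
      sd <- config$mean_sdtc_us +
        config$sd_sdtc * (rho * z[1] + sqrt(1 - rho^2) * z[2])
      if (rb > 0.5 && sd >= 100 && sd <= 3000 && feasible(rb, sd)) {
        return(c(rb, sd))
      }
    }
  }
  pars <- t(vapply(seq_len(n), function(i) draw_one(), numeric(2)))
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    rheobase_pct_mso = pars[, 1],
    sdtc_us = pars[, 2],
    io_spread_s = pmax(2, stats::rnorm(n, config$io_spread_s,
                                       config$io_spread_sd)),
    plateau_mv = stats::rlnorm(n, log(config$upper_plateau_median_mv),
                               log(config$upper_plateau_gsd))
  )
}

#' Apply a condition's drug effect to subject latents
#'
#' Condition-specific parameters follow
#' `rheobase' = (rheobase + rheobase_additive) * threshold_scale` and
#' `sdtc' = sdtc * sdtc_scale + sdtc_additive`; because modeled thresholds are
#' `rheobase / r(sdtc, tp)`, the multiplicative term scales every pulse
#' width's threshold by the same factor, while the additive SDTC/rheobase
#' combination reshapes the strength-duration curve. The reference condition
#' is the identity.
#'
#' @param latents One row (or tibble) of [draw_population()] output.
#' @param condition Condition label present in the config.
#' @param config A [sim_config()].
#' @return `latents` with `rheobase_pct_mso` and `sdtc_us` transformed.
#' @export
condition_latents <- function(latents, condition, config) {
  fx <- config$drug_effects[[condition]]
  if (is.null(fx)) stop("unknown condition: ", condition, call. = FALSE)
  if (is.null(fx$sdtc_scale)) fx$sdtc_scale <- 1
  out <- latents
  out$rheobase_pct_mso <-
    (latents$rheobase_pct_mso + fx$rheobase_additive) * fx$threshold_scale
  out$sdtc_us <- latents$sdtc_us * fx$sdtc_scale + fx$sdtc_additive
  if (any(out$rheobase_pct_mso <= 0) || any(out$sdtc_us <= 0)) {
    stop("drug effect for '", condition,
         "' produces non-positive parameters", call. = FALSE)
  }
  out
}

#' Simulate the trials of one session
#'
#' One subject in one condition: for each pulse width the true threshold
#' follows the strength-duration model; the preliminary RMT is the true
#' threshold plus a seeded uniform jitter; the 11 stimulus intensities are
#' the nominal levels times the preliminary RMT, rounded to the device
#' resolution and capped at the pulse width's output ceiling. The generating
#' sigmoid uses the subject's plateau and the noise-floor median as
#' asymptotes, with the midpoint placed so the curve crosses log10(0.05 mV)
#' exactly at the true threshold. Each trial records
#' `max(lognormal sigmoid draw, background draw)` as the MEP amplitude and an
#' independent background draw as the pre-stimulus noise amplitude.
#'
#' @param latents One row of condition-adjusted latents
#'   (see [condition_latents()]).
#' @param condition Condition label.
#' @param config A [sim_config()].
#' @param wfs Named list of waveforms from [waveform_family()].
#' @param seed Stream seed for this session.
#' @return A tibble of trials in the standard schema, with attributes
#'   `truth` (per-width true thresholds) and `truncated` (widths whose top
#'   levels hit the ceiling).
#' @export
simulate_session <- function(latents, condition, config, wfs, seed) {
  set.seed(seed)
  stopifnot(nrow(latents) == 1L)
  y_low_true <- log10(config$noise_floor_median_mv)
  y_high_true <- log10(latents$plateau_mv)
  y_star <- log10(0.05)
  sdlog_floor <- log(config$noise_floor_gsd)
  res <- config$intensity_resolution
  trials <- vector("list", length(config$pulse_widths_us))
  truth <- numeric(length(config$pulse_widths_us))
  truncated <- logical(length(config$pulse_widths_us))
  for (k in seq_along(config$pulse_widths_us)) {
    tp <- config$pulse_widths_us[k]
    r <- depolarization_factor(latents$sdtc_us, wfs[[as.character(tp)]])
    vth <- latents$rheobase_pct_mso / r
    truth[k] <- vth
    ceiling_tp <- mso_ceiling(tp)
    prelim <- round(vth + stats::runif(1, -config$prelim_jitter_pct_mso,
                                       config$prelim_jitter_pct_mso))
    raw_int <- config$nominal_levels / 100 * prelim
    intensities <- pmin(round(raw_int / res) * res, ceiling_tp)
    truncated[k] <- any(raw_int > ceiling_tp)
    xm <- vth + latents$io_spread_s *
      log((y_high_true - y_low_true) / (y_star - y_low_true) - 1)
    n_tr <- config$n_trials_per_intensity
    x <- rep(intensities, each = n_tr)
    mu <- io_sigmoid(x, y_low_true, y_high_true, xm, latents$io_spread_s)
    sig_amp <- 10^(mu + stats::rnorm(length(x), 0, config$trial_noise_sd_log10))
    floor_amp <- stats::rlnorm(length(x), log(config$noise_floor_median_mv),
                               sdlog_floor)
    noise_amp <- stats::rlnorm(length(x), log(config$noise_floor_median_mv),
                               sdlog_floor)
    trials[[k]] <- tibble::tibble(
      subject_id = latents$subject_id,
      condition = condition,
      pulse_width_us = tp,
      nominal_level_pct_rmt = rep(config$nominal_levels, each = n_tr),
      intensity_pct_mso = x,
      mep_pp_mv = pmax(sig_amp, floor_amp),
      noise_pp_mv = noise_amp
    )
  }
  out <- purrr::list_rbind(trials)
  attr(out, "truth") <- tibble::tibble(
    subject_id = latents$subject_id, condition = condition,
    pulse_width_us = config$pulse_widths_us,
    true_threshold_pct_mso = truth,
    truncated = truncated
  )
  out
}

#' Simulate a full crossover study
#'
#' All subjects x conditions of the configured design. Each session draws
#' from its own deterministic stream derived from the master seed, so any
#' subset is reproducible in isolation.
#'
#' @param config A [sim_config()].
#' @param wfs Optional named list of waveforms; defaults to the
#'   pseudorectangular family at the configured pulse widths.
#' @return A list of class `sim_study` with elements `trials` (trial tibble),
#'   `truth` (per subject x condition: true rheobase, SDTC, and per-width
#'   thresholds in long form) and `config`.
#' @export
simulate_study <- function(config = sim_config(), wfs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(wfs)) wfs <- waveform_family(config$pulse_widths_us)
  pop <- draw_population(config)
  sessions <- list()
  truths <- list()
  idx <- 1L
  for (i in seq_len(config$n_subjects)) {
    for (j in seq_along(config$conditions)) {
      cond <- config$conditions[j]
      lat <- condition_latents(pop[i, ], cond, config)
      ses <- simulate_session(lat, cond, config, wfs,
                              seed = stream_seed(config$seed, i, j))
      truths[[idx]] <- attr(ses, "truth") |>
        dplyr::mutate(rheobase_pct_mso = lat$rheobase_pct_mso,
                      sdtc_us = lat$sdtc_us)
      attr(ses, "truth") <- NULL
      sessions[[idx]] <- ses
      idx <- idx + 1L
    }
  }
  structure(list(
    trials = purrr::list_rbind(sessions),
    truth = purrr::list_rbind(truths),
    config = config
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d subjects x %d conditions, %d trials (seed %d)\n",
              x$config$n_subjects, length(x$config$conditions),
              nrow(x$trials), x$config$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the trial CSV, the ground-truth CSV, and the generating
#' configuration as YAML for full provenance.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(study$trials),
                   file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(study$truth),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  writeLines(yaml::as.yaml(unclass(study$config)),
             file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
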