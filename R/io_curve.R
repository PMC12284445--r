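#' Boltzmann sigmoid input-output curve
#'
#' The input-output relation between TMS intensity and log MEP amplitude:
#' `y = yl + (yh - yl) / (1 + exp((xm - x)/s))`, where `x` is stimulus
#' intensity (%MSO), `y` is log10 MEP amplitude (mV), `yl`/`yh` are the lower
#' and upper saturation levels, `xm` is the midpoint intensity and `s` the
#' spread (transition width) in %MSO.
#'
#' @param x Stimulus intensity, %MSO.
#' @param yl,yh Lower/upper asymptotes, log10(mV).
#' @param xm Midpoint intensity, %MSO.
#' @param s Spread, %MSO (> 0).
#' @return Predicted log10 amplitude(s).
#' @export
io_sigmoid <- function(x, yl, yh, xm, s) {
  yl + (yh - yl) / (1 + exp((xm - x) / s))
}

trial_columns <- c("subject_id", "condition", "pulse_width_us",
                   "intensity_pct_mso", "mep_pp_mv", "noise_pp_mv")

check_trial_schema <- function(trials, require_all = TRUE) {
  need <- if (require_all) trial_columns else
    c("intensity_pct_mso", "mep_pp_mv", "noise_pp_mv")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(trials)
}

#' Read a trial-level CSV
#'
#' Reads a UTF-8 CSV of TMS trials with the mandated columns `subject_id`,
#' `condition`, `pulse_width_us`, `intensity_pct_mso`, `mep_pp_mv`,
#' `noise_pp_mv` (an optional `nominal_level_pct_rmt` column is preserved).
#' Non-positive recorded amplitudes are invalid for the log-domain analysis;
#' they are clipped to 1e-4 mV with a warning, since real peak-to-peak EMG
#' noise is never exactly zero.
#'
#' @param path CSV file path.
#' @return A tibble of trials.
#' @export
read_trial_csv <- function(path) {
  trials <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_trial_schema(trials)
  for (col in c("mep_pp_mv", "noise_pp_mv")) {
    bad <- !is.finite(trials[[col]]) | trials[[col]] <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive value(s) in '", col,
              "' clipped to 1e-4 mV", call. = FALSE)
      trials[[col]][bad] <- 1e-4
    }
  }
  trials
}

#' Session-fixed sigmoid asymptotes from trial amplitudes
#'
#' The saturation levels of the input-output sigmoid are fixed across pulse
#' widths within a session (one subject in one condition): the lower asymptote
#' is the 10th percentile of the pre-stimulus (background EMG) peak-to-peak
#' amplitudes and the upper asymptote the 90th percentile of the MEP
#' peak-to-peak amplitudes, both pooled over all pulse widths and intensities
#' of the session, then log10-transformed. Because the log is monotone,
#' taking percentiles before or after the transform is equivalent.
#'
#' @param trials Trials of one session (>= 10 rows, positive amplitudes).
#' @param percentile_type Quantile estimation type passed to
#'   [stats::quantile()]; default 7 (linear interpolation between order
#'   statistics).
#' @return A list with `y_low` and `y_high` (log10 mV), class
#'   `session_asymptotes`.
#' @export
session_asymptotes <- function(trials, percentile_type = 7) {
  check_trial_schema(trials, require_all = FALSE)
  if (nrow(trials) < 10L) {
    stop("need at least 10 trials to estimate session asymptotes", call. = FALSE)
  }
  if (any(trials$mep_pp_mv <= 0) || any(trials$noise_pp_mv <= 0)) {
    stop("amplitudes must be positive", call. = FALSE)
  }
  y_low <- log10(stats::quantile(trials$noise_pp_mv, 0.10,
                                 type = percentile_type, names = FALSE))
  y_high <- log10(stats::quantile(trials$mep_pp_mv, 0.90,
                                  type = percentile_type, names = FALSE))
  crit <- log10(0.05)
  if (!(y_low < crit && crit < y_high)) {
    id <- if ("subject_id" %in% names(trials))
      paste0(" (subject ", trials$subject_id[1], ", ",
             if ("condition" %in% names(trials)) trials$condition[1] else "?", ")")
    else ""
    stop("session asymptotes do not bracket the 0.05 mV criterion", id,
         ": y_low = ", signif(y_low, 4), ", y_high = ", signif(y_high, 4),
         call. = FALSE)
  }
  structure(list(y_low = y_low, y_high = y_high), class = "session_asymptotes")
}

#' Median log response per stimulus intensity
#'
#' Log10-transforms the MEP amplitudes and takes the median over the trials
#' delivered at each distinct intensity, the summary to which the sigmoid is
#' fitted.
#'
#' @param trials Trials of one subject x condition x pulse width.
#' @return A tibble with columns `intensity_pct_mso`, `y` (median log10 mV)
#'   and `n_trials`, sorted by intensity.
#' @export
median_log_response <- function(trials) {
  check_trial_schema(trials, require_all = FALSE)
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  trials |>
    dplyr::group_by(intensity_pct_mso = .data$intensity_pct_mso) |>
    dplyr::summarise(y = stats::median(log10(.data$mep_pp_mv)),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$intensity_pct_mso)
}

#' Fit the input-output sigmoid with fixed asymptotes
#'
#' Least-squares fit of [io_sigmoid()] to median log responses, adjusting only
#' the midpoint `xm` and spread `s` while the session asymptotes stay fixed.
#' The optimization is bounded and deterministic: `xm` starts at the intensity
#' whose median response is nearest the mid-level `(yl+yh)/2`, the spread is
#' multi-started at 2, 5 and 10 %MSO within bounds `[0.5, 50]`, and the best
#' of the converged starts is returned (objective tolerance 1e-10).
#'
#' @param points A data frame from [median_log_response()] (columns
#'   `intensity_pct_mso`, `y`); at least 3 points.
#' @param asymptotes A [session_asymptotes()] object (or list with `y_low`,
#'   `y_high`).
#' @param s_bounds Lower/upper bounds on the spread, %MSO.
#' @param s_starts Spread starting values, %MSO.
#' @return An object of class `io_fit`: list with `y_low`, `y_high`, `xm`,
#'   `spread`, `sse`, `r_squared` (computed on the fitted median points),
#'   `n_points`, `s_at_bound` and `converged`.
#' @export
fit_io_curve <- function(points, asymptotes,
                         s_bounds = c(0.5, 50), s_starts = c(2, 5, 10)) {
  stopifnot(all(c("intensity_pct_mso", "y") %in% names(points)))
  x <- points$intensity_pct_mso
  y <- points$y
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct intensities to fit the sigmoid", call. = FALSE)
  }
  yl <- asymptotes$y_low
  yh <- asymptotes$y_high
  if (!(yl < yh)) stop("invalid asymptotes: y_low must be below y_high", call. = FALSE)

  obj <- function(par) {
    r <- y - io_sigmoid(x, yl, yh, par[1], par[2])
    sum(r * r)
  }
  xm0 <- x[which.min(abs(y - (yl + yh) / 2))]
  xr <- range(x)
  xm_bounds <- c(xr[1] - 2 * diff(xr), xr[2] + 2 * diff(xr))

  best <- NULL
  for (s0 in s_starts) {
    fit <- stats::nlminb(c(xm0, s0), obj,
                         lower = c(xm_bounds[1], s_bounds[1]),
                         upper = c(xm_bounds[2], s_bounds[2]),
                         control = list(abs.tol = 1e-10, rel.tol = 1e-12,
                                        iter.max = 500, eval.max = 1000))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  # polish to near machine precision (PORT stops on parameter tolerance)
  pol <- stats::optim(best$par, obj, method = "L-BFGS-B",
                      lower = c(xm_bounds[1], s_bounds[1]),
                      upper = c(xm_bounds[2], s_bounds[2]),
                      control = list(factr = 10, maxit = 200))
  if (pol$value <= best$objective) {
    best$par <- pol$par
    best$objective <- pol$value
  }
  if (is.null(best) || best$convergence %in% c(1L) && !is.finite(best$objective)) {
    stop("input-output curve fit failed to converge after multi-start", call. = FALSE)
  }
  sse <- best$objective
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  s_hat <- best$par[2]
  structure(list(
    y_low = yl, y_high = yh,
    xm = best$par[1], spread = s_hat,
    sse = sse, r_squared = r2, n_points = length(x),
    s_at_bound = (s_hat <= s_bounds[1] + 1e-8 || s_hat >= s_bounds[2] - 1e-8),
    converged = TRUE
  ), class = "io_fit")
}

#' @export
print.io_fit <- function(x, ...) {
  cat(sprintf("<io_fit> xm = %.3f %%MSO, s = %.3f %%MSO, R^2 = %.4f (%d points)%s\n",
              x$xm, x$spread, x$r_squared, x$n_points,
              if (x$s_at_bound) " [spread at bound]" else ""))
  invisible(x)
}

#' Invert a fitted input-output curve to the resting motor threshold
#'
#' The motor threshold is defined as the stimulus intensity at which the
#' fitted sigmoid crosses the MEP criterion (0.05 mV on the log10 scale):
#' `rmt = xm - s * ln((yh - yl)/(y* - yl) - 1)` with `y* = log10(criterion)`.
#' Requires the criterion to lie strictly between the asymptotes.
#'
#' @param fit An `io_fit` (or list with `y_low`, `y_high`, `xm`, `spread`).
#' @param criterion_mv MEP amplitude criterion in mV; default 0.05.
#' @return Threshold intensity in %MSO.
#' @export
invert_rmt <- function(fit, criterion_mv = 0.05) {
  y_star <- log10(criterion_mv)
  if (!(fit$y_low < y_star && y_star < fit$y_high)) {
    stop("criterion ", criterion_mv, " mV is outside the asymptote range (",
         signif(fit$y_low, 4), ", ", signif(fit$y_high, 4), ")", call. = FALSE)
  }
  fit$xm - fit$spread * log((fit$y_high - fit$y_low) / (y_star - fit$y_low) - 1)
}

#' Preliminary relative-frequency motor threshold
#'
#' The bedside threshold rule used to anchor the intensity grid of the
#' input-output protocol: the lowest whole-number intensity (in %MSO) at which
#' at least 5 of 10 stimuli evoke an MEP exceeding 0.05 mV, found by an
#' ascending 1-%MSO sweep.
#'
#' @param responder A function of one argument (intensity, %MSO) returning the
#'   trial outcomes at that intensity: either a logical vector
#'   (suprathreshold yes/no) or numeric MEP amplitudes in mV, of length
#'   `n_trials`.
#' @param start Sweep start intensity, %MSO.
#' @param ceiling Maximum deliverable intensity for this pulse width, %MSO.
#' @param threshold_mv MEP criterion in mV (default 0.05).
#' @param n_trials Trials per intensity (default 10).
#' @param n_required Suprathreshold trials required (default 5).
#' @return Threshold intensity, %MSO (integer-valued).
#' @export
preliminary_rmt <- function(responder, start, ceiling,
                            threshold_mv = 0.05, n_trials = 10, n_required = 5) {
  stopifnot(is.function(responder), start >= 1, ceiling >= start)
  for (x in seq(base::ceiling(start), floor(ceiling), by = 1)) {
    out <- responder(x)
    hits <- if (is.logical(out)) sum(out) else sum(out > threshold_mv)
    if (length(out) != n_trials) {
      stop("responder returned ", length(out), " outcomes; expected ", n_trials,
           call. = FALSE)
    }
    if (hits >= n_required) return(x)
  }
  stop("no intensity up to the ", ceiling,
       " %MSO ceiling met the relative-frequency criterion", call. = FALSE)
}

#' Fit input-output curves and thresholds for one session
#'
#' For one subject x condition: estimates the session-fixed asymptotes, then
#' per pulse width computes the median log responses, fits the sigmoid and
#' inverts it to the motor threshold.
#'
#' @param trials Trial table of one session (all pulse widths).
#' @param criterion_mv MEP criterion in mV for the threshold inversion.
#' @param percentile_type Passed to [session_asymptotes()].
#' @return A tibble with one row per pulse width: subject, condition,
#'   pulse_width_us, y_low, y_high, xm, spread, r_squared, n_points,
#'   s_at_bound, rmt_io.
#' @export
fit_io_session <- function(trials, criterion_mv = 0.05, percentile_type = 7) {
  check_trial_schema(trials)
  asym <- session_asymptotes(trials, percentile_type = percentile_type)
  trials |>
    dplyr::group_by(pulse_width_us = .data$pulse_width_us) |>
    dplyr::group_modify(function(d, key) {
      pts <- median_log_response(d)
      fit <- fit_io_curve(pts, asym)
      tibble::tibble(
        y_low = fit$y_low, y_high = fit$y_high,
        xm = fit$xm, spread = fit$spread,
        r_squared = fit$r_squared, n_points = fit$n_points,
        s_at_bound = fit$s_at_bound,
        rmt_io = invert_rmt(fit, criterion_mv)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(subject_id = trials$subject_id[1],
                  condition = trials$condition[1], .before = 1)
}

#' Fit input-output curves for a whole study
#'
#' Applies [fit_io_session()] to every subject x condition cell of a trial
#' table.
#'
#' @inheritParams fit_io_session
#' @return A tibble of per-curve fits (one row per subject x condition x
#'   pulse width).
#' @export
fit_io_study <- function(trials, criterion_mv = 0.05, percentile_type = 7) {
  check_trial_schema(trials)
  trials |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::group_split() |>
    purrr::map(fit_io_session, criterion_mv = criterion_mv,
               percentile_type = percentile_type) |>
    purrr::list_rbind()
}

#' Write the tidy threshold table
#'
#' @param io_fits Output of [fit_io_study()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_rmt_csv <- function(io_fits, path) {
  utils::write.csv(
    as.data.frame(io_fits[, c("subject_id", "condition", "pulse_width_us", "rmt_io")]),
    path, row.names = FALSE)
  invisible(path)
}

#' Write per-curve fits as JSON records
#'
#' @param io_fits Output of [fit_io_study()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_io_fits_json <- function(io_fits, path) {
  jsonlite::write_json(io_fits, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
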