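#' Normalized least-squares objective of the strength-duration fit
#'
#' Sum of squared relative deviations between the modeled and observed motor
#' thresholds across pulse widths:
#' `sum_p (Vth'(tp)/Vth(tp) - 1)^2`, with the modeled threshold
#' `Vth'(tp) = rheobase / r(tau_m, pulse)` from [model_threshold()]. The
#' relative (threshold-normalized) form weights each pulse width equally
#' despite the large absolute threshold differences, and makes the objective
#' scale-equivariant: multiplying all observed thresholds by a constant
#' rescales the fitted rheobase by the same constant and leaves the fitted
#' time constant unchanged.
#'
#' @param rheobase Candidate rheobase, %MSO (> 0).
#' @param sdtc_us Candidate strength-duration time constant, microseconds.
#' @param thresholds Named numeric vector of observed thresholds (%MSO), names
#'   = pulse widths in microseconds.
#' @param wfs Named list of waveforms (from [waveform_family()]) covering all
#'   pulse widths in `thresholds`.
#' @return The objective value (dimensionless, >= 0).
#' @export
sd_objective <- function(rheobase, sdtc_us, thresholds, wfs) {
  stopifnot(rheobase > 0, sdtc_us > 0)
  r <- sd_factors(sdtc_us, names(thresholds), wfs)
  sum((rheobase / (r * thresholds) - 1)^2)
}

# depolarization factors for one tau across the named pulse widths
sd_factors <- function(sdtc_us, width_names, wfs) {
  missing <- setdiff(width_names, names(wfs))
  if (length(missing)) {
    stop("no waveform configured for pulse width(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vapply(width_names, function(w) depolarization_factor(sdtc_us, wfs[[w]]),
         numeric(1))
}

#' Profiled rheobase for a fixed time constant
#'
#' The objective of [sd_objective()] is quadratic in the rheobase once the
#' time constant is fixed: with `a_p = 1/(r_p * Vth_p)` its unique minimizer
#' is `sum(a_p) / sum(a_p^2)`. This inner closed form reduces the
#' two-parameter fit to a one-dimensional search over the time constant.
#'
#' @inheritParams sd_objective
#' @return The profiled rheobase, %MSO.
#' @export
profile_rheobase <- function(sdtc_us, thresholds, wfs) {
  stopifnot(sdtc_us > 0)
  r <- sd_factors(sdtc_us, names(thresholds), wfs)
  a <- 1 / (r * thresholds)
  s2 <- sum(a * a)
  if (!is.finite(s2) || s2 <= 0) {
    stop("degenerate threshold set: profiled rheobase undefined", call. = FALSE)
  }
  sum(a) / s2
}

# profiled objective over a vector of tau values, exploiting the vectorized
# exact propagation over tau (columns = pulse widths)
profiled_objective <- function(tau, thresholds, wfs) {
  widths <- names(thresholds)
  r <- vapply(widths, function(w) depolarization_factor(tau, wfs[[w]]),
              numeric(length(tau)))
  r <- matrix(r, nrow = length(tau))
  a <- sweep(1 / r, 2, thresholds, "/")     # a_p = 1/(r_p V_p), rows = tau
  vinf <- rowSums(a) / rowSums(a * a)
  obj <- rowSums((a * vinf - 1)^2)
  list(objective = obj, rheobase = vinf)
}

new_sd_fit <- function(subject_id, condition, rheobase, sdtc, objective,
                       mode, boundary, n_widths) {
  structure(list(
    subject_id = subject_id, condition = condition,
    rheobase_pct_mso = rheobase, sdtc_us = sdtc,
    objective = objective, mode = mode, boundary = boundary,
    n_widths = n_widths, df_residual = n_widths - 2L
  ), class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf("<sd_fit:%s> rheobase = %.3f %%MSO, SDTC = %.1f us, objective = %.3g%s\n",
              x$mode,
              if (length(x$rheobase_pct_mso) == 1L) x$rheobase_pct_mso else NA,
              x$sdtc_us, x$objective,
              if (x$boundary) " [at search bound]" else ""))
  invisible(x)
}

#' Fit rheobase and strength-duration time constant for one threshold set
#'
#' Minimizes the normalized least-squares objective over (rheobase, SDTC) for
#' one subject x condition, given observed thresholds at two or more pulse
#' widths. The search profiles the rheobase in closed form at each node of a
#' dense log-spaced time-constant grid, then refines the best node by bounded
#' golden-section search. This is deterministic and globally robust for the
#' cheap one-dimensional profiled objective; a fit landing on a search bound
#' is flagged rather than silently accepted.
#'
#' @param thresholds Named numeric vector (names = pulse widths, us) of
#'   observed motor thresholds, %MSO; at least 2 distinct widths.
#' @param wfs Named list of waveforms from [waveform_family()].
#' @param sdtc_bounds Search bounds on the time constant, microseconds.
#'   Default `[50, 2000]`, bracketing reported cortical and peripheral values.
#' @param n_grid Number of log-spaced grid nodes (default 400).
#' @param subject_id,condition Optional labels carried into the result.
#' @return An object of class `sd_fit` with elements `rheobase_pct_mso`,
#'   `sdtc_us`, `objective`, `mode = "individual"`, `boundary` flag,
#'   `n_widths` and the residual degrees of freedom.
#' @export
fit_sd_individual <- function(thresholds, wfs,
                              sdtc_bounds = c(50, 2000), n_grid = 400,
                              subject_id = NA_character_,
                              condition = NA_character_) {
  thresholds <- validate_threshold_set(thresholds)
  grid <- exp(seq(log(sdtc_bounds[1]), log(sdtc_bounds[2]), length.out = n_grid))
  prof <- profiled_objective(grid, thresholds, wfs)
  i <- which.min(prof$objective)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(
    function(lt) profiled_objective(exp(lt), thresholds, wfs)$objective,
    lower = log(lo), upper = log(hi), tol = 1e-10)
  tau_hat <- exp(opt$minimum)
  obj_hat <- opt$objective
  # guard: the refined optimum must not be worse than the best grid node
  if (obj_hat > prof$objective[i]) {
    tau_hat <- grid[i]
    obj_hat <- prof$objective[i]
  }
  boundary <- i == 1L || i == n_grid ||
    tau_hat <= sdtc_bounds[1] * (1 + 1e-6) || tau_hat >= sdtc_bounds[2] * (1 - 1e-6)
  new_sd_fit(subject_id, condition,
             rheobase = profile_rheobase(tau_hat, thresholds, wfs),
             sdtc = tau_hat, objective = obj_hat,
             mode = "individual", boundary = boundary,
             n_widths = length(thresholds))
}

validate_threshold_set <- function(thresholds) {
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("'thresholds' must be named by pulse width (us)", call. = FALSE)
  }
  if (length(unique(names(thresholds))) < 2L) {
    stop("need thresholds at >= 2 distinct pulse widths", call. = FALSE)
  }
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("thresholds must be positive and finite", call. = FALSE)
  }
  thresholds[order(as.numeric(names(thresholds)))]
}

#' Fit a shared time constant with individual rheobases
#'
#' Sensitivity-analysis variant of the strength-duration fit: one common
#' time constant per condition across subjects, with subject-specific
#' rheobases. The total objective is the sum of each subject's normalized
#' least-squares objective; for fixed time constant each subject's rheobase
#' has the usual closed form, so the search remains one-dimensional.
#'
#' @param tsets Named list of threshold sets (one per subject), each as in
#'   [fit_sd_individual()].
#' @inheritParams fit_sd_individual
#' @return An object of class `sd_fit` with `mode = "shared"`, scalar
#'   `sdtc_us` and a named vector `rheobase_pct_mso` (one per subject).
#' @export
fit_sd_shared <- function(tsets, wfs, sdtc_bounds = c(50, 2000), n_grid = 400,
                          condition = NA_character_) {
  stopifnot(is.list(tsets), length(tsets) >= 1L)
  tsets <- lapply(tsets, validate_threshold_set)
  grid <- exp(seq(log(sdtc_bounds[1]), log(sdtc_bounds[2]), length.out = n_grid))
  total <- function(tau) {
    Reduce(`+`, lapply(tsets, function(th)
      profiled_objective(tau, th, wfs)$objective))
  }
  obj_grid <- total(grid)
  i <- which.min(obj_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(lt) total(exp(lt)),
                         lower = log(lo), upper = log(hi), tol = 1e-10)
  tau_hat <- exp(opt$minimum)
  obj_hat <- opt$objective
  if (obj_hat > obj_grid[i]) {
    tau_hat <- grid[i]
    obj_hat <- obj_grid[i]
  }
  rheo <- vapply(tsets, function(th) profile_rheobase(tau_hat, th, wfs),
                 numeric(1))
  boundary <- i == 1L || i == length(grid) ||
    tau_hat <= sdtc_bounds[1] * (1 + 1e-6) || tau_hat >= sdtc_bounds[2] * (1 - 1e-6)
  new_sd_fit(subject_id = names(tsets), condition = condition,
             rheobase = rheo, sdtc = tau_hat, objective = obj_hat,
             mode = "shared", boundary = boundary,
             n_widths = sum(lengths(tsets)))
}

#' Strength-duration fits for a tidy threshold table
#'
#' Runs [fit_sd_individual()] for every subject x condition of a tidy
#' threshold table (columns `subject_id`, `condition`, `pulse_width_us`,
#' `rmt_io`), or [fit_sd_shared()] per condition when `shared = TRUE`.
#'
#' @param rmt_table Tidy threshold table.
#' @param wfs Named list of waveforms from [waveform_family()].
#' @param shared Logical; fit one time constant per condition?
#' @param ... Passed to the underlying fitter.
#' @return A tibble with one row per subject x condition (individual mode) or
#'   per subject within condition sharing the condition-level `sdtc_us`
#'   (shared mode): columns `subject_id`, `condition`, `rheobase_pct_mso`,
#'   `sdtc_us`, `objective`, `mode`, `boundary`.
#' @export
fit_sd_study <- function(rmt_table, wfs, shared = FALSE, ...) {
  need <- c("subject_id", "condition", "pulse_width_us", "rmt_io")
  missing <- setdiff(need, names(rmt_table))
  if (length(missing)) {
    stop("threshold table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (shared) {
    rmt_table |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_split() |>
      purrr::map(function(d) {
        tsets <- split(d, d$subject_id) |>
          lapply(function(s) stats::setNames(s$rmt_io, s$pulse_width_us))
        fit <- fit_sd_shared(tsets, wfs, condition = d$condition[1], ...)
        tibble::tibble(
          subject_id = names(fit$rheobase_pct_mso),
          condition = d$condition[1],
          rheobase_pct_mso = unname(fit$rheobase_pct_mso),
          sdtc_us = fit$sdtc_us, objective = fit$objective,
          mode = "shared", boundary = fit$boundary
        )
      }) |>
      purrr::list_rbind()
  } else {
    rmt_table |>
      dplyr::group_by(.data$subject_id, .data$condition) |>
      dplyr::group_split() |>
      purrr::map(function(d) {
        fit <- fit_sd_individual(
          stats::setNames(d$rmt_io, d$pulse_width_us), wfs,
          subject_id = as.character(d$subject_id[1]),
          condition = d$condition[1], ...)
        tibble::tibble(
          subject_id = fit$subject_id, condition = fit$condition,
          rheobase_pct_mso = fit$rheobase_pct_mso, sdtc_us = fit$sdtc_us,
          objective = fit$objective, mode = "individual",
          boundary = fit$boundary
        )
      }) |>
      purrr::list_rbind()
  }
}

#' Write strength-duration fits
#'
#' @param sd_fits Output of [fit_sd_study()].
#' @param path Output path; `.json` writes JSON records, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_sd_fits <- function(sd_fits, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(sd_fits, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(sd_fits), path, row.names = FALSE)
  }
  invisible(path)
}
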