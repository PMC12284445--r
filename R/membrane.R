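#' Membrane configuration
#'
#' Wraps the single parameter of the first-order (leaky integrator) membrane
#' model: the membrane time constant, which in the strength-duration context
#' is the strength-duration time constant (SDTC).
#'
#' @param tau_m_us Membrane time constant in microseconds; must lie in
#'   `[10, 5000]`, a range bracketing reported cortical and peripheral values.
#' @return An object of class `membrane_config`.
#' @export
membrane_config <- function(tau_m_us) {
  if (!is.numeric(tau_m_us) || any(!is.finite(tau_m_us)) ||
      any(tau_m_us < 10) || any(tau_m_us > 5000)) {
    stop("'tau_m_us' must be finite and within [10, 5000] us", call. = FALSE)
  }
  structure(list(tau_m_us = tau_m_us), class = "membrane_config")
}

as_tau_m <- function(membrane) {
  if (inherits(membrane, "membrane_config")) membrane$tau_m_us else membrane
}

# Exact propagation of tau * dy/dt + y = e(t), y(0) = 0, across linear
# segments e(t) = e0 + slope*(t - t0). Vectorized over tau. Returns the
# maximum of y over t >= 0 (after the last segment e = 0 and y decays, so no
# new maximum can occur there for a positive running maximum).
propagate_segments <- function(tau, segs) {
  y <- rep(0, length(tau))
  ymax <- rep(0, length(tau))
  for (i in seq_len(nrow(segs))) {
    d <- segs$t1[i] - segs$t0[i]
    e0 <- segs$e0[i]
    sl <- segs$slope[i]
    # y(t0 + u) = e0 + sl*u - sl*tau + C * exp(-u/tau), C = y - (e0 - sl*tau)
    C <- y - (e0 - sl * tau)
    decay <- exp(-d / tau)
    y_end <- e0 + sl * d - sl * tau + C * decay
    ymax <- pmax(ymax, y_end)
    if (sl != 0) {
      # interior stationary point: exp(-u/tau) = sl*tau/C, u in (0, d)
      ratio <- sl * tau / C
      ok <- is.finite(ratio) & ratio > 0 & ratio < 1
      if (any(ok)) {
        u <- -tau[ok] * log(ratio[ok])
        inside <- u > 0 & u < d
        if (any(inside)) {
          uu <- u[inside]
          tau_i <- tau[ok][inside]
          C_i <- C[ok][inside]
          y_crit <- e0 + sl * uu - sl * tau_i + C_i * exp(-uu / tau_i)
          idx <- which(ok)[inside]
          ymax[idx] <- pmax(ymax[idx], y_crit)
        }
      }
    }
    y <- y_end
  }
  ymax
}

# Segment description of a waveform: analytic segments when the generating
# spec is available, otherwise piecewise-linear interpolation of the samples.
segments_for <- function(wf) {
  if (inherits(wf, "waveform_spec")) return(waveform_segments(wf))
  spec <- attr(wf, "spec")
  if (!is.null(spec)) return(waveform_segments(spec))
  t <- wf$t_us
  e <- wf$e_norm
  n <- length(t)
  if (n < 2L) stop("sampled waveform must have at least 2 samples", call. = FALSE)
  data.frame(
    t0 = t[-n], t1 = t[-1], e0 = e[-n],
    slope = diff(e) / diff(t)
  )
}

#' Peak membrane depolarization produced by a unit-amplitude pulse
#'
#' Solves the first-order membrane equation
#' `tau_m * dy/dt + y = e(t)`, `y(0) = 0`, for the normalized electric-field
#' pulse `e(t)` and returns the peak response `max_t y(t)` — the
#' depolarization factor `r`. The normalization is such that an infinitely
#' long unit plateau gives `r -> 1`; for a rectangular pulse of width `tp`,
#' `r = 1 - exp(-tp/tau_m)` (the Lapicque form).
#'
#' The solution is propagated exactly (piecewise-exponential closed form) over
#' the pulse's piecewise-linear segments — the analytic segments of the
#' generating [waveform_spec()] when available, otherwise linear interpolation
#' of the samples — so the result does not depend on the sampling step.
#'
#' @param membrane A [membrane_config()] or a numeric membrane time constant
#'   in microseconds (vectorized).
#' @param wf A `sampled_waveform` from [generate_waveform()] or a
#'   `waveform_spec`.
#' @return Depolarization factor(s) in `(0, 1]`, same length as the time
#'   constant input.
#' @export
#' @examples
#' wf <- generate_waveform(waveform_spec("rectangular", tp_us = 60, dt_us = 1))
#' depolarization_factor(60, wf)   # 1 - exp(-1)
depolarization_factor <- function(membrane, wf) {
  tau <- as_tau_m(membrane)
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0)) {
    stop("membrane time constant must be positive", call. = FALSE)
  }
  propagate_segments(tau, segments_for(wf))
}

#' Depolarization factor by trapezoidal numerical integration
#'
#' Independent numerical evaluation of the same quantity as
#' [depolarization_factor()], by implicit-trapezoid time stepping of the
#' membrane equation on a dense grid. Retained as a cross-check for the exact
#' piecewise-exponential propagation.
#'
#' @inheritParams depolarization_factor
#' @param dt_us Integration step in microseconds; defaults to the waveform's
#'   sampling step (or 0.05 us for a bare spec).
#' @return Depolarization factor (scalar `membrane` only).
#' @export
depolarization_factor_numeric <- function(membrane, wf, dt_us = NULL) {
  tau <- as_tau_m(membrane)
  stopifnot(length(tau) == 1L)
  if (tau <= 0) stop("membrane time constant must be positive", call. = FALSE)
  spec <- if (inherits(wf, "waveform_spec")) wf else attr(wf, "spec")
  if (!is.null(spec)) {
    if (is.null(dt_us)) dt_us <- spec$dt_us
    t_end <- spec$tp_us + spec$second_phase_width_us
    t <- seq(0, t_end, by = dt_us)
    e <- waveform_value(spec, t)
  } else {
    t <- wf$t_us
    e <- wf$e_norm
  }
  n <- length(t)
  y <- numeric(n)
  for (i in seq_len(n - 1L)) {
    h <- t[i + 1L] - t[i]
    a <- h / (2 * tau)
    y[i + 1L] <- (y[i] * (1 - a) + a * (e[i] + e[i + 1L])) / (1 + a)
  }
  max(y)
}

#' Closed-form depolarization factor for a rectangular pulse
#'
#' The Lapicque limit `1 - exp(-tp/tau_m)`: peak response of a first-order
#' membrane to a rectangular pulse of width `tp`. Serves as the analytic
#' oracle for the rectangular special case of [depolarization_factor()].
#'
#' @param tau_m_us Membrane time constant in microseconds (> 0, vectorized).
#' @param tp_us Pulse width in microseconds (> 0, vectorized).
#' @return `1 - exp(-tp_us/tau_m_us)`.
#' @export
depolarization_factor_rect <- function(tau_m_us, tp_us) {
  if (any(!is.finite(tau_m_us) & !is.infinite(tau_m_us)) || any(tau_m_us <= 0)) {
    stop("'tau_m_us' must be positive", call. = FALSE)
  }
  if (any(tp_us <= 0)) stop("'tp_us' must be positive", call. = FALSE)
  1 - exp(-tp_us / tau_m_us)
}

#' Modeled motor threshold for a given rheobase and membrane
#'
#' The strength-duration model of the resting motor threshold: the stimulus
#' amplitude at which the peak membrane depolarization reaches the firing
#' criterion scales as `rheobase / r(tau_m, pulse)`, where `r` is the
#' depolarization factor. The threshold decreases with pulse width and tends
#' to the rheobase for infinitely long pulses.
#'
#' @param rheobase_pct_mso Rheobase in %MSO (> 0).
#' @param membrane A [membrane_config()] or numeric time constant (us).
#' @param wf Waveform, as in [depolarization_factor()].
#' @return Modeled threshold(s) in %MSO.
#' @export
model_threshold <- function(rheobase_pct_mso, membrane, wf) {
  if (any(rheobase_pct_mso <= 0)) stop("'rheobase_pct_mso' must be positive", call. = FALSE)
  r <- depolarization_factor(membrane, wf)
  if (any(r <= 0)) stop("depolarization factor is not positive", call. = FALSE)
  rheobase_pct_mso / r
}
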