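#' Specify a TMS electric-field pulse
#'
#' Parametric description of the induced electric-field waveform of a
#' controllable-pulse-parameter (cTMS) stimulator. Two shapes are supported:
#' an ideal monophasic rectangular pulse, and the pseudorectangular pulse of
#' cTMS devices — an initial near-rectangular phase (optionally with a small
#' linear amplitude droop) followed by a longer, lower-amplitude phase of
#' opposite sign whose relative amplitude is the M-ratio.
#'
#' The M-ratio here is defined as the amplitude of the smaller (second) phase
#' divided by that of the larger (initial) phase, so it lies in `[0, 1)`.
#' Device descriptions sometimes quote the inverse ratio; with the initial
#' phase normalized to unit amplitude the convention used here is unambiguous.
#'
#' @param shape `"rectangular"` or `"ctms_pseudorect"`.
#' @param tp_us Width of the initial phase in microseconds (the pulse width
#'   `tp` of the strength-duration model). Must be positive.
#' @param m_ratio Amplitude of the second phase relative to the initial phase,
#'   in `[0, 1)`. Forced to 0 for rectangular pulses. Default 0.2.
#' @param second_phase_width_us Duration of the second phase in microseconds.
#'   Default `5 * tp_us` for pseudorectangular pulses, 0 for rectangular.
#' @param droop_fraction Fractional linear amplitude decay over the initial
#'   phase, in `[0, 1)`. Forced to 0 for rectangular pulses.
#' @param dt_us Sampling step in microseconds used by [generate_waveform()].
#'   Must satisfy `dt_us <= tp_us / 30`.
#'
#' @return An object of class `waveform_spec`.
#' @seealso [generate_waveform()], [depolarization_factor()]
#' @export
#' @examples
#' waveform_spec("ctms_pseudorect", tp_us = 60)
waveform_spec <- function(shape = c("ctms_pseudorect", "rectangular"),
                          tp_us,
                          m_ratio = NULL,
                          second_phase_width_us = NULL,
                          droop_fraction = 0,
                          dt_us = 0.5) {
  shape <- match.arg(shape)
  if (!is.numeric(tp_us) || length(tp_us) != 1L || !is.finite(tp_us) || tp_us <= 0) {
    stop("invalid waveform spec: 'tp_us' must be a positive number", call. = FALSE)
  }
  if (shape == "rectangular") {
    if (!is.null(m_ratio) && !isTRUE(all.equal(m_ratio, 0))) {
      stop("invalid waveform spec: 'm_ratio' must be 0 for rectangular pulses",
           call. = FALSE)
    }
    m_ratio <- 0
    if (is.null(second_phase_width_us)) second_phase_width_us <- 0
    if (!isTRUE(all.equal(droop_fraction, 0))) {
      stop("invalid waveform spec: 'droop_fraction' must be 0 for rectangular pulses",
           call. = FALSE)
    }
    droop_fraction <- 0
  } else {
    if (is.null(m_ratio)) m_ratio <- 0.2
    if (is.null(second_phase_width_us)) second_phase_width_us <- 5 * tp_us
  }
  if (!is.numeric(m_ratio) || length(m_ratio) != 1L || m_ratio < 0 || m_ratio >= 1) {
    stop("invalid waveform spec: 'm_ratio' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(second_phase_width_us) || length(second_phase_width_us) != 1L ||
      second_phase_width_us < 0) {
    stop("invalid waveform spec: 'second_phase_width_us' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(droop_fraction) || length(droop_fraction) != 1L ||
      droop_fraction < 0 || droop_fraction >= 1) {
    stop("invalid waveform spec: 'droop_fraction' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(dt_us) || length(dt_us) != 1L || dt_us <= 0 || dt_us > tp_us / 30) {
    stop("invalid waveform spec: 'dt_us' must be positive and <= tp_us/30",
         call. = FALSE)
  }
  structure(
    list(shape = shape, tp_us = tp_us, m_ratio = m_ratio,
         second_phase_width_us = second_phase_width_us,
         droop_fraction = droop_fraction, dt_us = dt_us),
    class = "waveform_spec"
  )
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform_spec> %s, tp = %g us", x$shape, x$tp_us))
  if (x$shape != "rectangular") {
    cat(sprintf(", M-ratio = %g, second phase = %g us, droop = %g",
                x$m_ratio, x$second_phase_width_us, x$droop_fraction))
  }
  cat(sprintf(", dt = %g us\n", x$dt_us))
  invisible(x)
}

# Analytic description of the pulse as segments with linearly varying
# amplitude: rows (t0, t1, e0, slope), e(t) = e0 + slope * (t - t0) on [t0, t1).
waveform_segments <- function(spec) {
  tp <- spec$tp_us
  segs <- data.frame(
    t0 = 0, t1 = tp, e0 = 1, slope = -spec$droop_fraction / tp
  )
  if (spec$second_phase_width_us > 0 && spec$m_ratio > 0) {
    segs <- rbind(segs, data.frame(
      t0 = tp, t1 = tp + spec$second_phase_width_us, e0 = -spec$m_ratio, slope = 0
    ))
  }
  segs
}

waveform_value <- function(spec, t) {
  segs <- waveform_segments(spec)
  e <- numeric(length(t))
  for (i in seq_len(nrow(segs))) {
    in_seg <- t >= segs$t0[i] & t < segs$t1[i]
    e[in_seg] <- segs$e0[i] + segs$slope[i] * (t[in_seg] - segs$t0[i])
  }
  e
}

#' Sample an electric-field waveform on a regular time grid
#'
#' Evaluates the parametric pulse of a [waveform_spec()] on a regular grid of
#' step `dt_us`, with amplitudes normalized so the peak of the initial phase
#' is 1. The generating spec is attached as an attribute so that downstream
#' membrane computations can use the exact piecewise-linear description rather
#' than the samples.
#'
#' @param spec A `waveform_spec`.
#' @param tail_us Zero-padding appended after the pulse, in microseconds.
#' @return A `tbl_df` with columns `t_us` (strictly increasing) and `e_norm`,
#'   of class `sampled_waveform`, carrying the spec in `attr(, "spec")`.
#' @export
generate_waveform <- function(spec, tail_us = 2 * spec$tp_us) {
  stopifnot(inherits(spec, "waveform_spec"))
  t_end <- spec$tp_us + spec$second_phase_width_us + tail_us
  t <- seq(0, t_end, by = spec$dt_us)
  wf <- tibble::tibble(t_us = t, e_norm = waveform_value(spec, t))
  attr(wf, "spec") <- spec
  class(wf) <- c("sampled_waveform", class(wf))
  wf
}

#' Device output ceilings per pulse width
#'
#' Maximum stimulator output (in %MSO) available at each pulse width of the
#' cTMS device: energy constraints limit longer pulses to lower amplitudes
#' (100% at 30 us, 73% at 60 us, 50% at 120 us). Used by the synthetic-data
#' generator and by trial validation; the membrane model itself is unit-free.
#'
#' @return A named numeric vector mapping pulse width (us) to ceiling (%MSO).
#' @export
mso_ceilings <- function() {
  c(`30` = 100, `60` = 73, `120` = 50)
}

#' @rdname mso_ceilings
#' @param pulse_width_us Pulse width in microseconds.
#' @export
mso_ceiling <- function(pulse_width_us) {
  ceil <- mso_ceilings()
  key <- as.character(pulse_width_us)
  out <- unname(ceil[key])
  out[is.na(out)] <- 100
  out
}

#' Build waveforms for a family of pulse widths
#'
#' Convenience constructor for the set of waveforms used in a study: one
#' waveform per pulse width, sharing shape and relative second-phase settings.
#'
#' @param pulse_widths_us Pulse widths in microseconds.
#' @param shape Waveform shape, as in [waveform_spec()].
#' @param m_ratio,droop_fraction,dt_us Passed to [waveform_spec()].
#' @return A named list of `sampled_waveform` objects, names = pulse widths.
#' @export
waveform_family <- function(pulse_widths_us = c(30, 60, 120),
                            shape = "ctms_pseudorect",
                            m_ratio = if (shape == "rectangular") 0 else 0.2,
                            droop_fraction = 0,
                            dt_us = 0.5) {
  wfs <- lapply(pulse_widths_us, function(tp) {
    generate_waveform(waveform_spec(
      shape = shape, tp_us = tp,
      m_ratio = if (shape == "rectangular") NULL else m_ratio,
      droop_fraction = droop_fraction,
      dt_us = min(dt_us, tp / 30)
    ))
  })
  names(wfs) <- as.character(pulse_widths_us)
  wfs
}

#' Serialize a waveform spec to YAML
#' @param spec A `waveform_spec`.
#' @return A YAML string.
#' @export
waveform_spec_to_yaml <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  yaml::as.yaml(unclass(spec))
}

#' Restore a waveform spec from YAML
#' @param text A YAML string produced by [waveform_spec_to_yaml()].
#' @return A `waveform_spec`.
#' @export
waveform_spec_from_yaml <- function(text) {
  x <- yaml::yaml.load(text)
  waveform_spec(
    shape = x$shape, tp_us = x$tp_us,
    m_ratio = if (x$shape == "rectangular") NULL else x$m_ratio,
    second_phase_width_us = x$second_phase_width_us,
    droop_fraction = x$droop_fraction, dt_us = x$dt_us
  )
}

#' Write a sampled waveform as a two-column CSV
#' @param wf A `sampled_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  utils::write.csv(as.data.frame(wf[, c("t_us", "e_norm")]), path,
                   row.names = FALSE)
  invisible(path)
}
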