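# shared fixtures for the test suite

rect_family <- function(widths = c(30, 60, 120)) {
  waveform_family(widths, shape = "rectangular")
}

ctms_family <- function(widths = c(30, 60, 120)) {
  waveform_family(widths, shape = "ctms_pseudorect")
}

# noise-free thresholds implied by the Lapicque model for a rectangular family
lapicque_thresholds <- function(rheobase, tau, widths = c(30, 60, 120)) {
  stats::setNames(rheobase / (1 - exp(-widths / tau)), widths)
}

# trials lying exactly on a known sigmoid (no noise, constant background)
exact_session_trials <- function(subject = "S01", condition = "placebo",
                                 width = 60,
                                 yl = -2, yh = 0.3, xm = 55, s = 6,
                                 intensities = seq(40, 70, by = 3),
                                 n_trials = 10, noise_mv = 0.01) {
  x <- rep(intensities, each = n_trials)
  tibble::tibble(
    subject_id = subject, condition = condition, pulse_width_us = width,
    intensity_pct_mso = x,
    mep_pp_mv = 10^io_sigmoid(x, yl, yh, xm, s),
    noise_pp_mv = noise_mv
  )
}

# fast small study config for pipeline-level tests
small_config <- function(seed = 101L, n_subjects = 5) {
  sim_config(n_subjects = n_subjects, seed = seed)
}
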