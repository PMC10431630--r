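# Waveform templates evaluated at arbitrary phase in [0, 1) (wrapped), unit
# amplitude.  pqrst is a fixed sum of Gaussian bumps sketching an ECG beat
# (P wave, QRS complex, T wave); it is a shape fixture, not a physiological
# simulator.
template_value <- function(template, ph) {
  ph <- ph %% 1
  bump <- function(c0, w, a) a * exp(-((ph - c0) / w)^2)
  switch(template,
    sine = sin(2 * pi * ph),
    pqrst = bump(0.20, 0.035, 0.15) +   # P
            bump(0.38, 0.012, -0.12) +  # Q
            bump(0.42, 0.016, 1.00) +   # R
            bump(0.46, 0.012, -0.25) +  # S
            bump(0.65, 0.050, 0.35),    # T
    square_smooth = 0.8 * tanh(sin(2 * pi * ph) / 0.2),
    stop(sprintf("unknown template '%s'", template))
  )
}

# Anomalous waveforms over L samples: deterministic functions of
# (shape, L, amplitude), so anomalies sharing one shape id are exact twins
# before noise (the recurrent / "twin freak" configuration).
anomaly_waveform <- function(shape, L, amplitude = 1) {
  t <- (seq_len(L) - 1) / L
  switch(shape,
    widened = amplitude * exp(-((t - 0.5) / 0.25)^2),                  # broad single hump
    inverted = -amplitude * exp(-((t - 0.5) / 0.12)^2),                # deep negative spike
    premature = amplitude * (1.3 * exp(-((t - 0.2) / 0.06)^2) -        # early large beat
                             0.3 * exp(-((t - 0.55) / 0.10)^2)),
    stop(sprintf("unknown anomaly shape '%s'", shape))
  )
}

#' Generate a quasi-periodic series with planted subsequence anomalies
#'
#' Emulates a long biosignal (ECG- or ABP-like): a normal waveform template
#' is repeated for `n_cycles` cycles of the given period, each cycle drawn
#' with its own small random amplitude, timing, and width perturbation
#' (beat-to-beat variability, universal in physiological recordings);
#' anomalous waveforms are spliced over the requested intervals, and i.i.d.
#' Gaussian noise is added.  Anomaly waveforms are deterministic functions of
#' their `(shape, length, amplitude)`, so planting the same shape several
#' times yields recurrent anomalies with *identical* underlying waveforms —
#' the configuration that defeats nearest-neighbor discord definitions.
#' Generation is a pure function of the arguments and `seed`.
#'
#' @param n_cycles Number of normal-pattern cycles (`>= 2`).
#' @param period Normal pattern length in samples (`>= 20`).
#' @param template Normal waveform id: `"pqrst"` (ECG-like beat, default),
#'   `"sine"`, or `"square_smooth"`.
#' @param anomalies `NULL` or a data.frame with one row per anomaly:
#'   `cycle` (0-based cycle index giving start `cycle * period`),
#'   `length` (samples), `shape` (`"widened"`, `"inverted"`, `"premature"`),
#'   and optionally `amplitude` (default 1).
#' @param noise_sd Standard deviation of additive Gaussian noise (`>= 0`),
#'   on the template's unit amplitude scale.
#' @param amplitude_jitter Per-cycle multiplicative amplitude sd (default 5%).
#' @param shift_jitter Per-cycle timing shift sd, in phase units of the
#'   period (default 0.005, i.e. half a sample at period 100).
#' @param width_jitter Per-cycle waveform width sd, relative (default 2%).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A list of class `tsg_synth`: `values` (numeric series), `truth`
#'   (data.frame of half-open 0-based intervals `start`, `end`, `shape`) and
#'   the echoed generation parameters.
#' @examples
#' s <- synth_series(10, period = 100,
#'                   anomalies = data.frame(cycle = 5, length = 110, shape = "inverted"),
#'                   noise_sd = 0.02, seed = 1)
#' length(s$values); s$truth
#' @export
synth_series <- function(n_cycles, period = 100, template = "pqrst",
                         anomalies = NULL, noise_sd = 0,
                         amplitude_jitter = 0.05, shift_jitter = 0.005,
                         width_jitter = 0.02, seed = NULL) {
  if (period < 20) stop("period must be >= 20")
  if (n_cycles < 2) stop("need at least 2 cycles")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_cycles <- as.integer(n_cycles)
  period <- as.integer(period)
  n <- n_cycles * period

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  jitter_on <- amplitude_jitter > 0 || shift_jitter > 0 || width_jitter > 0
  amp <- if (jitter_on) stats::rnorm(n_cycles, 1, amplitude_jitter) else rep(1, n_cycles)
  shift <- if (jitter_on) stats::rnorm(n_cycles, 0, shift_jitter) else rep(0, n_cycles)
  width <- if (jitter_on) stats::rnorm(n_cycles, 0, width_jitter) else rep(0, n_cycles)

  ph0 <- (seq_len(period) - 1) / period
  x <- numeric(n)
  for (c0 in seq_len(n_cycles)) {
    # warp: stretch about mid-cycle by (1 + width), then shift in time
    ph <- (ph0 - 0.5) * (1 + width[c0]) + 0.5 - shift[c0]
    x[((c0 - 1L) * period + 1L):(c0 * period)] <-
      amp[c0] * template_value(template, ph)
  }

  truth <- data.frame(start = integer(0), end = integer(0), shape = character(0))
  if (!is.null(anomalies) && nrow(anomalies) > 0) {
    a <- as.data.frame(anomalies)
    if (is.null(a$amplitude)) a$amplitude <- 1
    a$start <- as.integer(a$cycle * period)
    a$end <- a$start + as.integer(a$length)
    a <- a[order(a$start), , drop = FALSE]
    if (any(a$start < 0) || any(a$end > n))
      stop("anomaly interval falls outside the series")
    if (nrow(a) > 1) {
      gap <- a$start[-1] - a$end[-nrow(a)]
      if (any(gap < period))
        stop("anomaly intervals must be separated by at least one full period")
    }
    for (i in seq_len(nrow(a))) {
      idx <- (a$start[i] + 1L):a$end[i]
      x[idx] <- anomaly_waveform(a$shape[i], as.integer(a$length[i]), a$amplitude[i])
    }
    truth <- data.frame(start = a$start, end = a$end, shape = a$shape)
  }

  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)

  structure(list(values = x, truth = truth, period = period,
                 n_cycles = n_cycles, template = template,
                 noise_sd = noise_sd, amplitude_jitter = amplitude_jitter,
                 shift_jitter = shift_jitter, width_jitter = width_jitter,
                 seed = seed),
            class = "tsg_synth")
}

#' @export
print.tsg_synth <- function(x, ...) {
  cat(sprintf("synthetic series: %d samples (%d x period %d, template %s), %d planted anomaly(ies), noise sd %.3g\n",
              length(x$values), x$n_cycles, x$period, x$template,
              nrow(x$truth), x$noise_sd))
  invisible(x)
}

#' Suggest the normal-pattern period from the autocorrelation function
#'
#' Advisory helper: returns the lag `>= 2` that maximizes the sample
#' autocorrelation, typically the length of the repeating normal pattern; the
#' embedding window is then commonly set to `period - 20`.  The estimate is
#' flagged unreliable when the peak autocorrelation is weak (no periodic
#' structure) and is `NA` for a flat series.
#'
#' @param x Numeric series with `length(x) > 2 * max_lag`.
#' @param max_lag Largest lag considered.
#' @param min_acf Peak-autocorrelation threshold below which the estimate is
#'   flagged unreliable.
#' @return A list: `period` (integer or `NA`), `peak_acf`, `reliable`.
#' @export
estimate_period_hint <- function(x, max_lag = 500, min_acf = 0.3) {
  x <- as.numeric(x)
  if (length(x) <= 2 * max_lag) stop("series too short: need n > 2 * max_lag")
  if (stats::sd(x) == 0)
    return(list(period = NA_integer_, peak_acf = NA_real_, reliable = FALSE))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]  # lags 1..max_lag
  # candidate periods are local ACF maxima at lag >= 2; the raw maximum would
  # always be a small lag for any smooth signal
  k <- 2:(length(ac) - 1L)
  is_peak <- ac[k] > ac[k - 1L] & ac[k] >= ac[k + 1L]
  cand <- k[is_peak]
  if (!length(cand))
    return(list(period = NA_integer_, peak_acf = NA_real_, reliable = FALSE))
  best <- cand[which.max(ac[cand])]
  peak <- ac[best]
  list(period = as.integer(best), peak_acf = peak, reliable = peak >= min_acf)
}
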