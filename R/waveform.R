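#' Flow waveform over one cardiac cycle
#'
#' Stores a volumetric flow-rate waveform Q(t) in ml/s sampled uniformly over
#' one cardiac cycle, together with its complex Fourier amplitudes. The
#' harmonic representation is
#' \deqn{Q(t) = Q_0 + \sum_{n\ge1} \mathrm{Re}\,[Q_n e^{i\omega_n t}],
#'   \quad \omega_n = 2\pi n/T,}
#' where \eqn{Q_0} is the cycle mean. All harmonics up to Nyquist are kept so
#' the representation round-trips to the samples exactly (to floating-point).
#'
#' @param samples flow rate (ml/s) at uniformly spaced times `(0:(n-1)) * T/n`.
#' @param period cardiac cycle length T in seconds.
#' @return an object of class `flow_waveform` with fields `samples`, `period`,
#'   `times`, `mean_flow` (Q0) and `harmonics` (complex amplitudes Q_n,
#'   n = 1..floor(n_samples/2)).
#' @examples
#' wf <- flow_waveform(5 + 3 * sin(2 * pi * (0:63)/64), period = 60/68)
#' wf$mean_flow
#' @export
flow_waveform <- function(samples, period) {
  assert_that(is.numeric(samples) && length(samples) >= 4L &&
                all(is.finite(samples)),
              "samples must be finite numeric with length >= 4")
  assert_that(is_scalar_number(period) && period > 0, "period must be > 0")
  n <- length(samples)
  fc <- stats::fft(samples)/n
  n_harm <- n %/% 2L
  harmonics <- complex(real = numeric(0))
  if (n_harm >= 1L) {
    harmonics <- 2 * fc[2:(n_harm + 1L)]
    if (n %% 2L == 0L) {
      # Nyquist term appears once in the spectrum, not twice
      harmonics[n_harm] <- fc[n_harm + 1L]
    }
  }
  structure(list(samples = as.numeric(samples),
                 period = period,
                 times = (seq_len(n) - 1) * period/n,
                 mean_flow = Re(fc[1]),
                 harmonics = harmonics),
            class = "flow_waveform")
}

#' Evaluate a waveform at arbitrary times
#'
#' Evaluates the harmonic representation of a [flow_waveform()] at times `t`
#' (periodically extended), optionally truncated to the first `n_harmonics`
#' harmonics.
#'
#' @param waveform a `flow_waveform`.
#' @param t times in seconds.
#' @param n_harmonics number of harmonics to retain (default: all).
#' @return flow rate in ml/s at each `t`.
#' @export
waveform_eval <- function(waveform, t, n_harmonics = Inf) {
  stopifnot(inherits(waveform, "flow_waveform"))
  nh <- min(n_harmonics, length(waveform$harmonics))
  q <- rep(waveform$mean_flow, length(t))
  if (nh >= 1) {
    for (n in seq_len(nh)) {
      wn <- 2 * pi * n/waveform$period
      q <- q + Re(waveform$harmonics[n] * exp(1i * wn * t))
    }
  }
  q
}

#' Multiply a waveform by a scalar
#' @param waveform a `flow_waveform`.
#' @param factor positive scale factor applied to all samples.
#' @return the scaled `flow_waveform`.
#' @export
scale_waveform <- function(waveform, factor) {
  stopifnot(inherits(waveform, "flow_waveform"))
  assert_that(is_scalar_number(factor), "factor must be a finite number")
  flow_waveform(waveform$samples * factor, waveform$period)
}

#' Random multi-harmonic carotid-like waveform
#'
#' Generates a pulsatile flow waveform as a positive steady component plus
#' 2-4 random harmonics, the parametric stand-in used because published
#' carotid waveform tables are not part of this package. Defaults emulate a
#' common-carotid inflow at 68 bpm with a systolic peak 2-3x the mean.
#'
#' @param seed integer RNG seed.
#' @param n_harmonics number of nonzero harmonics (2-4 typical).
#' @param period cycle length, s (default 60/68 s, i.e. 68 bpm).
#' @param mean_flow cycle-mean flow, ml/s.
#' @param pulsatility relative amplitude of the first harmonic.
#' @param n_samples samples per cycle.
#' @return a `flow_waveform`.
#' @export
random_waveform <- function(seed, n_harmonics = 3, period = 60/68,
                            mean_flow = 6, pulsatility = 0.8,
                            n_samples = 64) {
  assert_that(n_harmonics >= 1, "need at least one harmonic")
  rng <- local({
    set.seed(seed)
    list(amp = stats::runif(n_harmonics, 0.3, 1),
         phase = stats::runif(n_harmonics, 0, 2 * pi))
  })
  amp <- rng$amp * mean_flow * pulsatility/seq_len(n_harmonics)
  tt <- (seq_len(n_samples) - 1) * period/n_samples
  q <- rep(mean_flow, n_samples)
  for (n in seq_len(n_harmonics)) {
    q <- q + amp[n] * cos(2 * pi * n * tt/period + rng$phase[n])
  }
  flow_waveform(q, period)
}

#' Read / write waveform CSV (columns t_s, Q_ml_s)
#'
#' @param path file path.
#' @return `read_waveform_csv`: a `flow_waveform`; the writer returns `path`
#'   invisibly.
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  assert_that(all(c("t_s", "Q_ml_s") %in% names(d)),
              "waveform CSV needs columns t_s, Q_ml_s")
  n <- nrow(d)
  dt <- diff(d$t_s)
  assert_that(all(abs(dt - dt[1]) < 1e-9), "waveform samples must be uniform")
  flow_waveform(d$Q_ml_s, period = n * dt[1])
}

#' @rdname read_waveform_csv
#' @param waveform a `flow_waveform` to write.
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "flow_waveform"))
  utils::write.csv(data.frame(t_s = waveform$times, Q_ml_s = waveform$samples),
                   path, row.names = FALSE)
  invisible(path)
}
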