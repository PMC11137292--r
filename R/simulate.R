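# Synthetic data generators. Dataset-1-like: extracellular action potentials
# (damped cosine under a Gaussian envelope) fired as a homogeneous Poisson
# process at 20 kHz, buried in additive Gaussian noise at a target SNR,
# with spike-centered 56-sample epochs for three spike classes plus a
# spike-free noise class. Dataset-2-like: a five-class EEG surrogate with
# class-specific amplitude and autocorrelation, one class ictal-like.

#' Action-potential template parameters
#'
#' The template is `V(t) = A cos(2 pi (t - tau_ph) / tau1) *
#' exp(-(2.3548 t / tau2)^2)`: a cosine at period `tau1` under a Gaussian
#' envelope whose full width at half maximum is `tau2` (2.3548 is the
#' FWHM-to-sigma conversion 2 sqrt(2 ln 2)).
#'
#' @param A Peak amplitude (arbitrary units, > 0).
#' @param tau1 Oscillation period (seconds, > 0).
#' @param tau2 Envelope FWHM (seconds, > 0).
#' @param tau_ph Phase offset (seconds).
#' @param class_id Integer class label (1..3).
#' @return A `spike_template_params` list.
#' @export
spike_template_params <- function(A, tau1, tau2, tau_ph = 0, class_id = 1L) {
  if (!is.finite(A) || A < 0) stop("'A' must be >= 0", call. = FALSE)
  if (tau1 <= 0 || tau2 <= 0) stop("'tau1' and 'tau2' must be > 0",
                                   call. = FALSE)
  structure(list(A = A, tau1 = tau1, tau2 = tau2, tau_ph = tau_ph,
                 class_id = as.integer(class_id)),
            class = "spike_template_params")
}

#' Default spike template set
#'
#' Three biphasic templates with distinct widths and amplitudes (class 3
#' the largest, amplitude ratios 1 : 1.1 : 1.5), qualitatively emulating a
#' three-unit extracellular recording. Values are package defaults chosen
#' for visual and spectral distinctness, not a fit to any particular
#' electrode dataset.
#'
#' @return List of three [spike_template_params()].
#' @export
default_spike_templates <- function() {
  list(
    spike_template_params(A = 1.0, tau1 = 1.2e-3, tau2 = 0.6e-3,
                          tau_ph = 0, class_id = 1L),
    spike_template_params(A = 1.1, tau1 = 1.6e-3, tau2 = 0.9e-3,
                          tau_ph = 0.2e-3, class_id = 2L),
    spike_template_params(A = 1.5, tau1 = 2.0e-3, tau2 = 1.2e-3,
                          tau_ph = 0, class_id = 3L)
  )
}

#' Sample an action-potential template on a regular grid
#'
#' @param p A [spike_template_params()].
#' @param sampling_rate Sampling rate in Hz.
#' @param support Window length in seconds; the template is evaluated on
#'   `t` in `[-support/2, support/2)`.
#' @return Numeric vector of `round(support * sampling_rate)` samples with
#'   peak magnitude at most `A`.
#' @export
spike_template <- function(p, sampling_rate, support) {
  stopifnot(inherits(p, "spike_template_params"))
  if (support <= 0 || sampling_rate <= 0) {
    stop("'support' and 'sampling_rate' must be > 0", call. = FALSE)
  }
  n <- round(support * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate - support / 2
  p$A * cos(2 * pi * (t - p$tau_ph) / p$tau1) *
    exp(-(2.3548 * t / p$tau2)^2)
}

#' Generate Poisson spike times with a refractory veto
#'
#' Homogeneous Poisson arrivals at `firing_rate`; any spike closer than
#' `refractory` to its accepted predecessor is discarded, which prevents
#' overlapping spike windows when `refractory` is set to one epoch length.
#'
#' @param firing_rate Mean rate in Hz (> 0).
#' @param duration Recording length in seconds (>= 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param refractory Minimum inter-spike interval in seconds (default 0).
#' @return Sorted numeric vector of spike times in `[0, duration)`.
#' @export
generate_spike_times <- function(firing_rate, duration, seed = NULL,
                                 refractory = 0) {
  if (firing_rate <= 0) stop("'firing_rate' must be > 0", call. = FALSE)
  if (duration < 0) stop("'duration' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (duration == 0) return(numeric(0))
  times <- numeric(0)
  t <- 0
  # draw inter-arrival gaps in chunks until past the end
  repeat {
    gaps <- stats::rexp(max(64L, ceiling(firing_rate * duration / 4)),
                        rate = firing_rate)
    times <- c(times, t + cumsum(gaps))
    t <- times[length(times)]
    if (t >= duration) break
  }
  times <- times[times < duration]
  if (refractory > 0 && length(times) > 1L) {
    keep <- logical(length(times))
    keep[1L] <- TRUE
    last <- times[1L]
    for (k in 2L:length(times)) {
      if (times[k] - last >= refractory) {
        keep[k] <- TRUE
        last <- times[k]
      }
    }
    times <- times[keep]
  }
  times
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' Adds i.i.d. zero-mean Gaussian noise scaled relative to the signal.
#' Three conventions are supported:
#' * `"peak"` (default): `snr` is peak amplitude over noise sd, the usual
#'   spike-sorting convention; `sd = max|signal| / snr`.
#' * `"rms"`: `snr` is signal RMS over noise sd; `sd = rms(signal) / snr`.
#' * `"noise-level"`: `snr` is a noise *level*, larger meaning noisier;
#'   `sd = snr * rms(signal)`. This is the convention of the synthetic
#'   spike sets the simulator emulates, whose difficulty increases with
#'   the nominal value (see [simulate_dataset1()]).
#'
#' An infinite `snr` under the first two conventions returns the signal
#' unchanged.
#'
#' @param signal Numeric vector with nonzero peak.
#' @param snr Positive ratio (interpreted per `sd_ref`).
#' @param seed Optional integer seed.
#' @param sd_ref `"peak"`, `"rms"`, or `"noise-level"`.
#' @return `signal` plus noise.
#' @export
add_noise_at_snr <- function(signal, snr, seed = NULL,
                             sd_ref = c("peak", "rms", "noise-level")) {
  sd_ref <- match.arg(sd_ref)
  if (!is.numeric(snr) || snr <= 0) stop("'snr' must be > 0", call. = FALSE)
  ref <- switch(sd_ref,
                peak = max(abs(signal)),
                rms = sqrt(mean(signal^2)),
                `noise-level` = sqrt(mean(signal^2)))
  if (ref == 0) stop("cannot set an SNR for an all-zero signal",
                     call. = FALSE)
  sd <- switch(sd_ref,
               peak = ref / snr,
               rms = ref / snr,
               `noise-level` = snr * ref)
  if (sd == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  signal + stats::rnorm(length(signal), mean = 0, sd = sd)
}

#' Simulate a labeled spike-epoch dataset
#'
#' Builds a single extracellular-style recording containing all three
#' spike classes: each template fires as an independent Poisson process at
#' `firing_rate`, merged with a one-epoch refractory veto so spike windows
#' never overlap. Gaussian noise is added at noise level `snr`, the whole
#' recording is normalized to `[0, 1]` against its extrema, and
#' spike-centered epochs of `epoch_len` samples are cut for labels 1..3. Spike-free stretches of the same recording
#' supply the noise class (label 4). A common recording and a single
#' normalization preserve the between-class amplitude relationships the
#' Gershgorin features discriminate on. Epochs are 2.8 ms at the defaults,
#' so windows are necessarily spike-aligned rather than free-running.
#'
#' @param n_per_class Epochs per class (default 100).
#' @param snr Nominal noise level, e.g. 0.5, 1.25, 2.0; the noise standard
#'   deviation is `snr * rms(clean recording)` (`sd_ref = "noise-level"`
#'   in [add_noise_at_snr()]), so larger values are noisier and
#'   classification gets monotonically harder across the conventional
#'   0.5 / 1.25 / 2.0 series.
#' @param sampling_rate Hz (default 20000).
#' @param duration Recording length in seconds (default 200).
#' @param firing_rate Mean firing rate per unit in Hz (default 3.3).
#' @param epoch_len Epoch length in samples (default 56).
#' @param templates List of three [spike_template_params()].
#' @param seed Optional integer seed for full determinism.
#' @return An `epoch_set` of `4 * n_per_class` normalized epochs with
#'   labels 1..3 (template class) and 4 (noise).
#' @examples
#' es <- simulate_dataset1(n_per_class = 10, snr = 2, duration = 10, seed = 1)
#' table(attr(es, "label"))
#' @export
simulate_dataset1 <- function(n_per_class = 100, snr = 2.0,
                              sampling_rate = 20000, duration = 200,
                              firing_rate = 3.3, epoch_len = 56,
                              templates = default_spike_templates(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (epoch_len < 2) stop("'epoch_len' must be >= 2", call. = FALSE)
  support <- epoch_len / sampling_rate
  half <- epoch_len %/% 2
  n_rec <- round(duration * sampling_rate)
  if (n_rec < epoch_len) stop("recording shorter than one epoch",
                              call. = FALSE)

  tmpl <- lapply(templates, spike_template,
                 sampling_rate = sampling_rate, support = support)
  if (any(lengths(tmpl) > epoch_len + 1L)) {
    stop("epoch length shorter than template support", call. = FALSE)
  }

  # merged event list (time, class) with a global one-epoch veto
  ev_t <- numeric(0)
  ev_k <- integer(0)
  for (k in seq_along(templates)) {
    st <- generate_spike_times(firing_rate, duration, refractory = support)
    ev_t <- c(ev_t, st)
    ev_k <- c(ev_k, rep.int(k, length(st)))
  }
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_k <- ev_k[ord]
  if (length(ev_t) > 1L) {
    keep <- logical(length(ev_t))
    keep[1L] <- TRUE
    last <- ev_t[1L]
    for (i in 2L:length(ev_t)) {
      if (ev_t[i] - last >= support) {
        keep[i] <- TRUE
        last <- ev_t[i]
      }
    }
    ev_t <- ev_t[keep]; ev_k <- ev_k[keep]
  }
  centers <- round(ev_t * sampling_rate) + 1L
  inside <- centers - half >= 1L & centers - half + epoch_len - 1L <= n_rec
  centers <- centers[inside]; ev_k <- ev_k[inside]

  clean <- numeric(n_rec)
  for (i in seq_along(centers)) {
    lo <- centers[i] - half
    hi <- lo + length(tmpl[[ev_k[i]]]) - 1L
    clean[lo:hi] <- clean[lo:hi] + tmpl[[ev_k[i]]]
  }
  qn <- normalize_recording(add_noise_at_snr(clean, snr,
                                             sd_ref = "noise-level"))

  spike_rows <- vector("list", length(templates))
  for (k in seq_along(templates)) {
    ck <- centers[ev_k == k]
    if (length(ck) < n_per_class) {
      stop(sprintf(
        "only %d class-%d spikes available for %d requested epochs; increase 'duration'",
        length(ck), k, n_per_class), call. = FALSE)
    }
    use <- ck[seq_len(n_per_class)]
    spike_rows[[k]] <- t(vapply(use, function(ctr) {
      lo <- ctr - half
      qn[lo:(lo + epoch_len - 1L)]
    }, numeric(epoch_len)))
  }

  # spike-free windows: stay two full epochs away from every spike center
  gap_edges <- c(0L, sort(centers), n_rec + 1L)
  wins <- vector("list", 0L)
  for (g in seq_len(length(gap_edges) - 1L)) {
    lo <- gap_edges[g] + 2L * epoch_len
    hi <- gap_edges[g + 1L] - 2L * epoch_len - epoch_len
    while (lo <= hi && length(wins) < n_per_class) {
      wins[[length(wins) + 1L]] <- qn[lo:(lo + epoch_len - 1L)]
      lo <- lo + epoch_len
    }
    if (length(wins) >= n_per_class) break
  }
  if (length(wins) < n_per_class) {
    stop("not enough spike-free stretches for the noise class", call. = FALSE)
  }
  noise_rows <- do.call(rbind, wins)

  m <- rbind(do.call(rbind, spike_rows), noise_rows)
  labels <- rep(seq_len(length(templates) + 1L), each = n_per_class)
  epoch_set(m, labels = labels)
}

# One surrogate EEG channel for a given condition class. Classes differ in
# amplitude scale and autocorrelation structure; class 5 is ictal-like
# (high-amplitude, amplitude-modulated rhythmic bursts, non-stationary).
surrogate_channel <- function(class_id, n_samples, sampling_rate) {
  t <- (seq_len(n_samples) - 1) / sampling_rate
  ar1 <- function(phi, n) as.numeric(stats::filter(stats::rnorm(n), phi,
                                                   method = "recursive"))
  osc <- function(f0, r, n) {
    # AR(2) resonance at f0 Hz with pole radius r
    th <- 2 * pi * f0 / sampling_rate
    as.numeric(stats::filter(stats::rnorm(n), c(2 * r * cos(th), -r^2),
                             method = "recursive"))
  }
  z <- switch(class_id,
    # 1: healthy scalp, eyes open - broadband, moderate alpha
    0.6 * scale_sd(osc(10, 0.90, n_samples)) +
      0.8 * scale_sd(ar1(0.7, n_samples)),
    # 2: healthy scalp, eyes closed - prominent alpha, larger amplitude
    1.6 * scale_sd(osc(10, 0.97, n_samples)) +
      0.6 * scale_sd(ar1(0.7, n_samples)),
    # 3: interictal, contralateral - slow, low amplitude
    0.7 * scale_sd(ar1(0.95, n_samples)),
    # 4: interictal, epileptogenic zone - slow background + sharp transients
    {
      bg <- 1.0 * scale_sd(ar1(0.95, n_samples))
      n_sp <- stats::rpois(1L, n_samples / sampling_rate)  # ~1 spike/s
      if (n_sp > 0) {
        pos <- sample.int(n_samples, n_sp)
        for (p in pos) {
          w <- round(0.04 * sampling_rate)
          idx <- p:min(p + w, n_samples)
          bg[idx] <- bg[idx] + 4 * exp(-((idx - p) / (w / 4))^2)
        }
      }
      bg
    },
    # 5: ictal - high-amplitude rhythmic 4 Hz activity in waxing bursts
    {
      env <- 1 + 3 * abs(sin(2 * pi * 0.25 * t + stats::runif(1, 0, pi)))
      4 * env * scale_sd(osc(4, 0.98, n_samples)) +
        0.5 * scale_sd(ar1(0.5, n_samples))
    }
  )
  z
}

scale_sd <- function(x) {
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate a surrogate multi-condition EEG dataset
#'
#' Generates single-channel recordings of `n_samples` points at
#' `sampling_rate` for five condition-like classes differing in amplitude
#' scale and stationarity (class 5 ictal-like with high-amplitude rhythmic
#' bursts). Channels are allocated round-robin over `classes`. This is a
#' statistical surrogate for testing the pipeline shape, not a model of
#' any particular electrode montage.
#'
#' @param n_channels Total number of channels.
#' @param n_samples Samples per channel (default 4096).
#' @param sampling_rate Hz (default 173.61).
#' @param classes Integer vector of class ids drawn from 1..5.
#' @param seed Optional integer seed.
#' @return A list with `signals` (`n_channels x n_samples` matrix, raw
#'   units), `label` (integer per channel), and `sampling_rate`.
#' @examples
#' sur <- simulate_eeg_surrogate(10, seed = 1)
#' ep <- surrogate_epochs(sur, N = 1024)
#' nrow(ep)  # 40
#' @export
simulate_eeg_surrogate <- function(n_channels, n_samples = 4096,
                                   sampling_rate = 173.61,
                                   classes = 1:5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(classes %in% 1:5), n_channels >= 1)
  labels <- rep_len(classes, n_channels)
  signals <- t(vapply(labels, surrogate_channel, numeric(n_samples),
                      n_samples = n_samples, sampling_rate = sampling_rate))
  list(signals = signals, label = as.integer(labels),
       sampling_rate = sampling_rate)
}

#' Normalize and segment surrogate EEG channels into labeled epochs
#'
#' Each channel is normalized against its own recording extrema and cut
#' into `floor(n_samples / N)` epochs inheriting the channel label.
#'
#' @param sur Output of [simulate_eeg_surrogate()].
#' @param N Epoch length in samples (default 1024).
#' @return An `epoch_set`.
#' @export
surrogate_epochs <- function(sur, N = 1024) {
  per <- ncol(sur$signals) %/% N
  rows <- lapply(seq_len(nrow(sur$signals)), function(ch) {
    unclass(segment_epochs(normalize_recording(sur$signals[ch, ]), N))
  })
  epoch_set(do.call(rbind, rows),
            labels = rep(sur$label, each = per))
}
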