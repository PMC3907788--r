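# Spike-train and spectral analysis: binned interspike-interval statistics,
# discrete-time firing rates, and trial-averaged periodograms of summed
# synaptic currents.

#' Spike-train set
#'
#' A per-neuron collection of ordered spike times for one trial, with trial
#' metadata.
#'
#' @param spikes Tibble with columns `neuron` (integer) and `time` (ms).
#' @param neurons Optional tibble describing the neurons (`neuron`,
#'   `cell_type`).
#' @param duration Trial duration (ms).
#' @param seed Trial seed.
#' @param condition Condition label.
#' @export
spike_train_set <- function(spikes, neurons = NULL, duration = NA_real_,
                            seed = NA_integer_, condition = NA_character_) {
  stopifnot(all(c("neuron", "time") %in% names(spikes)))
  spikes <- dplyr::arrange(as_tibble(spikes), .data$neuron, .data$time)
  if (any(spikes$time < 0) ||
      (!is.na(duration) && any(spikes$time > duration)))
    abort("spike times must lie within [0, duration]")
  structure(list(spikes = spikes, neurons = neurons, duration = duration,
                 seed = seed, condition = condition),
            class = "spike_train_set")
}

#' Coerce to a spike-train set
#' @param x A `spike_train_set` or a tibble/data.frame with `neuron`, `time`.
#' @export
as_spike_train_set <- function(x) {
  if (inherits(x, "spike_train_set")) return(x)
  if (is.data.frame(x)) return(spike_train_set(x))
  abort("cannot coerce to spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d spikes, %d neurons%s\n",
              nrow(x$spikes), length(unique(x$spikes$neuron)),
              if (!is.na(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' Binned interspike-interval statistics
#'
#' Computes per-neuron mean interspike intervals and coefficients of
#' variation in fixed-width bins across an epoch, plus the population
#' average per bin. Each interval is assigned to the bin containing its
#' terminating spike; bins with fewer than two intervals for a neuron are
#' reported as missing.
#'
#' @param spikes A spike-train set or `neuron`/`time` tibble.
#' @param epoch Length-2 numeric `c(t0, t1)` (ms); truncated to an integer
#'   number of bins.
#' @param bin_width Bin width (ms), default 500.
#' @param neurons Optional subset of neuron ids.
#' @param label Epoch label carried through (e.g. "stimulus",
#'   "persistent").
#' @return An `isi_summary`: `per_neuron` and `population` tibbles plus the
#'   bin edges.
#' @export
binned_isi_cv <- function(spikes, epoch, bin_width = 500, neurons = NULL,
                          label = NA_character_) {
  st <- as_spike_train_set(spikes)
  sp <- st$spikes
  if (!is.null(neurons)) sp <- sp[sp$neuron %in% neurons, , drop = FALSE]
  nbin <- floor((epoch[2] - epoch[1]) / bin_width + 1e-9)
  if (nbin < 1) abort("epoch shorter than one bin")
  edges <- epoch[1] + bin_width * (0:nbin)

  per <- list()
  for (n in unique(sp$neuron)) {
    tt <- sort(sp$time[sp$neuron == n])
    if (length(tt) < 2) next
    isi <- diff(tt)
    term <- tt[-1]
    keep <- term >= edges[1] & term < edges[nbin + 1]
    isi <- isi[keep]; term <- term[keep]
    if (!length(isi)) next
    bin <- findInterval(term, edges, rightmost.closed = FALSE)
    per[[length(per) + 1]] <- tibble(neuron = n, bin = bin, isi = isi)
  }
  long <- dplyr::bind_rows(per)
  if (!nrow(long)) {
    empty <- tibble(neuron = integer(), bin = integer(),
                    mean_isi = numeric(), cv = numeric(), n_isi = integer())
    return(structure(list(per_neuron = empty,
                          population = tibble(bin = integer(),
                                              mean_isi = numeric(),
                                              mean_cv = numeric()),
                          edges = edges, bin_width = bin_width,
                          label = label),
                     class = "isi_summary"))
  }
  per_neuron <- long |>
    dplyr::group_by(.data$neuron, .data$bin) |>
    dplyr::summarise(
      mean_isi = mean(.data$isi),
      cv = if (dplyr::n() >= 2) sd(.data$isi) / mean(.data$isi) else NA_real_,
      n_isi = dplyr::n(), .groups = "drop")
  population <- per_neuron |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_isi = mean(.data$mean_isi),
                     mean_cv = mean(.data$cv, na.rm = TRUE),
                     n_neurons = dplyr::n(), .groups = "drop")
  structure(list(per_neuron = per_neuron, population = population,
                 edges = edges, bin_width = bin_width, label = label),
            class = "isi_summary")
}

#' @export
print.isi_summary <- function(x, ...) {
  cat(sprintf("<isi_summary> %d bins of %g ms%s; population mean ISI %.1f ms\n",
              length(x$edges) - 1, x$bin_width,
              if (!is.na(x$label)) paste0(" [", x$label, "]") else "",
              mean(x$population$mean_isi)))
  invisible(x)
}

#' Population mean interspike interval over an epoch
#'
#' Convenience wrapper: binned statistics averaged across bins and neurons.
#'
#' @inheritParams binned_isi_cv
#' @return Mean ISI (ms), or `NA` if no neuron has two spikes in the epoch.
#' @export
population_mean_isi <- function(spikes, epoch, bin_width = 500,
                                neurons = NULL) {
  s <- binned_isi_cv(spikes, epoch, bin_width, neurons)
  if (!nrow(s$population)) return(NA_real_)
  mean(s$population$mean_isi)
}

#' Discrete-time firing-rate histogram
#'
#' Total spike counts of all (selected) neurons in 1 ms bins across an
#' epoch; the histogram total equals the number of spikes in the epoch.
#'
#' @inheritParams binned_isi_cv
#' @param bin_width Bin width (ms), default 1.
#' @return A tibble with `bin_start` and `count`.
#' @export
discrete_time_rate <- function(spikes, epoch, bin_width = 1, neurons = NULL) {
  st <- as_spike_train_set(spikes)
  sp <- st$spikes
  if (!is.null(neurons)) sp <- sp[sp$neuron %in% neurons, , drop = FALSE]
  edges <- seq(epoch[1], epoch[2], by = bin_width)
  if (edges[length(edges)] < epoch[2]) edges <- c(edges, epoch[2])
  tt <- sp$time[sp$time >= epoch[1] & sp$time <= epoch[2]]
  bin <- findInterval(pmin(tt, epoch[2] - 1e-9), edges,
                      rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  tibble(bin_start = edges[-length(edges)], count = counts)
}

#' Trial-averaged periodogram of summed synaptic currents
#'
#' For each trial the AMPA, NMDA and GABA-A currents summed over the
#' pyramidal population are added together over the analysis window, mean
#' subtracted, decimated to 1 kHz with anti-alias filtering, and a plain
#' (untapered) periodogram computed; periodograms are averaged across
#' trials. Scaling follows Parseval: the one-sided power sums to the
#' windowed signal variance.
#'
#' @param trials List of trial synaptic-current tibbles (columns `time`,
#'   `ampa`, `nmda`, `gabaa`), e.g. the `syn` element of simulation
#'   results.
#' @param window Length-2 numeric `c(t0, t1)` (ms); standard use is the 1 s
#'   period starting 3 s after stimulus end.
#' @param decimate_to Target sampling rate (Hz).
#' @return A `spectrum_result`: tibble `spectrum` (`freq` Hz, `power`),
#'   `n_trials`, `df` (frequency resolution, Hz).
#' @export
synaptic_current_spectrum <- function(trials, window, decimate_to = 1000) {
  stopifnot(length(trials) >= 1)
  specs <- lapply(trials, function(tr) {
    stopifnot(all(c("time", "ampa", "nmda", "gabaa") %in% names(tr)))
    dt_ms <- diff(tr$time[1:2])
    if (window[1] < min(tr$time) - 1e-9 ||
        window[2] > max(tr$time) + dt_ms + 1e-9)
      abort("analysis window extends past the recorded trace")
    keep <- tr$time >= window[1] & tr$time < window[2]
    x <- tr$ampa[keep] + tr$nmda[keep] + tr$gabaa[keep]
    fs <- 1000 / dt_ms
    q <- max(1L, as.integer(round(fs / decimate_to)))
    x <- decimate_signal(x, q)
    fs <- fs / q
    x <- x - mean(x)
    n <- length(x)
    ps <- Mod(fft(x))^2 / n^2
    half <- floor(n / 2)
    power <- 2 * ps[2:(half + 1)]
    if (n %% 2 == 0) power[half] <- power[half] / 2
    tibble(freq = (1:half) * fs / n, power = power)
  })
  freq <- specs[[1]]$freq
  pw <- rowMeans(do.call(cbind, lapply(specs, function(s) s$power)))
  structure(list(spectrum = tibble(freq = freq, power = pw),
                 n_trials = length(trials), df = freq[2] - freq[1],
                 window = window),
            class = "spectrum_result")
}

# staged FIR decimation (keeps per-stage factors small)
decimate_signal <- function(x, q) {
  while (q > 1) {
    stage <- if (q > 13) {
      f <- max(which(q %% 2:13 == 0)) + 1
      if (f < 2) 13 else f
    } else q
    x <- signal::decimate(x, stage, ftype = "fir")
    q <- q %/% stage
  }
  x
}

#' Frequency of the dominant spectral peak
#'
#' @param spec A `spectrum_result`.
#' @param fmin Ignore frequencies below this bound (Hz).
#' @return Peak frequency (Hz).
#' @export
peak_frequency <- function(spec, fmin = 5) {
  s <- spec$spectrum[spec$spectrum$freq >= fmin, , drop = FALSE]
  s$freq[which.max(s$power)]
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d trials, df = %.2f Hz, peak at %.1f Hz\n",
              x$n_trials, x$df, peak_frequency(x)))
  invisible(x)
}
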