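# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.spike_train_set <- function(x, ...) {
  out <- x$spikes
  if (!is.null(x$neurons))
    out <- dplyr::left_join(out, x$neurons, by = "neuron")
  out
}

#' @export
glance.spike_train_set <- function(x, ...) {
  tibble(n_spikes = nrow(x$spikes),
         n_neurons = length(unique(x$spikes$neuron)),
         duration = x$duration, seed = x$seed, condition = x$condition)
}

#' @export
tidy.isi_summary <- function(x, ...) x$per_neuron

#' @export
glance.isi_summary <- function(x, ...) {
  tibble(n_bins = length(x$edges) - 1, bin_width = x$bin_width,
         mean_isi = mean(x$population$mean_isi),
         mean_cv = mean(x$population$mean_cv, na.rm = TRUE),
         label = x$label)
}

#' @export
tidy.induction_result <- function(x, ...) x$grid

#' @export
glance.induction_result <- function(x, ...) {
  tibble(n_conditions = nrow(x$grid), n_trials = x$grid$n_trials[1],
         mean_probability = mean(x$grid$probability),
         manipulation = x$manipulation)
}

#' @export
tidy.spectrum_result <- function(x, ...) x$spectrum

#' @export
glance.spectrum_result <- function(x, ...) {
  tibble(peak_freq = peak_frequency(x), df = x$df, n_trials = x$n_trials)
}

#' @export
tidy.synchrony_result <- function(x, ...) {
  if (!is.null(x$pairs)) x$pairs
  else tibble(index = x$index, n_neurons = x$n_neurons)
}

#' @export
glance.synchrony_result <- function(x, ...) {
  tibble(index = x$index, n_neurons = x$n_neurons,
         epoch_start = x$epoch[1], epoch_end = x$epoch[2])
}

#' Raster plot of a spike-train set
#' @param object A [spike_train_set()].
#' @param ... Unused.
#' @export
autoplot.spike_train_set <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "neuron",
                  title = object$condition) +
    ggplot2::theme_minimal()
  if (!is.null(object$neurons) && "cell_type" %in% names(df))
    p <- p + ggplot2::aes(colour = .data$cell_type)
  p
}

#' Heat map of an induction-probability grid
#' @param object An induction result from [induction_probability_grid()].
#' @param ... Unused.
#' @export
autoplot.induction_result <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = factor(.data$nmda_ampa),
                               y = factor(.data$gabab_gabaa),
                               fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue4") +
    ggplot2::labs(x = "NMDA-to-AMPA ratio", y = "GABA-B-to-GABA-A ratio",
                  fill = "P(induction)") +
    ggplot2::theme_minimal()
}

#' Line plot of a trial-averaged periodogram
#' @param object A `spectrum_result`.
#' @param fmax Upper frequency bound for display (Hz).
#' @param ... Unused.
#' @export
autoplot.spectrum_result <- function(object, fmax = 100, ...) {
  df <- object$spectrum[object$spectrum$freq <= fmax, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "mean-square power") +
    ggplot2::theme_minimal()
}

#' Binned ISI / CV profile plot
#' @param object An `isi_summary`.
#' @param what `"mean_isi"` or `"mean_cv"`.
#' @param ... Unused.
#' @export
autoplot.isi_summary <- function(object, what = c("mean_isi", "mean_cv"),
                                 ...) {
  what <- match.arg(what)
  df <- object$population
  df$bin_start <- object$edges[df$bin]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start,
                                   y = .data[[what]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "bin start (ms)",
                  y = if (what == "mean_isi") "mean ISI (ms)" else "CV") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
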