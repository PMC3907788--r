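test_that("binned ISI statistics recover regular and Poisson trains", {
  st <- spike_train_set(tibble::tibble(
    neuron = 1L, time = seq(100, 9900, by = 100)), duration = 10000)
  s <- binned_isi_cv(st, epoch = c(0, 10000), bin_width = 500)
  expect_true(all(abs(s$per_neuron$mean_isi - 100) < 1e-9))
  expect_true(all(s$per_neuron$cv[s$per_neuron$n_isi >= 2] < 1e-9))
  # homogeneous Poisson: CV of exponential ISIs is 1
  set.seed(21)
  tt <- cumsum(rexp(20000, 1 / 50))
  st2 <- spike_train_set(tibble::tibble(neuron = 1L, time = tt),
                         duration = max(tt) + 1)
  # epoch-wide CV of exponential intervals is 1; use one bin spanning the
  # epoch so the estimate is not biased by small per-bin counts
  len <- floor(max(tt) / 500) * 500
  s2 <- binned_isi_cv(st2, epoch = c(0, len), bin_width = len)
  expect_lt(abs(s2$per_neuron$cv[1] - 1), 0.05)
  # short bins give the same picture up to small-sample bias
  s3 <- binned_isi_cv(st2, epoch = c(0, len), bin_width = 500)
  expect_gt(mean(s3$per_neuron$cv, na.rm = TRUE), 0.8)
  expect_lt(mean(s3$per_neuron$cv, na.rm = TRUE), 1.1)
})

test_that("empty spike sets yield all-missing summaries", {
  st <- spike_train_set(tibble::tibble(neuron = integer(),
                                       time = numeric()), duration = 1000)
  s <- binned_isi_cv(st, epoch = c(0, 1000))
  expect_equal(nrow(s$per_neuron), 0)
  expect_true(is.na(population_mean_isi(st, c(0, 1000))))
})

test_that("ISI statistics are invariant under a global time shift", {
  set.seed(5)
  base <- tibble::tibble(neuron = rep(1:3, each = 30),
                         time = runif(90, 0, 4000))
  a <- binned_isi_cv(spike_train_set(base, duration = 5000), c(0, 4000))
  shifted <- dplyr::mutate(base, time = time + 750)
  b <- binned_isi_cv(spike_train_set(shifted, duration = 6000),
                     c(750, 4750))
  expect_equal(a$per_neuron$mean_isi, b$per_neuron$mean_isi,
               tolerance = 1e-12)
  expect_equal(a$per_neuron$cv, b$per_neuron$cv, tolerance = 1e-12)
})

test_that("the discrete-time rate histogram counts every spike", {
  st <- spike_train_set(tibble::tibble(neuron = 1:20, time = rep(500, 20)),
                        duration = 1000)
  h <- discrete_time_rate(st, epoch = c(0, 1000))
  expect_equal(sum(h$count), 20)
  expect_equal(h$count[h$bin_start == 500], 20)
  set.seed(2)
  r <- tibble::tibble(neuron = sample(1:5, 300, TRUE),
                      time = runif(300, 0, 2000))
  h2 <- discrete_time_rate(spike_train_set(r, duration = 2000), c(0, 2000))
  expect_equal(sum(h2$count), 300)
  empty <- discrete_time_rate(
    spike_train_set(tibble::tibble(neuron = integer(), time = numeric()),
                    duration = 100), c(0, 100))
  expect_true(all(empty$count == 0))
})

test_that("the periodogram resolves a pure tone and satisfies Parseval", {
  t <- seq(0, 1000 - 0.025, by = 0.025)
  tone <- tibble::tibble(time = t, ampa = sin(2 * pi * 20 * t / 1000),
                         nmda = 0, gabaa = 0)
  sp <- synaptic_current_spectrum(list(tone), window = c(0, 1000))
  expect_lt(abs(peak_frequency(sp) - 20), sp$df + 1e-9)
  # Parseval at the decimated rate: total one-sided power ~ signal variance
  x <- tone$ampa
  q <- 40
  xd <- pfcmicro:::decimate_signal(x, q)
  xd <- xd - mean(xd)
  expect_lt(abs(sum(sp$spectrum$power) - stats::var(xd) *
                  (length(xd) - 1) / length(xd)) / stats::var(xd), 0.01)
})

test_that("trial-averaged white-noise spectra are flat", {
  set.seed(77)
  t <- seq(0, 1000 - 0.025, by = 0.025)
  trials <- lapply(1:10, function(i)
    tibble::tibble(time = t, ampa = rnorm(length(t)), nmda = 0, gabaa = 0))
  sp <- synaptic_current_spectrum(trials, window = c(0, 1000))
  pw <- sp$spectrum$power[sp$spectrum$freq > 5]
  expect_lt(max(pw) / stats::median(pw), 5)
})

test_that("windows outside the recording are rejected", {
  t <- seq(0, 100, by = 0.025)
  tr <- tibble::tibble(time = t, ampa = 0, nmda = 0, gabaa = 0)
  expect_error(synaptic_current_spectrum(list(tr), window = c(0, 500)),
               "window")
})

test_that("spike-train sets validate and round-trip through text files", {
  expect_error(spike_train_set(tibble::tibble(neuron = 1, time = -5),
                               duration = 100), "within")
  st <- spike_train_set(tibble::tibble(neuron = c(2L, 1L, 1L),
                                       time = c(30, 20, 10)),
                        duration = 100, seed = 4L, condition = "control")
  expect_equal(st$spikes$time, c(10, 20, 30))  # sorted per neuron
  path <- tempfile(fileext = ".csv")
  write_spike_trains(st, path)
  back <- read_spike_trains(path)
  expect_equal(back$spikes, st$spikes)
  expect_equal(back$duration, st$duration)
  expect_equal(back$condition, st$condition)
})
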