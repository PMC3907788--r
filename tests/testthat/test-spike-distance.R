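# independent oracle: the pairwise profile S(t) is piecewise linear between
# event breakpoints, so midpoint sampling integrates it exactly; this
# re-derivation shares no code with the package's trapezoidal path
midpoint_oracle <- function(sp1, sp2, t0, t1) {
  e1 <- sort(unique(c(t0, sp1[sp1 >= t0 & sp1 <= t1], t1)))
  e2 <- sort(unique(c(t0, sp2[sp2 >= t0 & sp2 <= t1], t1)))
  breaks <- sort(unique(c(e1, e2)))
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    tm <- (a + b) / 2
    p1 <- max(e1[e1 <= tm]); f1 <- min(e1[e1 >= tm])
    p2 <- max(e2[e2 <= tm]); f2 <- min(e2[e2 >= tm])
    x1 <- f1 - p1; x2 <- f2 - p2
    if (x1 <= 0 || x2 <= 0) next
    s1 <- (min(abs(p1 - e2)) * (f1 - tm) + min(abs(f1 - e2)) * (tm - p1)) / x1
    s2 <- (min(abs(p2 - e1)) * (f2 - tm) + min(abs(f2 - e1)) * (tm - p2)) / x2
    total <- total + (s1 * x2 + s2 * x1) / (2 * ((x1 + x2) / 2)^2) * (b - a)
  }
  total / (t1 - t0)
}

test_that("identical trains have zero SPIKE-distance", {
  tt <- c(100, 250, 400, 700, 900)
  st <- spike_train_set(tibble::tibble(neuron = rep(1:4, each = 5),
                                       time = rep(tt, 4)), duration = 1000)
  r <- spike_distance_index(st, epoch = c(0, 1000))
  expect_equal(r$index, 0, tolerance = 1e-12)
})

test_that("the pairwise distance matches the midpoint-sampling oracle", {
  sp1 <- c(100, 220, 340, 470, 600, 750, 880)
  sp2 <- sp1 + 37   # constant lag
  got <- pfcmicro:::spike_distance_pair(sp1, sp2, 0, 1000)
  want <- midpoint_oracle(sp1, sp2, 0, 1000)
  expect_lt(abs(got - want), 1e-6)
  expect_gt(got, 0)
  # random fixtures
  set.seed(14)
  for (i in 1:5) {
    a <- sort(runif(12, 0, 1000))
    b <- sort(runif(9, 0, 1000))
    expect_lt(abs(pfcmicro:::spike_distance_pair(a, b, 0, 1000) -
                    midpoint_oracle(a, b, 0, 1000)), 1e-6)
  }
})

test_that("the index is symmetric under neuron permutation", {
  set.seed(8)
  sp <- tibble::tibble(neuron = rep(1:5, each = 8),
                       time = runif(40, 0, 800))
  st <- spike_train_set(sp, duration = 800)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  sp2 <- dplyr::mutate(sp, neuron = perm[neuron])
  st2 <- spike_train_set(sp2, duration = 800)
  a <- spike_distance_index(st, c(0, 800))
  b <- spike_distance_index(st2, c(0, 800))
  expect_equal(a$index, b$index, tolerance = 1e-12)
})

test_that("the index is invariant under a global time shift", {
  set.seed(9)
  sp <- tibble::tibble(neuron = rep(1:3, each = 10),
                       time = runif(30, 0, 900))
  a <- spike_distance_index(spike_train_set(sp, duration = 1000),
                            c(0, 1000))
  sp2 <- dplyr::mutate(sp, time = time + 400)
  b <- spike_distance_index(spike_train_set(sp2, duration = 1500),
                            c(400, 1400))
  expect_equal(a$index, b$index, tolerance = 1e-9)
})

test_that("fewer than two active trains is flagged undefined", {
  st <- spike_train_set(tibble::tibble(neuron = 1L, time = c(10, 20)),
                        duration = 100)
  expect_warning(r <- spike_distance_index(st, c(0, 100)), "fewer")
  expect_true(is.na(r$index))
})

test_that("asynchronous trains score higher than near-synchronous ones", {
  base <- seq(50, 950, by = 60)
  near <- spike_train_set(tibble::tibble(
    neuron = rep(1:4, each = length(base)),
    time = rep(base, 4) + rep(c(0, 1, 2, 3), each = length(base))),
    duration = 1000)
  set.seed(10)
  far <- spike_train_set(tibble::tibble(
    neuron = rep(1:4, each = length(base)),
    time = as.numeric(vapply(1:4, function(i) sort(runif(length(base), 0,
                                                         1000)),
                             numeric(length(base))))),
    duration = 1000)
  expect_lt(spike_distance_index(near, c(0, 1000))$index,
            spike_distance_index(far, c(0, 1000))$index)
})
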