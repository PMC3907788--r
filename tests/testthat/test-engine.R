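# single passive compartment as a bare cell_model
passive_cell <- function(length = 20, diameter = 20, rm = 20,
                         e_leak = -70) {
  structure(list(
    cell_type = "PYR",
    compartments = data.frame(name = "soma", length = length,
                              diameter = diameter, parent = NA_character_,
                              stringsAsFactors = FALSE),
    passive = list(cm = 1.2, ra = 150, rm = rm, e_leak = e_leak),
    channels = list(), calcium = list(),
    v_rest_target = e_leak, v_init = e_leak
  ), class = "cell_model")
}

test_that("passive compartment follows the RC closed form", {
  cell <- passive_cell()
  area <- pi * 20 * 20 * 1e-8              # cm2
  r_mohm <- 20 / area / 1000               # rm (kOhm cm2) / area -> MOhm
  tau <- 20e3 * 1.2e-6 * 1000              # rm * cm in ms
  sim <- pfcmicro:::new_sim(list(cell))
  sim <- pfcmicro:::add_injection(sim, 1, "soma", 0, 200, 0.01)
  res <- pfcmicro:::run_sim(sim, sim_config(duration = 200))
  v_theory <- -70 + 0.01 * r_mohm * (1 - exp(-res$time / tau))
  err <- abs(res$v[, 1] - v_theory) / (0.01 * r_mohm)
  expect_lt(max(err[res$time > 1]), 0.01)
  # measured input resistance within 0.5% of rm/A
  expect_lt(abs(measure_input_resistance(cell, -0.005) - r_mohm) / r_mohm,
            0.005)
})

test_that("two-compartment cable matches the voltage-divider closed form", {
  cell <- passive_cell()
  cell$compartments <- data.frame(
    name = c("soma", "dend"), length = c(20, 100), diameter = c(20, 2),
    parent = c(NA_character_, "soma"), stringsAsFactors = FALSE)
  sim <- pfcmicro:::new_sim(list(cell))
  sim <- pfcmicro:::add_injection(sim, 1, "soma", 0, 2000, 0.01)
  res <- pfcmicro:::run_sim(sim, sim_config(duration = 2000),
                            record = c("1.soma", "1.dend"))
  # steady-state linear circuit: leak conductances + axial coupling
  g1 <- 1000 * pi * 20 * 20 * 1e-8 / 20    # uS
  g2 <- 1000 * pi * 100 * 2 * 1e-8 / 20
  ra <- 150
  rax <- ra * (20 / 2 * 1e-4) / (pi * (20 / 2 * 1e-4)^2) +
    ra * (100 / 2 * 1e-4) / (pi * (2 / 2 * 1e-4)^2)
  ga <- 1e6 / rax
  # solve 2x2: (g1+ga) dv1 - ga dv2 = I ; -ga dv1 + (g2+ga) dv2 = 0
  A <- matrix(c(g1 + ga, -ga, -ga, g2 + ga), 2, byrow = TRUE)
  dv <- solve(A, c(0.01, 0))
  n <- nrow(res$v)
  expect_lt(abs((res$v[n, 1] + 70) - dv[1]) / dv[1], 0.01)
  expect_lt(abs((res$v[n, 2] + 70) - dv[2]) / dv[2], 0.01)
})

test_that("cells at rest stay at rest", {
  cell <- build_cell("FS")
  res <- pfcmicro:::run_sim(pfcmicro:::new_sim(list(cell)),
                            sim_config(duration = 10000,
                                       record_stride = 100L))
  expect_equal(nrow(res$spikes), 0)
  expect_lt(max(abs(res$v[, 1] - cell$v_rest_target)), 1)
})

test_that("voltage traces converge as the step shrinks", {
  cell <- build_cell("RS")
  run_at <- function(dt) {
    sim <- pfcmicro:::new_sim(list(cell))
    sim <- pfcmicro:::add_injection(sim, 1, "soma", 50, 450, -0.02)
    pfcmicro:::run_sim(sim, sim_config(dt = dt, duration = 500,
                                       record_stride = round(0.2 / dt)))
  }
  a <- run_at(0.025)
  b <- run_at(0.0125)
  n <- min(nrow(a$v), nrow(b$v))
  rms <- sqrt(mean((a$v[1:n, 1] - b$v[1:n, 1])^2))
  expect_lt(rms, 0.5)
})

test_that("spike detection finds interpolated crossings with lockout", {
  t <- seq(0, 100, by = 0.1)
  expect_length(detect_spikes(-60 + 5 * sin(t), t), 0)
  # three template action potentials at known times
  v <- rep(-70, length(t))
  for (t0 in c(20, 50, 80)) {
    idx <- which(t >= t0 & t < t0 + 2)
    v[idx] <- -70 + 110 * exp(-((t[idx] - t0 - 1) / 0.5)^2)
  }
  got <- detect_spikes(v, t, threshold = 0, lockout = 2)
  expect_length(got, 3)
  expect_true(all(abs(got - c(20, 50, 80) - 0.6) < 1))
  expect_length(detect_spikes(v, t, threshold = 60), 0)
  # lockout suppresses a double crossing
  vv <- rep(-70, length(t)); vv[t > 10 & t < 11] <- 10
  expect_length(detect_spikes(vv, t, lockout = 5), 1)
})

test_that("identically-seeded network simulations are bit-identical", {
  spec <- network_spec(seed = 4)
  net1 <- build_network(spec)
  net2 <- build_network(spec)
  expect_identical(net1$synapses, net2$synapses)
  run1 <- run_induction_trial(spec, crit = induction_criterion(200, 300),
                              seed = 9)
  run2 <- run_induction_trial(spec, crit = induction_criterion(200, 300),
                              seed = 9)
  expect_identical(run1$spikes$spikes, run2$spikes$spikes)
})

test_that("synaptic conductance honors the latency", {
  pyr <- build_cell("PYR")
  fs <- build_cell("FS")
  sim <- pfcmicro:::new_sim(list(pyr, fs))
  sim <- pfcmicro:::add_injection(sim, 1, "soma", 100, 110, 2)
  kin <- synapse_kinetics("AMPA")
  sim <- pfcmicro:::add_synapse_rows(sim, tibble::tibble(
    pre = 1L, post = 2L, comp = "dendrite", receptor = "AMPA",
    tau_rise = kin$rise_tau, tau_decay = kin$decay_tau, erev = 0,
    weight = 1e-3, latency = 5, group = -1L))
  res <- pfcmicro:::run_sim(sim, sim_config(duration = 200),
                            record = c("1.soma", "2.dendrite"))
  spk <- res$spikes$time[res$spikes$neuron == 1][1]
  pre_window <- res$v[res$time < spk + 5 - 0.1 & res$time > 50, 2]
  # flat up to settling drift before spike + latency
  expect_lt(max(pre_window) - min(pre_window), 0.01)
  post_window <- res$v[res$time > spk + 5 & res$time < spk + 20, 2]
  expect_gt(max(post_window) - fs$v_rest_target, 0.1)
})
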