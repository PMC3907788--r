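test_that("magnesium unblock is sigmoidal with the closed-form midpoint", {
  expect_lt(mg_block_factor(-120), 0.05)
  expect_gt(mg_block_factor(60), 0.9)
  v_half <- log(1 / 3.57) / 0.062
  expect_equal(mg_block_factor(v_half), 0.5, tolerance = 1e-12)
  v <- seq(-100, 60, by = 5)
  expect_true(all(diff(mg_block_factor(v)) > 0))
  expect_error(mg_block_factor(Inf), "finite")
})

test_that("receptor kinetics validate their invariants", {
  expect_error(synapse_kinetics("AMPA", rise_tau = 3, decay_tau = 2),
               "exceed")
  a <- synapse_kinetics("AMPA"); n <- synapse_kinetics("NMDA")
  ga <- synapse_kinetics("GABAA"); gb <- synapse_kinetics("GABAB")
  expect_gt(n$decay_tau, a$decay_tau)
  expect_gt(gb$decay_tau, ga$decay_tau)
})

test_that("closed-form synaptic current behaves at its anchors", {
  inst <- synapse_instance(1, 2, "basal",
                           list(synapse_kinetics("AMPA", gmax = 1e-3)),
                           latency = 1.7)
  t <- seq(0, 50, by = 0.01)
  expect_true(all(synaptic_current(inst, numeric(0), -70, t) == 0))
  expect_true(all(synaptic_current(inst, 5, 0, t) == 0))  # at reversal
  # peak current within 2% of gmax * driving force at the bi-exponential peak
  i <- synaptic_current(inst, 5, -70, t)
  expect_lt(abs(min(i) - 1e-3 * (-70 - 0)) / abs(1e-3 * 70), 0.02)
  tr <- 0.5; td <- 3
  tpeak <- tr * td / (td - tr) * log(td / tr)
  expect_lt(abs(t[which.min(i)] - (5 + 1.7 + tpeak)), 0.05)
})

test_that("receptor mixes are constrained by connection class", {
  expect_error(synapse_instance(1, 2, "soma",
                                list(synapse_kinetics("AMPA"),
                                     synapse_kinetics("GABAA"))),
               "receptor mix")
  expect_error(synapse_instance(1, 2, "soma",
                                list(synapse_kinetics("GABAA")),
                                latency = 0), "positive")
})

test_that("GABA-B activation outlasts GABA-A for the same train", {
  spikes <- c(10, 20, 30)
  ga <- synapse_instance(1, 2, "distal",
                         list(synapse_kinetics("GABAA", gmax = 1e-3)))
  gb <- synapse_instance(1, 2, "distal",
                         list(synapse_kinetics("GABAB", gmax = 1e-3)))
  t <- seq(0, 1000, by = 0.5)
  ia <- abs(synaptic_current(ga, spikes, -60, t))
  ib <- abs(synaptic_current(gb, spikes, -60, t))
  last_above <- function(i) max(t[i > max(i) * 0.05])
  expect_gt(last_above(ib), last_above(ia))
})

test_that("NMDA charge scales linearly with the ratio", {
  t <- seq(0, 600, by = 0.1)
  q <- vapply(c(0.5, 1, 2), function(r) {
    inst <- synapse_instance(1, 2, "basal",
                             list(synapse_kinetics("NMDA",
                                                   gmax = 1e-3 * r)))
    sum(abs(synaptic_current(inst, 5, -60, t))) * 0.1
  }, numeric(1))
  expect_equal(q[2] / q[1], 2, tolerance = 1e-6)
  expect_equal(q[3] / q[2], 2, tolerance = 1e-6)
})

test_that("the unitary pyramidal AMPA synapse produces a 0.1 mV EPSP", {
  pyr <- build_cell("PYR")
  w <- default_syn_weights()$ampa_pyr
  peak <- unitary_epsp_peak(pyr, w)
  expect_lt(abs(peak - 0.1) / 0.1, 0.05)
  # doubling is at most linear at rest (no supralinear boost)
  peak2 <- unitary_epsp_peak(pyr, 2 * w)
  expect_gt(peak2, 0.1)
  expect_lte(peak2, 0.2 * 1.02)
  expect_equal(unitary_epsp_peak(pyr, 0), 0)
})

test_that("FS autapse construction follows the wiring rules", {
  fs <- build_cell("FS")
  aut <- fs_autapse(fs, neuron = 3L)
  expect_true(aut$is_autapse)
  expect_equal(aut$pre, aut$post)
  expect_equal(aut$post_compartment, "soma")
  expect_equal(aut$receptors[[1]]$receptor, "GABAA")
  expect_equal(aut$receptors[[1]]$reversal, -80)
  expect_error(fs_autapse(build_cell("RS")), "FS")
  net <- build_network(network_spec(seed = 1))
  auts <- net$synapses[net$synapses$class == "FS.FS.aut", ]
  expect_equal(nrow(auts), 2)           # one per FS model
  expect_true(all(auts$pre == auts$post))
  expect_true(all(auts$comp == "soma"))
})

test_that("removing the FS autapse cannot reduce FS excitability", {
  w <- default_syn_weights()$gabaa_fs_aut
  count_spikes <- function(aut_w) {
    fs <- build_cell("FS")
    sim <- pfcmicro:::new_sim(list(fs))
    sim <- pfcmicro:::add_injection(sim, 1, "soma", 200, 700, 0.2)
    if (aut_w > 0) {
      kin <- synapse_kinetics("GABAA")
      sim <- pfcmicro:::add_synapse_rows(sim, tibble::tibble(
        pre = 1L, post = 1L, comp = "soma", receptor = "GABAA",
        tau_rise = kin$rise_tau, tau_decay = kin$decay_tau,
        erev = kin$reversal, weight = aut_w, latency = 1, group = -1L))
    }
    nrow(pfcmicro:::run_sim(sim, sim_config(duration = 800))$spikes)
  }
  expect_gte(count_spikes(0), count_spikes(w))
})
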