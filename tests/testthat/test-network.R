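# hard-coded adjacency audit table: (source type, target type, compartment,
# contacts per connected pair) as published
published_adjacency <- function() {
  tibble::tribble(
    ~source, ~target, ~comp, ~n,
    "PYR", "PYR", "basal", 24L,
    "FS", "PYR", "soma", 15L,
    "RS", "PYR", "distal", 12L,
    "IS", "PYR", "distal", 10L,
    "PYR", "FS", "dendrite", 12L,
    "PYR", "RS", "dendrite", 14L,
    "PYR", "IS", "dendrite", 7L,
    "IS", "RS", "dendrite", 2L
  )
}

test_that("the control network matches the published adjacency", {
  net <- build_network(network_spec(seed = 2))
  pops <- net$populations
  typ <- setNames(pops$cell_type, pops$neuron)
  ga <- net$synapses[net$synapses$receptor %in% c("AMPA", "GABAA"), ]
  counts <- ga |>
    dplyr::filter(.data$pre != .data$post) |>
    dplyr::count(source = typ[as.character(.data$pre)],
                  target = typ[as.character(.data$post)],
                  comp = .data$comp, pre = .data$pre, post = .data$post)
  adj <- published_adjacency()
  for (i in seq_len(nrow(adj))) {
    sub <- counts[counts$source == adj$source[i] &
                    counts$target == adj$target[i], ]
    expect_true(all(sub$comp == adj$comp[i]),
                label = sprintf("%s->%s compartment", adj$source[i],
                                adj$target[i]))
    expect_true(all(sub$n == adj$n[i]),
                label = sprintf("%s->%s count", adj$source[i],
                                adj$target[i]))
    # every demanded pair exists
    n_src <- sum(pops$cell_type == adj$source[i])
    n_tgt <- sum(pops$cell_type == adj$target[i])
    expected_pairs <- n_src * n_tgt -
      (adj$source[i] == adj$target[i]) * n_src
    expect_equal(nrow(sub), expected_pairs)
  }
  # autapses: 8 contacts on every pyramidal, 1 somatic on every FS
  auts <- ga[ga$pre == ga$post, ]
  pyr_aut <- auts[typ[as.character(auts$pre)] == "PYR", ]
  expect_true(all(table(pyr_aut$pre) == 8))
  fs_aut <- auts[typ[as.character(auts$pre)] == "FS", ]
  expect_true(all(table(fs_aut$pre) == 1))
  expect_true(all(fs_aut$comp == "soma"))
})

test_that("inhibitory contacts onto a pyramidal stay below 13% of excitatory", {
  net <- build_network(network_spec(seed = 2))
  syn <- net$synapses[net$synapses$receptor %in% c("AMPA", "GABAA"), ]
  onto1 <- syn[syn$post == 1, ]
  n_exc <- sum(onto1$receptor == "AMPA") + 120  # incoming stimulus contacts
  n_inh <- sum(onto1$receptor == "GABAA")
  expect_lte(n_inh / n_exc, 0.13)
})

test_that("latency draws match the truncated-normal law", {
  x <- draw_latencies(1e5, seed = 42)
  expect_true(all(x > 0.1))
  # moments of N(1.7, 0.9) truncated below at 0.1, by numerical integration
  f <- function(v) dnorm(v, 1.7, 0.9)
  z <- integrate(f, 0.1, Inf)$value
  m1 <- integrate(function(v) v * f(v), 0.1, Inf)$value / z
  m2 <- integrate(function(v) v^2 * f(v), 0.1, Inf)$value / z
  sd_t <- sqrt(m2 - m1^2)
  expect_lt(abs(mean(x) - m1), 0.02)
  expect_lt(abs(mean(x) - 1.7), 0.1)    # truncation bias ~ +0.077
  expect_lt(abs(sd(x) - sd_t), 0.02)
  expect_identical(draw_latencies(10, seed = 7), draw_latencies(10, seed = 7))
})

test_that("knock-outs remove the population and all its synapses", {
  ctrl <- build_network(network_spec(seed = 3))
  ko <- apply_manipulation(ctrl, manipulation_spec("fs_ko"))
  expect_equal(nrow(ko$populations), 18)
  expect_false("FS" %in% ko$populations$cell_type)
  soma_inh <- ko$synapses[ko$synapses$comp == "soma" &
                            ko$synapses$receptor == "GABAA", ]
  expect_equal(nrow(soma_inh), 0)
  # purity: the control object is untouched
  expect_identical(ctrl, build_network(network_spec(seed = 3)))
  rs_ko <- apply_manipulation(ctrl, manipulation_spec("rs_ko"))
  expect_equal(nrow(rs_ko$populations), 19)
})

test_that("FS input scaling keeps the right contact counts", {
  spec <- network_spec(seed = 5)
  ctrl <- build_network(spec)
  same <- apply_manipulation(ctrl, manipulation_spec("fs_scale",
                                                     fs_fraction = 1))
  count_fs <- function(net) {
    typ <- setNames(net$populations$cell_type, net$populations$neuron)
    s <- net$synapses
    s <- s[s$receptor == "GABAA" & typ[as.character(s$pre)] == "FS" &
             typ[as.character(s$post)] == "PYR" & s$pre != s$post, ]
    table(paste(s$pre, s$post))
  }
  expect_true(all(count_fs(same) == 15))
  scaled <- apply_manipulation(ctrl, manipulation_spec("fs_scale",
                                                       fs_fraction = 0.4))
  expect_true(all(count_fs(scaled) == 6))    # round(0.4 * 15)
  # bookkeeping conservation: contacts removed = 2 FS x 16 Pyr x (15 - 6),
  # each with a GABA-A and a GABA-B component
  expect_equal(nrow(ctrl$synapses) - nrow(scaled$synapses),
               2 * 2 * 16 * (15 - 6))
  expect_error(apply_manipulation(scaled, manipulation_spec("fs_ko")),
               "control")
})

test_that("retargeting moves the FS projection without changing counts", {
  ctrl <- build_network(network_spec(seed = 6))
  d2 <- apply_manipulation(ctrl, manipulation_spec("fs_retarget",
                                                   retarget_site = "distal"))
  typ <- setNames(d2$populations$cell_type, d2$populations$neuron)
  fs_syn <- d2$synapses[typ[as.character(d2$synapses$pre)] == "FS" &
                          typ[as.character(d2$synapses$post)] == "PYR" &
                          d2$synapses$pre != d2$synapses$post, ]
  expect_true(all(fs_syn$comp == "distal"))
  expect_equal(sum(fs_syn$receptor == "GABAA"), 2 * 16 * 15)
})

test_that("reverse networks swap the somatic projection role and count", {
  rev <- build_network(network_spec(
    seed = 7, manipulation = manipulation_spec("reverse_rs")))
  expect_equal(sum(rev$populations$cell_type == "RS"), 2)
  expect_equal(sum(rev$populations$cell_type == "FS"), 1)
  typ <- setNames(rev$populations$cell_type, rev$populations$neuron)
  s <- rev$synapses[rev$synapses$receptor == "GABAA" &
                      rev$synapses$pre != rev$synapses$post, ]
  rs_pyr <- s[typ[as.character(s$pre)] == "RS" &
                typ[as.character(s$post)] == "PYR", ]
  expect_true(all(rs_pyr$comp == "soma"))
  expect_true(all(table(paste(rs_pyr$pre, rs_pyr$post)) == 15))
  fs_pyr <- s[typ[as.character(s$pre)] == "FS" &
                typ[as.character(s$post)] == "PYR", ]
  expect_true(all(fs_pyr$comp == "distal"))
  expect_true(all(table(paste(fs_pyr$pre, fs_pyr$post)) == 12))
})

test_that("background noise is Poisson with the IS rate elevated", {
  net <- build_network(network_spec(
    seed = 8, noise = list(rate = 0.02, rate_is = 0.035, unit = "per_ms",
                           amp = 0.1, tau = 2)))
  nz <- background_noise_sources(net, seed = 11, duration = 50000)
  # dispersion index of counts in 50 ms windows for one neuron
  t1 <- nz$time[nz$cell == 1]
  counts <- tabulate(findInterval(t1, seq(0, 50000, by = 50)), nbins = 1000)
  disp <- stats::var(counts) / mean(counts)
  expect_lt(abs(disp - 1), 0.1)
  # IS rate parameter exceeds the others
  rate_by <- tapply(nz$time, nz$cell, length) / 50
  is_id <- net$populations$neuron[net$populations$cell_type == "IS"]
  expect_gt(rate_by[as.character(is_id)], mean(rate_by[as.character(1:16)]))
  # zero rate -> no events
  net0 <- build_network(network_spec(
    seed = 8, noise = list(rate = 0, rate_is = 0, unit = "per_ms",
                           amp = 0.1, tau = 2)))
  expect_equal(nrow(background_noise_sources(net0, 1, 1000)), 0)
  # reproducible
  expect_identical(background_noise_sources(net, 11, 1000),
                   background_noise_sources(net, 11, 1000))
})

test_that("the network manifest aggregates the edge list", {
  net <- build_network(network_spec(seed = 9))
  man <- network_manifest(net)
  expect_true(all(c("pre", "post", "comp", "receptor", "n", "weight",
                    "mean_latency") %in% names(man)))
  expect_equal(sum(man$n), nrow(net$synapses))
})
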