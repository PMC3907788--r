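# Configuration serialization, spike-train persistence, experiment
# manifests and the reproducible experiment runner.

ratio_fields <- c("nmda_ampa_pyr", "nmda_ampa_fs", "nmda_ampa_rs",
                  "nmda_ampa_is", "gabab_gabaa", "rs_pyr_gabaa_scale",
                  "is_pyr_gabaa_scale")

#' Serialize a network specification to YAML
#'
#' Round-trips losslessly through [read_network_config()].
#'
#' @param spec A [network_spec()].
#' @param path Output file path.
#' @export
write_network_config <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  obj <- list(
    ratios = unclass(spec$ratios)[ratio_fields],
    manipulation = Filter(Negate(is.null), unclass(spec$manipulation)),
    seed = spec$seed,
    weights = spec$weights,
    noise = spec$noise,
    populations = list(n_pyr = spec$n_pyr, n_fs = spec$n_fs,
                       n_rs = spec$n_rs, n_is = spec$n_is)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a network specification from YAML
#' @param path File written by [write_network_config()].
#' @return A [network_spec()].
#' @export
read_network_config <- function(path) {
  obj <- yaml::read_yaml(path)
  network_spec(
    ratios = do.call(ratio_config, obj$ratios),
    manipulation = do.call(manipulation_spec, obj$manipulation),
    seed = obj$seed,
    weights = obj$weights,
    noise = obj$noise,
    n_pyr = obj$populations$n_pyr, n_fs = obj$populations$n_fs,
    n_rs = obj$populations$n_rs, n_is = obj$populations$n_is
  )
}

#' Write spike trains as delimited text
#'
#' Plain comma-separated `neuron,time` rows preceded by `#`-prefixed
#' metadata header lines; round-trips through [read_spike_trains()].
#'
#' @param st A [spike_train_set()].
#' @param path Output path.
#' @export
write_spike_trains <- function(st, path) {
  stopifnot(inherits(st, "spike_train_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# condition: %s", st$condition),
    sprintf("# seed: %s", st$seed),
    sprintf("# duration_ms: %s", format(st$duration, digits = 15)),
    "neuron,time"), con)
  writeLines(sprintf("%d,%s", st$spikes$neuron,
                     format(st$spikes$time, digits = 15, trim = TRUE,
                            scientific = FALSE)), con)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#' @param path File path.
#' @return A [spike_train_set()].
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body)
  spike_train_set(tibble(neuron = as.integer(df$neuron),
                         time = as.numeric(df$time)),
                  duration = as.numeric(meta("duration_ms")),
                  seed = suppressWarnings(as.integer(meta("seed"))),
                  condition = meta("condition"))
}

#' Experiment manifest
#'
#' A fully serializable description of a sweep: network spec, stimulus,
#' criterion, the ratio grid, trial count and base seed. Re-running an
#' archived manifest reproduces all outputs.
#'
#' @param network A [network_spec()].
#' @param stimulus A [stimulus_spec()].
#' @param criterion An [induction_criterion()].
#' @param nmda_ampa,gabab_gabaa Ratio grids.
#' @param n_trials Trials per condition.
#' @param base_seed Base seed.
#' @param out_dir Output bundle directory.
#' @export
experiment_manifest <- function(network = network_spec(),
                                stimulus = stimulus_spec(),
                                criterion = induction_criterion(),
                                nmda_ampa = 1.25, gabab_gabaa = 0.2,
                                n_trials = 10L, base_seed = 1L,
                                out_dir = "pfcmicro-run") {
  stopifnot(inherits(network, "network_spec"),
            inherits(stimulus, "stimulus_spec"),
            inherits(criterion, "induction_criterion"), n_trials >= 1)
  structure(list(network = network, stimulus = stimulus,
                 criterion = criterion, nmda_ampa = nmda_ampa,
                 gabab_gabaa = gabab_gabaa, n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed), out_dir = out_dir),
            class = "experiment_manifest")
}

#' Write / read an experiment manifest
#' @param manifest An [experiment_manifest()].
#' @param path YAML path.
#' @export
write_manifest <- function(manifest, path) {
  obj <- list(
    network = yaml::yaml.load(yaml::as.yaml(list(
      ratios = unclass(manifest$network$ratios)[ratio_fields],
      manipulation = Filter(Negate(is.null),
                            unclass(manifest$network$manipulation)),
      seed = manifest$network$seed,
      weights = manifest$network$weights,
      noise = manifest$network$noise,
      populations = list(n_pyr = manifest$network$n_pyr,
                         n_fs = manifest$network$n_fs,
                         n_rs = manifest$network$n_rs,
                         n_is = manifest$network$n_is)))),
    stimulus = unclass(manifest$stimulus),
    criterion = unclass(manifest$criterion),
    nmda_ampa = manifest$nmda_ampa,
    gabab_gabaa = manifest$gabab_gabaa,
    n_trials = manifest$n_trials,
    base_seed = manifest$base_seed,
    out_dir = manifest$out_dir
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  net <- network_spec(
    ratios = do.call(ratio_config, obj$network$ratios),
    manipulation = do.call(manipulation_spec, obj$network$manipulation),
    seed = obj$network$seed, weights = obj$network$weights,
    noise = obj$network$noise,
    n_pyr = obj$network$populations$n_pyr,
    n_fs = obj$network$populations$n_fs,
    n_rs = obj$network$populations$n_rs,
    n_is = obj$network$populations$n_is)
  stim <- do.call(stimulus_spec,
                  obj$stimulus[setdiff(names(obj$stimulus), "weight")])
  stim$weight <- obj$stimulus$weight
  experiment_manifest(network = net, stimulus = stim,
                      criterion = do.call(induction_criterion,
                                          obj$criterion),
                      nmda_ampa = obj$nmda_ampa,
                      gabab_gabaa = obj$gabab_gabaa,
                      n_trials = obj$n_trials, base_seed = obj$base_seed,
                      out_dir = obj$out_dir)
}

#' Run an experiment manifest
#'
#' Executes every (condition, trial) cell of the manifest, writing a
#' self-contained bundle: the manifest copy, per-trial spike-train tables,
#' a long-format results table, the probability map, and a log with
#' per-trial seeds. Trials whose spike-train file already exists are
#' skipped, so interrupted runs resume where they stopped.
#'
#' @param manifest An [experiment_manifest()].
#' @param quiet Suppress progress output.
#' @return The results tibble, invisibly; the bundle lands in
#'   `manifest$out_dir`.
#' @export
run_manifest <- function(manifest, quiet = FALSE) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(manifest$out_dir, "spikes"), showWarnings = FALSE)
  write_manifest(manifest, file.path(manifest$out_dir, "manifest.yaml"))
  logf <- file.path(manifest$out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  grid <- tidyr::expand_grid(nmda_ampa = manifest$nmda_ampa,
                             gabab_gabaa = manifest$gabab_gabaa)
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    sp <- manifest$network
    sp$ratios$nmda_ampa_pyr <- grid$nmda_ampa[gi]
    sp$ratios$gabab_gabaa <- grid$gabab_gabaa[gi]
    for (tr in seq_len(manifest$n_trials)) {
      seed <- manifest$base_seed + 1009L * gi + tr
      tag <- sprintf("g%02d_t%02d_s%d", gi, tr, seed)
      spf <- file.path(manifest$out_dir, "spikes", paste0(tag, ".csv"))
      if (file.exists(spf)) {
        st <- read_spike_trains(spf)
        ep <- analysis_epochs(manifest$stimulus, st$duration)
        out <- list(spikes = st, induced = NA)
        logline("skip %s (exists)", tag)
      } else {
        out <- run_induction_trial(sp, manifest$stimulus,
                                   manifest$criterion, seed = seed)
        write_spike_trains(out$spikes, spf)
        logline("run %s induced=%s", tag, out$induced)
      }
      ep <- analysis_epochs(manifest$stimulus, out$spikes$duration)
      pyr_ids <- seq_len(manifest$network$n_pyr)
      rate <- nrow(out$spikes$spikes[out$spikes$spikes$neuron %in% pyr_ids &
                     out$spikes$spikes$time >= ep$persistent[1], ]) /
        manifest$network$n_pyr / (diff(ep$persistent) / 1000)
      induced <- if (is.na(out$induced)) {
        w0 <- stimulus_end(manifest$stimulus) +
          manifest$criterion$window_start
        w1 <- w0 + manifest$criterion$window_length
        cnt <- vapply(pyr_ids, function(n)
          sum(out$spikes$spikes$neuron == n &
                out$spikes$spikes$time >= w0 &
                out$spikes$spikes$time <= w1), numeric(1))
        mean(cnt / (manifest$criterion$window_length / 1000) >=
               manifest$criterion$min_rate) >=
          manifest$criterion$min_fraction
      } else out$induced
      rows[[length(rows) + 1]] <- tibble(
        nmda_ampa = grid$nmda_ampa[gi], gabab_gabaa = grid$gabab_gabaa[gi],
        trial = tr, seed = seed, induced = induced,
        persistent_rate = rate)
      if (!quiet) message(sprintf("[%s] induced=%s", tag, induced))
    }
  }
  results <- dplyr::bind_rows(rows)
  utils::write.csv(results, file.path(manifest$out_dir, "results.csv"),
                   row.names = FALSE)
  pmap <- results |>
    dplyr::group_by(.data$nmda_ampa, .data$gabab_gabaa) |>
    dplyr::summarise(probability = mean(.data$induced),
                     n_trials = dplyr::n(), .groups = "drop")
  utils::write.csv(pmap, file.path(manifest$out_dir, "probability_map.csv"),
                   row.names = FALSE)
  invisible(results)
}
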