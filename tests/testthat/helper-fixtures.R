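# Shared fixtures, all generated in code.

# Small single-chromosome genome for fast unit tests.
tiny_genome <- function(length = 2e5, spacing = 300) {
  genome_spec(chrom_lengths = c(chrT = length), probe_spacing = spacing)
}

# Scenario with a handful of hotspots and configurable noise; zero noise and
# unit gains by default so identities hold exactly.
tiny_scenario <- function(intensity = c(10, 50, 120), effects = NULL,
                          de_novo = NULL, width = 1200, seed = 42,
                          kernel_shape = "gaussian", replicate_sigma = 0,
                          condition_sigma = 0, probe_sigma = 0,
                          gain_range = c(1, 1), n_replicate_pairs = 2) {
  n <- length(intensity)
  centers <- seq(4e4, 1.6e5, length.out = n)
  hs <- data.frame(
    chrom = "chrT",
    start = round(centers - width / 2),
    end = round(centers + width / 2),
    intensity = intensity
  )
  build_scenario(
    tiny_genome(), hs, effects = effects, de_novo = de_novo,
    replicate_sigma = replicate_sigma, condition_sigma = condition_sigma,
    probe_sigma = probe_sigma, gain_range = gain_range,
    kernel_shape = kernel_shape, n_replicate_pairs = n_replicate_pairs,
    seed = seed
  )
}

# Probe table with given IP/WCE ratios on a uniform grid (wce = 1).
probes_from_ratios <- function(ratios, spacing = 300) {
  n <- length(ratios)
  data.frame(
    chrom = rep("chrT", n), start = (seq_len(n) - 1) * spacing,
    end = seq_len(n) * spacing, ip = ratios, wce = rep(1, n)
  )
}

# One full run of the study-emulation scenario through the array pipeline,
# cached per seed because several test files look at the same run.
.preset_cache <- new.env(parent = emptyenv())
preset_pipeline_run <- function(seed = 20131001) {
  key <- as.character(seed)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  sc <- scenario_preset("paper-emulation", seed = seed)
  arrs <- simulate_all_arrays(sc)
  cfg <- pipeline_config(
    arrays = data.frame(name = names(arrs), condition = sc$arrays$condition,
                        pair = sc$arrays$pair),
    probes = arrs,
    intervals = scenario_truth(sc)[, c("chrom", "start", "end", "name")],
    calibration = sc$southern, refset = sc$refset, seed = seed
  )
  out <- list(scenario = sc, truth = scenario_truth(sc),
              result = run_pipeline(cfg))
  .preset_cache[[key]] <- out
  out
}

# Bivariate Gaussian null comparison data on the log scale.
null_comparison <- function(n = 288, rho = 0.8) {
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  list(x = 10^x, y = 10^y)
}
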