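test_that("scenario construction is deterministic and validates its inputs", {
  sc1 <- tiny_scenario(seed = 7, condition_sigma = 0.1, probe_sigma = 0.05)
  sc2 <- tiny_scenario(seed = 7, condition_sigma = 0.1, probe_sigma = 0.05)
  expect_identical(sc1$hotspots, sc2$hotspots)
  expect_identical(sc1$arrays, sc2$arrays)
  expect_identical(sc1$southern, sc2$southern)

  # zero hotspots: valid scenario with a flat truth track
  flat <- build_scenario(tiny_genome(),
                         data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), intensity = numeric()),
                         replicate_sigma = 0, condition_sigma = 0,
                         probe_sigma = 0, seed = 1)
  expect_equal(nrow(scenario_truth(flat)), 0)
  arr <- simulate_array_pair(flat, "A", 1)
  expect_equal(arr$ip / arr$wce, rep(1, nrow(arr)))

  hs <- data.frame(chrom = "chrT", start = c(100, 500), end = c(600, 900),
                   intensity = c(10, 10))
  expect_error(build_scenario(tiny_genome(), hs, seed = 1), "overlap")
  hs2 <- data.frame(chrom = "chrT", start = 100, end = 600, intensity = 10)
  expect_error(build_scenario(tiny_genome(), hs2, effects = c(2, 3), seed = 1),
               "length")
  expect_error(build_scenario(tiny_genome(), hs2, effects = -1, seed = 1),
               "> 0")
  expect_error(build_scenario(tiny_genome(), hs2, seed = 1,
                              replicate_sigma = -0.1), ">= 0")
})

test_that("study-emulation preset plants the documented truth", {
  sc <- scenario_preset("paper-emulation", seed = 11)
  truth <- scenario_truth(sc)
  expect_equal(nrow(truth), 288)
  expect_equal(sum(truth$class_truth == "increased"), 11)
  expect_equal(sum(truth$class_truth == "decreased"), 6)
  expect_equal(sum(truth$class_truth == "de_novo"), 1)
  expect_true(all(truth$intensity >= 1 & truth$intensity <= 400))
  expect_true(all(truth$effect[truth$class_truth == "increased"] >= 2 &
                    truth$effect[truth$class_truth == "increased"] <= 5))
  expect_true(all(truth$effect[truth$class_truth == "decreased"] >= 1 / 10 &
                    truth$effect[truth$class_truth == "decreased"] <= 1 / 3))
  expect_equal(truth$effect[truth$de_novo], 0)
  expect_equal(length(sc$refset), 6)
  expect_true(all(sc$refset %in% truth$name[truth$class_truth == "unchanged"]))
  expect_equal(nrow(sc$southern), 25)
})

test_that("array simulation is seeded and noiseless ratios equal planted enrichment", {
  sc <- tiny_scenario(intensity = 10, kernel_shape = "rect")
  a1 <- simulate_array_pair(sc, "A", 1)
  a2 <- simulate_array_pair(sc, "A", 1)
  expect_identical(a1, a2)

  hs <- scenario_truth(sc)
  mid <- (a1$start + a1$end) / 2
  inside <- mid >= hs$start & mid < hs$end
  expect_equal(a1$ip[inside] / a1$wce[inside], rep(10, sum(inside)))
  expect_equal(a1$ip[!inside] / a1$wce[!inside], rep(1, sum(!inside)))
})

test_that("noiseless integrated signal matches brute-force probe summation", {
  sc <- tiny_scenario(intensity = c(15, 80))
  arr <- simulate_array_pair(sc, "B", 1)
  prof <- normalize_profile(arr)
  truth <- scenario_truth(sc)
  tab <- integrate_hotspots(prof, truth[, c("chrom", "start", "end", "name")])
  # independent brute-force oracle over raw probes
  mid <- (arr$start + arr$end) / 2
  raw <- arr$ip / arr$wce
  raw <- raw / median(raw)
  for (k in seq_len(nrow(truth))) {
    sel <- mid >= truth$start[k] & mid < truth$end[k]
    oracle <- sum(pmax(raw[sel] - 1, 0) * (arr$end[sel] - arr$start[sel]))
    expect_equal(tab$integrated_signal[k], oracle, tolerance = 1e-12)
  }
})

test_that("replicate noise is calibrated to the r = 0.98 regime", {
  rs <- vapply(1:6, function(s) {
    sc <- scenario_preset("paper-emulation", seed = 100 + s)
    iv <- scenario_truth(sc)[, c("chrom", "start", "end", "name")]
    sig <- vapply(1:2, function(p) {
      integrate_hotspots(normalize_profile(simulate_array_pair(sc, "A", p)),
                         iv)$integrated_signal
    }, numeric(288))
    stats::cor(log10(sig[, 1]), log10(sig[, 2]))
  }, numeric(1))
  expect_true(all(rs >= 0.95 & rs <= 1.0))
})

test_that("lane time courses follow the kinetic model", {
  kin <- gel_kinetics(dsb_onset = 5, dsb_peak = 6.5, repair_end = 8,
                      max_broken = c(dsb1 = 0.05),
                      fragment_sizes = c(parental = 24, dsb1 = 12))
  lanes <- simulate_lane_timecourse(kin, c(3, 6.5, 9))
  # before onset: a single parental band, zero broken
  expect_equal(quantify_lane(lanes[[1]])$broken_pct, 0, tolerance = 1e-9)
  # at peak: planted 0.05 recovered to ~1e-6 relative
  expect_equal(quantify_lane(lanes[[2]])$broken_pct, 5, tolerance = 1e-5)
  # after repair completes
  expect_equal(quantify_lane(lanes[[3]])$broken_pct, 0, tolerance = 1e-9)

  kinS <- gel_kinetics(dsb_onset = 3, dsb_peak = 5, repair_end = 5,
                       rad50S = TRUE, max_broken = c(dsb1 = 0.08),
                       fragment_sizes = c(parental = 24, dsb1 = 12))
  broken <- vapply(simulate_lane_timecourse(kinS, c(0, 3, 4, 5)),
                   function(l) quantify_lane(l)$broken_pct, numeric(1))
  expect_false(is.unsorted(broken))
  expect_error(gel_kinetics(fragment_sizes = c(parental = -1, dsb1 = 2),
                            max_broken = c(dsb1 = 0.1)), "> 0")
  expect_error(simulate_lane_timecourse(kin, c(5, 3)), "sorted")
})

test_that("2D gel simulation conserves planted spot volumes", {
  one <- data.frame(name = "only", role = "IS", x = 0.5, y = 0.5, volume = 1)
  g <- simulate_2d_gel(one, noise_sigma = 0)
  q <- quantify_2d_spots(g)
  expect_equal(q$spots$raw_fraction, 1, tolerance = 1e-8)

  two <- data.frame(name = c("a", "b"), role = c("IS", "IH_small"),
                    x = c(0.3, 0.7), y = c(0.3, 0.7), volume = c(0.6, 0.4))
  g2 <- simulate_2d_gel(two, noise_sigma = 0)
  # brute-force pixel summation oracle
  total <- sum(g2$intensity)
  for (i in 1:2) {
    w <- g2$windows[i, ]
    ix <- g2$coords >= w$x0 & g2$coords <= w$x1
    iy <- g2$coords >= w$y0 & g2$coords <= w$y1
    expect_equal(sum(g2$intensity[ix, iy]) / total, two$volume[i],
                 tolerance = 1e-8)
  }
  expect_error(
    simulate_2d_gel(data.frame(name = "a", role = "IS", x = .5, y = .5,
                               volume = 1.2)), "sum")
})

test_that("mbs1 preset plants a 3:1 IS:IH ratio and HJ:NS of 1.3", {
  sp <- two_d_spot_preset("mbs1-25C")
  is_vol <- sp$volume[sp$role == "IS"]
  ih_vol <- sum(sp$volume[sp$role %in% c("IH_small", "IH_large")])
  expect_equal(is_vol / ih_vol, 3)
  expect_equal(is_vol + ih_vol, 0.021)
  expect_equal((is_vol + ih_vol) / sp$volume[sp$role == "NS"], 1.3,
               tolerance = 1e-12)
})

test_that("cross simulation follows the binomial model at the planted distance", {
  expect_equal(simulate_cross(true_distance_cM = 0, n_spores = 1e5,
                              seed = 3)$recombinants, 0)
  # closed-form inverse Haldane at 16 cM: R = (1 - exp(-0.32)) / 2
  R <- (1 - exp(-16 / 50)) / 2
  fr <- vapply(1:200, function(s) {
    simulate_cross(true_distance_cM = 16, n_spores = 1e4,
                   seed = s)$recombinants / 1e4
  }, numeric(1))
  se <- sqrt(R * (1 - R) / 1e4 / 200)
  expect_lt(abs(mean(fr) - R), 3 * se)

  counts <- vapply(1:100, function(s) {
    simulate_cross(freq_per_1e6 = 1200, n_spores = 1e6, seed = 1000 + s
                   )$recombinants
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1200), 3 * sqrt(1200 / 100))
  cc <- simulate_cross(freq_per_1e6 = 1200, n_spores = 1e6, seed = 5)
  expect_equal(cc$frequency, 1e6 * cc$recombinants / cc$total)
})
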