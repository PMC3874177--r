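test_that("median normalization divides out the genome median", {
  p <- probes_from_ratios(rep(2.5, 11))
  prof <- normalize_profile(p)
  expect_equal(prof$probes$ratio, rep(1, 11))
  expect_equal(prof$probes$log_ratio, rep(0, 11))

  p2 <- probes_from_ratios(c(1, 2, 4))
  prof2 <- normalize_profile(p2)
  expect_equal(prof2$probes$ratio, c(0.5, 1, 2))

  # idempotence: renormalizing an already-normalized profile changes nothing
  p3 <- probes_from_ratios(prof2$probes$ratio)
  expect_equal(normalize_profile(p3)$probes$ratio, prof2$probes$ratio,
               tolerance = 1e-13)

  bad <- probes_from_ratios(c(1, 2, 3))
  bad$wce[2] <- 0
  expect_error(normalize_profile(bad), "probe 2")
  expect_error(normalize_profile(probes_from_ratios(numeric(0))), "empty")
})

test_that("scale factor recovers planted log-scale compression", {
  sc <- tiny_scenario(intensity = c(20, 60, 150, 300))
  ref <- normalize_profile(simulate_array_pair(sc, "B", 1))
  refset <- scenario_truth(sc)[1:3, c("chrom", "start", "end", "name")]
  expect_equal(fit_scale_factor(ref, ref, refset), 1)

  compress <- function(profile, g) {
    profile$probes$log_ratio <- profile$probes$log_ratio * g
    profile$probes$ratio <- 10^profile$probes$log_ratio
    profile
  }
  expect_equal(fit_scale_factor(compress(ref, 1 / 1.2), ref, refset), 1.2,
               tolerance = 1e-9)
  # recovery within 1% for any planted factor in [0.5, 2]
  for (cf in c(0.5, 0.8, 1.1, 1.5, 2)) {
    got <- suppressWarnings(fit_scale_factor(compress(ref, 1 / cf), ref, refset))
    expect_equal(got, cf, tolerance = 0.01)
  }
  expect_warning(fit_scale_factor(compress(ref, 1 / 1.8), ref, refset),
                 "outside")
  zero <- ref
  zero$probes$log_ratio[] <- 0
  expect_error(fit_scale_factor(zero, ref, refset), "all-zero")
})

test_that("hotspot integration sums above-baseline ratio times probe width", {
  flat <- normalize_profile(probes_from_ratios(rep(1, 40)))
  iv <- data.frame(chrom = "chrT", start = c(0, 6000), end = c(3000, 9000),
                   name = c("a", "b"))
  expect_equal(integrate_hotspots(flat, iv)$integrated_signal, c(0, 0))

  # rectangular peak: ratio 11 over 3 probes of 300 bp -> 10 * 900 = 9000
  ratios <- rep(1, 41)
  ratios[10:12] <- 11
  prof <- normalize_profile(probes_from_ratios(ratios))
  peak <- data.frame(chrom = "chrT", start = 2700, end = 3600, name = "pk")
  expect_equal(integrate_hotspots(prof, peak)$integrated_signal, 9000)

  # linearity: doubling the above-baseline ratio doubles the signal
  ratios2 <- rep(1, 41)
  ratios2[10:12] <- 21
  prof2 <- normalize_profile(probes_from_ratios(ratios2))
  expect_equal(integrate_hotspots(prof2, peak)$integrated_signal, 18000)

  empty <- data.frame(chrom = "chrT", start = 2701, end = 2702, name = "none")
  expect_warning(tab <- integrate_hotspots(prof, empty), "no probe")
  expect_true(is.na(tab$integrated_signal))
  expect_error(integrate_hotspots(prof, peak[c(1, 1), ]), "overlap")
})

test_that("integration tracks planted truth across the emulation scenario", {
  sc <- tiny_scenario(intensity = c(12, 30, 70, 140, 280), seed = 9)
  prof <- normalize_profile(simulate_array_pair(sc, "B", 1))
  truth <- scenario_truth(sc)
  tab <- integrate_hotspots(prof, truth[, c("chrom", "start", "end", "name")])
  expect_gt(stats::cor(tab$integrated_signal, truth$true_signal), 0.9999)
})

test_that("breakage calibration fits a through-origin line and applies the threshold", {
  tab <- data.frame(name = paste0("h", 1:25), chrom = "chrT",
                    start = 1:25, end = 2:26,
                    integrated_signal = seq(500, 40000, length.out = 25))
  pairs <- data.frame(name = tab$name,
                      percent_broken = 0.001 * tab$integrated_signal)
  cal <- calibrate_breakage(tab, pairs)
  expect_equal(cal$model$slope, 0.001)
  expect_equal(cal$model$n_pairs, 25)
  expect_equal(cal$table$percent_breakage, 0.001 * tab$integrated_signal)
  expect_identical(cal$table$passes_threshold,
                   cal$table$percent_breakage > 0.3)

  # 5% multiplicative noise on 25 pairs: slope recovered within 5%
  noisy <- pairs
  withr::with_seed(21, {
    noisy$percent_broken <- noisy$percent_broken * exp(rnorm(25, 0, 0.05))
  })
  expect_equal(calibrate_breakage(tab, noisy)$model$slope, 0.001,
               tolerance = 0.05)

  expect_error(calibrate_breakage(tab, pairs[1, , drop = FALSE]),
               "at least 2")
  neg <- pairs
  neg$percent_broken <- -neg$percent_broken
  expect_error(calibrate_breakage(tab, neg), "slope")
})
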