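test_that("perfect agreement gives r = 1 and no outliers", {
  x <- 10^seq(1, 3, length.out = 10)
  fit <- fit_comparison(x, x)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$residual_sd, 0)
  expect_equal(fit$slope, 1)
  calls <- classify_outliers(fit)
  expect_true(all(calls$class == "unchanged"))
})

test_that("fit_comparison validates its inputs", {
  expect_error(fit_comparison(1:2, 1:2), "at least 3")
  expect_error(fit_comparison(c(1, 2, NA), c(1, 2, 3)), "non-finite")
  expect_error(fit_comparison(rep(5, 4), 1:4, log10 = FALSE), "variance")
  expect_error(fit_comparison(c(0, 1, 2), c(1, 2, 3)), "de novo")
})

test_that("a grossly displaced point is called increased", {
  withr::with_seed(5, {
    x <- 10^rnorm(50, 2, 0.5)
    y <- x * 10^rnorm(50, 0, 0.05)
  })
  y[7] <- y[7] * 10^(10 * 0.05)
  fit <- fit_comparison(x, y)
  calls <- classify_outliers(fit)
  expect_equal(calls$class[7], "increased")
})

test_that("95% prediction interval has ~5% outside rate on Gaussian nulls", {
  withr::with_seed(1234, {
    frac <- vapply(1:200, function(i) {
      d <- null_comparison(288)
      calls <- classify_outliers(fit_comparison(d$x, d$y))
      mean(calls$class != "unchanged")
    }, numeric(1))
  })
  expect_lt(abs(mean(frac) - 0.05), 0.01)
  # n = 288: expected outliers ~ 14 per comparison
  expect_true(mean(frac) * 288 > 11 && mean(frac) * 288 < 17)
})

test_that("swapping the axes swaps call direction and preserves r", {
  withr::with_seed(8, {
    x <- 10^rnorm(60, 2, 0.4)
    y <- x * 10^rnorm(60, 0, 0.03)
  })
  y[3] <- y[3] * 8   # up in y orientation
  y[9] <- y[9] / 8   # down in y orientation
  f1 <- fit_comparison(x, y)
  f2 <- fit_comparison(y, x)
  expect_equal(f1$pearson_r, f2$pearson_r)
  c1 <- classify_outliers(f1)
  c2 <- classify_outliers(f2)
  expect_equal(c1$class[3], "increased")
  expect_equal(c2$class[3], "decreased")
  expect_equal(c1$class[9], "decreased")
  expect_equal(c2$class[9], "increased")
})

test_that("raising a hotspot's y can only move it toward increased", {
  withr::with_seed(13, d <- null_comparison(100))
  base <- classify_outliers(fit_comparison(d$x, d$y))
  i <- which(base$class == "unchanged")[1]
  rank_of <- c(decreased = 1, unchanged = 2, increased = 3)
  prev <- rank_of[[base$class[i]]]
  for (mult in c(2, 5, 1000)) {
    y2 <- d$y
    y2[i] <- y2[i] * mult
    now <- rank_of[[classify_outliers(fit_comparison(d$x, y2))$class[i]]]
    expect_gte(now, prev)
    prev <- now
  }
  expect_equal(prev, 3)
})

test_that("reproducible calls are the same-direction intersection", {
  withr::with_seed(2, d <- null_comparison(50))
  calls <- classify_outliers(fit_comparison(d$x, d$y))
  rep2 <- intersect_reproducible(list(calls, calls))
  expect_setequal(rep2$increased, calls$name[calls$class == "increased"])
  expect_setequal(rep2$decreased, calls$name[calls$class == "decreased"])
  expect_error(intersect_reproducible(list(calls)), "at least 2")
  other <- calls
  other$name <- paste0(other$name, "_x")
  expect_error(intersect_reproducible(list(calls, other)), "universe")

  # two independent nulls: expected reproducible calls well below 1
  withr::with_seed(99, {
    n_rep <- vapply(1:20, function(i) {
      a <- null_comparison(288)
      b <- null_comparison(288)
      ra <- classify_outliers(fit_comparison(a$x, a$y))
      rb <- classify_outliers(fit_comparison(b$x, b$y))
      out <- intersect_reproducible(list(ra, rb))
      length(out$increased) + length(out$decreased)
    }, numeric(1))
  })
  expect_lt(mean(n_rep), 1.5)
})

test_that("de novo detection applies the half-threshold guard band", {
  tab <- data.frame(name = c("a", "b", "c"),
                    percent_breakage = c(2.0, 0.8, 0.25))
  expect_equal(detect_de_novo(tab, tab), character(0))
  tabB <- tab
  tabB$percent_breakage <- c(0.05, 0.8, 0.25)
  expect_equal(detect_de_novo(tab, tabB), "a")
  # B just under threshold but above the guard band: not de novo
  tabB2 <- tab
  tabB2$percent_breakage <- c(0.2, 0.8, 0.25)
  expect_equal(detect_de_novo(tab, tabB2), character(0))
  expect_error(detect_de_novo(tab, tab[c(2, 1, 3), ]), "universe")
})

test_that("planted >= 2-fold effects are fully recovered at low noise", {
  hits <- vapply(1:5, function(s) {
    intensity <- round(10^seq(1, 2.5, length.out = 30))
    effects <- rep(1, 30)
    effects[c(5, 12, 24)] <- c(2, 0.5, 2)
    sc <- tiny_scenario(
      intensity = intensity, effects = effects,
      replicate_sigma = 0.01, condition_sigma = 0.01, probe_sigma = 0.02,
      seed = 300 + s
    )
    iv <- scenario_truth(sc)[, c("chrom", "start", "end", "name")]
    calls <- lapply(1:2, function(p) {
      x <- integrate_hotspots(
        normalize_profile(simulate_array_pair(sc, "B", p)), iv)
      y <- integrate_hotspots(
        normalize_profile(simulate_array_pair(sc, "A", p)), iv)
      classify_outliers(fit_comparison(x$integrated_signal,
                                       y$integrated_signal, names = x$name))
    })
    rep2 <- intersect_reproducible(calls)
    truth <- scenario_truth(sc)
    setequal(rep2$increased, truth$name[truth$effect > 1]) &&
      setequal(rep2$decreased, truth$name[truth$effect < 1])
  }, logical(1))
  expect_true(all(hits))
})
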