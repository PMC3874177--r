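#' Genome layout for simulated tiling arrays
#'
#' Defines chromosome lengths and the regular probe spacing of the simulated
#' tiling array.  The desk scale (default) is a three-chromosome ~2.4 Mb
#' genome giving ~8,000 probes at 300 bp spacing; the full scale mirrors the
#' three fission-yeast chromosomes (~12.57 Mb) at 285 bp spacing, ~44,000
#' probes.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param probe_spacing probe spacing in bp (> 0).
#' @param scale shortcut preset, `"desk"` or `"full"`; ignored when
#'   `chrom_lengths` is supplied.
#' @return An object of class `dsb_genome`: list with `chrom_lengths`,
#'   `probe_spacing` and the per-chromosome probe counts.
#' @export
genome_spec <- function(chrom_lengths = NULL, probe_spacing = NULL,
                        scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- switch(scale,
      desk = c(chrI = 1e6, chrII = 8e5, chrIII = 6e5),
      full = c(chrI = 5.58e6, chrII = 4.54e6, chrIII = 2.45e6)
    )
    if (is.null(probe_spacing)) {
      probe_spacing <- switch(scale, desk = 300, full = 285)
    }
  }
  if (is.null(probe_spacing)) probe_spacing <- 300
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (probe_spacing <= 0) stop("probe_spacing must be > 0")
  structure(
    list(
      chrom_lengths = chrom_lengths,
      probe_spacing = probe_spacing,
      n_probes = floor(chrom_lengths / probe_spacing)
    ),
    class = "dsb_genome"
  )
}

#' Probe intervals of a simulated genome
#'
#' @param genome a `dsb_genome`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
probe_intervals <- function(genome) {
  stopifnot(inherits(genome, "dsb_genome"))
  sp <- genome$probe_spacing
  out <- lapply(names(genome$chrom_lengths), function(ch) {
    n <- genome$n_probes[[ch]]
    data.frame(
      chrom = rep(ch, n),
      start = (seq_len(n) - 1L) * sp,
      end = seq_len(n) * sp,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

.check_no_overlap <- function(hotspots) {
  for (ch in unique(hotspots$chrom)) {
    h <- hotspots[hotspots$chrom == ch, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    if (nrow(h) > 1 && any(h$start[-1] < h$end[-nrow(h)])) {
      stop("overlapping hotspot intervals on ", ch)
    }
  }
  invisible(TRUE)
}

#' Assemble a simulation scenario with planted truth
#'
#' Combines a genome, hotspot intervals with true enrichment intensities,
#' and per-hotspot condition effects into a scenario from which replicate
#' arrays for two conditions (A, the 25 degree analog; B, the 34 degree
#' baseline) can be simulated.  All random draws (condition-difference
#' deviations at unchanged hotspots, per-array log gains, Southern-blot
#' calibration pairs) are made here under `seed`, so the scenario object is
#' fully deterministic and the planted truth is retrievable from it.
#'
#' Noise model, on the log10 scale of integrated hotspot signal:
#' unchanged hotspots carry a condition deviation `v ~ U(-sqrt(3)*s, sqrt(3)*s)`
#' with `s = condition_sigma`, fixed across replicate inductions (so replicate
#' correlation stays near 0.98 while cross-condition correlation drops to
#' ~0.8); each simulated array adds an independent per-hotspot Gaussian
#' deviation with SD `replicate_sigma` and per-probe log-normal noise with SD
#' `probe_sigma`.
#'
#' @param genome a `dsb_genome`.
#' @param hotspots data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `intensity` (enrichment fold over background, >= 1);
#'   optional `name`.
#' @param effects numeric vector, one per hotspot: multiplicative factor
#'   applied to the hotspot amplitude in condition A relative to B.  Must be
#'   > 0 except where `de_novo` is TRUE (recorded as 0).
#' @param de_novo logical vector, one per hotspot: TRUE marks hotspots
#'   present only in condition A (amplitude 0 in B).
#' @param replicate_sigma,condition_sigma,probe_sigma noise SDs in log10
#'   units (see Details).
#' @param n_replicate_pairs number of replicate induction pairs (>= 1).
#' @param gain_range range of the per-array multiplicative log-scale gain
#'   (compression) applied to non-reference arrays; the condition-B pair-1
#'   array always has gain 1 and serves as the natural scaling reference.
#' @param kernel_shape `"gaussian"` (SD = width/4, truncated at 3 SD) or
#'   `"rect"` (flat over the interval).
#' @param calib_slope true percent-breakage per unit of noiseless integrated
#'   signal, used to plant per-hotspot breakage truth.
#' @param n_southern number of Southern-blot calibration pairs drawn from
#'   the planted breakage truth (5% log-normal measurement noise).
#' @param background background IP:WCE ratio level (arbitrary; 1 by default).
#' @param seed integer seed (required; no global RNG state is consumed).
#' @return An object of class `dsb_scenario`.
#' @export
build_scenario <- function(genome, hotspots, effects = NULL, de_novo = NULL,
                           replicate_sigma = 0.03, condition_sigma = 0.11,
                           probe_sigma = 0.05, n_replicate_pairs = 2,
                           gain_range = c(1, 1), kernel_shape = c("gaussian", "rect"),
                           calib_slope = 9.3e-5, n_southern = 25,
                           background = 1, seed) {
  stopifnot(inherits(genome, "dsb_genome"))
  kernel_shape <- match.arg(kernel_shape)
  if (missing(seed)) stop("seed is required")
  n <- nrow(hotspots)
  if (is.null(effects)) effects <- rep(1, n)
  if (is.null(de_novo)) de_novo <- rep(FALSE, n)
  if (length(effects) != n) stop("effects length (", length(effects),
                                 ") does not match hotspot count (", n, ")")
  if (length(de_novo) != n) stop("de_novo length does not match hotspot count")
  if (n > 0) {
    if (any(hotspots$end <= hotspots$start)) stop("hotspot end must exceed start")
    if (any(hotspots$intensity < 1)) stop("hotspot intensity must be >= 1")
    if (any(effects[!de_novo] <= 0)) stop("effects must be > 0 unless flagged de novo")
    .check_no_overlap(hotspots)
  }
  if (any(c(replicate_sigma, condition_sigma, probe_sigma) < 0)) {
    stop("noise SDs must be >= 0")
  }
  if (n_replicate_pairs < 1) stop("n_replicate_pairs must be >= 1")

  if (is.null(hotspots$name)) {
    hotspots$name <- sprintf("hs_%03d", seq_len(max(n, 0)))
  }
  hotspots$effect <- ifelse(de_novo, 0, effects)
  hotspots$de_novo <- de_novo
  hotspots$width <- hotspots$end - hotspots$start
  # noiseless integrated signal in (fold-above-baseline x bp) units
  hotspots$true_signal <- .kernel_area(hotspots, kernel_shape)
  hotspots$true_breakage_B <- ifelse(de_novo, 0, calib_slope * hotspots$true_signal)
  hotspots$true_breakage_A <- calib_slope * hotspots$true_signal *
    ifelse(de_novo, 1, effects)
  hotspots$class_truth <- ifelse(de_novo, "de_novo",
    ifelse(effects > 1, "increased", ifelse(effects < 1, "decreased", "unchanged"))
  )

  arrays <- expand.grid(
    condition = c("B", "A"), pair = seq_len(n_replicate_pairs),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )

  # scaling references: the six most intense unchanged hotspots, emulating
  # prominent hotspots shown by direct Southern blot to be broken to the
  # same extent in both conditions (their condition deviation is zero)
  unchanged <- which(hotspots$class_truth == "unchanged")
  refset <- unchanged[order(hotspots$intensity[unchanged], decreasing = TRUE)]
  refset <- hotspots$name[utils::head(refset, 6)]

  withr::with_seed(seed, {
    a <- sqrt(3) * condition_sigma
    v <- ifelse(hotspots$class_truth == "unchanged" & n > 0 &
                  !(hotspots$name %in% refset),
                stats::runif(max(n, 1), -a, a), 0)
    hotspots$cond_dev <- if (n > 0) v[seq_len(n)] else numeric(0)
    arrays$gain <- stats::runif(nrow(arrays), gain_range[1], gain_range[2])
    arrays$gain[arrays$condition == "B" & arrays$pair == 1] <- 1

    southern <- NULL
    # calibration anchors are hotspots broken to the same extent in both
    # conditions; a condition-specific anchor would tilt the through-origin
    # slope of whichever condition it was not measured in
    cand <- which(hotspots$class_truth == "unchanged")
    if (length(cand) < 2) cand <- which(!hotspots$de_novo)
    if (n > 0 && length(cand) >= 2) {
      take <- if (length(cand) > n_southern) sort(sample(cand, n_southern)) else cand
      southern <- data.frame(
        name = hotspots$name[take],
        percent_broken = hotspots$true_breakage_B[take] *
          exp(stats::rnorm(length(take), 0, 0.05)),
        stringsAsFactors = FALSE
      )
    }
  })

  structure(
    list(
      genome = genome,
      hotspots = hotspots,
      arrays = arrays,
      refset = refset,
      southern = southern,
      params = list(
        replicate_sigma = replicate_sigma,
        condition_sigma = condition_sigma,
        probe_sigma = probe_sigma,
        n_replicate_pairs = n_replicate_pairs,
        gain_range = gain_range,
        kernel_shape = kernel_shape,
        calib_slope = calib_slope,
        background = background
      ),
      seed = seed
    ),
    class = "dsb_scenario"
  )
}

# Noiseless integrated signal of each hotspot: sum over the probe grid of the
# in-interval kernel (fold above baseline) times probe width.  This is the
# quantity integrate_hotspots() recovers exactly at zero noise.
.kernel_area <- function(hotspots, kernel_shape) {
  if (nrow(hotspots) == 0) return(numeric(0))
  amp <- hotspots$intensity - 1
  if (kernel_shape == "rect") {
    return(amp * hotspots$width)
  }
  sdv <- hotspots$width / 4
  # mass of a 3-SD-truncated Gaussian over the +/- 2 SD interval, in bp units
  frac <- stats::pnorm(2) - stats::pnorm(-2)
  amp * sdv * sqrt(2 * pi) * frac
}

#' Packaged emulation scenario for the two-condition hotspot study
#'
#' Builds the default study-emulation scenario: 288 hotspots of log-normal
#' intensity (7- to 400-fold over background) on the desk-scale genome, with
#' 11 hotspots increased 4-5x in condition A, 6 decreased to 1/10-1/5, one
#' de novo hotspot present only in A, and the remainder unchanged; noise SDs
#' calibrated so replicate arrays correlate at r ~ 0.98-0.99 and the
#' cross-condition comparison of all 288 integrated values at r ~ 0.8.
#' Non-reference arrays receive log-scale gains in [1/1.3, 1/1.1], so the
#' fitted rescaling factors fall in the 1.1-1.3 band.
#'
#' @param preset preset name; only `"paper-emulation"` is defined.
#' @param seed integer seed.
#' @param genome optional `dsb_genome` (desk scale by default).
#' @return A `dsb_scenario`.
#' @export
scenario_preset <- function(preset = "paper-emulation", seed, genome = genome_spec()) {
  preset <- match.arg(preset, "paper-emulation")
  if (missing(seed)) stop("seed is required")
  n_hot <- 288L
  lens <- genome$chrom_lengths
  n_per <- round(n_hot * lens / sum(lens))
  n_per[1] <- n_per[1] + (n_hot - sum(n_per))

  hs <- withr::with_seed(seed + 211L, {
    rows <- list()
    for (ch in names(lens)) {
      k <- n_per[[ch]]
      slot <- lens[[ch]] / k
      width <- stats::runif(k, 900, 1800)
      center <- (seq_len(k) - 0.5) * slot + stats::runif(k, -400, 400)
      rows[[ch]] <- data.frame(
        chrom = ch,
        start = round(center - width / 2),
        end = round(center + width / 2),
        stringsAsFactors = FALSE
      )
    }
    hs <- do.call(rbind, rows)
    # log-normal enrichment fold, truncated to [8, 400] by inverse-CDF draw
    lo <- stats::plnorm(8, log(20), 0.75)
    hi <- stats::plnorm(400, log(20), 0.75)
    hs$intensity <- stats::qlnorm(stats::runif(n_hot, lo, hi), log(20), 0.75)
    hs$name <- sprintf("hs_%03d", seq_len(n_hot))

    effects <- rep(1, n_hot)
    de_novo <- rep(FALSE, n_hot)
    # plant differential hotspots among those intense enough that a 10-fold
    # reduction still leaves measurable (> threshold) breakage
    area <- (hs$intensity - 1) * (hs$end - hs$start) / 4 * sqrt(2 * pi) *
      (stats::pnorm(2) - stats::pnorm(-2))
    eligible <- which(area >= 3e4)
    planted <- sample(eligible, 18)
    effects[planted[1:11]] <- exp(stats::runif(11, log(4), log(5)))
    effects[planted[12:17]] <- exp(stats::runif(6, log(0.1), log(0.2)))
    de_novo[planted[18]] <- TRUE
    hs$..effects <- effects
    hs$..de_novo <- de_novo
    hs
  })

  effects <- hs$..effects
  de_novo <- hs$..de_novo
  hs$..effects <- NULL
  hs$..de_novo <- NULL

  build_scenario(
    genome = genome, hotspots = hs, effects = effects, de_novo = de_novo,
    replicate_sigma = 0.03, condition_sigma = 0.12, probe_sigma = 0.03,
    n_replicate_pairs = 2, gain_range = c(1 / 1.28, 1 / 1.12),
    kernel_shape = "gaussian", calib_slope = 1.5e-4, n_southern = 25,
    seed = seed
  )
}

#' Planted truth table of a scenario
#'
#' @param scenario a `dsb_scenario`.
#' @return data.frame of per-hotspot planted parameters.
#' @export
scenario_truth <- function(scenario) {
  stopifnot(inherits(scenario, "dsb_scenario"))
  scenario$hotspots
}
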