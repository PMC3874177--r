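#' Kinetic model for a DSB time-course gel
#'
#' Phenomenological break-and-repair kinetics: each DSB band's fraction of
#' lane DNA rises linearly from `dsb_onset` to its maximum at `dsb_peak`,
#' then (in repair-proficient cells) falls linearly to zero at
#' `repair_end`; in `rad50S` mode breaks are not repaired and the broken
#' fraction stays at its running maximum (non-decreasing in time).
#'
#' @param dsb_onset,dsb_peak,repair_end hours after meiotic induction
#'   (onset < peak <= repair_end).
#' @param max_broken named numeric vector: maximum fraction of lane DNA in
#'   each DSB fragment band (sum < 1).
#' @param fragment_sizes named numeric vector of fragment sizes in kb; must
#'   contain `parental` plus one entry per `max_broken` band.
#' @param rad50S logical; TRUE for the repair-deficient accumulation mode.
#' @param noise_sigma additive intensity noise SD per trace point.
#' @return An object of class `dsb_kinetics`.
#' @export
gel_kinetics <- function(dsb_onset = 5, dsb_peak = 6.5, repair_end = 8,
                         max_broken = c(dsb1 = 0.06, dsb2 = 0.04),
                         fragment_sizes = c(parental = 24, dsb1 = 15, dsb2 = 8),
                         rad50S = FALSE, noise_sigma = 0) {
  if (!(dsb_onset < dsb_peak && dsb_peak <= repair_end)) {
    stop("need dsb_onset < dsb_peak <= repair_end")
  }
  if (any(fragment_sizes <= 0)) stop("fragment sizes must be > 0")
  if (!"parental" %in% names(fragment_sizes)) {
    stop("fragment_sizes must include 'parental'")
  }
  if (!all(names(max_broken) %in% names(fragment_sizes))) {
    stop("every max_broken band needs a fragment size")
  }
  if (any(max_broken < 0) || sum(max_broken) >= 1) {
    stop("band fractions must be in [0,1) and sum to < 1")
  }
  structure(
    list(dsb_onset = dsb_onset, dsb_peak = dsb_peak, repair_end = repair_end,
         max_broken = max_broken, fragment_sizes = fragment_sizes,
         rad50S = rad50S, noise_sigma = noise_sigma),
    class = "dsb_kinetics"
  )
}

.broken_fraction <- function(kin, t) {
  up <- pmin(pmax((t - kin$dsb_onset) / (kin$dsb_peak - kin$dsb_onset), 0), 1)
  if (kin$rad50S || kin$repair_end == kin$dsb_peak) {
    down <- 1
  } else {
    down <- ifelse(t <= kin$dsb_peak, 1,
                   pmin(pmax((kin$repair_end - t) /
                               (kin$repair_end - kin$dsb_peak), 0), 1))
  }
  up * down
}

#' Electrophoretic mobility of a fragment
#'
#' Migration position on the unit lane, a monotone decreasing function of
#' log fragment size: `pos = 1.05 - 0.45 * log10(size_kb)`.
#'
#' @param size_kb fragment size in kb (> 0).
#' @return position in lane units.
#' @export
gel_position <- function(size_kb) {
  if (any(size_kb <= 0)) stop("fragment size must be > 0")
  1.05 - 0.45 * log10(size_kb)
}

#' Build a single densitometry lane from band fractions
#'
#' Each band is a Gaussian of the stated total fraction at the mobility
#' position of its fragment size; the lane trace sums to 1 before noise.
#' Band windows span +/- 6 band SDs.
#'
#' @param bands data.frame with `name`, `size_kb`, `fraction`, `role`
#'   (one of parental, dsb, R1, R2, other).
#' @param n_points trace resolution.
#' @param band_sd Gaussian band SD in lane units.
#' @param noise_sigma additive Gaussian noise SD (negative values clipped
#'   at 0).
#' @param seed seed for the noise draw (required when `noise_sigma > 0`).
#' @return An object of class `dsb_lane`: `position`, `intensity`,
#'   `windows` (name, start, end, role) and the planted `truth` fractions.
#' @export
build_lane <- function(bands, n_points = 1200, band_sd = 0.004,
                       noise_sigma = 0, seed = NULL) {
  stopifnot(all(c("name", "size_kb", "fraction", "role") %in% names(bands)))
  if (any(bands$size_kb <= 0)) stop("fragment size must be > 0")
  if (any(bands$fraction < 0) || sum(bands$fraction) > 1 + 1e-9) {
    stop("band fractions must be >= 0 and sum to <= 1")
  }
  pos <- seq(0, 1, length.out = n_points)
  ctr <- gel_position(bands$size_kb)
  intensity <- numeric(n_points)
  for (i in seq_len(nrow(bands))) {
    shape <- exp(-(pos - ctr[i])^2 / (2 * band_sd^2))
    intensity <- intensity + bands$fraction[i] * shape / sum(shape)
  }
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("seed is required when noise_sigma > 0")
    intensity <- withr::with_seed(seed, {
      pmax(intensity + stats::rnorm(n_points, 0, noise_sigma), 0)
    })
  }
  windows <- data.frame(
    name = bands$name,
    start = ctr - 6 * band_sd, end = ctr + 6 * band_sd,
    role = bands$role, stringsAsFactors = FALSE
  )
  if (any(windows$start < 0 | windows$end > 1)) {
    stop("band windows fall outside the lane; adjust fragment sizes")
  }
  o <- order(windows$start)
  if (nrow(windows) > 1 &&
      any(windows$start[o][-1] < windows$end[o][-nrow(windows)])) {
    stop("band windows overlap; fragment sizes too close for band_sd")
  }
  structure(
    list(position = pos, intensity = intensity, windows = windows,
         truth = stats::setNames(bands$fraction, bands$name)),
    class = "dsb_lane"
  )
}

#' Simulate a DSB time-course of gel lanes
#'
#' @param kinetics a `dsb_kinetics`.
#' @param timepoints hours, sorted ascending.
#' @param seed base seed for lane noise (each lane derives its own stream).
#' @param ... passed to [build_lane()] (`n_points`, `band_sd`).
#' @return named list of `dsb_lane` objects (one per timepoint, names
#'   like `"t5"`).
#' @export
simulate_lane_timecourse <- function(kinetics, timepoints, seed = 1, ...) {
  stopifnot(inherits(kinetics, "dsb_kinetics"))
  if (is.unsorted(timepoints, strictly = FALSE)) {
    stop("timepoints must be sorted ascending")
  }
  lanes <- lapply(seq_along(timepoints), function(i) {
    t <- timepoints[i]
    frac <- kinetics$max_broken * .broken_fraction(kinetics, t)
    bands <- data.frame(
      name = c("parental", names(frac)),
      size_kb = unname(kinetics$fragment_sizes[c("parental", names(frac))]),
      fraction = c(1 - sum(frac), unname(frac)),
      role = c("parental", rep("dsb", length(frac))),
      stringsAsFactors = FALSE
    )
    build_lane(bands, noise_sigma = kinetics$noise_sigma,
               seed = seed + 131L * i, ...)
  })
  names(lanes) <- paste0("t", timepoints)
  lanes
}

#' Simulate a 2D gel as a grid of Gaussian spots
#'
#' The grid is the sum of bivariate Gaussian spots (linear species, Y-arc
#' novel species, intersister and interhomolog Holliday-junction spots) over
#' a uniform baseline that carries the remaining signal fraction, plus
#' optional additive Gaussian noise.  Spot windows are squares of +/- 6 spot
#' SDs, so noiseless spot-volume recovery is exact to well below 1e-6.
#'
#' @param spots data.frame with `name`, `role` (linear, NS, IS, IH_small,
#'   IH_large), `x`, `y` (centers in unit coordinates) and `volume`
#'   (fraction of total signal; sum <= 1).
#' @param noise_sigma additive noise SD per pixel (intensity units).
#' @param n grid resolution (n x n pixels).
#' @param total total signal in intensity units (default 1e6).
#' @param spot_sd Gaussian spot SD in unit coordinates.
#' @param seed seed for the noise draw.
#' @return An object of class `dsb_gel2d`: intensity matrix, pixel
#'   coordinates, spot `windows` and the planted `truth` volumes.
#' @export
simulate_2d_gel <- function(spots, noise_sigma = 1, n = 200, total = 1e6,
                            spot_sd = 0.015, seed = 1) {
  stopifnot(all(c("name", "role", "x", "y", "volume") %in% names(spots)))
  if (any(spots$volume < 0) || sum(spots$volume) > 1 + 1e-9) {
    stop("spot volumes must be >= 0 and sum to <= 1")
  }
  is_xy <- spots[spots$role == "IS", c("x", "y")]
  ih_xy <- spots[spots$role %in% c("IH_small", "IH_large"), c("x", "y")]
  if (nrow(is_xy) && nrow(ih_xy)) {
    d <- outer(is_xy$x, ih_xy$x, "-")^2 + outer(is_xy$y, ih_xy$y, "-")^2
    if (any(d < (2 * spot_sd)^2)) {
      stop("IS and IH spots must sit at distinct coordinates")
    }
  }
  gx <- (seq_len(n) - 0.5) / n
  grid <- matrix(0, n, n)
  for (i in seq_len(nrow(spots))) {
    dx <- stats::dnorm(gx, spots$x[i], spot_sd)
    dy <- stats::dnorm(gx, spots$y[i], spot_sd)
    shape <- outer(dx, dy)
    grid <- grid + spots$volume[i] * total * shape / sum(shape)
  }
  baseline <- (1 - sum(spots$volume)) * total / n^2
  grid <- grid + baseline
  if (noise_sigma > 0) {
    grid <- withr::with_seed(seed, {
      pmax(grid + matrix(stats::rnorm(n^2, 0, noise_sigma), n, n), 0)
    })
  }
  half <- 6 * spot_sd
  windows <- data.frame(
    name = spots$name, role = spots$role,
    x0 = spots$x - half, x1 = spots$x + half,
    y0 = spots$y - half, y1 = spots$y + half,
    stringsAsFactors = FALSE
  )
  if (any(windows$x0 < 0 | windows$x1 > 1 | windows$y0 < 0 | windows$y1 > 1)) {
    stop("spot windows fall outside the grid")
  }
  structure(
    list(intensity = grid, coords = gx, windows = windows,
         truth = stats::setNames(spots$volume, spots$name),
         baseline_frac = 1 - sum(spots$volume)),
    class = "dsb_gel2d"
  )
}

#' Packaged 2D-gel spot presets
#'
#' `"mbs1-25C"`: the 7-hour single-gel preset -- total HJ signal 2.1% of
#' lane DNA split 3:1 between intersister and interhomolog junctions (the
#' two IH spots, from the heterozygous restriction-fragment sizes, share the
#' IH volume equally), novel species planted so HJ:NS = 1.3.
#' `"mbs1-25C-timecourse"`: 7/8/9-hour grids in which the novel species
#' decays faster than HJs, planting HJ:NS ratios 1.3, 1.7 and 2.6.
#'
#' @param preset preset name.
#' @return For `"mbs1-25C"` a spot data.frame for [simulate_2d_gel()]; for
#'   the time course a list with `times` and a list of spot data.frames.
#' @export
two_d_spot_preset <- function(preset = c("mbs1-25C", "mbs1-25C-timecourse")) {
  preset <- match.arg(preset)
  layout <- data.frame(
    name = c("linear", "NS", "IS", "IH_small", "IH_large"),
    role = c("linear", "NS", "IS", "IH_small", "IH_large"),
    x = c(0.20, 0.45, 0.40, 0.68, 0.75),
    y = c(0.25, 0.40, 0.72, 0.60, 0.25),
    stringsAsFactors = FALSE
  )
  mk <- function(hj_total, ns) {
    sp <- layout
    is_vol <- hj_total * 3 / 4
    ih_vol <- hj_total / 4 / 2
    sp$volume <- c(0.90, ns, is_vol, ih_vol, ih_vol)
    sp
  }
  if (preset == "mbs1-25C") {
    mk(hj_total = 0.021, ns = 0.021 / 1.3)
  } else {
    list(
      times = c(7, 8, 9),
      spots = list(
        mk(hj_total = 0.0195, ns = 0.0195 / 1.3),
        mk(hj_total = 0.0170, ns = 0.0170 / 1.7),
        mk(hj_total = 0.0130, ns = 0.0130 / 2.6)
      )
    )
  }
}

#' Simulate recombinant counts from a cross
#'
#' Recombinants are binomial draws among viable spores with success
#' probability taken either from a true map distance through the inverse
#' Haldane function (intergenic crossing over) or from a stated intragenic
#' recombinant frequency per 1e6 viable spores (gene conversion).
#'
#' @param true_distance_cM true map distance (intergenic mode).
#' @param freq_per_1e6 true recombinant frequency per 1e6 viable spores
#'   (intragenic mode); exactly one of the two must be given.
#' @param n_spores number of viable spores scored (> 0).
#' @param seed integer seed.
#' @return list with `recombinants`, `total` and `frequency` (per 1e6
#'   viable spores).
#' @export
simulate_cross <- function(true_distance_cM = NULL, freq_per_1e6 = NULL,
                           n_spores, seed) {
  if (is.null(true_distance_cM) == is.null(freq_per_1e6)) {
    stop("give exactly one of true_distance_cM or freq_per_1e6")
  }
  if (n_spores <= 0) stop("n_spores must be > 0")
  R <- if (!is.null(true_distance_cM)) {
    if (true_distance_cM < 0) stop("distance must be >= 0")
    haldane_R(true_distance_cM)
  } else {
    freq_per_1e6 / 1e6
  }
  rec <- withr::with_seed(seed, stats::rbinom(1, n_spores, R))
  list(recombinants = rec, total = n_spores, frequency = 1e6 * rec / n_spores)
}
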