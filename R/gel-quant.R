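#' Quantify a densitometry lane
#'
#' For each band window the area is the trace sum minus a linear baseline
#' interpolated between the window-edge intensities, clipped at 0; the
#' percent of total DNA broken is 100 times the summed fraction of the
#' dsb-role bands, with the whole-lane signal (all windows plus remaining
#' trace) as denominator.
#'
#' @param lane a `dsb_lane` (or a list with `position`, `intensity`,
#'   `windows`).
#' @return list with `bands` (per-window area, background-subtracted
#'   `fraction`, raw `raw_fraction`), `total`, `broken_pct` and
#'   `unassigned_fraction` (share of the lane outside every window).
#' @export
quantify_lane <- function(lane) {
  if (any(lane$intensity < 0)) stop("negative intensities in lane")
  total <- sum(lane$intensity)
  if (total <= 0) stop("lane total intensity is zero")
  w <- lane$windows
  area <- raw <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    idx <- which(lane$position >= w$start[i] & lane$position <= w$end[i])
    if (!length(idx)) stop("window ", w$name[i], " contains no trace points")
    edge <- lane$intensity[range(idx)]
    baseline <- seq(edge[1], edge[2], length.out = length(idx))
    raw[i] <- sum(lane$intensity[idx])
    area[i] <- max(raw[i] - sum(baseline), 0)
  }
  bands <- data.frame(
    name = w$name, role = w$role,
    area = area, fraction = area / total, raw_fraction = raw / total,
    stringsAsFactors = FALSE
  )
  list(
    bands = bands,
    total = total,
    broken_pct = 100 * sum(bands$fraction[bands$role == "dsb"]),
    unassigned_fraction = 1 - sum(bands$raw_fraction)
  )
}

#' Crossover DNA frequency from quantified lanes
#'
#' Crossover DNA is twice the fraction of the R2 recombinant-length
#' restriction fragment (partial digestion can contribute to R1, so only R2
#' is counted), expressed in percent and averaged over replicate lanes.
#'
#' @param quants a single result from [quantify_lane()] or a list of them.
#' @return percent crossover DNA (mean over lanes).
#' @export
crossover_frequency <- function(quants) {
  if (!is.null(quants$bands)) quants <- list(quants)
  per_lane <- vapply(quants, function(q) {
    r2 <- q$bands$fraction[q$bands$role == "R2"]
    if (!length(r2)) stop("no R2 window in lane quantification")
    2 * sum(r2) * 100
  }, numeric(1))
  mean(per_lane)
}

.window_pixels <- function(grid, w) {
  ix <- which(grid$coords >= w["x0"] & grid$coords <= w["x1"])
  iy <- which(grid$coords >= w["y0"] & grid$coords <= w["y1"])
  list(ix = ix, iy = iy)
}

#' Quantify spots on a 2D gel
#'
#' Spot volume is the window pixel sum minus the local median background
#' (median pixel intensity in a surrounding frame) times the window area,
#' clipped at 0.  Reports per-spot fractions of total signal, the
#' Holliday-junction frequency (percent of total DNA in IS + IH spots) and
#' the intersister:interhomolog ratio IS / (IH_small + IH_large); the ratio
#' is `NA` (undefined) when the IH volume is zero.
#'
#' @param grid a `dsb_gel2d`.
#' @param margin width of the background frame around each window, in
#'   pixels.
#' @return list with `spots` (per-window volume, `fraction`,
#'   `raw_fraction`), `total`, `hj_pct`, `is_ih_ratio` and
#'   `unassigned_fraction`.
#' @export
quantify_2d_spots <- function(grid, margin = 6L) {
  total <- sum(grid$intensity)
  if (total <= 0) stop("grid total signal is zero")
  n <- length(grid$coords)
  w <- grid$windows
  vol <- raw <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    px <- .window_pixels(grid, unlist(w[i, c("x0", "x1", "y0", "y1")]))
    if (!length(px$ix) || !length(px$iy)) stop("empty spot window ", w$name[i])
    raw[i] <- sum(grid$intensity[px$ix, px$iy])
    ox <- max(1, min(px$ix) - margin):min(n, max(px$ix) + margin)
    oy <- max(1, min(px$iy) - margin):min(n, max(px$iy) + margin)
    ring <- grid$intensity[ox, oy]
    inner <- matrix(FALSE, length(ox), length(oy))
    inner[match(px$ix, ox), match(px$iy, oy)] <- TRUE
    bg <- stats::median(ring[!inner])
    vol[i] <- max(raw[i] - bg * length(px$ix) * length(px$iy), 0)
  }
  spots <- data.frame(
    name = w$name, role = w$role,
    volume = vol, fraction = vol / total, raw_fraction = raw / total,
    stringsAsFactors = FALSE
  )
  is_vol <- sum(spots$volume[spots$role == "IS"])
  ih_vol <- sum(spots$volume[spots$role %in% c("IH_small", "IH_large")])
  list(
    spots = spots,
    total = total,
    hj_pct = 100 * sum(spots$fraction[spots$role %in%
                                        c("IS", "IH_small", "IH_large")]),
    is_ih_ratio = if (ih_vol > 0) is_vol / ih_vol else NA_real_,
    unassigned_fraction = 1 - sum(spots$raw_fraction)
  )
}

#' Holliday-junction / novel-species ratios over a time course
#'
#' Quantifies each 2D grid, reports the HJ and novel-species fractions of
#' total DNA per timepoint, their ratio, and whether the ratio is
#' non-decreasing over time (expected when the novel species, a putative
#' single-end-invasion precursor, decays faster than HJs).
#'
#' @param grids list of `dsb_gel2d`, one per timepoint.
#' @param times hours, same length as `grids`.
#' @return data.frame with `time`, `hj_fraction`, `ns_fraction`,
#'   `hj_ns_ratio`, plus attribute `monotone` (logical).
#' @export
timecourse_ratios <- function(grids, times) {
  if (length(grids) < 2) stop("need at least 2 timepoints")
  if (length(grids) != length(times)) stop("grids and times lengths differ")
  rows <- lapply(seq_along(grids), function(i) {
    q <- quantify_2d_spots(grids[[i]])
    hj <- sum(q$spots$fraction[q$spots$role %in% c("IS", "IH_small", "IH_large")])
    ns <- sum(q$spots$fraction[q$spots$role == "NS"])
    data.frame(time = times[i], hj_fraction = hj, ns_fraction = ns,
               hj_ns_ratio = if (ns > 0) hj / ns else NA_real_)
  })
  out <- do.call(rbind, rows)
  ratios <- out$hj_ns_ratio[!is.na(out$hj_ns_ratio)]
  attr(out, "monotone") <- !is.unsorted(ratios, strictly = FALSE)
  out
}
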