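#' Simulate one ChIP array (IP and WCE channels) from a scenario
#'
#' Generates per-probe IP and whole-cell-extract intensities for one array:
#' the probe-level true enrichment ratio is background x (1 + sum of hotspot
#' kernels), the hotspot amplitudes carry the planted condition effect plus
#' the scenario's condition and replicate noise, log-normal probe noise is
#' applied to both channels, and the array's log-scale gain compresses the
#' log ratio (so that cross-array rescaling has something real to undo).
#' With all noise SDs at zero and gain 1 the probe-level IP/WCE ratio equals
#' the planted enrichment exactly.
#'
#' Deterministic given the scenario and (condition, pair): the RNG stream is
#' derived from the scenario seed, so arrays can be generated in any order.
#'
#' @param scenario a `dsb_scenario`.
#' @param condition `"A"` (25 degree analog) or `"B"` (34 degree baseline).
#' @param pair replicate induction pair index (1..n_replicate_pairs).
#' @return data.frame with `chrom`, `start`, `end`, `ip`, `wce`.
#' @export
simulate_array_pair <- function(scenario, condition = c("A", "B"), pair = 1) {
  stopifnot(inherits(scenario, "dsb_scenario"))
  condition <- match.arg(condition)
  p <- scenario$params
  if (pair < 1 || pair > p$n_replicate_pairs) {
    stop("pair must be in 1..", p$n_replicate_pairs)
  }
  probes <- probe_intervals(scenario$genome)
  mid <- (probes$start + probes$end) / 2
  hs <- scenario$hotspots
  n_probe <- nrow(probes)
  n_hot <- nrow(hs)

  gain <- scenario$arrays$gain[scenario$arrays$condition == condition &
                                scenario$arrays$pair == pair]

  seed_arr <- scenario$seed + 1009L * pair + 37L * (condition == "A") + 5L
  withr::with_seed(seed_arr, {
    kernel <- numeric(n_probe)
    if (n_hot > 0) {
      # per-hotspot log10 amplitude deviation for this array
      eta <- stats::rnorm(n_hot, 0, p$replicate_sigma)
      if (condition == "A") eta <- eta + hs$cond_dev
      fac <- if (condition == "A") ifelse(hs$de_novo, 1, hs$effect)
             else ifelse(hs$de_novo, 0, 1)
      amp <- (hs$intensity - 1) * fac * 10^eta
      for (i in seq_len(n_hot)) {
        if (amp[i] == 0) next
        ctr <- (hs$start[i] + hs$end[i]) / 2
        if (p$kernel_shape == "rect") {
          sel <- which(probes$chrom == hs$chrom[i] &
                         mid >= hs$start[i] & mid < hs$end[i])
          if (length(sel)) kernel[sel] <- kernel[sel] + amp[i]
        } else {
          sdv <- hs$width[i] / 4
          sel <- which(probes$chrom == hs$chrom[i] & abs(mid - ctr) <= 3 * sdv)
          if (length(sel)) {
            kernel[sel] <- kernel[sel] +
              amp[i] * exp(-(mid[sel] - ctr)^2 / (2 * sdv^2))
          }
        }
      }
    }
    ratio <- p$background * (1 + kernel)
    wce <- 10^stats::rnorm(n_probe, 0, p$probe_sigma)
    ip_noise <- 10^stats::rnorm(n_probe, 0, p$probe_sigma)
    probes$ip <- wce * ratio^gain * ip_noise
    probes$wce <- wce
  })
  probes
}

#' Simulate all arrays of a scenario
#'
#' @param scenario a `dsb_scenario`.
#' @return named list of probe tables, one per array, names like `"A1"`,
#'   `"B1"`, ordered by pair then condition (B first).
#' @export
simulate_all_arrays <- function(scenario) {
  arr <- scenario$arrays
  out <- lapply(seq_len(nrow(arr)), function(i) {
    simulate_array_pair(scenario, arr$condition[i], arr$pair[i])
  })
  names(out) <- paste0(arr$condition, arr$pair)
  out
}
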