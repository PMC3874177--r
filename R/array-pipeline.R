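#' Median-normalize an IP:WCE probe profile
#'
#' Divides each probe's IP intensity by its WCE intensity and rescales so the
#' genome-median ratio is 1; the log10 of that ratio is the working signal
#' for cross-array scaling.
#'
#' @param probes data.frame with `chrom`, `start`, `end`, `ip`, `wce`.
#' @return An object of class `dsb_profile`: the probe table with `ratio`
#'   and `log_ratio` columns plus a `scale_factor` field (initialized to 1).
#' @export
normalize_profile <- function(probes) {
  if (is.null(probes) || nrow(probes) == 0) stop("empty probe table")
  req <- c("chrom", "start", "end", "ip", "wce")
  if (!all(req %in% names(probes))) {
    stop("probe table must have columns ", paste(req, collapse = ", "))
  }
  bad <- which(probes$wce <= 0)
  if (length(bad)) {
    stop("non-positive WCE intensity at probe ", bad[1], " (",
         probes$chrom[bad[1]], ":", probes$start[bad[1]], ")")
  }
  if (any(probes$ip < 0)) stop("negative IP intensity")
  raw <- probes$ip / probes$wce
  ratio <- raw / stats::median(raw)
  structure(
    list(
      probes = data.frame(
        chrom = probes$chrom, start = probes$start, end = probes$end,
        ratio = ratio, log_ratio = log10(ratio), stringsAsFactors = FALSE
      ),
      scale_factor = 1
    ),
    class = "dsb_profile"
  )
}

#' @export
print.dsb_profile <- function(x, ...) {
  cat("dsb_profile:", nrow(x$probes), "probes,",
      length(unique(x$probes$chrom)), "chromosomes, scale_factor =",
      format(x$scale_factor, digits = 4), "\n")
  invisible(x)
}

.probe_means_in <- function(profile, intervals) {
  mid <- (profile$probes$start + profile$probes$end) / 2
  vapply(seq_len(nrow(intervals)), function(k) {
    sel <- profile$probes$chrom == intervals$chrom[k] &
      mid >= intervals$start[k] & mid < intervals$end[k]
    if (!any(sel)) return(NA_real_)
    mean(profile$probes$log_ratio[sel])
  }, numeric(1))
}

#' Fit the cross-array log-scale factor against a reference profile
#'
#' Computes the multiplier `c` of the target profile's log10 ratios that
#' best matches the reference profile over a set of reference hotspots
#' (those broken to the same extent in all conditions): least squares
#' through the origin on the per-hotspot mean log ratios,
#' `c = sum(r * s) / sum(s^2)`.  A warning is emitted when the fitted factor
#' leaves the plausible [1.0, 1.5] band.
#'
#' @param profile,reference `dsb_profile` objects (target and reference).
#' @param refset data.frame of reference hotspot intervals (`chrom`,
#'   `start`, `end`; typically six).
#' @return the fitted scale factor (numeric scalar).
#' @export
fit_scale_factor <- function(profile, reference, refset) {
  stopifnot(inherits(profile, "dsb_profile"), inherits(reference, "dsb_profile"))
  s <- .probe_means_in(profile, refset)
  r <- .probe_means_in(reference, refset)
  if (anyNA(s) || anyNA(r)) stop("both profiles must cover every reference interval")
  if (sum(s^2) == 0) stop("target profile is all-zero over the reference set")
  cf <- sum(r * s) / sum(s^2)
  if (cf < 1.0 || cf > 1.5) {
    warning("fitted scale factor ", format(cf, digits = 4),
            " outside the expected [1.0, 1.5] band")
  }
  cf
}

#' Apply a log-scale factor to a profile
#'
#' @param profile a `dsb_profile`.
#' @param scale_factor multiplier for the log10 ratios (> 0).
#' @return the profile with `scale_factor` set.
#' @export
set_scale_factor <- function(profile, scale_factor) {
  stopifnot(inherits(profile, "dsb_profile"), scale_factor > 0)
  profile$scale_factor <- scale_factor
  profile
}

#' Pick the reference profile for cross-array scaling
#'
#' The reference is the array with the highest mean log ratio over the
#' reference hotspot set; ties are broken by input order.
#'
#' @param profiles list of `dsb_profile` objects.
#' @param refset reference intervals (see [fit_scale_factor()]).
#' @return index of the reference profile in `profiles`.
#' @export
select_reference_profile <- function(profiles, refset) {
  means <- vapply(profiles, function(p) mean(.probe_means_in(p, refset)),
                  numeric(1))
  which.max(means)
}

#' Integrate probe signal over hotspot intervals
#'
#' The integrated value of a hotspot is the sum over its probes (midpoint
#' rule) of the above-baseline linear ratio times probe width, after the
#' profile's scale factor has been applied in log space:
#' `sum(max(10^(c * log10(ratio)) - 1, 0) * width)`, in units of
#' bp x fold-above-baseline.  Intervals containing no probe are recorded as
#' `NA` with a warning.
#'
#' @param profile a `dsb_profile`.
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (0-based half-open, non-overlapping).
#' @return data.frame (hotspot table): `name`, `chrom`, `start`, `end`,
#'   `integrated_signal`.
#' @export
integrate_hotspots <- function(profile, intervals) {
  stopifnot(inherits(profile, "dsb_profile"))
  if (nrow(intervals) == 0) stop("no intervals supplied")
  .check_no_overlap(intervals)
  if (is.null(intervals$name)) {
    intervals$name <- paste0(intervals$chrom, ":", intervals$start, "-",
                             intervals$end)
  }
  cf <- profile$scale_factor
  pr <- profile$probes
  mid <- (pr$start + pr$end) / 2
  scaled <- 10^(cf * pr$log_ratio)
  excess <- pmax(scaled - 1, 0) * (pr$end - pr$start)
  sig <- vapply(seq_len(nrow(intervals)), function(k) {
    sel <- pr$chrom == intervals$chrom[k] &
      mid >= intervals$start[k] & mid < intervals$end[k]
    if (!any(sel)) return(NA_real_)
    sum(excess[sel])
  }, numeric(1))
  if (anyNA(sig)) {
    warning(sum(is.na(sig)), " interval(s) contain no probe; recorded as NA")
  }
  data.frame(
    name = intervals$name, chrom = intervals$chrom,
    start = intervals$start, end = intervals$end,
    integrated_signal = sig, stringsAsFactors = FALSE
  )
}

#' Calibrate integrated signal to percent DNA breakage
#'
#' Fits a through-origin least-squares line to Southern-blot calibration
#' pairs (hotspot, percent DNA broken) against the hotspot table's
#' integrated signal, then converts every hotspot's signal to percent
#' breakage and flags those above the breakage threshold.
#'
#' @param table hotspot table from [integrate_hotspots()].
#' @param southern_pairs data.frame with `name` and `percent_broken`.
#' @param threshold percent-breakage threshold for `passes_threshold`
#'   (default 0.3).
#' @return list with `model` (slope in percent per signal unit, `n_pairs`,
#'   `residual_sd`), `table` (with `percent_breakage` and
#'   `passes_threshold` columns) and `n_passing`.
#' @export
calibrate_breakage <- function(table, southern_pairs, threshold = 0.3) {
  m <- merge(southern_pairs, table[, c("name", "integrated_signal")], by = "name")
  m <- m[is.finite(m$integrated_signal) & m$integrated_signal > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 calibration pairs with positive signal")
  slope <- sum(m$percent_broken * m$integrated_signal) / sum(m$integrated_signal^2)
  if (slope <= 0) stop("non-positive calibration slope")
  resid <- m$percent_broken - slope * m$integrated_signal
  table$percent_breakage <- slope * table$integrated_signal
  table$passes_threshold <- !is.na(table$percent_breakage) &
    table$percent_breakage > threshold
  list(
    model = list(slope = slope, n_pairs = nrow(m),
                 residual_sd = stats::sd(resid)),
    table = table,
    n_passing = sum(table$passes_threshold)
  )
}
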