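#' Read a probe-level signal table
#'
#' Two on-disk layouts are supported: a five-column TSV
#' (`chrom start end ip wce`, 0-based half-open, `#` header lines) or a
#' pair of 4-column bedGraph files, one per channel, on identical probe
#' grids.  Parsing is strict: a malformed record aborts with its line
#' number.
#'
#' @param path path to the TSV or the IP-channel bedGraph.
#' @param format `"tsv"` or `"bedgraph"`.
#' @param wce_path WCE-channel bedGraph (bedGraph format only).
#' @return data.frame with `chrom`, `start`, `end`, `ip`, `wce`, sorted by
#'   (chrom, start).
#' @export
read_probe_table <- function(path, format = c("tsv", "bedgraph"),
                             wce_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
    n_head <- match(FALSE, is_comment, nomatch = length(lines) + 1L) - 1L
    df <- tryCatch(
      utils::read.table(path, comment.char = "#", header = FALSE,
                        col.names = c("chrom", "start", "end", "ip", "wce"),
                        colClasses = c("character", rep("numeric", 4))),
      error = function(e) stop("malformed probe table ", path, ": ",
                               conditionMessage(e))
    )
    .validate_probe_rows(df, n_head, path)
  } else {
    if (is.null(wce_path)) stop("bedGraph format needs wce_path")
    ip <- .import_bedgraph(path)
    wce <- .import_bedgraph(wce_path)
    if (!identical(ip[, c("chrom", "start", "end")],
                   wce[, c("chrom", "start", "end")])) {
      stop("IP and WCE bedGraph files are on different probe grids")
    }
    df <- data.frame(ip[, c("chrom", "start", "end")],
                     ip = ip$value, wce = wce$value,
                     stringsAsFactors = FALSE)
    .validate_probe_rows(df, 0L, path)
  }
}

.import_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    value = gr$score,
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start), , drop = FALSE]
}

.validate_probe_rows <- function(df, n_head, path) {
  bad <- which(df$start < 0 | df$end <= df$start | !is.finite(df$ip) |
                 !is.finite(df$wce))
  if (length(bad)) {
    stop("invalid probe record at line ", bad[1] + n_head, " of ", path)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a probe table as TSV
#'
#' @param probes probe data.frame (`chrom`, `start`, `end`, `ip`, `wce`).
#' @param path output path.
#' @export
write_probe_table <- function(probes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tip\twce\t(bp, 0-based half-open; intensities a.u.)",
             con)
  utils::write.table(probes[, c("chrom", "start", "end", "ip", "wce")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write one probe channel as bedGraph
#'
#' @param probes probe data.frame.
#' @param channel `"ip"` or `"wce"`.
#' @param path output path.
#' @export
write_probe_bedgraph <- function(probes, channel = c("ip", "wce"), path) {
  channel <- match.arg(channel)
  gr <- GenomicRanges::GRanges(
    probes$chrom,
    IRanges::IRanges(start = probes$start + 1L, end = probes$end),
    score = probes[[channel]]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read hotspot intervals from BED
#'
#' BED3 minimum; names are taken from column 4 when present, otherwise
#' auto-generated as `chrom:start-end`.  Overlapping intervals are an
#' error; output is sorted by (chrom, start).
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `name` (0-based
#'   half-open).
#' @export
read_intervals_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) stop("no intervals in ", path)
  if (!GenomicRanges::isDisjoint(gr)) stop("overlapping intervals in ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    stringsAsFactors = FALSE
  )
  auto <- is.na(df$name) | !nzchar(df$name)
  df$name[auto] <- paste0(df$chrom[auto], ":", df$start[auto], "-", df$end[auto])
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals (plus optional extra columns) as BED
#'
#' Writes BED4 from `chrom`/`start`/`end`/`name`; any further columns named
#' in `extra` are appended (BED6+ style, with score 0 and strand `.`).
#'
#' @param intervals data.frame of intervals (0-based half-open).
#' @param path output path.
#' @param extra character vector of extra column names to append.
#' @export
write_intervals_bed <- function(intervals, path, extra = NULL) {
  out <- intervals[, c("chrom", "start", "end", "name")]
  if (!is.null(extra)) {
    out$score <- 0
    out$strand <- "."
    for (cn in extra) out[[cn]] <- intervals[[cn]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read Southern-blot calibration pairs
#'
#' @param path TSV with columns `name` and `percent_broken` (`#` header).
#' @return data.frame.
#' @export
read_calibration_pairs <- function(path) {
  df <- utils::read.table(path, comment.char = "#", header = FALSE,
                          col.names = c("name", "percent_broken"),
                          colClasses = c("character", "numeric"))
  if (any(df$percent_broken < 0)) stop("negative percent_broken in ", path)
  df
}

#' Write a calibrated hotspot table as TSV
#'
#' @param table hotspot table (from [integrate_hotspots()] or
#'   [calibrate_breakage()]).
#' @param path output path.
#' @export
write_hotspot_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(table), collapse = "\t"),
                    "\t(bp; signal bp x fold; breakage %)"), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a hotspot table written by [write_hotspot_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_hotspot_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  cols <- strsplit(header, "\t")[[1]]
  cols <- cols[!grepl("^\\(", cols)]
  utils::read.table(path, comment.char = "#", header = FALSE,
                    col.names = cols, stringsAsFactors = FALSE)
}

#' Write a lane or 2D-grid trace with its window sidecar
#'
#' The trace/grid goes to `path` as a TSV matrix; the band/spot windows go
#' to `paste0(path, ".windows.tsv")` as key columns.
#'
#' @param obj a `dsb_lane` or `dsb_gel2d`.
#' @param path output path for the trace/grid.
#' @export
write_gel <- function(obj, path) {
  if (inherits(obj, "dsb_lane")) {
    utils::write.table(
      data.frame(position = obj$position, intensity = obj$intensity),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(obj, "dsb_gel2d")) {
    utils::write.table(obj$intensity, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    stop("unsupported object")
  }
  utils::write.table(obj$windows, paste0(path, ".windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lane trace and window sidecar written by [write_gel()]
#'
#' @param path trace path.
#' @return a `dsb_lane`.
#' @export
read_lane <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t")
  w <- utils::read.table(paste0(path, ".windows.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  structure(list(position = tr$position, intensity = tr$intensity,
                 windows = w, truth = NULL),
            class = "dsb_lane")
}
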