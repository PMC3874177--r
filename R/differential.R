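#' Fit the between-condition comparison of hotspot signals
#'
#' Ordinary least squares of condition-2 values on condition-1 values
#' (on the log10 scale by default), with the two-sided 95% prediction
#' interval for a new observation:
#' `yhat(x) +/- t(0.975, n-2) * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`.
#' The Pearson correlation is computed on the same (transformed) scale.
#'
#' @param x,y paired per-hotspot signals (arbitrary units).
#' @param names optional hotspot names.
#' @param log10 fit on the log10 scale (default TRUE; all values must then
#'   be > 0 -- zeros belong to the de novo path, not the regression).
#' @param level prediction-interval level (default 0.95).
#' @return An object of class `dsb_fit`: intercept, slope, `residual_sd`,
#'   `n`, `pearson_r`, the transformed data, and the PI machinery used by
#'   [pi_bounds()] and [classify_outliers()].
#' @export
fit_comparison <- function(x, y, names = NULL, log10 = TRUE, level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  if (log10) {
    if (any(x <= 0) || any(y <= 0)) {
      stop("log10 transform requires positive values; route zeros to de novo detection")
    }
    tx <- log10(x); ty <- log10(y)
  } else {
    tx <- x; ty <- y
  }
  if (stats::var(tx) == 0) stop("zero variance in x")
  if (is.null(names)) names <- sprintf("hs_%03d", seq_len(n))

  fit <- stats::lm(ty ~ tx)
  s <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      residual_sd = s,
      n = n,
      pearson_r = stats::cor(tx, ty),
      level = level,
      log10 = log10,
      xbar = mean(tx),
      Sxx = sum((tx - mean(tx))^2),
      tx = tx, ty = ty, names = names
    ),
    class = "dsb_fit"
  )
}

#' @export
print.dsb_fit <- function(x, ...) {
  cat(sprintf(
    "dsb_fit: n = %d, slope = %.3f, intercept = %.3f, r = %.3f, residual sd = %.4f (%s scale)\n",
    x$n, x$slope, x$intercept, x$pearson_r, x$residual_sd,
    if (x$log10) "log10" else "linear"))
  invisible(x)
}

#' Prediction-interval bounds at given x
#'
#' @param fit a `dsb_fit`.
#' @param x0 positions on the transformed scale of the fit.
#' @return data.frame with `fit`, `lower`, `upper`.
#' @export
pi_bounds <- function(fit, x0) {
  stopifnot(inherits(fit, "dsb_fit"))
  tcrit <- stats::qt(1 - (1 - fit$level) / 2, fit$n - 2)
  yhat <- fit$intercept + fit$slope * x0
  half <- tcrit * fit$residual_sd *
    sqrt(1 + 1 / fit$n + (x0 - fit$xbar)^2 / fit$Sxx)
  data.frame(fit = yhat, lower = yhat - half, upper = yhat + half)
}

#' Classify hotspots against the prediction interval
#'
#' A hotspot is `increased` when its y value lies strictly above the upper
#' PI limit at its x, `decreased` strictly below the lower limit, otherwise
#' `unchanged` (a point exactly on a limit is inside).
#'
#' @param fit a `dsb_fit` produced from the same data.
#' @return data.frame with `name`, `x`, `y` (transformed scale), `fitted`,
#'   `lower`, `upper`, `residual`, `class`.
#' @export
classify_outliers <- function(fit) {
  stopifnot(inherits(fit, "dsb_fit"))
  b <- pi_bounds(fit, fit$tx)
  cls <- ifelse(fit$ty > b$upper, "increased",
                ifelse(fit$ty < b$lower, "decreased", "unchanged"))
  data.frame(
    name = fit$names, x = fit$tx, y = fit$ty,
    fitted = b$fit, lower = b$lower, upper = b$upper,
    residual = fit$ty - b$fit, class = cls,
    stringsAsFactors = FALSE
  )
}

#' Intersect differential calls across comparisons
#'
#' A hotspot is reproducibly increased (decreased) when it is called
#' increased (decreased) in every provided comparison; order of the
#' comparisons is irrelevant.
#'
#' @param calls list (>= 2) of call tables from [classify_outliers()], all
#'   over the same hotspot universe.
#' @return list with `increased` and `decreased` name vectors and the
#'   per-comparison class matrix `provenance`.
#' @export
intersect_reproducible <- function(calls) {
  if (length(calls) < 2) stop("need at least 2 call sets")
  universe <- sort(calls[[1]]$name)
  for (cl in calls[-1]) {
    if (!identical(sort(cl$name), universe)) {
      stop("call sets cover different hotspot universes")
    }
  }
  mat <- vapply(calls, function(cl) cl$class[match(universe, cl$name)],
                character(length(universe)))
  mat <- matrix(mat, nrow = length(universe),
                dimnames = list(universe, names(calls)))
  list(
    increased = universe[apply(mat == "increased", 1, all)],
    decreased = universe[apply(mat == "decreased", 1, all)],
    provenance = mat
  )
}

#' Detect de novo hotspots between two calibrated tables
#'
#' A hotspot is de novo in condition A when its percent breakage exceeds the
#' threshold in A while staying below half the threshold in B (the guard
#' band avoids boundary flicker).
#'
#' @param tableA,tableB calibrated hotspot tables (with `percent_breakage`)
#'   over the same intervals.
#' @param threshold percent-breakage threshold (default 0.3).
#' @return character vector of de novo hotspot names.
#' @export
detect_de_novo <- function(tableA, tableB, threshold = 0.3) {
  if (!identical(tableA$name, tableB$name)) {
    stop("tables must cover the same hotspot universe in the same order")
  }
  sel <- !is.na(tableA$percent_breakage) & !is.na(tableB$percent_breakage) &
    tableA$percent_breakage > threshold &
    tableB$percent_breakage < threshold / 2
  tableA$name[sel]
}
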