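#' Read longitudinal bioluminescence series from CSV
#'
#' Expects columns `cell_line`, `mouse_id`, `day`, `radiance` (average
#' radiance in instrument units; taken as given, no image processing).
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with the four columns, validated: days
#'   non-negative integers, radiance strictly positive.
#' @export
readBioluminescence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "mouse_id", "day", "radiance")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("bioluminescence file lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  .validateSeries(df)
  df[need]
}

.validateSeries <- function(df) {
  if (!is.numeric(df$day) || any(df$day < 0)) {
    stop("days must be non-negative numbers")
  }
  if (!is.numeric(df$radiance) || any(!is.finite(df$radiance)) ||
      any(df$radiance <= 0)) {
    stop("radiance must be finite and strictly positive")
  }
  invisible(df)
}

#' Normalize radiance to day-0 growth ratios
#'
#' For each mouse, divides every radiance measurement by that mouse's
#' day-0 radiance, so the ratio at day 0 is exactly 1. Ratios are
#' invariant to rescaling a mouse's radiance by any positive constant.
#'
#' @param series `data.frame` with columns `cell_line`, `mouse_id`, `day`,
#'   `radiance` (one row per measurement; days unique per mouse, day 0
#'   required).
#' @return The input with rows ordered by cell line, mouse and day, plus a
#'   `ratio` column.
#' @export
growthRatio <- function(series) {
  .validateSeries(series)
  series <- series[order(series$cell_line, series$mouse_id, series$day), ,
                   drop = FALSE]
  key <- interaction(series$cell_line, series$mouse_id, drop = TRUE)
  parts <- lapply(split(series, key), function(s) {
    if (anyDuplicated(s$day)) {
      stop("duplicate day for mouse '", s$mouse_id[1L], "' of line '",
           s$cell_line[1L], "'")
    }
    if (!0 %in% s$day) {
      stop("mouse '", s$mouse_id[1L], "' of line '", s$cell_line[1L],
           "' has no day-0 measurement")
    }
    s$ratio <- s$radiance / s$radiance[s$day == 0]
    s
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$cell_line, out$mouse_id, out$day), , drop = FALSE]
}

#' Summarize in vivo growth per cell line
#'
#' Per cell line, the log10 of the mean (over that line's mice) of the
#' growth ratio at the readout day — the log10 "mean normalized average
#' radiance" scale used to plot in vivo growth.
#'
#' @param ratios Output of [growthRatio()].
#' @param day Readout day (default 28).
#' @param aggregate `"arithmetic"` (default): log10 of the arithmetic mean
#'   of ratios; `"geometric"`: mean of the log10 ratios.
#' @return Named numeric vector, one value per cell line (input order of
#'   first appearance). Errors if any mouse of a line lacks the readout
#'   day.
#' @export
summarizeGrowth <- function(ratios, day = 28,
                            aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  lines <- unique(ratios$cell_line)
  vals <- vapply(lines, function(ln) {
    s <- ratios[ratios$cell_line == ln, , drop = FALSE]
    mice <- unique(s$mouse_id)
    atDay <- s[s$day == day, , drop = FALSE]
    if (!setequal(atDay$mouse_id, mice)) {
      stop("cell line '", ln, "' has mice without a day-", day,
           " measurement")
    }
    if (aggregate == "arithmetic") log10(mean(atDay$ratio))
    else mean(log10(atDay$ratio))
  }, numeric(1))
  setNames(vals, lines)
}

#' Classify cell lines into RG vs MSG by in vivo growth
#'
#' `"max_gap"` (default, parameter-free) sorts the per-line summaries and
#' splits at the largest gap; lines above the gap midpoint form the
#' rapid-growth group (RG). `"fixed_threshold"` labels RG when the summary
#' strictly exceeds `threshold`. The max-gap split is invariant to adding
#' a constant to all summaries.
#'
#' @param g Named numeric vector from [summarizeGrowth()] (at least two
#'   lines).
#' @param method `"max_gap"` or `"fixed_threshold"`.
#' @param threshold Required for `"fixed_threshold"`; ignored otherwise.
#' @return List of class `"GrowthClassification"`: `labels` (named
#'   RG/MSG vector), `threshold` (the cut actually used), `method`.
#' @examples
#' classifyGrowth(c(A = 3.0, B = 2.8, C = 0.5, D = 0.3))
#' @export
classifyGrowth <- function(g, method = c("max_gap", "fixed_threshold"),
                           threshold = NULL) {
  method <- match.arg(method)
  if (length(g) < 2L || is.null(names(g))) {
    stop("'g' must be a named vector with at least two cell lines")
  }
  if (method == "fixed_threshold") {
    if (is.null(threshold)) stop("'fixed_threshold' requires 'threshold'")
    thr <- threshold
  } else {
    s <- sort(g)
    gaps <- diff(s)
    if (max(gaps) == 0) {
      stop("all growth summaries are equal: no valid max-gap split")
    }
    k <- which.max(gaps)
    thr <- (s[k] + s[k + 1L]) / 2
  }
  labels <- setNames(ifelse(g > thr, "RG", "MSG"), names(g))
  structure(list(labels = labels, threshold = unname(thr), method = method),
            class = "GrowthClassification")
}

#' @export
print.GrowthClassification <- function(x, ...) {
  cat("GrowthClassification (", x$method, ", threshold = ",
      format(x$threshold), "):\n", sep = "")
  cat("  RG: ", paste(names(x$labels)[x$labels == "RG"], collapse = ", "),
      "\n  MSG: ", paste(names(x$labels)[x$labels == "MSG"], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' In vitro growth from day-4 cell counts
#'
#' Converts day-4 counts to `log2(N(4)/N0)` per cell line; for replicate
#' counts, the mean of the per-replicate log2 values.
#'
#' @param counts Named numeric vector (one count per line) or named list
#'   of replicate count vectors.
#' @param n0 Number of cells seeded on day 0 (default 1.5e5).
#' @return Named numeric vector of log2 doublings over four days.
#' @examples
#' inVitroGrowth(list(A = c(2, 4, 8) * 1.5e5))  # mean of 1,2,3 = 2
#' @export
inVitroGrowth <- function(counts, n0 = 1.5e5) {
  .assertScalarNum(n0, "n0", positive = TRUE)
  if (!is.list(counts)) counts <- as.list(counts)
  if (is.null(names(counts))) stop("'counts' must be named by cell line")
  vals <- vapply(counts, function(x) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop("cell counts must be finite and strictly positive")
    }
    mean(log2(x / n0))
  }, numeric(1))
  setNames(vals, names(counts))
}

#' Correlate in vivo growth with a per-line covariate
#'
#' Joins the growth summary and a covariate (in vitro growth, or a log10
#' marker band intensity) by cell line and computes the correlation with
#' a two-sided p-value. The p-value is reported, not thresholded.
#'
#' @param g Named numeric vector from [summarizeGrowth()].
#' @param covariate Named numeric vector on the same cell lines (lines
#'   missing from either side are dropped with a warning).
#' @param method `"pearson"` (default; both axes are already
#'   log-transformed) or `"spearman"`.
#' @return List with `estimate`, `p.value`, `n`, `method`.
#' @export
correlateGrowthWithCovariate <- function(g, covariate,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(names(g), names(covariate))
  dropped <- setdiff(union(names(g), names(covariate)), shared)
  if (length(dropped)) {
    warning("cell line(s) without both measurements dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(shared) < 3L) {
    stop("correlation needs at least 3 shared cell lines; got ",
         length(shared))
  }
  a <- g[shared]
  b <- covariate[shared]
  if (sd(a) == 0 || sd(b) == 0) {
    stop("correlation undefined: zero variance in one of the vectors")
  }
  ct <- if (method == "spearman") {
    cor.test(a, b, method = "spearman", exact = FALSE)
  } else {
    cor.test(a, b, method = "pearson")
  }
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(shared), method = method)
}
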