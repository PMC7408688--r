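#' Read a survival cohort from CSV
#'
#' Expects columns `id`, `time_months`, `event` (1 = death observed, 0 =
#' censored), then one column per gene with expression values.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with the clinical columns first, then gene
#'   columns; validated (positive finite times, 0/1 events, finite
#'   expression).
#' @export
readSurvivalCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "time_months", "event")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  }
  .validateCohort(df)
  df
}

.validateCohort <- function(df) {
  if (any(!is.finite(df$time_months)) || any(df$time_months <= 0)) {
    stop("survival times must be finite and strictly positive")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  geneCols <- setdiff(colnames(df), c("id", "time_months", "event"))
  for (gc in geneCols) {
    if (!is.numeric(df[[gc]]) || any(!is.finite(df[[gc]]))) {
      stop("expression column '", gc, "' must be finite numeric")
    }
  }
  invisible(df)
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survivor curve with Greenwood variance and pointwise 95%
#' confidence intervals on the log(-log) scale, clipped to \[0, 1\].
#' Subjects censored at an event time are counted at risk at that time
#' (the standard convention).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return `data.frame` of class `"KMCurve"`, one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `greenwood_var`, `lower`, `upper`. Attributes `n` and `events` hold
#'   cohort totals.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 0, 1))  # S(1) = 2/3, S(3) = 0
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) {
    stop("'times' and 'events' must have equal length")
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("times must be finite and strictly positive")
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = 0.95)
  surv <- fit$surv
  # survfit's std.err is the SE of log S; Greenwood variance of S itself:
  gvar <- (surv * fit$std.err)^2
  lower <- fit$lower
  upper <- fit$upper
  # log-log CI is undefined at S = 1 and S = 0; collapse to the point value
  lower[is.na(lower)] <- surv[is.na(lower)]
  upper[is.na(upper)] <- surv[is.na(upper)]
  gvar[!is.finite(gvar)] <- NA_real_
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = surv, greenwood_var = gvar,
                    lower = pmin(pmax(lower, 0), 1),
                    upper = pmin(pmax(upper, 0), 1))
  attr(out, "n") <- length(times)
  attr(out, "events") <- sum(events)
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function from 0 to `horizon` — the
#' computable analog of "mean survival time" under right censoring.
#'
#' @param km A `"KMCurve"` from [kmEstimate()].
#' @param horizon Positive time horizon in the same units as the curve;
#'   defaults to the last observed time on the curve.
#' @return Restricted mean survival time (months, for monthly input).
#' @examples
#' meanSurvival(kmEstimate(c(1, 2, 3), c(1, 0, 1)), horizon = 3)  # 7/3
#' @export
meanSurvival <- function(km, horizon = NULL) {
  if (is.null(horizon)) horizon <- max(km$time)
  .assertScalarNum(horizon, "horizon", positive = TRUE)
  keep <- km$time <= horizon
  knots <- c(0, km$time[keep], horizon)
  s <- c(1, km$surv[keep])  # S is right-continuous: value holds until next knot
  sum(diff(knots) * s)
}

#' Two-sample log-rank test
#'
#' Standard log-rank test: at each distinct event time the expected death
#' count in group A is `n_Aj * d_j / n_j` with the hypergeometric
#' variance; the statistic is `(sum O - sum E)^2 / sum V`, referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param timesA,eventsA Follow-up times and 0/1 events for group A.
#' @param timesB,eventsB Same for group B.
#' @return List of class `"LogRankResult"`: `statistic`, `p.value`,
#'   `observed` and `expected` event counts per group, `df`.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB)) {
    stop("both groups must be non-empty")
  }
  if (sum(eventsA) + sum(eventsB) < 1) {
    stop("log-rank test requires at least one event")
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- factor(rep(c("A", "B"), c(length(timesA), length(timesB))))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  v <- fit$var[1L, 1L]
  if (v == 0) stop("log-rank variance is zero: no between-group information")
  stat <- unname(fit$chisq)
  structure(list(statistic = stat,
                 p.value = pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = setNames(as.numeric(fit$obs), levels(grp)),
                 expected = setNames(as.numeric(fit$exp), levels(grp)),
                 df = 1L),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat("Log-rank test: chisq =", format(x$statistic, digits = 4),
      "on 1 df, p =", format(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Dichotomize a cohort by gene expression
#'
#' Splits patients into high/low expression groups for a gene:
#' * `"median"`: high iff expression strictly above the cohort median;
#' * `"zscore_cut"`: high iff the z-score of expression exceeds `param`
#'   (default 0);
#' * `"optimal_logrank"` (default): scans candidate cuts at the expression
#'   quantiles 0.10-0.90 in steps of 0.05 and picks the cut minimizing the
#'   log-rank p-value. The scan is returned, and the result is flagged:
#'   selecting the cut by minimum p inflates the type-I error, so
#'   downstream p-values are descriptive.
#'
#' @param cohort Cohort `data.frame` as from [readSurvivalCohort()] or
#'   [simulateCohort()].
#' @param gene Gene column name.
#' @param strategy Splitting strategy (see above).
#' @param param Cut parameter for `"zscore_cut"`.
#' @return List of class `"Dichotomy"`: `gene`, `strategy`, `cut`
#'   (expression-scale cut value), `labels` (named "high"/"low" per
#'   patient), `n_high`, `n_low`, `scan` (`data.frame` of cut and p, for
#'   the optimal strategy), `selection_inflated` flag.
#' @export
dichotomize <- function(cohort, gene,
                        strategy = c("optimal_logrank", "median",
                                     "zscore_cut"),
                        param = 0) {
  strategy <- match.arg(strategy)
  if (!gene %in% colnames(cohort)) stop("gene '", gene, "' not in cohort")
  if (nrow(cohort) < 4L) stop("cohort must have at least 4 patients")
  x <- cohort[[gene]]
  if (sd(x) == 0) stop("constant expression for gene '", gene, "'")
  scan <- NULL
  if (strategy == "median") {
    cut <- median(x)
  } else if (strategy == "zscore_cut") {
    .assertScalarNum(param, "param")
    cut <- mean(x) + param * sd(x)
  } else {
    cand <- unique(quantile(x, probs = seq(0.10, 0.90, by = 0.05),
                            names = FALSE))
    p <- vapply(cand, function(cc) {
      hi <- x > cc
      if (!any(hi) || all(hi)) return(NA_real_)
      tryCatch(logrankTest(cohort$time_months[hi], cohort$event[hi],
                           cohort$time_months[!hi],
                           cohort$event[!hi])$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
    scan <- data.frame(cut = cand, p = p)
    if (all(is.na(p))) {
      stop("no valid split for gene '", gene, "' on the candidate grid")
    }
    cut <- cand[which.min(p)]  # ties: first (lowest) cut
  }
  high <- x > cut
  if (!any(high) || all(high)) {
    stop("degenerate split for gene '", gene, "': one group is empty")
  }
  structure(list(gene = gene, strategy = strategy, cut = unname(cut),
                 labels = setNames(ifelse(high, "high", "low"),
                                   as.character(cohort$id)),
                 n_high = sum(high), n_low = sum(!high), scan = scan,
                 selection_inflated = strategy == "optimal_logrank"),
            class = "Dichotomy")
}

#' Screen signature genes for survival association
#'
#' For each gene: dichotomize the cohort, run the log-rank test, and
#' compute the restricted mean survival time (RMST) of the high- and
#' low-expression groups over a common horizon. A gene is flagged
#' `"adverse-high"` when the high group's mean survival is shorter and
#' the raw p-value is below `alpha` (the high/low table sections), or
#' `"adverse-low"` for the reverse; otherwise `"ns"`. Raw p-values drive
#' the flag; Benjamini-Hochberg q-values are reported alongside.
#'
#' @param cohort Cohort `data.frame` (columns `id`, `time_months`,
#'   `event`, genes).
#' @param genes Character vector of gene names, or a
#'   [BrainSignature-class] (its up then down sets are screened).
#' @param strategy Passed to [dichotomize()].
#' @param alpha Raw-p flag level (default 0.05).
#' @param param Passed to [dichotomize()].
#' @param horizon RMST horizon; defaults to the largest observed time in
#'   the pooled cohort.
#' @return `data.frame` of class `"SurvivalScreen"`, one row per gene:
#'   `gene`, `n_high`, `n_low`, `cut`, `p_value`, `q_value`, `high_mean`,
#'   `low_mean`, `flag`. Genes failing (constant expression, degenerate
#'   split, no events) are skipped with a warning, not fatal.
#' @export
survivalScreen <- function(cohort, genes,
                           strategy = c("optimal_logrank", "median",
                                        "zscore_cut"),
                           alpha = 0.05, param = 0, horizon = NULL) {
  strategy <- match.arg(strategy)
  .assertScalarNum(alpha, "alpha", positive = TRUE)
  if (is(genes, "BrainSignature")) {
    genes <- c(signatureUp(genes), signatureDown(genes))
  }
  if (is.null(horizon)) horizon <- max(cohort$time_months)
  rows <- lapply(genes, function(g) {
    tryCatch({
      d <- dichotomize(cohort, g, strategy = strategy, param = param)
      hi <- d$labels == "high"
      lr <- logrankTest(cohort$time_months[hi], cohort$event[hi],
                        cohort$time_months[!hi], cohort$event[!hi])
      hm <- meanSurvival(kmEstimate(cohort$time_months[hi],
                                    cohort$event[hi]), horizon)
      lm_ <- meanSurvival(kmEstimate(cohort$time_months[!hi],
                                     cohort$event[!hi]), horizon)
      data.frame(gene = g, n_high = d$n_high, n_low = d$n_low,
                 cut = d$cut, p_value = lr$p.value, high_mean = hm,
                 low_mean = lm_, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("gene '", g, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(gene = character(), n_high = integer(),
                      n_low = integer(), cut = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      high_mean = numeric(), low_mean = numeric(),
                      flag = character(), stringsAsFactors = FALSE)
    class(out) <- c("SurvivalScreen", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$flag <- ifelse(out$p_value >= alpha, "ns",
                     ifelse(out$high_mean < out$low_mean,
                            "adverse-high", "adverse-low"))
  out <- out[, c("gene", "n_high", "n_low", "cut", "p_value", "q_value",
                 "high_mean", "low_mean", "flag")]
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  attr(out, "selection_inflated") <- strategy == "optimal_logrank"
  attr(out, "horizon") <- horizon
  class(out) <- c("SurvivalScreen", "data.frame")
  out
}
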