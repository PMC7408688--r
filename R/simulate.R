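#' Simulate a planted-signature expression matrix
#'
#' Generates a nine-sample log2 expression matrix with the structure the
#' signature filter assumes: per-gene baselines drawn uniformly from
#' `baselineRange`; independent Gaussian log2-scale noise of sd `noiseSd`
#' in each of the seven MSG samples; and a log2 shift of `+effectDelta`
#' added to both RG samples for the planted up genes (`-effectDelta` for
#' planted down genes). The two RG samples are modeled as replicate
#' measurements of the shared rapid-growth expression state: each gets
#' independent jitter of sd `rgInconsistencySd` around that state, so the
#' within-RG consistency criterion is exercised by a dispersion the
#' filter is designed to tolerate, while the MSG lines carry the full
#' between-line biological noise. Samples are named after the nine cell
#' lines, with RG = UACC-893 and MDA-MB-453.
#'
#' @param nGenes Total genes (default 2000).
#' @param nUp,nDown Planted up/down counts (default 40 each).
#' @param effectDelta Planted log2 shift on both RG samples (default 2.5).
#' @param noiseSd Log2-scale Gaussian noise sd of the MSG samples
#'   (default 0.3).
#' @param baselineRange Interval for per-gene baselines (default c(4, 12)).
#' @param rgInconsistencySd Sd of the replicate jitter between the two RG
#'   samples (default 0.1).
#' @param seed Integer seed; the call is deterministic under a fixed seed
#'   and does not disturb the caller's RNG state.
#' @return List: `expression` ([BrainExpression-class] with groups
#'   attached), `truth` (list of planted `up`/`down` gene names).
#' @examples
#' sim <- simulateExpression(nGenes = 100, nUp = 3, nDown = 3, seed = 7)
#' sim$truth$up
#' @export
simulateExpression <- function(nGenes = 2000, nUp = 40, nDown = 40,
                               effectDelta = 2.5, noiseSd = 0.3,
                               baselineRange = c(4, 12),
                               rgInconsistencySd = 0.1, seed = NULL) {
  if (nUp + nDown > nGenes) stop("nUp + nDown must not exceed nGenes")
  if (noiseSd < 0 || rgInconsistencySd < 0) stop("sds must be >= 0")
  .assertScalarNum(effectDelta, "effectDelta")
  .withSeed(seed, {
    samples <- cellLines()
    genes <- sprintf("g%05d", seq_len(nGenes))
    up <- genes[seq_len(nUp)]
    down <- genes[nUp + seq_len(nDown)]
    baseline <- runif(nGenes, baselineRange[1L], baselineRange[2L])
    rgIdx <- match(rgLines(), samples)
    msgIdx <- setdiff(seq_along(samples), rgIdx)
    m <- matrix(baseline, nGenes, 9L, dimnames = list(genes, samples))
    m[, msgIdx] <- m[, msgIdx] +
      matrix(rnorm(nGenes * length(msgIdx), 0, noiseSd), nGenes)
    m[up, rgIdx] <- m[up, rgIdx] + effectDelta
    m[down, rgIdx] <- m[down, rgIdx] - effectDelta
    m[, rgIdx] <- m[, rgIdx] +
      matrix(rnorm(nGenes * 2L, 0, rgInconsistencySd), nGenes, 2L)
    list(expression = BrainExpression(m, level = "gene",
                                      groups = defaultGroups()),
         truth = list(up = up, down = down))
  })
}

#' Simulate a right-censored proportional-hazards survival cohort
#'
#' Per-gene expression is standard normal; event times are exponential
#' with rate `baselineHazard * exp(sum(beta * expression))`; censoring
#' times are exponential with rate `censoringRate`, truncated at
#' `horizonMonths` (administrative censoring). Observed time is the
#' minimum, the event indicator marks death observed first.
#'
#' @param nPatients Cohort size (default 2000, at least 4).
#' @param beta Named numeric vector: per-gene log hazard ratio per SD of
#'   expression (0 = null gene). Names become the gene columns.
#' @param baselineHazard Exponential event rate per month (default 0.01,
#'   a median survival near 69 months).
#' @param censoringRate Exponential censoring rate per month
#'   (default 0.004, roughly a quarter of records censored before the
#'   horizon at the default baseline hazard).
#' @param horizonMonths Administrative censoring horizon (default 300).
#' @param seed Integer seed (see [simulateExpression()]).
#' @return List: `cohort` (`data.frame` with `id`, `time_months`, `event`
#'   and one column per gene), `truth` (the `beta` vector).
#' @export
simulateCohort <- function(nPatients = 2000, beta = c(gene1 = 0),
                           baselineHazard = 0.01, censoringRate = 0.004,
                           horizonMonths = 300, seed = NULL) {
  if (nPatients < 4L) stop("nPatients must be at least 4")
  .assertScalarNum(baselineHazard, "baselineHazard", positive = TRUE)
  .assertScalarNum(censoringRate, "censoringRate", positive = TRUE)
  .assertScalarNum(horizonMonths, "horizonMonths", positive = TRUE)
  if (is.null(names(beta))) {
    names(beta) <- paste0("gene", seq_along(beta))
  }
  .withSeed(seed, {
    x <- matrix(rnorm(nPatients * length(beta)), nPatients, length(beta),
                dimnames = list(NULL, names(beta)))
    rate <- baselineHazard * exp(drop(x %*% beta))
    tEvent <- rexp(nPatients, rate)
    tCens <- pmin(rexp(nPatients, censoringRate), horizonMonths)
    cohort <- data.frame(id = sprintf("P%05d", seq_len(nPatients)),
                         time_months = pmin(tEvent, tCens),
                         event = as.integer(tEvent <= tCens),
                         stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(x))
    list(cohort = cohort, truth = beta)
  })
}

#' Simulate longitudinal bioluminescence radiance series
#'
#' Exponential tumor growth with multiplicative lognormal measurement
#' noise: `radiance(t) = radiance0 * 2^(t / doublingTime) * exp(e)` with
#' `e ~ N(0, sigma)` and `sigma = sqrt(log(1 + noiseCv^2))`; the day-0
#' measurement is noisy too. `doublingTime = Inf` gives flat growth
#' (noise only).
#'
#' @param doublingTimes Named numeric vector of doubling times in days,
#'   one per cell line. Defaults to the nine lines with 3.5 days for the
#'   two RG lines and 14 days for the seven MSG lines.
#' @param nMice Mice per cell line (default 3).
#' @param days Measurement days (default `c(0, 7, 14, 21, 28)`,
#'   bioluminescence every seven days).
#' @param radiance0 True day-0 radiance, instrument units (default 1e5).
#' @param noiseCv Coefficient of variation of the multiplicative noise
#'   (default 0.2).
#' @param seed Integer seed (see [simulateExpression()]).
#' @return List: `series` (`data.frame` with `cell_line`, `mouse_id`,
#'   `day`, `radiance`), `labels` (named RG/MSG truth when derivable from
#'   the default lines, else `NULL`), `doubling_times`.
#' @export
simulateBioluminescence <- function(doublingTimes = NULL, nMice = 3,
                                    days = c(0, 7, 14, 21, 28),
                                    radiance0 = 1e5, noiseCv = 0.2,
                                    seed = NULL) {
  if (is.null(doublingTimes)) {
    doublingTimes <- setNames(ifelse(cellLines() %in% rgLines(), 3.5, 14),
                              cellLines())
  }
  if (is.null(names(doublingTimes))) {
    stop("'doublingTimes' must be named by cell line")
  }
  if (any(doublingTimes <= 0)) stop("doubling times must be > 0")
  if (nMice < 1L) stop("nMice must be at least 1")
  if (noiseCv < 0) stop("noiseCv must be >= 0")
  .assertScalarNum(radiance0, "radiance0", positive = TRUE)
  if (!0 %in% days || is.unsorted(days, strictly = TRUE)) {
    stop("'days' must be strictly increasing and include day 0")
  }
  sigma <- sqrt(log(1 + noiseCv^2))
  .withSeed(seed, {
    parts <- lapply(names(doublingTimes), function(ln) {
      dt <- doublingTimes[[ln]]
      do.call(rbind, lapply(seq_len(nMice), function(mi) {
        r <- radiance0 * 2^(days / dt) * exp(rnorm(length(days), 0, sigma))
        data.frame(cell_line = ln, mouse_id = paste0(ln, "_m", mi),
                   day = days, radiance = r, stringsAsFactors = FALSE)
      }))
    })
    series <- do.call(rbind, parts)
    rownames(series) <- NULL
    labels <- if (setequal(names(doublingTimes), cellLines())) {
      defaultGroups()[names(doublingTimes)]
    } else NULL
    list(series = series, labels = labels, doubling_times = doublingTimes)
  })
}
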