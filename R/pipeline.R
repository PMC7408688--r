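#' Run the full analysis pipeline
#'
#' Orchestrates the three stages end to end: growth classification (if a
#' bioluminescence series is given), signature extraction (always;
#' expression and groups are required), and the survival screen (if a
#' cohort is given). Writes a results bundle to the output directory and
#' returns it invisibly. With fixed inputs, config and seed the bundle is
#' byte-identical across runs; wall-clock timestamps appear only in the
#' run log (`run.log`), never in the data files.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   flat keys:
#' \describe{
#'   \item{`expression`, `groups`}{paths to the expression TSV and the
#'     sample-group TSV (required).}
#'   \item{`series`}{optional path to a bioluminescence CSV.}
#'   \item{`cohort`}{optional path to a survival-cohort CSV.}
#'   \item{`zCut`, `rgConsistencyCut`, `rgMsgCut`}{signature thresholds
#'     (default 1.0 each).}
#'   \item{`rgZMode`}{`"mean"` (default) or `"each"`.}
#'   \item{`growthMethod`, `growthDay`, `growthThreshold`}{classification
#'     method (`"max_gap"` default), readout day (28), and the fixed
#'     threshold when applicable.}
#'   \item{`dichotomyStrategy`, `alpha`}{survival-screen settings
#'     (`"optimal_logrank"`, 0.05).}
#'   \item{`outDir`}{output directory (required).}
#'   \item{`seed`}{integer seed recorded in the bundle; the pipeline
#'     stages themselves are deterministic.}
#' }
#' @return Invisibly, a list of class `"ResultsBundle"`: `config` echo,
#'   `package_version`, `seed`, and per-stage results (`growth`,
#'   `signature`, `survival`; optional stages are the string
#'   `"skipped"`). On stage failure the partial output files are removed
#'   and the error is re-thrown tagged with the stage name.
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulateExpression(nGenes = 300, nUp = 5, nDown = 5, seed = 1)
#' writeExpressionMatrix(sim$expression, file.path(dir, "expr.tsv"))
#' g <- defaultGroups()
#' writeLines(paste(names(g), g, sep = "\t"), file.path(dir, "groups.tsv"))
#' bundle <- runPipeline(list(expression = file.path(dir, "expr.tsv"),
#'                            groups = file.path(dir, "groups.tsv"),
#'                            outDir = file.path(dir, "out"), seed = 1))
#' bundle$signature$n_up
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  defaults <- list(zCut = 1.0, rgConsistencyCut = 1.0, rgMsgCut = 1.0,
                   rgZMode = "mean", growthMethod = "max_gap",
                   growthDay = 28, growthThreshold = NULL,
                   dichotomyStrategy = "optimal_logrank", alpha = 0.05,
                   seed = NULL)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[k] <- defaults[k]
  }
  for (k in c("expression", "groups", "outDir")) {
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  }
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  logLines <- character()
  note <- function(stage, msg) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage,
                   "] ", msg)
    logLines <<- c(logLines, line)
    message(line)
  }
  out <- function(name) {
    p <- file.path(outDir, name)
    written <<- c(written, p)
    p
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)  # remove partial outputs
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  bundle <- list(config = config[!vapply(config, is.null, logical(1))],
                 package_version = as.character(packageVersion("brainsig")),
                 seed = config$seed)

  # --- growth ---------------------------------------------------------
  if (!is.null(config$series)) {
    bundle$growth <- runStage("classify-growth", {
      note("classify-growth", paste("reading", config$series))
      series <- readBioluminescence(config$series)
      ratios <- growthRatio(series)
      summ <- summarizeGrowth(ratios, day = config$growthDay)
      cls <- classifyGrowth(summ, method = config$growthMethod,
                            threshold = config$growthThreshold)
      write.table(data.frame(cell_line = names(summ),
                             in_vivo_growth = unname(summ),
                             label = unname(cls$labels[names(summ)])),
                  out("growth_summary.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      note("classify-growth",
           paste0("RG = {", paste(names(cls$labels)[cls$labels == "RG"],
                                  collapse = ", "), "}"))
      list(summary = as.list(summ), labels = as.list(cls$labels),
           threshold = cls$threshold, method = cls$method,
           day = config$growthDay)
    })
  } else {
    bundle$growth <- "skipped"
  }

  # --- signature ------------------------------------------------------
  bundle$signature <- runStage("extract-signature", {
    note("extract-signature", paste("reading", config$expression))
    expr <- readExpressionMatrix(config$expression)
    groups <- readSampleGroups(config$groups)
    expr <- assignGroups(expr, groups)
    gs <- computeGeneStats(expr)
    thr <- signatureThresholds(config$zCut, config$rgConsistencyCut,
                               config$rgMsgCut)
    sig <- extractSignature(gs, thr, rgZMode = config$rgZMode)
    writeGeneStats(gs, sig, out("gene_stats.tsv"))
    writeGeneSets(sig, out("signature.gmt"))
    clOrder <- NULL
    if (length(signatureUp(sig)) + length(signatureDown(sig)) >= 2L) {
      cl <- clusterSignature(expr, sig)
      clOrder <- cl$order
      writeLines(clOrder, out("clustering_order.tsv"))
    } else {
      note("extract-signature", "fewer than 2 signature features; clustering skipped")
    }
    note("extract-signature",
         paste0(length(signatureUp(sig)), " up / ",
                length(signatureDown(sig)), " down"))
    list(n_up = length(signatureUp(sig)),
         n_down = length(signatureDown(sig)),
         up = signatureUp(sig), down = signatureDown(sig),
         venn_sizes = lapply(vennSets(sig), length),
         thresholds = sig@thresholds,
         clustering_order = clOrder)
  })

  # --- survival -------------------------------------------------------
  if (!is.null(config$cohort)) {
    bundle$survival <- runStage("survival", {
      note("survival", paste("reading", config$cohort))
      cohort <- readSurvivalCohort(config$cohort)
      sigGenes <- c(bundle$signature$up, bundle$signature$down)
      present <- intersect(sigGenes, colnames(cohort))
      absent <- setdiff(sigGenes, present)
      if (length(absent)) {
        note("survival", paste(length(absent),
                               "signature gene(s) absent from the cohort"))
      }
      screen <- survivalScreen(cohort, present,
                               strategy = config$dichotomyStrategy,
                               alpha = config$alpha)
      write.table(screen, out("survival_screen.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
      note("survival", paste(sum(screen$flag != "ns"), "of",
                             nrow(screen), "genes flagged"))
      list(n_screened = nrow(screen),
           n_flagged = sum(screen$flag != "ns"),
           strategy = config$dichotomyStrategy, alpha = config$alpha,
           selection_inflated = isTRUE(attr(screen, "selection_inflated")),
           table = screen)
    })
  } else {
    bundle$survival <- "skipped"
  }

  jsonlite::write_json(bundle, file.path(outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(logLines, file.path(outDir, "run.log"))
  class(bundle) <- "ResultsBundle"
  invisible(bundle)
}

#' @export
print.ResultsBundle <- function(x, ...) {
  cat("ResultsBundle (brainsig", x$package_version, ")\n")
  for (st in c("growth", "signature", "survival")) {
    if (identical(x[[st]], "skipped")) {
      cat("  ", st, ": skipped\n", sep = "")
    } else {
      cat("  ", st, ": done\n", sep = "")
    }
  }
  invisible(x)
}
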