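#' BrainExpression: a log2 expression matrix with group labels
#'
#' S4 container for a genes/probes x samples matrix of log2 intensities,
#' extending [SummarizedExperiment::SummarizedExperiment]. The single assay
#' `"exprs"` holds the values; an optional `group` column of `colData`
#' assigns each sample to the rapid-growth (`"RG"`) or medium-to-slow-growth
#' (`"MSG"`) group; `metadata(x)$level` records whether rows are probes or
#' collapsed genes.
#'
#' Validity requires finite values, non-empty unique feature and sample
#' identifiers, and (when present) group labels restricted to RG/MSG with
#' both groups non-empty.
#'
#' @aliases BrainExpression-class
#' @exportClass BrainExpression
setClass("BrainExpression", contains = "SummarizedExperiment")

setValidity("BrainExpression", function(object) {
  msgs <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'exprs' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m)) msgs <- c(msgs, "'exprs' must be numeric")
    else if (any(!is.finite(m))) msgs <- c(msgs, "'exprs' values must all be finite")
  }
  if (is.null(rownames(object)) || nrow(object) == 0L) {
    msgs <- c(msgs, "feature identifiers (rownames) are required")
  } else if (anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "duplicate feature identifiers")
  }
  if (is.null(colnames(object)) || ncol(object) == 0L) {
    msgs <- c(msgs, "sample identifiers (colnames) are required")
  } else if (anyDuplicated(colnames(object))) {
    msgs <- c(msgs, "duplicate sample identifiers")
  }
  lv <- metadata(object)$level
  if (!is.null(lv) && !lv %in% c("probe", "gene")) {
    msgs <- c(msgs, "metadata 'level' must be 'probe' or 'gene'")
  }
  if ("group" %in% colnames(colData(object))) {
    g <- as.character(colData(object)$group)
    ok <- tryCatch({
      .validateGroupLabels(setNames(g, colnames(object)))
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BrainExpression object
#'
#' @param values Numeric matrix of log2 intensities with unique rownames
#'   (features) and colnames (samples). Values must be finite: upstream
#'   normalization and log2 transformation are assumed done.
#' @param level `"gene"` or `"probe"`; whether rows are collapsed gene
#'   symbols or array probes.
#' @param groups Optional named character vector mapping every sample to
#'   `"RG"` or `"MSG"`.
#' @return A [BrainExpression-class] object.
#' @examples
#' m <- matrix(rnorm(18), 2, 9,
#'             dimnames = list(c("TM4SF1", "CSTA"), cellLines()))
#' be <- BrainExpression(m, groups = defaultGroups())
#' be
#' @export
BrainExpression <- function(values, level = c("gene", "probe"), groups = NULL) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  se <- SummarizedExperiment(assays = list(exprs = values))
  obj <- new("BrainExpression", se)
  metadata(obj)$level <- level
  if (!is.null(groups)) obj <- assignGroups(obj, groups)
  validObject(obj)
  obj
}

#' BrainSignature: up/down brain-colonization signature gene sets
#'
#' S4 result of [extractSignature()]: the upregulated and downregulated
#' signature feature sets, the per-feature statistics restricted to the
#' signature, the four Venn partition sets, and the thresholds used.
#'
#' @slot up character; features upregulated in the RG.
#' @slot down character; features downregulated in the RG.
#' @slot stats [S4Vectors::DataFrame] of per-feature statistics
#'   (`rg_logfc`, `rg_msg_logfc`, `rg_z`, `msg_z`) for `up` and `down`.
#' @slot venn list of four character vectors: `rg_up`, `rg_down`,
#'   `msg_up`, `msg_down`.
#' @slot thresholds list echoing the thresholds and the RG z-score mode.
#' @aliases BrainSignature-class
#' @exportClass BrainSignature
setClass("BrainSignature",
         representation(up = "character", down = "character",
                        stats = "DFrame", venn = "list",
                        thresholds = "list"))

setValidity("BrainSignature", function(object) {
  msgs <- character()
  if (length(intersect(object@up, object@down))) {
    msgs <- c(msgs, "up and down sets must be disjoint")
  }
  need <- c("rg_up", "rg_down", "msg_up", "msg_down")
  if (!all(need %in% names(object@venn))) {
    msgs <- c(msgs, "venn must contain rg_up, rg_down, msg_up, msg_down")
  } else {
    if (length(intersect(object@venn$rg_up, object@venn$rg_down))) {
      msgs <- c(msgs, "venn rg_up and rg_down must be disjoint")
    }
    if (length(intersect(object@venn$msg_up, object@venn$msg_down))) {
      msgs <- c(msgs, "venn msg_up and msg_down must be disjoint")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BrainExpression", function(object) {
  g <- sampleGroups(object)
  cat("BrainExpression (", metadata(object)$level, "-level): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  if (is.null(g)) {
    cat("  groups: unassigned\n")
  } else {
    cat("  groups: RG = ", sum(g == "RG"), ", MSG = ", sum(g == "MSG"), "\n",
        sep = "")
  }
})

setMethod("show", "BrainSignature", function(object) {
  cat("BrainSignature: ", length(object@up), " up / ", length(object@down),
      " down (", length(object@up) + length(object@down), " features)\n",
      sep = "")
  vs <- vapply(object@venn, length, integer(1))
  cat("  Venn sets: ", paste(names(vs), vs, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  thresholds: z > ", object@thresholds$zCut,
      ", |RG consistency logFC| < ", object@thresholds$rgConsistencyCut,
      ", |RG-MSG logFC| > ", object@thresholds$rgMsgCut,
      " (RG z mode: ", object@thresholds$rgZMode, ")\n", sep = "")
})
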