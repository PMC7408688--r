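#' Accessors for BrainExpression and BrainSignature
#'
#' @param x A [BrainExpression-class] or [BrainSignature-class] object.
#' @param groups Named character vector mapping every sample of `x` to
#'   `"RG"` or `"MSG"`.
#' @return `exprValues()`: the numeric log2 matrix. `sampleGroups()`: the
#'   named RG/MSG vector, or `NULL` if unassigned. `featureLevel()`:
#'   `"gene"` or `"probe"`. `assignGroups()`: `x` with groups set.
#'   `signatureUp()`/`signatureDown()`: character feature sets.
#'   `signatureStats()`: per-feature statistics `DataFrame`.
#'   `vennSets()`: the four Venn partition sets.
#' @name brainsig-accessors
NULL

#' @rdname brainsig-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname brainsig-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname brainsig-accessors
#' @export
setGeneric("featureLevel", function(x) standardGeneric("featureLevel"))

#' @rdname brainsig-accessors
#' @export
setGeneric("assignGroups", function(x, groups) standardGeneric("assignGroups"))

#' @rdname brainsig-accessors
#' @export
setGeneric("signatureUp", function(x) standardGeneric("signatureUp"))

#' @rdname brainsig-accessors
#' @export
setGeneric("signatureDown", function(x) standardGeneric("signatureDown"))

#' @rdname brainsig-accessors
#' @export
setGeneric("signatureStats", function(x) standardGeneric("signatureStats"))

#' @rdname brainsig-accessors
#' @export
setGeneric("vennSets", function(x) standardGeneric("vennSets"))

#' @rdname brainsig-accessors
setMethod("exprValues", "BrainExpression", function(x) {
  SummarizedExperiment::assay(x, "exprs")
})

#' @rdname brainsig-accessors
setMethod("sampleGroups", "BrainExpression", function(x) {
  cd <- colData(x)
  if (!"group" %in% colnames(cd)) return(NULL)
  setNames(as.character(cd$group), colnames(x))
})

#' @rdname brainsig-accessors
setMethod("featureLevel", "BrainExpression", function(x) metadata(x)$level)

#' @rdname brainsig-accessors
setMethod("assignGroups", "BrainExpression", function(x, groups) {
  missing <- setdiff(colnames(x), names(groups))
  if (length(missing)) {
    stop("samples without a group assignment: ",
         paste(missing, collapse = ", "))
  }
  .validateGroupLabels(groups)
  colData(x)$group <- unname(groups[colnames(x)])
  validObject(x)
  x
})

#' @rdname brainsig-accessors
setMethod("signatureUp", "BrainSignature", function(x) x@up)

#' @rdname brainsig-accessors
setMethod("signatureDown", "BrainSignature", function(x) x@down)

#' @rdname brainsig-accessors
setMethod("signatureStats", "BrainSignature", function(x) x@stats)

#' @rdname brainsig-accessors
setMethod("vennSets", "BrainSignature", function(x) x@venn)
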