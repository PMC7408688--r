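#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers,
#' feature identifiers in the first column, and a numeric body ("." decimal,
#' no quoting). Values are taken as already log2-transformed and
#' normalized; only finiteness is validated.
#'
#' @param path Path to the TSV file.
#' @param level `"gene"` or `"probe"`.
#' @return A [BrainExpression-class] object preserving file order.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, level = c("gene", "probe")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("malformed expression file (no features or no sample columns): ",
         path)
  }
  feats <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(feats)) {
    stop("duplicate feature id(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]], feats[bad[1L, 1L]],
                 samples[bad[1L, 2L]]))
  }
  dimnames(vals) <- list(feats, samples)
  BrainExpression(vals, level = level)
}

#' Write a log2 expression matrix to TSV
#'
#' Values are written with 17 significant digits so that
#' write-then-read round trips are exact for IEEE doubles.
#'
#' @param x A [BrainExpression-class] object or numeric matrix with
#'   dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- if (is(x, "BrainExpression")) exprValues(x) else x
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop("'x' must be a BrainExpression or a matrix with dimnames")
  }
  header <- paste(c("feature", colnames(m)), collapse = "\t")
  chr <- array(.fmtNum(m), dim = dim(m))
  lines <- c(header,
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], chr[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-to-group assignment from TSV
#'
#' Headerless two-column tab-delimited file: sample id, group label
#' (`RG` or `MSG`). Both groups must be non-empty. Whether every sample of
#' an expression matrix is covered is checked when the two are joined
#' (see [assignGroups()]), not here.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample id to `"RG"`/`"MSG"`.
#' @export
readSampleGroups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, check.names = FALSE, quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("malformed group file (expected two tab-separated columns): ", path)
  }
  groups <- setNames(df[[2L]], df[[1L]])
  .validateGroupLabels(groups)
  groups
}

#' Collapse probe-level rows to gene level
#'
#' @param x A probe-level [BrainExpression-class] object.
#' @param map Named character vector mapping every probe id of `x` to a
#'   gene symbol (many-to-one allowed).
#' @param method `"max_mean"` keeps, per gene, the probe with the highest
#'   row mean (the common microarray convention; ties broken by input
#'   order); `"mean"` averages probes per gene.
#' @return A gene-level [BrainExpression-class] object with one row per
#'   distinct gene, in order of first appearance.
#' @export
collapseProbes <- function(x, map, method = c("max_mean", "mean")) {
  method <- match.arg(method)
  if (!is(x, "BrainExpression")) stop("'x' must be a BrainExpression")
  if (!identical(featureLevel(x), "probe")) {
    stop("'x' must be probe-level (featureLevel(x) == 'probe')")
  }
  m <- exprValues(x)
  missing <- setdiff(rownames(m), names(map))
  if (length(missing)) {
    stop("probe(s) missing from the probe-gene map: ",
         paste(missing, collapse = ", "))
  }
  genes <- unname(map[rownames(m)])
  geneOrder <- unique(genes)
  rows <- lapply(geneOrder, function(g) {
    idx <- which(genes == g)
    if (method == "mean") {
      colMeans(m[idx, , drop = FALSE])
    } else {
      rm_ <- rowMeans(m[idx, , drop = FALSE])
      m[idx[which.max(rm_)], ]
    }
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(geneOrder, colnames(m))
  BrainExpression(out, level = "gene", groups = sampleGroups(x))
}

#' Write signature gene sets to a GMT file
#'
#' Two records, `RG_UP` and `RG_DOWN`, one per line:
#' `name<TAB>description<TAB>member1<TAB>member2...`. Empty sets are
#' written as valid zero-member records.
#'
#' @param sig A [BrainSignature-class] object, or a list with character
#'   elements `up` and `down`.
#' @param path Output path.
#' @param description Description field written for both records.
#' @return Invisibly, `path`.
#' @seealso [readGeneSets()]
#' @export
writeGeneSets <- function(sig, path,
                          description = "brain-colonization signature") {
  if (is(sig, "BrainSignature")) {
    sig <- list(up = signatureUp(sig), down = signatureDown(sig))
  }
  lines <- c(paste(c("RG_UP", description, sig$up), collapse = "\t"),
             paste(c("RG_DOWN", description, sig$down), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name to members).
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT record: ", l)
    f[-c(1L, 2L)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  sets
}
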