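#' Per-gene z-scores across samples
#'
#' Standardizes every row of the log2 matrix across all samples jointly:
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation by
#' default. Constant rows map to all-zero z by convention; their count is
#' reported via [message()].
#'
#' @param x A [BrainExpression-class] object or numeric matrix with at
#'   least two columns.
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator).
#' @return Numeric matrix of z-scores, same dimensions and dimnames as the
#'   input.
#' @examples
#' zscoreMatrix(rbind(a = c(1, 2, 3)))
#' @export
zscoreMatrix <- function(x, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  m <- if (is(x, "BrainExpression")) exprValues(x) else x
  if (!is.matrix(m) || !is.numeric(m)) stop("'x' must be a numeric matrix")
  n <- ncol(m)
  if (n < 2L) stop("z-scores need at least two samples")
  mu <- rowMeans(m)
  centered <- m - mu
  ss <- rowSums(centered^2)
  s <- sqrt(ss / (if (sdType == "sample") n - 1L else n))
  const <- s == 0
  s[const] <- 1  # avoid 0/0; rows overwritten below
  z <- centered / s
  if (any(const)) {
    z[const, ] <- 0
    message(sum(const), " constant feature(s) mapped to z = 0")
  }
  z
}

#' Per-gene signature statistics
#'
#' Computes, for every feature, the quantities the signature filter uses:
#' \describe{
#'   \item{`rg_logfc`}{within-RG consistency log2 fold-change: expression
#'     in the second RG sample of `rgOrder` minus the first (by default
#'     MDA-MB-453 minus UACC-893).}
#'   \item{`rg_msg_logfc`}{RG mean minus MSG mean on the log2 scale.}
#'   \item{`rg_z`, `msg_z`}{group means of the per-sample z-scores
#'     (computed across all samples jointly).}
#'   \item{`rg_z_min`, `rg_z_max`}{the smaller/larger of the two RG
#'     samples' z-scores, for the stricter "each RG sample exceeds" mode.}
#' }
#'
#' @param x A [BrainExpression-class] object or numeric log2 matrix.
#' @param groups Named RG/MSG vector; defaults to `sampleGroups(x)`.
#'   RG must contain exactly two samples (the consistency logFC is a
#'   pairwise difference).
#' @param rgOrder Ordered pair of RG sample ids; the logFC is second minus
#'   first. Defaults to `rgLines()` when those are the RG samples,
#'   otherwise to the RG samples in matrix column order.
#' @param sdType Passed to [zscoreMatrix()].
#' @return [S4Vectors::DataFrame] with one row per feature and columns
#'   `feature`, `rg_logfc`, `rg_msg_logfc`, `rg_z`, `msg_z`, `rg_z_min`,
#'   `rg_z_max`. The full z-score matrix, the groups and `rgOrder` are
#'   attached as metadata.
#' @export
computeGeneStats <- function(x, groups = NULL, rgOrder = NULL,
                             sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  m <- if (is(x, "BrainExpression")) exprValues(x) else x
  if (is.null(groups) && is(x, "BrainExpression")) groups <- sampleGroups(x)
  if (is.null(groups)) stop("no group assignment supplied or attached")
  .validateGroupLabels(groups)
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing)) {
    stop("samples without a group assignment: ",
         paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(m)]
  rg <- names(groups)[groups == "RG"]
  msg <- names(groups)[groups == "MSG"]
  if (length(rg) != 2L) {
    stop("the within-RG consistency logFC requires exactly 2 RG samples; got ",
         length(rg))
  }
  if (is.null(rgOrder)) {
    rgOrder <- if (setequal(rg, rgLines())) rgLines() else rg
  }
  if (!setequal(rgOrder, rg) || length(rgOrder) != 2L) {
    stop("'rgOrder' must be an ordering of the two RG samples")
  }
  z <- suppressMessages(zscoreMatrix(m, sdType = sdType))
  zr <- z[, rg, drop = FALSE]
  out <- DataFrame(
    feature = rownames(m),
    rg_logfc = unname(m[, rgOrder[2L]] - m[, rgOrder[1L]]),
    rg_msg_logfc = unname(rowMeans(m[, rg, drop = FALSE]) -
                          rowMeans(m[, msg, drop = FALSE])),
    rg_z = unname(rowMeans(zr)),
    msg_z = unname(rowMeans(z[, msg, drop = FALSE])),
    rg_z_min = unname(pmin(zr[, 1L], zr[, 2L])),
    rg_z_max = unname(pmax(zr[, 1L], zr[, 2L])),
    row.names = rownames(m))
  metadata(out) <- list(z = z, groups = groups, rgOrder = rgOrder)
  out
}

#' Signature filter thresholds
#'
#' @param zCut Z-score cut (default 1.0): up/down requires the RG (or MSG)
#'   z-score strictly above `zCut` / below `-zCut`.
#' @param rgConsistencyCut Within-RG consistency bound (default 1.0): the
#'   two RG samples must agree, `|rg_logfc|` strictly below the cut.
#' @param rgMsgCut RG-vs-MSG differential cut (default 1.0):
#'   `|rg_msg_logfc|` strictly above the cut, in the concordant direction.
#' @return List of validated thresholds.
#' @export
signatureThresholds <- function(zCut = 1.0, rgConsistencyCut = 1.0,
                                rgMsgCut = 1.0) {
  .assertScalarNum(zCut, "zCut", positive = TRUE)
  .assertScalarNum(rgConsistencyCut, "rgConsistencyCut", positive = TRUE)
  .assertScalarNum(rgMsgCut, "rgMsgCut", positive = TRUE)
  list(zCut = zCut, rgConsistencyCut = rgConsistencyCut, rgMsgCut = rgMsgCut)
}

# RG z-score criterion under the selected mode; strict inequalities.
.rgZUp <- function(stats, zCut, rgZMode) {
  if (rgZMode == "mean") stats$rg_z > zCut else stats$rg_z_min > zCut
}
.rgZDown <- function(stats, zCut, rgZMode) {
  if (rgZMode == "mean") stats$rg_z < -zCut else stats$rg_z_max < -zCut
}

#' Venn partition of up/down regulated features by group
#'
#' The four sets displayed in the Venn diagrams, all with strict
#' inequalities:
#' * `rg_up`: `-cut < rg_logfc < cut` and RG z-score `> zCut`
#' * `rg_down`: `-cut < rg_logfc < cut` and RG z-score `< -zCut`
#' * `msg_up`: `msg_z > zCut`
#' * `msg_down`: `msg_z < -zCut`
#'
#' @param stats Output of [computeGeneStats()].
#' @param thresholds Output of [signatureThresholds()].
#' @param rgZMode `"mean"`: the RG z-score is the mean of the two RG
#'   samples' z-scores (default); `"each"`: both RG samples must
#'   individually pass the cut.
#' @return Named list of four character vectors.
#' @export
vennPartition <- function(stats, thresholds = signatureThresholds(),
                          rgZMode = c("mean", "each")) {
  rgZMode <- match.arg(rgZMode)
  cons <- stats$rg_logfc > -thresholds$rgConsistencyCut &
          stats$rg_logfc < thresholds$rgConsistencyCut
  f <- stats$feature
  list(rg_up   = f[cons & .rgZUp(stats, thresholds$zCut, rgZMode)],
       rg_down = f[cons & .rgZDown(stats, thresholds$zCut, rgZMode)],
       msg_up  = f[stats$msg_z > thresholds$zCut],
       msg_down = f[stats$msg_z < -thresholds$zCut])
}

#' Extract the brain-colonization signature
#'
#' Applies the two three-way conjunctions that define the signature, with
#' strict inequalities throughout:
#' * **up**: `-cut < rg_logfc < cut`, `rg_msg_logfc > rgMsgCut`, and RG
#'   z-score `> zCut`;
#' * **down**: `-cut < rg_logfc < cut`, `rg_msg_logfc < -rgMsgCut`, and RG
#'   z-score `< -zCut`.
#'
#' The two sets are disjoint by construction, and each is a subset of the
#' corresponding Venn set at identical thresholds. Negating every
#' expression value swaps the up and down sets exactly.
#'
#' @inheritParams vennPartition
#' @return A [BrainSignature-class] object.
#' @examples
#' sim <- simulateExpression(nGenes = 200, nUp = 5, nDown = 5, seed = 1)
#' gs <- computeGeneStats(sim$expression)
#' extractSignature(gs)
#' @export
extractSignature <- function(stats, thresholds = signatureThresholds(),
                             rgZMode = c("mean", "each")) {
  rgZMode <- match.arg(rgZMode)
  cons <- stats$rg_logfc > -thresholds$rgConsistencyCut &
          stats$rg_logfc < thresholds$rgConsistencyCut
  up <- cons & stats$rg_msg_logfc > thresholds$rgMsgCut &
        .rgZUp(stats, thresholds$zCut, rgZMode)
  down <- cons & stats$rg_msg_logfc < -thresholds$rgMsgCut &
          .rgZDown(stats, thresholds$zCut, rgZMode)
  venn <- vennPartition(stats, thresholds, rgZMode)
  keep <- up | down
  new("BrainSignature",
      up = stats$feature[up], down = stats$feature[down],
      stats = stats[keep, , drop = FALSE], venn = venn,
      thresholds = c(thresholds, list(rgZMode = rgZMode)))
}

#' Hierarchically cluster signature features
#'
#' Agglomerative clustering of feature rows of a z-score submatrix, as
#' used to order the rows of the signature heatmap. Columns are not
#' clustered (samples stay in fixed group order, RG first). Deterministic:
#' ties are broken by input order, and the leaf order follows the merge
#' tree's standard left-before-right convention.
#'
#' @param z Numeric matrix (features x samples), typically the z-score
#'   rows of the signature features; or a [BrainExpression-class] plus
#'   `sig` to subset.
#' @param sig Optional [BrainSignature-class]; when supplied with a
#'   `BrainExpression` `z`, the z-score rows of `up` then `down` features
#'   are clustered.
#' @param linkage `"complete"` (default, the usual heatmap default) or
#'   `"average"`.
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson correlation between rows).
#' @return List of class `"SignatureClustering"` with elements `order`
#'   (leaf-ordered feature names), `merge`, `height` (as in
#'   [stats::hclust()]) and `hclust` (the full object).
#' @export
clusterSignature <- function(z, sig = NULL,
                             linkage = c("complete", "average"),
                             distance = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (is(z, "BrainExpression")) {
    zm <- suppressMessages(zscoreMatrix(z))
    if (!is.null(sig)) {
      feats <- c(signatureUp(sig), signatureDown(sig))
      zm <- zm[feats, , drop = FALSE]
    }
    g <- sampleGroups(z)
    if (!is.null(g)) {  # fixed column order: RG first
      zm <- zm[, c(names(g)[g == "RG"], names(g)[g == "MSG"]), drop = FALSE]
    }
    z <- zm
  }
  if (!is.matrix(z) || nrow(z) < 2L) {
    stop("clustering needs at least 2 signature features")
  }
  d <- if (distance == "euclidean") {
    dist(z, method = "euclidean")
  } else {
    stats::as.dist(1 - stats::cor(t(z)))
  }
  hc <- hclust(d, method = linkage)
  structure(list(order = rownames(z)[hc$order], merge = hc$merge,
                 height = hc$height, hclust = hc),
            class = "SignatureClustering")
}

#' @export
print.SignatureClustering <- function(x, ...) {
  cat("SignatureClustering of", length(x$order), "features;",
      "first leaves:", paste(utils::head(x$order, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Write per-feature signature statistics to TSV
#'
#' One row per feature with columns `feature`, `rg_logfc`, `rg_msg_logfc`,
#' `rg_z`, `msg_z` and `flag` (`up`, `down` or `none`).
#'
#' @param stats Output of [computeGeneStats()].
#' @param sig A [BrainSignature-class] used for the flag column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGeneStats <- function(stats, sig, path) {
  flag <- rep("none", nrow(stats))
  flag[stats$feature %in% signatureUp(sig)] <- "up"
  flag[stats$feature %in% signatureDown(sig)] <- "down"
  df <- data.frame(feature = stats$feature,
                   rg_logfc = stats$rg_logfc,
                   rg_msg_logfc = stats$rg_msg_logfc,
                   rg_z = stats$rg_z, msg_z = stats$msg_z,
                   flag = flag, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
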