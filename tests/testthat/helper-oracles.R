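# Independent brute-force oracles and fixture builders. These deliberately
# use plain loops and hand formulas, never the package's vectorized paths.

# random log2 matrix with the nine cell-line samples
randomExpr <- function(nGenes, seed) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * 9, mean = 8, sd = 1.5), nGenes, 9,
              dimnames = list(sprintf("g%04d", seq_len(nGenes)), cellLines()))
  m
}

# per-gene loop recomputation of all signature statistics
bruteGeneStats <- function(m, groups, rgOrder) {
  rg <- names(groups)[groups == "RG"]
  msg <- names(groups)[groups == "MSG"]
  out <- data.frame(feature = rownames(m), rg_logfc = NA_real_,
                    rg_msg_logfc = NA_real_, rg_z = NA_real_,
                    msg_z = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    s <- stats::sd(x)
    z <- if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    names(z) <- colnames(m)
    out$rg_logfc[i] <- x[rgOrder[2]] - x[rgOrder[1]]
    out$rg_msg_logfc[i] <- mean(x[rg]) - mean(x[msg])
    out$rg_z[i] <- mean(z[rg])
    out$msg_z[i] <- mean(z[msg])
  }
  out
}

# exhaustive per-gene predicate evaluation of the signature filter
bruteSignature <- function(m, groups, rgOrder, zCut = 1, consCut = 1,
                           msgCut = 1) {
  st <- bruteGeneStats(m, groups, rgOrder)
  up <- character(); down <- character()
  for (i in seq_len(nrow(st))) {
    cons <- st$rg_logfc[i] > -consCut && st$rg_logfc[i] < consCut
    if (cons && st$rg_msg_logfc[i] > msgCut && st$rg_z[i] > zCut) {
      up <- c(up, st$feature[i])
    }
    if (cons && st$rg_msg_logfc[i] < -msgCut && st$rg_z[i] < -zCut) {
      down <- c(down, st$feature[i])
    }
  }
  list(up = up, down = down)
}

# exhaustive Venn partition
bruteVenn <- function(m, groups, rgOrder, zCut = 1, consCut = 1) {
  st <- bruteGeneStats(m, groups, rgOrder)
  sets <- list(rg_up = character(), rg_down = character(),
               msg_up = character(), msg_down = character())
  for (i in seq_len(nrow(st))) {
    cons <- st$rg_logfc[i] > -consCut && st$rg_logfc[i] < consCut
    if (cons && st$rg_z[i] > zCut) sets$rg_up <- c(sets$rg_up, st$feature[i])
    if (cons && st$rg_z[i] < -zCut) sets$rg_down <- c(sets$rg_down, st$feature[i])
    if (st$msg_z[i] > zCut) sets$msg_up <- c(sets$msg_up, st$feature[i])
    if (st$msg_z[i] < -zCut) sets$msg_down <- c(sets$msg_down, st$feature[i])
  }
  sets
}

# O(n^3) agglomerative clustering from first principles (complete or
# average linkage on a distance matrix); returns merge heights in order.
bruteAgglomerate <- function(d, linkage = "complete") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestH <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        h <- if (linkage == "complete") max(dd) else mean(dd)
        if (h < bestH) { bestH <- h; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bestH)
  }
  heights
}

# empirical survivor function at each event time (no-censoring oracle)
ecdfSurvivor <- function(times) {
  ts <- sort(unique(times))
  vapply(ts, function(t) mean(times > t), numeric(1))
}

# write a standard nine-line group TSV
writeGroupsTsv <- function(path, groups = defaultGroups()) {
  writeLines(paste(names(groups), groups, sep = "\t"), path)
  path
}
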