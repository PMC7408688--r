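test_that("z-scores standardize rows and zero out constant genes", {
  expect_equal(unname(zscoreMatrix(rbind(a = c(1, 2, 3)))[1, ]),
               c(-1, 0, 1))
  expect_message(z <- zscoreMatrix(rbind(a = c(5, 5, 5), b = c(1, 2, 3))),
                 "1 constant feature")
  expect_equal(unname(z["a", ]), c(0, 0, 0))
  expect_error(zscoreMatrix(matrix(1, 3, 1)), "two samples")
})

test_that("gene stats match hand values and a per-gene loop oracle", {
  groups <- defaultGroups()
  m <- randomExpr(6, seed = 5)
  # constant groups: RG both 4, MSG all 2
  m[1, ] <- ifelse(colnames(m) %in% rgLines(), 4, 2)
  # RG pair 10 / 11.5 in rgOrder
  m[2, "UACC-893"] <- 10; m[2, "MDA-MB-453"] <- 11.5
  gs <- computeGeneStats(m, groups)
  expect_equal(gs$rg_logfc[1], 0)
  expect_equal(gs$rg_msg_logfc[1], 2)
  expect_equal(gs$rg_logfc[2], 1.5)

  big <- randomExpr(500, seed = 42)
  got <- computeGeneStats(big, groups)
  want <- bruteGeneStats(big, groups, rgLines())
  expect_equal(got$rg_logfc, want$rg_logfc)
  expect_equal(got$rg_msg_logfc, want$rg_msg_logfc)
  expect_equal(got$rg_z, want$rg_z)
  expect_equal(got$msg_z, want$msg_z)

  oneRg <- setNames(c("RG", rep("MSG", 8)), cellLines())
  expect_error(computeGeneStats(big, oneRg), "exactly 2 RG samples")
})

test_that("Venn partition applies strict criteria, matching brute force", {
  m <- randomExpr(400, seed = 7)
  gs <- computeGeneStats(m, defaultGroups())
  got <- vennPartition(gs)
  want <- bruteVenn(m, defaultGroups(), rgLines())
  for (s in names(want)) expect_setequal(got[[s]], want[[s]])

  # boundary conventions on a crafted stats table
  st <- S4Vectors::DataFrame(feature = c("consViol", "zBoundary"),
                             rg_logfc = c(1.5, 0),
                             rg_msg_logfc = c(2, 2),
                             rg_z = c(2, 1.0),
                             msg_z = c(0, 0),
                             rg_z_min = c(2, 1.0), rg_z_max = c(2, 1.0))
  v <- vennPartition(st)
  expect_false("consViol" %in% v$rg_up)   # |rg_logfc| bound violated
  expect_false("zBoundary" %in% v$rg_up)  # strict: z == cut excluded
  sig <- extractSignature(st)
  expect_length(signatureUp(sig), 0)
})

test_that("signature extraction equals exhaustive predicate evaluation", {
  for (seed in 1:5) {
    m <- randomExpr(300, seed = 200 + seed)
    gs <- computeGeneStats(m, defaultGroups())
    sig <- extractSignature(gs)
    want <- bruteSignature(m, defaultGroups(), rgLines())
    expect_setequal(signatureUp(sig), want$up)
    expect_setequal(signatureDown(sig), want$down)
    # Venn consistency at identical thresholds
    expect_true(all(signatureUp(sig) %in% vennSets(sig)$rg_up))
    expect_true(all(signatureDown(sig) %in% vennSets(sig)$rg_down))
  }
})

test_that("negating the matrix swaps up and down sets exactly", {
  m <- randomExpr(300, seed = 9)
  g <- defaultGroups()
  a <- extractSignature(computeGeneStats(m, g))
  b <- extractSignature(computeGeneStats(-m, g))
  expect_setequal(signatureUp(a), signatureDown(b))
  expect_setequal(signatureDown(a), signatureUp(b))
})

test_that("thresholds act monotonically on the signature sets", {
  m <- randomExpr(400, seed = 13)
  gs <- computeGeneStats(m, defaultGroups())
  base <- extractSignature(gs, signatureThresholds(0.5, 1.0, 0.5))
  stricterZ <- extractSignature(gs, signatureThresholds(0.9, 1.0, 0.5))
  stricterFc <- extractSignature(gs, signatureThresholds(0.5, 1.0, 0.9))
  looserCons <- extractSignature(gs, signatureThresholds(0.5, 2.0, 0.5))
  expect_true(all(signatureUp(stricterZ) %in% signatureUp(base)))
  expect_true(all(signatureDown(stricterZ) %in% signatureDown(base)))
  expect_true(all(signatureUp(stricterFc) %in% signatureUp(base)))
  expect_true(all(signatureDown(stricterFc) %in% signatureDown(base)))
  expect_true(all(signatureUp(base) %in% signatureUp(looserCons)))
  expect_true(all(signatureDown(base) %in% signatureDown(looserCons)))
})

test_that("the strict per-sample RG z mode is a subset of the mean mode", {
  m <- randomExpr(500, seed = 21)
  gs <- computeGeneStats(m, defaultGroups())
  thr <- signatureThresholds(0.5, 1.0, 0.5)
  meanMode <- extractSignature(gs, thr, rgZMode = "mean")
  eachMode <- extractSignature(gs, thr, rgZMode = "each")
  expect_true(all(signatureUp(eachMode) %in% signatureUp(meanMode)))
  expect_true(all(signatureDown(eachMode) %in% signatureDown(meanMode)))
})

test_that("hierarchical clustering is deterministic and matches brute force", {
  z <- rbind(A = c(0, 0, 0), B = c(0, 0, 0), C = c(5, 5, 5))
  cl <- clusterSignature(z)
  expect_equal(cl$height[1], 0)                  # identical rows merge at 0
  expect_setequal(rownames(z)[-cl$merge[1, ]], c("A", "B"))  # nearest pair first

  set.seed(31)
  z20 <- matrix(rnorm(20 * 9), 20, 9,
                dimnames = list(sprintf("f%02d", 1:20), cellLines()))
  for (link in c("complete", "average")) {
    cl20 <- clusterSignature(z20, linkage = link)
    expect_equal(cl20$height, bruteAgglomerate(dist(z20), link))
    expect_setequal(cl20$order, rownames(z20))   # leaf order is a permutation
  }
  expect_error(clusterSignature(z20[1, , drop = FALSE]), "at least 2")
})
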