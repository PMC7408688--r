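test_that("expression TSV read/write round-trips exactly and preserves order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "a\t1\t2", "b\t3\t4", "c\t5\t6"), path)
  be <- readExpressionMatrix(path)
  expect_identical(rownames(be), c("a", "b", "c"))
  expect_identical(colnames(be), c("s1", "s2"))
  expect_equal(unname(exprValues(be)),
               matrix(c(1, 3, 5, 2, 4, 6), 3, 2))

  set.seed(11)
  m <- matrix(rnorm(200 * 9), 200, 9,
              dimnames = list(sprintf("g%03d", 1:200), cellLines()))
  out <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, out)
  back <- readExpressionMatrix(out)
  expect_identical(exprValues(back), m)  # full precision
})

test_that("malformed expression files are rejected with located errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1", "A\t1", "A\t2"), dup)
  expect_error(readExpressionMatrix(dup), "duplicate feature")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "A\t1\toops"), bad)
  expect_error(readExpressionMatrix(bad), "'oops'.*feature 'A'.*sample 's2'")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("feature\ts1", empty)
  expect_error(readExpressionMatrix(empty), "malformed")
})

test_that("sample group files are validated", {
  ok <- withr::local_tempfile(fileext = ".tsv")
  writeGroupsTsv(ok)
  g <- readSampleGroups(ok)
  expect_identical(sum(g == "RG"), 2L)
  expect_identical(sum(g == "MSG"), 7L)
  expect_setequal(names(g)[g == "RG"], rgLines())

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tRG", "B\tFAST"), bad)
  expect_error(readSampleGroups(bad), "unknown group label")

  onlyMsg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tMSG", "B\tMSG"), onlyMsg)
  expect_error(readSampleGroups(onlyMsg), "non-empty")
})

test_that("probe collapse matches its definition and a brute-force oracle", {
  m <- rbind(p1 = c(5, 5), p2 = c(7, 7), p3 = c(1, 3))
  colnames(m) <- c("s1", "s2")
  be <- BrainExpression(m, level = "probe")
  map <- c(p1 = "G", p2 = "G", p3 = "H")

  mm <- collapseProbes(be, map, method = "max_mean")
  expect_equal(exprValues(mm)["G", ], c(s1 = 7, s2 = 7))  # higher-mean probe
  expect_equal(exprValues(mm)["H", ], c(s1 = 1, s2 = 3))  # single probe unchanged

  set.seed(3)
  probes <- sprintf("p%02d", 1:50)
  genes <- sample(sprintf("G%02d", 1:20), 50, replace = TRUE)
  names(genes) <- probes
  mr <- matrix(rnorm(50 * 4), 50, 4,
               dimnames = list(probes, paste0("s", 1:4)))
  got <- collapseProbes(BrainExpression(mr, level = "probe"), genes,
                        method = "mean")
  expect_identical(nrow(got), length(unique(genes)))
  for (g in rownames(got)) {
    expect_equal(exprValues(got)[g, ],
                 colMeans(mr[names(genes)[genes == g], , drop = FALSE]))
  }

  expect_error(collapseProbes(be, c(p1 = "G"), method = "mean"),
               "missing from the probe-gene map")
})

test_that("GMT gene sets round-trip, including empty sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGeneSets(list(up = c("A", "B"), down = "C"), path, description = "d")
  lines <- readLines(path)
  expect_identical(lines[1], "RG_UP\td\tA\tB")
  back <- readGeneSets(path)
  expect_identical(back, list(RG_UP = c("A", "B"), RG_DOWN = "C"))

  writeGeneSets(list(up = character(), down = character()), path)
  back <- readGeneSets(path)
  expect_length(back$RG_UP, 0)
  expect_length(back$RG_DOWN, 0)
  expect_named(back, c("RG_UP", "RG_DOWN"))
})

test_that("BrainExpression enforces its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(BrainExpression(m * NA), "finite")
  expect_error(assignGroups(BrainExpression(m), c(x = "RG", y = "FAST")),
               "unknown group label")
  expect_error(assignGroups(BrainExpression(m), c(x = "RG")), "without a group")
  be <- assignGroups(BrainExpression(m), c(x = "RG", y = "MSG"))
  expect_identical(sampleGroups(be), c(x = "RG", y = "MSG"))
})
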