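# Build a full synthetic input set in `dir` and return a pipeline config.
makePipelineInputs <- function(dir, seed = 1, withGrowth = TRUE,
                               withCohort = TRUE) {
  sim <- simulateExpression(nGenes = 400, nUp = 6, nDown = 6, seed = seed)
  exprPath <- file.path(dir, "expr.tsv")
  writeExpressionMatrix(sim$expression, exprPath)
  groupsPath <- writeGroupsTsv(file.path(dir, "groups.tsv"))
  cfg <- list(expression = exprPath, groups = groupsPath,
              outDir = file.path(dir, "out"), seed = seed)
  if (withGrowth) {
    bl <- simulateBioluminescence(seed = seed)
    cfg$series <- file.path(dir, "series.csv")
    write.csv(bl$series, cfg$series, row.names = FALSE)
  }
  if (withCohort) {
    beta <- setNames(rep(c(0.6, 0), c(2, 2)),
                     c(sim$truth$up[1:2], sim$truth$down[1:2]))
    co <- simulateCohort(nPatients = 150, beta = beta, seed = seed)
    cfg$cohort <- file.path(dir, "cohort.csv")
    write.csv(co$cohort, cfg$cohort, row.names = FALSE)
  }
  cfg
}
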