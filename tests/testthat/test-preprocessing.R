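test_that("log2 fold change matches hand-computed ratios", {
  pairs <- CaseControlPairSet(
    caseIntensity = matrix(c(8, 5, 3), 1, 3),
    controlIntensity = matrix(c(2, 5, 12), 1, 3),
    pairIds = "p1", geneIds = c("g1", "g2", "g3")
  )
  fc <- computeLog2FoldChange(pairs, outcome = 1)
  expect_equal(unname(foldChanges(fc)[1, ]), c(2, 0, -2))
  expect_identical(geneIds(fc), c("g1", "g2", "g3"))
})

test_that("fold change is antisymmetric in case and control", {
  set.seed(5)
  for (i in 1:5) {
    a <- matrix(exp(rnorm(12)), 3, 4)
    b <- matrix(exp(rnorm(12)), 3, 4)
    fwd <- computeLog2FoldChange(CaseControlPairSet(a, b), outcome = c(0, 1, 1))
    rev <- computeLog2FoldChange(CaseControlPairSet(b, a), outcome = c(0, 1, 1))
    expect_equal(foldChanges(fwd), -foldChanges(rev), tolerance = 1e-12)
  }
})

test_that("non-positive intensities are rejected with their location", {
  a <- matrix(c(1, 2, 0.5, 4), 2, 2)
  b <- matrix(c(1, 2, 3, 4), 2, 2)
  a[2, 2] <- -1
  expect_error(
    CaseControlPairSet(a, b, pairIds = c("p1", "p2"), geneIds = c("gA", "gB")),
    "pair 'p2', gene 'gB'"
  )
  b[1, 1] <- 0
  a[2, 2] <- 1
  expect_error(
    CaseControlPairSet(a, b, pairIds = c("p1", "p2"), geneIds = c("gA", "gB")),
    "pair 'p1', gene 'gA'"
  )
})

test_that("datasets round-trip through disk exactly", {
  x <- FoldChangeSet(matrix(rnorm(6), 3, 2,
                            dimnames = list(paste0("s", 1:3), c("gA", "gB"))),
                     outcome = c(1, 0, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDataset(x, path)
  back <- readDataset(path)
  expect_equal(foldChanges(back), foldChanges(x), tolerance = 1e-12)
  expect_identical(geneIds(back), geneIds(x))
  expect_identical(sampleIds(back), sampleIds(x))
  expect_identical(unname(outcome(back)), unname(outcome(x)))
})

test_that("comma-delimited files are auto-detected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,g1,g2,outcome", "s1,0.5,-1.25,1", "s2,-0.5,2.0,0",
               "s3,1.5,0.25,1"), path)
  x <- readDataset(path)
  expect_equal(dim(foldChanges(x)), c(3L, 2L))
  expect_identical(unname(outcome(x)), c(1L, 0L, 1L))
  expect_equal(foldChanges(x)["s2", "g2"], 2.0)
})

test_that("malformed datasets are rejected with a location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\toutcome", "s1\t0.5\t2", "s2\t1\t0"), path)
  expect_error(readDataset(path), "0/1.*row 1")
  writeLines(c("sample_id\tg1\toutcome", "s1\tNA\t1", "s2\t1\t0"), path)
  expect_error(readDataset(path), "row 1, gene 'g1'")
  writeLines(c("sample_id\tg1\tg1\toutcome", "s1\t1\t2\t1", "s2\t1\t2\t0"), path)
  expect_error(readDataset(path), "duplicate gene")
  writeLines(c("sample_id\tg1\toutcome", "s1\tnot_a_number\t1", "s2\t1\t0"), path)
  expect_error(readDataset(path), "row 1, gene 'g1'")
})

test_that("outcomes other than 0/1 are rejected at construction", {
  m <- matrix(rnorm(4), 2, 2)
  expect_error(FoldChangeSet(m, outcome = c(1, 2)), "0/1")
  expect_error(FoldChangeSet(m, outcome = c(1, NA)), "0/1")
  expect_error(FoldChangeSet(matrix(c(1, Inf, 0, 1), 2, 2), outcome = c(0, 1)),
               "finite")
})

makeStabilityReport <- function(probs, jaccard = 0.5) {
  ever <- names(probs)[probs > 0]
  cs <- diag(probs[ever], nrow = length(ever))
  dimnames(cs) <- list(ever, ever)
  methods::new("StabilityReport",
    selectionProbability = probs, coSelection = cs,
    jaccardValues = jaccard, stabilityPoint = mean(jaccard),
    stabilityInterval = c(min(jaccard), max(jaccard)),
    expectedOverlap = expectedOverlap(mean(jaccard), length(ever)),
    replicateSetSizes = c(1L, 1L), emptyPairsExcluded = 0L,
    fullDataSet = ever, B = 2L, seed = 1L, nFailed = 0L, redraws = 0L,
    modelConfig = ElasticNetConfig(), bootConfig = BootstrapConfig(B = 2))
}

test_that("gene tables are sorted by selection probability, descending", {
  dir <- withr::local_tempdir()
  writeReport(makeStabilityReport(c(g2 = 0.3, g1 = 0.9, g3 = 0)), dir)
  tab <- read.delim(file.path(dir, "gene_table.tsv"))
  expect_identical(tab$gene_id, c("g1", "g2"))
  expect_equal(tab$selection_probability, c(0.9, 0.3))
})

test_that("an empty selected-gene universe yields an empty table with header", {
  dir <- withr::local_tempdir()
  writeReport(makeStabilityReport(c(g1 = 0, g2 = 0)), dir)
  tab <- read.delim(file.path(dir, "gene_table.tsv"))
  expect_identical(colnames(tab), c("gene_id", "selection_probability"))
  expect_identical(nrow(tab), 0L)
})

test_that("report summaries survive a write/read round trip", {
  dir <- withr::local_tempdir()
  rep <- makeStabilityReport(c(g1 = 0.8, g2 = 0.4), jaccard = c(0.25, 0.5))
  writeReport(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "stability_summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$stability_point, rep@stabilityPoint)
  expect_equal(js$stability_middle80, rep@stabilityInterval)
  expect_equal(js$expected_overlap, rep@expectedOverlap)
  expect_equal(js$full_data_set_size, length(rep@fullDataSet))
  expect_equal(js$B, rep@B)
  vals <- read.delim(file.path(dir, "jaccard_values.tsv"))
  expect_equal(vals$jaccard, rep@jaccardValues)
})
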