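.configList <- function(cfg) {
  s <- methods::slotNames(class(cfg))
  out <- lapply(s, function(nm) slot(cfg, nm))
  names(out) <- s
  out
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @describeIn writeReport validation tables: \code{calibration.tsv}
#'   (predicted, observed_apparent, observed_corrected, lower80, upper80),
#'   \code{bootstrap_summary.tsv} (per-metric apparent/optimism/corrected
#'   and middle-.8 interval), \code{bootstrap_replicates.tsv} (the
#'   per-replicate corrected values behind the distributions), and a
#'   machine-readable \code{validation_summary.json}.
#' @export
setMethod("writeReport", signature("ValidationReport", "character"),
function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- c("brier", "concordance")
  summary <- data.frame(
    metric = metrics,
    apparent = unname(report@apparent[metrics]),
    mean_optimism = unname(report@optimism[metrics]),
    corrected = unname(report@corrected[metrics]),
    lower80 = vapply(report@intervals[metrics], `[`, numeric(1), 1L),
    upper80 = vapply(report@intervals[metrics], `[`, numeric(1), 2L)
  )
  paths <- c(
    .writeTsv(summary, file.path(dir, "bootstrap_summary.tsv")),
    .writeTsv(report@calibration, file.path(dir, "calibration.tsv")),
    .writeTsv(report@replicates, file.path(dir, "bootstrap_replicates.tsv"))
  )
  js <- list(
    apparent = as.list(report@apparent),
    mean_optimism = as.list(report@optimism),
    corrected = as.list(report@corrected),
    root_corrected_brier = sqrt(unname(report@corrected["brier"])),
    middle80 = report@intervals,
    null_model_selected = all(abs(report@apparent["concordance"] - 0.5) < 1e-12),
    B = report@B, seed = report@seed, n_failed = report@nFailed,
    redraws = report@redraws,
    model_config = .configList(report@modelConfig),
    bootstrap_config = .configList(report@bootConfig)
  )
  jp <- file.path(dir, "validation_summary.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
})

#' @describeIn writeReport stability tables: \code{gene_table.tsv}
#'   (gene_id, selection_probability; genes ever selected, ordered by
#'   selection probability descending, ties by gene id),
#'   \code{co_selection.tsv} (long-format pair fractions over the
#'   ever-selected genes), \code{jaccard_values.tsv}, and
#'   \code{stability_summary.json}.
#' @export
setMethod("writeReport", signature("StabilityReport", "character"),
function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- report@selectionProbability
  keep <- names(p)[p > 0]
  ord <- keep[order(-p[keep], keep)]
  geneTab <- data.frame(gene_id = ord,
                        selection_probability = unname(p[ord]))
  cs <- report@coSelection
  coTab <- if (length(cs)) {
    idx <- which(upper.tri(cs, diag = FALSE), arr.ind = TRUE)
    data.frame(gene1 = rownames(cs)[idx[, 1]],
               gene2 = colnames(cs)[idx[, 2]],
               co_selection = cs[idx])
  } else {
    data.frame(gene1 = character(0), gene2 = character(0),
               co_selection = numeric(0))
  }
  paths <- c(
    .writeTsv(geneTab, file.path(dir, "gene_table.tsv")),
    .writeTsv(coTab[order(-coTab$co_selection, coTab$gene1, coTab$gene2), ],
              file.path(dir, "co_selection.tsv")),
    .writeTsv(data.frame(jaccard = report@jaccardValues),
              file.path(dir, "jaccard_values.tsv"))
  )
  js <- list(
    stability_point = report@stabilityPoint,
    stability_middle80 = report@stabilityInterval,
    expected_overlap = report@expectedOverlap,
    full_data_set_size = length(report@fullDataSet),
    full_data_genes = report@fullDataSet,
    replicate_set_sizes = report@replicateSetSizes,
    empty_pairs_excluded = report@emptyPairsExcluded,
    B = report@B, seed = report@seed, n_failed = report@nFailed,
    redraws = report@redraws,
    model_config = .configList(report@modelConfig),
    bootstrap_config = .configList(report@bootConfig)
  )
  jp <- file.path(dir, "stability_summary.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
})

#' Run the full analysis end to end and write a report directory
#'
#' Fits the elastic-net path with criterion-based penalty selection,
#' runs the optimism-corrected bootstrap validation and the bootstrap
#' stability analysis, and writes every table plus a run manifest. With a
#' \linkS4class{SimulationConfig} input the dataset is simulated first and
#' written (with its ground-truth sidecar) into the directory; the same
#' applies to a \linkS4class{SyntheticDataset}. Given one configuration,
#' two runs produce byte-identical report tables; the manifest's timestamp
#' is metadata outside that contract.
#'
#' @param input a \linkS4class{FoldChangeSet}, \linkS4class{SyntheticDataset},
#'   \linkS4class{SimulationConfig}, or a dataset file path for
#'   \code{\link{readDataset}}.
#' @param dir output directory (created; partially written outputs are
#'   removed on failure).
#' @param modelConfig an \linkS4class{ElasticNetConfig}.
#' @param bootConfig a \linkS4class{BootstrapConfig}.
#' @param verbose log replicate progress to stderr.
#' @return invisibly, a list with the \code{validation} and
#'   \code{stability} reports and the selected \code{fit}.
#' @export
runFullAnalysis <- function(input, dir,
                            modelConfig = ElasticNetConfig(),
                            bootConfig = BootstrapConfig(),
                            verbose = FALSE) {
  created <- !dir.exists(dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(if (created) dir else list.files(dir, full.names = TRUE),
                          recursive = TRUE), add = TRUE)

  truth <- NULL
  if (is.character(input)) {
    x <- readDataset(input)
    inputPath <- input
  } else if (is(input, "SimulationConfig")) {
    sim <- simulateDataset(input)
    x <- dataset(sim)
    truth <- sim
    inputPath <- file.path(dir, "dataset.tsv")
    writeDataset(x, inputPath)
  } else if (is(input, "SyntheticDataset")) {
    x <- dataset(input)
    truth <- input
    inputPath <- file.path(dir, "dataset.tsv")
    writeDataset(x, inputPath)
  } else if (is(input, "FoldChangeSet")) {
    x <- input
    inputPath <- file.path(dir, "dataset.tsv")
    writeDataset(x, inputPath)
  } else {
    stop("unsupported input of class ", class(input)[1])
  }
  if (!is.null(truth)) {
    jsonlite::write_json(list(
      true_support = truth@trueSupport, true_signs = truth@trueSigns,
      true_intercept = truth@trueIntercept,
      realized_prevalence = truth@realizedPrevalence,
      simulation_config = .configList(truth@config)
    ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  }

  path <- fitPenaltyPath(x, config = modelConfig)
  sel <- selectByCriterion(path, modelConfig, n = length(outcome(x)))
  val <- optimismValidate(x, modelConfig = modelConfig,
                          bootConfig = bootConfig, verbose = verbose)
  stab <- stabilityAnalysis(x, modelConfig = modelConfig,
                            bootConfig = bootConfig, verbose = verbose)
  writeReport(val, dir)
  writeReport(stab, dir)

  coefTab <- data.frame(gene_id = sel$genes,
                        coefficient = unname(sel$fit@coefficients[sel$genes]))
  .writeTsv(coefTab[order(-abs(coefTab$coefficient), coefTab$gene_id), ],
            file.path(dir, "selected_coefficients.tsv"))

  manifest <- list(
    package = "enetBoot",
    version = as.character(packageVersion("enetBoot")),
    seed = bootConfig@seed,
    model_config = .configList(modelConfig),
    bootstrap_config = .configList(bootConfig),
    input = list(path = inputPath,
                 md5 = unname(tools::md5sum(inputPath)),
                 n = length(outcome(x)), p = length(geneIds(x))),
    selected = list(k = sel$fit@k, lambda = sel$fit@lambda,
                    aic_prime = sel$fit@aicPrime,
                    null_model_selected = sel$fit@k == 0L),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(list(validation = val, stability = stab, fit = sel$fit,
                 path = path))
}
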