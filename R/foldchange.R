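#' Construct a FoldChangeSet
#'
#' @param values numeric matrix of log2 fold changes, samples as rows and
#'   genes as columns (the orientation used by the file formats and by the
#'   modeling functions). Internally the assay is stored genes x samples.
#' @param outcome binary 0/1 vector, one value per sample; 1 indicates
#'   metastatic spread.
#' @param sampleIds,geneIds identifiers; default to the dimnames of
#'   \code{values}, or \code{sample1..n} / \code{gene1..p}.
#' @return a \linkS4class{FoldChangeSet}.
#' @examples
#' x <- FoldChangeSet(matrix(rnorm(12), 3, 4), outcome = c(0, 1, 1))
#' dim(foldChanges(x))
#' @export
FoldChangeSet <- function(values, outcome,
                          sampleIds = rownames(values),
                          geneIds = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("fold-change values must be numeric")
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(values)))
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(ncol(values)))
  if (length(outcome) != nrow(values))
    stop("outcome length (", length(outcome), ") must match the sample count (",
         nrow(values), ")")
  if (anyNA(outcome) || !all(outcome %in% c(0, 1)))
    stop("outcome must be coded 0/1 with no missing values")
  assay <- t(values)
  dimnames(assay) <- list(geneIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2fc = assay),
    colData = S4Vectors::DataFrame(outcome = as.integer(outcome),
                                   row.names = sampleIds)
  )
  methods::new("FoldChangeSet", se)
}

#' @describeIn FoldChangeSet samples x genes fold-change matrix.
#' @param x a FoldChangeSet.
#' @export
setMethod("foldChanges", "FoldChangeSet", function(x) {
  t(SummarizedExperiment::assay(x, "log2fc"))
})

#' @describeIn FoldChangeSet the 0/1 outcome, named by sample id.
#' @export
setMethod("outcome", "FoldChangeSet", function(x) {
  y <- SummarizedExperiment::colData(x)$outcome
  names(y) <- colnames(x)
  y
})

#' @describeIn FoldChangeSet gene identifiers.
#' @export
setMethod("geneIds", "FoldChangeSet", function(x) rownames(x))

#' @describeIn FoldChangeSet sample identifiers.
#' @export
setMethod("sampleIds", "FoldChangeSet", function(x) colnames(x))

setMethod("show", "FoldChangeSet", function(object) {
  y <- outcome(object)
  cat("FoldChangeSet:", ncol(object), "samples x", nrow(object),
      "genes (log2 case/control fold changes)\n")
  cat(sprintf("  outcome: %d/%d positive (prevalence %.3f)\n",
              sum(y), length(y), mean(y)))
})

#' Construct a CaseControlPairSet
#'
#' @param caseIntensity,controlIntensity strictly positive linear-scale
#'   expression matrices, pairs x genes, identical dimensions and gene
#'   order.
#' @param pairIds,geneIds identifiers; default to dimnames.
#' @return a \linkS4class{CaseControlPairSet}.
#' @export
CaseControlPairSet <- function(caseIntensity, controlIntensity,
                               pairIds = rownames(caseIntensity),
                               geneIds = colnames(caseIntensity)) {
  caseIntensity <- as.matrix(caseIntensity)
  controlIntensity <- as.matrix(controlIntensity)
  if (is.null(pairIds)) pairIds <- paste0("pair", seq_len(nrow(caseIntensity)))
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(ncol(caseIntensity)))
  obj <- methods::new("CaseControlPairSet",
    pairIds = as.character(pairIds),
    caseIntensity = unname(caseIntensity),
    controlIntensity = unname(controlIntensity),
    geneIds = as.character(geneIds)
  )
  .checkPositiveIntensities(obj)
  obj
}

.checkPositiveIntensities <- function(pairs) {
  for (what in c("caseIntensity", "controlIntensity")) {
    m <- slot(pairs, what)
    bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-positive or missing %s at pair '%s', gene '%s'",
        sub("Intensity", "", what),
        pairs@pairIds[bad[1, 1]], pairs@geneIds[bad[1, 2]]
      ))
    }
  }
  invisible(TRUE)
}

setMethod("show", "CaseControlPairSet", function(object) {
  cat("CaseControlPairSet:", length(object@pairIds), "pairs x",
      length(object@geneIds), "genes (linear-scale intensities)\n")
})

#' Log2 fold changes from paired case-control intensities
#'
#' Entry (i, g) is \code{log2(case[i, g]) - log2(control[i, g])}: the log2
#' fold change of the case over its matched control. Matching the control
#' in this way absorbs lab batch effects shared within a pair.
#'
#' @param pairs a \linkS4class{CaseControlPairSet}.
#' @param outcome binary 0/1 vector, one per pair, attached to the result.
#' @return a \linkS4class{FoldChangeSet} with the pairs as samples.
#' @examples
#' pairs <- CaseControlPairSet(matrix(c(8, 3), 1), matrix(c(2, 12), 1))
#' foldChanges(computeLog2FoldChange(pairs, outcome = 1))  # 2 and -2
#' @export
computeLog2FoldChange <- function(pairs, outcome) {
  stopifnot(is(pairs, "CaseControlPairSet"))
  .checkPositiveIntensities(pairs)
  fc <- log2(pairs@caseIntensity) - log2(pairs@controlIntensity)
  FoldChangeSet(fc, outcome, sampleIds = pairs@pairIds, geneIds = pairs@geneIds)
}

.sniffDelimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  nTab <- lengths(regmatches(header, gregexpr("\t", header)))
  nCom <- lengths(regmatches(header, gregexpr(",", header)))
  if (nTab == 0L && nCom == 0L)
    stop("could not detect a tab or comma delimiter in the header of ", path)
  if (nTab >= nCom) "\t" else ","
}

#' Read a fold-change dataset from delimited text
#'
#' Expects a header row, one row per sample, a sample-id column (first
#' column when named \code{sample_id}, otherwise row names are generated),
#' numeric gene columns, and a 0/1 outcome column. Tab and comma delimiters
#' are auto-detected. Missing values, non-numeric cells, non-binary
#' outcomes and duplicate gene names are rejected with their location;
#' the upstream pipeline is expected to deliver a complete matrix.
#'
#' @param path file path.
#' @param outcomeColumn name of the outcome column (default
#'   \code{"outcome"}).
#' @return a \linkS4class{FoldChangeSet}; gene order is preserved from the
#'   file.
#' @seealso \code{\link{writeDataset}} for the inverse.
#' @export
readDataset <- function(path, outcomeColumn = "outcome") {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniffDelimiter(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (!outcomeColumn %in% colnames(df))
    stop("outcome column '", outcomeColumn, "' not found in ", path)
  hasId <- colnames(df)[1] == "sample_id"
  ids <- if (hasId) df[["sample_id"]] else paste0("sample", seq_len(nrow(df)))
  cn <- colnames(df)
  geneCols <- cn[!cn %in% c(outcomeColumn, if (hasId) "sample_id")]
  if (anyDuplicated(geneCols))
    stop("duplicate gene column name(s): ",
         paste(unique(geneCols[duplicated(geneCols)]), collapse = ", "))
  yRaw <- df[[outcomeColumn]]
  if (anyNA(yRaw) || !all(yRaw %in% c("0", "1"))) {
    bad <- which(is.na(yRaw) | !yRaw %in% c("0", "1"))[1]
    stop("outcome column '", outcomeColumn, "' must contain only 0/1; row ",
         bad, " has '", yRaw[bad], "'")
  }
  vals <- suppressWarnings(
    vapply(geneCols, function(g) as.numeric(df[[g]]), numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, geneCols))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing or non-numeric value at row ", bad[1, 1], ", gene '",
         geneCols[bad[1, 2]], "'")
  FoldChangeSet(vals, as.integer(yRaw), sampleIds = ids, geneIds = geneCols)
}

#' Write a fold-change dataset as tab-delimited text
#'
#' One row per sample: \code{sample_id}, gene columns in matrix order, and
#' the outcome column last. Values round-trip through
#' \code{\link{readDataset}} to within 1e-12.
#'
#' @param x a \linkS4class{FoldChangeSet}.
#' @param path output file path.
#' @param outcomeColumn outcome column name (default \code{"outcome"}).
#' @return invisibly, \code{path}.
#' @export
writeDataset <- function(x, path, outcomeColumn = "outcome") {
  stopifnot(is(x, "FoldChangeSet"))
  m <- foldChanges(x)
  df <- data.frame(sample_id = sampleIds(x),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[[outcomeColumn]] <- unname(outcome(x))
  colnames(df) <- c("sample_id", geneIds(x), outcomeColumn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
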