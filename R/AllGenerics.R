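#' Extract the fold-change matrix, samples as rows
#'
#' @param x a \linkS4class{FoldChangeSet}.
#' @return numeric matrix, samples x genes, log2 scale.
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' Extract the binary outcome vector
#'
#' @param x a \linkS4class{FoldChangeSet} or \linkS4class{SyntheticDataset}.
#' @return integer 0/1 vector named by sample id (1 = metastasis present).
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' Gene and sample identifiers
#'
#' @param x an object carrying gene/sample ids.
#' @return character vector of identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Genes with a nonzero coefficient
#'
#' @param x a \linkS4class{ModelFit} or \linkS4class{PenaltyPath} (for a
#'   path, the selected fit's gene set).
#' @return character vector of gene ids; slopes with absolute value above
#'   1e-12 count as nonzero.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' The fit chosen by the information criterion
#'
#' @param x a \linkS4class{PenaltyPath}.
#' @return the selected \linkS4class{ModelFit}.
#' @export
setGeneric("selectedFit", function(x) standardGeneric("selectedFit"))

#' Predicted outcome probabilities
#'
#' Inverse-logit of the linear predictor \eqn{\beta_0 + \sum_j \beta_j
#' x_{ij}}; every output lies strictly inside (0, 1) up to floating point.
#'
#' @param fit a \linkS4class{ModelFit}.
#' @param x a \linkS4class{FoldChangeSet} or samples x genes matrix whose
#'   gene universe matches the fit.
#' @return numeric vector of per-sample probabilities.
#' @export
setGeneric("predictProbabilities", function(fit, x) standardGeneric("predictProbabilities"))

#' Write a report to delimited-text files
#'
#' @param report a \linkS4class{ValidationReport} or
#'   \linkS4class{StabilityReport}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
setGeneric("writeReport", function(report, dir) standardGeneric("writeReport"))
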