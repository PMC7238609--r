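#' @import methods
#' @importFrom stats lowess plogis qlogis quantile rbinom rnorm runif approx
#' @importFrom utils read.delim write.table packageVersion combn
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom glmnet glmnet
NULL

#' FoldChangeSet: case-minus-control log2 fold changes with a binary outcome
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"log2fc"},
#' of per-gene log2 fold changes (case intensity over matched-control
#' intensity), genes as rows and samples (case-control pairs) as columns,
#' with the binary metastasis outcome in \code{colData(x)$outcome}.
#'
#' Modeling code and the file formats use the transposed orientation,
#' samples as rows and genes as columns; use \code{\link{foldChanges}} to
#' obtain that matrix.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso \code{\link{FoldChangeSet}}, \code{\link{foldChanges}},
#'   \code{\link{outcome}}
#' @export
setClass("FoldChangeSet", contains = "SummarizedExperiment")

setValidity("FoldChangeSet", function(object) {
  msg <- character()
  if (!"log2fc" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2fc' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "log2fc"))))
    msg <- c(msg, "all fold-change values must be finite (missing values are not supported)")
  cd <- SummarizedExperiment::colData(object)
  if (!"outcome" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain an 'outcome' column")
  } else {
    y <- cd$outcome
    if (!all(y %in% c(0L, 1L))) msg <- c(msg, "outcome must be coded 0/1")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn)) msg <- c(msg, "gene ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Paired case-control expression intensities
#'
#' Linear-scale (strictly positive) expression intensities for matched
#' case-control pairs, prior to fold-change construction. Rows are pairs,
#' columns genes, identically ordered in both tables.
#'
#' @slot pairIds character, unique pair identifiers.
#' @slot caseIntensity numeric matrix, pairs x genes, strictly positive.
#' @slot controlIntensity numeric matrix, same dimensions and gene order.
#' @slot geneIds character, unique gene/probe identifiers.
#' @seealso \code{\link{computeLog2FoldChange}}
#' @export
setClass("CaseControlPairSet",
  representation(
    pairIds = "character",
    caseIntensity = "matrix",
    controlIntensity = "matrix",
    geneIds = "character"
  )
)

setValidity("CaseControlPairSet", function(object) {
  msg <- character()
  ca <- object@caseIntensity; co <- object@controlIntensity
  if (!identical(dim(ca), dim(co)))
    msg <- c(msg, "case and control tables must have identical dimensions")
  if (nrow(ca) != length(object@pairIds))
    msg <- c(msg, "pairIds length must match the number of rows")
  if (ncol(ca) != length(object@geneIds))
    msg <- c(msg, "geneIds length must match the number of columns")
  if (anyDuplicated(object@pairIds)) msg <- c(msg, "pairIds must be unique")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "geneIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Elastic-net model configuration
#'
#' Tuning knobs for the penalized logistic regression path. \code{alpha}
#' mixes the L1 and L2 penalties (0.5 weights them equally, the a-priori
#' choice used throughout); the penalty strength itself is scanned over
#' \code{nLambda} log-spaced values down to \code{lambdaMinRatio} times the
#' smallest penalty that zeroes every slope, and chosen by \code{criterion}.
#'
#' @slot alpha numeric in [0, 1], L1/L2 mixing parameter.
#' @slot nLambda integer >= 2, path length.
#' @slot lambdaMinRatio numeric in (0, 1), smallest/largest penalty ratio.
#' @slot standardize logical, standardize predictors internally (coefficients
#'   are always reported on the original data scale).
#' @slot criterion \code{"aic_prime"} (default) or \code{"aicc_prime"}, the
#'   small-sample variant with an extra \code{2k(k+1)/(n-k-1)} penalty.
#' @slot tol numeric, solver convergence threshold.
#' @slot maxIter integer, solver iteration cap.
#' @seealso \code{\link{ElasticNetConfig}}, \code{\link{fitPenaltyPath}}
#' @export
setClass("ElasticNetConfig",
  representation(
    alpha = "numeric", nLambda = "integer", lambdaMinRatio = "numeric",
    standardize = "logical", criterion = "character", tol = "numeric",
    maxIter = "integer"
  ),
  prototype(
    alpha = 0.5, nLambda = 100L, lambdaMinRatio = 1e-3,
    standardize = TRUE, criterion = "aic_prime", tol = 1e-7,
    maxIter = 100000L
  )
)

setValidity("ElasticNetConfig", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@nLambda < 2L) msg <- c(msg, "nLambda must be >= 2")
  if (object@lambdaMinRatio <= 0 || object@lambdaMinRatio >= 1)
    msg <- c(msg, "lambdaMinRatio must lie in (0, 1)")
  if (!object@criterion %in% c("aic_prime", "aicc_prime"))
    msg <- c(msg, "criterion must be 'aic_prime' or 'aicc_prime'")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A single fitted penalized logistic model
#'
#' Coefficients are on the original (unstandardized) data scale; the
#' intercept is never penalized. \code{loglik} is the unpenalized Bernoulli
#' log-likelihood evaluated at the penalized estimates, \code{nullLoglik}
#' the intercept-only maximum, and \code{aicPrime} the modified Akaike
#' criterion \code{2 (loglik - nullLoglik) - 2 k} where \code{k} counts
#' nonzero slopes (the intercept excluded).
#'
#' @slot intercept numeric scalar.
#' @slot coefficients named numeric, one slope per gene.
#' @slot lambda numeric, penalty strength of this path point.
#' @slot k integer, number of nonzero slope coefficients.
#' @slot loglik,nullLoglik,aicPrime numeric scalars.
#' @slot converged logical, solver convergence flag.
#' @export
setClass("ModelFit",
  representation(
    intercept = "numeric", coefficients = "numeric", lambda = "numeric",
    k = "integer", loglik = "numeric", nullLoglik = "numeric",
    aicPrime = "numeric", converged = "logical"
  ),
  prototype(converged = TRUE)
)

setValidity("ModelFit", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L) msg <- c(msg, "intercept must be scalar")
  if (object@k != sum(abs(object@coefficients) > 1e-12))
    msg <- c(msg, "k must equal the number of nonzero slope coefficients")
  if (length(object@loglik) == 1L && is.finite(object@loglik) && object@loglik > 1e-8)
    msg <- c(msg, "Bernoulli log-likelihood cannot be positive")
  if (length(msg)) msg else TRUE
})

#' Elastic-net regularization path with criterion-based selection
#'
#' @slot lambdas numeric, strictly decreasing penalty values.
#' @slot fits list of \linkS4class{ModelFit}, one per lambda.
#' @slot selectedIndex integer, index of the fit maximizing the criterion
#'   (ties broken toward larger lambda, i.e. the sparser model).
#' @slot criterion character, the criterion used.
#' @export
setClass("PenaltyPath",
  representation(
    lambdas = "numeric", fits = "list", selectedIndex = "integer",
    criterion = "character"
  )
)

setValidity("PenaltyPath", function(object) {
  msg <- character()
  if (length(object@lambdas) != length(object@fits))
    msg <- c(msg, "one fit per lambda required")
  if (length(object@lambdas) > 1L && any(diff(object@lambdas) >= 0))
    msg <- c(msg, "lambdas must be strictly decreasing")
  if (length(object@selectedIndex) == 1L &&
      (object@selectedIndex < 1L || object@selectedIndex > length(object@fits)))
    msg <- c(msg, "selectedIndex out of range")
  if (length(msg)) msg else TRUE
})

#' Bootstrap configuration
#'
#' @slot B integer >= 2, number of bootstrap replicates.
#' @slot seed integer, master seed; every report records it. Per-replicate
#'   substreams are derived from it, so results do not depend on execution
#'   order.
#' @slot maxRedraws integer, cap on redraws of a resample whose outcome
#'   has fewer than two samples in either class.
#' @slot maxJaccardPairs integer, cap on the number of replicate pairs used
#'   for the stability distribution (random pairs beyond the cap).
#' @slot pairing \code{"pairs"} (default, Jaccard over replicate pairs) or
#'   \code{"original"} (each replicate set against the full-data set).
#' @export
setClass("BootstrapConfig",
  representation(
    B = "integer", seed = "integer", maxRedraws = "integer",
    maxJaccardPairs = "integer", pairing = "character"
  ),
  prototype(
    B = 500L, seed = 1L, maxRedraws = 100L, maxJaccardPairs = 10000L,
    pairing = "pairs"
  )
)

setValidity("BootstrapConfig", function(object) {
  msg <- character()
  if (object@B < 2L) msg <- c(msg, "B must be >= 2")
  if (object@maxRedraws < 1L) msg <- c(msg, "maxRedraws must be >= 1")
  if (object@maxJaccardPairs < 1L) msg <- c(msg, "maxJaccardPairs must be >= 1")
  if (!object@pairing %in% c("pairs", "original"))
    msg <- c(msg, "pairing must be 'pairs' or 'original'")
  if (length(msg)) msg else TRUE
})

#' Optimism-corrected internal validation report
#'
#' For Brier score and concordance: the apparent (training-data) value, the
#' mean bootstrap optimism, the corrected point estimate
#' (apparent minus mean optimism), the per-replicate corrected values, and
#' their middle-.8 interval (0.1/0.9 quantiles). The calibration curve is
#' corrected pointwise on a shared predicted-probability grid, with a
#' pointwise middle-.8 band.
#'
#' @slot apparent,optimism,corrected named numeric vectors with elements
#'   \code{brier} and \code{concordance}.
#' @slot replicates data.frame of per-replicate corrected values.
#' @slot intervals list of length-2 numeric vectors (middle-.8).
#' @slot calibration data.frame with columns \code{predicted},
#'   \code{observed_apparent}, \code{observed_corrected}, \code{lower80},
#'   \code{upper80}.
#' @slot B,seed integers; \code{nFailed} replicates skipped;
#'   \code{redraws} total degenerate-resample redraws.
#' @slot modelConfig,bootConfig the configurations used.
#' @export
setClass("ValidationReport",
  representation(
    apparent = "numeric", optimism = "numeric", corrected = "numeric",
    replicates = "data.frame", intervals = "list", calibration = "data.frame",
    B = "integer", seed = "integer", nFailed = "integer", redraws = "integer",
    modelConfig = "ElasticNetConfig", bootConfig = "BootstrapConfig"
  )
)

setValidity("ValidationReport", function(object) {
  msg <- character()
  need <- c("brier", "concordance")
  for (s in c("apparent", "optimism", "corrected"))
    if (!all(need %in% names(slot(object, s))))
      msg <- c(msg, sprintf("slot '%s' must be named with %s", s, paste(need, collapse = ", ")))
  if (!length(msg)) {
    gap <- abs(object@corrected[need] - (object@apparent[need] - object@optimism[need]))
    if (any(gap > 1e-12)) msg <- c(msg, "corrected must equal apparent - mean optimism")
  }
  for (iv in object@intervals)
    if (length(iv) == 2L && iv[1] > iv[2]) msg <- c(msg, "interval endpoints must be ordered")
  if (length(msg)) msg else TRUE
})

#' Bootstrap feature-selection stability report
#'
#' @slot selectionProbability named numeric, per-gene fraction of replicates
#'   in which the gene's coefficient is nonzero.
#' @slot coSelection numeric matrix over the ever-selected genes; entry
#'   (g, h) is the fraction of replicates selecting both; the diagonal equals
#'   the selection probability.
#' @slot jaccardValues numeric, pairwise Jaccard overlaps between replicate
#'   gene sets (pairs of two empty sets excluded).
#' @slot stabilityPoint numeric, mean of \code{jaccardValues} (NA when all
#'   pairs were empty-empty).
#' @slot stabilityInterval numeric length 2, middle-.8 of the Jaccard values.
#' @slot expectedOverlap integer, stability times the full-data selected-set
#'   size, rounded to the nearest integer (NA when stability is undefined).
#' @slot replicateSetSizes integer, selected-set size per replicate.
#' @slot emptyPairsExcluded integer, count of excluded empty-empty pairs.
#' @slot fullDataSet character, genes selected on the full data.
#' @slot B,seed,nFailed,redraws integers; configs echoed.
#' @export
setClass("StabilityReport",
  representation(
    selectionProbability = "numeric", coSelection = "matrix",
    jaccardValues = "numeric", stabilityPoint = "numeric",
    stabilityInterval = "numeric", expectedOverlap = "integer",
    replicateSetSizes = "integer", emptyPairsExcluded = "integer",
    fullDataSet = "character", B = "integer", seed = "integer",
    nFailed = "integer", redraws = "integer",
    modelConfig = "ElasticNetConfig", bootConfig = "BootstrapConfig"
  )
)

setValidity("StabilityReport", function(object) {
  msg <- character()
  p <- object@selectionProbability
  if (length(p) && (min(p) < 0 || max(p) > 1))
    msg <- c(msg, "selection probabilities must lie in [0, 1]")
  cs <- object@coSelection
  if (length(cs)) {
    g <- rownames(cs)
    if (any(abs(diag(cs) - p[g]) > 1e-12))
      msg <- c(msg, "coSelection diagonal must equal the selection probability")
    lim <- outer(p[g], p[g], pmin)
    if (any(cs > lim + 1e-12))
      msg <- c(msg, "coSelection cannot exceed either marginal selection probability")
  }
  if (length(object@stabilityPoint) == 1L && is.finite(object@stabilityPoint) &&
      (object@stabilityPoint < 0 || object@stabilityPoint > 1))
    msg <- c(msg, "stabilityPoint must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic fold-change simulation configuration
#'
#' Defaults emulate the motivating study design: 88 case-control pairs with
#' outcome prevalence 0.25, genes in correlated blocks (many correlated
#' genes to choose from), and a sparse logistic signal. The gene count
#' defaults to 2000 for desk-scale work; the full 12404 is supported.
#'
#' @slot n integer, sample (pair) count.
#' @slot p integer, gene count.
#' @slot blockSize integer, genes per correlated block (last block may be
#'   shorter when blockSize does not divide p).
#' @slot rho numeric in [0, 1), within-block correlation.
#' @slot nSignal integer, number of true predictor genes.
#' @slot effectSize numeric, absolute logistic coefficient per signal gene
#'   (signs alternate across the support).
#' @slot targetPrevalence numeric in [0, 1], marginal outcome probability
#'   the intercept is calibrated to.
#' @slot seed integer.
#' @export
setClass("SimulationConfig",
  representation(
    n = "integer", p = "integer", blockSize = "integer", rho = "numeric",
    nSignal = "integer", effectSize = "numeric", targetPrevalence = "numeric",
    seed = "integer"
  ),
  prototype(
    n = 88L, p = 2000L, blockSize = 10L, rho = 0.5, nSignal = 10L,
    effectSize = 0.5, targetPrevalence = 0.25, seed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSignal > object@p) msg <- c(msg, "nSignal cannot exceed p")
  if (object@nSignal < 0L) msg <- c(msg, "nSignal must be >= 0")
  if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho must lie in [0, 1)")
  if (object@targetPrevalence < 0 || object@targetPrevalence > 1)
    msg <- c(msg, "targetPrevalence must lie in [0, 1]")
  if (object@blockSize < 1L) msg <- c(msg, "blockSize must be >= 1")
  if (object@n < 1L || object@p < 1L) msg <- c(msg, "n and p must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset with recorded ground truth
#'
#' @slot data \linkS4class{FoldChangeSet}, the simulated matrix and outcome.
#' @slot trueSupport character, ids of the true predictor genes.
#' @slot trueSigns numeric, +1/-1 per support gene.
#' @slot trueIntercept numeric, calibrated logistic intercept.
#' @slot trueProbabilities numeric, per-sample outcome probability.
#' @slot realizedPrevalence numeric, mean of the drawn outcome.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("SyntheticDataset",
  representation(
    data = "FoldChangeSet", trueSupport = "character", trueSigns = "numeric",
    trueIntercept = "numeric", trueProbabilities = "numeric",
    realizedPrevalence = "numeric", config = "SimulationConfig"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  if (length(object@trueSupport) != length(object@trueSigns))
    msg <- c(msg, "one sign per support gene required")
  if (length(object@trueProbabilities) &&
      (min(object@trueProbabilities) <= 0 || max(object@trueProbabilities) >= 1))
    msg <- c(msg, "true probabilities must lie strictly inside (0, 1)")
  if (length(msg)) msg else TRUE
})
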