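#' Elastic-net configuration constructor
#'
#' @param alpha L1/L2 mixing parameter in [0, 1]; 0.5 (the default) weighs
#'   the two penalties equally. At 0.5 the penalty
#'   \eqn{\lambda[\alpha \sum|\beta_j| + ((1-\alpha)/2)\sum\beta_j^2]} is
#'   equivalent, up to the penalty scale absorbed by the path, to the
#'   symmetric form \eqn{(1-\alpha)\sum|\beta_j| + \alpha\sum\beta_j^2}.
#' @param nLambda path length (default 100).
#' @param lambdaMinRatio smallest/largest penalty ratio (default 1e-3).
#' @param standardize standardize predictors internally (default TRUE);
#'   reported coefficients are always on the original data scale.
#' @param criterion \code{"aic_prime"} (default) or \code{"aicc_prime"}.
#' @param tol solver convergence threshold (default 1e-7).
#' @param maxIter solver iteration cap.
#' @return an \linkS4class{ElasticNetConfig}.
#' @export
ElasticNetConfig <- function(alpha = 0.5, nLambda = 100L, lambdaMinRatio = 1e-3,
                             standardize = TRUE, criterion = "aic_prime",
                             tol = 1e-7, maxIter = 100000L) {
  methods::new("ElasticNetConfig", alpha = alpha, nLambda = as.integer(nLambda),
               lambdaMinRatio = lambdaMinRatio, standardize = standardize,
               criterion = criterion, tol = tol, maxIter = as.integer(maxIter))
}

.bernoulliLoglik <- function(p, y) {
  eps <- 1e-15
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

.asOutcome <- function(y) {
  if (is(y, "FoldChangeSet")) y <- outcome(y)
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  y
}

#' Intercept-only (null) logistic model
#'
#' The maximum-likelihood intercept is the log-odds of the outcome mean;
#' every slope is zero, so the modified Akaike criterion is exactly 0 -- the
#' reference value any path fit must beat to be selected.
#'
#' @param y 0/1 outcome vector or a \linkS4class{FoldChangeSet}.
#' @param geneIds optional gene universe for the (all-zero) coefficient
#'   vector; taken from \code{y} when it is a FoldChangeSet.
#' @return a \linkS4class{ModelFit} with \code{k = 0} and
#'   \code{aicPrime = 0}.
#' @examples
#' fit <- fitNullModel(c(rep(1, 22), rep(0, 66)))
#' fit@intercept            # log(0.25/0.75)
#' @export
fitNullModel <- function(y, geneIds = NULL) {
  if (is(y, "FoldChangeSet") && is.null(geneIds)) geneIds <- geneIds(y)
  y <- .asOutcome(y)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present to fit a model")
  m <- mean(y)
  ll <- .bernoulliLoglik(rep(m, length(y)), y)
  beta <- numeric(length(geneIds))
  names(beta) <- geneIds
  methods::new("ModelFit",
    intercept = qlogis(m), coefficients = beta, lambda = Inf, k = 0L,
    loglik = ll, nullLoglik = ll, aicPrime = 0, converged = TRUE)
}

#' Modified Akaike criterion
#'
#' \deqn{AIC' = LR\chi^2 - 2k = 2(\ell - \ell_0) - 2k,} where \eqn{\ell} is
#' the unpenalized Bernoulli log-likelihood at the (penalized) estimates,
#' \eqn{\ell_0} the intercept-only maximum, and \eqn{k} the number of
#' nonzero slopes. Larger is better; the null model scores exactly 0.
#' Counting nonzero slopes overstates the effective number of parameters of
#' a shrunken fit, i.e. the criterion penalizes somewhat more strongly than
#' an exact effective-dimension account would.
#'
#' @param loglik unpenalized log-likelihood of the fit.
#' @param nullLoglik intercept-only maximum log-likelihood.
#' @param k nonzero slope count (intercept excluded).
#' @return the criterion value.
#' @examples
#' aicPrime(-40, -50, 10)  # 0
#' aicPrime(-30, -50, 5)   # 30
#' @export
aicPrime <- function(loglik, nullLoglik, k) {
  if (k < 0) stop("k must be nonnegative")
  if (loglik < nullLoglik - 1e-8)
    stop("loglik below the null log-likelihood: the model must nest the intercept-only model")
  2 * (loglik - nullLoglik) - 2 * k
}

.aiccPrime <- function(loglik, nullLoglik, k, n) {
  if (k >= n - 1L) return(-Inf)
  aicPrime(loglik, nullLoglik, k) - 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the elastic-net regularization path
#'
#' Maximizes the Bernoulli log-likelihood penalized by
#' \eqn{\lambda[\alpha\sum_j|\beta_j| + ((1-\alpha)/2)\sum_j\beta_j^2]}
#' (intercept unpenalized) over a log-spaced grid of \eqn{\lambda} from
#' \eqn{\lambda_{max}} (the smallest penalty that zeroes every slope) down
#' to \code{lambdaMinRatio} times that. The solver is
#' \code{\link[glmnet]{glmnet}}; each path point is augmented with its
#' unpenalized log-likelihood and modified Akaike criterion, and the
#' criterion-maximizing fit is marked selected.
#'
#' @param x a \linkS4class{FoldChangeSet}, or a samples x genes numeric
#'   matrix (then \code{y} is required).
#' @param y 0/1 outcome; taken from \code{x} when it is a FoldChangeSet.
#' @param config an \linkS4class{ElasticNetConfig}.
#' @return a \linkS4class{PenaltyPath}. The fit at the largest penalty has
#'   \code{k = 0} and criterion 0.
#' @examples
#' sim <- simulateDataset(SimulationConfig(n = 60, p = 40, seed = 7))
#' path <- fitPenaltyPath(dataset(sim))
#' selectedFit(path)@k
#' @export
fitPenaltyPath <- function(x, y = NULL, config = ElasticNetConfig()) {
  if (is(x, "FoldChangeSet")) {
    if (is.null(y)) y <- outcome(x)
    x <- foldChanges(x)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("gene", seq_len(ncol(x)))
  y <- .asOutcome(y)
  if (nrow(x) != length(y)) stop("sample count of x and y must agree")
  if (nrow(x) < 4L) stop("at least 4 samples are required")
  if (!all(is.finite(x))) stop("non-finite values in the fold-change matrix")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  methods::validObject(config)

  null <- fitNullModel(y, geneIds = colnames(x))
  n <- length(y)
  # glmnet warns about small class counts on every bootstrap resample of a
  # low-prevalence outcome; the degenerate-resample guard already enforces
  # the minimum we require, so silence that one warning
  g <- withCallingHandlers(
    glmnet::glmnet(
      x, y, family = "binomial", alpha = config@alpha,
      nlambda = config@nLambda, lambda.min.ratio = config@lambdaMinRatio,
      standardize = config@standardize, thresh = config@tol,
      maxit = config@maxIter, intercept = TRUE
    ),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  lambdas <- g$lambda
  beta <- as.matrix(g$beta)           # p x nlambda, original scale
  a0 <- g$a0
  fits <- vector("list", length(lambdas))
  for (j in seq_along(lambdas)) {
    b <- beta[, j]
    b[abs(b) <= 1e-12] <- 0
    k <- sum(b != 0)
    eta <- drop(a0[j] + x %*% b)
    ll <- .bernoulliLoglik(plogis(eta), y)
    # shrinkage can leave the likelihood marginally below the null at the
    # boundary; clamp sub-tolerance deficits so the criterion is well defined
    if (ll < null@loglik && ll > null@loglik - 1e-8) ll <- null@loglik
    fits[[j]] <- methods::new("ModelFit",
      intercept = unname(a0[j]), coefficients = b, lambda = lambdas[j],
      k = as.integer(k), loglik = ll, nullLoglik = null@loglik,
      aicPrime = aicPrime(ll, null@loglik, k),
      converged = TRUE)
  }
  path <- methods::new("PenaltyPath",
    lambdas = lambdas, fits = fits, selectedIndex = 1L,
    criterion = config@criterion)
  path@selectedIndex <- .criterionArgmax(path, config, n)
  methods::validObject(path)
  path
}

.criterionValues <- function(path, config, n) {
  vapply(path@fits, function(f) {
    switch(config@criterion,
      aic_prime = f@aicPrime,
      aicc_prime = .aiccPrime(f@loglik, f@nullLoglik, f@k, n)
    )
  }, numeric(1))
}

.criterionArgmax <- function(path, config, n) {
  crit <- .criterionValues(path, config, n)
  # lambdas are decreasing, so the first maximum is the sparser model
  which.max(crit)
}

#' Select the criterion-maximizing fit from a path
#'
#' Ties are broken toward the larger penalty, i.e. the sparser model.
#'
#' @param path a \linkS4class{PenaltyPath}.
#' @param config the \linkS4class{ElasticNetConfig} naming the criterion.
#' @param n sample count, needed for the small-sample criterion; inferred
#'   as unnecessary for \code{"aic_prime"}.
#' @return list with elements \code{fit} (a \linkS4class{ModelFit}) and
#'   \code{genes} (character, the nonzero-coefficient gene set).
#' @export
selectByCriterion <- function(path, config = ElasticNetConfig(), n = NA_integer_) {
  if (!length(path@fits)) stop("empty penalty path")
  if (config@criterion == "aicc_prime" && is.na(n))
    stop("n is required for the aicc_prime criterion")
  idx <- .criterionArgmax(path, config, n)
  fit <- path@fits[[idx]]
  list(fit = fit, genes = selectedGenes(fit), index = idx)
}

#' @describeIn selectedGenes nonzero-coefficient genes of a single fit.
#' @export
setMethod("selectedGenes", "ModelFit", function(x) {
  names(x@coefficients)[abs(x@coefficients) > 1e-12]
})

#' @describeIn selectedGenes gene set of the path's selected fit.
#' @export
setMethod("selectedGenes", "PenaltyPath", function(x) {
  selectedGenes(x@fits[[x@selectedIndex]])
})

#' @describeIn selectedFit the fit at \code{selectedIndex}.
#' @export
setMethod("selectedFit", "PenaltyPath", function(x) x@fits[[x@selectedIndex]])

#' @describeIn predictProbabilities matrix input.
#' @export
setMethod("predictProbabilities", signature("ModelFit", "matrix"), function(fit, x) {
  p <- length(fit@coefficients)
  if (ncol(x) != p)
    stop("gene universe mismatch: fit has ", p, " genes, matrix has ", ncol(x))
  if (!is.null(colnames(x)) && !is.null(names(fit@coefficients)) &&
      !identical(colnames(x), names(fit@coefficients)))
    stop("gene ids of the matrix do not match the fit")
  plogis(drop(fit@intercept + x %*% fit@coefficients))
})

#' @describeIn predictProbabilities FoldChangeSet input.
#' @export
setMethod("predictProbabilities", signature("ModelFit", "FoldChangeSet"),
  function(fit, x) predictProbabilities(fit, foldChanges(x)))

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: lambda = %.4g, k = %d nonzero genes, AIC' = %.3f\n",
              object@lambda, object@k, object@aicPrime))
})

setMethod("show", "PenaltyPath", function(object) {
  sel <- object@fits[[object@selectedIndex]]
  cat(sprintf(
    "PenaltyPath: %d penalty values (lambda %.4g .. %.4g), criterion %s\n",
    length(object@lambdas), max(object@lambdas), min(object@lambdas),
    object@criterion))
  cat(sprintf("  selected: lambda = %.4g, k = %d, AIC' = %.3f\n",
              sel@lambda, sel@k, sel@aicPrime))
})
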