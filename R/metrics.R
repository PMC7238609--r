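#' Brier score
#'
#' Mean squared difference \eqn{n^{-1}\sum(\hat y_i - y_i)^2} between
#' predicted probabilities and the 0/1 outcome: a one-number summary of
#' calibration. The constant predictor at the outcome prevalence
#' \eqn{\bar p} scores exactly \eqn{\bar p(1-\bar p)}.
#'
#' @param predicted probabilities in [0, 1].
#' @param y 0/1 outcome of the same length.
#' @return the score, in [0, 1]; lower is better.
#' @examples
#' brierScore(rep(0.25, 88), c(rep(1, 22), rep(0, 66)))  # 0.1875
#' @export
brierScore <- function(predicted, y) {
  y <- .asOutcome(y)
  if (length(predicted) != length(y)) stop("predicted and y must have equal length")
  if (anyNA(predicted) || min(predicted) < 0 || max(predicted) > 1)
    stop("predictions must lie in [0, 1]")
  mean((predicted - y)^2)
}

#' Concordance probability (AUC)
#'
#' The probability that a randomly chosen positive receives a higher
#' predicted probability than a randomly chosen negative, with ties counted
#' one half -- the Mann-Whitney U scaled to [0, 1], equal to the area under
#' the ROC curve. Computed via midranks, so it is invariant under any
#' strictly increasing transform of the predictions; a constant predictor
#' scores exactly 0.5.
#'
#' @param predicted numeric scores (probabilities or any monotone score).
#' @param y 0/1 outcome, both classes present.
#' @return concordance in [0, 1].
#' @examples
#' concordance(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
concordance <- function(predicted, y) {
  y <- .asOutcome(y)
  if (length(predicted) != length(y)) stop("predicted and y must have equal length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes are required for concordance")
  r <- rank(predicted)                      # midranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' LOWESS calibration curve
#'
#' Smooths the 0/1 outcome as a function of the predicted probability with
#' LOWESS (locally weighted linear regression, tricube kernel, span 2/3 by
#' default, no robustness iterations -- with a binary response the robust
#' reweighting would treat the minority class as outliers and bias the
#' curve) and evaluates the smooth on an even grid spanning the prediction
#' range. A well-calibrated model
#' tracks the diagonal: among observations predicted \eqn{\hat p}, a
#' proportion \eqn{\hat p} should be positive. Smoothed proportions are
#' clipped to [0, 1].
#'
#' @param predicted probabilities in [0, 1], at least 10 of them.
#' @param y 0/1 outcome.
#' @param span LOWESS span in (0, 1] (default 2/3).
#' @param gridSize number of evaluation points (default 50).
#' @return data.frame with columns \code{predicted} (the grid, increasing)
#'   and \code{observed} (smoothed positive proportion), plus attribute
#'   \code{span}.
#' @export
calibrationCurve <- function(predicted, y, span = 2 / 3, gridSize = 50L) {
  y <- .asOutcome(y)
  if (length(predicted) != length(y)) stop("predicted and y must have equal length")
  if (length(y) < 10L) stop("at least 10 samples are required for the calibration curve")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  grid <- seq(min(predicted), max(predicted), length.out = gridSize)
  observed <- .lowessEval(predicted, y, span, grid)
  out <- data.frame(predicted = grid, observed = pmin(pmax(observed, 0), 1))
  attr(out, "span") <- span
  out
}

# LOWESS smooth of y on x evaluated at `at` by linear interpolation between
# the fitted points (constant beyond the data range). No robustness
# iterations: with a 0/1 response the bisquare reweighting treats the
# minority class as outliers and biases the smoothed proportion, so the
# plain tricube local-linear fit is the right estimator here.
# A degenerate constant-x design collapses to the mean of y.
.lowessEval <- function(x, y, span, at) {
  if (diff(range(x)) < .Machine$double.eps * max(1, abs(x[1]))) {
    return(rep(mean(y), length(at)))
  }
  sm <- lowess(x, y, f = span, iter = 0L, delta = 0)
  approx(sm$x, sm$y, xout = at, rule = 2, ties = mean)$y
}

#' Jaccard overlap of two gene sets
#'
#' \eqn{|S_1 \cap S_2| / |S_1 \cup S_2|}: the stability measure for
#' feature selection under resampling. Undefined (error) when both sets
#' are empty; the bootstrap machinery excludes and counts such pairs.
#'
#' @param s1,s2 character vectors of gene ids (duplicates ignored).
#' @return overlap in [0, 1]; symmetric in its arguments.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  u <- length(union(s1, s2))
  if (u == 0L) stop("Jaccard overlap of two empty sets is undefined")
  length(intersect(s1, s2)) / u
}

#' Expected gene-set overlap implied by a stability value
#'
#' For a selected set of a given size with pairwise Jaccard stability
#' \eqn{s}, the expected overlap with the set chosen on similar data is
#' about \eqn{s} times the set size, rounded to the nearest integer
#' (round-half-to-even).
#'
#' @param stability Jaccard stability in [0, 1].
#' @param setSize selected-set size (nonnegative integer).
#' @return integer gene count.
#' @examples
#' expectedOverlap(0.16, 108)  # 17
#' @export
expectedOverlap <- function(stability, setSize) {
  if (stability < 0 || stability > 1) stop("stability must lie in [0, 1]")
  if (setSize < 0) stop("setSize must be nonnegative")
  as.integer(round(stability * setSize))
}
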