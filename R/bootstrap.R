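#' Bootstrap configuration constructor
#'
#' @param B replicate count (default 500).
#' @param seed master seed; all resampling randomness derives from it via
#'   per-replicate substreams, so reports are bit-reproducible and
#'   independent of execution order.
#' @param maxRedraws cap on redrawing a resample whose outcome has fewer
#'   than two samples in either class (default 100).
#' @param maxJaccardPairs cap on replicate pairs entering the stability
#'   distribution (default 10000; random pairs beyond it).
#' @param pairing \code{"pairs"} (default) for Jaccard over replicate
#'   pairs, \code{"original"} for each replicate against the full-data set.
#' @return a \linkS4class{BootstrapConfig}.
#' @export
BootstrapConfig <- function(B = 500L, seed = 1L, maxRedraws = 100L,
                            maxJaccardPairs = 10000L, pairing = "pairs") {
  methods::new("BootstrapConfig", B = as.integer(B), seed = as.integer(seed),
               maxRedraws = as.integer(maxRedraws),
               maxJaccardPairs = as.integer(maxJaccardPairs),
               pairing = pairing)
}

#' Middle-.8 interval of a bootstrap distribution
#'
#' The 0.1 and 0.9 empirical quantiles with linear interpolation between
#' order statistics (position \eqn{1 + q(n-1)}).
#'
#' @param values numeric, at least 2 values.
#' @return numeric length 2, \code{c(low, high)}.
#' @examples
#' middle80(1:11)  # 2, 10
#' @export
middle80 <- function(values) {
  if (length(values) < 2L) stop("at least 2 values are required")
  unname(quantile(values, c(0.1, 0.9), type = 7, names = FALSE, na.rm = FALSE))
}

#' Draw one class-balanced bootstrap resample
#'
#' Samples n indices with replacement; the resampling unit is the
#' case-control pair (one row of the fold-change matrix), since matched
#' controls are inseparable from their cases. Resamples are redrawn (up to
#' \code{maxRedraws} times) until each outcome class contains at least two
#' samples drawn from at least two distinct source pairs -- a resample
#' whose positives are all copies of one pair cannot support a refit.
#'
#' @param y 0/1 outcome defining n and the classes.
#' @param maxRedraws redraw cap (default 100).
#' @return integer indices of length n, with attribute \code{"draws"} (the
#'   number of draws used).
#' @export
bootstrapResample <- function(y, maxRedraws = 100L) {
  y <- .asOutcome(y)
  n <- length(y)
  if (n < 4L) stop("at least 4 samples are required to resample")
  for (draw in seq_len(maxRedraws)) {
    idx <- sample.int(n, n, replace = TRUE)
    uniq <- unique(idx)
    tab <- c(sum(y[idx] == 0), sum(y[idx] == 1),
             sum(y[uniq] == 0), sum(y[uniq] == 1))
    if (all(tab >= 2L)) {
      attr(idx, "draws") <- draw
      return(idx)
    }
  }
  stop("could not draw a resample with >= 2 samples per class in ",
       maxRedraws, " attempts (pathological class imbalance)")
}

.replicateSeeds <- function(seed, B) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, B)
}

.asMatrixOutcome <- function(x, y) {
  if (is(x, "FoldChangeSet")) {
    if (is.null(y)) y <- outcome(x)
    x <- foldChanges(x)
  }
  list(x = as.matrix(x), y = .asOutcome(y))
}

# One full realization of the modeling procedure: path fit plus
# criterion-based penalty selection. Tuning is inside, so every bootstrap
# replicate re-tunes the penalty.
.fullProcedure <- function(x, y, config) {
  path <- fitPenaltyPath(x, y, config)
  sel <- selectByCriterion(path, config, n = length(y))
  sel
}

# Run the replicate loop shared by validation and stability. `payload` maps
# (fit, idx) computed on a resample to whatever the caller records.
.bootstrapLoop <- function(x, y, modelConfig, bootConfig, payload,
                           verbose = FALSE) {
  B <- bootConfig@B
  seeds <- .replicateSeeds(bootConfig@seed, B)
  out <- vector("list", B)
  redraws <- 0L
  nFailed <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    res <- tryCatch({
      idx <- bootstrapResample(y, bootConfig@maxRedraws)
      redraws <- redraws + attr(idx, "draws") - 1L
      sel <- .fullProcedure(x[idx, , drop = FALSE], y[idx], modelConfig)
      payload(sel, idx)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nFailed <- nFailed + 1L
      out[b] <- list(NULL)
      if (verbose) message("replicate ", b, " failed: ", conditionMessage(res))
    } else {
      out[[b]] <- res
    }
    if (verbose && b %% 50L == 0L) message("replicate ", b, "/", B)
  }
  if (B - nFailed < ceiling(0.9 * B))
    stop("too many failed bootstrap replicates: ", nFailed, " of ", B)
  list(results = out, nFailed = nFailed, redraws = redraws)
}

#' Optimism-corrected bootstrap validation
#'
#' Estimates how much the apparent (training-data) Brier score, concordance
#' and calibration curve overstate out-of-sample performance, using all of
#' the data and no held-out split. The full modeling procedure -- path fit
#' and criterion-based penalty selection -- is rerun on every bootstrap
#' resample; the per-replicate optimism is the metric on the resample minus
#' the same model's metric on the original data, and the corrected estimate
#' is the apparent value minus the mean optimism. For the Brier score the
#' optimism is therefore typically negative (the resample error understates
#' the true error), so the corrected Brier is larger than the apparent one.
#' The calibration curve is corrected pointwise on a 50-point grid spanning
#' the apparent prediction range.
#'
#' @param x a \linkS4class{FoldChangeSet}, or samples x genes matrix.
#' @param y 0/1 outcome (taken from \code{x} when it is a FoldChangeSet).
#' @param modelConfig an \linkS4class{ElasticNetConfig}.
#' @param bootConfig a \linkS4class{BootstrapConfig}.
#' @param verbose log replicate progress to stderr.
#' @return a \linkS4class{ValidationReport}.
#' @export
optimismValidate <- function(x, y = NULL, modelConfig = ElasticNetConfig(),
                             bootConfig = BootstrapConfig(), verbose = FALSE) {
  d <- .asMatrixOutcome(x, y)
  x <- d$x; y <- d$y
  span <- 2 / 3

  sel <- .fullProcedure(x, y, modelConfig)
  predApp <- predictProbabilities(sel$fit, x)
  apparent <- c(brier = brierScore(predApp, y), concordance = concordance(predApp, y))
  grid <- seq(min(predApp), max(predApp), length.out = 50L)
  calApp <- pmin(pmax(.lowessEval(predApp, y, span, grid), 0), 1)

  payload <- function(bsel, idx) {
    predBoot <- predictProbabilities(bsel$fit, x[idx, , drop = FALSE])
    predOrig <- predictProbabilities(bsel$fit, x)
    yBoot <- y[idx]
    list(
      optimism = c(
        brier = brierScore(predBoot, yBoot) - brierScore(predOrig, y),
        concordance = concordance(predBoot, yBoot) - concordance(predOrig, y)
      ),
      calOptimism = pmin(pmax(.lowessEval(predBoot, yBoot, span, grid), 0), 1) -
        pmin(pmax(.lowessEval(predOrig, y, span, grid), 0), 1)
    )
  }
  loop <- .bootstrapLoop(x, y, modelConfig, bootConfig, payload, verbose)
  ok <- !vapply(loop$results, is.null, logical(1))
  opt <- do.call(rbind, lapply(loop$results[ok], `[[`, "optimism"))
  calOpt <- do.call(rbind, lapply(loop$results[ok], `[[`, "calOptimism"))

  meanOpt <- colMeans(opt)
  corrected <- apparent - meanOpt
  replicates <- data.frame(
    brier_corrected = apparent["brier"] - opt[, "brier"],
    concordance_corrected = apparent["concordance"] - opt[, "concordance"],
    row.names = NULL
  )
  calCorrectedReps <- matrix(rep(calApp, each = nrow(calOpt)), nrow = nrow(calOpt)) - calOpt
  calCorrectedReps <- pmin(pmax(calCorrectedReps, 0), 1)
  calibration <- data.frame(
    predicted = grid,
    observed_apparent = calApp,
    observed_corrected = pmin(pmax(calApp - colMeans(calOpt), 0), 1),
    lower80 = apply(calCorrectedReps, 2, function(v) middle80(v)[1]),
    upper80 = apply(calCorrectedReps, 2, function(v) middle80(v)[2])
  )
  methods::new("ValidationReport",
    apparent = apparent, optimism = meanOpt, corrected = corrected,
    replicates = replicates,
    intervals = list(brier = middle80(replicates$brier_corrected),
                     concordance = middle80(replicates$concordance_corrected)),
    calibration = calibration,
    B = bootConfig@B, seed = bootConfig@seed,
    nFailed = loop$nFailed, redraws = loop$redraws,
    modelConfig = modelConfig, bootConfig = bootConfig)
}

#' Bootstrap stability of the selected gene set
#'
#' Reruns the full modeling procedure on bootstrap resamples and records
#' each replicate's selected gene set. Reports per-gene selection
#' probabilities, pairwise co-selection fractions (for genes ever
#' selected), the distribution of pairwise Jaccard overlaps between
#' replicate sets with its middle-.8 interval, and the expected overlap
#' (stability times the full-data selected-set size, rounded). Pairs of
#' two empty sets have undefined overlap and are excluded but counted; an
#' empty set against a nonempty one scores 0.
#'
#' @inheritParams optimismValidate
#' @return a \linkS4class{StabilityReport}.
#' @export
stabilityAnalysis <- function(x, y = NULL, modelConfig = ElasticNetConfig(),
                              bootConfig = BootstrapConfig(), verbose = FALSE) {
  d <- .asMatrixOutcome(x, y)
  x <- d$x; y <- d$y
  genes <- colnames(x)

  full <- .fullProcedure(x, y, modelConfig)
  payload <- function(bsel, idx) bsel$genes
  loop <- .bootstrapLoop(x, y, modelConfig, bootConfig, payload, verbose)
  sets <- loop$results[!vapply(loop$results, is.null, logical(1))]
  nOk <- length(sets)

  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) memb <- matrix(memb, nrow = 1L)
  rownames(memb) <- genes
  selProb <- rowMeans(memb)
  ever <- genes[selProb > 0]
  coSel <- if (length(ever)) {
    m <- memb[ever, , drop = FALSE] + 0
    tcrossprod(m) / nOk
  } else {
    matrix(numeric(0), 0, 0)
  }

  stab <- .jaccardDistribution(sets, full$genes, bootConfig)
  expOver <- if (is.finite(stab$point)) {
    expectedOverlap(stab$point, length(full$genes))
  } else NA_integer_

  methods::new("StabilityReport",
    selectionProbability = selProb,
    coSelection = coSel,
    jaccardValues = stab$values,
    stabilityPoint = stab$point,
    stabilityInterval = stab$interval,
    expectedOverlap = expOver,
    replicateSetSizes = vapply(sets, length, integer(1)),
    emptyPairsExcluded = stab$emptyPairs,
    fullDataSet = full$genes,
    B = bootConfig@B, seed = bootConfig@seed,
    nFailed = loop$nFailed, redraws = loop$redraws,
    modelConfig = modelConfig, bootConfig = bootConfig)
}

.jaccardDistribution <- function(sets, fullSet, bootConfig) {
  if (bootConfig@pairing == "original") {
    pairs <- cbind(seq_along(sets), 0L)   # second member = full-data set
  } else {
    nPairs <- length(sets) * (length(sets) - 1L) / 2
    if (nPairs <= bootConfig@maxJaccardPairs) {
      pairs <- t(utils::combn(length(sets), 2L))
    } else {
      set.seed(bootConfig@seed + 1L)
      i <- sample.int(length(sets), bootConfig@maxJaccardPairs, replace = TRUE)
      j <- sample.int(length(sets) - 1L, bootConfig@maxJaccardPairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)      # uniform pairs without self-pairing
      pairs <- cbind(i, j)
    }
  }
  vals <- numeric(0)
  emptyPairs <- 0L
  for (r in seq_len(nrow(pairs))) {
    s1 <- sets[[pairs[r, 1L]]]
    s2 <- if (pairs[r, 2L] == 0L) fullSet else sets[[pairs[r, 2L]]]
    if (length(s1) == 0L && length(s2) == 0L) {
      emptyPairs <- emptyPairs + 1L
    } else {
      vals <- c(vals, jaccard(s1, s2))
    }
  }
  list(
    values = vals,
    point = if (length(vals)) mean(vals) else NA_real_,
    interval = if (length(vals) >= 2L) middle80(vals) else c(NA_real_, NA_real_),
    emptyPairs = emptyPairs
  )
}

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport (optimism-corrected bootstrap, B =", object@B, ")\n")
  for (m in c("brier", "concordance")) {
    iv <- object@intervals[[m]]
    cat(sprintf(
      "  %-11s apparent %.4f  optimism %+.4f  corrected %.4f  middle-.8 [%.4f, %.4f]\n",
      m, object@apparent[m], object@optimism[m], object@corrected[m], iv[1], iv[2]))
  }
  cat(sprintf("  root corrected Brier: %.4f\n", sqrt(object@corrected["brier"])))
  if (object@nFailed > 0L) cat("  failed replicates:", object@nFailed, "\n")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport (bootstrap, B =", object@B, ")\n")
  cat(sprintf("  full-data selected set: %d genes\n", length(object@fullDataSet)))
  if (is.finite(object@stabilityPoint)) {
    cat(sprintf("  Jaccard stability: %.4f  middle-.8 [%.4f, %.4f]\n",
                object@stabilityPoint, object@stabilityInterval[1],
                object@stabilityInterval[2]))
    cat(sprintf("  expected overlap on similar data: %d genes\n",
                object@expectedOverlap))
  } else {
    cat("  Jaccard stability undefined: all replicate pairs were empty-empty (",
        object@emptyPairsExcluded, " excluded)\n", sep = "")
  }
})
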