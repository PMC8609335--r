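#' Label permutation scheme
#'
#' Identity labels are shuffled independently within every
#' (participant, head view, familiarity) cell, preserving each cell's label
#' multiset; the analysis is then repeated on the shuffled labels
#' (\code{nPermutations} times, 100 in the reference analysis).
#'
#' @param nPermutations number of label permutations (default 100).
#' @param seed integer seed; permutation \code{index} is reproducible from
#'   seed + index.
#' @export
permutationScheme <- function(nPermutations = 100, seed = 1) {
  structure(list(nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed)),
            class = "permutationScheme")
}

#' Permute identity labels within subject x view cells
#'
#' @param samples a \linkS4class{SampleSet}.
#' @param scheme a \code{\link{permutationScheme}}.
#' @param index permutation index (1-based); the same seed and index always
#'   give the same permutation.
#' @return a \linkS4class{SampleSet} with permuted identity labels and
#'   untouched data values.
#' @export
permuteLabels <- function(samples, scheme, index) {
  si <- samples@sampleInfo
  cells <- split(seq_len(nrow(si)),
                 interaction(si$subject, si$view, si$familiarity, drop = TRUE))
  withSeed(childSeed(scheme$seed, "permute", index), {
    for (ix in cells)
      si$identity[ix] <- samples@sampleInfo$identity[ix][sample(length(ix))]
  })
  new("SampleSet", values = samples@values, sampleInfo = si)
}

#' Fold accuracies under label permutations
#'
#' Repeats the between-subject decoding for every location and fold with
#' permuted identity labels.
#'
#' @param samples a \linkS4class{SampleSet}.
#' @param locations a \linkS4class{SearchlightSet}, \linkS4class{ROIMap}, or
#'   list of vertex-index vectors.
#' @param folds data.frame from \code{\link{makeFolds}}.
#' @param condition familiarity condition.
#' @param scheme a \code{\link{permutationScheme}}.
#' @param config \code{\link{classifierConfig}} settings.
#' @return numeric array (locations x folds x permutations).
#' @export
permutedAccuracies <- function(samples, locations, folds, condition, scheme,
                               config = classifierConfig()) {
  nodeSets <- .nodeSetsOf(locations)
  out <- array(NA_real_,
               c(length(nodeSets), nrow(folds), scheme$nPermutations),
               dimnames = list(names(nodeSets), NULL, NULL))
  for (p in seq_len(scheme$nPermutations)) {
    perm <- permuteLabels(samples, scheme, p)
    out[, , p] <- .mvpcAccuracy(perm, nodeSets, folds, condition, config)
  }
  out
}

.nodeSetsOf <- function(locations) {
  if (is(locations, "SearchlightSet")) {
    stats::setNames(locations@members, as.character(locations@centers))
  } else if (is(locations, "ROIMap")) {
    stats::setNames(lapply(seq_along(locations@roiNames),
                           function(i) roiVertices(locations, i)),
                    locations@roiNames)
  } else if (is.list(locations)) {
    locations
  } else stop("unsupported locations object")
}

#' Bootstrap null distribution of mean accuracies
#'
#' Each bootstrap draw samples \code{nFolds} fold-level accuracies with
#' replacement from the pooled permuted folds of a location and records their
#' mean (10,000 draws of 70 folds in the reference analysis).
#'
#' @param permAcc array (locations x folds x permutations) from
#'   \code{\link{permutedAccuracies}}, or a locations x pooled-values matrix.
#' @param nBootstrap number of draws (default 10000).
#' @param nFolds folds per draw (default: the fold dimension of permAcc).
#' @param seed integer seed.
#' @param chance chance accuracy (default 0.25).
#' @param stratify "pooled" (default): folds are resampled i.i.d. from the
#'   union of all permutations' folds; "permutation": each draw resamples
#'   its folds within a single randomly chosen permutation, so the
#'   between-permutation spread of the mean is retained.  The pooled variant
#'   understates the variance of the observed mean when fold accuracies are
#'   correlated; see the package vignette.
#' @return a \linkS4class{NullDistribution}.
#' @export
buildNull <- function(permAcc, nBootstrap = 10000, nFolds = NULL, seed = 1,
                      chance = 0.25, stratify = c("pooled", "permutation")) {
  stratify <- match.arg(stratify)
  is3d <- length(dim(permAcc)) == 3
  if (is3d) {
    nLoc <- dim(permAcc)[1]
    if (is.null(nFolds)) nFolds <- dim(permAcc)[2]
    pool <- matrix(permAcc, nLoc)
    rownames(pool) <- dimnames(permAcc)[[1]]
  } else {
    if (stratify == "permutation")
      stop("stratified sampling needs the locations x folds x permutations array")
    pool <- as.matrix(permAcc)
    nLoc <- nrow(pool)
    if (is.null(nFolds)) stop("nFolds required for a pooled matrix")
  }
  if (!ncol(pool)) stop("empty permutation pool")
  locNames <- rownames(pool)
  if (is.null(locNames)) locNames <- as.character(seq_len(nLoc))
  draws <- withSeed(childSeed(seed, "bootstrap"), {
    if (stratify == "pooled") {
      t(vapply(seq_len(nLoc), function(l) {
        m <- matrix(sample(pool[l, ], nBootstrap * nFolds, replace = TRUE),
                    nBootstrap, nFolds)
        rowMeans(m)
      }, numeric(nBootstrap)))
    } else {
      nPerm <- dim(permAcc)[3]
      t(vapply(seq_len(nLoc), function(l) {
        pp <- sample.int(nPerm, nBootstrap, replace = TRUE)
        vapply(pp, function(p)
          mean(sample(permAcc[l, , p], nFolds, replace = TRUE)),
          numeric(1))
      }, numeric(nBootstrap)))
    }
  })
  new("NullDistribution", draws = draws, locations = locNames, chance = chance)
}

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: %d locations x %d bootstrap draws; grand mean %.3f (chance %.2f)\n",
              nrow(object@draws), ncol(object@draws), mean(object@draws),
              object@chance))
})

#' Bias-corrected empirical p-value
#'
#' One-sided: (number of null draws >= observed + 1) / (draws + 1); ties
#' count as exceedances, keeping the estimate conservative.  Two-sided: the
#' same rule on absolute values (used for difference maps).
#'
#' @param observed numeric vector of observed statistics (one per location).
#' @param null a \linkS4class{NullDistribution} or numeric matrix
#'   (locations x draws).
#' @param sided "one" or "two".
#' @return numeric vector of p-values in (0, 1].
#' @export
empiricalP <- function(observed, null, sided = c("one", "two")) {
  sided <- match.arg(sided)
  draws <- if (is(null, "NullDistribution")) null@draws else as.matrix(null)
  if (length(observed) != nrow(draws))
    stop("one observed value per null distribution row required")
  n <- ncol(draws)
  if (!n) stop("empty null distribution")
  vapply(seq_along(observed), function(l) {
    if (sided == "one") (sum(draws[l, ] >= observed[l]) + 1) / (n + 1)
    else (sum(abs(draws[l, ]) >= abs(observed[l])) + 1) / (n + 1)
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' Standard step-up BH with monotonicity enforcement.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with q (adjusted values) and significant (q <= alpha).
#' @export
fdrBH <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(list(q = numeric(0), significant = logical(0)))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Permutation statistics for an accuracy map
#'
#' Mean observed accuracy per location, one-sided bias-corrected empirical
#' p-value against the bootstrap null, and BH-FDR adjusted q-values.
#'
#' @param observed an \linkS4class{AccuracyResult}.
#' @param null a \linkS4class{NullDistribution} over the same locations.
#' @param alpha FDR level (default 0.05).
#' @return data.frame: location, observed, p, q, significant.
#' @export
statMap <- function(observed, null, alpha = 0.05) {
  if (!identical(observed@locations, null@locations))
    stop("location mismatch between accuracies and null")
  obs <- rowMeans(observed@accuracy)
  p <- empiricalP(obs, null, sided = "one")
  bh <- fdrBH(p, alpha)
  data.frame(location = observed@locations, observed = obs, p = p,
             q = bh$q, significant = bh$significant, row.names = NULL)
}

#' Floored condition-difference map with permutation inference
#'
#' Fold-mean accuracies of the two conditions are floored at chance (values
#' below 25 percent carry no information but would inflate the difference),
#' then subtracted (personal - visual).  The null rebuilds the same statistic
#' \code{nBootstrap} times from independently bootstrapped permuted folds per
#' condition; inference is two-sided on absolute values with BH-FDR.
#'
#' @param personal,visual \linkS4class{AccuracyResult} objects with matching
#'   locations and fold structure.
#' @param permPersonal,permVisual arrays from \code{\link{permutedAccuracies}}.
#' @param nBootstrap bootstrap draws (default 10000).
#' @param chance chance level (default 0.25).
#' @param seed integer seed.
#' @param alpha FDR level.
#' @return data.frame: location, personal, visual, difference, p, q,
#'   significant.
#' @export
differenceMap <- function(personal, visual, permPersonal, permVisual,
                          nBootstrap = 10000, chance = 0.25, seed = 1,
                          alpha = 0.05) {
  if (!identical(personal@locations, visual@locations))
    stop("location mismatch between conditions")
  if (ncol(personal@accuracy) != ncol(visual@accuracy))
    stop("fold structure mismatch between conditions")
  nLoc <- length(personal@locations)
  nFolds <- ncol(personal@accuracy)
  obsP <- pmax(rowMeans(personal@accuracy), chance)
  obsV <- pmax(rowMeans(visual@accuracy), chance)
  obsD <- obsP - obsV
  poolP <- matrix(permPersonal, nLoc)
  poolV <- matrix(permVisual, nLoc)
  nullD <- withSeed(childSeed(seed, "bootstrap", 1L), {
    t(vapply(seq_len(nLoc), function(l) {
      dp <- rowMeans(matrix(sample(poolP[l, ], nBootstrap * nFolds, replace = TRUE),
                            nBootstrap, nFolds))
      dv <- rowMeans(matrix(sample(poolV[l, ], nBootstrap * nFolds, replace = TRUE),
                            nBootstrap, nFolds))
      pmax(dp, chance) - pmax(dv, chance)
    }, numeric(nBootstrap)))
  })
  p <- empiricalP(obsD, nullD, sided = "two")
  bh <- fdrBH(p, alpha)
  data.frame(location = personal@locations, personal = obsP, visual = obsV,
             difference = obsD, p = p, q = bh$q, significant = bh$significant,
             row.names = NULL)
}

#' Write a statistics table as TSV
#' @param x data.frame from \code{\link{statMap}} or
#'   \code{\link{differenceMap}}.
#' @param path output file.
#' @export
writeStatMap <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
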