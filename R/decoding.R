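#' Average response patterns across runs
#'
#' Unweighted mean of each condition's pattern across runs, yielding
#' identities x views samples per familiarity (20 samples for the 4 x 5
#' layout).
#'
#' @param ps a \linkS4class{PatternSet} with per-run samples.
#' @return a \linkS4class{PatternSet} with one sample per condition
#'   (run = NA).
#' @export
averageRuns <- function(ps) {
  si <- ps@sampleInfo
  key <- interaction(si$familiarity, si$identity, si$view, drop = TRUE)
  full <- expand.grid(familiarity = unique(si$familiarity),
                      identity = unique(si$identity), view = unique(si$view))
  have <- unique(paste(si$familiarity, si$identity, si$view))
  want <- paste(full$familiarity, full$identity, full$view)
  if (!all(want %in% have))
    stop("incomplete design: missing condition(s) ",
         paste(setdiff(want, have), collapse = "; "))
  groups <- split(seq_len(nrow(si)), key)
  vals <- t(vapply(groups, function(ix)
    colMeans(ps@values[ix, , drop = FALSE]), numeric(ncol(ps@values))))
  info <- si[vapply(groups, `[`, integer(1), 1L),
             c("familiarity", "identity", "view")]
  info$run <- NA_integer_
  rownames(info) <- NULL
  new("PatternSet", values = vals, betas = vals, sampleInfo = info,
      statistic = ps@statistic)
}

#' Assemble a multi-subject sample set
#'
#' Stacks run-averaged pattern sets (already projected into one common
#' reference space) from several subjects into the decoding container.
#'
#' @param patternSets list of run-averaged \linkS4class{PatternSet}.
#' @param subjects subject ids (default seq_along).
#' @return a \linkS4class{SampleSet}.
#' @export
combineSubjects <- function(patternSets, subjects = seq_along(patternSets)) {
  vals <- do.call(rbind, lapply(patternSets, function(p) p@values))
  info <- do.call(rbind, Map(function(p, s) {
    df <- p@sampleInfo[c("familiarity", "identity", "view")]
    df$subject <- s
    df
  }, patternSets, subjects))
  rownames(info) <- NULL
  new("SampleSet", values = vals,
      sampleInfo = info[c("subject", "familiarity", "identity", "view")])
}

setMethod("show", "SampleSet", function(object) {
  si <- object@sampleInfo
  cat(sprintf("SampleSet: %d samples x %d vertices; %d subjects, %d familiarity conditions, %d identities x %d views\n",
              nrow(si), ncol(object@values), length(unique(si$subject)),
              length(unique(si$familiarity)), length(unique(si$identity)),
              length(unique(si$view))))
})

#' Nested cross-validation folds across subjects and head views
#'
#' One fold per (left-out subject, left-out view) pair, subject-major order:
#' 14 subjects x 5 views give the 70 folds of the reference analysis.
#' Training uses the remaining subjects' samples at the remaining views, so
#' train and test are independent at both the participant and the stimulus
#' level.
#'
#' @param nSubjects number of subjects, >= 2.
#' @param nViews number of head views, >= 2.
#' @return data.frame with columns testSubject, testView.
#' @export
makeFolds <- function(nSubjects, nViews) {
  if (nSubjects < 2) stop("need at least 2 subjects for between-subject folds")
  if (nViews < 2) stop("need at least 2 views for cross-view folds")
  data.frame(testSubject = rep(seq_len(nSubjects), each = nViews),
             testView = rep(seq_len(nViews), nSubjects))
}

#' Classifier settings for between-subject MVPC
#'
#' One-vs-one linear soft-margin SVMs with vote counting; prediction ties are
#' broken by summed decision values, then by the lowest class index.  With
#' \code{cost = NULL} the regularization parameter is scaled by the data
#' norm, C = 1 / mean squared sample norm of the training set.
#'
#' @param cost fixed SVM cost, or NULL for norm-scaled.
#' @param scaleFeatures z-scale features inside the SVM (default FALSE: no
#'   normalization beyond the upstream t-values/z-scoring).
#' @export
classifierConfig <- function(cost = NULL, scaleFeatures = FALSE) {
  list(cost = cost, scaleFeatures = scaleFeatures)
}

# train on (trainX, trainY), return predicted labels for testX
.svmPredict <- function(trainX, trainY, testX, config) {
  classes <- sort(unique(trainY))
  if (length(classes) < 2) stop("fewer than 2 classes in training labels")
  cost <- config$cost
  if (is.null(cost)) {
    msn <- mean(rowSums(trainX^2))
    cost <- if (is.finite(msn) && msn > 0) 1 / msn else 1
  }
  fit <- e1071::svm(trainX, factor(trainY, levels = classes),
                    kernel = "linear", cost = cost,
                    scale = config$scaleFeatures, fitted = FALSE)
  k <- length(classes)
  # pairwise (one-vs-one) decision values computed directly from the dual
  # solution; identical to predict(..., decision.values = TRUE)
  K <- testX %*% t(fit$SV)
  nSV <- fit$nSV
  start <- c(1L, cumsum(nSV)[-k] + 1L)
  votes <- matrix(0, nrow(testX), k)
  score <- matrix(0, nrow(testX), k)
  p <- 0L
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    p <- p + 1L
    ia <- start[a]:(start[a] + nSV[a] - 1L)
    ib <- start[b]:(start[b] + nSV[b] - 1L)
    d <- K[, ia, drop = FALSE] %*% fit$coefs[ia, b - 1] +
      K[, ib, drop = FALSE] %*% fit$coefs[ib, a] - fit$rho[p]
    # libsvm groups classes by order of appearance: group g is class labels[g]
    ca <- fit$labels[a]; cb <- fit$labels[b]
    votes[, ca] <- votes[, ca] + (d > 0)
    votes[, cb] <- votes[, cb] + (d <= 0)
    score[, ca] <- score[, ca] + d
    score[, cb] <- score[, cb] - d
  }
  # max votes; ties by summed decision value; remaining ties by lowest class
  out <- integer(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) best <- best[score[i, best] == max(score[i, best])]
    out[i] <- best[1]
  }
  classes[out]
}

# train/test row indices of one fold within a familiarity-filtered SampleSet
.foldIndices <- function(si, fold) {
  train <- which(si$subject != fold$testSubject & si$view != fold$testView)
  test <- which(si$subject == fold$testSubject & si$view == fold$testView)
  list(train = train, test = test)
}

#' Run one cross-validation fold on a vertex set
#'
#' Trains the identity classifier on all training-subject samples at the
#' training views and tests on the left-out subject's samples at the
#' left-out view.
#'
#' @param samples a \linkS4class{SampleSet}.
#' @param nodes vertex indices to use as features (nonempty).
#' @param fold one-row data.frame with testSubject and testView.
#' @param condition familiarity condition to decode.
#' @param config \code{\link{classifierConfig}} settings.
#' @return fraction of correctly predicted identities.
#' @export
runFold <- function(samples, nodes, fold, condition = NULL,
                    config = classifierConfig()) {
  if (!length(nodes)) stop("empty vertex set")
  si <- samples@sampleInfo
  keep <- if (is.null(condition)) seq_len(nrow(si)) else which(si$familiarity == condition)
  si <- si[keep, , drop = FALSE]
  vals <- samples@values[keep, nodes, drop = FALSE]
  ix <- .foldIndices(si, fold)
  pred <- .svmPredict(vals[ix$train, , drop = FALSE], si$identity[ix$train],
                      vals[ix$test, , drop = FALSE], config)
  mean(pred == si$identity[ix$test])
}

# shared engine: accuracies for a list of vertex sets over all folds
.mvpcAccuracy <- function(samples, nodeSets, folds, condition, config,
                          identity = NULL) {
  si <- samples@sampleInfo
  keep <- if (is.null(condition)) seq_len(nrow(si)) else which(si$familiarity == condition)
  si <- si[keep, , drop = FALSE]
  vals <- samples@values[keep, , drop = FALSE]
  if (is.null(identity)) identity <- si$identity
  acc <- matrix(NA_real_, length(nodeSets), nrow(folds))
  for (f in seq_len(nrow(folds))) {
    ix <- .foldIndices(si, folds[f, ])
    yTrain <- identity[ix$train]
    yTest <- identity[ix$test]
    for (l in seq_along(nodeSets)) {
      pred <- .svmPredict(vals[ix$train, nodeSets[[l]], drop = FALSE], yTrain,
                          vals[ix$test, nodeSets[[l]], drop = FALSE], config)
      acc[l, f] <- mean(pred == yTest)
    }
  }
  acc
}

#' Searchlight between-subject MVPC
#'
#' Decodes identity within every searchlight for every fold; each
#' searchlight's accuracy is keyed by its center vertex.
#'
#' @param samples a \linkS4class{SampleSet} in one common reference space.
#' @param searchlights a \linkS4class{SearchlightSet} (radius 10 mm in the
#'   reference analysis).
#' @param folds data.frame from \code{\link{makeFolds}}.
#' @param condition familiarity condition to decode.
#' @param config \code{\link{classifierConfig}} settings.
#' @return an \linkS4class{AccuracyResult} (searchlight centers x folds).
#' @export
searchlightMVPC <- function(samples, searchlights, folds, condition,
                            config = classifierConfig()) {
  acc <- .mvpcAccuracy(samples, searchlights@members, folds, condition, config)
  new("AccuracyResult", locations = as.character(searchlights@centers),
      accuracy = acc, folds = folds, condition = condition)
}

#' ROI between-subject MVPC
#'
#' As \code{\link{searchlightMVPC}} with each ROI's vertex set in place of a
#' searchlight.
#'
#' @param samples a \linkS4class{SampleSet}.
#' @param rois a \linkS4class{ROIMap}.
#' @param folds data.frame from \code{\link{makeFolds}}.
#' @param condition familiarity condition to decode.
#' @param config \code{\link{classifierConfig}} settings.
#' @return an \linkS4class{AccuracyResult} (ROIs x folds).
#' @export
roiMVPC <- function(samples, rois, folds, condition,
                    config = classifierConfig()) {
  nodeSets <- lapply(seq_along(rois@roiNames), function(i) roiVertices(rois, i))
  empty <- lengths(nodeSets) == 0
  if (any(empty)) stop("empty ROI: ", paste(rois@roiNames[empty], collapse = ", "))
  acc <- .mvpcAccuracy(samples, nodeSets, folds, condition, config)
  new("AccuracyResult", locations = rois@roiNames, accuracy = acc,
      folds = folds, condition = condition)
}

#' Mean accuracy per location
#' @param x an \linkS4class{AccuracyResult}.
#' @export
meanAccuracy <- function(x) {
  stats::setNames(rowMeans(x@accuracy), x@locations)
}

setMethod("show", "AccuracyResult", function(object) {
  cat(sprintf("AccuracyResult (%s): %d locations x %d folds; mean accuracy %.3f\n",
              object@condition, nrow(object@accuracy), ncol(object@accuracy),
              mean(object@accuracy)))
})

#' Export accuracies as a long-format table
#'
#' @param x an \linkS4class{AccuracyResult}.
#' @param path optional TSV output path.
#' @return data.frame with condition, location, fold_subject, fold_view,
#'   accuracy.
#' @export
accuracyTable <- function(x, path = NULL) {
  df <- data.frame(
    condition = x@condition,
    location = rep(x@locations, times = ncol(x@accuracy)),
    fold_subject = rep(x@folds$testSubject, each = nrow(x@accuracy)),
    fold_view = rep(x@folds$testView, each = nrow(x@accuracy)),
    accuracy = as.vector(x@accuracy))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
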