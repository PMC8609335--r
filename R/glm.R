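#' Joint nuisance and high-pass projection
#'
#' Removes, in a single least-squares projection, the supplied nuisance
#' columns together with the slow-drift subspace: per-run polynomial trends up
#' to \code{polyOrder} and all discrete-cosine components with frequency below
#' \code{highpassHz}.  The output is orthogonal to the removed subspace; input
#' already orthogonal to it passes through unchanged.
#'
#' @param ts numeric matrix (vertices x time).
#' @param nuisance numeric matrix (time x k) of nuisance series, or NULL.
#' @param tr repetition time (s).
#' @param highpassHz high-pass cutoff in Hz (default 0.0066).
#' @param polyOrder polynomial detrending order included in the removed
#'   subspace (default 1: constant and linear drift).
#' @return vertices x time matrix of residuals.
#' @export
projectOutNuisance <- function(ts, nuisance = NULL, tr = 1.25,
                               highpassHz = 0.0066, polyOrder = 1) {
  nT <- ncol(ts)
  B <- driftBasis(nT, tr, highpassHz, polyOrder)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nT) stop("nuisance time length mismatch")
    B <- cbind(B, nuisance)
  }
  if (ncol(B) >= nT) stop("removed subspace has rank >= number of time points")
  Q <- qr.Q(qr(B))
  ts - (ts %*% Q) %*% t(Q)
}

# constant + polynomial trend + sub-cutoff discrete cosine basis
driftBasis <- function(nT, tr, highpassHz, polyOrder = 1) {
  t01 <- seq(0, 1, length.out = nT)
  B <- vapply(0:polyOrder, function(p) t01^p, numeric(nT))
  K <- floor(2 * nT * tr * highpassHz)
  if (K > 0) {
    dct <- vapply(seq_len(K), function(k)
      cos(pi * k * (seq_len(nT) - 0.5) / nT), numeric(nT))
    B <- cbind(B, dct)
  }
  B
}

#' Build the task GLM design matrix
#'
#' One HRF-convolved regressor per stimulus image per run (the regressors of
#' interest), one regressor for participant "same" button presses, one for the
#' extra lead trial of each run (a single condition pooled over runs), and
#' per-run polynomial drift columns up to \code{polyOrder}.  Runs are
#' concatenated along time; regressors of interest are nonzero only within
#' their own run.
#'
#' @param runDesigns list of \linkS4class{RunDesign} (possibly mixed
#'   familiarity conditions).
#' @param hrf an \linkS4class{HRFSpec}; stimulus events are convolved for the
#'   stimulus duration stored in it.
#' @param tr repetition time (s).
#' @param nViews number of head views (labels decode to identity/view
#'   view-fastest; default 5).
#' @param responses optional data.frame of button-press events with columns
#'   run, onset (s); modeled as a single condition.
#' @param polyOrder per-run polynomial order (default 3).
#' @param nullLabel fixation label carrying no regressor (default: the
#'   largest label).
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesign <- function(runDesigns, hrf = hrfSpec(), tr = 1.25, nViews = 5,
                        responses = NULL, polyOrder = 3, nullLabel = NULL) {
  if (!length(runDesigns)) stop("no run designs supplied")
  nTimesPerRun <- as.integer(vapply(runDesigns,
                                    function(d) ceiling(runDuration(d) / tr),
                                    numeric(1)))
  runStarts <- cumsum(c(1L, nTimesPerRun[-length(nTimesPerRun)]))
  totalT <- sum(nTimesPerRun)
  if (is.null(nullLabel))
    nullLabel <- max(vapply(runDesigns, function(d) max(d@trials$label), numeric(1)))
  cols <- list()
  info <- list()
  leadCol <- numeric(totalT)
  respCol <- numeric(totalT)
  for (r in seq_along(runDesigns)) {
    d <- runDesigns[[r]]
    rows <- runStarts[r]:(runStarts[r] + nTimesPerRun[r] - 1L)
    tr_df <- d@trials
    stim <- tr_df[!tr_df$is_lead & tr_df$label != nullLabel, , drop = FALSE]
    for (lab in sort(unique(stim$label))) {
      ons <- stim$onset[stim$label == lab]
      reg <- hrfRegressor(ons, rep(hrf@duration, length(ons)),
                          rep(1, length(ons)), nTimesPerRun[r], tr, hrf)
      col <- numeric(totalT)
      col[rows] <- reg
      cols[[length(cols) + 1L]] <- col
      info[[length(info) + 1L]] <- data.frame(
        kind = "interest", run = d@runIndex, familiarity = d@familiarity,
        identity = (lab - 1) %/% nViews + 1, view = (lab - 1) %% nViews + 1,
        name = sprintf("run%02d_%s_label%02d", d@runIndex, d@familiarity, lab))
    }
    leads <- tr_df[tr_df$is_lead & tr_df$label != nullLabel, , drop = FALSE]
    if (nrow(leads)) {
      reg <- hrfRegressor(leads$onset, rep(hrf@duration, nrow(leads)),
                          rep(1, nrow(leads)), nTimesPerRun[r], tr, hrf)
      leadCol[rows] <- leadCol[rows] + reg
    }
    if (!is.null(responses)) {
      ev <- responses[responses$run == d@runIndex, , drop = FALSE]
      if (nrow(ev)) {
        reg <- hrfRegressor(ev$onset, rep(0.5, nrow(ev)), rep(1, nrow(ev)),
                            nTimesPerRun[r], tr, hrf)
        respCol[rows] <- respCol[rows] + reg
      }
    }
  }
  X <- do.call(cbind, cols)
  infoDf <- do.call(rbind, info)
  if (any(leadCol != 0)) {
    X <- cbind(X, leadCol)
    infoDf <- rbind(infoDf, data.frame(kind = "lead", run = NA, familiarity = NA,
                                       identity = NA, view = NA, name = "lead_trial"))
  }
  if (any(respCol != 0)) {
    X <- cbind(X, respCol)
    infoDf <- rbind(infoDf, data.frame(kind = "response", run = NA, familiarity = NA,
                                       identity = NA, view = NA, name = "button_same"))
  }
  for (r in seq_along(runDesigns)) {
    rows <- runStarts[r]:(runStarts[r] + nTimesPerRun[r] - 1L)
    t01 <- seq(0, 1, length.out = length(rows))
    for (p in 0:polyOrder) {
      col <- numeric(totalT)
      col[rows] <- t01^p
      X <- cbind(X, col)
      infoDf <- rbind(infoDf, data.frame(
        kind = "poly", run = runDesigns[[r]]@runIndex, familiarity = NA,
        identity = NA, view = NA,
        name = sprintf("run%02d_poly%d", runDesigns[[r]]@runIndex, p)))
    }
  }
  colnames(X) <- infoDf$name
  rownames(infoDf) <- NULL
  new("DesignMatrix", values = X, info = infoDf, tr = tr,
      runStarts = as.integer(runStarts))
}

#' Number of regressors of interest in a design
#' @param design a \linkS4class{DesignMatrix}.
#' @export
nInterestRegressors <- function(design) sum(design@info$kind == "interest")

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d time points x %d regressors (%d of interest), TR %.3g s, %d runs\n",
              nrow(object@values), ncol(object@values),
              nInterestRegressors(object), object@tr, length(object@runStarts)))
})

#' Ordinary least-squares GLM with t-statistics
#'
#' Fits a single model with all conditions; t = beta / SE with residual
#' degrees of freedom (time points - regressors).  Only the regressors of
#' interest are packaged into the returned \linkS4class{PatternSet}.
#'
#' @param ts numeric matrix (vertices x time).
#' @param design a \linkS4class{DesignMatrix} of full column rank.
#' @return a \linkS4class{PatternSet} with t-values and betas
#'   (samples x vertices).
#' @export
fitGLM <- function(ts, design) {
  X <- design@values
  if (ncol(ts) != nrow(X)) stop("time length mismatch between data and design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  Y <- t(ts)                        # time x vertices
  beta <- qr.coef(qx, Y)            # regressors x vertices
  res <- Y - X %*% beta
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tval <- beta / se
  keep <- design@info$kind == "interest"
  info <- design@info[keep, c("familiarity", "identity", "view", "run")]
  rownames(info) <- NULL
  new("PatternSet", values = tval[keep, , drop = FALSE],
      betas = beta[keep, , drop = FALSE],
      sampleInfo = info, statistic = "t")
}

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet: %d condition samples x %d vertices (%s-values)\n",
              nrow(object@values), ncol(object@values), object@statistic))
})
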