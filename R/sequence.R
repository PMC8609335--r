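#' Generate a Type-1 Index-1 (T1I1) trial sequence
#'
#' A T1I1 sequence over \code{nLabels} labels is \code{nLabels^2 + 1} trials
#' long, starts and ends with the same label, and presents every ordered pair
#' of labels (repeats included) exactly once as adjacent trials.  The default
#' \code{"balanced"} construction additionally guarantees the label-block
#' property used for run splitting: every consecutive disjoint window of
#' \code{nLabels} trials (over trials 1..nLabels^2) contains each label
#' exactly once, so a 63-trial run of a 21-label design shows each image
#' three times.  Block-balanced sequences do not exist for very small
#' alphabets (3, 4 and 5); there the \code{"eulerian"} construction (a random
#' Eulerian circuit on the complete arc set, T1I1 but not block-balanced) is
#' used instead.
#'
#' @param nLabels alphabet size, >= 2.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param method "auto" (balanced for nLabels >= 6 or nLabels == 2, eulerian
#'   otherwise), "balanced", or "eulerian".
#' @return a \linkS4class{TrialSequence}.
#' @export
generateT1I1 <- function(nLabels, seed = NULL,
                         method = c("auto", "balanced", "eulerian")) {
  method <- match.arg(method)
  nLabels <- as.integer(nLabels)
  if (is.na(nLabels) || nLabels < 2) stop("nLabels must be >= 2")
  if (method == "auto")
    method <- if (nLabels >= 6 || nLabels == 2) "balanced" else "eulerian"
  labels <- withSeed(seed, {
    if (method == "balanced") {
      s <- t1i1_block_search(nLabels)
      attempts <- 1L
      while (!length(s) && attempts < 50L) {  # extremely rare for nLabels >= 6
        s <- t1i1_block_search(nLabels)
        attempts <- attempts + 1L
      }
      if (!length(s)) stop("block-balanced search failed for nLabels = ", nLabels)
      s
    } else {
      .eulerianT1I1(nLabels)
    }
  })
  new("TrialSequence", labels = as.integer(labels), nLabels = nLabels)
}

# random Eulerian circuit on the complete digraph with self-loops
# (Hierholzer with randomized arc choice); returns the n^2 + 1 vertex walk
.eulerianT1I1 <- function(n) {
  remaining <- lapply(seq_len(n), function(v) sample(rep(seq_len(n), 1L)))
  if (n == 1L) return(c(1L, 1L))
  start <- sample.int(n, 1L)
  circuit <- integer(0)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]
    if (length(remaining[[v]])) {
      w <- remaining[[v]][1L]
      remaining[[v]] <- remaining[[v]][-1L]
      stack <- c(stack, w)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(circuit)
}

setMethod("show", "TrialSequence", function(object) {
  cat(sprintf("TrialSequence: %d labels, length %d (first/last label %d)\n",
              object@nLabels, length(object@labels), object@labels[1]))
})

#' Validate the T1I1 property of a sequence
#'
#' @param x a \linkS4class{TrialSequence} or an integer label vector with
#'   attribute-free labels in 1..nLabels.
#' @param nLabels alphabet size (taken from the object if omitted).
#' @return TRUE, or a logical FALSE whose \code{"report"} attribute lists the
#'   violations (wrong length, open ends, missing/duplicated ordered pairs).
#' @export
isT1I1 <- function(x, nLabels = NULL) {
  if (is(x, "TrialSequence")) {
    labels <- x@labels
    if (is.null(nLabels)) nLabels <- x@nLabels
  } else {
    labels <- as.integer(x)
    if (is.null(nLabels)) nLabels <- max(labels)
  }
  report <- character(0)
  if (length(labels) != nLabels^2 + 1)
    report <- c(report, sprintf("length %d, expected %d", length(labels), nLabels^2 + 1))
  if (length(labels) >= 2 && labels[1] != labels[length(labels)])
    report <- c(report, "first and last labels differ")
  if (length(labels) >= 2) {
    pair <- paste(labels[-length(labels)], labels[-1], sep = "->")
    cnt <- table(pair)
    all_pairs <- as.vector(outer(seq_len(nLabels), seq_len(nLabels),
                                 function(a, b) paste(a, b, sep = "->")))
    missing <- setdiff(all_pairs, names(cnt))
    dup <- names(cnt)[cnt > 1]
    if (length(missing))
      report <- c(report, paste("missing pairs:", paste(missing, collapse = " ")))
    if (length(dup))
      report <- c(report, paste("duplicated pairs:", paste(dup, collapse = " ")))
  }
  ok <- length(report) == 0
  if (!ok) attr(ok, "report") <- report
  ok
}

#' Reverse a trial sequence
#'
#' An inverted T1I1 sequence is itself a T1I1 sequence; sequence order was
#' counterbalanced across participants by inverting the sequences for every
#' other participant.
#'
#' @param x a \linkS4class{TrialSequence}.
#' @export
reverseSequence <- function(x) {
  new("TrialSequence", labels = rev(x@labels), nLabels = x@nLabels)
}

#' Relationship matrices for the face-identity stimulus set
#'
#' Labels enumerate (identity, view) pairs view-fastest, followed by one null
#' (fixation) label.  Three binary symmetric matrices are returned: same
#' identity, same head view, and mirror-symmetric head view (left/right
#' profile and left/right half-profile pairs).  Diagonals are 1 ("same"
#' relations); the null label relates only to itself.
#'
#' @param nIdentities number of identities (default 4).
#' @param nViews number of head views, ordered left profile, left half,
#'   frontal, right half, right profile (default 5).
#' @return named list of three nLabels x nLabels matrices
#'   (nLabels = nIdentities * nViews + 1).
#' @export
faceRelationshipMatrices <- function(nIdentities = 4, nViews = 5) {
  nStim <- nIdentities * nViews
  n <- nStim + 1L
  ident <- rep(seq_len(nIdentities), each = nViews)
  view <- rep(seq_len(nViews), nIdentities)
  same <- function(v) outer(v, v, "==") * 1
  idM <- viewM <- mirM <- diag(1, n, n)
  idM[seq_len(nStim), seq_len(nStim)] <- same(ident)
  viewM[seq_len(nStim), seq_len(nStim)] <- same(view)
  mirrorOf <- rev(seq_len(nViews))  # view k mirrors view nViews + 1 - k
  mm <- outer(view, view, function(a, b) (mirrorOf[a] == b & a != b) * 1)
  mirM[seq_len(nStim), seq_len(nStim)] <- mm
  diag(mirM) <- 1
  list(identity = idM, view = viewM, mirror = mirM)
}

#' Detection-power efficiency of a trial sequence
#'
#' For each relationship matrix a parametric regressor is built whose value
#' at trial t (t >= 2) is the relation between the labels at trials t - 1 and
#' t; the regressor is HRF-convolved at TR resolution and entered, with an
#' intercept, into a design matrix X.  Efficiency is the inverse of the
#' summed estimator variances of the relationship regressors,
#' 1 / trace((X'X)^-1 restricted to those regressors).  A rank-deficient
#' design (e.g. a constant relationship regressor collinear with the
#' intercept) yields efficiency 0 with a warning.
#'
#' @param seq a \linkS4class{TrialSequence}.
#' @param rels list of nLabels x nLabels relationship matrices.
#' @param hrf an \linkS4class{HRFSpec} (default \code{hrfSpec()}).
#' @param tr repetition time in seconds.
#' @param trialDuration trial length in seconds (default 5).
#' @return non-negative efficiency score.
#' @export
sequenceEfficiency <- function(seq, rels, hrf = hrfSpec(), tr = 1.25,
                               trialDuration = 5) {
  n <- seq@nLabels
  ok <- vapply(rels, function(m) all(dim(m) == c(n, n)), logical(1))
  if (!all(ok)) stop("relationship matrices must be nLabels x nLabels")
  lab <- seq@labels
  nt <- length(lab)
  onsets <- (seq_len(nt) - 1) * trialDuration
  # cover the full hemodynamic tail of the final trial
  nTime <- ceiling((nt * trialDuration + 32) / tr)
  amps <- lapply(rels, function(m) c(0, m[cbind(lab[-nt], lab[-1])]))
  if (any(vapply(amps, function(a) length(unique(a[-1])) == 1, logical(1)))) {
    warning("constant relationship regressor (collinear with the intercept); returning efficiency 0")
    return(0)
  }
  regs <- vapply(amps, function(a)
    hrfRegressor(onsets, rep(trialDuration, nt), a, nTime, tr, hrf),
    numeric(nTime))
  X <- cbind(1, regs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient efficiency design; returning 0")
    return(0)
  }
  xtxInv <- chol2inv(chol(crossprod(X)))
  1 / sum(diag(xtxInv)[-1])
}

#' Select the most efficient candidate sequences
#'
#' @param candidates list of \linkS4class{TrialSequence}.
#' @param rels,hrf,tr,trialDuration passed to \code{\link{sequenceEfficiency}}.
#' @param k number of sequences to keep.
#' @return the k candidates with the highest efficiency, in decreasing order
#'   of efficiency; ties keep the original candidate order (a duplicated best
#'   candidate is returned twice before any other).
#' @export
selectTopSequences <- function(candidates, rels, hrf = hrfSpec(), tr = 1.25,
                               k = 2, trialDuration = 5) {
  if (!length(candidates)) stop("no candidate sequences")
  if (k > length(candidates)) stop("k exceeds the number of candidates")
  eff <- vapply(candidates, sequenceEfficiency, numeric(1), rels = rels,
                hrf = hrf, tr = tr, trialDuration = trialDuration)
  ord <- order(-eff)  # stable: ties keep candidate order
  out <- candidates[ord[seq_len(k)]]
  attr(out, "efficiency") <- eff[ord[seq_len(k)]]
  out
}

#' Generate a T1I1 sequence chained to an existing one
#'
#' Draws sequences until one starts with \code{first}'s final label, so the
#' two can be concatenated into the longer design that run splitting
#' consumes.
#'
#' @param first a \linkS4class{TrialSequence}.
#' @param seed optional integer seed for the attempt stream.
#' @param maxTries attempts before giving up.
#' @return a \linkS4class{TrialSequence} starting with \code{first}'s final
#'   label.
#' @export
chainedT1I1 <- function(first, seed = NULL, maxTries = 200L) {
  target <- first@labels[length(first@labels)]
  for (k in seq_len(maxTries)) {
    s <- generateT1I1(first@nLabels,
                      seed = if (is.null(seed)) NULL else seed + k)
    if (s@labels[1] == target) return(s)
  }
  stop("could not generate a chained sequence")
}

#' Default trial micro-timing
#'
#' Each stimulus trial is 5 s: three 500-ms presentations separated by 50-ms
#' gaps followed by 3,400 ms of fixation; runs start and end with 15 s of
#' fixation.
#' @export
trialTiming <- function() {
  list(trialDuration = 5, leadIn = 15, leadOut = 15,
       presentation = 0.5, gap = 0.05, fixation = 3.4)
}

#' Partition two chained T1I1 sequences into run designs
#'
#' \code{seqB} must start with \code{seqA}'s final label; the two are
#' concatenated (dropping \code{seqB}'s duplicated first element) and the
#' first \code{nRuns * trialsPerRun} trials are split, in order, into runs.
#' An extra lead trial is prepended to each run: run 1 repeats its own first
#' label, later runs repeat the previous run's final label.  The lead trial
#' is not counted in \code{trialsPerRun}.
#'
#' @param seqA,seqB \linkS4class{TrialSequence} objects over the same labels.
#' @param nRuns number of runs (default 10).
#' @param trialsPerRun stimulus+null trials per run (default 63).
#' @param timing list from \code{\link{trialTiming}}.
#' @param nullLabel label index treated as the fixation (null) trial
#'   (default nLabels).
#' @param familiarity condition tag stored in each run (default "personal").
#' @return list of \linkS4class{RunDesign}.
#' @export
buildRunDesigns <- function(seqA, seqB, nRuns = 10, trialsPerRun = 63,
                            timing = trialTiming(), nullLabel = seqA@nLabels,
                            familiarity = "personal") {
  if (seqA@nLabels != seqB@nLabels) stop("sequences use different alphabets")
  if (seqB@labels[1] != seqA@labels[length(seqA@labels)])
    stop("seqB must start with seqA's final label")
  concat <- c(seqA@labels, seqB@labels[-1])
  need <- nRuns * trialsPerRun
  if (need > length(concat)) stop("not enough trials for the requested runs")
  trials <- concat[seq_len(need)]
  out <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    runLabels <- trials[((r - 1) * trialsPerRun + 1):(r * trialsPerRun)]
    lead <- if (r == 1) runLabels[1] else out[[r - 1]]@trials$label[trialsPerRun + 1]
    lab <- c(lead, runLabels)
    onset <- timing$leadIn + (seq_along(lab) - 1) * timing$trialDuration
    tr_df <- data.frame(label = lab, onset = onset,
                        duration = timing$trialDuration,
                        is_null = lab == nullLabel,
                        is_lead = c(TRUE, rep(FALSE, trialsPerRun)))
    out[[r]] <- new("RunDesign", runIndex = as.integer(r), trials = tr_df,
                    familiarity = familiarity, leadIn = timing$leadIn,
                    leadOut = timing$leadOut)
  }
  out
}

#' Total duration of a run in seconds
#' @param design a \linkS4class{RunDesign}.
#' @export
runDuration <- function(design) {
  tr <- design@trials
  max(tr$onset + tr$duration) + design@leadOut
}

setMethod("show", "RunDesign", function(object) {
  tr <- object@trials
  cat(sprintf("RunDesign %d (%s): %d trials (+%d lead), %d null; %.0f s\n",
              object@runIndex, object@familiarity, sum(!tr$is_lead),
              sum(tr$is_lead), sum(tr$is_null & !tr$is_lead),
              runDuration(object)))
})

#' Write run designs as BIDS-style events tables
#'
#' One \code{events.tsv} per run with columns onset, duration, trial_type,
#' is_null, is_lead, plus a JSON sidecar recording timing and familiarity.
#'
#' @param designs list of \linkS4class{RunDesign}.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
writeEventsTSV <- function(designs, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in designs) {
    tr <- d@trials
    ev <- data.frame(onset = tr$onset, duration = tr$duration,
                     trial_type = paste0("label", tr$label),
                     is_null = as.integer(tr$is_null),
                     is_lead = as.integer(tr$is_lead))
    f <- file.path(dir, sprintf("%s-%02d_events.tsv", prefix, d@runIndex))
    utils::write.table(ev, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  side <- list(familiarity = designs[[1]]@familiarity,
               lead_in_s = designs[[1]]@leadIn, lead_out_s = designs[[1]]@leadOut,
               n_runs = length(designs))
  jsonlite::write_json(side, file.path(dir, paste0(prefix, "_events.json")),
                       auto_unbox = TRUE)
  invisible(dir)
}
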