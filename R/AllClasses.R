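#' @import methods
NULL

#' Triangulated cortical surface stand-in
#'
#' Holds vertex coordinates, triangles, a medial-wall mask, per-vertex
#' hemisphere labels, and the precomputed graph-geodesic distance matrix
#' (shortest paths along mesh edges with Euclidean edge weights).  Vertices in
#' different hemispheres are at infinite distance from each other.
#'
#' @slot coords numeric matrix (vertices x 3), positions in mm.
#' @slot triangles integer matrix (faces x 3) of 1-based vertex indices.
#' @slot medialWall logical vector, TRUE for masked (medial-wall) vertices.
#' @slot hemisphere character vector of per-vertex hemisphere tags ("L"/"R").
#' @slot geo numeric matrix of pairwise geodesic distances (mm).
#' @export
setClass("SurfaceMesh",
  representation(coords = "matrix", triangles = "matrix",
                 medialWall = "logical", hemisphere = "character",
                 geo = "matrix"))

setValidity("SurfaceMesh", function(object) {
  n <- nrow(object@coords)
  msg <- character(0)
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (ncol(object@triangles) != 3) msg <- c(msg, "triangles must have 3 columns")
  tri <- object@triangles
  if (length(tri) && (min(tri) < 1 || max(tri) > n))
    msg <- c(msg, "triangle vertex indices out of range")
  if (length(object@medialWall) != n) msg <- c(msg, "medialWall length mismatch")
  if (length(object@hemisphere) != n) msg <- c(msg, "hemisphere length mismatch")
  if (!all(dim(object@geo) == c(n, n))) msg <- c(msg, "geo distance matrix dim mismatch")
  if (length(msg)) msg else TRUE
})

#' Set of surface searchlights
#'
#' One geodesic disk per (non-masked) center vertex.
#'
#' @slot centers integer vector of center vertex indices.
#' @slot members list of integer vectors, disk membership per center.
#' @slot radius numeric, disk radius in mm.
#' @export
setClass("SearchlightSet",
  representation(centers = "integer", members = "list", radius = "numeric"))

setValidity("SearchlightSet", function(object) {
  if (length(object@centers) != length(object@members))
    return("centers and members length mismatch")
  ok <- mapply(function(ctr, mem) ctr %in% mem, object@centers, object@members)
  if (!all(ok)) return("every center must belong to its own searchlight")
  TRUE
})

#' Disjoint regions of interest on a surface mesh
#'
#' @slot roiNames character vector of ROI labels.
#' @slot centers integer vector of refined center vertices (one per ROI).
#' @slot assignment integer vector over vertices: ROI index or NA.
#' @export
setClass("ROIMap",
  representation(roiNames = "character", centers = "integer",
                 assignment = "integer"))

setValidity("ROIMap", function(object) {
  if (length(object@roiNames) != length(object@centers))
    return("one center per ROI required")
  if (anyDuplicated(object@centers)) return("duplicate ROI centers")
  idx <- object@assignment[!is.na(object@assignment)]
  if (length(idx) && (min(idx) < 1 || max(idx) > length(object@roiNames)))
    return("assignment indexes nonexistent ROI")
  TRUE
})

#' Type-1 Index-1 trial sequence
#'
#' Serially balanced label sequence of length nLabels^2 + 1 in which every
#' ordered pair of labels (self-pairs included) occurs exactly once as
#' adjacent elements, and the last label repeats the first.
#'
#' @slot labels integer vector of 1-based labels.
#' @slot nLabels integer, alphabet size.
#' @export
setClass("TrialSequence",
  representation(labels = "integer", nLabels = "integer"))

#' Timed trial listing for one functional run
#'
#' Trials carry a label, onset, and duration; fixation (null) trials and the
#' prepended lead trial are flagged.  The lead trial repeats either the run's
#' own first label (run 1) or the previous run's final label.
#'
#' @slot runIndex integer run number.
#' @slot trials data.frame with columns label, onset, duration, is_null,
#'   is_lead.
#' @slot familiarity character, the familiarity condition shown in this run.
#' @slot leadIn,leadOut numeric fixation padding (s) at run start/end.
#' @export
setClass("RunDesign",
  representation(runIndex = "integer", trials = "data.frame",
                 familiarity = "character", leadIn = "numeric",
                 leadOut = "numeric"))

setValidity("RunDesign", function(object) {
  tr <- object@trials
  need <- c("label", "onset", "duration", "is_null", "is_lead")
  if (!all(need %in% names(tr))) return("trials missing required columns")
  if (is.unsorted(tr$onset, strictly = TRUE)) return("onsets must be strictly increasing")
  TRUE
})

#' Canonical double-gamma hemodynamic response specification
#'
#' @slot peakShape,peakScale gamma parameters of the positive lobe.
#' @slot undershootShape,undershootScale gamma parameters of the undershoot.
#' @slot undershootRatio relative undershoot amplitude.
#' @slot duration numeric, stimulus (boxcar) duration in seconds.
#' @slot amplitude numeric scale factor of the kernel.
#' @export
setClass("HRFSpec",
  representation(peakShape = "numeric", peakScale = "numeric",
                 undershootShape = "numeric", undershootScale = "numeric",
                 undershootRatio = "numeric", duration = "numeric",
                 amplitude = "numeric"))

setValidity("HRFSpec", function(object) {
  if (object@duration <= 0) return("duration must be > 0")
  if (object@peakShape <= 0 || object@peakScale <= 0) return("invalid peak parameters")
  TRUE
})

#' GLM design matrix with labeled regressors
#'
#' @slot values numeric matrix (time x regressors), runs concatenated.
#' @slot info data.frame with one row per column of \code{values}: kind
#'   ("interest", "response", "lead", "poly"), run, familiarity, identity,
#'   view, name.
#' @slot tr numeric repetition time (s).
#' @slot runStarts integer vector: first row of each run in \code{values}.
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", info = "data.frame", tr = "numeric",
                 runStarts = "integer"))

setValidity("DesignMatrix", function(object) {
  if (nrow(object@info) != ncol(object@values))
    return("one info row per design column required")
  int <- object@info$kind == "interest"
  if (any(int)) {
    z <- apply(object@values[, int, drop = FALSE], 2, function(x) all(x == 0))
    if (any(z)) return("all-zero regressor of interest")
  }
  TRUE
})

#' Per-condition response patterns for one subject
#'
#' Rows are condition samples (identity x view, optionally x run), columns
#' are surface vertices; values are GLM t-statistics (or betas).
#'
#' @slot values numeric matrix (samples x vertices) of t-values.
#' @slot betas numeric matrix (samples x vertices) of OLS estimates.
#' @slot sampleInfo data.frame: familiarity, identity, view, run.
#' @slot statistic character, "t".
#' @export
setClass("PatternSet",
  representation(values = "matrix", betas = "matrix",
                 sampleInfo = "data.frame", statistic = "character"))

setValidity("PatternSet", function(object) {
  if (nrow(object@sampleInfo) != nrow(object@values))
    return("one sampleInfo row per sample required")
  need <- c("familiarity", "identity", "view", "run")
  if (!all(need %in% names(object@sampleInfo)))
    return("sampleInfo missing required columns")
  key <- object@sampleInfo[c("familiarity", "identity", "view", "run")]
  if (anyDuplicated(key)) return("duplicate condition samples within a run")
  TRUE
})

#' Run-averaged multi-subject sample set for decoding
#'
#' Rows are run-averaged condition samples from all subjects (for each subject
#' and familiarity: identities x views samples); columns are vertices in one
#' common (reference) space.
#'
#' @slot values numeric matrix (samples x vertices).
#' @slot sampleInfo data.frame: subject, familiarity, identity, view.
#' @export
setClass("SampleSet",
  representation(values = "matrix", sampleInfo = "data.frame"))

setValidity("SampleSet", function(object) {
  si <- object@sampleInfo
  if (nrow(si) != nrow(object@values)) return("one sampleInfo row per sample")
  need <- c("subject", "familiarity", "identity", "view")
  if (!all(need %in% names(si))) return("sampleInfo missing required columns")
  cnt <- table(si$subject, si$familiarity)
  if (length(cnt) && length(unique(as.vector(cnt))) > 1)
    return("unequal sample counts across subject x familiarity cells")
  TRUE
})

#' Whole-cortex functional alignment map for one subject
#'
#' Sparse vertex-space to vertex-space linear transform aggregated from
#' searchlight Procrustes solutions; entries outside the union of searchlight
#' supports are zero.
#'
#' @slot subject integer subject index.
#' @slot transform sparse Matrix (vertices x vertices); a time x vertex data
#'   matrix X maps into the common space as X %*% transform.
#' @slot radius numeric searchlight radius (mm) used during estimation.
#' @export
setClass("AlignmentMap",
  representation(subject = "integer", transform = "ANY", radius = "numeric"))

#' Common model space fitted by searchlight hyperalignment
#'
#' @slot reference integer, index of the reference subject.
#' @slot maps list of \linkS4class{AlignmentMap}, one per subject.
#' @slot meta list of training metadata (iterations, radius, aggregation).
#' @export
setClass("CommonSpaceModel",
  representation(reference = "integer", maps = "list", meta = "list"))

setValidity("CommonSpaceModel", function(object) {
  if (!length(object@maps)) return("no alignment maps")
  d <- vapply(object@maps, function(m) nrow(m@transform), integer(1))
  if (length(unique(d)) != 1) return("alignment maps differ in dimension")
  TRUE
})

#' Per-location, per-fold decoding accuracies
#'
#' @slot locations character vector of location names (searchlight center
#'   vertices or ROI names).
#' @slot accuracy numeric matrix (locations x folds), fractions correct.
#' @slot folds data.frame with columns testSubject, testView.
#' @slot condition character familiarity condition decoded.
#' @export
setClass("AccuracyResult",
  representation(locations = "character", accuracy = "matrix",
                 folds = "data.frame", condition = "character"))

setValidity("AccuracyResult", function(object) {
  a <- object@accuracy
  if (nrow(a) != length(object@locations)) return("one accuracy row per location")
  if (ncol(a) != nrow(object@folds)) return("one accuracy column per fold")
  if (any(a < 0 | a > 1)) return("accuracies outside [0, 1]")
  TRUE
})

#' Bootstrap null distribution of mean accuracies
#'
#' Each draw is the mean of n folds resampled with replacement from the pooled
#' permuted fold-level accuracies.
#'
#' @slot draws numeric matrix (locations x bootstrap draws).
#' @slot locations character location names.
#' @slot chance numeric chance level (0.25 for 4-way identity decoding).
#' @export
setClass("NullDistribution",
  representation(draws = "matrix", locations = "character", chance = "numeric"))
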