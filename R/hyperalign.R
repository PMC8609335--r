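#' Orthogonal Procrustes solution
#'
#' The orthogonal transform R minimizing ||source %*% R - target||_F over
#' orthogonal matrices (SVD of the cross-product; no scaling, no translation
#' beyond any column standardization done upstream).  Degenerate all-zero
#' input yields the identity with a warning.
#'
#' @param source,target numeric matrices (samples x features) with matching
#'   dimensions.
#' @return features x features orthogonal matrix.
#' @export
procrustes <- function(source, target) {
  if (!all(dim(source) == dim(target))) stop("dimension mismatch")
  if (ncol(source) < 1) stop("at least one feature required")
  M <- crossprod(source, target)
  if (all(M == 0)) {
    warning("degenerate all-zero cross-product; returning identity")
    return(diag(ncol(source)))
  }
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

#' Whole-cortex searchlight hyperalignment
#'
#' Estimates, per searchlight, orthogonal Procrustes transforms aligning
#' every subject's movie time series to an evolving template (initialized
#' from the reference subject, then refined against the group mean over
#' \code{nIterations} passes), and aggregates the searchlight solutions into
#' one sparse whole-cortex \linkS4class{AlignmentMap} per subject.  With the
#' default \code{"mean"} aggregation each row of the summed transform is
#' divided by the number of searchlights containing that vertex, so that
#' identical inputs map onto themselves; \code{"sum"} leaves the overlapping
#' solutions unnormalized.
#'
#' Time series are z-scored per vertex before alignment.  Masked
#' (medial-wall) vertices belong to no searchlight, so transforms never mix
#' information across the mask.
#'
#' @param movieData list of vertices x time matrices, one per subject, all on
#'   the same mesh.
#' @param searchlights a \linkS4class{SearchlightSet} (radius 20 mm in the
#'   reference analysis).
#' @param nIterations template refinement passes (default 3).
#' @param reference index of the reference subject (default 1).
#' @param aggregate "mean" (default) or "sum".
#' @return a \linkS4class{CommonSpaceModel}.
#' @export
searchlightHyperalign <- function(movieData, searchlights, nIterations = 3,
                                  reference = 1,
                                  aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  nS <- length(movieData)
  if (nS < 2) stop("at least two subjects required")
  dims <- vapply(movieData, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("subjects differ in vertex count or time length")
  n <- dims[1, 1]
  Z <- lapply(movieData, function(x) t(zscoreRows(x)))  # time x vertices
  nSL <- length(searchlights@centers)
  trip_i <- vector("list", nS); trip_j <- vector("list", nS)
  trip_x <- vector("list", nS)
  rowCount <- matrix(0, n, nS)
  for (sl in seq_len(nSL)) {
    mem <- searchlights@members[[sl]]
    d <- length(mem)
    X <- lapply(Z, function(z) z[, mem, drop = FALSE])
    R <- rep(list(diag(d)), nS)
    # pass 1: incremental alignment to a running template seeded by the reference
    template <- X[[reference]]
    count <- 1
    for (s in setdiff(seq_len(nS), reference)) {
      R[[s]] <- procrustesQuiet(X[[s]], template)
      template <- (template * count + X[[s]] %*% R[[s]]) / (count + 1)
      count <- count + 1
    }
    # later passes: realign everyone to the current group mean
    for (it in seq_len(max(0, nIterations - 1))) {
      template <- Reduce(`+`, Map(function(x, r) x %*% r, X, R)) / nS
      for (s in seq_len(nS)) R[[s]] <- procrustesQuiet(X[[s]], template)
    }
    idx <- rep(mem, times = d)   # column-major order of as.numeric(R)
    jdx <- rep(mem, each = d)
    for (s in seq_len(nS)) {
      trip_i[[s]][[sl]] <- idx
      trip_j[[s]][[sl]] <- jdx
      trip_x[[s]][[sl]] <- as.numeric(R[[s]])
      rowCount[mem, s] <- rowCount[mem, s] + 1
    }
  }
  maps <- vector("list", nS)
  for (s in seq_len(nS)) {
    Tm <- Matrix::sparseMatrix(i = unlist(trip_i[[s]]), j = unlist(trip_j[[s]]),
                               x = unlist(trip_x[[s]]), dims = c(n, n))
    if (aggregate == "mean") {
      sc <- ifelse(rowCount[, s] > 0, 1 / rowCount[, s], 0)
      Tm <- Matrix::Diagonal(x = sc) %*% Tm
    }
    maps[[s]] <- new("AlignmentMap", subject = as.integer(s),
                     transform = methods::as(Tm, "CsparseMatrix"),
                     radius = searchlights@radius)
  }
  new("CommonSpaceModel", reference = as.integer(reference), maps = maps,
      meta = list(iterations = nIterations, radius = searchlights@radius,
                  aggregate = aggregate, nSubjects = nS))
}

# procrustes() without the all-zero warning noise inside searchlight loops
procrustesQuiet <- function(source, target) {
  M <- crossprod(source, target)
  if (all(M == 0)) return(diag(ncol(source)))
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

#' Apply an alignment map to data
#'
#' @param map an \linkS4class{AlignmentMap}.
#' @param data vertices x samples (or vertices x time) matrix.
#' @return matrix of the same shape in the map's output space.
#' @export
applyAlignment <- function(map, data) {
  if (nrow(data) != nrow(map@transform)) stop("vertex dimension mismatch")
  as.matrix(Matrix::t(map@transform) %*% data)
}

#' Project data into the reference subject's space
#'
#' Composes the subject's projection into the common space with the
#' transpose of the reference subject's projection, applied as a single
#' linear operation.
#'
#' @param data vertices x samples matrix in the subject's anatomical space.
#' @param mapSubject the subject's \linkS4class{AlignmentMap}.
#' @param mapReference the reference subject's \linkS4class{AlignmentMap}.
#' @return vertices x samples matrix in the reference subject's space.
#' @export
projectToReference <- function(data, mapSubject, mapReference) {
  if (nrow(mapSubject@transform) != nrow(mapReference@transform))
    stop("alignment maps built on different meshes")
  if (nrow(data) != nrow(mapSubject@transform)) stop("vertex dimension mismatch")
  combined <- mapSubject@transform %*% Matrix::t(mapReference@transform)
  as.matrix(Matrix::t(combined) %*% data)
}

setMethod("show", "AlignmentMap", function(object) {
  nz <- Matrix::nnzero(object@transform)
  cat(sprintf("AlignmentMap: subject %d, %d x %d transform (%d nonzero), searchlight radius %.0f mm\n",
              object@subject, nrow(object@transform), ncol(object@transform),
              nz, object@radius))
})

setMethod("show", "CommonSpaceModel", function(object) {
  cat(sprintf("CommonSpaceModel: %d subjects, reference %d, %d iterations, %s aggregation\n",
              length(object@maps), object@reference,
              object@meta$iterations, object@meta$aggregate))
})

#' Serialize an alignment map as sparse triplets
#'
#' Writes a tab-separated triplet table (row, col, value; 0-based indices)
#' and a JSON header with the subject, radius and matrix dimension.
#'
#' @param map an \linkS4class{AlignmentMap}.
#' @param prefix output path prefix.
#' @export
writeAlignmentMap <- function(map, prefix) {
  tm <- methods::as(methods::as(map@transform, "generalMatrix"), "TsparseMatrix")
  df <- data.frame(row = tm@i, col = tm@j, value = tm@x)
  utils::write.table(df, paste0(prefix, "_triplets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(subject = map@subject, radius = map@radius,
                            dim = nrow(map@transform)),
                       paste0(prefix, "_header.json"), auto_unbox = TRUE)
  invisible(prefix)
}
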