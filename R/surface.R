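#' Construct a SurfaceMesh and precompute geodesic distances
#'
#' Geodesic distance is the shortest path along mesh edges with Euclidean
#' edge weights (not exact polyhedral geodesics); vertices with no connecting
#' path (e.g. different hemispheres) are at distance \code{Inf}.
#'
#' @param coords numeric matrix (vertices x 3), mm.
#' @param triangles integer matrix (faces x 3), 1-based vertex indices.
#' @param medialWall logical vector of masked vertices (default none).
#' @param hemisphere character vector of hemisphere tags (default all "L").
#' @return a \linkS4class{SurfaceMesh}.
#' @export
surfaceMesh <- function(coords, triangles,
                        medialWall = rep(FALSE, nrow(coords)),
                        hemisphere = rep("L", nrow(coords))) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  n <- nrow(coords)
  edges <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  w <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                     coords[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  geo <- igraph::distances(g, weights = w)
  dimnames(geo) <- NULL
  new("SurfaceMesh", coords = coords, triangles = triangles,
      medialWall = medialWall, hemisphere = hemisphere, geo = geo)
}

#' Number of vertices of a mesh
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
nVertices <- function(mesh) nrow(mesh@coords)

#' Pairwise geodesic distance matrix of a mesh
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
geodesicDistances <- function(mesh) mesh@geo

#' Medial-wall mask accessor
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @export
medialWall <- function(mesh) mesh@medialWall

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices (%d masked), %d triangles, hemispheres: %s\n",
              nVertices(object), sum(object@medialWall), nrow(object@triangles),
              paste(unique(object@hemisphere), collapse = "/")))
})

# unit icosahedron vertices/faces
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

# subdivide each triangle into 4, reprojecting onto the unit sphere
.subdivide <- function(v, f) {
  key <- function(a, b) paste(min(a, b), max(a, b))
  mid <- new.env(parent = emptyenv())
  getMid <- function(a, b) {
    k <- key(a, b)
    if (!is.null(mid[[k]])) return(mid[[k]])
    m <- (v[a, ] + v[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    v <<- rbind(v, m)
    mid[[k]] <- nrow(v)
    nrow(v)
  }
  nf <- matrix(0L, 0, 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
    ab <- getMid(a, b); bc <- getMid(b, c_); ca <- getMid(c_, a)
    nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
  }
  list(v = v, f = nf)
}

# icosphere with `subdiv` subdivision levels (0 -> 12, 1 -> 42, 2 -> 162, ...)
.icosphere <- function(subdiv) {
  s <- .icosahedron()
  for (i in seq_len(subdiv)) s <- .subdivide(s$v, s$f)
  s
}

#' Synthetic two-hemisphere cortical mesh
#'
#' Builds two subdivided icosahedra (one per hemisphere) scaled so that the
#' typical inter-vertex spacing matches \code{spacing} mm, making millimetre
#' radii for searchlights and ROIs meaningful at desk scale.  Vertices facing
#' the opposite hemisphere within \code{medialAngle} radians of the medial
#' pole are flagged as medial wall.
#'
#' @param subdiv icosphere subdivision level (1 -> 42 vertices per
#'   hemisphere, 2 -> 162, 3 -> 642).
#' @param spacing target mean edge length in mm (default 3).
#' @param medialAngle angular radius (radians) of the medial-wall cap
#'   (default 0.45, masking a small patch per hemisphere).
#' @return a \linkS4class{SurfaceMesh} with hemispheres "L" and "R".
#' @export
corticalMesh <- function(subdiv = 1, spacing = 3, medialAngle = 0.45) {
  s <- .icosphere(subdiv)
  ed <- unique(t(apply(rbind(s$f[, 1:2], s$f[, 2:3], s$f[, c(1, 3)]), 1, sort)))
  meanEdge <- mean(sqrt(rowSums((s$v[ed[, 1], ] - s$v[ed[, 2], ])^2)))
  R <- spacing / meanEdge
  v <- s$v * R
  nh <- nrow(v)
  offset <- 3 * R
  coordsL <- sweep(v, 2, c(-offset, 0, 0), "+")
  coordsR <- sweep(v, 2, c(offset, 0, 0), "+")
  coords <- rbind(coordsL, coordsR)
  triangles <- rbind(s$f, s$f + nh)
  # medial wall: cap facing the other hemisphere (pole +x for L, -x for R)
  angL <- acos(pmin(1, pmax(-1, s$v[, 1])))        # angle from +x pole
  angR <- acos(pmin(1, pmax(-1, -s$v[, 1])))       # angle from -x pole
  medialWall <- c(angL < medialAngle, angR < medialAngle)
  hemisphere <- rep(c("L", "R"), each = nh)
  surfaceMesh(coords, triangles, medialWall, hemisphere)
}

#' Geodesic disk of vertices around a center
#'
#' All non-masked vertices whose graph-geodesic distance from \code{center}
#' is at most \code{radius} mm (the center included).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param center vertex index (must be non-masked and in range).
#' @param radius disk radius in mm, >= 0.
#' @return sorted integer vector of vertex indices.
#' @export
geodesicDisk <- function(mesh, center, radius) {
  n <- nVertices(mesh)
  if (length(center) != 1 || is.na(center) || center < 1 || center > n)
    stop("invalid center: out of range")
  if (mesh@medialWall[center]) stop("invalid center: vertex is in the medial wall")
  if (radius < 0) stop("radius must be >= 0")
  d <- mesh@geo[center, ]
  sort(which(d <= radius & !mesh@medialWall))
}

#' Searchlights centered on every non-masked vertex
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param radius disk radius in mm, > 0.
#' @return a \linkS4class{SearchlightSet}.
#' @export
makeSearchlights <- function(mesh, radius) {
  if (radius <= 0) stop("radius must be > 0")
  centers <- which(!mesh@medialWall)
  members <- lapply(centers, function(ctr) geodesicDisk(mesh, ctr, radius))
  new("SearchlightSet", centers = as.integer(centers), members = members,
      radius = radius)
}

setMethod("show", "SearchlightSet", function(object) {
  sizes <- lengths(object@members)
  cat(sprintf("SearchlightSet: %d searchlights, radius %.1f mm, %d-%d members (median %d)\n",
              length(object@centers), object@radius, min(sizes), max(sizes),
              as.integer(stats::median(sizes))))
})

#' Contrast-based ROI construction
#'
#' Each seed peak is refined to the vertex with the maximum statistic within
#' \code{refineRadius} mm; the ROI is the \code{roiRadius}-mm geodesic disk
#' around the refined center; vertices claimed by several ROIs go to the one
#' with the smaller geodesic distance to its center (ties: the ROI earlier in
#' the seed list, with a warning).  Peak eligibility is thresholded at
#' \code{thresholds[1]}; if no vertex in the refinement disk passes, the
#' second, more lenient cutoff is tried; if none passes either, an error is
#' raised.
#'
#' @param tmap numeric per-vertex statistic (e.g. a contrast t-map).
#' @param seeds named integer vector of seed peak vertices.
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param refineRadius mm radius of the center-refinement disk (default 3).
#' @param roiRadius mm radius of each ROI disk (default 15).
#' @param thresholds two statistic cutoffs for peak eligibility
#'   (default c(1.96, 1.65)).
#' @return a \linkS4class{ROIMap}.
#' @export
defineROIs <- function(tmap, seeds, mesh, refineRadius = 3, roiRadius = 15,
                       thresholds = c(1.96, 1.65)) {
  if (anyDuplicated(seeds)) stop("seed peaks must be distinct")
  if (any(mesh@medialWall[seeds])) stop("seed peaks must be non-masked")
  if (is.null(names(seeds))) names(seeds) <- paste0("roi", seq_along(seeds))
  centers <- integer(length(seeds))
  for (i in seq_along(seeds)) {
    disk <- geodesicDisk(mesh, seeds[i], refineRadius)
    elig <- disk[tmap[disk] >= thresholds[1]]
    if (!length(elig)) elig <- disk[tmap[disk] >= thresholds[2]]
    if (!length(elig))
      stop(sprintf("no vertex near seed '%s' passes either threshold", names(seeds)[i]))
    centers[i] <- elig[which.max(tmap[elig])]
  }
  if (anyDuplicated(centers)) stop("duplicate refined ROI centers")
  n <- nVertices(mesh)
  assignment <- rep(NA_integer_, n)
  bestDist <- rep(Inf, n)
  tied <- FALSE
  for (i in seq_along(centers)) {
    disk <- geodesicDisk(mesh, centers[i], roiRadius)
    d <- mesh@geo[centers[i], disk]
    closer <- d < bestDist[disk]
    ties <- d == bestDist[disk] & !is.na(assignment[disk])
    if (any(ties)) tied <- TRUE
    upd <- disk[closer]
    assignment[upd] <- i
    bestDist[upd] <- d[closer]
  }
  if (tied)
    warning("geodesic distance ties resolved in favor of the earlier seed")
  new("ROIMap", roiNames = names(seeds), centers = centers,
      assignment = assignment)
}

#' Vertices assigned to one ROI
#' @param rois a \linkS4class{ROIMap}.
#' @param name ROI name or index.
#' @export
roiVertices <- function(rois, name) {
  i <- if (is.character(name)) match(name, rois@roiNames) else as.integer(name)
  if (is.na(i)) stop("unknown ROI: ", name)
  which(!is.na(rois@assignment) & rois@assignment == i)
}

setMethod("show", "ROIMap", function(object) {
  cat(sprintf("ROIMap: %d disjoint ROIs (%s); %d vertices assigned\n",
              length(object@roiNames), paste(object@roiNames, collapse = ", "),
              sum(!is.na(object@assignment))))
})

#' Write a mesh as plain-text vertex and triangle tables
#'
#' Two tab-separated files are produced: \code{<prefix>_vertices.tsv}
#' (columns x, y, z, medial_wall, hemisphere) and
#' \code{<prefix>_triangles.tsv} (columns v1, v2, v3, 0-based indices).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param prefix output path prefix.
#' @export
writeSurfaceMesh <- function(mesh, prefix) {
  vt <- data.frame(x = mesh@coords[, 1], y = mesh@coords[, 2],
                   z = mesh@coords[, 3],
                   medial_wall = as.integer(mesh@medialWall),
                   hemisphere = mesh@hemisphere)
  utils::write.table(vt, paste0(prefix, "_vertices.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tt <- as.data.frame(mesh@triangles - 1L)
  names(tt) <- c("v1", "v2", "v3")
  utils::write.table(tt, paste0(prefix, "_triangles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a mesh written by \code{writeSurfaceMesh}
#' @param prefix path prefix used when writing.
#' @return a \linkS4class{SurfaceMesh}.
#' @export
readSurfaceMesh <- function(prefix) {
  vt <- utils::read.table(paste0(prefix, "_vertices.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  tt <- utils::read.table(paste0(prefix, "_triangles.tsv"), header = TRUE,
                          sep = "\t")
  surfaceMesh(as.matrix(vt[, c("x", "y", "z")]), as.matrix(tt) + 1L,
              medialWall = vt$medial_wall == 1, hemisphere = vt$hemisphere)
}
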