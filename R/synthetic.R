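#' Configuration of a synthetic multi-subject world
#'
#' Describes the study layout (subjects, identities, head views, familiarity
#' conditions, runs), the cortical stand-in mesh, the region partition, and
#' the signal-to-noise amplitudes.  Noise has unit standard deviation per
#' vertex and time point, so an SNR of s means signal components are drawn
#' with standard deviation s per latent dimension.
#'
#' @slot nSubjects,nIdentities,nViews,nFamiliarities,nRuns integers.
#' @slot movieLength number of movie time points.
#' @slot snrCore,snrExtended signal amplitudes of core-like and extended-like
#'   regions.
#' @slot arCoef lag-1 autocorrelation of the noise (default 0, white).
#' @slot blockSize maximal size of a locally orthogonal mixing block.
#' @slot mesh the \linkS4class{SurfaceMesh} the world lives on.
#' @slot regions list with elements \code{core} and \code{extended} (lists of
#'   vertex-index vectors, one per region) and \code{null} (vertex vector).
#' @slot seed integer seed making the world fully reproducible.
#' @export
setClass("WorldConfig",
  representation(nSubjects = "integer", nIdentities = "integer",
                 nViews = "integer", nFamiliarities = "integer",
                 nRuns = "integer", movieLength = "integer",
                 snrCore = "numeric", snrExtended = "numeric",
                 arCoef = "numeric", blockSize = "integer",
                 mesh = "SurfaceMesh", regions = "list", seed = "integer"))

setValidity("WorldConfig", function(object) {
  msg <- character(0)
  if (object@nSubjects < 2) msg <- c(msg, "nSubjects must be >= 2")
  if (object@snrCore < 0 || object@snrExtended < 0) msg <- c(msg, "SNRs must be >= 0")
  rg <- object@regions
  if (!all(c("core", "extended", "null") %in% names(rg)))
    msg <- c(msg, "regions must have core, extended and null entries")
  else {
    all_v <- c(unlist(rg$core), unlist(rg$extended), rg$null)
    if (anyDuplicated(all_v)) msg <- c(msg, "region sets must be disjoint")
    if (!length(all_v)) msg <- c(msg, "empty region partition")
    if (any(object@mesh@medialWall[all_v]))
      msg <- c(msg, "regions must not include medial-wall vertices")
  }
  if (length(msg)) msg else TRUE
})

#' Default region partition of a mesh
#'
#' Places the core-like region on the left hemisphere (disk around its
#' lateral pole) and the extended-like region on the right hemisphere (disk
#' around its lateral pole); everything else that is non-masked is the null
#' region.  Hemispheres host the two systems separately because searchlight
#' alignment transforms mix information within a searchlight's reach: on a
#' desk-scale mesh only the disconnected opposite hemisphere is guaranteed
#' free of smearing from a signal region.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param radius region disk radius in mm.
#' @return list with elements core, extended (lists of vertex vectors,
#'   named by hemisphere) and null (vertex vector).
#' @export
makeRegionPartition <- function(mesh, radius = 5) {
  hemis <- sort(unique(mesh@hemisphere))
  lateralPole <- function(h) {
    idx <- which(mesh@hemisphere == h & !mesh@medialWall)
    idx[which.max(abs(mesh@coords[idx, 1]))]
  }
  coreCenter <- lateralPole(hemis[1])
  coreSet <- geodesicDisk(mesh, coreCenter, radius)
  extended <- list()
  if (length(hemis) > 1) {
    extCenter <- lateralPole(hemis[2])
    extended[[hemis[2]]] <- geodesicDisk(mesh, extCenter, radius)
  } else {
    # single-hemisphere mesh: extended at the antipode of the core
    idx <- which(!mesh@medialWall)
    far <- idx[which.max(mesh@geo[coreCenter, idx])]
    extended[[hemis[1]]] <- setdiff(geodesicDisk(mesh, far, radius), coreSet)
  }
  core <- stats::setNames(list(coreSet), hemis[1])
  taken <- c(unlist(core), unlist(extended))
  nullSet <- setdiff(which(!mesh@medialWall), taken)
  list(core = core, extended = extended, null = nullSet)
}

#' Create a world configuration
#'
#' Defaults mirror the study layout: 14 subjects, 4 identities x 5 head
#' views x 2 familiarity conditions, 10 runs per familiarity.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param nSubjects,nIdentities,nViews,nFamiliarities,nRuns study layout.
#' @param movieLength movie time points used for hyperalignment training.
#' @param snrCore,snrExtended signal amplitudes (unit-variance noise).
#' @param arCoef lag-1 noise autocorrelation.
#' @param blockSize maximal mixing-block size.
#' @param regions region partition (default \code{makeRegionPartition(mesh)}).
#' @param regionRadius radius passed to \code{makeRegionPartition} when
#'   \code{regions} is NULL.
#' @param seed integer seed.
#' @return a \linkS4class{WorldConfig}.
#' @export
worldConfig <- function(mesh, nSubjects = 14, nIdentities = 4, nViews = 5,
                        nFamiliarities = 2, nRuns = 10, movieLength = 300,
                        snrCore = 2, snrExtended = 2, arCoef = 0,
                        blockSize = 24, regions = NULL, regionRadius = 5,
                        seed = 1) {
  if (is.null(regions)) regions <- makeRegionPartition(mesh, regionRadius)
  new("WorldConfig", nSubjects = as.integer(nSubjects),
      nIdentities = as.integer(nIdentities), nViews = as.integer(nViews),
      nFamiliarities = as.integer(nFamiliarities), nRuns = as.integer(nRuns),
      movieLength = as.integer(movieLength), snrCore = snrCore,
      snrExtended = snrExtended, arCoef = arCoef,
      blockSize = as.integer(blockSize), mesh = mesh, regions = regions,
      seed = as.integer(seed))
}

#' Ground-truth synthetic world
#'
#' Shared latents, per-subject locally orthogonal mixing transforms, and the
#' block/region bookkeeping from which subject data are emitted.
#'
#' @slot config the generating \linkS4class{WorldConfig}.
#' @slot blocks list; each element has vertices, region
#'   ("core"/"extended"/"null") and amp (signal amplitude).
#' @slot movieLatents list of latent movie series (block dim x time).
#' @slot idComp,viewComp,famComp lists of latent condition components per
#'   block: identity (dim x nFam x nId, view-invariant), view
#'   (dim x nFam x nView), familiarity offset (dim x nFam).
#' @slot mixings list over subjects of lists over blocks of orthogonal
#'   matrices.
#' @export
setClass("SyntheticWorld",
  representation(config = "WorldConfig", blocks = "list",
                 movieLatents = "list", idComp = "list", viewComp = "list",
                 famComp = "list", mixings = "list"))

#' Generate the ground truth of a synthetic world
#'
#' Deterministic given the config seed.  Identity components (the decodable,
#' view-invariant signal) are present in core-like regions for both
#' familiarity conditions, in extended-like regions for the "personal"
#' condition only, and absent in null regions; view and familiarity
#' components are present in core and extended regions for both conditions.
#' Null regions carry no signal at all.  Each subject mixes each block's
#' latent dimensions into its own vertex basis through an independent random
#' orthogonal transform.
#'
#' @param config a \linkS4class{WorldConfig}.
#' @return a \linkS4class{SyntheticWorld}.
#' @export
generateWorld <- function(config) {
  validObject(config)
  rg <- config@regions
  mkBlocks <- function(vset, region, amp) {
    if (!length(vset)) return(list())
    chunks <- split(vset, ceiling(seq_along(vset) / config@blockSize))
    lapply(chunks, function(v) list(vertices = as.integer(v), region = region,
                                    amp = amp))
  }
  blocks <- c(
    unlist(lapply(rg$core, mkBlocks, region = "core", amp = config@snrCore),
           recursive = FALSE),
    unlist(lapply(rg$extended, mkBlocks, region = "extended",
                  amp = config@snrExtended), recursive = FALSE),
    mkBlocks(rg$null, "null", 0))
  names(blocks) <- NULL
  nF <- config@nFamiliarities; nI <- config@nIdentities; nV <- config@nViews
  withSeed(childSeed(config@seed, "world"), {
    movieLatents <- list(); idComp <- list(); viewComp <- list(); famComp <- list()
    for (b in seq_along(blocks)) {
      d <- length(blocks[[b]]$vertices)
      movieLatents[[b]] <- matrix(stats::rnorm(d * config@movieLength), d)
      idc <- array(stats::rnorm(d * nF * nI), c(d, nF, nI))
      if (blocks[[b]]$region == "extended" && nF > 1)
        idc[, 2:nF, ] <- 0          # identity signal only for "personal"
      if (blocks[[b]]$region == "null") idc[] <- 0
      vc <- array(stats::rnorm(d * nF * nV), c(d, nF, nV))
      fc <- matrix(stats::rnorm(d * nF), d, nF)
      if (blocks[[b]]$region == "null") { vc[] <- 0; fc[] <- 0 }
      idComp[[b]] <- idc; viewComp[[b]] <- vc; famComp[[b]] <- fc
    }
    mixings <- lapply(seq_len(config@nSubjects), function(s)
      lapply(blocks, function(bl) randomOrthogonal(length(bl$vertices))))
    new("SyntheticWorld", config = config, blocks = blocks,
        movieLatents = movieLatents, idComp = idComp, viewComp = viewComp,
        famComp = famComp, mixings = mixings)
  })
}

setMethod("show", "SyntheticWorld", function(object) {
  cfg <- object@config
  reg <- vapply(object@blocks, function(b) b$region, character(1))
  cat(sprintf(
    "SyntheticWorld: %d subjects, %d identities x %d views x %d familiarity, %d runs\n  %d mixing blocks (%d core, %d extended, %d null), mesh %d vertices, seed %d\n",
    cfg@nSubjects, cfg@nIdentities, cfg@nViews, cfg@nFamiliarities, cfg@nRuns,
    length(object@blocks), sum(reg == "core"), sum(reg == "extended"),
    sum(reg == "null"), nVertices(cfg@mesh), cfg@seed))
})

# latent condition pattern of one block (dim-length vector)
.blockPattern <- function(world, b, fam, id, view) {
  world@idComp[[b]][, fam, id] + world@viewComp[[b]][, fam, view] +
    world@famComp[[b]][, fam]
}

# full-mesh vertex pattern for one condition and subject (signal only)
.subjectPattern <- function(world, subject, fam, id, view) {
  n <- nVertices(world@config@mesh)
  out <- numeric(n)
  for (b in seq_along(world@blocks)) {
    bl <- world@blocks[[b]]
    if (bl$amp == 0 || !length(bl$vertices)) next
    lat <- .blockPattern(world, b, fam, id, view)
    out[bl$vertices] <- bl$amp * as.numeric(world@mixings[[subject]][[b]] %*% lat)
  }
  out
}

# add AR(1) or white noise, unit marginal sd
.noiseMatrix <- function(nr, nc, arCoef) {
  e <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (arCoef != 0) {
    for (j in 2:nc) e[, j] <- arCoef * e[, j - 1] + sqrt(1 - arCoef^2) * e[, j]
  }
  e
}

#' Emit one subject's movie time series
#'
#' The shared latent movie series mixed into the subject's vertex basis at
#' the region's signal amplitude, plus unit-variance noise.  Stands in for
#' the movie-watching data used to train hyperalignment.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param subject subject index.
#' @param noiseSd noise standard deviation (default 1; 0 gives the noiseless
#'   embedded latents).
#' @return vertices x time matrix.
#' @export
emitSubjectMovie <- function(world, subject, noiseSd = 1) {
  cfg <- world@config
  if (subject < 1 || subject > cfg@nSubjects) stop("subject out of range")
  n <- nVertices(cfg@mesh)
  withSeed(childSeed(cfg@seed, "world", 1000L + subject), {
    out <- noiseSd * .noiseMatrix(n, cfg@movieLength, cfg@arCoef)
    for (b in seq_along(world@blocks)) {
      bl <- world@blocks[[b]]
      if (bl$amp == 0 || !length(bl$vertices)) next
      out[bl$vertices, ] <- out[bl$vertices, ] +
        bl$amp * world@mixings[[subject]][[b]] %*% world@movieLatents[[b]]
    }
    out
  })
}

#' Emit one subject's per-run condition response patterns
#'
#' A pattern-level shortcut past the BOLD/GLM stage: for every run and
#' condition (familiarity x identity x view) the subject's mixed ground-truth
#' pattern plus fresh unit-variance noise.  Statistically this matches the
#' t-patterns the GLM stage estimates from the trial-level series, and it is
#' what the recovery analyses decode.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param subject subject index.
#' @param nRuns number of runs (default from the config).
#' @param noiseSd per-run pattern noise sd (default 1).
#' @return a \linkS4class{PatternSet} (samples x vertices).
#' @export
emitSubjectPatterns <- function(world, subject, nRuns = NULL, noiseSd = 1) {
  cfg <- world@config
  if (subject < 1 || subject > cfg@nSubjects) stop("subject out of range")
  if (is.null(nRuns)) nRuns <- cfg@nRuns
  n <- nVertices(cfg@mesh)
  fams <- c("personal", "visual")[seq_len(cfg@nFamiliarities)]
  grid <- expand.grid(view = seq_len(cfg@nViews), identity = seq_len(cfg@nIdentities),
                      familiarity = seq_len(cfg@nFamiliarities),
                      run = seq_len(nRuns))
  withSeed(childSeed(cfg@seed, "world", 2000L + subject), {
    vals <- matrix(0, nrow(grid), n)
    for (i in seq_len(nrow(grid))) {
      sig <- .subjectPattern(world, subject, grid$familiarity[i],
                             grid$identity[i], grid$view[i])
      vals[i, ] <- sig + noiseSd * stats::rnorm(n)
    }
    info <- data.frame(familiarity = fams[grid$familiarity],
                       identity = grid$identity, view = grid$view,
                       run = grid$run)
    new("PatternSet", values = vals, betas = vals, sampleInfo = info,
        statistic = "synthetic")
  })
}

#' Nuisance generator settings for task runs
#'
#' Six motion-like columns (slow random walks) and six physiological-like
#' columns (respiratory/cardiac-band sinusoids with phase noise) per run.
#'
#' @param motionSd random-walk step sd.
#' @param physioSd physiological amplitude sd.
#' @param loadingSd per-vertex loading sd of the nuisance series.
#' @export
nuisanceSpec <- function(motionSd = 0.05, physioSd = 1, loadingSd = 0.3) {
  list(motionSd = motionSd, physioSd = physioSd, loadingSd = loadingSd,
       nMotion = 6L, nPhysio = 6L)
}

# one run's nuisance table (time x 12)
.makeNuisance <- function(nT, tr, spec) {
  mot <- vapply(seq_len(spec$nMotion), function(j)
    cumsum(stats::rnorm(nT, sd = spec$motionSd)), numeric(nT))
  tsec <- (seq_len(nT) - 1) * tr
  phys <- vapply(seq_len(spec$nPhysio), function(j) {
    f <- stats::runif(1, 0.08, 0.35)      # respiratory / aliased cardiac band
    spec$physioSd * sin(2 * pi * f * tsec + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(nT, sd = 0.2)
  }, numeric(nT))
  colnames(mot) <- paste0("motion", seq_len(spec$nMotion))
  colnames(phys) <- paste0("physio", seq_len(spec$nPhysio))
  cbind(mot, phys)
}

#' Emit one subject's trial-level BOLD-like task runs
#'
#' Each run is the HRF-convolved condition responses of its trial sequence
#' (patterns from the ground truth via the subject's mixing), plus polynomial
#' drift, nuisance contributions (6 motion-like + 6 physiological-like
#' series with random vertex loadings), and unit-variance noise.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param subject subject index.
#' @param runDesigns list of \linkS4class{RunDesign}.
#' @param tr repetition time (s), > 0.
#' @param hrf an \linkS4class{HRFSpec}.
#' @param nuisance settings from \code{\link{nuisanceSpec}}.
#' @param driftSd sd of the random per-run polynomial drift coefficients.
#' @param noiseSd thermal noise sd (default 1).
#' @param nViews number of head views used to decode labels.
#' @return list with elements \code{series} (list of vertices x time
#'   matrices) and \code{nuisance} (list of time x 12 matrices), one per run.
#' @export
emitSubjectTaskRuns <- function(world, subject, runDesigns, tr = 1.25,
                                hrf = hrfSpec(), nuisance = nuisanceSpec(),
                                driftSd = 0.5, noiseSd = 1, nViews = NULL) {
  if (tr <= 0) stop("TR must be > 0")
  if (!length(runDesigns)) stop("no run designs supplied")
  cfg <- world@config
  if (is.null(nViews)) nViews <- cfg@nViews
  n <- nVertices(cfg@mesh)
  fams <- c("personal", "visual")[seq_len(cfg@nFamiliarities)]
  withSeed(childSeed(cfg@seed, "world", 3000L + subject), {
    series <- list(); nuis <- list()
    for (r in seq_along(runDesigns)) {
      d <- runDesigns[[r]]
      nT <- as.integer(ceiling(runDuration(d) / tr))
      famIdx <- match(d@familiarity, fams)
      if (is.na(famIdx)) famIdx <- 1L
      run <- noiseSd * .noiseMatrix(n, nT, cfg@arCoef)
      trdf <- d@trials
      stim <- trdf[!trdf$is_null, , drop = FALSE]
      nullLab <- cfg@nIdentities * cfg@nViews + 1L
      for (lab in unique(stim$label)) {
        if (lab == nullLab) next
        ons <- stim$onset[stim$label == lab]
        reg <- hrfRegressor(ons, rep(hrf@duration, length(ons)),
                            rep(1, length(ons)), nT, tr, hrf)
        id <- (lab - 1) %/% nViews + 1
        vw <- (lab - 1) %% nViews + 1
        pat <- .subjectPattern(world, subject, famIdx, id, vw)
        nz <- which(pat != 0)
        if (length(nz)) run[nz, ] <- run[nz, ] + outer(pat[nz], reg)
      }
      t01 <- seq(0, 1, length.out = nT)
      driftCoef <- stats::rnorm(4, sd = driftSd)
      drift <- driftCoef[1] + driftCoef[2] * t01 + driftCoef[3] * t01^2 +
        driftCoef[4] * t01^3
      nu <- .makeNuisance(nT, tr, nuisance)
      load <- matrix(stats::rnorm(n * ncol(nu), sd = nuisance$loadingSd), n)
      run <- run + matrix(drift, n, nT, byrow = TRUE) + load %*% t(nu)
      series[[r]] <- run
      nuis[[r]] <- nu
    }
    list(series = series, nuisance = nuis)
  })
}
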