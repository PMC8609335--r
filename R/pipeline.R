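#' Pipeline configuration
#'
#' Bundles per-stage settings with a single global seed that is fanned out
#' deterministically into per-stage child seeds.
#'
#' @param seed global integer seed.
#' @param scale "tiny" (4 subjects, 42-vertex hemispheres, 2 runs) or "demo"
#'   (14 subjects, 162-vertex hemispheres, 10 runs, the study layout).
#' @param snrCore,snrExtended signal amplitudes of the synthetic world.
#' @param alignRadius searchlight radius (mm) for hyperalignment (default 20).
#' @param decodeRadius searchlight radius (mm) for decoding (default 10).
#' @param nIterations hyperalignment template passes.
#' @param reference reference subject index.
#' @param nPermutations label permutations (default 100).
#' @param nBootstrap bootstrap draws (default 1000 at demo scale; the full
#'   reference analysis uses 10,000).
#' @param patternSource "direct" (pattern-level emission) or "glm"
#'   (trial-level runs through nuisance projection and GLM).
#' @export
pipelineConfig <- function(seed = 1, scale = c("tiny", "demo"), snrCore = 2,
                           snrExtended = 2, alignRadius = 20,
                           decodeRadius = 10, nIterations = 3, reference = 1,
                           nPermutations = 100, nBootstrap = 1000,
                           patternSource = c("direct", "glm")) {
  scale <- match.arg(scale)
  patternSource <- match.arg(patternSource)
  list(seed = as.integer(seed), scale = scale, snrCore = snrCore,
       snrExtended = snrExtended, alignRadius = alignRadius,
       decodeRadius = decodeRadius, nIterations = nIterations,
       reference = reference, nPermutations = nPermutations,
       nBootstrap = nBootstrap, patternSource = patternSource)
}

#' Build a synthetic fixture world
#'
#' "tiny" builds 4 subjects on 42-vertex hemispheres with 2 runs (decodes in
#' well under a minute); "demo" mirrors the study layout with 14 subjects on
#' 162-vertex hemispheres and 10 runs.
#'
#' @param scale "tiny" or "demo".
#' @param seed integer seed.
#' @param snrCore,snrExtended signal amplitudes (default 2; set 0 for a
#'   signal-free null world).
#' @param nSubjects,nRuns optional overrides of the scale's subject and run
#'   counts.
#' @return a \linkS4class{SyntheticWorld}.
#' @export
makeFixture <- function(scale = c("tiny", "demo"), seed = 1, snrCore = 2,
                        snrExtended = 2, nSubjects = NULL, nRuns = NULL) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    mesh <- corticalMesh(1)
    cfg <- worldConfig(mesh, nSubjects = nSubjects %||% 4, nRuns = nRuns %||% 2,
                       movieLength = 150,
                       snrCore = snrCore, snrExtended = snrExtended,
                       regionRadius = 5, seed = childSeed(seed, "fixture"))
  } else {
    # 6 mm spacing keeps a 20 mm searchlight local on the 162-vertex sphere,
    # so the null disk sits beyond searchlight reach of both signal systems
    mesh <- corticalMesh(2, spacing = 6)
    cfg <- worldConfig(mesh, nSubjects = nSubjects %||% 14,
                       nRuns = nRuns %||% 10, movieLength = 300,
                       snrCore = snrCore, snrExtended = snrExtended,
                       regionRadius = 12, seed = childSeed(seed, "fixture"))
  }
  generateWorld(cfg)
}

#' Hyperalign a synthetic world's subjects from their movie data
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param radius searchlight radius in mm (default 20).
#' @param nIterations template passes (default 3).
#' @param reference reference subject (default 1).
#' @return a \linkS4class{CommonSpaceModel}.
#' @export
alignWorld <- function(world, radius = 20, nIterations = 3, reference = 1) {
  movies <- lapply(seq_len(world@config@nSubjects),
                   function(s) emitSubjectMovie(world, s))
  sls <- makeSearchlights(world@config@mesh, radius)
  searchlightHyperalign(movies, sls, nIterations = nIterations,
                        reference = reference)
}

#' Emit, align and average a world's task patterns into a SampleSet
#'
#' Per subject: per-run condition patterns are emitted, averaged across
#' runs, and (when a common-space model is supplied) projected into the
#' reference subject's space; with \code{model = NULL} the anatomical
#' (unaligned) patterns are returned instead.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param model a \linkS4class{CommonSpaceModel} or NULL.
#' @param nRuns runs to emit (default from the config).
#' @return a \linkS4class{SampleSet}.
#' @export
worldSampleSet <- function(world, model = NULL, nRuns = NULL) {
  nS <- world@config@nSubjects
  ref <- if (is.null(model)) NULL else model@maps[[model@reference]]
  sets <- lapply(seq_len(nS), function(s) {
    avg <- averageRuns(emitSubjectPatterns(world, s, nRuns = nRuns))
    if (!is.null(model)) {
      proj <- projectToReference(t(avg@values), model@maps[[s]], ref)
      avg@values <- t(proj)
    }
    avg
  })
  combineSubjects(sets)
}

#' Region-partition ROIs of a synthetic world
#'
#' One ROI per core-like and extended-like region plus one null-region ROI:
#' the disk of null vertices on the core hemisphere geodesically farthest
#' from the core center.  Any residual searchlight smearing reaching that
#' disk comes from the core region and is therefore matched across the two
#' familiarity conditions.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @return an \linkS4class{ROIMap}.
#' @export
regionROIs <- function(world) {
  mesh <- world@config@mesh
  rg <- world@config@regions
  sets <- list()
  for (h in names(rg$core)) sets[[paste0("core_", h)]] <- rg$core[[h]]
  for (h in names(rg$extended)) sets[[paste0("extended_", h)]] <- rg$extended[[h]]
  coreVerts <- rg$core[[1]]
  coreCenter <- coreVerts[which.min(rowSums(mesh@geo[coreVerts, coreVerts,
                                                     drop = FALSE]))]
  coreHemi <- mesh@hemisphere[coreCenter]
  nullL <- rg$null[mesh@hemisphere[rg$null] == coreHemi]
  far <- nullL[which.max(mesh@geo[coreCenter, nullL])]
  nullSize <- max(lengths(sets))
  ord <- order(mesh@geo[far, nullL])
  sets[["null"]] <- sort(nullL[ord[seq_len(min(nullSize, length(nullL)))]])
  assignment <- rep(NA_integer_, nVertices(mesh))
  centers <- integer(length(sets))
  for (i in seq_along(sets)) {
    assignment[sets[[i]]] <- i
    centers[i] <- sets[[i]][1]
  }
  new("ROIMap", roiNames = names(sets), centers = centers,
      assignment = assignment)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order: world generation, pattern
#' emission (optionally through the trial-level GLM path), searchlight
#' hyperalignment, projection into the reference space, run averaging,
#' ROI decoding for both familiarity conditions, permutation/bootstrap
#' inference, and the floored personal-visual difference map.  When
#' \code{outDir} is given, stage outputs are written as TSV/JSON and hashed
#' into the manifest.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @param outDir optional output directory.
#' @return list with the stage results and a manifest data.frame (stage,
#'   seconds, files, md5).
#' @export
runPipeline <- function(config, outDir = NULL) {
  t_all <- proc.time()[3]
  manifest <- data.frame(stage = character(0), seconds = numeric(0),
                         files = character(0), md5 = character(0))
  record <- function(stage, t0, files = "") {
    md5 <- if (nzchar(files)) paste(tools::md5sum(strsplit(files, ";")[[1]]),
                                    collapse = ";") else ""
    manifest <<- rbind(manifest, data.frame(stage = stage,
                                            seconds = round(proc.time()[3] - t0, 2),
                                            files = files, md5 = md5))
  }
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  t0 <- proc.time()[3]
  world <- makeFixture(config$scale, seed = config$seed,
                       snrCore = config$snrCore,
                       snrExtended = config$snrExtended)
  record("world", t0)

  t0 <- proc.time()[3]
  model <- alignWorld(world, radius = config$alignRadius,
                      nIterations = config$nIterations,
                      reference = config$reference)
  record("hyperalign", t0)

  t0 <- proc.time()[3]
  if (config$patternSource == "glm") {
    samples <- .glmSampleSet(world, model, config)
  } else {
    samples <- worldSampleSet(world, model)
  }
  record("patterns", t0)

  t0 <- proc.time()[3]
  rois <- regionROIs(world)
  folds <- makeFolds(world@config@nSubjects, world@config@nViews)
  conds <- c("personal", "visual")[seq_len(world@config@nFamiliarities)]
  acc <- lapply(conds, function(cc) roiMVPC(samples, rois, folds, cc))
  names(acc) <- conds
  accFiles <- ""
  if (!is.null(outDir)) {
    fs <- vapply(conds, function(cc) {
      f <- file.path(outDir, paste0("accuracy_", cc, ".tsv"))
      accuracyTable(acc[[cc]], f)
      f
    }, character(1))
    accFiles <- paste(fs, collapse = ";")
  }
  record("decode", t0, accFiles)

  t0 <- proc.time()[3]
  scheme <- permutationScheme(config$nPermutations,
                              seed = childSeed(config$seed, "infer"))
  perm <- lapply(conds, function(cc)
    permutedAccuracies(samples, rois, folds, cc, scheme))
  names(perm) <- conds
  stats <- lapply(conds, function(cc) {
    null <- buildNull(perm[[cc]], nBootstrap = config$nBootstrap,
                      seed = childSeed(config$seed, "bootstrap"))
    statMap(acc[[cc]], null)
  })
  names(stats) <- conds
  diff <- NULL
  if (length(conds) == 2) {
    diff <- differenceMap(acc[["personal"]], acc[["visual"]],
                          perm[["personal"]], perm[["visual"]],
                          nBootstrap = config$nBootstrap,
                          seed = childSeed(config$seed, "bootstrap", 2L))
  }
  statFiles <- ""
  if (!is.null(outDir)) {
    fs <- vapply(conds, function(cc) {
      f <- file.path(outDir, paste0("statmap_", cc, ".tsv"))
      writeStatMap(stats[[cc]], f)
      f
    }, character(1))
    if (!is.null(diff)) {
      f <- file.path(outDir, "statmap_difference.tsv")
      writeStatMap(diff, f)
      fs <- c(fs, f)
    }
    statFiles <- paste(fs, collapse = ";")
  }
  record("infer", t0, statFiles)

  manifest <- rbind(manifest, data.frame(stage = "total",
                                         seconds = round(proc.time()[3] - t_all, 2),
                                         files = "", md5 = ""))
  if (!is.null(outDir)) {
    jsonlite::write_json(list(seed = config$seed, scale = config$scale,
                              manifest = manifest),
                         file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  }
  list(world = world, model = model, samples = samples, rois = rois,
       folds = folds, accuracy = acc, stats = stats, difference = diff,
       manifest = manifest)
}

# trial-level path: emit BOLD-like runs, project out nuisance + drift, fit
# the GLM, project t-patterns to the reference space, average runs
.glmSampleSet <- function(world, model, config) {
  cfg <- world@config
  tr <- 1.25
  nLabels <- cfg@nIdentities * cfg@nViews + 1L
  seqSeed <- childSeed(config$seed, "sequence")
  seqA <- generateT1I1(nLabels, seed = seqSeed)
  seqB <- .chainedSequence(seqA, seed = seqSeed + 1L)
  conds <- c("personal", "visual")[seq_len(cfg@nFamiliarities)]
  perRun <- nLabels * 3L
  nRuns <- min(cfg@nRuns, (2L * nLabels^2 + 1L - 1L) %/% perRun)
  designs <- unlist(lapply(conds, function(cc)
    buildRunDesigns(seqA, seqB, nRuns = nRuns, trialsPerRun = perRun,
                    familiarity = cc)), recursive = FALSE)
  for (i in seq_along(designs))
    designs[[i]]@runIndex <- as.integer(i)
  ref <- model@maps[[model@reference]]
  sets <- lapply(seq_len(cfg@nSubjects), function(s) {
    runs <- emitSubjectTaskRuns(world, s, designs, tr = tr)
    clean <- lapply(seq_along(runs$series), function(r)
      projectOutNuisance(runs$series[[r]], runs$nuisance[[r]], tr = tr))
    design <- buildDesign(designs, tr = tr, nViews = cfg@nViews)
    ps <- fitGLM(do.call(cbind, clean), design)
    avg <- averageRuns(ps)
    proj <- projectToReference(t(avg@values), model@maps[[s]], ref)
    avg@values <- t(proj)
    avg
  })
  combineSubjects(sets)
}

# internal alias kept for the pipeline's private call sites
.chainedSequence <- function(first, seed = NULL, maxTries = 200L)
  chainedT1I1(first, seed = seed, maxTries = maxTries)
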