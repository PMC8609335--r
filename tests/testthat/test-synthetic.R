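test_that("worlds are deterministic given the seed and validate their config", {
  mesh <- corticalMesh(1)
  cfg <- worldConfig(mesh, nSubjects = 3, nRuns = 2, movieLength = 60, seed = 5)
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(w1@movieLatents, w2@movieLatents)
  expect_identical(w1@mixings, w2@mixings)
  expect_identical(emitSubjectMovie(w1, 2), emitSubjectMovie(w2, 2))
  expect_identical(emitSubjectPatterns(w1, 3)@values,
                   emitSubjectPatterns(w2, 3)@values)
  expect_error(worldConfig(mesh, nSubjects = 1), "nSubjects")
  expect_error(worldConfig(mesh, snrCore = -1), "SNRs")
  badRegions <- makeRegionPartition(mesh, 5)
  badRegions$null <- c(badRegions$null, badRegions$core[[1]][1])
  expect_error(worldConfig(mesh, regions = badRegions), "disjoint")
})

test_that("mixing blocks are orthogonal and patterns decompose as stated", {
  world <- tinyWorld()
  for (s in 1:2) for (b in seq_along(world@blocks)) {
    O <- world@mixings[[s]][[b]]
    expect_equal(crossprod(O), diag(nrow(O)), tolerance = 1e-10)
  }
  cfg <- world@config
  # identity component: 4 distinct identity vectors repeated across views
  for (b in which(vapply(world@blocks, function(x) x$region == "core",
                         logical(1)))) {
    idc <- world@idComp[[b]]
    expect_identical(dim(idc), c(length(world@blocks[[b]]$vertices),
                                 cfg@nFamiliarities, cfg@nIdentities))
    expect_identical(nrow(unique(t(matrix(idc[, 1, ], nrow = dim(idc)[1])))),
                     4L)
    # pattern = identity + view + familiarity components
    lat <- hyperMVPC:::.blockPattern(world, b, 1, 2, 3)
    expect_equal(lat, idc[, 1, 2] + world@viewComp[[b]][, 1, 3] +
                   world@famComp[[b]][, 1], tolerance = 1e-12)
  }
  # extended blocks carry identity information only for "personal"
  for (b in which(vapply(world@blocks, function(x) x$region == "extended",
                         logical(1)))) {
    expect_true(all(world@idComp[[b]][, 2, ] == 0))
    expect_false(all(world@idComp[[b]][, 1, ] == 0))
  }
  # null blocks carry nothing
  for (b in which(vapply(world@blocks, function(x) x$region == "null",
                         logical(1)))) {
    expect_true(all(world@idComp[[b]] == 0))
    expect_true(all(world@viewComp[[b]] == 0))
  }
})

test_that("zero SNR produces pure noise with no decodable structure", {
  world0 <- tinyNullWorld()
  expect_true(all(hyperMVPC:::.subjectPattern(world0, 1, 1, 1, 1) == 0))
  m <- emitSubjectMovie(world0, 1)
  expect_equal(mean(m), 0, tolerance = 0.02)
  expect_equal(stats::sd(as.numeric(m)), 1, tolerance = 0.02)
})

test_that("movie series have the configured length and embed the latents", {
  world <- tinyWorld()
  m <- emitSubjectMovie(world, 2)
  expect_identical(ncol(m), world@config@movieLength)
  expect_identical(nrow(m), nVertices(world@config@mesh))
  # noiseless + identity mixing: the latents appear in the vertex basis
  w2 <- world
  w2@mixings <- lapply(w2@mixings, function(subj)
    lapply(subj, function(O) diag(nrow(O))))
  m0 <- emitSubjectMovie(w2, 1, noiseSd = 0)
  b <- which(vapply(world@blocks, function(x) x$region == "core", logical(1)))[1]
  verts <- world@blocks[[b]]$vertices
  expect_equal(m0[verts, ],
               world@blocks[[b]]$amp * world@movieLatents[[b]],
               tolerance = 1e-12)
  # null-region vertices carry no movie signal
  nullVerts <- world@config@regions$null
  expect_true(all(m0[nullVerts, ] == 0))
})

test_that("anatomically aligned subjects share no vertex-level correlation", {
  world <- tinyWorld()
  m1 <- emitSubjectMovie(world, 1)
  m2 <- emitSubjectMovie(world, 2)
  verts <- c(unlist(world@config@regions$core),
             unlist(world@config@regions$extended))
  cors <- vapply(verts, function(v) stats::cor(m1[v, ], m2[v, ]), numeric(1))
  # independent random rotations: node-wise correlations center on zero
  # (individual vertices retain chance-level correlations of order
  # 1/sqrt(block dimension), so only the mean is constrained)
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("task runs assemble HRF responses, drift, nuisance and noise", {
  world <- tinyWorld()
  sA <- generateT1I1(21, seed = 51)
  sB <- hyperMVPC:::.chainedSequence(sA, seed = 950)
  designs <- buildRunDesigns(sA, sB, nRuns = 2, familiarity = "personal")
  out <- emitSubjectTaskRuns(world, 1, designs, tr = 1.25)
  expect_length(out$series, 2)
  expect_length(out$nuisance, 2)
  nT <- as.integer(ceiling(runDuration(designs[[1]]) / 1.25))
  expect_identical(nT, 280L)                       # 15 + 64 x 5 + 15 s at TR 1.25
  expect_identical(dim(out$series[[1]]), c(nVertices(world@config@mesh), nT))
  expect_identical(ncol(out$nuisance[[1]]), 12L)   # 6 motion + 6 physio
  expect_error(emitSubjectTaskRuns(world, 1, designs, tr = 0), "TR")
  expect_error(emitSubjectTaskRuns(world, 1, list()), "no run designs")

  # single-event noiseless run: the response is a scaled HRF on responsive nodes
  d1 <- new("RunDesign", runIndex = 1L,
            trials = data.frame(label = 1L, onset = 15, duration = 5,
                                is_null = FALSE, is_lead = FALSE),
            familiarity = "personal", leadIn = 15, leadOut = 15)
  quiet <- emitSubjectTaskRuns(world, 1, list(d1), tr = 1.25,
                               nuisance = nuisanceSpec(0, 0, 0),
                               driftSd = 0, noiseSd = 0)
  run <- quiet$series[[1]]
  pat <- hyperMVPC:::.subjectPattern(world, 1, 1, 1, 1)
  v <- which(pat != 0)[1]
  reg <- hrfRegressor(15, hrfSpec()@duration, 1, ncol(run), 1.25, hrfSpec())
  expect_equal(run[v, ], pat[v] * reg, tolerance = 1e-10)
  expect_true(all(run[pat == 0, ] == 0))
})

test_that("GLM recovers emitted patterns from trial-level runs", {
  world <- cachedFixture("glmWorld", {
    mesh <- corticalMesh(1)
    generateWorld(worldConfig(mesh, nSubjects = 2, nRuns = 2,
                              movieLength = 50, seed = 31))
  })
  sA <- generateT1I1(21, seed = 61)
  sB <- hyperMVPC:::.chainedSequence(sA, seed = 960)
  designs <- buildRunDesigns(sA, sB, nRuns = 2, familiarity = "personal")
  out <- emitSubjectTaskRuns(world, 1, designs, tr = 1.25, noiseSd = 0.5)
  clean <- lapply(1:2, function(r)
    projectOutNuisance(out$series[[r]], out$nuisance[[r]], tr = 1.25))
  dm <- buildDesign(designs, tr = 1.25, nViews = 5)
  ps <- fitGLM(do.call(cbind, clean), dm)
  avg <- averageRuns(ps)
  # estimated t-patterns correlate with the generating patterns
  cors <- vapply(seq_len(nrow(avg@values)), function(i) {
    si <- avg@sampleInfo[i, ]
    truth <- hyperMVPC:::.subjectPattern(world, 1, 1, si$identity, si$view)
    stats::cor(avg@values[i, truth != 0], truth[truth != 0])
  }, numeric(1))
  expect_gt(mean(cors), 0.8)
})
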