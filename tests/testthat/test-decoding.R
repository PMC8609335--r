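# small labeled sample sets built by hand
toySampleSet <- function(nSubj = 3, nId = 4, nView = 5, nVert = 6, sd = 1,
                         signal = NULL, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(view = seq_len(nView), identity = seq_len(nId),
                      subject = seq_len(nSubj))
  vals <- matrix(rnorm(nrow(grid) * nVert, sd = sd), nrow(grid))
  if (!is.null(signal))
    vals <- vals + t(vapply(seq_len(nrow(grid)),
                            function(i) signal[grid$identity[i], ],
                            numeric(nVert)))
  info <- data.frame(subject = grid$subject, familiarity = "personal",
                     identity = grid$identity, view = grid$view)
  new("SampleSet", values = vals, sampleInfo = info)
}

test_that("run averaging yields one sample per condition", {
  world <- tinyWorld()
  ps <- emitSubjectPatterns(world, 1, nRuns = 10)
  avg <- averageRuns(ps)
  expect_identical(nrow(avg@values), 2L * 4L * 5L)   # 20 per familiarity
  expect_true(all(is.na(avg@sampleInfo$run)))
  # unweighted mean oracle for one condition
  pick <- ps@sampleInfo$familiarity == "personal" &
    ps@sampleInfo$identity == 2 & ps@sampleInfo$view == 3
  o <- colMeans(ps@values[pick, , drop = FALSE])
  a <- avg@sampleInfo$familiarity == "personal" &
    avg@sampleInfo$identity == 2 & avg@sampleInfo$view == 3
  expect_equal(as.numeric(avg@values[a, ]), o, tolerance = 1e-12)
  # single run: averaging is the identity
  one <- emitSubjectPatterns(world, 1, nRuns = 1)
  avg1 <- averageRuns(one)
  expect_equal(sort(avg1@values[, 1]), sort(one@values[, 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # opposite runs cancel
  flip <- one
  flip@values <- rbind(one@values, -one@values)
  flip@sampleInfo <- rbind(one@sampleInfo,
                           transform(one@sampleInfo, run = 2L))
  expect_lt(max(abs(averageRuns(flip)@values)), 1e-12)
  # missing condition errors
  broken <- one
  drop <- !(one@sampleInfo$identity == 1 & one@sampleInfo$view == 1 &
              one@sampleInfo$familiarity == "personal")
  broken@values <- one@values[drop, ]
  broken@sampleInfo <- one@sampleInfo[drop, ]
  expect_error(averageRuns(broken), "incomplete")
})

test_that("fold construction is the exhaustive subject x view product", {
  f <- makeFolds(14, 5)
  expect_identical(nrow(f), 70L)
  expect_identical(nrow(unique(f)), 70L)
  expect_identical(f$testSubject[1:5], rep(1L, 5))   # subject-major order
  f22 <- makeFolds(2, 2)
  expect_identical(f22, data.frame(testSubject = c(1L, 1L, 2L, 2L),
                                   testView = c(1L, 2L, 1L, 2L)))
  expect_error(makeFolds(1, 5), "2 subjects")
  expect_error(makeFolds(3, 1), "2 views")
})

test_that("folds never leak the test subject or test view into training", {
  samples <- toySampleSet()
  si <- samples@sampleInfo
  folds <- makeFolds(3, 5)
  for (i in seq_len(nrow(folds))) {
    ix <- hyperMVPC:::.foldIndices(si, folds[i, ])
    expect_false(any(si$subject[ix$train] == folds$testSubject[i]))
    expect_false(any(si$view[ix$train] == folds$testView[i]))
    expect_true(all(si$subject[ix$test] == folds$testSubject[i]))
    expect_true(all(si$view[ix$test] == folds$testView[i]))
    expect_identical(length(ix$train), 2L * 4L * 4L)
    expect_identical(length(ix$test), 4L)
  }
})

test_that("a memorizable fixture reaches accuracy 1 and noise stays at chance", {
  # strong identity signal: test samples are noiseless copies of the
  # training-set class means
  sig <- diag(4) %x% matrix(1, 1, 2) * 10   # 4 identities x 8 vertices
  samples <- toySampleSet(nVert = 8, sd = 0.01, signal = sig)
  folds <- makeFolds(3, 5)
  accs <- vapply(seq_len(nrow(folds)), function(i)
    runFold(samples, 1:8, folds[i, ], "personal"), numeric(1))
  expect_true(all(accs == 1))
  # pure noise: long-run mean near 4-class chance
  noise <- toySampleSet(nSubj = 4, nVert = 6, sd = 1, seed = 9)
  folds4 <- makeFolds(4, 5)
  acc0 <- vapply(seq_len(nrow(folds4)), function(i)
    runFold(noise, 1:6, folds4[i, ], "personal"), numeric(1))
  expect_gt(mean(acc0), 0.15)
  expect_lt(mean(acc0), 0.35)
  expect_error(runFold(noise, integer(0), folds4[1, ], "personal"), "empty")
})

test_that("the one-vs-one vote matches a brute-force separator on a toy problem", {
  # 2 vertices, 2 identities, linearly separable point clouds
  set.seed(11)
  grid <- expand.grid(view = 1:5, identity = 1:2, subject = 1:3)
  mu <- rbind(c(2, 0), c(-2, 0))
  vals <- mu[grid$identity, ] + matrix(rnorm(nrow(grid) * 2, sd = 0.3),
                                       ncol = 2)
  samples <- new("SampleSet", values = vals,
                 sampleInfo = data.frame(subject = grid$subject,
                                         familiarity = "personal",
                                         identity = grid$identity,
                                         view = grid$view))
  fold <- data.frame(testSubject = 3L, testView = 5L)
  ix <- hyperMVPC:::.foldIndices(samples@sampleInfo, fold)
  # brute-force: enumerate many linear separators, keep any that perfectly
  # splits training, predict test by majority over all such separators
  tr <- vals[ix$train, ]; trY <- samples@sampleInfo$identity[ix$train]
  te <- vals[ix$test, ]; teY <- samples@sampleInfo$identity[ix$test]
  votes <- matrix(0, nrow(te), 2)
  nSep <- 0L
  for (a in seq(0, pi, length.out = 360)) {
    w <- c(cos(a), sin(a))
    proj <- as.numeric(tr %*% w)
    thr <- (max(proj[trY == 2]) + min(proj[trY == 1])) / 2
    if (all((proj > thr) == (trY == 1))) {
      pred <- ifelse(as.numeric(te %*% w) > thr, 1L, 2L)
      votes[cbind(seq_len(nrow(te)), pred)] <-
        votes[cbind(seq_len(nrow(te)), pred)] + 1
      nSep <- nSep + 1L
    }
  }
  expect_gt(nSep, 0L)
  oracle <- max.col(votes)
  acc <- runFold(samples, 1:2, fold, "personal")
  expect_equal(acc, mean(oracle == teY))
  expect_equal(acc, 1)
})

test_that("fewer than two training classes is an error", {
  samples <- toySampleSet(nId = 1, nView = 5)
  expect_error(runFold(samples, 1:6, data.frame(testSubject = 1L,
                                                testView = 1L), "personal"),
               "classes")
})

test_that("searchlight and ROI decoding agree on identical vertex sets", {
  world <- tinyWorld()
  samp <- worldSampleSet(world, NULL, nRuns = 1)
  mesh <- world@config@mesh
  sls <- makeSearchlights(mesh, 6)
  pick <- 5L
  folds <- makeFolds(4, 5)[1:6, ]
  slAcc <- searchlightMVPC(samp,
                           new("SearchlightSet", centers = sls@centers[pick],
                               members = sls@members[pick], radius = 6),
                           folds, "visual")
  roi <- new("ROIMap", roiNames = "patch", centers = sls@centers[pick],
             assignment = {
               a <- rep(NA_integer_, nVertices(mesh))
               a[sls@members[[pick]]] <- 1L
               a
             })
  roiAcc <- roiMVPC(samp, roi, folds, "visual")
  expect_equal(as.numeric(slAcc@accuracy), as.numeric(roiAcc@accuracy))
  expect_identical(ncol(slAcc@accuracy), nrow(folds))  # one column per fold
  # empty ROI errors
  bad <- new("ROIMap", roiNames = c("patch", "void"),
             centers = c(sls@centers[pick], 1L),
             assignment = roi@assignment)
  expect_error(roiMVPC(samp, bad, folds, "visual"), "empty ROI")
})

test_that("accuracy tables round-trip in long format", {
  world <- tinyWorld()
  samp <- worldSampleSet(world, NULL, nRuns = 1)
  rois <- regionROIs(world)
  folds <- makeFolds(4, 5)[1:4, ]
  acc <- roiMVPC(samp, rois, folds, "personal")
  df <- accuracyTable(acc)
  expect_identical(nrow(df), length(acc@locations) * 4L)
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 1))
  expect_setequal(unique(df$location), acc@locations)
})
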