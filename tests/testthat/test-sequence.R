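test_that("21-label sequences have the serially balanced structure", {
  s <- generateT1I1(21, seed = 7)
  expect_length(s@labels, 442)
  expect_identical(s@labels[1], s@labels[442])
  expect_true(isT1I1(s))
  expect_true(t1i1Oracle(s@labels, 21))
  # label-block property: every disjoint 21-trial window holds all labels
  blocks <- matrix(s@labels[1:441], nrow = 21)
  expect_true(all(apply(blocks, 2, function(b) length(unique(b)) == 21)))
  # inversion closure
  expect_true(isT1I1(reverseSequence(s)))
  expect_true(t1i1Oracle(rev(s@labels), 21))
})

test_that("binary sequences match the exhaustive enumeration", {
  # all valid length-5 binary T1I1 sequences by brute force
  grid <- expand.grid(rep(list(1:2), 5))
  valid <- grid[apply(grid, 1, function(r) t1i1Oracle(as.integer(r), 2)), ]
  expect_true(nrow(valid) > 0)
  for (sd in 1:5) {
    s <- generateT1I1(2, seed = sd)
    expect_true(any(apply(valid, 1, function(r) all(r == s@labels))))
    pairs <- sort(paste0(s@labels[-5], s@labels[-1]))
    expect_identical(pairs, c("11", "12", "21", "22"))
  }
})

test_that("small-alphabet sequences certify against the oracle validator", {
  for (n in 2:4) for (sd in 1:8) {
    s <- generateT1I1(n, seed = sd)
    expect_true(t1i1Oracle(s@labels, n))
  }
  for (n in c(6, 7)) {
    s <- generateT1I1(n, seed = 3)
    expect_true(t1i1Oracle(s@labels, n))
  }
  expect_error(generateT1I1(1), ">= 2")
})

test_that("the validator reports specific violations", {
  ok <- generateT1I1(3, seed = 1)
  expect_true(isT1I1(ok))
  # constant sequence: missing pairs reported
  bad <- isT1I1(c(1L, 1L, 1L, 1L, 1L), nLabels = 2)
  expect_false(bad)
  rep_ <- paste(attr(bad, "report"), collapse = " ")
  expect_match(rep_, "1->2")
  expect_match(rep_, "2->1")
  expect_match(rep_, "2->2")
  # deletion breaks the length invariant
  del <- isT1I1(ok@labels[-3], nLabels = 3)
  expect_false(del)
  expect_match(paste(attr(del, "report"), collapse = " "), "length")
})

test_that("run partitioning yields balanced 63-trial runs with lead trials", {
  sA <- generateT1I1(21, seed = 11)
  sB <- hyperMVPC:::.chainedSequence(sA, seed = 500)
  runs <- buildRunDesigns(sA, sB, nRuns = 10, trialsPerRun = 63)
  expect_length(runs, 10)
  for (r in seq_len(10)) {
    tr <- runs[[r]]@trials
    stim <- tr[!tr$is_lead, ]
    expect_identical(nrow(stim), 63L)
    counts <- table(factor(stim$label, levels = 1:21))
    expect_true(all(counts == 3))           # each image 3x, 3 nulls
    expect_identical(sum(stim$is_null), 3L)
    expect_true(all(diff(tr$onset) == 5))
    # lead trial: run 1 repeats its own first label, later runs the
    # previous run's final label
    lead <- tr$label[tr$is_lead]
    if (r == 1) expect_identical(lead, stim$label[1])
    else expect_identical(lead,
                          utils::tail(runs[[r - 1]]@trials$label, 1))
    # 15 s lead-in/lead-out around 64 x 5 s trials
    expect_equal(runDuration(runs[[r]]), 15 + 64 * 5 + 15)
  }
  # block property survives the concatenation used for runs
  concat <- c(sA@labels, sB@labels[-1])[1:630]
  wins <- matrix(concat, nrow = 21)
  expect_true(all(apply(wins, 2, function(b) length(unique(b)) == 21)))
})

test_that("run partitioning degenerate and error cases", {
  sA <- generateT1I1(3, seed = 2)
  sB <- hyperMVPC:::.chainedSequence(sA, seed = 600)
  one <- buildRunDesigns(sA, sB, nRuns = 1, trialsPerRun = 19)
  expect_identical(one[[1]]@trials$label[!one[[1]]@trials$is_lead],
                   c(sA@labels, sB@labels[-1]))
  expect_error(buildRunDesigns(sA, sB, nRuns = 5, trialsPerRun = 63),
               "not enough")
  sC <- generateT1I1(3, seed = 3)
  if (sC@labels[1] != sA@labels[10])
    expect_error(buildRunDesigns(sA, sC), "final label")
})

test_that("efficiency matches a direct normal-equations computation", {
  s <- generateT1I1(3, seed = 4)
  set.seed(9)
  m <- matrix(stats::runif(9), 3); m <- (m + t(m)) / 2; diag(m) <- 1
  rels <- list(m)
  hrf <- hrfSpec(duration = 1.6)
  eff <- sequenceEfficiency(s, rels, hrf, tr = 1.25, trialDuration = 5)
  # independent oracle: rebuild the regressor and invert normal equations
  lab <- s@labels
  amp <- c(0, m[cbind(lab[-10], lab[-1])])
  nTime <- ceiling((10 * 5 + 32) / 1.25)
  reg <- hrfRegressor((0:9) * 5, rep(5, 10), amp, nTime, 1.25, hrf)
  X <- cbind(1, reg)
  oracle <- 1 / solve(t(X) %*% X)[2, 2]
  expect_equal(eff, oracle, tolerance = 1e-10)
})

test_that("reversal preserves efficiency for symmetric relations", {
  s <- generateT1I1(3, seed = 6)
  set.seed(10)
  rels <- lapply(1:2, function(i) {
    m <- matrix(stats::runif(9), 3); m <- (m + t(m)) / 2; diag(m) <- 1; m
  })
  e1 <- sequenceEfficiency(s, rels)
  e2 <- sequenceEfficiency(reverseSequence(s), rels)
  expect_equal(e1, e2, tolerance = 1e-3)
})

test_that("degenerate all-ones relations flag rank deficiency", {
  s <- generateT1I1(3, seed = 8)
  ones <- matrix(1, 3, 3)
  expect_warning(eff <- sequenceEfficiency(s, list(ones)), "constant|rank")
  expect_identical(eff, 0)
  expect_error(sequenceEfficiency(s, list(matrix(1, 2, 2))), "nLabels")
})

test_that("scaling the HRF amplitude scales efficiency quadratically", {
  s <- generateT1I1(3, seed = 12)
  set.seed(13)
  m <- matrix(stats::runif(9), 3); diag(m) <- 1
  e1 <- sequenceEfficiency(s, list(m), hrfSpec(amplitude = 1))
  e3 <- sequenceEfficiency(s, list(m), hrfSpec(amplitude = 3))
  expect_equal(e3 / e1, 9, tolerance = 1e-8)
})

test_that("top-sequence selection follows a full-sort oracle", {
  rels <- faceRelationshipMatrices(2, 2)  # 5 labels
  cands <- lapply(1:6, function(sd) generateT1I1(5, seed = sd))
  eff <- vapply(cands, sequenceEfficiency, numeric(1), rels = rels)
  top <- selectTopSequences(cands, rels, k = 3)
  oracle <- cands[order(-eff)][1:3]
  expect_identical(lapply(top, function(x) x@labels),
                   lapply(oracle, function(x) x@labels))
  all6 <- selectTopSequences(cands, rels, k = 6)
  expect_identical(attr(all6, "efficiency"), sort(eff, decreasing = TRUE))
  # a duplicated best candidate is returned twice before any other
  dup <- c(cands[which.max(eff)], cands)
  topDup <- selectTopSequences(dup, rels, k = 2)
  expect_identical(topDup[[1]]@labels, topDup[[2]]@labels)
  expect_error(selectTopSequences(list(), rels, k = 1), "no candidate")
  expect_error(selectTopSequences(cands, rels, k = 10), "exceeds")
})

test_that("face relationship matrices encode identity, view and mirror structure", {
  rels <- faceRelationshipMatrices(4, 5)
  expect_true(all(vapply(rels, function(m) isTRUE(all.equal(m, t(m))), logical(1))))
  expect_true(all(vapply(rels, function(m) all(diag(m) == 1), logical(1))))
  # label 1 = (id 1, view 1 left profile); label 5 = (id 1, view 5 right profile)
  expect_identical(rels$identity[1, 5], 1)
  expect_identical(rels$view[1, 5], 0)
  expect_identical(rels$mirror[1, 5], 1)   # mirror-symmetric profiles
  expect_identical(rels$mirror[2, 4], 1)   # half profiles
  expect_identical(rels$mirror[1, 4], 0)
  # null label relates only to itself
  expect_true(all(rels$identity[21, 1:20] == 0))
})

test_that("events tables round-trip run designs", {
  sA <- generateT1I1(3, seed = 21)
  sB <- hyperMVPC:::.chainedSequence(sA, seed = 700)
  runs <- buildRunDesigns(sA, sB, nRuns = 2, trialsPerRun = 9,
                          familiarity = "visual")
  d <- file.path(tempdir(), "events")
  writeEventsTSV(runs, d, prefix = "vis")
  ev <- utils::read.table(file.path(d, "vis-01_events.tsv"), header = TRUE,
                          sep = "\t")
  expect_identical(nrow(ev), 10L)
  expect_identical(sum(ev$is_lead), 1L)
  expect_true(file.exists(file.path(d, "vis_events.json")))
})
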