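test_that("L1 distance matches hand sums and rejects grid mismatches", {
  g <- makeGrid(1500, 1500.2, 0.2)
  a <- newSignature(g, c(0, 0))
  b <- newSignature(g, c(1, 2))
  expect_equal(l1Distance(a, b), 3)
  expect_equal(l1Distance(a, a), 0)
  g2 <- makeGrid(1500, 1500.4, 0.2)
  expect_error(l1Distance(a, newSignature(g2, c(1, 2, 3))), "grids")
})

test_that("L1 distance satisfies the metric axioms on random signatures", {
  set.seed(55)
  g <- smallGrid(80)
  for (i in 1:25) {
    x <- randomSignature(g); y <- randomSignature(g); z <- randomSignature(g)
    dxy <- l1Distance(x, y)
    expect_gte(dxy, 0)
    expect_equal(l1Distance(x, x), 0)
    expect_equal(dxy, l1Distance(y, x))                       # symmetry
    expect_lte(dxy, l1Distance(x, z) + l1Distance(z, y) + 1e-9)  # triangle
  }
})

test_that("identification picks the nearest neighbour with full distance map", {
  p <- smallParams(responseScale = 1e5, seed = 6L)
  concs <- c(0, 0.01, 0.02, 0.03)
  e <- generateExperiment(p, concs, permutationSeed = 2L)
  lib <- e@training

  # a training signature identifies as itself, distance 0, positive margin
  r <- identifySignature(lib@signatures[[2]], lib)
  expect_equal(r@assigned, 0.01)
  expect_equal(unname(r@distances["0.01"]), 0)
  expect_gt(r@margin, 0)

  # noiseless blind between two training points assigns the nearer one
  near <- buildSignature(list(generateSweep(p, 0.014)))
  expect_equal(identifySignature(near, lib)@assigned, 0.01)

  # invariant to library input order (library sorts by concentration)
  libRev <- trainingLibrary(rev(lib@signatures), rev(concentrations(lib)))
  expect_equal(identifySignature(near, libRev)@assigned, 0.01)

  # invariant to a constant offset added to blind and library alike
  off <- function(s) newSignature(s@grid, meanPower(s) + 500, nSweeps(s))
  libOff <- trainingLibrary(lapply(lib@signatures, off), concentrations(lib))
  rOff <- identifySignature(off(near), libOff)
  expect_equal(rOff@assigned, 0.01)
  expect_equal(rOff@distances, identifySignature(near, lib)@distances)

  # missing scan propagates as no-data
  nd <- identifySignature(NULL, lib)
  expect_true(nd@noData)
  expect_true(is.na(nd@assigned))
})

test_that("scalar matching reproduces every published blind assignment", {
  # water-in-alcohol at 10,000 ppm spacing
  m <- list(
    training = c("0" = 0, "10000" = 873013, "20000" = 1917048,
                 "30000" = 3116386, "40000" = 4260250, "50000" = 5598519),
    blinds = c("Blind-2" = 33157, "Blind-5" = 864963, "Blind-6" = 1910652,
               "Blind-3" = 3086471, "Blind-1" = 4250653, "Blind-4" = 5556104))
  got <- matchBlindsScalar(m$training, m$blinds)
  expect_equal(got, c("Blind-2" = 0, "Blind-5" = 10000, "Blind-6" = 20000,
                      "Blind-3" = 30000, "Blind-1" = 40000, "Blind-4" = 50000))

  # bleach table: one blind recorded without data passes through unassigned
  m5 <- fixtureMapsFor("exp4")
  got5 <- matchBlindsScalar(m5$training, m5$blinds)
  expect_true(is.na(got5["Blind-3"]))
  ok <- !is.na(got5)
  expect_equal(got5[ok], m5$truth[ok])

  # all four fixture tables: every assignable blind correct
  nAssignable <- 0
  for (e in c("exp1", "exp2", "exp3", "exp4")) {
    m <- fixtureMapsFor(e)
    got <- matchBlindsScalar(m$training, m$blinds)
    ok <- !is.na(got)
    nAssignable <- nAssignable + sum(ok)
    expect_equal(got[ok], m$truth[ok], info = e)
  }
  expect_equal(nAssignable, 16)

  # degenerate cases
  expect_equal(unname(matchBlindsScalar(c("0" = 0), c(b1 = 5, b2 = 1e6))),
               c(0, 0))
  expect_error(matchBlindsScalar(numeric(0), c(b1 = 1)), "empty")
  expect_error(matchBlindsScalar(c("1000" = 5), c(b1 = 1)), "reference")
})

test_that("distance tables are reference-anchored and ordered by nearness", {
  p <- calibratedParams(33157, 864963, 10000, grid = smallGrid(150), seed = 9L)
  concs <- c(0, 0.01, 0.02, 0.03, 0.04, 0.05)
  e <- generateExperiment(p, concs, permutationSeed = 10L)
  blinds <- lapply(e@blindSweeps, buildSignature)
  tab <- distanceTable(e@training, blinds, 0)

  train <- tab[tab$role == "train", ]
  expect_equal(train$distance[train$ppm == 0], 0)
  expect_true(all(diff(train$distance) > 0))  # monotone in concentration
  test <- tab[tab$role == "test", ]
  expect_true(!is.unsorted(test$distance))

  # each blind's distance is within one noise floor of its solution's
  # training distance (triangle inequality through the shared truth)
  truthDist <- train$distance[match(e@answerKey * 1e6, train$ppm)]
  blindDist <- tab$distance[match(names(e@blindSweeps), tab$label)]
  expect_true(all(abs(blindDist - truthDist) <= 2 * 33157))

  expect_error(distanceTable(e@training, blinds, 0.99), "not in the library")
})

test_that("blind trials score correctly, excluding no-data blinds", {
  # noiseless: perfect accuracy
  p0 <- smallParams(responseScale = 1e5, seed = 12L)
  e0 <- generateExperiment(p0, c(0, 0.01, 0.02), permutationSeed = 13L)
  t0 <- runBlindTrial(e0)
  expect_equal(t0@accuracy, 1)
  expect_equal(t0@nTotal, 3L)
  expect_equal(unname(t0@assignments), unname(t0@truth))

  # a blind with zero sweeps is excluded from the denominator
  e0@blindSweeps[[2]] <- list()
  t1 <- runBlindTrial(e0)
  expect_equal(t1@nTotal, 2L)
  expect_equal(t1@excluded, names(e0@blindSweeps)[2])
  expect_equal(t1@accuracy, 1)

  # zero separation between two solutions: accuracy ~ 0.5 over many seeds
  set.seed(77)
  acc <- vapply(1:200, function(i) {
    p <- smallParams(noiseSigma = 5, responseScale = 0, nSweeps = 2L, n = 40)
    runBlindTrial(generateExperiment(p, c(0, 0.01), permutationSeed = i))@accuracy
  }, numeric(1))
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.65)
})

test_that("one-to-one assignment is a bijection and agrees when separations are clear", {
  p <- calibratedParams(33157, 864963, 10000, grid = smallGrid(150), seed = 31L)
  e <- generateExperiment(p, c(0, 0.01, 0.02, 0.03), permutationSeed = 32L)
  ti <- runBlindTrial(e)
  t1 <- runBlindTrial(e, assignment = "oneToOne")
  expect_identical(t1@assignments, ti@assignments)
  expect_equal(t1@accuracy, 1)

  # with zero separation, independent matching may reuse a label but the
  # one-to-one mode always yields a bijection
  set.seed(60)
  p0 <- smallParams(noiseSigma = 5, responseScale = 0, nSweeps = 2L, n = 40)
  e0 <- generateExperiment(p0, c(0, 0.01, 0.02), permutationSeed = 61L)
  t0 <- runBlindTrial(e0, assignment = "oneToOne")
  expect_setequal(unname(t0@assignments), c(0, 0.01, 0.02))
})

test_that("accuracy is monotone non-increasing in the noise level", {
  spacingDist <- 1000  # noiseless separation at the 1% spacing used
  sigmas <- c(2, 20, 120)
  meanAcc <- vapply(sigmas, function(sg) {
    acc <- vapply(1:60, function(i) {
      set.seed(1000 + i)
      p <- smallParams(noiseSigma = sg, responseScale = spacingDist / 0.01,
                       nSweeps = 3L, n = 60)
      runBlindTrial(generateExperiment(p, c(0, 0.01), permutationSeed = i))@accuracy
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  expect_true(all(diff(meanAcc) <= 0))
  expect_equal(meanAcc[1], 1)  # spacing/noise ratio >> 1
  expect_lt(meanAcc[3], 0.9)   # noise-dominated regime loses accuracy
})
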