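test_that("noiseless generation reproduces the deterministic model exactly", {
  p <- smallParams(responseScale = 5000)
  # c = 0, sigma = 0: power is the baseline exactly
  base <- generateSweep(p, 0)
  p0 <- generatorParams(grid = p@grid, baseline = p@baseline,
                        response = p@response, responseScale = 0)
  expect_identical(power(base), power(generateSweep(p0, 0)))

  # noiseless L1 distance between two concentrations is |g(c1)-g(c2)| * scale
  s1 <- buildSignature(list(generateSweep(p, 0.01)))
  s2 <- buildSignature(list(generateSweep(p, 0.04)))
  expect_equal(l1Distance(s1, s2), 0.03 * 5000, tolerance = 1e-12)

  # with a convex response g(c) = c + q c^2
  pq <- smallParams(responseScale = 5000, quadCoef = 2)
  s1 <- buildSignature(list(generateSweep(pq, 0.01)))
  s2 <- buildSignature(list(generateSweep(pq, 0.04)))
  gdiff <- (0.04 + 2 * 0.04^2) - (0.01 + 2 * 0.01^2)
  expect_equal(l1Distance(s1, s2), gdiff * 5000, tolerance = 1e-9)
})

test_that("generation is bitwise reproducible under a fixed seed", {
  p <- smallParams(noiseSigma = 4, responseScale = 1000)
  set.seed(99); a <- generateSweep(p, 0.02)
  set.seed(99); b <- generateSweep(p, 0.02)
  expect_identical(power(a), power(b))

  ps <- smallParams(noiseSigma = 4, responseScale = 1000, seed = 123L)
  e1 <- generateExperiment(ps, c(0, 0.01), permutationSeed = 5L)
  e2 <- generateExperiment(ps, c(0, 0.01), permutationSeed = 5L)
  expect_identical(e1@answerKey, e2@answerKey)
  expect_identical(meanPower(e1@training@signatures[[1]]),
                   meanPower(e2@training@signatures[[1]]))
  expect_identical(power(e1@blindSweeps[[1]][[3]]),
                   power(e2@blindSweeps[[1]][[3]]))
})

test_that("expected self-distance closed form and its inverse agree", {
  expect_equal(expectedSelfDistance(1, 1, 2), sqrt(4 / (2 * pi)),
               tolerance = 1e-12)
  # inverse pair round trip
  sig <- calibrateNoiseSigma(33157, 7501, 10)
  expect_equal(expectedSelfDistance(sig, 7501, 10), 33157, tolerance = 1e-9)
  expect_equal(sig, 12.39, tolerance = 1e-3)
  # linear in the target
  expect_equal(calibrateNoiseSigma(19475, 7501, 10), sig * 19475 / 33157,
               tolerance = 1e-12)
  expect_equal(calibrateNoiseSigma(0, 7501, 10), 0)
})

test_that("Monte-Carlo self-distance matches the closed form within 3 SE", {
  set.seed(2024)
  n <- 300
  p <- smallParams(noiseSigma = 8, nSweeps = 10L, n = n)
  reps <- 250
  d <- vapply(seq_len(reps), function(i) {
    l1Distance(simulateSignature(p, 0), simulateSignature(p, 0))
  }, numeric(1))
  expected <- expectedSelfDistance(8, n, 10)
  se <- sd(d) / sqrt(reps)
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("noise sigma is recoverable from rescan pairs within 5% at full grid size", {
  set.seed(31)
  sigma <- calibrateNoiseSigma(33157, 7501, 10)
  p <- generatorParams(responseScale = 0, noiseSigma = sigma, nSweeps = 10L)
  d <- mean(vapply(1:3, function(i) {
    l1Distance(simulateSignature(p, 0), simulateSignature(p, 0))
  }, numeric(1)))
  sigmaHat <- calibrateNoiseSigma(d, 7501, 10)
  expect_lt(abs(sigmaHat - sigma) / sigma, 0.05)
})

test_that("response-scale calibration gives the stated per-ppm slope", {
  expect_equal(calibrateResponseScale(864963, 0.01), 86496300)
  expect_equal(calibrateResponseScale(864963, 0.01) / 1e6, 86.4963,
               tolerance = 1e-9)  # about 86.5 per ppm
  expect_equal(calibrateResponseScale(156608, 0.002) / 1e6, 78.304)
  expect_equal(calibrateResponseScale(0, 0.01), 0)
  expect_error(calibrateResponseScale(1, 0), "> 0")
})

test_that("optional drift adds a smooth zero-default perturbation", {
  # off by default: drift-free sweeps are the pure model
  p <- smallParams(responseScale = 100, n = 120)
  expect_equal(p@driftSigma, 0)
  pd <- generatorParams(grid = smallGrid(120), responseScale = 100,
                        driftSigma = 10, driftWidthMhz = 8)
  set.seed(14)
  drift <- power(generateSweep(pd, 0)) - power(generateSweep(p, 0))
  expect_equal(sd(drift), 10, tolerance = 1e-9)
  # smooth: neighbouring points move together far more than white noise would
  expect_lt(sd(diff(drift)), 0.5 * sd(drift))
})

test_that("generated experiments have the blind-protocol structure", {
  concs <- c(0, 0.01, 0.02, 0.03, 0.04, 0.05)
  p <- smallParams(noiseSigma = 1, responseScale = 1e5, seed = 3L)
  e <- generateExperiment(p, concs, permutationSeed = 17L)
  expect_length(e@training, 6)
  expect_length(e@blindSweeps, 6)
  expect_setequal(e@answerKey, concs)
  expect_true(all(vapply(e@blindSweeps[[1]],
                         function(s) is.na(label(s)), logical(1))))
  expect_error(generateExperiment(p, c(0.01, 0.01)), "distinct")
  expect_error(generateExperiment(p, 0.01), "length")

  # noiseless: every blind's nearest neighbour is its true label with
  # margin = responseScale * spacing
  p0 <- smallParams(responseScale = 1e5, seed = 4L)
  e0 <- generateExperiment(p0, concs, permutationSeed = 18L)
  for (i in seq_along(e0@blindSweeps)) {
    r <- identifySignature(buildSignature(e0@blindSweeps[[i]]), e0@training)
    expect_equal(r@assigned, e0@answerKey[i])
    expect_equal(r@margin, 1e5 * 0.01, tolerance = 1e-6)
  }
})
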