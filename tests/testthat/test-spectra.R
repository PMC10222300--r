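test_that("grid arithmetic is inclusive and rejects non-commensurate steps", {
  expect_equal(nPoints(makeGrid(1500, 3000, 0.2)), 7501L)
  expect_equal(nPoints(defaultGrid()), 7501L)
  expect_equal(nPoints(makeGrid(1500, 1500.2, 0.2)), 2L)
  g <- makeGrid(1500, 1501, 0.5)
  expect_equal(nPoints(g), 3L)
  expect_equal(frequencies(g), c(1500.0, 1500.5, 1501.0))
  f <- frequencies(defaultGrid())
  expect_length(f, 7501)
  expect_true(all(diff(f) > 0))
  expect_equal(f[7501], 3000, tolerance = 1e-9)

  expect_error(makeGrid(1500, 1501, 0.3), "not an integer")
  expect_error(makeGrid(1500, 1500, 0.2), "startMhz")
  expect_error(makeGrid(1500, 1501, -0.5), "stepMhz")
})

test_that("buildSignature averages per frequency and validates its input", {
  g <- makeGrid(1500, 1500.2, 0.2)
  sig <- buildSignature(list(newSweep(g, c(1, 3), 1), newSweep(g, c(3, 5), 2)))
  expect_equal(meanPower(sig), c(2, 4))
  expect_equal(nSweeps(sig), 2L)

  # single sweep: signature identical to that sweep
  s <- newSweep(g, c(7.25, -1.5), 1, label = "x")
  one <- buildSignature(list(s))
  expect_identical(meanPower(one), power(s))
  expect_equal(nSweeps(one), 1L)
  expect_equal(label(one), "x")

  expect_error(buildSignature(list()), "no data")
  g2 <- makeGrid(1500, 1500.4, 0.2)
  expect_error(buildSignature(list(s, newSweep(g2, c(1, 2, 3)))), "grid")
  expect_error(buildSignature(list(s, newSweep(g, c(1, 2), 2, label = "y"))),
               "label")
})

test_that("signature of a pooled sweep set is the midpoint of equal-size half-signatures", {
  set.seed(42)
  g <- smallGrid(50)
  for (rep in 1:5) {
    a <- lapply(1:4, function(i) newSweep(g, rnorm(50), i))
    b <- lapply(5:8, function(i) newSweep(g, rnorm(50), i))
    whole <- buildSignature(c(a, b))
    expect_equal(meanPower(whole),
                 (meanPower(buildSignature(a)) + meanPower(buildSignature(b))) / 2)
  }
})

test_that("variance of the n-sweep mean is sigma^2 / n", {
  set.seed(101)
  p <- smallParams(noiseSigma = 3, nSweeps = 10L, n = 60)
  reps <- 400
  sims <- vapply(seq_len(reps),
                 function(i) meanPower(simulateSignature(p, 0)),
                 numeric(60))
  empVar <- mean(apply(sims, 1, var))  # pooled over frequencies
  expect_equal(empVar, 9 / 10, tolerance = 0.1)
})

test_that("sweep CSV round trip is lossless and malformed files are rejected", {
  set.seed(7)
  p <- smallParams(noiseSigma = 5, responseScale = 1000, nSweeps = 3L, n = 40)
  sweeps <- lapply(1:3, function(i) generateSweep(p, 0.02, i, label = "2% solute"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSweepsCsv(sweeps, path)
  back <- readSweepsCsv(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(power(back[[i]]), power(sweeps[[i]]))
    expect_equal(label(back[[i]]), "2% solute")
  }
  # blinded labels survive as NA
  writeSweepsCsv(list(newSweep(smallGrid(40), rnorm(40))), path)
  expect_true(is.na(label(readSweepsCsv(path)[[1]])))

  # missing power cell
  df <- utils::read.csv(path)
  df$power[3] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(readSweepsCsv(path), "missing")

  # descending frequency column
  df <- utils::read.csv(path)
  df$power[3] <- 0
  df <- df[rev(seq_len(nrow(df))), ]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(readSweepsCsv(path), "increasing")
})

test_that("signature CSV round trip is lossless", {
  set.seed(8)
  p <- smallParams(noiseSigma = 2, nSweeps = 4L, n = 30)
  sig <- simulateSignature(p, 0, label = "base")
  path <- withr::local_tempfile(fileext = ".csv")
  writeSignatureCsv(sig, path)
  back <- readSignatureCsv(path)
  expect_identical(meanPower(back), meanPower(sig))
  expect_equal(nSweeps(back), 4L)
  expect_equal(label(back), "base")
})

test_that("solution specs expose ppm consistently", {
  s <- solutionSpec("isopropyl alcohol", "deionized water", 0.01)
  expect_equal(ppm(s), 10000)
  expect_equal(ppm(solutionSpec("water", "NaCl", 0.002, basis = "mass")), 2000)
  expect_error(solutionSpec("a", "b", 1.5), "fraction")
})
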