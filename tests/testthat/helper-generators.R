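# Small-grid factories for fast simulation tests. The generator model is
# grid-size agnostic, so properties checked on a few hundred frequencies
# hold on the full 7501-point acquisition grid.

smallGrid <- function(n = 201) makeGrid(1500, 1500 + 0.2 * (n - 1), 0.2)

smallParams <- function(noiseSigma = 0, responseScale = 0, nSweeps = 10L,
                        seed = NA_integer_, n = 201, quadCoef = 0) {
  generatorParams(grid = smallGrid(n), responseScale = responseScale,
                  noiseSigma = noiseSigma, nSweeps = nSweeps, seed = seed,
                  quadCoef = quadCoef)
}

# random signature on a shared grid, for metric-property loops
randomSignature <- function(grid, scale = 100) {
  newSignature(grid, stats::rnorm(nPoints(grid), 0, scale))
}

# scalar training/blind/truth maps from a packaged distance fixture
fixtureMapsFor <- function(experiment) {
  df <- loadDistanceFixture(experiment)
  tr <- df[df$role == "train", ]
  te <- df[df$role == "test", ]
  list(training = stats::setNames(tr$distance, tr$ppm),
       blinds = stats::setNames(te$distance, te$label),
       truth = stats::setNames(te$ppm, te$label))
}
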