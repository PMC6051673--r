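# Shared fixtures: all synthetic, built in code at test time.

# A small 3-region study configuration that runs in well under a second per
# run; used wherever the full-size reference study would be wasteful.
tinyRegions <- function() {
  list(motor = blockVoxels(2:3, 2:3, 2:3),
       thalamus = blockVoxels(6:7, 2:3, 2:3),
       cerebellum = blockVoxels(2:3, 6:7, 2:3))
}

tinyCoupling <- function() {
  rn <- c("motor", "thalamus", "cerebellum")
  C <- matrix(0.15, 3, 3, dimnames = list(rn, rn))
  C["motor", "thalamus"] <- C["thalamus", "motor"] <- 0.4
  C["motor", "cerebellum"] <- C["cerebellum", "motor"] <- 0.3
  diag(C) <- 1
  C
}

tinyConfig <- function(seed = 1L, nSubjects = 3L, nTimepoints = 40L,
                       snr = 2, deltas = NULL, dropout = TRUE, ...) {
  if (is.null(deltas)) {
    d <- ecmap:::couplingDelta(c("motor", "thalamus", "cerebellum"),
                               list(c("motor", "thalamus")), 0.3)
    deltas <- list(POST_ON_left = d, POST_ON_right = d)
  }
  syntheticConfig(gridShape = c(8L, 8L, 4L), nTimepoints = nTimepoints,
                  nSubjects = nSubjects, regionBlocks = tinyRegions(),
                  baseCoupling = tinyCoupling(), couplingDeltas = deltas,
                  hubLabel = "motor", snr = snr,
                  dropoutVoxels = if (dropout) blockVoxels(6:7, 6:7, 4)
                                  else matrix(integer(0), 0, 3),
                  rngSeed = seed, ...)
}

# random standardized time-series matrix on a 1D grid
randomTs <- function(V, T, seed = 1) {
  set.seed(seed)
  timeSeriesMatrix(matrix(rnorm(V * T), V, T))
}

# the frozen 13-subject clinical fixture
updrsFixture <- function() updrsScores()
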