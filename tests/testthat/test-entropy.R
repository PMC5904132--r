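test_that("band power and normalization evaluate exactly", {
  expect_equal(bandPower(c(1, -1, 2)), 6)
  expect_equal(bandPower(numeric(3)), 0)
  x <- rnorm(10)
  expect_equal(bandPower(3 * x), 9 * bandPower(x), tolerance = 1e-12)
  expect_error(bandPower(numeric(0)), "empty")

  expect_equal(normalizePowers(2, 1, 1), c(0.5, 0.25, 0.25))
  expect_equal(normalizePowers(5, 0, 0), c(1, 0, 0))
  set.seed(1)
  for (i in 1:20) {
    p <- normalizePowers(runif(1), runif(1), runif(1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(normalizePowers(0, 0, 0), "degenerate")
})

test_that("rhythm entropy has its exact values, bounds and symmetries", {
  expect_equal(rhythmEntropy(c(1, 1, 1) / 3), log2(3), tolerance = 1e-12)
  expect_equal(rhythmEntropy(c(1, 0, 0)), 0)
  expect_equal(rhythmEntropy(c(0.5, 0.25, 0.25)), 1.5, tolerance = 1e-12)
  expect_error(rhythmEntropy(c(-0.1, 0.6, 0.5)), "nonnegative")

  set.seed(7)
  for (i in 1:25) {
    p <- as.vector(stats::rgamma(3, 1)); p <- p / sum(p)
    en <- rhythmEntropy(p)
    expect_gte(en, 0); expect_lte(en, log2(3) + 1e-12)
    # permutation symmetry
    expect_equal(en, rhythmEntropy(p[c(3, 1, 2)]), tolerance = 1e-12)
    # mixing toward uniform never decreases entropy
    ens <- vapply(seq(0, 1, by = 0.1), function(a)
      rhythmEntropy((1 - a) * p + a / 3), numeric(1))
    expect_true(all(diff(ens) >= -1e-12))
  }
})

test_that("entropy is invariant to overall amplitude scaling of the source", {
  set.seed(3)
  x <- simulateBandSource(c(0.6, 0.3, 0.1), 100, 500, 250, seed = 8)
  en <- function(sig) {
    pw <- vapply(list(c(4, 8), c(8, 13), c(13, 30)), function(b)
      rhenet:::fftBandPower(sig, 250, b[1], b[2]), numeric(1))
    rhythmEntropy(pw / sum(pw))
  }
  expect_equal(en(x), en(17.3 * x), tolerance = 1e-12)
})

mkSourceSet <- function(a, band, labels = rep(c("error", "correct"),
                                              length.out = dim(a)[1])) {
  methods::new("SourceSet", data = a, band = band, sfreq = 250,
               labels = factor(labels, levels = c("error", "correct")),
               rt = rep(500, dim(a)[1]))
}

test_that("feature extraction preserves trials and flags degenerate ones", {
  nT <- 4; nD <- 2; nS <- 50
  set.seed(2)
  mk <- function() array(rnorm(nT * nD * nS), c(nT, nD, nS))
  src <- list(theta = mkSourceSet(mk(), "theta"),
              alpha = mkSourceSet(mk(), "alpha"),
              beta = mkSourceSet(mk(), "beta"))
  ft <- rhythmEntropyFeatures(src)
  expect_equal(nTrials(ft), 4L)
  expect_equal(dim(featureValues(ft)), c(4L, 2L))
  expect_true(all(featureValues(ft) >= 0 & featureValues(ft) <= log2(3)))

  # zero out every band of trial 3, dipole 1 -> that trial is excluded
  for (b in names(src)) src[[b]]@data[3, 1, ] <- 0
  expect_warning(ft2 <- rhythmEntropyFeatures(src), "degenerate")
  expect_equal(nTrials(ft2), 3L)
  expect_equal(ft2@excluded, 3L)

  expect_error(rhythmEntropyFeatures(src[c("theta", "alpha")]), "beta")
})

test_that("features recover the analytic entropy of the generating proportions", {
  # band-structured source signals, decomposed by the band filters and fed
  # to the feature extractor: mean entropy close to the analytic value
  nT <- 6; nS <- 500
  buildFt <- function(props) {
    a <- array(0, c(nT, 1, nS))
    for (i in seq_len(nT))
      a[i, 1, ] <- simulateBandSource(props, nS, nS, 250, seed = 40 + i)
    ep <- epochSet(a, 250, rep(c("error", "correct"), 3))
    bands <- extractBands(ep)
    src <- lapply(names(bands), function(nm)
      mkSourceSet(epochData(bands[[nm]]), nm))
    names(src) <- names(bands)
    rhythmEntropyFeatures(src)
  }
  ftU <- buildFt(c(1, 1, 1) / 3)
  expect_equal(mean(featureValues(ftU)), log2(3), tolerance = 0.1)
  ftC <- buildFt(c(0.9, 0.05, 0.05))
  expect_equal(mean(featureValues(ftC)), rhythmEntropy(c(0.9, 0.05, 0.05)),
               tolerance = 0.15)
})
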