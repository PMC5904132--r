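mkEpochs <- function(mats, sfreq = 250, labels = NULL) {
  nT <- length(mats)
  if (is.null(labels)) labels <- rep(c("error", "correct"), length.out = nT)
  a <- array(0, c(nT, nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_len(nT)) a[i, , ] <- mats[[i]]
  epochSet(a, sfreq, labels, rt = 100 + seq_len(nT))
}

test_that("continuous recordings are epoched around events", {
  rec <- matrix(seq_len(2 * 1000), nrow = 2, byrow = TRUE)
  ep <- epochContinuous(rec, sfreq = 250, events = c(100L, 500L),
                        tmin = 0, tmax = 0.2, labels = c("error", "correct"))
  expect_equal(nTrials(ep), 2L)
  expect_equal(dim(epochData(ep))[3], 50L)       # 0.2 s at 250 Hz
  expect_equal(epochData(ep)[1, 1, 1], 100)
  expect_equal(epochData(ep)[2, 1, 1], 500)
  # pre-event window
  epPre <- epochContinuous(rec, 250, events = 500L, tmin = -0.1, tmax = 0.1)
  expect_equal(epochData(epPre)[1, 1, 1], 475)
  # events falling off the edge are dropped with a warning
  expect_warning(epEdge <- epochContinuous(rec, 250, events = c(990L, 500L),
                                           tmin = 0, tmax = 0.2),
                 "dropped")
  expect_equal(nTrials(epEdge), 1L)
  expect_error(suppressWarnings(
    epochContinuous(rec, 250, events = 999L, tmin = 0, tmax = 1)), "no events")
})

test_that("amplitude rejection removes transient-artifact trials only", {
  quiet <- matrix(5 * sin(seq(0, 10, length.out = 100)), 2, 100, byrow = TRUE)
  spike <- quiet; spike[1, 50] <- 80          # exceeds the +/-75 uV criterion
  ep <- mkEpochs(list(quiet, spike, quiet))
  out <- rejectArtifactTrials(ep, threshold = 75)
  expect_equal(nTrials(out), 2L)
  expect_equal(attr(out, "rejected"), 2L)
  # labels and reaction times stay aligned with survivors
  expect_equal(as.character(trialLabels(out)), c("error", "error"))
  expect_equal(reactionTimes(out), c(101, 103))

  # bounded input is untouched; infinite threshold is the identity
  expect_identical(epochData(rejectArtifactTrials(ep, 1000)), epochData(ep))
  expect_identical(epochData(rejectArtifactTrials(ep, Inf)), epochData(ep))

  expect_error(rejectArtifactTrials(ep, threshold = 0), "all trials")
})

test_that("band-pass filtering attenuates out-of-band content and keeps the passband", {
  t <- seq_len(500) / 250
  tone <- function(f) matrix(sin(2 * pi * f * t), 1, 500)
  p <- function(e) sum(epochData(e)^2)

  e50 <- bandpassEpochs(mkEpochs(list(tone(50))))
  expect_lt(p(e50) / sum(tone(50)^2), 0.01)

  e10 <- bandpassEpochs(mkEpochs(list(tone(10))))
  expect_equal(sqrt(p(e10) / sum(tone(10)^2)), 1, tolerance = 0.05)

  dc <- bandpassEpochs(mkEpochs(list(matrix(7, 1, 500))))
  expect_lt(abs(mean(epochData(dc))), 0.05)

  expect_error(bandpassEpochs(mkEpochs(list(tone(10))), low = 0.1, high = 200),
               "Nyquist")
})

test_that("average re-referencing zeroes channel means and is idempotent", {
  set.seed(2)
  ep <- mkEpochs(list(matrix(rnorm(300, mean = 4), 3, 100)))
  out <- rereference(ep, "average")
  expect_lt(max(abs(colMeans(epochData(out)[1, , ]))), 1e-10)
  expect_equal(epochData(rereference(out, "average")), epochData(out),
               tolerance = 1e-12)
  expect_error(rereference(ep, "rest"), "leadfield")
})

test_that("REST recovers infinity-referenced potentials better than the raw reference", {
  set.seed(9)
  lf <- makeLeadfield(32, 64, seed = 3)
  A <- gainMatrix(lf)
  corRaw <- corRest <- numeric(15)
  for (tr in seq_len(15)) {
    S <- matrix(rnorm(64 * 120), 64, 120)
    vInf <- A %*% S
    vRef <- sweep(vInf, 2, vInf[10, ], "-")   # recorded against channel 10
    ep <- epochSet(array(vRef, c(1, 32, 120)), 250, "error")
    rest <- rereference(ep, "rest", leadfield = lf)
    corRaw[tr] <- cor(as.vector(vRef), as.vector(vInf))
    corRest[tr] <- cor(as.vector(epochData(rest)[1, , ]), as.vector(vInf))
  }
  expect_gt(mean(corRest), mean(corRaw))
  expect_gt(mean(corRest), 0.9)
})

test_that("band decomposition routes tones to their band and conserves broadband power", {
  t <- seq_len(500) / 250
  dominantBand <- function(f) {
    ep <- mkEpochs(list(matrix(sin(2 * pi * f * t), 1, 500)))
    bands <- extractBands(ep)
    pw <- vapply(bands, function(b) sum(epochData(b)^2), numeric(1))
    names(which.max(pw))
  }
  expect_equal(dominantBand(6), "theta")
  expect_equal(dominantBand(10), "alpha")
  expect_equal(dominantBand(20), "beta")

  # 10 Hz tone: at least 90% of the output energy is in the alpha copy
  ep <- mkEpochs(list(matrix(sin(2 * pi * 10 * t), 1, 500)))
  bands <- extractBands(ep)
  pw <- vapply(bands, function(b) sum(epochData(b)^2), numeric(1))
  expect_gt(pw["alpha"] / sum(pw), 0.9)

  # white noise: band powers sum to the 4-30 Hz total within leakage tolerance
  set.seed(5)
  wn <- matrix(rnorm(500), 1, 500)
  bands <- extractBands(mkEpochs(list(wn)))
  total <- rhenet:::fftBandPower(wn[1, ], 250, 4, 30, rightClosed = TRUE)
  bandSum <- sum(vapply(bands, function(b) sum(epochData(b)^2), numeric(1)))
  expect_equal(bandSum / total, 1, tolerance = 0.1)
})

test_that("filters are zero-phase: no lag between band-limited input and output", {
  set.seed(1)
  x <- rhenet:::bandLimitedNoise(500, 250, 8, 13)
  y <- epochData(extractBands(mkEpochs(list(matrix(x, 1, 500))))$alpha)[1, 1, ]
  cc <- ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})
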