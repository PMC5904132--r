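mkFit <- function(coeffs, Tn, uc = 1e-3, sfreq = 250) {
  # constant-coefficient MVAARFit built directly (no fitting)
  d <- dim(coeffs)
  arr <- array(0, c(d[1], d[2], d[3], Tn))
  for (t in seq_len(Tn)) arr[, , , t] <- coeffs
  methods::new("MVAARFit", coeffs = arr, order = dim(coeffs)[3],
               uc = uc, residuals = matrix(0, d[1], Tn),
               nodeNames = sprintf("node%d", seq_len(d[1])), sfreq = sfreq)
}

test_that("region averaging follows its definition", {
  S <- rbind(sin(1:50), sin(1:50), -sin(1:50), cos(1:50))
  out <- regionTimeSeries(S, list(a = 4L))
  expect_equal(out[1, ], cos(1:50))                      # single dipole
  expect_equal(regionTimeSeries(S, list(b = c(1L, 2L)))[1, ], sin(1:50))
  expect_equal(max(abs(regionTimeSeries(S, list(c = c(1L, 3L))))), 0)  # antiphase
  expect_error(regionTimeSeries(S, list(integer(0))), "non-empty")
  expect_error(regionTimeSeries(S, list(1:2, 2:3)), "disjoint")
})

test_that("Kalman MVAAR recovers time-invariant coefficients", {
  co <- array(0, c(2, 2, 1))
  co[1, 1, 1] <- 0.3; co[2, 2, 1] <- 0.3; co[2, 1, 1] <- 0.5
  sim <- simulateMvarNodes(co, 2000, seed = 4)
  fit <- fitMvaarKalman(sim$series, p = 1, uc = 1e-3)
  avg <- apply(coefArray(fit)[, , 1, 501:2000], c(1, 2), mean)
  expect_equal(avg[2, 1], 0.5, tolerance = 0.1)
  expect_equal(avg[1, 2], 0, tolerance = 0.1)

  # independent white noise: all cross terms near zero
  set.seed(5)
  wn <- matrix(rnorm(2 * 1500), 2, 1500)
  avgW <- apply(coefArray(fitMvaarKalman(wn, 1))[, , 1, 301:1500], c(1, 2), mean)
  expect_lt(max(abs(avgW[row(avgW) != col(avgW)])), 0.1)

  # deterministic
  expect_identical(coefArray(fitMvaarKalman(sim$series, 1)),
                   coefArray(fitMvaarKalman(sim$series, 1)))
  expect_error(fitMvaarKalman(matrix(c(1, NA, 1, 1), 2, 2), 1), "finite")
  expect_error(fitMvaarKalman(wn[, 1:15], 1), "too short")
})

test_that("SBC selects the generating VAR order", {
  co <- array(0, c(3, 3, 2))
  diag(co[, , 1]) <- 0.4; co[2, 1, 1] <- 0.3; diag(co[, , 2]) <- 0.3
  hits <- vapply(1:10, function(s)
    selectOrderSbc(simulateMvarNodes(co, 3000, seed = 50 + s)$series, 5) == 2L,
    logical(1))
  expect_gte(mean(hits), 0.8)

  set.seed(2)
  small <- vapply(1:6, function(s)
    selectOrderSbc(matrix(rnorm(2 * 800), 2, 800), 4), integer(1))
  expect_gt(mean(small == 1L), 0.5)       # white noise: smallest order wins
  expect_true(all(small >= 1L & small <= 4L))
  expect_error(selectOrderSbc(matrix(rnorm(20), 2, 10), 4), "too short")
})

test_that("transfer function honours its closed-form cases", {
  # no dynamics: H is the identity at every frequency and time
  H0 <- transferFunction(mkFit(array(0, c(2, 2, 1)), Tn = 4))
  expect_equal(max(abs(H0[1, 2, , ])), 0)
  expect_equal(max(abs(H0[1, 1, , ] - 1)), 0)

  # decoupled diagonal AR: off-diagonal H stays zero
  coD <- array(0, c(2, 2, 1)); diag(coD[, , 1]) <- 0.5
  HD <- transferFunction(mkFit(coD, Tn = 3))
  expect_equal(max(Mod(HD[1, 2, , ])), 0)
  expect_equal(max(Mod(HD[2, 1, , ])), 0)

  # coupled 1 -> 2: driven direction carries transfer, reverse does not;
  # oracle: H = (I - w e^{-i 2 pi f / fs})^-1 computed independently per f
  co <- array(0, c(2, 2, 1)); diag(co[, , 1]) <- 0.4; co[2, 1, 1] <- 0.5
  fit <- mkFit(co, Tn = 2)
  H <- transferFunction(fit, freqs = c(5, 10, 20))
  for (fi in seq_along(c(5, 10, 20))) {
    f <- c(5, 10, 20)[fi]
    Ho <- solve(diag(2) - co[, , 1] * exp(-2i * pi * f / 250))
    expect_equal(H[, , fi, 1], Ho, tolerance = 1e-12)
  }
  expect_gt(min(Mod(H[2, 1, , ])), 0)
  expect_equal(max(Mod(H[1, 2, , ])), 0)
})

test_that("ADTF normalization makes receiver rows sum to one", {
  set.seed(6)
  H <- array(complex(real = rnorm(3 * 3 * 4 * 5), imaginary = rnorm(180)),
             c(3, 3, 4, 5))
  io <- adtfNormalize(H)
  expect_equal(as.vector(apply(io, c(1, 3, 4), sum)), rep(1, 60),
               tolerance = 1e-10)
  expect_true(all(io >= 0 & io <= 1))

  # two-line independent oracle
  oracle <- Mod(H)^2
  for (i in 1:3) for (f in 1:4) for (t in 1:5)
    oracle[i, , f, t] <- oracle[i, , f, t] / sum(Mod(H[i, , f, t])^2)
  expect_equal(io, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # identity H: diagonal pattern
  Hi <- array(0i, c(2, 2, 1, 1)); Hi[1, 1, 1, 1] <- 1 + 0i; Hi[2, 2, 1, 1] <- 1 + 0i
  expect_equal(Re(adtfNormalize(Hi)[, , 1, 1]), diag(2), ignore_attr = TRUE)
})

test_that("band integration averages in-band bins", {
  io <- array(0.25, c(2, 2, 10, 3))
  expect_equal(integrateAdtf(io, freqs = 1:10, f1 = 2, f2 = 7),
               array(0.25, c(2, 2, 3)), tolerance = 1e-12)
  io2 <- array(rep(c(0, 1), each = 2 * 2 * 5), c(2, 2, 10, 1))
  expect_equal(as.vector(integrateAdtf(io2, freqs = 1:10, f1 = 1, f2 = 10)),
               rep(0.5, 4))
  expect_error(integrateAdtf(io, freqs = 1:10, f1 = 50, f2 = 60), "no frequency")
})

test_that("the fused integrated-ADTF path equals the composed one", {
  co <- array(0, c(3, 3, 1))
  diag(co[, , 1]) <- 0.4; co[2, 1, 1] <- 0.3; co[3, 2, 1] <- 0.3
  sim <- simulateMvarNodes(co, 400, seed = 3)
  fit <- fitMvaarKalman(sim$series, p = 1)
  composed <- integrateAdtf(adtfNormalize(transferFunction(fit)))
  fused <- rhenet:::integratedAdtfFromFit(fit)
  expect_equal(composed, fused, tolerance = 1e-12)
  expect_true(all(fused >= 0 & fused <= 1))
})

test_that("phase-randomized surrogates preserve per-node amplitude spectra", {
  set.seed(8)
  X <- matrix(rnorm(3 * 501), 3, 501)       # odd length exercises symmetry
  Xs <- phaseRandomize(X, seed = 4)
  for (i in 1:3) {
    expect_lt(max(abs(Mod(fft(Xs[i, ])) - Mod(fft(X[i, ])))) /
                max(Mod(fft(X[i, ]))), 1e-8)
  }
  expect_true(is.numeric(Xs))
  # even length too
  Xe <- matrix(rnorm(2 * 400), 2, 400)
  Xse <- phaseRandomize(Xe, seed = 5)
  expect_lt(max(abs(Mod(fft(Xse[1, ])) - Mod(fft(Xe[1, ])))), 1e-6)
})

test_that("surrogate thresholds detect a planted coupling and not its reverse", {
  co <- array(0, c(2, 2, 1)); diag(co[, , 1]) <- 0.5; co[2, 1, 1] <- 0.6
  sim <- simulateMvarNodes(co, 1500, seed = 6)
  net <- computeTvNetwork(sim$series, p = 1, nSurrogates = 50, seed = 9)
  keep <- (net@burnIn + 1):1500
  sig <- significantEdges(net)
  expect_gte(mean(sig[2, 1, keep]), 0.8)    # true edge 1 -> 2
  expect_lt(mean(sig[1, 2, keep]), 0.5)     # reverse direction
})

test_that("net flow is an antisymmetric difference", {
  expect_equal(netFlow(0.4, 0.4), 0)
  expect_equal(netFlow(0.6, 0.2), 0.4)
  expect_equal(netFlow(0.2, 0.6), -netFlow(0.6, 0.2))
})
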