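# Shared fixtures built in code: a small analysis wrapper used by several
# test files, plus simple utilities.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Simulate one dataset and run it through preprocessing, inversion and
# feature extraction (the front half of the pipeline).
datasetFeatures <- function(cfg) {
  ds <- simulateDataset(cfg)
  e <- rereference(bandpassEpochs(rejectArtifactTrials(ds$epochs)))
  bands <- extractBands(e)
  inv <- computeInverseOperator(ds$leadfield, snr = 5)
  src <- lapply(names(bands), function(nm) applyInverse(inv, bands[[nm]], band = nm))
  names(src) <- names(bands)
  list(ds = ds, features = rhythmEntropyFeatures(src))
}

# LOOCV with per-fold R-squared dipole selection at `frac`.
classifySelected <- function(features, frac = 0.6, seed = 5L) {
  loocvRbfSvm(featureValues(features), trialLabels(features),
              selector = function(X, y)
                selectDipoles(rhenet:::r2PerColumn(X, y), frac),
              seed = seed)
}

# Wrap a plain matrix of per-trial per-dipole values as a FeatureTable.
# Values must be valid entropies (in [0, log2 3]).
asFeatureTable <- function(values, labels, rt = rep(500, nrow(values))) {
  methods::new("FeatureTable",
               values = values,
               labels = factor(labels, levels = c("error", "correct")),
               rt = rt,
               bandPowers = array(1, c(nrow(values), ncol(values), 3L)),
               excluded = integer(0))
}

# Cache for results shared across acceptance blocks within one run.
.acceptanceCache <- new.env(parent = emptyenv())
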