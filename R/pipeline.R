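#' Pipeline run configuration
#'
#' Aggregates every stage parameter of the end-to-end analysis with the
#' method's conventional defaults: amplitude rejection at 75 uV, 0.1-30 Hz
#' band-pass, assumed inverse SNR 5, selection threshold 0.6 of the maximum
#' R-squared, the 21-value penalty grid, Kalman update coefficient 1e-3 and
#' 200 phase-randomized surrogates.
#'
#' @param sim a [SimConfig-class] describing the synthetic dataset.
#' @param rejectUv artifact rejection threshold (uV).
#' @param bandLow,bandHigh broadband filter edges (Hz).
#' @param reref re-referencing method (\code{"average"} or \code{"rest"}).
#' @param snr assumed SNR of the inverse operator.
#' @param thresholdFrac R-squared selection threshold fraction.
#' @param nested nested (per-fold) grid search for C.
#' @param perFoldSelection recompute dipole selection in each LOOCV fold.
#' @param uc Kalman update coefficient.
#' @param nSurrogates surrogate count for network significance (0 disables).
#' @param maxNodes maximum number of network nodes (top dipoles by R-squared).
#' @return A list of class \code{"rhenetRunConfig"}; serializes losslessly
#'   through [writeRunConfig()] / [readRunConfig()].
#' @export
runConfig <- function(sim = simConfig(), rejectUv = 75, bandLow = 0.1,
                      bandHigh = 30, reref = "average", snr = 5,
                      thresholdFrac = 0.6, nested = TRUE,
                      perFoldSelection = TRUE, uc = 1e-3, nSurrogates = 200L,
                      maxNodes = 3L) {
  structure(list(sim = sim, rejectUv = rejectUv, bandLow = bandLow,
                 bandHigh = bandHigh, reref = reref, snr = snr,
                 thresholdFrac = thresholdFrac, nested = nested,
                 perFoldSelection = perFoldSelection, uc = uc,
                 nSurrogates = as.integer(nSurrogates),
                 maxNodes = as.integer(maxNodes)),
            class = "rhenetRunConfig")
}

#' Serialize / restore a run configuration
#'
#' @param config a \code{rhenetRunConfig} from [runConfig()].
#' @param path JSON file path.
#' @return \code{readRunConfig} returns the restored config;
#'   \code{writeRunConfig} returns \code{path} invisibly.
#' @export
writeRunConfig <- function(config, path) {
  simSlots <- methods::slotNames("SimConfig")
  sim <- lapply(simSlots, function(s) methods::slot(config$sim, s))
  names(sim) <- simSlots
  obj <- config
  obj$sim <- sim
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- obj$sim
  sim <- simConfig(nChannels = s$nChannels, nDipoles = s$nDipoles,
                   sfreq = s$sfreq, epochLen = s$epochLen,
                   nTrialsPerClass = s$nTrialsPerClass,
                   activeDipoles = s$activeDipoles,
                   bandPropsError = s$bandPropsError,
                   bandPropsCorrect = s$bandPropsCorrect,
                   sensorSnr = s$sensorSnr,
                   backgroundLevel = s$backgroundLevel,
                   rtModel = lapply(s$rtModel, as.numeric),
                   seed = s$seed)
  runConfig(sim = sim, rejectUv = obj$rejectUv, bandLow = obj$bandLow,
            bandHigh = obj$bandHigh, reref = obj$reref, snr = obj$snr,
            thresholdFrac = obj$thresholdFrac, nested = obj$nested,
            perFoldSelection = obj$perFoldSelection, uc = obj$uc,
            nSurrogates = obj$nSurrogates, maxNodes = obj$maxNodes)
}

#' Run the full synthetic end-to-end analysis
#'
#' Executes the seven pipeline stages -- simulate, preprocess, invert,
#' features, classify, network, stats -- writing per-stage outputs and a
#' manifest (parameter echo, seeds, per-stage timing) to \code{outDir}.
#' Re-running with an identical configuration reproduces every output
#' exactly: all randomness derives from the config seed.
#'
#' @param config a \code{rhenetRunConfig} from [runConfig()].
#' @param outDir output directory (created if missing); NULL skips writing.
#' @return Invisibly, a list with the stage results: \code{epochs},
#'   \code{truth}, \code{features}, \code{r2map}, \code{eval},
#'   \code{networks} (per class), \code{stats} and \code{manifest}.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  stopifnot(inherits(config, "rhenetRunConfig"))
  stages <- character(0)
  timing <- numeric(0)
  tick <- function(name, expr) {
    t0 <- proc.time()[[3L]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    timing <<- c(timing, proc.time()[[3L]] - t0)
    res
  }
  sim <- config$sim

  ds <- tick("simulate", simulateDataset(sim))

  epochs <- tick("preprocess", {
    e <- bandpassEpochs(ds$epochs, low = config$bandLow, high = config$bandHigh)
    e <- rejectArtifactTrials(e, threshold = config$rejectUv)
    rereference(e, method = config$reref,
                leadfield = if (config$reref == "rest") ds$leadfield else NULL)
  })

  inv <- tick("invert", computeInverseOperator(ds$leadfield, snr = config$snr))
  bands <- extractBands(epochs)
  sources <- lapply(names(bands), function(nm)
    applyInverse(inv, bands[[nm]], band = nm))
  names(sources) <- names(bands)

  features <- tick("features", {
    ft <- rhythmEntropyFeatures(sources)
    balanceClasses(ft, seed = childSeed(sim@seed, 11L))
  })

  clf <- tick("classify", {
    r2map <- computeR2Map(features, thresholdFrac = config$thresholdFrac)
    sel <- if (config$perFoldSelection)
      function(Xtr, ytr) selectDipoles(r2PerColumn(Xtr, ytr),
                                       config$thresholdFrac)
    else NULL
    Xall <- if (config$perFoldSelection) features@values
            else features@values[, r2map@selected, drop = FALSE]
    eval <- loocvRbfSvm(Xall, features@labels, selector = sel,
                        nested = config$nested,
                        seed = childSeed(sim@seed, 12L))
    list(r2map = r2map, eval = eval)
  })

  networks <- tick("network", {
    nodes <- clf$r2map@selected[
      order(clf$r2map@r2[clf$r2map@selected], decreasing = TRUE)]
    nodes <- sort(utils::head(nodes, config$maxNodes))
    regions <- as.list(nodes)
    names(regions) <- sprintf("dip%03d", nodes)
    out <- list()
    for (cls in levels(epochs@labels)) {
      idx <- which(epochs@labels == cls)
      erp <- apply(epochs@data[idx, , , drop = FALSE], c(2L, 3L), mean)
      src <- inv@W %*% erp
      series <- regionTimeSeries(src, regions)
      out[[cls]] <- computeTvNetwork(series, sfreq = epochs@sfreq,
                                     uc = config$uc,
                                     nSurrogates = config$nSurrogates,
                                     seed = childSeed(sim@seed, 13L))
    }
    out
  })

  statsRes <- tick("stats", {
    meanEn <- rowMeans(features@values[, clf$r2map@selected, drop = FALSE])
    res <- list()
    for (cls in c("error", "correct")) {
      idx <- which(features@labels == cls)
      res[[paste0("rt_vs_entropy_", cls)]] <-
        tryCatch(pearsonRtEntropy(features@rt[idx], meanEn[idx]),
                 error = function(e) NULL)
    }
    res$meanEntropy <- tapply(meanEn, features@labels, mean)
    res
  })

  manifest <- list(
    package = "rhenet",
    version = as.character(utils::packageVersion("rhenet")),
    seed = sim@seed,
    stages = stages,
    timingSec = round(timing, 3),
    parameters = list(rejectUv = config$rejectUv,
                      band = c(config$bandLow, config$bandHigh),
                      reref = config$reref, snr = config$snr,
                      thresholdFrac = config$thresholdFrac,
                      nested = config$nested,
                      perFoldSelection = config$perFoldSelection,
                      uc = config$uc, nSurrogates = config$nSurrogates,
                      cGrid = defaultCGrid())
  )

  result <- list(epochs = epochs, truth = ds$truth, features = features,
                 r2map = clf$r2map, eval = clf$eval, networks = networks,
                 stats = statsRes, manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRunConfig(config, file.path(outDir, "config.json"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    ft <- features
    utils::write.csv(
      data.frame(trial = seq_len(nTrials(ft)), label = ft@labels, rt = ft@rt,
                 ft@values), file.path(outDir, "features.csv"),
      row.names = FALSE)
    utils::write.csv(
      data.frame(dipole = seq_along(clf$r2map@r2), r2 = clf$r2map@r2,
                 selected = seq_along(clf$r2map@r2) %in% clf$r2map@selected,
                 projected = clf$r2map@projected),
      file.path(outDir, "selection.csv"), row.names = FALSE)
    ev <- clf$eval
    jsonlite::write_json(
      list(ca = ev@ca, se = ev@se, sp = ev@sp, auc = ev@auc,
           confusion = as.list(ev@confusion)),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    edges <- do.call(rbind, lapply(names(networks), function(cls) {
      net <- networks[[cls]]
      n <- length(net@nodeNames); Tn <- dim(net@integrated)[3L]
      do.call(rbind, lapply(seq_len(n), function(i)
        do.call(rbind, lapply(setdiff(seq_len(n), i), function(j)
          data.frame(class = cls, from = net@nodeNames[j],
                     to = net@nodeNames[i], time = seq_len(Tn),
                     adtf = net@integrated[i, j, ],
                     null95 = if (length(net@nullThresholds))
                       net@nullThresholds[i, j] else NA_real_,
                     significant = if (length(net@significant))
                       net@significant[i, j, ] else NA)))))
    }))
    utils::write.csv(edges, file.path(outDir, "network_edges.csv"),
                     row.names = FALSE)
    statRows <- do.call(rbind, lapply(c("error", "correct"), function(cls) {
      a <- statsRes[[paste0("rt_vs_entropy_", cls)]]
      data.frame(statistic = paste0("rt_vs_entropy_", cls),
                 r = if (is.null(a)) NA_real_ else a@r,
                 t = if (is.null(a)) NA_real_ else a@t,
                 p = if (is.null(a)) NA_real_ else a@p,
                 n = if (is.null(a)) NA_integer_ else a@n,
                 meanEntropy = unname(statsRes$meanEntropy[cls]))
    }))
    statRows$nTestsPerformed <- sum(!is.na(statRows$p))
    utils::write.csv(statRows, file.path(outDir, "stats.csv"),
                     row.names = FALSE)
  }
  invisible(result)
}
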