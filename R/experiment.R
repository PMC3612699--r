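#' Run a reproducible experiment from a configuration
#'
#' Drives the full pipeline for one of four experiment kinds, writing every
#' artifact (config echo, manifests, training logs, result CSVs, an RDS
#' checkpoint of the trained model) to an output directory so the run is
#' fully regenerable from the echoed config alone.
#'
#' Kinds:
#' \describe{
#'   \item{baseline}{train and report train/test accuracy at the three vote
#'     modes (none / vote2d / full).}
#'   \item{occlusion}{train the recurrent and both backprop networks and
#'     sweep occlusion levels (recurrent evaluated intact and
#'     feedback-lesioned).}
#'   \item{semantics}{train with and without semantic clamping and report
#'     the IT distance matrices and their correlations with the target.}
#'   \item{completion}{per-cycle completion trajectories at the configured
#'     occlusion levels, intact vs feedback-lesioned.}
#' }
#'
#' @param config A named list or the path of a YAML file. Recognized fields
#'   (with defaults): \code{kind}, \code{seed}, \code{outDir}, \code{dataset}
#'   (arguments of \code{\link{syntheticDatasetSpec}}), \code{network}
#'   (\code{v2Size}, \code{itSize}, \code{semSize}, \code{kwtaPct}),
#'   \code{frontend} (\code{nOrientations}, \code{nScales}, \code{filterSize},
#'   \code{poolSize}), \code{train} (arguments of \code{\link{trainProtocol}}
#'   plus \code{nTestExemplars}), \code{occlusionLevels}, \code{voteMode},
#'   \code{semantics} (\code{units}, \code{pctActive}, \code{clusters},
#'   \code{within}, \code{between}, \code{shapeIters}).
#' @return Invisibly, the output directory path; results are also returned
#'   in \code{attr(, "results")}.
#' @export
runExperiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg[setdiff(names(cfg), "outDir")],
                   file.path(cfg$outDir, "config.yaml"))

  ds <- makeSyntheticDataset(do.call(syntheticDatasetSpec,
                                     c(cfg$dataset, list(seed = cfg$seed))))
  writeManifest(ds$manifest, file.path(cfg$outDir, "manifest.csv"))
  split <- splitTrainTest(ds$manifest, cfg$train$nTestExemplars,
                          seed = mixSeed(cfg$seed, 2))
  bank <- do.call(buildFilterBank, cfg$frontend)
  protocol <- trainProtocol(epochs = cfg$train$epochs, lrate = cfg$train$lrate,
                            hebbMix = cfg$train$hebbMix,
                            useSemantics = identical(cfg$kind, "semantics"),
                            stopAccuracy = cfg$train$stopAccuracy,
                            seed = mixSeed(cfg$seed, 3))
  semCfg <- cfg$semantics
  patterns <- NULL; target <- NULL
  needSem <- cfg$kind %in% c("semantics", "completion")
  if (needSem || !is.null(cfg$network$semSize)) {
    target <- makeTargetDM(length(ds$categories), semCfg$clusters,
                           within = semCfg$within, between = semCfg$between,
                           seed = mixSeed(cfg$seed, 4))
    patterns <- shapePatterns(
      initPatterns(length(ds$categories), semCfg$units, semCfg$pctActive,
                   seed = mixSeed(cfg$seed, 5)),
      target, maxIters = semCfg$shapeIters, seed = mixSeed(cfg$seed, 6))
    cfg$network$semSize <- semCfg$units
  }
  spec <- kwtaNetworkSpec(bank, ds$spec$imageSize, ds$categories,
                          v2Size = cfg$network$v2Size,
                          itSize = cfg$network$itSize,
                          semSize = cfg$network$semSize,
                          kwtaPct = cfg$network$kwtaPct)
  results <- switch(cfg$kind,
    baseline = runBaseline(cfg, ds, split, spec, protocol),
    occlusion = runOcclusion(cfg, ds, split, spec, protocol, bank),
    semantics = runSemantics(cfg, ds, split, spec, protocol, patterns, target),
    completion = runCompletion(cfg, ds, split, spec, protocol, patterns))
  invisible(structure(cfg$outDir, results = results))
}

validateConfig <- function(config) {
  defaults <- list(
    kind = "baseline", seed = 1, outDir = "revis-run",
    dataset = list(nCategories = 5, exemplarsPerCategory = 3,
                   rendersPerExemplar = 2, imageSize = 24),
    frontend = list(nOrientations = 4, nScales = 2, filterSize = 7,
                    poolSize = 4),
    network = list(v2Size = 120, itSize = 80, semSize = NULL, kwtaPct = 0.15),
    train = list(epochs = 15, lrate = 0.1, hebbMix = 0.01,
                 nTestExemplars = 1, stopAccuracy = NULL),
    occlusionLevels = c(0, 0.25, 0.5),
    voteMode = "vote2d",
    semantics = list(units = 40, pctActive = 0.25, clusters = 2,
                     within = 0.6, between = 0.2, shapeIters = 1500))
  problems <- character()
  for (nm in names(config)) if (!nm %in% names(defaults))
    problems <- c(problems, paste0("unknown config field: ", nm))
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  if (!cfg$kind %in% c("baseline", "occlusion", "semantics", "completion"))
    problems <- c(problems, paste0("unknown kind: ", cfg$kind))
  if (cfg$dataset$exemplarsPerCategory <= cfg$train$nTestExemplars)
    problems <- c(problems,
                  "exemplarsPerCategory must exceed nTestExemplars")
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  cfg
}

trainRecurrent <- function(cfg, ds, split, spec, protocol, patterns = NULL) {
  net <- buildNetwork(spec, seed = mixSeed(cfg$seed, 10))
  trainNetwork(net, ds, split$train, protocol, patterns = patterns)
}

runBaseline <- function(cfg, ds, split, spec, protocol) {
  tr <- trainRecurrent(cfg, ds, split, spec, protocol)
  write.csv(tr$log, file.path(cfg$outDir, "train_log.csv"), row.names = FALSE)
  saveRDS(tr$net, file.path(cfg$outDir, "checkpoint.rds"))
  rows <- do.call(rbind, lapply(c("none", "vote2d", "full"), function(vm) {
    data.frame(voteMode = vm,
      trainAcc = as.numeric(evaluateAccuracy(tr$net, ds, split$train, vm,
                                             seed = mixSeed(cfg$seed, 20))),
      testAcc = as.numeric(evaluateAccuracy(tr$net, ds, split$test, vm,
                                            seed = mixSeed(cfg$seed, 21))))
  }))
  write.csv(rows, file.path(cfg$outDir, "accuracy.csv"), row.names = FALSE)
  rows
}

runOcclusion <- function(cfg, ds, split, spec, protocol, bank) {
  tr <- trainRecurrent(cfg, ds, split, spec, protocol)
  bps <- trainBpNetwork(
    buildBpNetwork("sparse", bank, ds$spec$imageSize, ds$categories,
                   v2Size = cfg$network$v2Size, itSize = cfg$network$itSize,
                   kwtaPct = cfg$network$kwtaPct,
                   seed = mixSeed(cfg$seed, 11)),
    ds, split$train, epochs = protocol$epochs, seed = protocol$seed)
  bpd <- trainBpNetwork(
    buildBpNetwork("distrib", bank, ds$spec$imageSize, ds$categories,
                   v2Size = cfg$network$v2Size, itSize = cfg$network$itSize,
                   seed = mixSeed(cfg$seed, 12)),
    ds, split$train, epochs = protocol$epochs, seed = protocol$seed)
  models <- list(recurrent = tr$net, noFeedback = lesionFeedback(tr$net),
                 bpSparse = bps$bp, bpDistrib = bpd$bp)
  sweep <- occlusionSweep(models, ds, split$train,
                          levels = cfg$occlusionLevels,
                          seed = mixSeed(cfg$seed, 30))
  write.csv(sweep, file.path(cfg$outDir, "occlusion_sweep.csv"),
            row.names = FALSE)
  saveRDS(models, file.path(cfg$outDir, "checkpoint.rds"))
  sweep
}

runSemantics <- function(cfg, ds, split, spec, protocol, patterns, target) {
  withSem <- trainRecurrent(cfg, ds, split, spec, protocol, patterns)
  protNo <- protocol; protNo$useSemantics <- FALSE
  noSem <- trainRecurrent(cfg, ds, split, spec, protNo)
  evalMan <- if (nrow(split$test)) split$test else split$train
  dmWith <- categoryDM(withSem$net, ds, evalMan)
  dmWithout <- categoryDM(noSem$net, ds, evalMan)
  res <- list(
    dmWith = dmWith, dmWithout = dmWithout, target = target,
    correlations = data.frame(
      comparison = c("withSemantics_vs_target", "withoutSemantics_vs_target",
                     "with_vs_without"),
      r = c(dmCorrelation(dmWith, target), dmCorrelation(dmWithout, target),
            dmCorrelation(dmWith, dmWithout))))
  write.csv(res$correlations, file.path(cfg$outDir, "dm_correlations.csv"),
            row.names = FALSE)
  write.csv(dmWith, file.path(cfg$outDir, "dm_with_semantics.csv"))
  write.csv(dmWithout, file.path(cfg$outDir, "dm_without_semantics.csv"))
  saveRDS(list(withSem = withSem$net, noSem = noSem$net),
          file.path(cfg$outDir, "checkpoint.rds"))
  res
}

runCompletion <- function(cfg, ds, split, spec, protocol, patterns) {
  tr <- trainRecurrent(cfg, ds, split, spec, protocol, patterns)
  lesioned <- lesionFeedback(tr$net)
  evalMan <- if (nrow(split$test)) split$test else split$train
  rows <- do.call(rbind, lapply(cfg$occlusionLevels, function(O)
    do.call(rbind, lapply(seq_len(min(nrow(evalMan), 10)), function(i) {
      img <- renderImage(ds, evalMan[i, ])
      s <- mixSeed(cfg$seed, 40, i)
      intact <- completionTrajectory(tr$net, img, O, occlusionSeed = s)
      les <- completionTrajectory(lesioned, img, O, occlusionSeed = s)
      rbind(cbind(model = "recurrent", item = i, O = O, intact),
            cbind(model = "noFeedback", item = i, O = O, les))
    }))))
  write.csv(rows, file.path(cfg$outDir, "completion_trajectories.csv"),
            row.names = FALSE)
  saveRDS(tr$net, file.path(cfg$outDir, "checkpoint.rds"))
  rows
}
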