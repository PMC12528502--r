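# End-to-end experiment orchestration: phantom cohort -> preprocessing ->
# DRRs -> four-way loss ablation -> masked evaluation -> statistical
# comparison, with every artifact reconstructible from (config, seed).

#' Default experiment configuration
#'
#' A nested configuration covering every stage; any sub-field can be
#' overridden. Can be serialized to/read from YAML.
#'
#' @param nPatients cohort size.
#' @param gridShape phantom grid.
#' @param nFractions fractions per patient.
#' @param variant model variant.
#' @param baseChannels,nLevels model size.
#' @param epochs training epochs.
#' @param seed global seed, propagated to every stage.
#' @param outDir artifact directory.
#' @return A list of class \code{"experimentConfig"}.
#' @export
experimentConfig <- function(nPatients = 4L, gridShape = c(32L, 32L, 16L),
                             nFractions = 3L, variant = "fusion_skip_res",
                             baseChannels = 8L, nLevels = 3L, epochs = 3L,
                             seed = 1L, outDir = tempfile("orthocbct_")) {
  structure(list(
    seed = as.integer(seed),
    outDir = outDir,
    phantom = list(nPatients = as.integer(nPatients),
                   gridShape = as.integer(gridShape),
                   nFractions = as.integer(nFractions),
                   splitFractions = c(0.5, 0.25, 0.25)),
    model = list(variant = variant, baseChannels = as.integer(baseChannels),
                 nLevels = as.integer(nLevels)),
    train = list(epochs = as.integer(epochs)),
    feature = list(seed = 7L, baseChannels = 4L)),
    class = "experimentConfig")
}

#' @rdname experimentConfig
#' @param path YAML file with the same nesting.
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- experimentConfig()
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

#' Run a full experiment
#'
#' Generates the phantom cohort (writing NIfTI volumes and the manifest),
#' trains the configured architecture under all four loss configurations
#' from identical initial weights, evaluates each on the test split, runs
#' the statistical comparison on mMAE, and writes histories, checkpoints,
#' metric reports, the comparison table and a provenance record to the
#' output directory.
#'
#' @param config an \code{\link{experimentConfig}} (or YAML path).
#' @return List with \code{cohort}, \code{ablation}, \code{comparison} and
#'   \code{dir}, invisibly.
#' @export
runExperiment <- function(config = experimentConfig()) {
  if (is.character(config)) config <- readExperimentConfig(config)
  stopifnot(inherits(config, "experimentConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    cat(sprintf("[%s] %s done in %.1fs\n", format(Sys.time(), "%H:%M:%S"),
                name, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  ph <- config$phantom
  cohort <- stage("phantom", {
    spec <- phantomSpec(gridShape = ph$gridShape, nFractions = ph$nFractions)
    makeCohort(spec, ph$nPatients, splitFractions = ph$splitFractions,
               seed = config$seed, outDir = file.path(config$outDir, "cohort"))
  })

  mcfg <- modelConfig(config$model$variant, inShape3d = ph$gridShape,
                      baseChannels = config$model$baseChannels,
                      nLevels = config$model$nLevels)
  tcfg <- trainConfig(epochs = config$train$epochs, seed = config$seed)
  fspec <- featureExtractorSpec(seed = config$feature$seed,
                                baseChannels = config$feature$baseChannels)

  abl <- stage("ablation", runAblation(cohort, mcfg, tcfg, fspec))

  for (nm in names(abl$runs)) {
    tag <- gsub("[^A-Za-z]", "", nm)
    hist <- abl$runs[[nm]]$history
    con <- file(file.path(config$outDir, sprintf("history_%s.jsonl", tag)), "w")
    for (i in seq_len(nrow(hist)))
      writeLines(jsonlite::toJSON(as.list(hist[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    close(con)
    saveCheckpoint(abl$runs[[nm]]$best,
                   file.path(config$outDir, sprintf("ckpt_%s.R", tag)))
    utils::write.csv(abl$perCase[[nm]],
                     file.path(config$outDir, sprintf("metrics_%s.csv", tag)),
                     row.names = FALSE)
  }
  utils::write.csv(abl$summary, file.path(config$outDir, "summary.csv"),
                   row.names = FALSE)

  cmp <- stage("comparison", {
    tables <- lapply(abl$perCase, function(df) df$mmae)
    compareLosses(tables)
  })
  jsonlite::write_json(
    list(groups = cmp@groups, omnibus_p = cmp@omnibusP,
         pairwise_adjusted_p = as.data.frame(cmp@pairwiseP),
         stars = as.data.frame(cmp@stars)),
    file.path(config$outDir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  prov <- list(config = unclass(config),
               configHash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                                collapse = ""))),
               package = as.character(utils::packageVersion("OrthoCBCT")),
               r = R.version.string, timestamp = format(Sys.time()))
  jsonlite::write_json(prov, file.path(config$outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, ablation = abl, comparison = cmp,
                 dir = config$outDir))
}

#' Synthesize a volume from files
#'
#' Inference path: reads (or accepts) a checkpoint, a DRR pair and a
#' planning volume, preprocesses the pCT (truncate/normalize, core mask),
#' synthesizes the volume and writes it as NIfTI in both the normalized and
#' the HU domain (through the pCT's recorded range).
#'
#' @param ckpt checkpoint record or path (see \code{\link{saveCheckpoint}}).
#' @param drrs a \linkS4class{ProjectionPair}, or path to a 3D volume NIfTI
#'   from which the pair is rendered.
#' @param pct a \linkS4class{VolumeImage} (HU) or NIfTI path.
#' @param outPrefix output path prefix; writes
#'   \code{<prefix>_norm.nii.gz} and \code{<prefix>_hu.nii.gz}.
#' @return The synthetic normalized \linkS4class{VolumeImage}, invisibly.
#' @export
inferVolume <- function(ckpt, drrs, pct, outPrefix = NULL) {
  if (is.character(ckpt)) ckpt <- loadCheckpoint(ckpt)
  model <- restoreModel(ckpt)
  if (is.character(pct)) pct <- readVolume(pct)
  pctN <- truncateNormalize(pct)
  core <- centralRegionMask(dim(volData(pct)))
  pctIn <- volData(pctN) * core
  if (is.character(drrs))
    drrs <- renderPair(volData(truncateNormalize(readVolume(drrs))) * core,
                       raster = rep(model$cfg$inRaster2d, 2))
  t0 <- Sys.time()
  s <- predictVolume(model, drrs, volumeImage(pctIn, voxelSpacing(pct),
                                              domain = "normalized01"))
  cat(sprintf("inference: %.3fs\n",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  if (!is.null(outPrefix)) {
    writeVolume(volumeImage(volData(s), voxelSpacing(pct),
                            domain = "normalized01"),
                paste0(outPrefix, "_norm.nii.gz"))
    rng <- normRange(pctN)
    writeVolume(volumeImage(volData(s) * (rng[2] - rng[1]) + rng[1],
                            voxelSpacing(pct)),
                paste0(outPrefix, "_hu.nii.gz"))
  }
  invisible(s)
}
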