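#' Build the study analysis mask
#'
#' Mirrors the artifact-masking procedure: a per-run intensity mask for
#' every post-surgery run (conditions whose label starts with "POST"),
#' combined across runs with logical AND, then optionally intersected with
#' an anatomical search-space mask.
#'
#' @param study a [SyntheticStudy-class] (or named list of runs with names
#'   "subject.condition").
#' @param fraction intensity threshold fraction (default 0.4).
#' @param anatomical optional [VoxelMask-class] search space.
#' @return a [VoxelMask-class].
#' @export
studyMask <- function(study, fraction = 0.4, anatomical = NULL) {
  runs <- if (is(study, "SyntheticStudy")) study@runs else study
  post <- runs[grepl("\\.POST", names(runs))]
  if (!length(post)) post <- runs
  masks <- lapply(post, intensityMask, fraction = fraction)
  m <- combineMasksAll(masks)
  if (!is.null(anatomical)) m <- maskConjunction(m, anatomical)
  m
}

#' Compute EC maps for every run of a study
#'
#' @param study a [SyntheticStudy-class] or named list of [BOLDRun-class].
#' @param mask analysis [VoxelMask-class].
#' @param variant EC variant (default "add").
#' @param fwhmMm optional Gaussian smoothing FWHM applied before extraction.
#' @param ... passed to [ecMap()].
#' @return named list of [ECMap-class], one per run.
#' @export
ecStudy <- function(study, mask, variant = "add", fwhmMm = NULL, ...) {
  runs <- if (is(study, "SyntheticStudy")) study@runs else study
  lapply(runs, function(run) {
    if (!is.null(fwhmMm) && fwhmMm > 0) run <- gaussianSmooth(run, fwhmMm)
    ecMap(extractTimeSeries(run, mask), variant = variant, ...)
  })
}

#' Assemble per-run maps into the design's V x N matrix
#'
#' Columns follow the design row order ("subject.condition"); every map must
#' share an identical voxel index (guaranteed when all runs used the same
#' mask and no voxel was dropped in some runs only — mismatches are an
#' error).
#'
#' @param maps named list of [ECMap-class] or [CorrelationMap-class].
#' @param design a [StudyDesign-class].
#' @return V x N numeric matrix with attribute "voxelIndex".
#' @export
mapMatrix <- function(maps, design) {
  wanted <- rownames(design@design)
  miss <- setdiff(wanted, names(maps))
  if (length(miss))
    stop("missing maps for: ", paste(utils::head(miss, 5), collapse = ", "))
  ref <- maps[[wanted[1]]]@voxelIndex
  out <- matrix(0, nrow(ref), length(wanted))
  for (j in seq_along(wanted)) {
    m <- maps[[wanted[j]]]
    if (!identical(dim(m@voxelIndex), dim(ref)) ||
        max(abs(m@voxelIndex - ref)) > 0)
      stop("voxel index mismatch across maps; use a common mask")
    out[, j] <- m@values
  }
  attr(out, "voxelIndex") <- ref
  out
}

#' Group inference over a stack of maps
#'
#' Fits the flexible-factorial GLM and evaluates a battery of contrasts,
#' returning one [StatMap-class] and one cluster table per contrast.
#'
#' @param maps V x N matrix (see [mapMatrix()]) or named list of maps.
#' @param design a [StudyDesign-class].
#' @param contrasts list of [ContrastSpec-class] (default: the standard
#'   eleven-contrast battery).
#' @param qLevel FDR level for cluster extraction (default 0.05).
#' @param voxelIndex,dm,affine geometry (taken from the map attribute / the
#'   first map when available).
#' @param excludeVoxels passed to [extractClusters()].
#' @return list with `fit`, `stats` (named list of StatMap) and `clusters`
#'   (named list of data.frames).
#' @export
groupAnalysis <- function(maps, design, contrasts = NULL, qLevel = 0.05,
                          voxelIndex = NULL, dm = NULL, affine = NULL,
                          excludeVoxels = NULL) {
  if (is.list(maps) && !is.matrix(maps)) {
    first <- maps[[1]]
    if (is.null(dm)) dm <- first@gridDim
    if (is.null(affine)) affine <- first@affine
    maps <- mapMatrix(maps, design)
  }
  if (is.null(voxelIndex)) voxelIndex <- attr(maps, "voxelIndex")
  if (is.null(contrasts)) contrasts <- contrastBattery(design@conditions)
  fit <- fitGLM(maps, design)
  stats <- lapply(contrasts, contrastTMap, fit = fit,
                  voxelIndex = voxelIndex, dm = dm, affine = affine)
  clusters <- lapply(stats, extractClusters, qLevel = qLevel,
                     excludeVoxels = excludeVoxels)
  list(fit = fit, stats = stats, clusters = clusters)
}

#' Seed-based correlation analysis for a study
#'
#' For each seed region: per-run seed-to-voxel correlation maps (Fisher z by
#' default) over the analysis mask, fed to the same flexible-factorial
#' group model.  Seed voxels are retained in the maps (their trivial
#' self-correlations) but excluded from cluster reporting.
#'
#' @param study a [SyntheticStudy-class] or named run list.
#' @param mask analysis [VoxelMask-class].
#' @param seeds list of [SeedRegion-class] (e.g. from [seedsFromStatMap()]).
#' @param design a [StudyDesign-class].
#' @param contrasts,qLevel as in [groupAnalysis()].
#' @param fisher Fisher z-transform before modelling (default TRUE).
#' @return named list (one entry per seed) of [groupAnalysis()] results,
#'   each with the per-run `maps` attached.
#' @export
seedAnalysis <- function(study, mask, seeds, design, contrasts = NULL,
                         qLevel = 0.05, fisher = TRUE) {
  runs <- if (is(study, "SyntheticStudy")) study@runs else study
  out <- list()
  for (i in seq_along(seeds)) {
    seed <- seeds[[i]]
    cmaps <- lapply(names(runs), function(nm) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      ts <- extractTimeSeries(runs[[nm]], mask)
      correlationMap(ts, seedTimecourse(runs[[nm]], seed), fisher = fisher,
                     subject = parts[1],
                     condition = paste(parts[-1], collapse = "."))
    })
    names(cmaps) <- names(runs)
    seedVox <- which(seed@mask@data)
    ga <- groupAnalysis(cmaps, design, contrasts = contrasts,
                        qLevel = qLevel,
                        excludeVoxels = indexToVoxel(seedVox,
                                                     dim(seed@mask@data)))
    ga$maps <- cmaps
    ga$seed <- seed
    out[[paste0("seed", i)]] <- ga
  }
  out
}

writeProvenance <- function(outDir, stage, params) {
  info <- list(stage = stage, params = params,
               package = as.character(utils::packageVersion("ecmap")),
               r = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(info, file.path(outDir,
                                       paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline stages
#'
#' Disk-oriented orchestration of the full analysis.  `runSimulate` writes a
#' synthetic study (NIfTI runs, motion traces, clinical TSV, ground-truth
#' JSON); `runEC`, `runGroup`, `runSeedCorr`, `runClinical` and `runQC`
#' execute the downstream stages, each writing its artifacts plus a
#' provenance JSON into `outDir` and returning its results invisibly.
#' `runPipeline` chains all stages from a config list (or YAML file path)
#' with fields `synthetic` (arguments to [syntheticConfig()]), `variant`,
#' `fwhmMm`, `maskFraction`, `qLevel`, `seedContrast` and `outDir`.
#' No stage mutates its inputs; reruns with the same config are
#' reproducible.
#'
#' @param config a [SyntheticConfig-class] (for `runSimulate`) or pipeline
#'   config list / YAML path (for `runPipeline`).
#' @param outDir output directory (created if needed).
#' @return see details; each stage returns its artifacts invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config, outDir) {
  dir.create(file.path(outDir, "runs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "motion"), showWarnings = FALSE)
  study <- generateStudy(config)
  for (nm in names(study@runs))
    writeBOLDRun(study@runs[[nm]],
                 file.path(outDir, "runs", paste0(nm, ".nii.gz")))
  for (nm in names(study@motion))
    writeMotionTrace(study@motion[[nm]],
                     file.path(outDir, "motion", paste0(nm, ".par")))
  utils::write.table(study@clinical, file.path(outDir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- study@truth
  truthJson <- list(
    hubLabel = truth$hubLabel,
    coupling = lapply(truth$coupling, function(m) unname(as.matrix(m))),
    regionVoxels = lapply(truth$regionVoxels, function(m) unname(m)),
    dropoutVoxels = unname(truth$dropoutVoxels),
    modulatedRegions = truth$modulatedRegions)
  jsonlite::write_json(truthJson, file.path(outDir, "truth.json"),
                       digits = NA)
  writeProvenance(outDir, "simulate",
                  list(seed = config@rngSeed,
                       grid = config@gridShape,
                       nSubjects = config@nSubjects,
                       nTimepoints = config@nTimepoints))
  invisible(study)
}

#' @rdname pipeline
#' @param study a [SyntheticStudy-class] (in-memory path; otherwise runs are
#'   read back from `outDir`).
#' @param variant,fwhmMm,maskFraction,qLevel analysis parameters.
#' @export
runEC <- function(outDir, study = NULL, variant = "add", fwhmMm = NULL,
                  maskFraction = 0.4) {
  if (is.null(study)) stop("runEC requires the study object (use runSimulate first)")
  mask <- studyMask(study, fraction = maskFraction)
  writeVoxelMask(mask, file.path(outDir, "mask.nii.gz"))
  maps <- ecStudy(study, mask, variant = variant, fwhmMm = fwhmMm)
  ecDir <- file.path(outDir, "ec")
  dir.create(ecDir, showWarnings = FALSE)
  for (nm in names(maps)) {
    writeMapNifti(maps[[nm]], file.path(ecDir, paste0(nm, "_", variant, ".nii.gz")))
    m <- maps[[nm]]
    jsonlite::write_json(list(variant = m@variant,
                              iterations = m@iterations,
                              converged = m@converged,
                              uniquePerron = m@uniquePerron),
                         file.path(ecDir, paste0(nm, "_", variant, ".json")),
                         auto_unbox = TRUE)
  }
  writeProvenance(outDir, "ec", list(variant = variant,
                                     maskFraction = maskFraction,
                                     fwhmMm = fwhmMm %||% 0))
  invisible(list(mask = mask, maps = maps))
}

#' @rdname pipeline
#' @param ecResult result of [runEC()].
#' @export
runGroup <- function(outDir, study, ecResult, qLevel = 0.05) {
  design <- buildDesign(sprintf("sub%02d", seq_len(study@config@nSubjects)),
                        study@config@conditions)
  ga <- groupAnalysis(ecResult$maps, design, qLevel = qLevel)
  gDir <- file.path(outDir, "group")
  dir.create(gDir, showWarnings = FALSE)
  for (nm in names(ga$stats)) {
    writeMapNifti(ga$stats[[nm]], file.path(gDir, paste0(nm, ".nii.gz")))
    writeClusterTable(ga$clusters[[nm]],
                      file.path(gDir, paste0("clusters_", nm, ".tsv")))
  }
  writeProvenance(outDir, "group", list(qLevel = qLevel,
                                        nContrasts = length(ga$stats)))
  invisible(c(ga, list(design = design)))
}

#' @rdname pipeline
#' @param groupResult result of [runGroup()].
#' @param seedContrast contrast whose significant clusters define the seeds
#'   (default the weighted bilateral ON contrast).
#' @export
runSeedCorr <- function(outDir, study, ecResult, groupResult,
                        seedContrast = "POST_ON_minus_PRE_ON",
                        qLevel = 0.05) {
  stat <- groupResult$stats[[seedContrast]]
  if (is.null(stat)) stop("unknown seed contrast: ", seedContrast)
  seeds <- seedsFromStatMap(stat, qThreshold = qLevel)
  sDir <- file.path(outDir, "seedcorr")
  dir.create(sDir, showWarnings = FALSE)
  if (!length(seeds)) {
    writeProvenance(outDir, "seedcorr", list(seedContrast = seedContrast,
                                             nSeeds = 0))
    return(invisible(list(seeds = list(), analyses = list())))
  }
  for (i in seq_along(seeds)) {
    writeVoxelMask(seeds[[i]]@mask,
                   file.path(sDir, sprintf("seed%d.nii.gz", i)))
    jsonlite::write_json(list(sourceContrast = seeds[[i]]@sourceContrast,
                              peakMM = seeds[[i]]@peakMM),
                         file.path(sDir, sprintf("seed%d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  analyses <- seedAnalysis(study, ecResult$mask, seeds,
                           groupResult$design, qLevel = qLevel)
  for (nm in names(analyses))
    for (cn in names(analyses[[nm]]$clusters))
      writeClusterTable(analyses[[nm]]$clusters[[cn]],
                        file.path(sDir, paste0(nm, "_clusters_", cn, ".tsv")))
  writeProvenance(outDir, "seedcorr", list(seedContrast = seedContrast,
                                           nSeeds = length(seeds)))
  invisible(list(seeds = seeds, analyses = analyses))
}

#' @rdname pipeline
#' @param clinicalPath TSV path; defaults to the study's synthetic table,
#'   falling back to the bundled UPDRS-III scores when no study is given.
#' @export
runClinical <- function(outDir, study = NULL, clinicalPath = NULL) {
  tab <- if (!is.null(clinicalPath)) readClinicalTable(clinicalPath)
         else if (!is.null(study)) study@clinical
         else updrsScores()
  anova <- rmAnova2x2(tab)
  battery <- treatmentEffectBattery(tab)
  report <- list(
    anova = list(FMethod = anova$FMethod, FState = anova$FState,
                 FInteraction = anova$FInteraction,
                 df = c(anova$df1, anova$df2),
                 p = c(method = anova$pMethod, state = anova$pState,
                       interaction = anova$pInteraction)),
    effects = battery$effects, tests = battery$tests,
    alpha = battery$alpha)
  jsonlite::write_json(report, file.path(outDir, "clinical_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeProvenance(outDir, "clinical", list(n = nrow(tab)))
  invisible(list(anova = anova, battery = battery))
}

#' @rdname pipeline
#' @export
runQC <- function(outDir, study) {
  qc <- motionQCTable(study@motion)
  utils::write.table(qc, file.path(outDir, "motion_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeProvenance(outDir, "qc", list(nRuns = nrow(qc)))
  invisible(qc)
}

#' @rdname pipeline
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  outDir <- outDir %||% config$outDir %||% stop("outDir required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  synth <- do.call(syntheticConfig, config$synthetic %||% list())
  study <- runSimulate(synth, outDir)
  ec <- runEC(outDir, study, variant = config$variant %||% "add",
              fwhmMm = config$fwhmMm,
              maskFraction = config$maskFraction %||% 0.4)
  grp <- runGroup(outDir, study, ec, qLevel = config$qLevel %||% 0.05)
  sc <- runSeedCorr(outDir, study, ec, grp,
                    seedContrast = config$seedContrast %||% "POST_ON_minus_PRE_ON",
                    qLevel = config$qLevel %||% 0.05)
  cl <- runClinical(outDir, study)
  qc <- runQC(outDir, study)
  invisible(list(study = study, ec = ec, group = grp, seedcorr = sc,
                 clinical = cl, qc = qc))
}
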