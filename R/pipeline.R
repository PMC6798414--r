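#' Default pipeline configuration
#'
#' Nested list of every stage parameter with the package defaults: a small
#' synthetic imaging cohort, J = 3 compartments, nontrivial-proportion
#' threshold 1e-2, 32-level GLCM, per-SD Cox hazard ratios with BH
#' correction at FDR 0.1, and the co-expression/elastic-net radiogenomic
#' stage (off by default).  Unknown keys in a user config are rejected.
#'
#' @return a named nested list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    outDir = NULL,
    synth = list(nSubjects = 8L, shape = c(10L, 10L, 4L),
                 timepoints = c(0, 1, 2, 3, 4, 5, 6, 7),
                 dirichletAlpha = c(1, 1, 1), cornerFraction = 0.05,
                 noiseSigma = 0.02, survivalBeta = 0.7,
                 baselineScale = 5, censorRate = 0.3),
    segment = list(enabled = FALSE, c = 2L, minSize = 10L),
    decompose = list(J = 3L, selectJ = FALSE, candidateJ = c(1L, 2L, 3L, 4L),
                     preference = "median", damping = 0.9,
                     nontrivialThreshold = 1e-2),
    features = list(levels = 32L, voxelSpacing = c(1, 1, 1)),
    survival = list(endpoint = "rfs", fdr = 0.1, pruneR = 0.7,
                    cutoffQuantiles = c(0.1, 0.9)),
    radiogenomics = list(enabled = FALSE, nGenes = 600L,
                         moduleSizes = c(100L, 80L, 60L), targetR = 0.59,
                         noiseSd = 0.3, power = 5, minSize = 60L,
                         mergeHeight = 0.25, topCorrGenes = 100L,
                         folds = 10L, gmt = NULL))
}

.checkConfigKeys <- function(config, reference = defaultConfig(),
                             path = "config") {
  extra <- setdiff(names(config), names(reference))
  if (length(extra))
    stop("unknown ", path, " keys: ", paste(extra, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(reference[[nm]]) && !is.null(names(reference[[nm]])) &&
        is.list(config[[nm]]))
      .checkConfigKeys(config[[nm]], reference[[nm]], paste0(path, "$", nm))
  }
  invisible(TRUE)
}

# Merge a partial user config over the defaults (unknown keys rejected).
.mergeConfig <- function(config) {
  ref <- defaultConfig()
  .checkConfigKeys(config, ref)
  merge1 <- function(def, usr) {
    for (nm in names(usr)) {
      def[[nm]] <- if (is.list(def[[nm]]) && !is.null(names(def[[nm]])) &&
                       is.list(usr[[nm]])) merge1(def[[nm]], usr[[nm]])
                   else usr[[nm]]
    }
    def
  }
  merge1(ref, config)
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips the nested configuration list; unknown keys are rejected on
#' read.
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  config <- yaml::read_yaml(path)
  .checkConfigKeys(config)
  config
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration with known ground truth: for each subject a
#' synthetic tumour is generated (convex mixture of three compartment
#' curves), optionally re-segmented from its early-enhancement volume,
#' decomposed by convex analysis of mixtures into plasma-input / fast-flow /
#' slow-flow subregions, and the 14 radiomic features are extracted from
#' the whole tumour and each subregion.  Survival linked to a designated
#' feature is simulated and every feature is tested by univariate Cox with
#' BH correction; the top feature is stratified at its optimal log-rank
#' cutoff.  When the radiogenomic stage is enabled, linked block-modular
#' expression is generated, modules and eigengenes detected, the
#' module-feature correlations computed, and an elastic-net signature
#' fitted (with hypergeometric enrichment when a GMT file is supplied).
#' Every stage seed derives deterministically from the master seed, and a
#' provenance record of all parameters is returned (and written to
#' `outDir` with the tables when set).
#'
#' @param config partial configuration list merged over [defaultConfig()].
#' @return list with `features` (subject x region feature table),
#'   `survival`, `cox` (per-feature univariate results with `pAdjusted`),
#'   `cutoff`, `models` (per-subject [CompartmentModel-class]s),
#'   `radiogenomics` (NULL unless enabled), `provenance`.
#' @export
runFull <- function(config = list()) {
  cfg <- .mergeConfig(config)
  seed <- cfg$seed
  sy <- cfg$synth

  curves <- generateKineticCurves(J = 3L, timepoints = sy$timepoints,
                                  seed = deriveSeed(seed, 1))
  roleNames <- c("whole", .ROLE_SET)
  models <- vector("list", sy$nSubjects)
  featRows <- vector("list", sy$nSubjects)
  for (s in seq_len(sy$nSubjects)) {
    tum <- generateMixtureImage(curves, shape = sy$shape,
                                dirichletAlpha = sy$dirichletAlpha,
                                cornerFraction = sy$cornerFraction,
                                noiseSigma = sy$noiseSigma,
                                seed = deriveSeed(seed, 100 + s))
    mask <- tum@mask
    if (cfg$segment$enabled) {
      enh <- tum@image[, , , 2] - tum@image[, , , 1]
      centre <- round(colMeans(which(mask, arr.ind = TRUE)))
      mask <- extractTumourMask(enh, centre, c = cfg$segment$c,
                                minSize = cfg$segment$minSize,
                                seed = deriveSeed(seed, 200 + s))
    }
    pk <- pixelKineticMatrix(tum@image, mask, sy$timepoints)
    model <- camDecompose(pk, J = cfg$decompose$J,
                          selectJ = cfg$decompose$selectJ,
                          candidateJ = cfg$decompose$candidateJ,
                          preference = cfg$decompose$preference,
                          damping = cfg$decompose$damping,
                          seed = deriveSeed(seed, 300 + s))
    memb <- assignSubregions(model@K, model@roles,
                             cfg$decompose$nontrivialThreshold)
    regions <- list(whole = mask)
    for (r in .ROLE_SET) {
      m <- array(FALSE, dim = dim(mask))
      m[pk$pixelIndex[memb[, r]]] <- TRUE
      regions[[r]] <- m
    }
    series <- buildSeries(tum@image[, , , 1],
                          tum@image[, , , 2],
                          tum@image[, , , dim(tum@image)[4]])
    ft <- featureTable(series, regions, levels = cfg$features$levels,
                       voxelSpacing = cfg$features$voxelSpacing)
    ft <- cbind(subject = paste0("S", s), ft)
    models[[s]] <- model
    featRows[[s]] <- ft
  }
  features <- do.call(rbind, featRows)

  # survival linked to the whole-tumour S0 maximum probability
  whole <- features[features$region == "whole", , drop = FALSE]
  linked <- as.numeric(scale(whole$S0_maximum_probability))
  surv <- generateSurvival(linked, beta = sy$survivalBeta,
                           baselineScale = sy$baselineScale,
                           censorRate = sy$censorRate,
                           seed = deriveSeed(seed, 2))
  featCols <- .FEATURE_NAMES[vapply(.FEATURE_NAMES, function(f)
    stats::sd(whole[[f]]) > 1e-12, logical(1))]
  cox <- do.call(rbind, lapply(featCols, function(f) {
    cu <- coxUnivariate(whole[[f]], surv)
    data.frame(feature = f, beta = cu$beta, hr = cu$hr, p = cu$p,
               cIndex = cu$cIndex, stringsAsFactors = FALSE)
  }))
  cox$pAdjusted <- bhAdjust(cox$p)
  top <- cox$feature[which.min(cox$p)]
  cutoff <- tryCatch(
    optimalCutoff(whole[[top]], surv,
                  quantiles = cfg$survival$cutoffQuantiles),
    error = function(e) NULL)

  rg <- NULL
  if (cfg$radiogenomics$enabled) {
    rc <- cfg$radiogenomics
    ex <- generateExpression(nGenes = rc$nGenes, nSubjects = nrow(whole),
                             moduleSizes = rc$moduleSizes,
                             linkedFeature = linked, targetR = rc$targetR,
                             noiseSd = rc$noiseSd,
                             seed = deriveSeed(seed, 3))
    expr <- filterGenes(ex$expression, topK = rc$nGenes)
    mods <- detectModules(expr, power = rc$power, minSize = rc$minSize,
                          mergeHeight = rc$mergeHeight)
    mfc <- moduleFeatureCorrelation(mods, linked)
    sig <- elasticNetSignature(expr, linked, topCorrGenes = rc$topCorrGenes,
                               folds = min(rc$folds, nrow(whole)),
                               seed = deriveSeed(seed, 4))
    enr <- if (!is.null(rc$gmt))
      hypergeometricEnrichment(sig@genes, readGmt(rc$gmt), rownames(expr))
    rg <- list(modules = mods, moduleFeature = mfc, signature = sig,
               enrichment = enr, truth = ex$truth)
  }

  prov <- list(package = "camrad",
               version = as.character(utils::packageVersion("camrad")),
               config = cfg, date = format(Sys.Date()))
  out <- list(features = features, survival = surv, cox = cox,
              cutoff = cutoff, models = models, radiogenomics = rg,
              provenance = prov)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(features, file.path(cfg$outDir, "features.tsv"))
    writeTsv(surv, file.path(cfg$outDir, "survival.tsv"))
    writeTsv(cox, file.path(cfg$outDir, "cox_univariate.tsv"))
    writeJsonReport(prov, file.path(cfg$outDir, "provenance.json"))
  }
  out
}
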