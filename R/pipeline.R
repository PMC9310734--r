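#' Pipeline configuration
#'
#' Assembles and validates the single configuration object driving
#' [runPipeline()]. Every analysis parameter surfaces as a named key with
#' the framework's standard default (10,000 Mantel/MMRR permutations, 500
#' GDM permutations, alpha 0.05, 0.4 degree hull buffer, 100 m elevation
#' margin, tier costs 1/2/4/8/16 via quantiles, 10,000 background points,
#' 80/20 train split, 10 replicate niche fits, 4 CV blocks). By default the
#' pipeline simulates its inputs; supply `input` (list with `beagle`,
#' `sampleSheet`, `elevation`, `bioclim`, `epochs`, `occurrences` paths) to
#' run on files instead.
#'
#' @param ... overrides of the defaults listed above.
#' @return validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1,
    # synthetic landscape
    gridRows = 48, gridCols = 48, extent = c(-79, -78, -1, 0),
    roughness = 0.8, spectralExponent = 2,
    # localities and genotypes
    nLocalities = 5, nIndPerLocality = 13, minSepKm = 20, nearPairKm = 12,
    nSites = 5000, depthMean = 8, errorRate = 0.01,
    divergenceSigma = 1.5, runInbreeding = TRUE,
    # occurrences and niche model
    nOccurrences = 400, nBackground = 10000, trainFrac = 0.8, enmReps = 10,
    enmLambda = 0.001, enmMaxit = 500, blockCVReps = 3,
    hullBufferDeg = 0.4, elevMarginM = 100, excludeEpochModels = character(0),
    # matrix statistics
    mantelPerm = 10000, mmrrPerm = 10000, gdmPerm = 500, alpha = 0.05,
    fstTol = 1e-6, fstMaxIter = 200,
    input = NULL, outDir = NULL
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipelineConfig()] arguments.
#' @return validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

validatePipelineConfig <- function(cfg) {
  num <- c("seed", "gridRows", "gridCols", "roughness", "nLocalities",
           "nIndPerLocality", "nSites", "depthMean", "errorRate",
           "nOccurrences", "nBackground", "trainFrac", "enmReps",
           "mantelPerm", "mmrrPerm", "gdmPerm", "alpha")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]]))
      stop("config field '", f, "' must be a single number")
  }
  if (cfg$nLocalities < 3) stop("config field 'nLocalities' must be >= 3")
  if (!is.null(cfg$input)) {
    need <- c("beagle", "sampleSheet", "elevation", "bioclim", "epochs", "occurrences")
    miss <- setdiff(need, names(cfg$input))
    if (length(miss)) stop("config field 'input' is missing: ", paste(miss, collapse = ", "))
    paths <- c(cfg$input$beagle, cfg$input$sampleSheet, cfg$input$elevation,
               unlist(cfg$input$bioclim), unlist(cfg$input$epochs), cfg$input$occurrences)
    bad <- paths[!file.exists(paths)]
    if (length(bad)) stop("config 'input' paths do not exist: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# stage wrapper: uniform error reporting with the failing stage named
runStage <- function(name, log, expr) {
  t0 <- proc.time()[3]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage %-12s %6.1f s", name, proc.time()[3] - t0))
  out
}

#' Run the full landscape-genomics pipeline
#'
#' Executes all stages in dependency order — landscape simulation (or file
#' input), occurrence and locality placement, terrain-coupled genotype
#' simulation, genotype-likelihood population genetics (theta-pi on
#' intersected variable sites, heterozygosity, inbreeding, pairwise FST),
#' niche suitability modelling with evaluation and MESS, the three
#' resistance surfaces and their least-cost distance matrices, and the
#' matrix-statistics cascade (Mantel tests of IBD / IBR_Terrain /
#' IBR_Habitat / IBI / IBE against normalized FST, MMRR of the best
#' predictor plus IBE, and GDM with backward elimination against FST).
#'
#' @param config a [pipelineConfig()] list or path to a YAML config.
#' @param verbose print per-stage wall time.
#' @return list of class `PipelineReport`; see Details in the vignette.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!inherits(config, "PipelineConfig")) config <- pipelineConfig(config)
  log <- if (verbose) function(msg) message(msg) else function(msg) invisible(NULL)
  seeds <- subSeeds(config$seed, 8)
  out <- list(config = unclass(config), seed = config$seed)

  dat <- runStage("inputs", log, loadPipelineInputs(config, seeds))
  out$localities <- dat$localities
  epochNames <- names(dat$epochs)

  resist <- runStage("terrain", log, {
    tri <- terrainRuggedness(dat$elevation)
    triMasked <- elevationMask(tri, dat$occurrences, elevation = dat$elevation,
                               hullBufferDeg = config$hullBufferDeg,
                               elevMarginM = config$elevMarginM)
    occTRI <- extractAt(tri, dat$occurrences$lon, dat$occurrences$lat)
    costTerr <- triCostSurface(triMasked, occTRI)
    tgTerr <- buildTransitionGraph(costTerr)
    list(tri = tri, costTerr = costTerr,
         ibrTerrain = leastCostDistances(tgTerr, dat$localities, kind = "IBR_Terrain"))
  })

  if (is.null(dat$gl)) {
    sim <- runStage("genotypes", log, {
      popCov <- distanceCoupledCov(resist$ibrTerrain, sigma = config$divergenceSigma)
      truth <- metapopulationTruth(
        nPops = nrow(dat$localities@centroids),
        nIndPerPop = as.vector(table(factor(dat$localities@samples$locality,
                                            levels = dat$localities@centroids$locality))),
        fstTarget = 0, nSites = config$nSites, depthMean = config$depthMean,
        errorRate = config$errorRate, popCov = popCov, seed = seeds[3])
      s <- simulateGenotypeLikelihoods(truth)
      s$gl@individuals <- dat$localities@samples$individual
      s
    })
    dat$gl <- sim$gl
    out$truth <- sim$truth
  }

  out$popgen <- runStage("popgen", log, {
    loc <- dat$localities
    locNames <- loc@centroids$locality
    glByLoc <- lapply(locNames, function(l)
      subsetGL(dat$gl, individuals = loc@samples$individual[loc@samples$locality == l]))
    names(glByLoc) <- locNames
    shared <- intersectSites(lapply(glByLoc, variableSites))
    theta <- vapply(glByLoc, function(g) {
      thetaPi(estimateSFS(subsetGL(g, sites = shared), maxIter = 200, tol = 1e-6))$thetaPiPerSite
    }, numeric(1))
    het <- individualHeterozygosity(dat$gl)
    inb <- if (isTRUE(config$runInbreeding)) estimateInbreeding(dat$gl, tol = 1e-5) else NULL
    fst <- fstMatrix(dat$gl, loc, tol = config$fstTol, maxIter = config$fstMaxIter)
    # within-locality mating pattern: individual-level IBD Mantel tests of
    # genetic distance against log geographic distance
    withinIBD <- do.call(rbind, lapply(locNames, function(l) {
      idx <- loc@samples$locality == l
      if (sum(idx) < 4) return(NULL)
      mt <- tryCatch({
        gd <- pairwiseGeneticDistance(glByLoc[[l]])
        geo <- suppressWarnings(geographicDistanceMatrix(loc@samples[idx, ],
                                                         level = "individual",
                                                         logTransform = TRUE))
        mantelTest(geo, gd, nPerm = min(config$mantelPerm, 999), seed = seeds[2])
      }, error = function(e) NULL)
      if (is.null(mt)) NULL else data.frame(locality = l, r = mt$r, p = mt$p)
    }))
    list(thetaPi = theta, nSharedSites = length(shared), heterozygosity = het,
         inbreeding = inb, fst = fst, withinIBD = withinIBD)
  })

  enm <- runStage("enm", log, {
    model <- fitSuitability(dat$occurrences, dat$bioclim,
                            nBackground = config$nBackground,
                            trainFrac = config$trainFrac, reps = config$enmReps,
                            lambda = config$enmLambda, maxit = config$enmMaxit,
                            seed = seeds[4])
    cv <- blockCVSummary(dat$occurrences, dat$bioclim, config, seeds[5])
    suitByEpoch <- lapply(dat$epochs, function(models) {
      keep <- setdiff(names(models), config$excludeEpochModels)
      reps <- lapply(models[keep], function(bc) predictSuitability(model, bc)@values)
      geoRaster(Reduce(`+`, reps) / length(reps), dat$elevation@extent)
    })
    refEnv <- as.data.frame(lapply(dat$bioclim, function(r)
      extractAt(r, dat$occurrences$lon, dat$occurrences$lat)))
    mess <- lapply(dat$epochs[setdiff(epochNames, "current")], function(models) {
      lapply(models, function(bc) messSurface(refEnv, bc))
    })
    list(model = model, blockCV = cv, suitability = suitByEpoch, mess = mess,
         stability = habitatStability(suitByEpoch))
  })
  out$enm <- enm

  out$resistance <- runStage("resistance", log, {
    maskIt <- function(r, below) elevationMask(r, dat$occurrences, elevation = dat$elevation,
                                               hullBufferDeg = config$hullBufferDeg,
                                               elevMarginM = config$elevMarginM,
                                               maskBelow = below)
    costHab <- suitabilityCostSurface(maskIt(enm$suitability$current, TRUE))
    costIbi <- suitabilityCostSurface(maskIt(enm$stability, FALSE),
                                      provenance = "one-minus-stability")
    list(costTerrain = resist$costTerr, costHabitat = costHab, costStability = costIbi,
         IBR_Terrain = resist$ibrTerrain,
         IBR_Habitat = leastCostDistances(buildTransitionGraph(costHab),
                                          dat$localities, kind = "IBR_Habitat"),
         IBI = leastCostDistances(buildTransitionGraph(costIbi),
                                  dat$localities, kind = "IBI"))
  })

  out$matrices <- runStage("matrices", log, {
    ibd <- geographicDistanceMatrix(dat$localities)
    env <- as.data.frame(lapply(dat$bioclim, function(r)
      extractAt(r, dat$localities@centroids$lon, dat$localities@centroids$lat)))
    rownames(env) <- dat$localities@centroids$locality
    ibe <- environmentalDistanceMatrix(env)
    list(IBD = ibd, IBR_Terrain = out$resistance$IBR_Terrain,
         IBR_Habitat = out$resistance$IBR_Habitat, IBI = out$resistance$IBI,
         IBE = ibe, FST = out$popgen$fst, normFST = normalizeFst(out$popgen$fst))
  })

  out$stats <- runStage("stats", log, {
    preds <- out$matrices[c("IBD", "IBR_Terrain", "IBR_Habitat", "IBI", "IBE")]
    mantel <- lapply(preds, function(m)
      mantelTest(m, out$matrices$normFST, nPerm = config$mantelPerm,
                 standardizeByMean = TRUE, seed = seeds[6]))
    mantelTable <- data.frame(
      predictor = names(preds),
      r = vapply(mantel, `[[`, numeric(1), "r"),
      r2 = vapply(mantel, `[[`, numeric(1), "r2"),
      p = vapply(mantel, `[[`, numeric(1), "p"), row.names = NULL)
    nonIbe <- mantelTable[mantelTable$predictor != "IBE", ]
    best <- nonIbe$predictor[which.max(nonIbe$r2)]
    mm <- mmrr(out$matrices$normFST, out$matrices[c(best, "IBE")],
               nPerm = config$mmrrPerm, seed = seeds[7])
    gdm <- gdmBackwardElimination(out$matrices$FST, preds, nPerm = config$gdmPerm,
                                  alpha = config$alpha, seed = seeds[8])
    list(mantel = mantelTable, mantelDetails = mantel, mmrrPredictors = c(best, "IBE"),
         mmrr = mm, gdm = gdm)
  })

  if (!is.null(config$outDir)) runStage("write", log, writePipelineOutputs(out, dat, config))
  class(out) <- "PipelineReport"
  out
}

# simulate pipeline inputs, or read them from the configured paths
loadPipelineInputs <- function(config, seeds) {
  if (!is.null(config$input)) {
    inp <- config$input
    bioclim <- lapply(inp$bioclim, readAsciiGrid)
    epochs <- lapply(inp$epochs, function(models) lapply(models, function(m)
      lapply(m, readAsciiGrid)))
    return(list(elevation = readAsciiGrid(inp$elevation), bioclim = bioclim,
                epochs = epochs, occurrences = utils::read.csv(inp$occurrences),
                localities = readSampleSheet(inp$sampleSheet),
                gl = readBeagle(inp$beagle)))
  }
  bundle <- generateLandscape(config$gridRows, config$gridCols, extent = config$extent,
                              roughness = config$roughness,
                              spectralExponent = config$spectralExponent, seed = seeds[1])
  suit <- trueSuitability(bundle, "current")
  occ <- generateOccurrences(suit, config$nOccurrences, seed = seeds[2])
  habitat <- elevationMask(bundle$elevation, occ, hullBufferDeg = config$hullBufferDeg,
                           elevMarginM = config$elevMarginM)
  loc <- placeLocalities(habitat, config$nLocalities, config$nIndPerLocality,
                         minSepKm = config$minSepKm, nearPairKm = config$nearPairKm,
                         seed = seeds[1])
  # one circulation model per epoch in the synthetic setting
  epochs <- lapply(bundle$epochs, function(bc) list(gcm1 = bc))
  list(elevation = bundle$elevation, bioclim = bundle$bioclim, epochs = epochs,
       occurrences = occ, localities = loc, gl = NULL, bundle = bundle)
}

# fourfold spatial-block cross-validation of the niche model
blockCVSummary <- function(occ, bioclim, config, seed) {
  cv <- spatialBlockCV(occ, k = 4, seed = seed)
  folds <- Filter(function(f) length(f$test) >= 5 && length(f$train) >= 20, cv$folds)
  res <- lapply(folds, function(f) {
    m <- fitSuitability(occ[f$train, , drop = FALSE], bioclim,
                        nBackground = min(config$nBackground, 2000),
                        reps = config$blockCVReps, trainFrac = config$trainFrac,
                        lambda = config$enmLambda, seed = seed)
    bg <- meta(m)$backgroundIdx
    ctr <- cellCenters(bioclim[[1]])
    bgPts <- data.frame(lon = as.vector(ctr$lon)[bg], lat = as.vector(ctr$lat)[bg])
    ev <- evaluateModel(m, occ[f$test, , drop = FALSE], bgPts, bioclim)
    c(auc = ev$auc, tss = ev$tss)
  })
  do.call(rbind, res)
}

writePipelineOutputs <- function(out, dat, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$outDir, f)
  if (!is.null(dat$gl)) writeBeagle(dat$gl, pth("genotype_likelihoods.beagle"))
  writeSampleSheet(dat$localities, pth("samples.csv"))
  if (!is.null(out$truth)) writeTruthJson(out$truth, pth("truth.json"))
  writeAsciiGrid(dat$elevation, pth("elevation.asc"))
  for (nm in names(out$matrices))
    writeDistanceMatrixCsv(out$matrices[[nm]], pth(paste0("matrix_", nm, ".csv")))
  utils::write.csv(out$stats$mantel, pth("mantel_table.csv"), row.names = FALSE)
  utils::write.csv(data.frame(predictor = names(out$stats$mmrr$coefficients),
                              coefficient = out$stats$mmrr$coefficients,
                              t = out$stats$mmrr$tstat, p = out$stats$mmrr$pCoef),
                   pth("mmrr_table.csv"), row.names = FALSE)
  hist <- do.call(rbind, lapply(seq_along(out$stats$gdm@history), function(i)
    cbind(round = i, out$stats$gdm@history[[i]])))
  utils::write.csv(hist, pth("gdm_elimination.csv"), row.names = FALSE)
  cfgPath <- pth("config.json")
  jsonlite::write_json(out$config, cfgPath, auto_unbox = TRUE, digits = NA, null = "null")
  prov <- list(seed = out$seed, configHash = unname(tools::md5sum(cfgPath)),
               packageVersion = as.character(utils::packageVersion("landpop")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, pth("provenance.json"), auto_unbox = TRUE)
  invisible(config$outDir)
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport (seed", x$seed, ")\n")
  cat(sprintf("  theta_pi per site: %s\n",
              paste(signif(x$popgen$thetaPi, 3), collapse = ", ")))
  cat(sprintf("  FST range: %.4f - %.4f\n",
              min(lowerTri(x$popgen$fst)), max(lowerTri(x$popgen$fst))))
  cat("  Mantel table:\n")
  print(x$stats$mantel, row.names = FALSE)
  cat(sprintf("  GDM: %.1f%% deviance explained; retained: %s\n",
              x$stats$gdm@devianceExplained,
              paste(colnames(x$stats$gdm@coefficients), collapse = ", ")))
  invisible(x)
}

#' Validate a file's read/write round trip
#'
#' Reads a supported file (beagle genotype likelihoods, Esri ASCII grid,
#' labelled distance-matrix CSV, sample sheet CSV), writes it back to a
#' temporary path, re-reads it, and compares the two objects (values to
#' 1e-12, metadata preserved).
#'
#' @param path input file.
#' @param format `"auto"` (by extension/content) or one of `"beagle"`,
#'   `"asciigrid"`, `"matrix"`, `"samplesheet"`.
#' @return list with `ok` (logical), `format`, and `maxAbsDiff`.
#' @export
validateIORoundtrip <- function(path, format = c("auto", "beagle", "asciigrid", "matrix", "samplesheet")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.beagle(\\.gz)?$", path)) "beagle"
      else if (grepl("\\.asc$", path)) "asciigrid"
      else {
        first <- readLines(path, n = 1L)
        if (grepl("^marker\\t", first)) "beagle"
        else if (grepl("^ncols", tolower(first))) "asciigrid"
        else if (grepl("individual", first)) "samplesheet"
        else "matrix"
      }
  }
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
  on.exit(unlink(tmp))
  if (format == "beagle") {
    a <- readBeagle(path); writeBeagle(a, tmp); b <- readBeagle(tmp)
    d <- max(abs(a@gl - b@gl))
    ok <- d < 1e-12 && identical(a@sites, b@sites) && identical(a@individuals, b@individuals)
  } else if (format == "asciigrid") {
    a <- readAsciiGrid(path); writeAsciiGrid(a, tmp); b <- readAsciiGrid(tmp)
    d <- max(abs(a@values - b@values), na.rm = TRUE)
    if (!any(!is.na(a@values))) d <- 0
    ok <- d < 1e-12 && identical(is.na(a@values), is.na(b@values)) &&
      max(abs(a@extent - b@extent)) < 1e-12
  } else if (format == "matrix") {
    a <- readDistanceMatrixCsv(path); writeDistanceMatrixCsv(a, tmp)
    b <- readDistanceMatrixCsv(tmp)
    d <- max(abs(a@values - b@values))
    ok <- d < 1e-12 && identical(rownames(a@values), rownames(b@values))
  } else {
    a <- readSampleSheet(path); writeSampleSheet(a, tmp); b <- readSampleSheet(tmp)
    d <- max(abs(a@samples$lon - b@samples$lon), abs(a@samples$lat - b@samples$lat))
    ok <- d < 1e-10 && identical(a@samples$individual, b@samples$individual)
  }
  list(ok = ok, format = format, maxAbsDiff = d)
}
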