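#' @include AllClasses.R AllGenerics.R simulate.R evidence.R reconstruct.R
#' @include fitness.R expression.R
NULL

#' Build a run configuration
#'
#' A run is a pure function of (configuration, code version): the returned
#' list is fully serializable (YAML/JSON) and every stochastic stage derives
#' from the single \code{seed}.
#'
#' @param seed integer seed for the whole run.
#' @param nStrains population size.
#' @param map list: either \code{list(source = "generator", n, totalLength)}
#'   or \code{list(source = "file", path = ...)}.
#' @param sim named list overriding \code{\link{SimParams}} defaults
#'   (e.g. \code{list(meanEvents = 4.42)}); \code{plantCausalRegion = TRUE}
#'   plants the del20K-analogue region from the map.
#' @param evidence list of evidence options: \code{baseline}, \code{noise},
#'   \code{circularRecovery}, \code{junctionRate}, \code{pcrtagReads},
#'   \code{supportMin}.
#' @param analysis list of analysis options: \code{scanMethod},
#'   \code{alpha}, \code{nPerm}, \code{kMax}, \code{excludeFlagged},
#'   \code{esr} (logical: run the expression/ESR stage), \code{esrTop}
#'   (number of top-recovery strains scored), \code{deThreshold}.
#' @param outputDir directory for persisted artifacts (\code{NULL}: none).
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(seed = 1L, nStrains = 219L,
                      map = list(source = "generator", n = 40L,
                                 totalLength = 1028952L),
                      sim = list(plantCausalRegion = TRUE),
                      evidence = list(baseline = 100, noise = FALSE,
                                      circularRecovery = 1 / 3,
                                      junctionRate = 20, pcrtagReads = 300L,
                                      supportMin = 1L),
                      analysis = list(scanMethod = "welch", alpha = 0.05,
                                      nPerm = 1000L, kMax = 4L,
                                      excludeFlagged = TRUE, esr = TRUE,
                                      esrTop = 2L, deThreshold = 0.001),
                      outputDir = NULL) {
  defaults <- runConfigDefaults()
  cfg <- list(seed = as.integer(seed), nStrains = as.integer(nStrains),
              map = utils::modifyList(defaults$map, map),
              sim = utils::modifyList(defaults$sim, sim),
              evidence = utils::modifyList(defaults$evidence, evidence),
              analysis = utils::modifyList(defaults$analysis, analysis),
              outputDir = outputDir)
  cfg
}

#' @rdname runConfig
#' @export
runConfigDefaults <- function() {
  list(map = list(source = "generator", n = 40L, totalLength = 1028952L,
                  path = NULL),
       sim = list(plantCausalRegion = TRUE, trisomyFraction = 0),
       evidence = list(baseline = 100, noise = FALSE,
                       circularRecovery = 1 / 3, junctionRate = 20,
                       pcrtagReads = 300L, supportMin = 1L),
       analysis = list(scanMethod = "welch", alpha = 0.05, nPerm = 1000L,
                       kMax = 4L, excludeFlagged = TRUE, esr = TRUE,
                       esrTop = 2L, deThreshold = 0.001))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: a config list (defaults filled in).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y[intersect(names(y),
                                 c("seed", "nStrains", "map", "sim",
                                   "evidence", "analysis", "outputDir"))])
}

#' @rdname readRunConfig
#' @param config a config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.simParamsFromConfig <- function(cfg, map) {
  simArgs <- cfg$sim
  plant <- isTRUE(simArgs$plantCausalRegion)
  simArgs$plantCausalRegion <- NULL
  known <- names(formals(SimParams))
  simArgs <- simArgs[intersect(names(simArgs), known)]
  params <- do.call(SimParams, simArgs)
  if (plant && length(params@causalRegion) == 0L)
    params@causalRegion <- causalRegionIds(map)
  params
}

# ---- user-supplied measurement tables --------------------------------------

#' Read user-supplied measurement tables
#'
#' Readers for the optional external inputs: OD600 growth curves
#' (tab-separated \code{time_min}, \code{od600}), colony-size tables
#' (\code{strain}, \code{colony_mm}) and gene-expression count matrices
#' (genes x strains, first column the gene id).
#'
#' @param path file path.
#' @return \code{readGrowthCurve}: a data.frame usable by
#'   \code{\link{doublingTime}}; \code{readColonySizes}: a named list of
#'   numeric vectors (one per strain); \code{readExpressionCounts}: a
#'   numeric matrix with gene rownames.
#' @export
readGrowthCurve <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("time_min", "od600") %in% names(df)))
    stop("growth curve file needs columns time_min and od600")
  df[order(df$time_min), c("time_min", "od600")]
}

#' @rdname readGrowthCurve
#' @export
readColonySizes <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("strain", "colony_mm") %in% names(df)))
    stop("colony size file needs columns strain and colony_mm")
  split(df$colony_mm, df$strain)
}

#' @rdname readGrowthCurve
#' @export
readExpressionCounts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Summarize a screened population
#'
#' @param population a \linkS4class{ScramblePopulation} or list of
#'   \linkS4class{StrainRecord}.
#' @param decompositions optional list of \linkS4class{EventDecomposition}
#'   (one per strain, e.g. from the reconstruction path); when absent the
#'   simulator's recorded events are summarized instead.
#' @param map optional \linkS4class{SegmentMap} for molecule size ranges.
#' @return list: \code{n}, \code{meanEvents} (2 decimals; circularization
#'   not counted, matching how the screen pools its three event types),
#'   \code{totalEvents}, \code{pctCircular} / \code{pctLinear} (nearest
#'   percent), \code{pctLossGe85AmongCircular}, \code{typeFractions}, and
#'   \code{sizeRangeKb} per topology when a map is given.
#' @export
summarizePopulation <- function(population, decompositions = NULL,
                                map = NULL) {
  recs <- if (is(population, "ScramblePopulation")) population@strains
  else population
  stopifnot(length(recs) >= 1L)
  if (is.null(map) && is(population, "ScramblePopulation"))
    map <- population@map
  evLists <- if (is.null(decompositions))
    lapply(recs, function(r) r@events)
  else lapply(decompositions, function(d) d@events)
  kinds <- lapply(evLists, eventKinds)
  core <- vapply(kinds, function(k) sum(k != "circularization"), integer(1))
  topo <- vapply(recs, function(r) r@structure@topology, character(1))
  circ <- topo == "circular"
  retained <- vapply(recs, function(r) r@retainedFraction, numeric(1))
  pool <- unlist(lapply(kinds, function(k) k[k != "circularization"]))
  types <- c("deletion", "inversion", "duplication")
  cts <- vapply(types, function(tp) sum(pool == tp), numeric(1))
  out <- list(n = length(recs),
              meanEvents = round(sum(core) / length(recs), 2L),
              totalEvents = sum(core),
              pctCircular = round(100 * mean(circ)),
              pctLinear = round(100 * mean(!circ)),
              pctLossGe85AmongCircular = if (any(circ))
                round(100 * mean(retained[circ] <= 0.15)) else NA,
              typeFractions = if (sum(cts) > 0) cts / sum(cts) else cts)
  if (!is.null(map)) {
    lens <- segLengths(map)
    sizes <- vapply(recs, function(r)
      sum(lens[r@structure@segIds]) / 1000, numeric(1))
    rng <- function(sel) if (any(sel))
      round(range(sizes[sel])) else c(NA, NA)
    out$sizeRangeKb <- list(circular = rng(circ), linear = rng(!circ))
  }
  out
}

#' Run the full pipeline: simulate, observe, reconstruct, analyze
#'
#' Stages: segment map; population simulation; evidence generation; ploidy
#' flagging; structure reconstruction and event decomposition; population
#' classification; fitness statistics (growth recovery, retention
#' regression, association scan — ploidy-flagged strains are excluded from
#' the scan and the ESR stage but retained in the report with their flag);
#' expression/ESR scoring of the disome parent and top-recovery strains.
#' All randomness derives from \code{config$seed}; the report contains no
#' wall-clock fields, so the same configuration reproduces it byte for byte.
#'
#' @param config list from \code{\link{runConfig}}.
#' @param verbose emit progress messages.
#' @return a run-report list (see the shipped JSON schema); written to
#'   \code{outputDir} along with intermediate artifacts when configured.
#' @export
runPipeline <- function(config = runConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))

  map <- stage("map", {
    if (identical(config$map$source, "file")) loadSegmentMap(config$map$path)
    else syntheticSegmentMap(config$map$n, config$map$totalLength)
  })
  say("map: ", nSegments(map), " segments, ", totalLength(map), " bp")

  params <- stage("params", .simParamsFromConfig(config, map))
  seed <- config$seed

  pop <- stage("simulate",
               simulatePopulation(map, params, config$nStrains,
                                  seed = seed))
  refColonies <- stage("simulate",
                       referenceColonySizes(params, seed = seed + 1L))
  say("simulated ", length(pop), " strains")

  ev <- config$evidence
  evidence <- stage("evidence", lapply(seq_along(pop@strains), function(i)
    generateEvidence(pop@strains[[i]], map, baseline = ev$baseline,
                     noise = isTRUE(ev$noise),
                     circularRecovery = ev$circularRecovery,
                     junctionRate = ev$junctionRate,
                     pcrtagReads = ev$pcrtagReads,
                     seed = seed + 1000L + i)))
  ploidy <- stage("evidence", lapply(evidence, flagPloidyAnomaly))
  flagged <- vapply(ploidy, `[[`, logical(1), "flag")
  say(sum(flagged), " strains flagged for ploidy anomaly")

  an <- config$analysis
  ref <- referenceStructure(map)
  decomps <- stage("reconstruct", lapply(seq_along(pop@strains), function(i) {
    g <- buildGraph(evidence[[i]], map, supportMin = ev$supportMin)
    cands <- inferStructures(g, map, cap = 50L)
    minEventDistance(ref, cands[[1L]], map, kMax = an$kMax)
  }))
  classification <- stage("classify", classifyPopulation(decomps))
  say("pooled deletion fraction ",
      round(100 * classification$typeFractions[["deletion"]], 1), "%")

  recovery <- vapply(pop@strains, function(r)
    growthRecoveryRate(r@colonySizesMm, refColonies)$valuePct, numeric(1))
  keep <- if (isTRUE(an$excludeFlagged)) !flagged else rep(TRUE, length(pop))
  reg <- stage("fitness", retentionRecoveryRegression(pop@strains[keep]))
  delMat <- deletionMatrix(pop, map)
  scan <- stage("fitness",
                associationScan(delMat[keep, , drop = FALSE],
                                recovery[keep], method = an$scanMethod,
                                nPerm = an$nPerm, alpha = an$alpha,
                                seed = seed + 2L))

  esrTable <- NULL
  if (isTRUE(an$esr)) {
    esrTable <- stage("expression", {
      parent <- assignFitness(
        simulateStrain(map, SimParams(meanEvents = 0,
                                      circularizationProb = 0,
                                      causalRegion = params@causalRegion),
                       strainId = "disomeParent"),
        params, seed = seed + 3L)
      ord <- order(recovery, decreasing = TRUE)
      top <- ord[!flagged[ord]][seq_len(min(an$esrTop, sum(keep)))]
      sel <- c(list(parent), pop@strains[top])
      se <- simulateExpression(sel, map, seed = seed + 4L)
      esrReversalReport(se, makeEsrGeneSets(), disome = "disomeParent",
                        deThreshold = an$deThreshold)
    })
  }

  summary <- summarizePopulation(pop, decomps, map)
  cfgNoOut <- config; cfgNoOut$outputDir <- NULL
  report <- list(
    provenance = list(configHash = .configHash(cfgNoOut), seed = seed,
                      package = "ScrambleDisome",
                      version = as.character(
                        utils::packageVersion("ScrambleDisome"))),
    population = summary,
    classification = list(
      typeFractions = as.list(classification$typeFractions),
      meanEvents = classification$meanEvents,
      circularFraction = classification$circularFraction,
      minimalFraction = mean(vapply(decomps, function(d) d@isMinimal,
                                    logical(1)))),
    ploidy = list(nFlagged = sum(flagged),
                  flaggedStrains = strainIds(pop)[flagged],
                  excludedFromScan = isTRUE(an$excludeFlagged)),
    fitness = list(r = reg$r, slope = reg$slope,
                   intercept = reg$intercept,
                   recoveryRangePct = range(recovery)),
    associationScan = list(
      nTested = sum(is.na(scan$reason)),
      topSegment = scan$segment[which.min(scan$p)],
      topP = min(scan$p, na.rm = TRUE),
      passing = scan$segment[scan$pass]),
    esr = if (!is.null(esrTable))
      lapply(seq_len(nrow(esrTable)), function(i) as.list(esrTable[i, ]))
    else NULL)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- config$outputDir
    writeSegmentMap(map, file.path(out, "segment_map.tsv"))
    structs <- lapply(pop@strains, function(r) r@structure)
    names(structs) <- strainIds(pop)
    writeStructures(structs, file.path(out, "structures.tsv"))
    utils::write.table(scan, file.path(out, "association_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunConfig(cfgNoOut, file.path(out, "config.yaml"))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

#' Validate a run report against the shipped schema
#'
#' The package ships a JSON schema describing the report
#' (\code{inst/schema/report-schema.json}); this checks required fields and
#' primitive types recursively.
#'
#' @param report a report list from \code{\link{runPipeline}} or a path to a
#'   report JSON file.
#' @return \code{TRUE} invisibly; stops with the list of violations
#'   otherwise.
#' @export
validateReport <- function(report) {
  if (is.character(report))
    report <- jsonlite::fromJSON(report, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(system.file("schema", "report-schema.json",
                                           package = "ScrambleDisome"),
                               simplifyVector = FALSE)
  errs <- character(0)
  check <- function(node, sch, path) {
    tp <- sch$type
    if (identical(tp, "object")) {
      if (!is.list(node)) {
        errs <<- c(errs, paste0(path, ": expected object")); return()
      }
      for (req in sch$required)
        if (is.null(node[[req]]))
          errs <<- c(errs, paste0(path, ".", req, ": missing"))
      for (nm in names(sch$properties))
        if (!is.null(node[[nm]]))
          check(node[[nm]], sch$properties[[nm]], paste0(path, ".", nm))
    } else if (identical(tp, "number")) {
      if (!is.numeric(unlist(node)))
        errs <<- c(errs, paste0(path, ": expected number"))
    } else if (identical(tp, "string")) {
      if (!is.character(unlist(node)) && !is.null(unlist(node)))
        errs <<- c(errs, paste0(path, ": expected string"))
    } else if (identical(tp, "array")) {
      if (!is.null(sch$items) && length(node))
        for (el in node) check(el, sch$items, paste0(path, "[]"))
    }
  }
  check(report, schema, "report")
  if (length(errs)) stop("report schema violations: ",
                         paste(errs, collapse = "; "))
  invisible(TRUE)
}
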