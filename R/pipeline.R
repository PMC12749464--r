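# End-to-end orchestration. The exported R functions are the package's
# interface; runPipeline() chains the stages from a configuration list (or
# YAML file), writes each stage's artifact plus a manifest with input
# hashes, the config snapshot and wall-clock timings, and is deterministic
# given the seed.

#' Default pipeline configuration
#'
#' @param seed RNG seed for the simulation stage
#' @param n cohort size when simulating
#' @param k number of clusters to cut
#' @param indel indel cost
#' @param costMethod \code{"trate"}, \code{"constant"} or \code{"file"}
#' @param wardVariant \code{"ward.D2"} or \code{"ward.D"}
#' @param kScan range of k for the quality scan table
#' @param missingRate interior-gap rate passed to the generator
#' @param runModels fit the staged model series (slowest stage)
#' @return named configuration list
#' @export
pipelineConfig <- function(seed = 1, n = 500, k = 6, indel = 1,
                           costMethod = "trate", wardVariant = "ward.D2",
                           kScan = 2:8, missingRate = 0, runModels = FALSE) {
  list(seed = seed, n = n, k = k, indel = indel, costMethod = costMethod,
       wardVariant = wardVariant, kScan = kScan, missingRate = missingRate,
       runModels = runModels)
}

#' Run the full pipeline
#'
#' Stages: simulate (or load persons/marriages files) -> build sequences
#' -> estimate costs -> OM distance matrix -> Ward clustering at k ->
#' quality indices and k scan -> cluster summaries -> optionally the
#' staged model series on the analytic table. Every artifact is written
#' under \code{outDir} along with \code{manifest.json} (config snapshot,
#' md5 of written artifacts, stage timings).
#'
#' @param config list from [pipelineConfig()], or a path to a YAML file
#'   with the same keys
#' @param outDir output directory (created if missing); \code{NULL} skips
#'   all file output
#' @param personsFile,marriagesFile optional input CSVs; when given, the
#'   simulation stage is skipped and sequences are built from these
#'   records (the analytic/model stage then requires \code{runModels =
#'   FALSE} unless an analytic table is supplied via \code{analytic})
#' @param analytic optional analytic table overriding the simulated one
#' @return list with \code{sequences}, \code{exclusions}, \code{rates},
#'   \code{scheme}, \code{distances}, \code{tree}, \code{clusters},
#'   \code{quality}, \code{scan}, \code{summaries}, and (when available)
#'   \code{sim}, \code{series}, \code{manifest}
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        personsFile = NULL, marriagesFile = NULL,
                        analytic = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfgDefaults <- pipelineConfig()
  for (nm in names(cfgDefaults))
    if (is.null(config[[nm]])) config[[nm]] <- cfgDefaults[[nm]]
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  out <- list(config = config)

  if (!is.null(personsFile)) {
    persons <- readPersons(personsFile)
    marriages <- readMarriages(marriagesFile)
    rawStates <- NULL
  } else {
    gc2 <- generatorConfig(n = config$n, missingRate = config$missingRate)
    sim <- simulateCohort(gc2, seed = config$seed)
    out$sim <- sim
    persons <- sim$persons
    marriages <- sim$marriages
    rawStates <- sim$rawStates
    if (is.null(analytic)) analytic <- sim$analytic
  }
  tick("simulate")

  built <- buildCohort(persons, marriages, rawStates = rawStates)
  out$sequences <- built$sequences
  out$exclusions <- built$exclusions
  tick("build_sequences")

  out$rates <- estimateTransitionRates(out$sequences)
  out$scheme <- switch(config$costMethod,
    trate = trateCosts(out$rates, indel = config$indel),
    constant = constantCosts(indel = config$indel),
    file = readCostScheme(config$costsFile),
    stop("unknown costMethod: ", config$costMethod))
  tick("costs")

  out$distances <- pairwiseMatrix(out$sequences, out$scheme)
  tick("distances")

  out$tree <- wardLinkage(out$distances, variant = config$wardVariant)
  out$clusters <- cutTree(out$tree, k = config$k)
  tick("cluster")

  out$quality <- qualityIndices(out$distances, out$clusters)
  out$scan <- qualityScan(out$distances, out$tree, kRange = config$kScan)
  tick("quality")

  out$summaries <- summarizeClusters(out$sequences, out$clusters)
  tick("summarize")

  if (isTRUE(config$runModels) && !is.null(analytic)) {
    keep <- analytic$person_id %in% personIds(out$sequences)
    out$series <- runModelSeries(analytic[keep, , drop = FALSE])
    tick("fit")
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    writeSequences(out$sequences, p("sequences.csv"))
    write.csv(out$exclusions, p("exclusions.csv"), row.names = FALSE)
    writeCostScheme(out$scheme, p("costs.csv"))
    writeDistances(out$distances, p("distances.csv"))
    writeLabels(out$clusters, p("labels.csv"))
    writeQuality(out$quality, p("quality.json"))
    write.csv(out$scan, p("quality_scan.csv"), row.names = FALSE)
    if (!is.null(out$series))
      write.csv(out$series$table, p("model_series.csv"), row.names = FALSE)
    arts <- list.files(outDir, full.names = TRUE)
    arts <- arts[basename(arts) != "manifest.json"]
    manifest <- list(
      config = config,
      timings_sec = as.list(timings),
      artifacts = as.list(setNames(unname(tools::md5sum(arts)),
                                   basename(arts))),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("PartnerTraj")))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    out$manifest <- manifest
  }
  out
}
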