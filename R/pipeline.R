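#' @include AllClasses.R loop-sets.R feature-matrix.R classify.R importance.R io.R
NULL

## deterministic checksum of an R object (Horner hash of its deparse)
.checksum <- function(obj) {
    bytes <- utf8ToInt(paste(deparse(obj), collapse = "\n"))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%010d", as.integer(h))
}

#' Build a pipeline run configuration
#'
#' Exactly one of `simulation` (a [SimConfig-class]) or `inputs` (paths to
#' real interaction/peak/read files) must be given.
#'
#' @param outputDir directory for artifacts and the run manifest.
#' @param simulation a [SimConfig-class], or NULL when using real inputs.
#' @param inputs NULL, or a list with `replicate_a`, `replicate_b` (BEDPE),
#'   `peaks` (BED), `tracks_dir` (BED + `.libsize` per track) and `schema`
#'   (data.frame name/category).
#' @param maxGap anchor-matching gap in bp (default 2000).
#' @param nBins bins per track (default 1500).
#' @param windowBins anchor-window size in bins (default 100).
#' @param ksTolerance KS acceptance threshold for distance matching.
#' @param candidateFactor candidate negatives generated per positive.
#' @param maxSpan maximum candidate loop length in bp; `NULL` (default)
#'   caps candidates at the maximum positive loop length, so the candidate
#'   pool spans the same distance range the matching must reproduce.
#' @param split a [SplitSpec-class].
#' @param algorithms classifier names to run.
#' @param categories feature-category subsets to evaluate.
#' @param writeMatrix write the full feature matrix as TSV (can be large).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a `loopPipelineConfig` list.
#' @export
loopPipelineConfig <- function(outputDir = tempfile("loopforge_run_"),
                               simulation = SimConfig(),
                               inputs = NULL,
                               maxGap = 2000, nBins = 1500L,
                               windowBins = 100L, ksTolerance = 0.1,
                               candidateFactor = 5, maxSpan = NULL,
                               split = SplitSpec(),
                               algorithms = .algorithms,
                               categories = "All",
                               writeMatrix = TRUE,
                               seed = 1L) {
    structure(list(outputDir = outputDir, simulation = simulation,
                   inputs = inputs, maxGap = maxGap,
                   nBins = as.integer(nBins),
                   windowBins = as.integer(windowBins),
                   ksTolerance = ksTolerance,
                   candidateFactor = candidateFactor, maxSpan = maxSpan,
                   split = split, algorithms = algorithms,
                   categories = categories, writeMatrix = writeMatrix,
                   seed = as.integer(seed)),
              class = "loopPipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Recognizes the fields of [loopPipelineConfig()] in snake_case, with
#' `simulation` given as a [SimConfig-class] block.
#'
#' @param path YAML file.
#' @return a `loopPipelineConfig` list.
#' @export
loadRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    split <- SplitSpec(trainFraction = y$split$train_fraction %||% 0.8,
                       seed = as.integer(y$split$seed %||% y$seed %||% 1L),
                       stratified = y$split$stratified %||% TRUE)
    loopPipelineConfig(
        outputDir = y$output_dir %||% tempfile("loopforge_run_"),
        simulation = if (!is.null(y$simulation))
            .configFromList(y$simulation) else NULL,
        inputs = y$inputs,
        maxGap = y$max_gap %||% 2000, nBins = y$n_bins %||% 1500L,
        windowBins = y$window_bins %||% 100L,
        ksTolerance = y$ks_tolerance %||% 0.1,
        candidateFactor = y$candidate_factor %||% 5,
        maxSpan = y$max_span,
        split = split,
        algorithms = unlist(y$algorithms) %||% .algorithms,
        categories = unlist(y$categories) %||% "All",
        writeMatrix = y$write_matrix %||% TRUE,
        seed = as.integer(y$seed %||% 1L))
}

#' Validate a pipeline configuration
#'
#' Checks the configuration invariants without mutating state.
#'
#' @param config a `loopPipelineConfig` list.
#' @return character vector of problems; empty means valid.
#' @export
validateConfig <- function(config) {
    p <- character()
    hasSim <- !is.null(config$simulation)
    hasInputs <- !is.null(config$inputs)
    if (hasSim == hasInputs)
        p <- c(p, "exactly one of 'simulation' or 'inputs' must be present")
    if (hasSim && !is(config$simulation, "SimConfig"))
        p <- c(p, "'simulation' must be a SimConfig")
    if (hasSim && is(config$simulation, "SimConfig")) {
        msg <- validObject(config$simulation, test = TRUE)
        if (is.character(msg)) p <- c(p, paste0("simulation: ", msg))
    }
    if (hasInputs) {
        need <- c("replicate_a", "replicate_b", "peaks", "tracks_dir")
        miss <- setdiff(need, names(config$inputs))
        if (length(miss))
            p <- c(p, sprintf("inputs missing: %s",
                              paste(miss, collapse = ", ")))
        for (f in intersect(need, names(config$inputs))) {
            path <- config$inputs[[f]]
            if (!file.exists(path))
                p <- c(p, sprintf("input file not found: %s", path))
        }
    }
    badCat <- setdiff(config$categories, .subsetCategories)
    if (length(badCat))
        p <- c(p, sprintf("unknown category: %s",
                          paste(badCat, collapse = ", ")))
    badAlg <- setdiff(config$algorithms, .algorithms)
    if (length(badAlg))
        p <- c(p, sprintf("unknown algorithm: %s",
                          paste(badAlg, collapse = ", ")))
    if (config$windowBins %% 2L != 0L)
        p <- c(p, "window_bins must be even")
    if (config$nBins %% 3L != 0L)
        p <- c(p, "n_bins must be divisible by 3")
    if (config$maxGap < 0) p <- c(p, "max_gap must be >= 0")
    if (config$ksTolerance <= 0) p <- c(p, "ks_tolerance must be > 0")
    if (config$candidateFactor < 1)
        p <- c(p, "candidate_factor must be >= 1")
    msg <- validObject(config$split, test = TRUE)
    if (is.character(msg)) p <- c(p, paste0("split: ", msg))
    p
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full loop-prediction pipeline
#'
#' Simulate (or load) the inputs, build the labeled loop set (replicate
#' intersection, candidate negatives, positive-overlap filtering, distance
#' matching, balancing), build the feature matrix, train and evaluate the
#' configured algorithms per category, extract importance profiles for the
#' tree-based learners, and write all artifacts plus a JSON run manifest
#' recording seeds, the config checksum and per-stage cardinalities.
#'
#' @param config a `loopPipelineConfig` list (validated first; problems
#'   abort the run).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
    problems <- validateConfig(config)
    if (length(problems))
        stop(paste(c("invalid configuration:", problems), collapse = "\n  "))
    outDir <- config$outputDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- config$seed
    manifest <- list(package = "loopForge",
                     version = as.character(utils::packageVersion("loopForge")),
                     seed = seed,
                     configChecksum = .checksum(unclass(config)[
                         setdiff(names(config), "outputDir")]),
                     created = format(Sys.time(), tz = "UTC"),
                     stages = list())

    ## inputs
    if (!is.null(config$simulation)) {
        data <- .stage("simulate", {
            ds <- simulateLoopDataset(config$simulation, seed = seed)
            list(repA = ds@replicateA, repB = ds@replicateB,
                 peaks = ds@peaks, tracks = ds@tracks,
                 schema = schemaFromProfiles(config$simulation@assayProfiles))
        })
    } else {
        data <- .stage("load-inputs", {
            schema <- if (!is.null(config$inputs$schema))
                config$inputs$schema else defaultTrackSchema()
            tracks <- lapply(schema$name, function(nm)
                readTrackBed(config$inputs$tracks_dir, nm))
            list(repA = readBedpe(config$inputs$replicate_a),
                 repB = readBedpe(config$inputs$replicate_b),
                 peaks = readPeaksBed(config$inputs$peaks),
                 tracks = tracks, schema = schema)
        })
    }
    manifest$stages$inputs <- list(replicateA = length(data$repA),
                                   replicateB = length(data$repB),
                                   peaks = length(data$peaks),
                                   tracks = length(data$tracks))

    ## labeled loop set
    sets <- .stage("loop-sets", {
        positives <- intersectReplicates(data$repA, data$repB, config$maxGap)
        if (length(positives) < 4L)
            stop("too few replicated positive loops")
        maxSpan <- config$maxSpan %||% max(loopLength(positives))
        candidates <- generateCandidateNegatives(
            data$peaks, nCandidates = config$candidateFactor * length(positives),
            maxSpan = maxSpan, seed = stageSeed(seed, 21L))
        candidates <- removePositiveOverlaps(candidates, positives,
                                             config$maxGap)
        if (length(candidates) < length(positives))
            stop("not enough candidate negatives after filtering")
        negatives <- matchDistanceDistribution(
            candidates, positives, nTarget = length(positives),
            seed = stageSeed(seed, 22L), ksTolerance = config$ksTolerance)
        list(positives = positives, candidates = candidates,
             negatives = negatives)
    })
    manifest$stages$loopSets <- list(
        positives = length(sets$positives),
        candidates = length(sets$candidates),
        negatives = length(sets$negatives),
        ksStatistic = attr(sets$negatives, "ksStatistic"))
    labeled <- .stage("loop-sets", buildLabeledSet(sets$positives,
                                                   sets$negatives))
    writeBedpe(labeled, file.path(outDir, "labeled_loops.bedpe"))

    ## feature matrix
    fm <- .stage("feature-matrix",
        buildFeatureMatrix(labeled, data$tracks, data$schema, config$nBins))
    manifest$stages$featureMatrix <- list(loops = ncol(fm),
                                          features = nrow(fm),
                                          tracks = nrow(data$schema),
                                          nBins = config$nBins)
    if (isTRUE(config$writeMatrix))
        writeFeatureMatrix(fm, file.path(outDir, "feature_matrix.tsv"))

    ## classification per category
    specs <- lapply(config$algorithms, modelSpec,
                    seed = stageSeed(seed, 31L))
    names(specs) <- config$algorithms
    allResults <- list()
    treeAlgs <- intersect(config$algorithms,
                          c("decision_tree", "random_forest", "xgboost"))
    manifest$stages$importance <- list()
    for (cat in config$categories) {
        fmC <- .stage(paste0("subset-", cat),
                      selectSubset(fm, cat, config$windowBins))
        res <- .stage(paste0("classify-", cat),
                      runComparison(fmC, specs, config$split))
        allResults[[cat]] <- res
        models <- attr(res, "models")
        for (alg in intersect(treeAlgs, names(models))) {
            prof <- .stage(paste0("importance-", cat, "-", alg), {
                p <- featureImportance(models[[alg]])
                writeImportanceRanking(p, file.path(outDir,
                    sprintf("importance_%s_%s.tsv", cat, alg)), k = 30L)
                p
            })
            manifest$stages$importance[[paste(cat, alg, sep = ":")]] <-
                list(anchorConcentration =
                         anchorConcentration(prof, config$windowBins))
        }
    }
    results <- do.call(rbind, c(allResults, make.row.names = FALSE))
    utils::write.table(results, file.path(outDir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$classify <- list(
        rows = nrow(results), ok = sum(results$status == "ok"),
        algorithms = length(config$algorithms),
        categories = length(config$categories))

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
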