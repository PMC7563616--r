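# Shared fixture builders. Simulated datasets are cached per session so the
# heavier ones are built once and reused across test files.

.forgeCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
    if (!exists(name, envir = .forgeCache))
        assign(name, builder(), envir = .forgeCache)
    get(name, envir = .forgeCache)
}

# five-track profile set with planted signal restricted to the architectural
# tracks (CTCF/RAD21 anchors, everything else pure background)
archOnlyProfiles <- function(factor = 10) {
    list(AssayProfile("CTCF", "architectural", "anchor", factor),
         AssayProfile("RAD21", "architectural", "anchor", factor),
         AssayProfile("ATF3", "tf", "background", 1),
         AssayProfile("REST", "tf", "background", 1),
         AssayProfile("H3K36me3", "histone", "background", 1))
}

# same five tracks but TF tracks carry equal anchor signal
archPlusTfProfiles <- function(factor = 10) {
    list(AssayProfile("CTCF", "architectural", "anchor", factor),
         AssayProfile("RAD21", "architectural", "anchor", factor),
         AssayProfile("ATF3", "tf", "anchor", factor),
         AssayProfile("REST", "tf", "anchor", factor),
         AssayProfile("H3K36me3", "histone", "background", 1))
}

# labeled matrix from a simulated dataset: positives = true loops,
# negatives = distance-matched decoy peak pairs (no planted signal)
plantedMatrix <- function(ds, seed = 1L) {
    pos <- ds@trueLoops
    decoys <- ds@peaks[ds@peaks$isDecoy]
    cand <- generateCandidateNegatives(decoys, 10L * length(pos),
                                       maxSpan = max(loopLength(pos)),
                                       seed = seed)
    neg <- suppressWarnings(
        matchDistanceDistribution(cand, pos, length(pos), seed = seed + 1L))
    lab <- buildLabeledSet(pos, neg)
    buildFeatureMatrix(lab, ds@tracks,
                       schemaFromProfiles(ds@config@assayProfiles), 1500L)
}

archDataset <- function() cached("archDataset", function()
    simulateLoopDataset(SimConfig(chromSizes = c(simA = 5e7, simB = 3e7),
                                  nLoops = 500L,
                                  assayProfiles = archOnlyProfiles(),
                                  nDecoyPeaks = 3000L, seed = 42L)))

archMatrix <- function() cached("archMatrix", function()
    plantedMatrix(archDataset(), seed = 7L))

tfDataset <- function() cached("tfDataset", function()
    simulateLoopDataset(SimConfig(chromSizes = c(simA = 5e7, simB = 3e7),
                                  nLoops = 500L,
                                  assayProfiles = archPlusTfProfiles(),
                                  nDecoyPeaks = 3000L, seed = 43L)))

tfMatrix <- function() cached("tfMatrix", function()
    plantedMatrix(tfDataset(), seed = 9L))

# two simulated cell lines: shared architectural signal, disjoint
# cell-specific TF signal (ATF3/SP1 in line 1, REST/MAX in line 2)
cellPairProfiles <- function(factor = 10) {
    list(AssayProfile("CTCF", "architectural", "anchor", factor, 0L),
         AssayProfile("RAD21", "architectural", "anchor", factor, 0L),
         AssayProfile("ATF3", "tf", "anchor", factor, 1L),
         AssayProfile("SP1", "tf", "anchor", factor, 1L),
         AssayProfile("REST", "tf", "anchor", factor, 2L),
         AssayProfile("MAX", "tf", "anchor", factor, 2L))
}

cellPairMatrices <- function() cached("cellPairMatrices", function() {
    cfg <- SimConfig(chromSizes = c(simA = 5e7, simB = 3e7), nLoops = 500L,
                     assayProfiles = cellPairProfiles(),
                     nDecoyPeaks = 3000L, seed = 44L)
    pair <- simulateCellLinePair(cfg)
    list(line1 = plantedMatrix(pair$line1, seed = 11L),
         line2 = plantedMatrix(pair$line2, seed = 13L))
})

# tiny 23-track dataset on a small genome (structural checks, io tests)
tinyFullDataset <- function() cached("tinyFullDataset", function()
    simulateLoopDataset(SimConfig(chromSizes = c(mini = 4e6), nLoops = 4L,
                                  loopLengthRange = c(1e4, 1e5),
                                  assayProfiles = defaultAssayProfiles(),
                                  nDecoyPeaks = 20L, backgroundRate = 1e-4,
                                  seed = 3L)))

tinyFullMatrix <- function() cached("tinyFullMatrix", function() {
    ds <- tinyFullDataset()
    lab <- buildLabeledSet(ds@trueLoops[1:2], ds@trueLoops[3:4])
    buildFeatureMatrix(lab, ds@tracks, defaultTrackSchema(), 1500L)
})

# small in-silico feature matrix built directly (no genomics), for fast
# classifier and importance tests: positives get `effect` added on the
# architectural anchor-window bins
makeToyMatrix <- function(n = 200L, nBins = 30L,
                          schema = data.frame(
                              name = c("CTCF", "ATF3"),
                              category = c("architectural", "tf")),
                          effect = 2, windowBins = 6L, seed = 1L,
                          shuffle = FALSE) {
    set.seed(seed)
    nf <- nrow(schema) * nBins
    M <- matrix(stats::rexp(nf * n), nf, n)
    labels <- rep(c(1L, 0L), length.out = n)
    rd <- loopForge:::.featureSchema(schema, nBins)
    sigRows <- rd$category == "architectural" &
        rd$absolute_bin %in% anchorWindowBins(nBins, windowBins)
    M[sigRows, labels == 1L] <- M[sigRows, labels == 1L] + effect
    if (shuffle) labels <- sample(labels)
    rownames(M) <- rownames(rd)
    colnames(M) <- paste0("loop_", seq_len(n))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = M), rowData = rd,
        colData = S4Vectors::DataFrame(label = labels,
                                       row.names = colnames(M)))
    S4Vectors::metadata(se)$nBins <- nBins
    S4Vectors::metadata(se)$schema <- schema
    S4Vectors::metadata(se)$category <- "All"
    new("LoopFeatureMatrix", se)
}

# plain loop set with given lengths (bp), one per length
loopsOfLength <- function(lengths, chrom = "chrS", gapStart = 1e6,
                          anchorWidth = 2000) {
    n <- length(lengths)
    s0 <- gapStart + (seq_len(n) - 1) * 3e6
    LoopSet(chrom = chrom, leftStart = s0, leftEnd = s0 + anchorWidth,
            rightStart = s0 + lengths - anchorWidth,
            rightEnd = s0 + lengths,
            provenance = "toy")
}
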