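simProfiles <- list(AssayProfile("CTCF", "architectural"))

test_that("simulateLoops respects counts, widths and the log-uniform law", {
    cfg <- SimConfig(chromSizes = c(simA = 6e7), nLoops = 1000L,
                     assayProfiles = simProfiles, seed = 1L)
    ## empty case
    cfg0 <- SimConfig(chromSizes = c(simA = 6e7), nLoops = 0L,
                      assayProfiles = simProfiles)
    expect_length(simulateLoops(cfg0, seed = 1L), 0L)
    ## seed determinism
    a <- simulateLoops(cfg, seed = 7L)
    b <- simulateLoops(cfg, seed = 7L)
    expect_identical(GenomicRanges::start(leftAnchors(a)),
                     GenomicRanges::start(leftAnchors(b)))
    expect_identical(GenomicRanges::end(rightAnchors(a)),
                     GenomicRanges::end(rightAnchors(b)))
    ## lengths inside the configured range, anchors of configured width
    L <- loopLength(a)
    expect_true(all(L >= 1e4 & L <= 5e5))
    expect_true(all(GenomicRanges::width(leftAnchors(a)) == 2000L))
    expect_length(a, 1000L)
    expect_false(any(duplicated(paste(GenomicRanges::start(leftAnchors(a)),
                                      L))))
    ## sample CDF of log-lengths vs the log-uniform sampling law
    ks <- suppressWarnings(stats::ks.test(log10(L), "punif",
                                          log10(1e4), log10(5e5)))$statistic
    expect_lte(unname(ks), 0.05)
})

test_that("placement fails cleanly when chromosomes are too small", {
    cfg <- SimConfig(chromSizes = c(tiny = 6e3), nLoops = 10L,
                     loopLengthRange = c(1e4, 5e5),
                     assayProfiles = simProfiles)
    expect_error(simulateLoops(cfg, seed = 1L), "too small")
})

test_that("replicates reproduce truth exactly when noise-free", {
    cfg <- SimConfig(chromSizes = c(simA = 6e7), nLoops = 200L,
                     replicateJitterSd = 0, replicateDropout = 0,
                     assayProfiles = simProfiles)
    loops <- simulateLoops(cfg, seed = 2L)
    reps <- simulateReplicates(loops, cfg, seed = 3L)
    for (r in reps) {
        expect_identical(GenomicRanges::start(leftAnchors(r)),
                         GenomicRanges::start(leftAnchors(loops)))
        expect_identical(GenomicRanges::end(rightAnchors(r)),
                         GenomicRanges::end(rightAnchors(loops)))
    }
})

test_that("replicate jitter matches the half-normal mean and keeps invariants", {
    sd <- 500
    cfg <- SimConfig(chromSizes = c(simA = 8e7), nLoops = 1000L,
                     replicateJitterSd = sd, replicateDropout = 0,
                     assayProfiles = simProfiles)
    loops <- simulateLoops(cfg, seed = 4L)
    reps <- simulateReplicates(loops, cfg, seed = 5L)
    r <- reps$a
    expect_length(r, 1000L)  # no dropout
    ## widths preserved, ordering preserved
    expect_true(all(GenomicRanges::width(leftAnchors(r)) ==
                    GenomicRanges::width(leftAnchors(loops))))
    expect_true(all(GenomicRanges::end(leftAnchors(r)) <=
                    GenomicRanges::start(rightAnchors(r)) - 1))
    ## |shift| has the half-normal mean sd * sqrt(2/pi); test within 3 SE.
    ## A few loops may have had their jitter dropped to preserve ordering,
    ## which only biases the mean down by a negligible amount at sd = 500.
    shifts <- c(GenomicRanges::start(leftAnchors(r)) -
                GenomicRanges::start(leftAnchors(loops)),
                GenomicRanges::start(rightAnchors(r)) -
                GenomicRanges::start(rightAnchors(loops)))
    mu <- sd * sqrt(2 / pi)
    se <- sd * sqrt(1 - 2 / pi) / sqrt(length(shifts))
    expect_lt(abs(mean(abs(shifts)) - mu), 3 * se + 0.5)
})

test_that("dropout removes loops at the configured rate", {
    cfg <- SimConfig(chromSizes = c(simA = 8e7), nLoops = 1000L,
                     replicateJitterSd = 0, replicateDropout = 0.3,
                     assayProfiles = simProfiles)
    loops <- simulateLoops(cfg, seed = 6L)
    reps <- simulateReplicates(loops, cfg, seed = 7L)
    sdBin <- sqrt(1000 * 0.7 * 0.3)
    expect_lt(abs(length(reps$a) - 700), 3 * sdBin)
    expect_lt(abs(length(reps$b) - 700), 3 * sdBin)
    ## every replicate loop derives from a true loop (ids preserved)
    expect_true(all(loopIds(reps$a) %in% loopIds(loops)))
})

test_that("track simulation: degenerate background and rate conservation", {
    cfg <- SimConfig(chromSizes = c(simA = 2e7), nLoops = 100L,
                     assayProfiles = simProfiles, backgroundRate = 0)
    loops <- simulateLoops(cfg, seed = 8L)
    ## background_rate = 0: enrichment is a multiplier on the background,
    ## so no reads arise anywhere; the track is still a valid (empty) object
    tr <- simulateTrack(simProfiles[[1]], loops, cfg, seed = 9L)
    anchors <- c(GenomicRanges::granges(leftAnchors(loops)),
                 GenomicRanges::granges(rightAnchors(loops)))
    expect_length(trackReads(tr), 0L)
    expect_true(all(IRanges::overlapsAny(trackReads(tr), anchors,
                                         type = "within")))
    expect_identical(librarySize(tr), 1)
    ## rate conservation: N within 3 sqrt(lambda) of expectation
    cfg2 <- SimConfig(chromSizes = c(simA = 2e7), nLoops = 100L,
                      assayProfiles = simProfiles, backgroundRate = 2e-3)
    loops2 <- simulateLoops(cfg2, seed = 10L)
    tr2 <- simulateTrack(simProfiles[[1]], loops2, cfg2, seed = 11L)
    anchorBp <- sum(GenomicRanges::width(anchors))
    lambda <- 2e-3 * 2e7 + 2e-3 * (10 - 1) * anchorBp
    expect_lt(abs(length(trackReads(tr2)) - lambda), 3 * sqrt(lambda))
})

test_that("anchor enrichment recovers the configured rate ratio", {
    cfg <- SimConfig(chromSizes = c(simA = 8e7), nLoops = 1000L,
                     assayProfiles = simProfiles, backgroundRate = 2e-3)
    loops <- simulateLoops(cfg, seed = 12L)
    tr <- simulateTrack(simProfiles[[1]], loops, cfg, seed = 13L)
    reads <- trackReads(tr)
    mids <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(reads),
        IRanges::IRanges(start = floor((GenomicRanges::start(reads) - 1 +
                                        GenomicRanges::end(reads)) / 2) + 1,
                         width = 1))
    anchors <- c(GenomicRanges::granges(leftAnchors(loops)),
                 GenomicRanges::granges(rightAnchors(loops)))
    anchorBp <- GenomicRanges::reduce(anchors)
    ## flanks: same-width windows 20 kb left of each left anchor, dropping
    ## any that happen to overlap another loop's enriched anchor
    flanks <- GenomicRanges::shift(GenomicRanges::granges(leftAnchors(loops)),
                                   -20000L)
    flanks <- flanks[!IRanges::overlapsAny(flanks, anchors)]
    inAnchor <- sum(IRanges::overlapsAny(mids, anchorBp))
    inFlank <- sum(IRanges::overlapsAny(mids, flanks))
    ratio <- (inAnchor / sum(GenomicRanges::width(anchorBp))) /
             (inFlank / sum(GenomicRanges::width(flanks)))
    expect_gt(ratio, 10 * 0.8)
    expect_lt(ratio, 10 * 1.2)
})

test_that("null enrichment leaves anchors at background coverage", {
    prof <- AssayProfile("flat", "tf", "anchor", enrichmentFactor = 1)
    cfg <- SimConfig(chromSizes = c(simA = 2e7), nLoops = 200L,
                     assayProfiles = list(prof), backgroundRate = 2e-3)
    loops <- simulateLoops(cfg, seed = 20L)
    anchors <- c(GenomicRanges::granges(leftAnchors(loops)),
                 GenomicRanges::granges(rightAnchors(loops)))
    flanks <- GenomicRanges::shift(GenomicRanges::granges(leftAnchors(loops)),
                                   -20000L)
    ## compare per-bp midpoint rates over disjoint base sets (anchors can
    ## overlap each other; flanks can graze anchors)
    anchorsU <- GenomicRanges::reduce(anchors)
    flanksU <- GenomicRanges::setdiff(GenomicRanges::reduce(flanks), anchorsU)
    ## pooled Poisson counts over 50 simulations: rate-equality test must
    ## not reject at alpha = 0.01
    nA <- 0; nF <- 0
    for (s in seq_len(50L)) {
        tr <- simulateTrack(prof, loops, cfg, seed = 100L + s)
        reads <- trackReads(tr)
        mids <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(reads),
            IRanges::IRanges(start = floor((GenomicRanges::start(reads) - 1 +
                                            GenomicRanges::end(reads)) / 2) + 1,
                             width = 1))
        nA <- nA + sum(IRanges::overlapsAny(mids, anchorsU))
        nF <- nF + sum(IRanges::overlapsAny(mids, flanksU))
    }
    pv <- stats::poisson.test(c(nA, nF),
                              c(sum(GenomicRanges::width(anchorsU)),
                                sum(GenomicRanges::width(flanksU))))$p.value
    expect_gt(pv, 0.01)
})

test_that("peak sets count anchors plus decoys and keep decoys clear of anchors", {
    cfg <- SimConfig(chromSizes = c(simA = 4e7), nLoops = 100L,
                     assayProfiles = simProfiles, nDecoyPeaks = 50L)
    loops <- simulateLoops(cfg, seed = 14L)
    peaks <- simulatePeaks(loops, cfg, seed = 15L)
    nAnchors <- length(unique(c(GenomicRanges::granges(leftAnchors(loops)),
                                GenomicRanges::granges(rightAnchors(loops)))))
    expect_identical(length(peaks), nAnchors + 50L)
    expect_identical(nAnchors, 200L)  # distinct anchors for 100 random loops
    ## no decoys at all
    cfg0 <- SimConfig(chromSizes = c(simA = 4e7), nLoops = 100L,
                      assayProfiles = simProfiles, nDecoyPeaks = 0L)
    expect_identical(length(simulatePeaks(loops, cfg0, seed = 16L)), nAnchors)
    ## decoys are farther than the matching gap from every true anchor
    decoys <- peaks[peaks$isDecoy]
    anchors <- peaks[!peaks$isDecoy]
    d <- GenomicRanges::distanceToNearest(decoys, anchors)
    expect_true(all(S4Vectors::mcols(d)$distance > 2000))
    ## sorted by coordinate
    expect_false(is.unsorted(GenomicRanges::start(peaks[
        GenomicRanges::seqnames(peaks) == "simA"])))
})

test_that("whole-dataset simulation is seed-deterministic", {
    cfg <- SimConfig(chromSizes = c(simA = 1e7), nLoops = 30L,
                     assayProfiles = archOnlyProfiles(), nDecoyPeaks = 40L,
                     backgroundRate = 5e-4, seed = 99L)
    d1 <- simulateLoopDataset(cfg)
    d2 <- simulateLoopDataset(cfg)
    expect_identical(GenomicRanges::start(leftAnchors(d1@trueLoops)),
                     GenomicRanges::start(leftAnchors(d2@trueLoops)))
    expect_identical(length(d1@replicateA), length(d2@replicateA))
    for (nm in names(d1@tracks)) {
        expect_identical(GenomicRanges::start(trackReads(d1@tracks[[nm]])),
                         GenomicRanges::start(trackReads(d2@tracks[[nm]])))
    }
    ## different cell lines differ (independent loops)
    d3 <- simulateLoopDataset(cfg, cellLine = 2L)
    expect_false(identical(GenomicRanges::start(leftAnchors(d3@trueLoops)),
                           GenomicRanges::start(leftAnchors(d1@trueLoops))))
})

test_that("cell-specific profiles are silent in the other line", {
    cfg <- SimConfig(chromSizes = c(simA = 1e7), nLoops = 50L,
                     assayProfiles = cellPairProfiles(), nDecoyPeaks = 20L,
                     backgroundRate = 5e-4, seed = 77L)
    ds2 <- simulateLoopDataset(cfg, cellLine = 2L)
    ## ATF3 is line-1 specific: in line 2 its read count should be close to
    ## the pure background expectation, far below the enriched CTCF count
    nATF3 <- length(trackReads(ds2@tracks[["ATF3"]]))
    nCTCF <- length(trackReads(ds2@tracks[["CTCF"]]))
    lambdaBg <- 5e-4 * 1e7
    expect_lt(abs(nATF3 - lambdaBg), 4 * sqrt(lambdaBg))
    expect_gt(nCTCF, nATF3 * 1.1)
})
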