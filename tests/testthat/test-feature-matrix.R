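test_that("extendedRegion spans 3L and clamps at chromosome bounds", {
    loop <- LoopSet("c", 100000, 102000, 148000, 150000)
    reg <- extendedRegion(loop)
    expect_identical(GenomicRanges::start(reg) - 1L, 50000L)
    expect_identical(GenomicRanges::end(reg), 200000L)
    expect_identical(GenomicRanges::width(reg), 150000L)
    ## ratio region-length / loop-length = 3 for any unclamped loop
    ls <- loopsOfLength(c(2e4, 7e4, 3e5))
    expect_equal(GenomicRanges::width(extendedRegion(ls)) /
                 loopLength(ls), rep(3, 3))
    ## clamped at the chromosome start, with a warning
    nearStart <- LoopSet("c", 10000, 12000, 48000, 50000)
    expect_warning(regC <- extendedRegion(nearStart), "clamped")
    expect_identical(GenomicRanges::start(regC), 1L)  # 0-based position 0
})

test_that("partitionBins tiles the region exactly with near-equal widths", {
    reg <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 3000))
    grid <- partitionBins(reg, 1500L)
    expect_identical(grid@nBins, 1500L)
    expect_true(all(diff(grid@boundaries) == 2))
    ## indivisible length: widths in {2, 3}, total preserved
    reg2 <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 3001))
    g2 <- partitionBins(reg2, 1500L)
    w <- diff(g2@boundaries)
    expect_true(all(w %in% c(2, 3)))
    expect_identical(sum(w), 3001)
    ## too-short region
    expect_error(partitionBins(
        GenomicRanges::GRanges("c", IRanges::IRanges(1, 100)), 1500L),
        "shorter")
})

test_that("bin grids tile arbitrary regions without gaps or overlaps", {
    set.seed(5)
    for (i in 1:20) {
        len <- sample(1500:500000, 1)
        s0 <- sample(0:1e6, 1)
        reg <- GenomicRanges::GRanges("c",
            IRanges::IRanges(s0 + 1, s0 + len))
        g <- partitionBins(reg, 1500L)
        b <- g@boundaries
        expect_identical(b[1], as.numeric(s0))
        expect_identical(b[length(b)], as.numeric(s0 + len))
        w <- diff(b)
        expect_lte(max(w) - min(w), 1)
        expect_identical(sum(w), as.numeric(len))
    }
})

test_that("scoreBins counts read midpoints and normalizes to RPKM scale", {
    reg <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 1500000))
    grid <- partitionBins(reg, 1500L)  # 1000 bp bins
    ## empty track
    empty <- ReadTrack("e", GenomicRanges::GRanges(), librarySize = 1e6)
    expect_identical(scoreBins(empty, grid), rep(0, 1500))
    ## one read with its midpoint in bin 42, library 1e6, 1 kb bins -> 1.0
    tr <- ReadTrack("t", data.frame(chrom = "c", start = 41475, end = 41525),
                    librarySize = 1e6)
    sc <- scoreBins(tr, grid)
    expect_identical(sc[42], 1.0)
    expect_identical(sum(sc != 0), 1L)
    ## boundary convention: midpoint exactly at a boundary goes to the
    ## right-hand bin (half-open bins)
    tr2 <- ReadTrack("t2", data.frame(chrom = "c", start = 975, end = 1025),
                     librarySize = 1e6)
    expect_identical(scoreBins(tr2, grid, raw = TRUE)[2], 1L)
})

test_that("bin counts conserve the midpoint-in-region total", {
    ds <- tinyFullDataset()
    loops <- ds@trueLoops
    regions <- extendedRegion(loops)
    for (tr in ds@tracks[c("CTCF", "RNAseq", "H3K27me3")]) {
        reads <- trackReads(tr)
        m0 <- floor((GenomicRanges::start(reads) - 1 +
                     GenomicRanges::end(reads)) / 2)
        for (j in seq_along(loops)) {
            grid <- partitionBins(regions[j], 1500L)
            onChrom <- as.character(GenomicRanges::seqnames(reads)) ==
                as.character(GenomicRanges::seqnames(regions[j]))
            expected <- sum(onChrom &
                            m0 >= GenomicRanges::start(regions[j]) - 1 &
                            m0 < GenomicRanges::end(regions[j]))
            expect_identical(sum(scoreBins(tr, grid, raw = TRUE)), expected)
        }
    }
})

test_that("buildFeatureMatrix lays out features track-major with labels", {
    fm <- tinyFullMatrix()
    expect_identical(nrow(fm), 23L * 1500L)  # 34,500 features
    expect_identical(ncol(fm), 4L)
    rd <- SummarizedExperiment::rowData(fm)
    ## track-major: first 1500 features belong to the first schema track
    expect_identical(unique(rd$track[1:1500]), defaultTrackSchema()$name[1])
    expect_identical(rd$absolute_bin[1:3], 1:3)
    ## window naming at the thirds
    expect_identical(rd$window[c(1, 500, 501, 1000, 1001, 1500)],
                     c("left", "left", "in", "in", "right", "right"))
    expect_identical(rownames(fm)[1501], paste0(defaultTrackSchema()$name[2],
                                                "_left_1"))
    expect_identical(SummarizedExperiment::colData(fm)$label, c(1L, 1L, 0L, 0L))
    expect_true(all(SummarizedExperiment::assay(fm) >= 0))
})

test_that("single-track and empty loop sets keep the full column schema", {
    ds <- tinyFullDataset()
    schema1 <- data.frame(name = "CTCF", category = "architectural")
    lab <- buildLabeledSet(ds@trueLoops[1:2], ds@trueLoops[3:4])
    fm1 <- buildFeatureMatrix(lab, ds@tracks["CTCF"], schema1, 1500L)
    expect_identical(nrow(fm1), 1500L)
    fm0 <- buildFeatureMatrix(lab[0], ds@tracks["CTCF"], schema1, 1500L)
    expect_identical(dim(fm0), c(1500L, 0L))
    expect_identical(rownames(fm0), rownames(fm1))
})

test_that("schema mismatches name the offending track", {
    ds <- tinyFullDataset()
    lab <- buildLabeledSet(ds@trueLoops[1:2], ds@trueLoops[3:4])
    expect_error(buildFeatureMatrix(lab, ds@tracks[-1],
                                    defaultTrackSchema(), 1500L),
                 "DNase")
    expect_error(buildFeatureMatrix(
        lab, ds@tracks, data.frame(name = "CTCF",
                                   category = "architectural"), 1500L),
        "not in schema")
})

test_that("doubling library size halves every score exactly", {
    ds <- tinyFullDataset()
    lab <- buildLabeledSet(ds@trueLoops[1:2], ds@trueLoops[3:4])
    schema1 <- data.frame(name = "CTCF", category = "architectural")
    tr <- ds@tracks[["CTCF"]]
    tr2 <- ReadTrack("CTCF", trackReads(tr), librarySize = 2 * librarySize(tr))
    fmA <- buildFeatureMatrix(lab, list(tr), schema1, 1500L)
    fmB <- buildFeatureMatrix(lab, list(tr2), schema1, 1500L)
    expect_identical(SummarizedExperiment::assay(fmA),
                     2 * SummarizedExperiment::assay(fmB))
})

test_that("anchor windows straddle the window boundaries symmetrically", {
    expect_identical(anchorWindowBins(1500L, 100L),
                     c(451:550, 951:1050))
    expect_identical(anchorWindowBins(1500L, 2L), c(500L, 501L, 1000L, 1001L))
    expect_error(anchorWindowBins(1500L, 99L), "even")
    expect_error(anchorWindowBins(1500L, 600L), "at most")
    ## one track at defaults: 200 indices; two tracks: offset by nBins
    schema1 <- data.frame(name = "a", category = "tf")
    expect_length(anchorWindowColumns(schema1, 1500L, 100L), 200L)
    schema2 <- data.frame(name = c("a", "b"), category = c("tf", "tf"))
    cols <- anchorWindowColumns(schema2, 1500L, 100L)
    expect_length(cols, 400L)
    expect_true(all(cols[201:400] == cols[1:200] + 1500L))
})

test_that("category subsets carve the documented column counts", {
    fm <- tinyFullMatrix()
    expect_identical(nrow(selectSubset(fm, "All")), 34500L)
    expect_identical(nrow(selectSubset(fm, "Architectural")), 3000L)
    expect_identical(nrow(selectSubset(fm, "TF")), 13500L)
    expect_identical(nrow(selectSubset(fm, "Transcription")), 31500L)
    expect_identical(nrow(selectSubset(fm, "Architectural-anchors")), 400L)
    expect_identical(nrow(selectSubset(fm, "TF-anchors")), 1800L)
    expect_error(selectSubset(fm, "Bogus"), "valid categories")
    ## rows and labels unchanged
    sub <- selectSubset(fm, "TF")
    expect_identical(SummarizedExperiment::colData(sub)$label,
                     SummarizedExperiment::colData(fm)$label)
    ## idempotence
    twice <- selectSubset(selectSubset(fm, "TF-anchors"), "TF-anchors")
    expect_identical(rownames(twice),
                     rownames(selectSubset(fm, "TF-anchors")))
    expect_identical(SummarizedExperiment::assay(twice),
                     SummarizedExperiment::assay(selectSubset(fm,
                                                              "TF-anchors")))
})

test_that("feature layout is stable across matrices with the same schema", {
    ds <- tinyFullDataset()
    labA <- buildLabeledSet(ds@trueLoops[1:2], ds@trueLoops[3:4])
    labB <- buildLabeledSet(ds@trueLoops[3:4], ds@trueLoops[1:2])
    fmA <- buildFeatureMatrix(labA, ds@tracks, defaultTrackSchema(), 1500L)
    fmB <- buildFeatureMatrix(labB, ds@tracks, defaultTrackSchema(), 1500L)
    expect_identical(rownames(fmA), rownames(fmB))
    expect_identical(as.data.frame(SummarizedExperiment::rowData(fmA)),
                     as.data.frame(SummarizedExperiment::rowData(fmB)))
})

test_that("feature matrices round-trip through tab-delimited text", {
    ds <- tinyFullDataset()
    lab <- buildLabeledSet(ds@trueLoops[1:2], ds@trueLoops[3:4])
    schema <- data.frame(name = c("CTCF", "RAD21"),
                         category = c("architectural", "architectural"))
    fm <- buildFeatureMatrix(lab, ds@tracks[c("CTCF", "RAD21")], schema, 300L)
    path <- tempfile(fileext = ".tsv")
    writeFeatureMatrix(fm, path)
    back <- readFeatureMatrix(path)
    expect_identical(rownames(back), rownames(fm))
    expect_identical(SummarizedExperiment::colData(back)$label,
                     SummarizedExperiment::colData(fm)$label)
    expect_equal(SummarizedExperiment::assay(back),
                 SummarizedExperiment::assay(fm))
    expect_identical(S4Vectors::metadata(back)$nBins, 300L)
    unlink(path)
})
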