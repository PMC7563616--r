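#' @include AllClasses.R loopset-methods.R
NULL

## Stage-seed derivation: one user-facing seed fans out to per-stage seeds so
## stages are individually reproducible. Kept inside 32-bit integer range.
stageSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 10007) %%
               2147483587) + 1L
}

.withSeed <- function(seed, expr) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    expr
}

#' Default assay profiles: the 23-track schema
#'
#' One profile per assay of the default track schema, covering chromatin
#' accessibility (DNase-seq), expression (RNA-seq), RNA Pol2 binding,
#' promoter/enhancer and gene-body histone marks, the architectural proteins
#' CTCF and RAD21, and nine transcription factors. Architectural, TF,
#' accessibility, Pol2 and promoter/enhancer marks are enriched at loop
#' anchors; gene-body and repressive marks plus expression are dispersed
#' within the loop span.
#'
#' @param enrichmentFactor rate multiplier applied to every enriched profile.
#' @param tfCellSplit if TRUE, alternate the nine TF tracks between simulated
#'   cell lines 1 and 2 (disjoint cell-specific subsets), leaving all other
#'   tracks active in both lines; used to emulate cross-cell transfer.
#' @return list of [AssayProfile-class].
#' @export
defaultAssayProfiles <- function(enrichmentFactor = 10, tfCellSplit = FALSE) {
    tab <- defaultTrackSchema()
    mode <- ifelse(tab$name %in% c("RNAseq", "H3K36me3", "H4K20me1",
                                   "H3K27me3", "H3K9me3"),
                   "within_loop", "anchor")
    cellSpec <- integer(nrow(tab))
    if (tfCellSplit) {
        tfIdx <- which(tab$category == "tf")
        cellSpec[tfIdx] <- rep_len(c(1L, 2L), length(tfIdx))
    }
    lapply(seq_len(nrow(tab)), function(i)
        AssayProfile(tab$name[i], tab$category[i], mode[i],
                     enrichmentFactor, cellSpec[i]))
}

#' Default track schema
#'
#' The 23 assays quantified per loop: DNase-seq (accessibility), RNA-seq
#' (expression), POLR2A and POLR2AphosphoS5 (pol2), eight histone marks,
#' CTCF and RAD21 (architectural) and nine transcription factors (tf).
#'
#' @return data.frame with columns `name` and `category`.
#' @export
defaultTrackSchema <- function() {
    data.frame(
        name = c("DNase", "RNAseq", "POLR2A", "POLR2AphosphoS5",
                 "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac",
                 "H3K36me3", "H4K20me1", "H3K27me3", "H3K9me3",
                 "CTCF", "RAD21",
                 "ATF3", "CEBPB", "JUND", "MAX", "REST", "SIN3A", "SP1",
                 "SRF", "YY1"),
        category = c("accessibility", "expression", "pol2", "pol2",
                     rep("histone", 8L),
                     rep("architectural", 2L),
                     rep("tf", 9L)),
        stringsAsFactors = FALSE)
}

#' Derive a track schema from assay profiles
#' @param profiles list of [AssayProfile-class].
#' @return data.frame with columns `name` and `category`.
#' @export
schemaFromProfiles <- function(profiles) {
    data.frame(name = vapply(profiles, function(p) p@name, character(1)),
               category = vapply(profiles, function(p) p@category,
                                 character(1)),
               stringsAsFactors = FALSE)
}

#' Simulate chromatin loops
#'
#' Places `nLoops` loops on the configured chromosomes: loop length is drawn
#' log-uniformly within `loopLengthRange`, the left-anchor start uniformly
#' along the chromosome (chromosome chosen proportionally to its length), and
#' both anchors get width `anchorWidth`. Duplicate placements are redrawn so
#' the returned loops are non-identical.
#'
#' @param config a [SimConfig-class].
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param maxRounds bound on redraw rounds before signalling that the
#'   chromosomes are too small for the requested loops.
#' @return a [LoopSet-class] with `seqlengths` set from the config.
#' @export
simulateLoops <- function(config, seed = NULL, maxRounds = 100L) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    .withSeed(seed, NULL)
    n <- config@nLoops
    sizes <- config@chromSizes
    if (n > 0L && max(sizes) < config@loopLengthRange[1])
        stop("chromosome too small for requested loops")
    aw <- config@anchorWidth
    lr <- log10(config@loopLengthRange)
    got <- data.frame(chrom = character(), s0 = numeric(), L = numeric())
    rounds <- 0L
    while (nrow(got) < n) {
        rounds <- rounds + 1L
        if (rounds > maxRounds)
            stop("chromosome too small for requested loops")
        m <- max(n - nrow(got), 16L)
        chrom <- sample(names(sizes), m, replace = TRUE,
                        prob = sizes / sum(sizes))
        L <- round(10^stats::runif(m, lr[1], lr[2]))
        L <- pmax(L, 2 * aw)
        ok <- L <= sizes[chrom]
        chrom <- chrom[ok]; L <- L[ok]
        s0 <- floor(stats::runif(length(L)) * (sizes[chrom] - L + 1))
        got <- rbind(got, data.frame(chrom = chrom, s0 = s0, L = L))
        got <- got[!duplicated(got[c("chrom", "s0", "L")]), , drop = FALSE]
        if (nrow(got) > n) got <- got[seq_len(n), , drop = FALSE]
    }
    LoopSet(chrom = got$chrom,
            leftStart = got$s0, leftEnd = got$s0 + aw,
            rightStart = got$s0 + got$L - aw, rightEnd = got$s0 + got$L,
            provenance = "simulated:truth", seqlengths = sizes)
}

#' Simulate two replicate interaction calls
#'
#' Each replicate retains each true loop independently with probability
#' `1 - replicateDropout` and shifts each anchor by rounded Gaussian noise
#' (sd `replicateJitterSd`), preserving anchor widths. Shifts that would push
#' an anchor over a chromosome end are clamped (with a message); shifts that
#' would break the left-before-right ordering are dropped for that loop.
#'
#' @param loops true [LoopSet-class] (non-empty).
#' @param config a [SimConfig-class].
#' @param seed optional seed.
#' @return list with elements `a` and `b`, two [LoopSet-class]s.
#' @export
simulateReplicates <- function(loops, config, seed = NULL) {
    stopifnot(is(loops, "LoopSet"), length(loops) > 0L)
    .withSeed(seed, NULL)
    sizes <- config@chromSizes
    one <- function(tag) {
        n <- length(loops)
        keep <- stats::runif(n) >= config@replicateDropout
        l <- loops[which(keep)]
        m <- length(l)
        if (m == 0L)
            return(initialize(l, provenance = paste0("simulated:rep", tag)))
        sd <- config@replicateJitterSd
        dl <- as.integer(round(stats::rnorm(m, 0, sd)))
        dr <- as.integer(round(stats::rnorm(m, 0, sd)))
        chrom <- as.character(seqnames(l@left))
        lim <- sizes[chrom]
        ls0 <- (start(l@left) - 1) + dl; le0 <- end(l@left) + dl
        rs0 <- (start(l@right) - 1) + dr; re0 <- end(l@right) + dr
        ## clamp at chromosome bounds, preserving widths
        clampLo <- pmax(0, -ls0); clampHi <- pmin(0, lim - le0)
        nClamp <- sum(clampLo > 0 | clampHi < 0)
        ls0 <- ls0 + clampLo + clampHi; le0 <- le0 + clampLo + clampHi
        clampLo <- pmax(0, -rs0); clampHi <- pmin(0, lim - re0)
        nClamp <- nClamp + sum(clampLo > 0 | clampHi < 0)
        rs0 <- rs0 + clampLo + clampHi; re0 <- re0 + clampLo + clampHi
        if (nClamp > 0)
            message(sprintf("replicate %s: clamped %d anchor shift(s) at chromosome bounds",
                            tag, nClamp))
        ## drop the jitter where it would break left-before-right ordering
        badOrd <- le0 > rs0
        if (any(badOrd)) {
            ls0[badOrd] <- start(l@left[badOrd]) - 1
            le0[badOrd] <- end(l@left[badOrd])
            rs0[badOrd] <- start(l@right[badOrd]) - 1
            re0[badOrd] <- end(l@right[badOrd])
        }
        LoopSet(chrom = chrom, leftStart = ls0, leftEnd = le0,
                rightStart = rs0, rightEnd = re0, id = loopIds(l),
                provenance = paste0("simulated:rep", tag),
                seqlengths = sizes)
    }
    list(a = one("A"), b = one("B"))
}

#' Simulate one assay read track
#'
#' Background reads follow a homogeneous Poisson process at `backgroundRate`
#' reads per bp genome-wide. Profiles with `enrichmentMode = "anchor"` add
#' reads inside each loop anchor and `"within_loop"` inside the span between
#' the anchors, so that the local read rate is
#' `backgroundRate * enrichmentFactor`. Reads have the fixed configured
#' length; the library size is the total number of simulated reads.
#'
#' @param profile an [AssayProfile-class].
#' @param loops the true [LoopSet-class] (enrichment targets).
#' @param config a [SimConfig-class].
#' @param seed optional seed.
#' @param cellLine which simulated cell line is being generated; profiles
#'   with a non-zero `cellSpecific` other than this line fall back to
#'   background-only.
#' @return a [ReadTrack-class].
#' @export
simulateTrack <- function(profile, loops, config, seed = NULL,
                          cellLine = 1L) {
    stopifnot(is(profile, "AssayProfile"), is(config, "SimConfig"))
    .withSeed(seed, NULL)
    sizes <- config@chromSizes
    rl <- config@readLength
    rate <- config@backgroundRate
    ## background
    chroms <- character(); starts0 <- numeric()
    for (ch in names(sizes)) {
        nbg <- stats::rpois(1L, rate * sizes[[ch]])
        if (nbg > 0L) {
            chroms <- c(chroms, rep(ch, nbg))
            starts0 <- c(starts0,
                         floor(stats::runif(nbg) * (sizes[[ch]] - rl + 1)))
        }
    }
    ## enrichment surplus
    active <- profile@enrichmentMode != "background" &&
        profile@enrichmentFactor > 1 &&
        (profile@cellSpecific == 0L || profile@cellSpecific == cellLine)
    if (active && length(loops) > 0L) {
        if (profile@enrichmentMode == "anchor") {
            regChrom <- rep(as.character(seqnames(loops@left)), 2L)
            regS0 <- c(start(loops@left) - 1, start(loops@right) - 1)
            regE0 <- c(end(loops@left), end(loops@right))
        } else {
            regChrom <- as.character(seqnames(loops@left))
            regS0 <- end(loops@left)
            regE0 <- start(loops@right) - 1
        }
        w <- regE0 - regS0
        keep <- w > 0
        regChrom <- regChrom[keep]; regS0 <- regS0[keep]; w <- w[keep]
        nx <- stats::rpois(length(w), rate * (profile@enrichmentFactor - 1) * w)
        if (sum(nx) > 0L) {
            idx <- rep(seq_along(nx), nx)
            span <- pmax(w[idx] - rl, 0)
            pos0 <- regS0[idx] + floor(stats::runif(length(idx)) * (span + 1))
            chroms <- c(chroms, regChrom[idx])
            starts0 <- c(starts0, pos0)
        }
    }
    gr <- GRanges(chroms, IRanges(start = starts0 + 1,
                                  width = rl))
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    ## library size = total simulated reads, floored at 1 so a degenerate
    ## zero-rate track still yields a valid normalizer
    ReadTrack(profile@name, gr, librarySize = max(1L, length(gr)))
}

#' Simulate a peak set
#'
#' One peak per distinct true-loop anchor, plus `nDecoyPeaks` decoy peaks of
#' the same width placed uniformly across the genome but never closer than
#' `minAnchorGap` bp to any true anchor (so decoys can never satisfy the
#' anchor-matching rule against a true anchor at the default 2 kb gap).
#'
#' @param loops the true [LoopSet-class].
#' @param config a [SimConfig-class].
#' @param seed optional seed.
#' @param minAnchorGap minimum edge-to-edge distance (bp) between a decoy and
#'   any true anchor; must exceed the loop-matching `maxGap` in use.
#' @return sorted GRanges of peaks with an `isDecoy` metadata column.
#' @export
simulatePeaks <- function(loops, config, seed = NULL, minAnchorGap = 5000L) {
    .withSeed(seed, NULL)
    sizes <- config@chromSizes
    anchors <- unique(c(granges(leftAnchors(loops)),
                        granges(rightAnchors(loops))))
    names(anchors) <- NULL
    aw <- config@anchorWidth
    ## padded exclusion zones, built free of seqinfo so padding may run past
    ## chromosome ends without triggering out-of-bound machinery
    forbid <- GRanges(as.character(seqnames(anchors)),
                      IRanges(start = pmax(1L, start(anchors) - minAnchorGap),
                              end = end(anchors) + minAnchorGap))
    nd <- config@nDecoyPeaks
    decS0 <- numeric(); decChrom <- character()
    attempts <- 0L
    while (length(decS0) < nd && attempts < 200L) {
        attempts <- attempts + 1L
        m <- max((nd - length(decS0)) * 2L, 32L)
        ch <- sample(names(sizes), m, replace = TRUE,
                     prob = sizes / sum(sizes))
        s0 <- floor(stats::runif(m) * (sizes[ch] - aw + 1))
        cand <- GRanges(ch, IRanges(start = s0 + 1, width = aw))
        ok <- !IRanges::overlapsAny(cand, forbid)
        decChrom <- c(decChrom, ch[ok]); decS0 <- c(decS0, s0[ok])
        dup <- duplicated(paste(decChrom, decS0))
        decChrom <- decChrom[!dup]; decS0 <- decS0[!dup]
    }
    if (length(decS0) > nd) { decChrom <- decChrom[seq_len(nd)]
                              decS0 <- decS0[seq_len(nd)] }
    decoys <- GRanges(decChrom, IRanges(start = decS0 + 1, width = aw))
    mcols(anchors)$isDecoy <- rep(FALSE, length(anchors))
    mcols(decoys)$isDecoy <- rep(TRUE, length(decoys))
    peaks <- c(anchors, decoys)
    GenomicRanges::sort(peaks, ignore.strand = TRUE)
}

#' Simulate a full dataset (one cell line)
#'
#' Runs [simulateLoops()], [simulateReplicates()], [simulatePeaks()] and
#' [simulateTrack()] for every configured assay profile, with per-stage seeds
#' derived from `seed` so the whole dataset is reproducible.
#'
#' @param config a [SimConfig-class].
#' @param cellLine simulated cell line (1 or 2); controls which
#'   `cellSpecific` profiles are enriched. Lines get independent loops.
#' @param seed base seed; defaults to `config@seed`.
#' @return a [SimulatedDataset-class].
#' @export
simulateLoopDataset <- function(config, cellLine = 1L, seed = NULL) {
    if (is.null(seed)) seed <- config@seed
    base <- stageSeed(seed, 1000L * cellLine)
    loops <- simulateLoops(config, seed = stageSeed(base, 1L))
    reps <- if (length(loops) > 0L)
        simulateReplicates(loops, config, seed = stageSeed(base, 2L))
    else list(a = loops, b = loops)
    peaks <- simulatePeaks(loops, config, seed = stageSeed(base, 3L))
    tracks <- lapply(seq_along(config@assayProfiles), function(i)
        simulateTrack(config@assayProfiles[[i]], loops, config,
                      seed = stageSeed(base, 10L + i), cellLine = cellLine))
    names(tracks) <- vapply(tracks, trackName, character(1))
    new("SimulatedDataset", trueLoops = loops, replicateA = reps$a,
        replicateB = reps$b, peaks = peaks, tracks = tracks,
        config = config, cellLine = as.integer(cellLine))
}

#' Simulate a pair of cell lines with disjoint cell-specific TF signal
#'
#' Both lines share the architectural (and other non-cell-specific)
#' enrichment structure, while TF tracks are enriched only in their assigned
#' line; the track schema is identical across lines, which is what makes
#' trained models transferable in principle.
#'
#' @param config a [SimConfig-class]; its profiles should carry the
#'   cell-specific assignment (see [defaultAssayProfiles()] with
#'   `tfCellSplit = TRUE`).
#' @param seed base seed; defaults to `config@seed`.
#' @return list with [SimulatedDataset-class] elements `line1` and `line2`.
#' @export
simulateCellLinePair <- function(config, seed = NULL) {
    list(line1 = simulateLoopDataset(config, cellLine = 1L, seed = seed),
         line2 = simulateLoopDataset(config, cellLine = 2L, seed = seed))
}
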