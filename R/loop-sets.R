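#' @include AllClasses.R loopset-methods.R
NULL

#' Anchor matching with a maximum gap
#'
#' Two anchor intervals match when they lie on the same chromosome and
#' either overlap or are separated by an edge-to-edge gap of at most
#' `maxGap` bp (the bound is inclusive). Intervals on different chromosomes
#' never match. Vectorized element-wise over two parallel GRanges.
#'
#' @param a,b GRanges of equal length (or length 1, recycled).
#' @param maxGap maximum allowed gap in bp (default 2000).
#' @return logical vector.
#' @export
anchorsMatch <- function(a, b, maxGap = 2000) {
    if (length(maxGap) != 1L || is.na(maxGap) || maxGap < 0)
        stop("maxGap must be a single non-negative number")
    n <- max(length(a), length(b))
    if (length(a) == 1L) a <- rep(a, n)
    if (length(b) == 1L) b <- rep(b, n)
    stopifnot(length(a) == length(b))
    sameChrom <- as.character(seqnames(a)) == as.character(seqnames(b))
    ## 0-based edge-to-edge gap; 0 when overlapping
    gap <- pmax((start(b) - 1) - end(a), (start(a) - 1) - end(b), 0)
    sameChrom & gap <= maxGap
}

#' Loop matching: both anchors must match
#'
#' Two loops match (share both anchors) when their left anchors match and
#' their right anchors match under [anchorsMatch()] with the same `maxGap`.
#'
#' @param l1,l2 [LoopSet-class]s of equal length (or length 1, recycled).
#' @param maxGap maximum anchor gap in bp.
#' @return logical vector.
#' @export
loopsMatch <- function(l1, l2, maxGap = 2000) {
    anchorsMatch(leftAnchors(l1), leftAnchors(l2), maxGap) &
        anchorsMatch(rightAnchors(l1), rightAnchors(l2), maxGap)
}

## For each loop of a, is there any match in b? Overlap join on padded left
## anchors, then the both-anchor check on candidate pairs.
.matchedInB <- function(a, b, maxGap) {
    if (length(a) == 0L) return(logical(0))
    if (length(b) == 0L) return(rep(FALSE, length(a)))
    hitsL <- suppressWarnings(GenomicRanges::findOverlaps(
        leftAnchors(a), leftAnchors(b), maxgap = maxGap,
        ignore.strand = TRUE))
    if (length(hitsL) == 0L) return(rep(FALSE, length(a)))
    qi <- S4Vectors::queryHits(hitsL); si <- S4Vectors::subjectHits(hitsL)
    okR <- anchorsMatch(rightAnchors(a)[qi], rightAnchors(b)[si], maxGap)
    out <- rep(FALSE, length(a))
    out[unique(qi[okR])] <- TRUE
    out
}

#' Intersect replicate loop calls
#'
#' Retains the loops of `a` that have at least one match in `b` (both
#' anchors matching within `maxGap`). Retained loops keep `a`'s coordinates
#' and order.
#'
#' @param a,b [LoopSet-class]s (two replicates).
#' @param maxGap maximum anchor gap in bp (default 2000).
#' @return a [LoopSet-class].
#' @export
intersectReplicates <- function(a, b, maxGap = 2000) {
    keep <- .matchedInB(a, b, maxGap)
    out <- a[which(keep)]
    initialize(out, provenance = paste0(provenance(a), ":replicated"))
}

#' Generate candidate negative loops from peak pairs
#'
#' Candidates pair two distinct peaks on the same chromosome, ordered
#' left-before-right with non-overlapping anchors and an outer span of at
#' most `maxSpan` bp. Duplicate pairs are removed. When the full pair space
#' is small it is enumerated (and subsampled to `nCandidates` if larger);
#' otherwise pairs are rejection-sampled.
#'
#' @param peaks GRanges of peaks.
#' @param nCandidates number of candidates requested.
#' @param maxSpan maximum loop length in bp (default `Inf`).
#' @param seed optional seed.
#' @return a [LoopSet-class] (up to `nCandidates` loops).
#' @export
generateCandidateNegatives <- function(peaks, nCandidates, maxSpan = Inf,
                                       seed = NULL) {
    .withSeed(seed, NULL)
    chrom <- as.character(seqnames(peaks))
    perChrom <- split(seq_along(peaks), chrom)
    perChrom <- perChrom[vapply(perChrom, length, integer(1)) >= 2L]
    if (length(perChrom) == 0L)
        stop("insufficient peaks: need >= 2 peaks on one chromosome")
    nPairs <- vapply(perChrom, function(ix)
        choose(length(ix), 2), numeric(1))
    s0 <- start(peaks) - 1; e0 <- end(peaks)

    makeLoops <- function(i, j) {  # i before j by start
        swap <- s0[i] > s0[j] | (s0[i] == s0[j] & e0[i] > e0[j])
        tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
        ok <- e0[i] <= s0[j] &                       # non-overlapping anchors
              (e0[j] - s0[i]) <= maxSpan &
              i != j
        cbind(i[ok], j[ok])
    }

    pairs <- NULL
    if (sum(nPairs) <= max(4 * nCandidates, 20000)) {
        for (ix in perChrom) {
            cmb <- utils::combn(ix, 2L)
            pairs <- rbind(pairs, makeLoops(cmb[1L, ], cmb[2L, ]))
        }
        if (!is.null(pairs) && nrow(pairs))
            pairs <- unique(pairs)
        if (is.null(pairs) || nrow(pairs) == 0L)
            stop("insufficient peaks: no valid same-chromosome pair")
        if (nrow(pairs) > nCandidates)
            pairs <- pairs[sample(nrow(pairs), nCandidates), , drop = FALSE]
    } else {
        got <- matrix(integer(0), ncol = 2L)
        rounds <- 0L
        while (nrow(got) < nCandidates && rounds < 500L) {
            rounds <- rounds + 1L
            m <- max((nCandidates - nrow(got)) * 3L, 64L)
            ch <- sample(names(perChrom), m, replace = TRUE,
                         prob = nPairs / sum(nPairs))
            i <- integer(m); j <- integer(m)
            for (cn in unique(ch)) {
                sel <- which(ch == cn); ix <- perChrom[[cn]]
                i[sel] <- ix[ceiling(stats::runif(length(sel)) * length(ix))]
                j[sel] <- ix[ceiling(stats::runif(length(sel)) * length(ix))]
            }
            got <- unique(rbind(got, makeLoops(i, j)))
        }
        if (nrow(got) == 0L)
            stop("insufficient peaks: no valid pair found (maxSpan too small?)")
        pairs <- got[seq_len(min(nrow(got), nCandidates)), , drop = FALSE]
    }
    i <- pairs[, 1L]; j <- pairs[, 2L]
    LoopSet(chrom = chrom[i], leftStart = s0[i], leftEnd = e0[i],
            rightStart = s0[j], rightEnd = e0[j],
            id = paste0("neg_", seq_along(i)),
            provenance = "candidate-negatives")
}

#' Filter candidates that overlap experimental loops
#'
#' Removes every candidate that matches (shares both anchors within
#' `maxGap`) any positive loop. Candidates sharing only a single anchor with
#' a positive are retained.
#'
#' @param candidates,positives [LoopSet-class]s.
#' @param maxGap maximum anchor gap in bp.
#' @return the filtered candidate [LoopSet-class].
#' @export
removePositiveOverlaps <- function(candidates, positives, maxGap = 2000) {
    drop <- .matchedInB(candidates, positives, maxGap)
    candidates[which(!drop)]
}

## Two-sample Kolmogorov-Smirnov statistic (no p-value machinery needed).
.ksStat <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L) return(NA_real_)
    z <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
}

#' Match the genomic-distance distribution of negatives to positives
#'
#' Selects `nTarget` candidates whose loop-length distribution matches the
#' positives', by density-ratio importance resampling on log10 loop length:
#' both densities are estimated with a Gaussian kernel (bandwidth by the
#' standard reference rule), each candidate is weighted by
#' positive-density / candidate-density (capped at the `weightCap` quantile
#' of the positive weights, and 0 outside the positives' support), and
#' `nTarget` candidates are drawn without replacement proportionally to the
#' weights. The selection is accepted when the KS statistic of log-lengths
#' versus the positives is at most `ksTolerance`; otherwise it is redrawn up
#' to `maxRounds` times and the best-achieved set is returned with a
#' warning.
#'
#' @param candidates,positives [LoopSet-class]s; `length(candidates) >=
#'   nTarget` and positives non-empty (unless `nTarget` is 0).
#' @param nTarget number of negatives to select.
#' @param seed optional seed.
#' @param ksTolerance acceptance threshold on the KS statistic (default 0.1).
#' @param maxRounds bound on resampling rounds (default 25).
#' @param weightCap quantile at which importance weights are capped.
#' @return a [LoopSet-class] with an attribute `ksStatistic` reporting the
#'   achieved KS statistic.
#' @export
matchDistanceDistribution <- function(candidates, positives, nTarget,
                                      seed = NULL, ksTolerance = 0.1,
                                      maxRounds = 25L, weightCap = 0.99) {
    .withSeed(seed, NULL)
    nTarget <- as.integer(nTarget)
    if (nTarget == 0L) {
        out <- candidates[integer(0)]
        attr(out, "ksStatistic") <- NA_real_
        return(out)
    }
    stopifnot(length(positives) > 0L)
    if (length(candidates) < nTarget)
        stop("need at least nTarget candidates")
    x <- log10(loopLength(positives))
    y <- log10(loopLength(candidates))
    dp <- stats::density(x, bw = "nrd0")
    w <- stats::approx(dp$x, dp$y, xout = y, yleft = 0, yright = 0)$y
    dc <- stats::density(y, bw = "nrd0")
    cy <- stats::approx(dc$x, dc$y, xout = y, rule = 2)$y
    w <- w / pmax(cy, 1e-12)
    if (any(w > 0)) {
        cap <- stats::quantile(w[w > 0], weightCap, names = FALSE)
        w <- pmin(w, cap)
    }
    if (sum(w > 0) < nTarget) {
        warning("fewer candidates inside the positive length support than ",
                "nTarget; topping up uniformly")
        w[w == 0] <- min(w[w > 0], na.rm = TRUE) * 1e-6
    }
    ## inclusion probabilities proportional to the weights, capped at 1
    ## (iterative redistribution of the capped surplus)
    p <- nTarget * w / sum(w)
    for (it in seq_len(100L)) {
        if (max(p) <= 1 + 1e-12) break
        over <- p >= 1
        p[over] <- 1
        slack <- nTarget - sum(over)
        if (slack <= 0 || sum(p[!over]) <= 0) break
        p[!over] <- p[!over] * slack / sum(p[!over])
    }
    p <- pmin(p, 1)
    ## systematic PPS draw along length-sorted candidates: the stratification
    ## makes the selected ECDF track the weighted target closely
    ord <- order(y)
    cum <- cumsum(p[ord])
    drawOnce <- function() {
        u <- stats::runif(1)
        sel <- ord[findInterval(u + seq_len(floor(sum(p))) - 1, cum) + 1L]
        sel <- unique(sel[!is.na(sel)])
        if (length(sel) < nTarget) {  # top up from unselected, by weight
            rest <- setdiff(ord, sel)
            rest <- rest[order(-w[rest])]
            sel <- c(sel, rest[seq_len(nTarget - length(sel))])
        }
        sel[seq_len(nTarget)]
    }
    best <- NULL; bestKs <- Inf
    for (round in seq_len(maxRounds)) {
        sel <- drawOnce()
        ks <- .ksStat(x, y[sel])
        if (ks < bestKs) { bestKs <- ks; best <- sel }
        if (bestKs <= ksTolerance) break
    }
    if (bestKs > ksTolerance)
        warning(sprintf(paste0("distance matching: KS %.3f exceeds tolerance ",
                               "%.3f after %d round(s); returning best set"),
                        bestKs, ksTolerance, maxRounds))
    out <- candidates[sort(best)]
    out <- initialize(out, provenance = "matched-negatives")
    attr(out, "ksStatistic") <- bestKs
    out
}

#' Assemble the labeled loop set
#'
#' Concatenates equally many positives and negatives (positives first) with
#' binary labels: 1 for positives, 0 for negatives.
#'
#' @param positives,negatives [LoopSet-class]s of equal length.
#' @return a [LabeledLoopSet-class].
#' @export
buildLabeledSet <- function(positives, negatives) {
    if (length(positives) != length(negatives))
        stop("positives and negatives must have equal size; downsample first")
    combined <- c(positives, negatives)
    new("LabeledLoopSet", left = combined@left, right = combined@right,
        provenance = "labeled",
        labels = c(rep(1L, length(positives)), rep(0L, length(negatives))))
}
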