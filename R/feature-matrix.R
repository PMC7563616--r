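#' @include AllClasses.R loopset-methods.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.subsetCategories <- c("All", "Transcription", "Architectural", "TF",
                       "Architectural-anchors", "TF-anchors")

#' Extended 3L region of a loop
#'
#' Given a loop of length `L` (outer span, left anchor start to right anchor
#' end), extends `L` bp to each side, giving a region of length `3L` whose
#' middle third is the loop itself. Regions reaching past a chromosome start
#' (or past its recorded end) are clamped with a warning; bin grids are then
#' built on the clamped region.
#'
#' @param loops a [LoopSet-class].
#' @return GRanges parallel to the loops.
#' @export
extendedRegion <- function(loops) {
    L <- loopLength(loops)
    s0 <- (start(loops@left) - 1) - L
    e0 <- end(loops@right) + L
    clamped <- s0 < 0
    s0 <- pmax(s0, 0)
    lens <- seqlengths(loops@left)[as.character(seqnames(loops@left))]
    over <- !is.na(lens) & e0 > lens
    e0 <- ifelse(over, lens, e0)
    if (any(clamped | over, na.rm = TRUE))
        warning(sprintf("extended region clamped at chromosome bounds for %d loop(s)",
                        sum(clamped | over, na.rm = TRUE)))
    gr <- GRanges(seqnames(loops@left), IRanges(start = s0 + 1, end = e0))
    names(gr) <- loopIds(loops)
    gr
}

#' Partition a region into near-equal bins
#'
#' Bin boundaries are `b_i = start + round(i * length / nBins)`, giving
#' contiguous, non-overlapping bins that cover the region exactly, with
#' widths differing by at most 1 bp.
#'
#' @param region GRanges of length 1; its length must be at least `nBins` bp.
#' @param nBins number of bins (default 1500).
#' @return a [BinGrid-class].
#' @export
partitionBins <- function(region, nBins = 1500L) {
    stopifnot(length(region) == 1L)
    nBins <- as.integer(nBins)
    s0 <- start(region) - 1; e0 <- end(region)
    len <- e0 - s0
    if (len < nBins)
        stop(sprintf("region length %d is shorter than nBins = %d", len, nBins))
    b <- s0 + floor((0:nBins) * (len / nBins) + 0.5)
    new("BinGrid", region = granges(region), boundaries = as.numeric(b),
        nBins = nBins)
}

## counts of sorted 0-based midpoints falling in [b_j-1, b_j)
.binCountsSorted <- function(mids, boundaries) {
    n <- length(boundaries) - 1L
    if (length(mids) == 0L) return(integer(n))
    idx <- findInterval(mids, boundaries)
    keep <- idx >= 1L & idx <= n & mids < boundaries[n + 1L]
    tabulate(idx[keep], nbins = n)
}

#' Score one track over a bin grid
#'
#' Each read is assigned to the bin containing its midpoint
#' (`floor((start + end)/2)` in 0-based coordinates); per-bin scores are
#' `count / (bin length in kb x library size in millions)` — a
#' reads-per-kb-per-million convention normalizing by both bin genomic
#' length and sequencing depth.
#'
#' @param track a [ReadTrack-class].
#' @param grid a [BinGrid-class].
#' @param raw if TRUE return integer midpoint counts instead of normalized
#'   scores.
#' @return numeric vector of length `nBins`.
#' @export
scoreBins <- function(track, grid, raw = FALSE) {
    stopifnot(is(track, "ReadTrack"), is(grid, "BinGrid"))
    reads <- track@reads
    chr <- as.character(seqnames(grid@region))
    reads <- reads[as.character(seqnames(reads)) == chr]
    m0 <- sort(floor(((start(reads) - 1) + end(reads)) / 2))
    cnt <- .binCountsSorted(m0, grid@boundaries)
    if (raw) return(cnt)
    w <- diff(grid@boundaries)
    cnt / ((w / 1000) * (track@librarySize / 1e6))
}

.windowOf <- function(absBin, nBins) {
    third <- nBins %/% 3L
    ifelse(absBin <= third, "left",
           ifelse(absBin <= 2L * third, "in", "right"))
}

.windowPosition <- function(absBin, nBins) {
    third <- nBins %/% 3L
    as.integer(absBin - (ceiling(absBin / third) - 1L) * third)
}

## feature annotation table for one schema
.featureSchema <- function(schema, nBins) {
    absBin <- rep(seq_len(nBins), times = nrow(schema))
    track <- rep(schema$name, each = nBins)
    category <- rep(schema$category, each = nBins)
    window <- .windowOf(absBin, nBins)
    position <- .windowPosition(absBin, nBins)
    DataFrame(track = track, category = category, window = window,
              position = position, absolute_bin = absBin,
              row.names = paste(track, window, position, sep = "_"))
}

#' Build the loops-by-features matrix
#'
#' For every loop, the 3L extended region is partitioned into `nBins` bins
#' and every track is scored per bin ([scoreBins()]). Features are ordered
#' track-major (track 1 bins 1..nBins, then track 2, ...), with tracks in
#' schema order; the result is a [LoopFeatureMatrix-class]
#' (SummarizedExperiment: rows = features, columns = loops) carrying the
#' loop labels in `colData` and the feature schema in `rowData`.
#'
#' @param loops a [LabeledLoopSet-class] (or plain [LoopSet-class]; labels
#'   then NA).
#' @param tracks list of [ReadTrack-class]; names must match the schema
#'   exactly.
#' @param schema data.frame with columns `name`, `category`
#'   (default [defaultTrackSchema()]).
#' @param nBins bins per track (default 1500; must be divisible by 3).
#' @return a [LoopFeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(loops, tracks,
                               schema = defaultTrackSchema(),
                               nBins = 1500L) {
    nBins <- as.integer(nBins)
    if (nBins %% 3L != 0L)
        stop("nBins must be divisible by 3 (left/in/right windows)")
    trackNames <- vapply(tracks, trackName, character(1))
    if (anyDuplicated(trackNames)) stop("track names must be unique")
    missing <- setdiff(schema$name, trackNames)
    if (length(missing))
        stop(sprintf("missing track(s): %s", paste(missing, collapse = ", ")))
    extra <- setdiff(trackNames, schema$name)
    if (length(extra))
        stop(sprintf("track(s) not in schema: %s",
                     paste(extra, collapse = ", ")))
    tracks <- tracks[match(schema$name, trackNames)]

    nLoops <- length(loops)
    regions <- if (nLoops) suppressWarnings(extendedRegion(loops)) else GRanges()
    ## per-track, per-chromosome sorted read midpoints
    midIndex <- lapply(tracks, function(tr) {
        r <- tr@reads
        m0 <- floor(((start(r) - 1) + end(r)) / 2)
        lapply(split(m0, as.character(seqnames(r))), sort)
    })
    libs <- vapply(tracks, librarySize, numeric(1))

    nT <- nrow(schema)
    M <- matrix(0, nrow = nT * nBins, ncol = nLoops)
    for (j in seq_len(nLoops)) {
        grid <- partitionBins(regions[j], nBins)
        b <- grid@boundaries
        w <- diff(b)
        chr <- as.character(seqnames(regions[j]))
        denom <- (w / 1000) / 1e6  # times librarySize below
        for (t in seq_len(nT)) {
            mids <- midIndex[[t]][[chr]]
            cnt <- if (is.null(mids)) integer(nBins)
                   else .binCountsSorted(mids, b)
            M[((t - 1L) * nBins + 1L):(t * nBins), j] <-
                cnt / (denom * libs[t])
        }
    }
    rd <- .featureSchema(schema, nBins)
    rownames(M) <- rownames(rd)
    labels <- if (is(loops, "LabeledLoopSet")) loops@labels
              else rep(NA_integer_, nLoops)
    cd <- DataFrame(label = labels,
                    loop_length = if (nLoops) loopLength(loops) else integer(),
                    row.names = loopIds(loops))
    colnames(M) <- rownames(cd)
    se <- SummarizedExperiment(assays = list(score = M), rowData = rd,
                               colData = cd)
    metadata(se)$nBins <- nBins
    metadata(se)$schema <- schema
    metadata(se)$category <- "All"
    new("LoopFeatureMatrix", se)
}

#' Absolute bins of the anchor windows
#'
#' The `windowBins/2` bins on each side of the left-anchor boundary (between
#' the left flank and the loop interior) plus the same around the
#' right-anchor boundary. At defaults (1500 bins, 100-bin windows) these are
#' absolute bins 451--550 and 951--1050.
#'
#' @param nBins bins per track; @param windowBins total bins per anchor
#'   window (even, at most `nBins/3`).
#' @return integer vector of `2 * windowBins` absolute bin indices.
#' @export
anchorWindowBins <- function(nBins = 1500L, windowBins = 100L) {
    nBins <- as.integer(nBins); windowBins <- as.integer(windowBins)
    if (windowBins %% 2L != 0L)
        stop("windowBins must be even (half on each side of the boundary)")
    third <- nBins %/% 3L
    if (windowBins > third) stop("windowBins must be at most nBins/3")
    h <- windowBins %/% 2L
    c((third - h + 1L):(third + h),
      (2L * third - h + 1L):(2L * third + h))
}

#' Column indices of anchor-window features for a whole schema
#'
#' Indices into the track-major full feature layout: for each track, the
#' anchor-window bins of [anchorWindowBins()] (`2 * windowBins` indices per
#' track).
#'
#' @param schema data.frame with column `name` (track order).
#' @param nBins,windowBins see [anchorWindowBins()].
#' @return sorted integer vector of feature indices.
#' @export
anchorWindowColumns <- function(schema, nBins = 1500L, windowBins = 100L) {
    bins <- anchorWindowBins(nBins, windowBins)
    nT <- nrow(schema)
    sort(as.integer(outer(bins, (seq_len(nT) - 1L) * as.integer(nBins), "+")))
}

#' Carve a feature-category subset of the matrix
#'
#' * `All`: identity.
#' * `Architectural`: CTCF/RAD21-category tracks, all bins.
#' * `TF`: transcription-factor tracks, all bins.
#' * `Transcription`: every non-architectural track, all bins.
#' * `Architectural-anchors`, `TF-anchors`: same tracks restricted to the
#'   anchor windows ([anchorWindowBins()]).
#'
#' Loops (columns) and labels are unchanged; the operation is idempotent.
#'
#' @param fm a [LoopFeatureMatrix-class].
#' @param category one of `All`, `Transcription`, `Architectural`, `TF`,
#'   `Architectural-anchors`, `TF-anchors`.
#' @param windowBins anchor-window size for the `-anchors` categories.
#' @return a [LoopFeatureMatrix-class].
#' @export
selectSubset <- function(fm, category, windowBins = 100L) {
    if (!category %in% .subsetCategories)
        stop(sprintf("unknown category '%s'; valid categories: %s",
                     category, paste(.subsetCategories, collapse = ", ")))
    rd <- rowData(fm)
    keep <- switch(category,
        "All" = rep(TRUE, nrow(fm)),
        "Architectural" = rd$category == "architectural",
        "TF" = rd$category == "tf",
        "Transcription" = rd$category != "architectural",
        "Architectural-anchors" = rd$category == "architectural" &
            rd$absolute_bin %in% anchorWindowBins(metadata(fm)$nBins,
                                                  windowBins),
        "TF-anchors" = rd$category == "tf" &
            rd$absolute_bin %in% anchorWindowBins(metadata(fm)$nBins,
                                                  windowBins))
    out <- fm[keep, ]
    metadata(out)$category <- category
    out
}

#' Write / read a feature matrix as tab-delimited text
#'
#' Rows are loops; the first columns are `loop_id` and `label`, followed by
#' one column per feature (`track_window_position`). Comment lines (`#`)
#' record the bin count and the track schema so the matrix can be
#' reconstructed exactly.
#'
#' @param fm a [LoopFeatureMatrix-class]; @param path output file.
#' @return `writeFeatureMatrix` returns `path` invisibly;
#'   `readFeatureMatrix` returns a [LoopFeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(fm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nBins\t%d", metadata(fm)$nBins), con)
    writeLines(sprintf("# category\t%s", metadata(fm)$category), con)
    sch <- metadata(fm)$schema
    writeLines(sprintf("# track\t%s\t%s", sch$name, sch$category), con)
    df <- data.frame(loop_id = colnames(fm),
                     label = colData(fm)$label,
                     t(assay(fm)), check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "# ")]
    nBins <- as.integer(sub("# nBins\t", "",
                            hdr[startsWith(hdr, "# nBins")]))
    category <- sub("# category\t", "", hdr[startsWith(hdr, "# category")])
    schLines <- strsplit(sub("# track\t", "",
                             hdr[startsWith(hdr, "# track")]), "\t")
    schema <- data.frame(name = vapply(schLines, `[`, "", 1L),
                         category = vapply(schLines, `[`, "", 2L),
                         stringsAsFactors = FALSE)
    tab <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                             header = TRUE, sep = "\t", check.names = FALSE)
    M <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
    colnames(M) <- tab$loop_id
    rd <- .featureSchema(schema, nBins)
    keep <- rownames(rd) %in% rownames(M)
    rd <- rd[keep, , drop = FALSE]
    M <- M[rownames(rd), , drop = FALSE]
    cd <- DataFrame(label = as.integer(tab$label),
                    row.names = tab$loop_id)
    se <- SummarizedExperiment(assays = list(score = M), rowData = rd,
                               colData = cd)
    metadata(se)$nBins <- nBins
    metadata(se)$schema <- schema
    metadata(se)$category <- category
    new("LoopFeatureMatrix", se)
}
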