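#' @include AllClasses.R loopset-methods.R synthetic-data.R
#' @importFrom rtracklayer import export
NULL

#' Write / read loops as BEDPE
#'
#' Six tab-separated coordinate columns (`chrom1 start1 end1 chrom2 start2
#' end2`, 0-based half-open) plus a `name` column; [LabeledLoopSet-class]s
#' gain a `label` column. A single `#`-prefixed header line records the
#' columns, so empty sets still produce valid files.
#'
#' @param loops a [LoopSet-class] or [LabeledLoopSet-class].
#' @param path output file.
#' @return `writeBedpe` returns `path` invisibly; `readBedpe` returns a
#'   [LoopSet-class] (or [LabeledLoopSet-class] when a label column is
#'   present).
#' @export
writeBedpe <- function(loops, path) {
    labeled <- is(loops, "LabeledLoopSet")
    cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name",
              if (labeled) "label")
    df <- data.frame(
        chrom1 = as.character(seqnames(loops@left)),
        start1 = start(loops@left) - 1, end1 = end(loops@left),
        chrom2 = as.character(seqnames(loops@right)),
        start2 = start(loops@right) - 1, end2 = end(loops@right),
        name = loopIds(loops))
    if (labeled) df$label <- loops@labels
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(cols, collapse = "\t")), con)
    if (nrow(df))
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeBedpe
#' @param provenance origin tag for the returned set (default: the file).
#' @param seqlengths optional named chromosome lengths.
#' @export
readBedpe <- function(path, provenance = basename(path), seqlengths = NULL) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0L) {
        out <- LoopSet(provenance = provenance)
        return(out)
    }
    tab <- utils::read.table(text = lines, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 6L) stop(sprintf("%s: BEDPE needs >= 6 columns", path))
    if (any(tab[[1L]] != tab[[4L]]))
        stop(sprintf("%s: inter-chromosomal rows are not supported", path))
    id <- if (ncol(tab) >= 7L) as.character(tab[[7L]]) else NULL
    out <- LoopSet(chrom = tab[[1L]], leftStart = tab[[2L]],
                   leftEnd = tab[[3L]], rightStart = tab[[5L]],
                   rightEnd = tab[[6L]], id = id, provenance = provenance,
                   seqlengths = seqlengths)
    if (ncol(tab) >= 8L)
        out <- new("LabeledLoopSet", left = out@left, right = out@right,
                   provenance = provenance, labels = as.integer(tab[[8L]]))
    out
}

#' Write / read a peak set as BED
#'
#' BED4 with the name column marking `anchor` vs `decoy` peaks.
#'
#' @param peaks GRanges (optionally with an `isDecoy` metadata column).
#' @param path file path.
#' @return `writePeaksBed` returns `path` invisibly; `readPeaksBed` a
#'   GRanges with an `isDecoy` column.
#' @export
writePeaksBed <- function(peaks, path) {
    gr <- granges(peaks)
    isDecoy <- mcols(peaks)$isDecoy
    if (is.null(isDecoy)) isDecoy <- rep(FALSE, length(peaks))
    mcols(gr)$name <- ifelse(isDecoy, "decoy", "anchor")
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' @rdname writePeaksBed
#' @export
readPeaksBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- mcols(gr)$name
    mcols(gr) <- NULL
    mcols(gr)$isDecoy <- if (is.null(nm)) rep(FALSE, length(gr))
                         else nm == "decoy"
    gr
}

#' Write / read one assay track as BED plus a library-size sidecar
#'
#' Reads go to `<name>.bed` (BED3, 0-based half-open) and the integer
#' library size to `<name>.libsize` next to it.
#'
#' @param track a [ReadTrack-class].
#' @param dir directory for the pair of files.
#' @return `writeTrackBed` returns the BED path invisibly; `readTrackBed`
#'   returns a [ReadTrack-class].
#' @export
writeTrackBed <- function(track, dir) {
    path <- file.path(dir, paste0(track@name, ".bed"))
    rtracklayer::export(granges(track@reads), path, format = "BED")
    writeLines(sprintf("%d", as.integer(track@librarySize)),
               file.path(dir, paste0(track@name, ".libsize")))
    invisible(path)
}

#' @rdname writeTrackBed
#' @param name track name (basename of the BED file).
#' @export
readTrackBed <- function(dir, name) {
    path <- file.path(dir, paste0(name, ".bed"))
    reads <- if (file.size(path) == 0) GRanges()
             else granges(rtracklayer::import(path, format = "BED"))
    lib <- as.numeric(readLines(file.path(dir, paste0(name, ".libsize"))))
    ReadTrack(name, reads, librarySize = lib)
}

.configToList <- function(config) {
    list(chrom_sizes = as.list(config@chromSizes),
         n_loops = config@nLoops,
         loop_length_range = config@loopLengthRange,
         anchor_width = config@anchorWidth,
         replicate_jitter_sd = config@replicateJitterSd,
         replicate_dropout = config@replicateDropout,
         n_decoy_peaks = config@nDecoyPeaks,
         background_rate = config@backgroundRate,
         read_length = config@readLength,
         seed = config@seed,
         assay_profiles = lapply(config@assayProfiles, function(p)
             list(name = p@name, category = p@category,
                  enrichment_mode = p@enrichmentMode,
                  enrichment_factor = p@enrichmentFactor,
                  cell_specific = p@cellSpecific)))
}

.configFromList <- function(lst) {
    profiles <- if (is.null(lst$assay_profiles)) defaultAssayProfiles()
        else lapply(lst$assay_profiles, function(p)
            AssayProfile(p$name, p$category,
                         p$enrichment_mode %||% "anchor",
                         p$enrichment_factor %||% 10,
                         as.integer(p$cell_specific %||% 0L)))
    SimConfig(chromSizes = unlist(lst$chrom_sizes),
              nLoops = lst$n_loops %||% 1000L,
              loopLengthRange = unlist(lst$loop_length_range) %||% c(1e4, 5e5),
              anchorWidth = lst$anchor_width %||% 2000L,
              replicateJitterSd = lst$replicate_jitter_sd %||% 200,
              replicateDropout = lst$replicate_dropout %||% 0.1,
              assayProfiles = profiles,
              nDecoyPeaks = lst$n_decoy_peaks %||% 2000L,
              backgroundRate = lst$background_rate %||% 2e-3,
              readLength = lst$read_length %||% 50L,
              seed = lst$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated dataset to plain-text fixtures
#'
#' Writes the replicate interaction tables (and the truth) as BEDPE, peaks
#' as BED, one BED + `.libsize` sidecar per track under `tracks/`, and the
#' generating configuration as YAML. [readFixtures()] reconstructs the
#' dataset exactly.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param dir writable output directory (created if needed).
#' @return data.frame manifest (columns `file`, `type`) listing every file
#'   written, one BED per assay in the schema.
#' @export
writeFixtures <- function(dataset, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create fixture directory: %s", dir))
    trackDir <- file.path(dir, "tracks")
    dir.create(trackDir, showWarnings = FALSE)
    cfg <- .configToList(dataset@config)
    cfg$cell_line <- dataset@cellLine
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    writeBedpe(dataset@trueLoops, file.path(dir, "true_loops.bedpe"))
    writeBedpe(dataset@replicateA, file.path(dir, "replicate_a.bedpe"))
    writeBedpe(dataset@replicateB, file.path(dir, "replicate_b.bedpe"))
    writePeaksBed(dataset@peaks, file.path(dir, "peaks.bed"))
    manifest <- data.frame(
        file = c("config.yaml", "true_loops.bedpe", "replicate_a.bedpe",
                 "replicate_b.bedpe", "peaks.bed"),
        type = c("config", "loops", "loops", "loops", "peaks"))
    for (tr in dataset@tracks) {
        writeTrackBed(tr, trackDir)
        manifest <- rbind(manifest, data.frame(
            file = file.path("tracks", paste0(tr@name, c(".bed", ".libsize"))),
            type = c("reads", "libsize")))
    }
    utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest
}

#' @rdname writeFixtures
#' @export
readFixtures <- function(dir) {
    cfgList <- yaml::read_yaml(file.path(dir, "config.yaml"))
    config <- .configFromList(cfgList)
    sl <- config@chromSizes
    tracks <- lapply(config@assayProfiles, function(p)
        readTrackBed(file.path(dir, "tracks"), p@name))
    names(tracks) <- vapply(tracks, trackName, character(1))
    new("SimulatedDataset",
        trueLoops = readBedpe(file.path(dir, "true_loops.bedpe"),
                              provenance = "simulated:truth",
                              seqlengths = sl),
        replicateA = readBedpe(file.path(dir, "replicate_a.bedpe"),
                               provenance = "simulated:repA",
                               seqlengths = sl),
        replicateB = readBedpe(file.path(dir, "replicate_b.bedpe"),
                               provenance = "simulated:repB",
                               seqlengths = sl),
        peaks = readPeaksBed(file.path(dir, "peaks.bed")),
        tracks = tracks, config = config,
        cellLine = as.integer(cfgList$cell_line %||% 1L))
}
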