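#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

## ---------------------------------------------------------------------------
## LoopSet
## ---------------------------------------------------------------------------

#' LoopSet: a collection of chromatin loops
#'
#' A loop is a pair of anchor intervals on the same chromosome, with the left
#' anchor strictly before the right one (anchors may touch but not overlap).
#' Anchors are stored as two parallel [GenomicRanges::GRanges] objects; loop
#' ids are the names of the anchor ranges.
#'
#' @slot left GRanges of left anchors (one per loop).
#' @slot right GRanges of right anchors, parallel to `left`.
#' @slot provenance free-text origin tag (e.g. file name or "simulated").
#'
#' @details Derived quantities: the loop length `L` is the outer span from the
#' left anchor's start to the right anchor's end; the anchor distance is the
#' inner gap between the anchors. Both are reported in base pairs using
#' 0-based half-open arithmetic, matching the BEDPE files the set is read
#' from and written to.
#'
#' @examples
#' ls <- LoopSet(chrom = "chr1", leftStart = c(1e5, 4e5), leftEnd = c(1.02e5, 4.02e5),
#'               rightStart = c(2e5, 6e5), rightEnd = c(2.02e5, 6.02e5))
#' loopLength(ls)
#' @export
setClass("LoopSet",
    slots = c(left = "GRanges", right = "GRanges", provenance = "character"))

setValidity("LoopSet", function(object) {
    l <- object@left; r <- object@right
    if (length(l) != length(r))
        return("left and right anchor sets differ in length")
    if (length(l) == 0L) return(TRUE)
    if (!identical(as.character(seqnames(l)), as.character(seqnames(r))))
        return("left and right anchors must lie on the same chromosome")
    bad <- end(l) > start(r) - 1L  # 0-based: left.end must be <= right.start
    if (any(bad))
        return(sprintf("anchors out of order (left.end > right.start) for %d loop(s)",
                       sum(bad)))
    ids <- names(l)
    if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
        return("loop ids (names of anchors) must be present and unique")
    if (!identical(ids, names(r)))
        return("left and right anchor names must agree")
    TRUE
})

#' Construct a LoopSet
#'
#' Coordinates are 0-based half-open, as in BED/BEDPE.
#'
#' @param chrom chromosome name(s), recycled.
#' @param leftStart,leftEnd,rightStart,rightEnd anchor coordinates (bp,
#'   0-based half-open).
#' @param id loop identifiers; defaults to `loop_1..n`.
#' @param provenance free-text origin tag.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a [LoopSet-class] object.
#' @export
LoopSet <- function(chrom = character(), leftStart = integer(),
                    leftEnd = integer(), rightStart = integer(),
                    rightEnd = integer(), id = NULL,
                    provenance = "constructed", seqlengths = NULL) {
    n <- length(leftStart)
    chrom <- rep_len(as.character(chrom), n)
    if (is.null(id)) id <- if (n) paste0("loop_", seq_len(n)) else character()
    left <- GRanges(chrom, IRanges(start = as.integer(leftStart) + 1L,
                                   end = as.integer(leftEnd)))
    right <- GRanges(chrom, IRanges(start = as.integer(rightStart) + 1L,
                                    end = as.integer(rightEnd)))
    names(left) <- id; names(right) <- id
    if (!is.null(seqlengths)) {
        seqlengths(left) <- seqlengths[GenomeInfoDb::seqlevels(left)]
        seqlengths(right) <- seqlengths[GenomeInfoDb::seqlevels(right)]
    }
    new("LoopSet", left = left, right = right, provenance = provenance)
}

## ---------------------------------------------------------------------------
## LabeledLoopSet
## ---------------------------------------------------------------------------

#' LabeledLoopSet: loops with binary class labels
#'
#' @slot labels integer vector of 0/1 labels (1 = experimental/positive),
#'   parallel to the loops.
#' @export
setClass("LabeledLoopSet", contains = "LoopSet",
    slots = c(labels = "integer"))

setValidity("LabeledLoopSet", function(object) {
    if (length(object@labels) != length(object@left))
        return("labels must be parallel to loops")
    if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
        return("labels must be 0 or 1")
    TRUE
})

## ---------------------------------------------------------------------------
## ReadTrack
## ---------------------------------------------------------------------------

#' ReadTrack: aligned reads of one sequencing assay
#'
#' @slot name assay/track name (unique within a schema).
#' @slot reads GRanges of read intervals (unstranded coverage semantics).
#' @slot librarySize total mapped reads of the experiment, used as the
#'   per-track normalizer; may exceed the number of loaded reads when only a
#'   region was loaded.
#' @export
setClass("ReadTrack",
    slots = c(name = "character", reads = "GRanges", librarySize = "numeric"))

setValidity("ReadTrack", function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
        return("track name must be a single non-empty string")
    if (length(object@librarySize) != 1L || is.na(object@librarySize) ||
        object@librarySize <= 0)
        return("librarySize must be a single positive number")
    TRUE
})

#' Construct a ReadTrack
#'
#' @param name track name.
#' @param reads GRanges of reads, or a data.frame with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates.
#' @param librarySize total mapped reads; defaults to `length(reads)`.
#' @return a [ReadTrack-class].
#' @export
ReadTrack <- function(name, reads, librarySize = NULL) {
    if (is.data.frame(reads))
        reads <- GRanges(reads$chrom,
                         IRanges(start = reads$start + 1, end = reads$end))
    if (is.null(librarySize)) librarySize <- length(reads)
    new("ReadTrack", name = as.character(name), reads = reads,
        librarySize = as.numeric(librarySize))
}

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' AssayProfile: enrichment profile of one simulated assay
#'
#' @slot name track name.
#' @slot category feature category, one of `architectural`, `tf`, `histone`,
#'   `accessibility`, `expression`, `pol2`.
#' @slot enrichmentMode where reads are enriched: `anchor` (at loop anchors),
#'   `within_loop` (dispersed between the anchors), or `background` (none).
#' @slot enrichmentFactor local rate multiplier over background (>= 1).
#' @slot cellSpecific 0 = enriched in every simulated cell line; 1 or 2 =
#'   enriched only in that line (background elsewhere).
#' @export
setClass("AssayProfile",
    slots = c(name = "character", category = "character",
              enrichmentMode = "character", enrichmentFactor = "numeric",
              cellSpecific = "integer"))

setValidity("AssayProfile", function(object) {
    if (!object@enrichmentMode %in% c("anchor", "within_loop", "background"))
        return("enrichmentMode must be anchor, within_loop or background")
    if (object@enrichmentFactor < 1)
        return("enrichmentFactor must be >= 1")
    if (!object@cellSpecific %in% 0:2)
        return("cellSpecific must be 0 (all lines), 1 or 2")
    if (!object@category %in% .featureCategories)
        return(sprintf("category must be one of: %s",
                       paste(.featureCategories, collapse = ", ")))
    TRUE
})

.featureCategories <- c("architectural", "tf", "histone", "accessibility",
                        "expression", "pol2")

#' @rdname AssayProfile-class
#' @param name,category,enrichmentMode,enrichmentFactor,cellSpecific see slots.
#' @export
AssayProfile <- function(name, category, enrichmentMode = "anchor",
                         enrichmentFactor = 10, cellSpecific = 0L) {
    new("AssayProfile", name = as.character(name),
        category = as.character(category),
        enrichmentMode = as.character(enrichmentMode),
        enrichmentFactor = as.numeric(enrichmentFactor),
        cellSpecific = as.integer(cellSpecific))
}

#' SimConfig: parameters of the synthetic-data generator
#'
#' The defaults describe the study conditions the generator emulates: loops
#' with a log-uniform length spread of 10--500 kb (the one-to-hundreds-of-kb
#' scale typical of cohesin loops), 2 kb anchors, two jittered replicate
#' interaction calls, a RAD21-like peak set with decoys, and Poisson read
#' tracks with 10-fold enrichment at anchors or within loops.
#'
#' @slot chromSizes named numeric vector, chromosome name -> length (bp).
#' @slot nLoops number of true loops to simulate.
#' @slot loopLengthRange `(min, max)` bp for log-uniform loop-length sampling.
#' @slot anchorWidth anchor width in bp.
#' @slot replicateJitterSd sd (bp) of the rounded Gaussian anchor jitter
#'   applied to replicate calls.
#' @slot replicateDropout probability in `[0, 1)` that a replicate misses a
#'   true loop.
#' @slot assayProfiles list of [AssayProfile-class] objects (the track schema).
#' @slot nDecoyPeaks number of decoy peaks placed away from true anchors.
#' @slot backgroundRate background read rate (reads per bp).
#' @slot readLength fixed simulated read length (bp).
#' @slot seed integer seed from which stage seeds are derived.
#' @export
setClass("SimConfig",
    slots = c(chromSizes = "numeric", nLoops = "integer",
              loopLengthRange = "numeric", anchorWidth = "integer",
              replicateJitterSd = "numeric", replicateDropout = "numeric",
              assayProfiles = "list", nDecoyPeaks = "integer",
              backgroundRate = "numeric", readLength = "integer",
              seed = "integer"))

setValidity("SimConfig", function(object) {
    if (length(object@chromSizes) == 0L || is.null(names(object@chromSizes)))
        return("chromSizes must be a named vector of chromosome lengths")
    if (any(object@chromSizes <= 0)) return("chromosome lengths must be > 0")
    if (object@nLoops < 0L) return("nLoops must be >= 0")
    r <- object@loopLengthRange
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
        return("loopLengthRange must be (min, max) with 0 < min <= max")
    if (object@anchorWidth <= 0L) return("anchorWidth must be > 0")
    if (r[1] < 2 * object@anchorWidth)
        return("loopLengthRange min must be >= 2 * anchorWidth")
    if (object@replicateDropout < 0 || object@replicateDropout >= 1)
        return("replicateDropout must be in [0, 1)")
    if (object@replicateJitterSd < 0) return("replicateJitterSd must be >= 0")
    if (object@backgroundRate < 0) return("backgroundRate must be >= 0")
    if (object@readLength <= 0L) return("readLength must be > 0")
    nm <- vapply(object@assayProfiles, function(p) p@name, character(1))
    if (anyDuplicated(nm)) return("assay profile names must be unique")
    TRUE
})

#' @rdname SimConfig-class
#' @param chromSizes,nLoops,loopLengthRange,anchorWidth,replicateJitterSd,replicateDropout,assayProfiles,nDecoyPeaks,backgroundRate,readLength,seed see slots.
#' @export
SimConfig <- function(chromSizes = c(simA = 5e7, simB = 3e7),
                      nLoops = 1000L,
                      loopLengthRange = c(1e4, 5e5),
                      anchorWidth = 2000L,
                      replicateJitterSd = 200,
                      replicateDropout = 0.1,
                      assayProfiles = defaultAssayProfiles(),
                      nDecoyPeaks = 2000L,
                      backgroundRate = 2e-3,
                      readLength = 50L,
                      seed = 1L) {
    new("SimConfig",
        chromSizes = stats::setNames(as.numeric(chromSizes),
                                     names(chromSizes)),
        nLoops = as.integer(nLoops),
        loopLengthRange = as.numeric(loopLengthRange),
        anchorWidth = as.integer(anchorWidth),
        replicateJitterSd = as.numeric(replicateJitterSd),
        replicateDropout = as.numeric(replicateDropout),
        assayProfiles = assayProfiles, nDecoyPeaks = as.integer(nDecoyPeaks),
        backgroundRate = as.numeric(backgroundRate),
        readLength = as.integer(readLength), seed = as.integer(seed))
}

#' SimulatedDataset: one simulated "cell line"
#'
#' @slot trueLoops,replicateA,replicateB [LoopSet-class]s: ground truth and
#'   two jittered replicate interaction calls.
#' @slot peaks GRanges of peak calls (one per distinct true anchor + decoys).
#' @slot tracks list of [ReadTrack-class], one per assay profile.
#' @slot config the generating [SimConfig-class].
#' @slot cellLine which simulated line (1 or 2) the tracks correspond to.
#' @export
setClass("SimulatedDataset",
    slots = c(trueLoops = "LoopSet", replicateA = "LoopSet",
              replicateB = "LoopSet", peaks = "GRanges", tracks = "list",
              config = "SimConfig", cellLine = "integer"))

## ---------------------------------------------------------------------------
## Feature matrix
## ---------------------------------------------------------------------------

#' BinGrid: the 1500-bin partition of a 3L extended loop region
#'
#' @slot region GRanges of length 1, the extended region.
#' @slot boundaries numeric vector of `nBins + 1` increasing 0-based
#'   positions; first = region start, last = region end; bin widths differ by
#'   at most 1 bp.
#' @slot nBins number of bins.
#' @export
setClass("BinGrid",
    slots = c(region = "GRanges", boundaries = "numeric", nBins = "integer"))

setValidity("BinGrid", function(object) {
    b <- object@boundaries
    if (length(b) != object@nBins + 1L)
        return("boundaries must have nBins + 1 entries")
    if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
    if (b[1] != start(object@region) - 1 || b[length(b)] != end(object@region))
        return("boundaries must span the region exactly")
    w <- diff(b)
    if (max(w) - min(w) > 1) return("bin widths must differ by at most 1 bp")
    TRUE
})

#' LoopFeatureMatrix: loops-by-features learning substrate
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the binned
#' track scores. Following Bioconductor convention, rows are features
#' (track x bin) and columns are loops; `rowData` carries the feature schema
#' (`track`, `category`, `window`, `position`, `absolute_bin`) and `colData`
#' carries the loop `label`. Scores are reads per kb per million mapped reads.
#' @export
setClass("LoopFeatureMatrix", contains = "SummarizedExperiment")

setValidity("LoopFeatureMatrix", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    need <- c("track", "category", "window", "position", "absolute_bin")
    if (!all(need %in% colnames(rd)))
        return(sprintf("rowData must carry: %s", paste(need, collapse = ", ")))
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData must carry a 'label' column")
    if (is.null(metadata(object)$nBins))
        return("metadata must record nBins")
    a <- SummarizedExperiment::assay(object)
    if (length(a) && (any(!is.finite(a)) || any(a < 0)))
        return("scores must be finite and non-negative")
    TRUE
})

## ---------------------------------------------------------------------------
## Classification
## ---------------------------------------------------------------------------

#' ModelSpec: one classifier configuration
#'
#' @slot algorithm one of `decision_tree`, `random_forest`, `xgboost`,
#'   `svm_rbf`, `mlp`, `deep_ann`.
#' @slot hyperparameters named list; unknown keys are rejected at
#'   construction. Defaults follow the study configuration (see
#'   [defaultHyperparameters()]).
#' @slot seed integer seed fixed for all stochastic learners.
#' @export
setClass("ModelSpec",
    slots = c(algorithm = "character", hyperparameters = "list",
              seed = "integer"))

#' SplitSpec: train/test partition parameters
#'
#' @slot trainFraction fraction of rows used for training (default 0.8).
#' @slot seed partition seed.
#' @slot stratified preserve the class ratio within rounding (default TRUE).
#' @export
setClass("SplitSpec",
    slots = c(trainFraction = "numeric", seed = "integer",
              stratified = "logical"))

setValidity("SplitSpec", function(object) {
    f <- object@trainFraction
    if (length(f) != 1L || f <= 0 || f >= 1)
        return("trainFraction must be in (0, 1)")
    TRUE
})

#' @rdname SplitSpec-class
#' @param trainFraction,seed,stratified see slots.
#' @export
SplitSpec <- function(trainFraction = 0.8, seed = 1L, stratified = TRUE) {
    new("SplitSpec", trainFraction = as.numeric(trainFraction),
        seed = as.integer(seed), stratified = isTRUE(stratified))
}

#' TrainedLoopModel: a fitted classifier bound to its feature schema
#'
#' @slot spec the [ModelSpec-class] used.
#' @slot fit the fitted estimator (backend object).
#' @slot fingerprint ordered feature names of the training matrix;
#'   predictions are only accepted on matrices with an identical fingerprint.
#' @slot standardization `NULL`, or `list(center, scale)` applied to inputs
#'   (fit on training data) for scale-sensitive learners.
#' @slot meta training metadata: rows, class balance, dataset tag, timestamp.
#' @export
setClass("TrainedLoopModel",
    slots = c(spec = "ModelSpec", fit = "ANY", fingerprint = "character",
              standardization = "ANY", meta = "list"))

setValidity("TrainedLoopModel", function(object) {
    if (length(object@fingerprint) == 0L)
        return("schema fingerprint must be non-empty")
    TRUE
})

#' ConfusionCounts: 2x2 confusion tallies for a designated positive class
#'
#' @slot tp,fp,fn,tn non-negative counts; their sum is the number of
#'   evaluated rows.
#' @export
setClass("ConfusionCounts",
    slots = c(tp = "integer", fp = "integer", fn = "integer", tn = "integer"))

setValidity("ConfusionCounts", function(object) {
    v <- c(object@tp, object@fp, object@fn, object@tn)
    if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative")
    TRUE
})

#' @rdname ConfusionCounts-class
#' @param tp,fp,fn,tn counts, or see [confusionCounts()] to tally from vectors.
#' @export
ConfusionCounts <- function(tp, fp, fn, tn) {
    new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
        fn = as.integer(fn), tn = as.integer(tn))
}

#' MetricsReport: accuracy, precision, recall and F1
#'
#' Metrics follow the standard confusion-matrix definitions: accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, with precision/recall/F1 defined as 0 when their
#' denominator is 0.
#'
#' @slot accuracy,precision,recall,f1 values in `[0, 1]`.
#' @slot averaging `positive_class`, `macro` or `weighted` (class-support
#'   weighted; the default for headline reports).
#' @slot perClass per-class breakdown (data.frame: class, support,
#'   precision, recall, f1).
#' @slot counts the underlying [ConfusionCounts-class].
#' @slot tags named character: free annotations (algorithm, category,
#'   source/target dataset for cross-application).
#' @export
setClass("MetricsReport",
    slots = c(accuracy = "numeric", precision = "numeric", recall = "numeric",
              f1 = "numeric", averaging = "character", perClass = "data.frame",
              counts = "ConfusionCounts", tags = "character"))

setValidity("MetricsReport", function(object) {
    v <- c(object@accuracy, object@precision, object@recall, object@f1)
    if (any(v < -1e-12 | v > 1 + 1e-12)) return("metrics must lie in [0, 1]")
    TRUE
})

## ---------------------------------------------------------------------------
## Importance
## ---------------------------------------------------------------------------

#' ImportanceProfile: per-(track, bin) feature importance
#'
#' @slot values non-negative importances named by feature
#'   (`track_window_position`), aligned to the model's schema fingerprint;
#'   when `normalized`, they sum to 1 (tolerance 1e-9).
#' @slot model tag of the producing model (algorithm + importance type:
#'   impurity decrease for tree/forest, gain for gradient boosting).
#' @slot normalized logical flag.
#' @slot nBins bins per track in the source matrix.
#' @slot trackOrder track names in schema order (tie-break order for
#'   rankings).
#' @export
setClass("ImportanceProfile",
    slots = c(values = "numeric", model = "character", normalized = "logical",
              nBins = "integer", trackOrder = "character"))

setValidity("ImportanceProfile", function(object) {
    if (any(object@values < 0)) return("importances must be >= 0")
    if (is.null(names(object@values))) return("values must be named")
    if (object@normalized &&
        abs(sum(object@values) - 1) > 1e-9)
        return("normalized importances must sum to 1 (tolerance 1e-9)")
    TRUE
})
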