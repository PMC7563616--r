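#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for LoopSet and friends
#'
#' `leftAnchors`/`rightAnchors` return the anchor GRanges; `loopIds` the
#' stable identifiers; `loopLength` the outer span `L` (left anchor start to
#' right anchor end, bp); `anchorDistance` the inner gap between anchors
#' (bp); `loopLabels` the 0/1 labels of a [LabeledLoopSet-class].
#'
#' @param x a [LoopSet-class] (or [LabeledLoopSet-class]).
#' @return vectors parallel to the loops.
#' @name LoopSet-accessors
NULL

#' @rdname LoopSet-accessors
#' @export
setMethod("leftAnchors", "LoopSet", function(x) x@left)
#' @rdname LoopSet-accessors
#' @export
setMethod("rightAnchors", "LoopSet", function(x) x@right)
#' @rdname LoopSet-accessors
#' @export
setMethod("loopIds", "LoopSet", function(x) names(x@left))
#' @rdname LoopSet-accessors
#' @export
setMethod("provenance", "LoopSet", function(x) x@provenance)

#' @rdname LoopSet-accessors
#' @export
setMethod("loopLength", "LoopSet", function(x)
    end(x@right) - (start(x@left) - 1L))

#' @rdname LoopSet-accessors
#' @export
setMethod("anchorDistance", "LoopSet", function(x)
    (start(x@right) - 1L) - end(x@left))

#' @rdname LoopSet-accessors
#' @export
setMethod("loopLabels", "LabeledLoopSet", function(x) x@labels)

#' @export
setMethod("length", "LoopSet", function(x) length(x@left))

#' Subset a LoopSet
#' @param x a LoopSet; @param i index vector; @param j,...,drop ignored.
#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, left = x@left[i], right = x@right[i])
})

#' @export
setMethod("[", "LabeledLoopSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, left = x@left[i], right = x@right[i],
               labels = x@labels[i])
})

#' Concatenate LoopSets
#'
#' Ids are made unique by suffixing duplicates from the second set.
#' @param x,... LoopSets.
#' @export
setMethod("c", "LoopSet", function(x, ...) {
    others <- list(...)
    out <- x
    for (y in others) {
        idsY <- loopIds(y)
        dup <- idsY %in% loopIds(out)
        if (any(dup)) idsY[dup] <- paste0(idsY[dup], "_b")
        l <- y@left; r <- y@right
        names(l) <- idsY; names(r) <- idsY
        out <- initialize(out,
            left = suppressWarnings(c(out@left, l)),
            right = suppressWarnings(c(out@right, r)))
    }
    out
})

setMethod("show", "LoopSet", function(object) {
    cat(sprintf("%s with %d loop(s) [%s]\n", class(object), length(object),
                object@provenance))
    if (length(object)) {
        L <- loopLength(object)
        cat(sprintf("  chromosomes: %s\n",
                    paste(unique(as.character(seqnames(object@left))),
                          collapse = ", ")))
        cat(sprintf("  loop length (bp): min %d / median %d / max %d\n",
                    min(L), as.integer(stats::median(L)), max(L)))
    }
    if (is(object, "LabeledLoopSet") && length(object))
        cat(sprintf("  labels: %d positive, %d negative\n",
                    sum(object@labels == 1L), sum(object@labels == 0L)))
    invisible(NULL)
})

#' @rdname ReadTrack-class
#' @param x a ReadTrack.
#' @export
setMethod("trackName", "ReadTrack", function(x) x@name)
#' @rdname ReadTrack-class
#' @export
setMethod("trackReads", "ReadTrack", function(x) x@reads)
#' @rdname ReadTrack-class
#' @export
setMethod("librarySize", "ReadTrack", function(x) x@librarySize)

setMethod("show", "ReadTrack", function(object) {
    cat(sprintf("ReadTrack '%s': %d read(s), library size %g\n",
                object@name, length(object@reads), object@librarySize))
    invisible(NULL)
})

setMethod("show", "MetricsReport", function(object) {
    cat(sprintf("MetricsReport (%s averaging)\n", object@averaging))
    if (length(object@tags))
        cat(sprintf("  %s\n", paste(names(object@tags), object@tags,
                                    sep = "=", collapse = ", ")))
    cat(sprintf("  accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
                object@accuracy, object@precision, object@recall, object@f1))
    invisible(NULL)
})

setMethod("show", "TrainedLoopModel", function(object) {
    cat(sprintf("TrainedLoopModel: %s (%d features, %s rows)\n",
                object@spec@algorithm, length(object@fingerprint),
                ifelse(is.null(object@meta$nTrain), "?", object@meta$nTrain)))
    invisible(NULL)
})

setMethod("show", "ImportanceProfile", function(object) {
    cat(sprintf("ImportanceProfile [%s]: %d features%s\n", object@model,
                length(object@values),
                if (object@normalized) ", normalized (sum = 1)" else ""))
    invisible(NULL)
})

setMethod("show", "SimulatedDataset", function(object) {
    cat(sprintf(paste0("SimulatedDataset (cell line %d): %d true loops, ",
                       "replicates %d/%d, %d peaks, %d tracks\n"),
                object@cellLine, length(object@trueLoops),
                length(object@replicateA), length(object@replicateB),
                length(object@peaks), length(object@tracks)))
    invisible(NULL)
})
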