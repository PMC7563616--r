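#' @include AllClasses.R classify.R
NULL

.parseFeatureNames <- function(nm, nBins) {
    m <- regmatches(nm, regexec("^(.+)_(left|in|right)_([0-9]+)$", nm))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad))
        stop(sprintf("unparseable feature name(s): %s",
                     paste(utils::head(nm[bad], 3L), collapse = ", ")))
    track <- vapply(m, `[`, "", 2L)
    window <- vapply(m, `[`, "", 3L)
    position <- as.integer(vapply(m, `[`, "", 4L))
    third <- nBins %/% 3L
    offset <- c(left = 0L, `in` = third, right = 2L * third)
    data.frame(track = track, window = window, position = position,
               absolute_bin = position + offset[window],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract feature importance from a tree-based model
#'
#' Decision trees and random forests report impurity-decrease importance;
#' gradient boosting reports gain. SVM, MLP and deep networks assign no
#' native importance during training and raise an error. Importances are
#' aligned 1:1 to the model's schema fingerprint (features the learner never
#' used get 0) and normalized to sum 1.
#'
#' @param model a [TrainedLoopModel-class] with algorithm `decision_tree`,
#'   `random_forest` or `xgboost`.
#' @param ... unused.
#' @return an [ImportanceProfile-class].
#' @export
setMethod("featureImportance", "TrainedLoopModel", function(model, ...) {
    alg <- model@spec@algorithm
    fp <- model@fingerprint
    raw <- switch(alg,
        decision_tree = {
            vi <- model@fit$variable.importance
            if (is.null(vi)) stats::setNames(numeric(0), character(0)) else vi
        },
        random_forest = model@fit$variable.importance,
        xgboost = {
            imp <- xgboost::xgb.importance(model = model@fit)
            stats::setNames(imp$Gain, imp$Feature)
        },
        stop(sprintf("no native importance for algorithm '%s' (only %s)",
                     alg, "decision_tree, random_forest and xgboost")))
    type <- if (alg == "xgboost") "gain" else "impurity"
    v <- stats::setNames(numeric(length(fp)), fp)
    raw <- raw[names(raw) %in% fp]
    v[names(raw)] <- raw
    s <- sum(v)
    normalized <- s > 0
    if (normalized) v <- v / s
    else warning("all importances are zero (no splits); profile unnormalized")
    nBins <- model@meta$nBins
    if (is.null(nBins)) nBins <- 1500L
    ann <- .parseFeatureNames(fp, nBins)
    new("ImportanceProfile", values = v, model = paste(alg, type, sep = ":"),
        normalized = normalized, nBins = as.integer(nBins),
        trackOrder = unique(ann$track))
})

#' Rank the top-k important features
#'
#' Features are sorted by importance (descending); ties are broken
#' deterministically by track order in the schema, then ascending absolute
#' bin. Each entry carries the left/in/right window name and within-window
#' position (left = bins 1..nBins/3, in = the loop itself, right = the
#' right flank).
#'
#' @param profile an [ImportanceProfile-class].
#' @param k number of features to report (`k >= 1`; larger than the number
#'   of features returns all).
#' @return data.frame: rank, feature, track, window, position,
#'   absolute_bin, importance.
#' @export
topFeatures <- function(profile, k = 10L) {
    stopifnot(is(profile, "ImportanceProfile"), k >= 1L)
    ann <- .parseFeatureNames(names(profile@values), profile@nBins)
    ord <- order(-profile@values, match(ann$track, profile@trackOrder),
                 ann$absolute_bin)
    k <- min(as.integer(k), length(ord))
    sel <- ord[seq_len(k)]
    data.frame(rank = seq_len(k), feature = names(profile@values)[sel],
               track = ann$track[sel], window = ann$window[sel],
               position = ann$position[sel],
               absolute_bin = ann$absolute_bin[sel],
               importance = unname(profile@values[sel]),
               row.names = NULL)
}

#' Position-specific importance profile of one track
#'
#' The importances of that track in absolute-bin order (length `nBins`;
#' bins absent from the profile's schema, e.g. outside anchor windows for
#' anchor-subset models, are 0). The anchor boundaries sit between bins
#' `nBins/3` and `nBins/3 + 1` (left) and `2 nBins/3` and `2 nBins/3 + 1`
#' (right).
#'
#' @param profile an [ImportanceProfile-class].
#' @param track track name.
#' @return numeric vector of length `nBins`, with the anchor boundary bins
#'   recorded in attribute `anchorBoundaries`.
#' @export
trackProfile <- function(profile, track) {
    stopifnot(is(profile, "ImportanceProfile"))
    if (!track %in% profile@trackOrder)
        stop(sprintf("unknown track '%s'; profile has: %s", track,
                     paste(profile@trackOrder, collapse = ", ")))
    ann <- .parseFeatureNames(names(profile@values), profile@nBins)
    out <- numeric(profile@nBins)
    sel <- ann$track == track
    out[ann$absolute_bin[sel]] <- profile@values[sel]
    third <- profile@nBins %/% 3L
    attr(out, "anchorBoundaries") <- c(left = third, right = 2L * third)
    out
}

#' Fraction of importance concentrated in the anchor windows
#'
#' Sums the importance over the anchor-window bins ([anchorWindowBins()]) of
#' every track, as a fraction of the total. For a uniform profile over a
#' full 1500-bin matrix this is 200/1500.
#'
#' @param profile a normalized [ImportanceProfile-class].
#' @param windowBins anchor-window size in bins (default 100).
#' @return fraction in `[0, 1]`.
#' @export
anchorConcentration <- function(profile, windowBins = 100L) {
    stopifnot(is(profile, "ImportanceProfile"))
    total <- sum(profile@values)
    if (total == 0) return(NA_real_)
    bins <- anchorWindowBins(profile@nBins, windowBins)
    ann <- .parseFeatureNames(names(profile@values), profile@nBins)
    sum(profile@values[ann$absolute_bin %in% bins]) / total
}

#' Write a top-k ranking as tab-delimited text
#' @param profile an [ImportanceProfile-class]; @param path output file;
#' @param k ranking depth.
#' @return `path`, invisibly.
#' @export
writeImportanceRanking <- function(profile, path, k = 10L) {
    utils::write.table(topFeatures(profile, k), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
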