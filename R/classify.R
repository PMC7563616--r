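#' @include AllClasses.R feature-matrix.R dense-net.R
NULL

.algorithms <- c("decision_tree", "random_forest", "xgboost", "svm_rbf",
                 "mlp", "deep_ann")

#' Default hyperparameters per algorithm
#'
#' The study configuration: decision tree of maximum depth 10 with the
#' entropy split criterion (a `criterion` switch allows Gini); random forest
#' with 250 trees of maximum depth 8; gradient boosting with 100 estimators,
#' learning rate 0.1 and maximum depth 3; RBF-kernel SVM with C = 100;
#' multi-layer perceptron with L2 alpha 0.001 and an adaptive learning rate;
#' and a deep network with hidden layers 120-30-10 (relu), dropout 0.2 after
#' the first two, and a sigmoid output unit.
#'
#' @param algorithm one of `decision_tree`, `random_forest`, `xgboost`,
#'   `svm_rbf`, `mlp`, `deep_ann`.
#' @return named list of defaults.
#' @export
defaultHyperparameters <- function(algorithm) {
    switch(match.arg(algorithm, .algorithms),
        decision_tree = list(max_depth = 10L, criterion = "entropy",
                             min_split = 20L, cp = 0),
        random_forest = list(n_estimators = 250L, max_depth = 8L,
                             mtry = NULL),
        xgboost = list(n_estimators = 100L, learning_rate = 0.1,
                       max_depth = 3L),
        svm_rbf = list(C = 100, gamma = NULL, standardize = TRUE),
        mlp = list(hidden = mlpHiddenPreset("two-layer"), alpha = 0.001,
                   learning_rate = "adaptive", lr_init = 0.001,
                   epochs = 40L, batch_size = 32L, standardize = TRUE),
        deep_ann = list(hidden = c(120L, 30L, 10L), dropout = c(0.2, 0.2, 0),
                        epochs = 30L, batch_size = 32L, lr = 0.001,
                        alpha = 0, standardize = TRUE))
}

#' Construct a ModelSpec
#'
#' @param algorithm classifier name (see [defaultHyperparameters()]).
#' @param ... hyperparameter overrides; unknown keys are rejected.
#' @param seed seed fixed for all stochastic parts of training.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(algorithm, ..., seed = 1L) {
    algorithm <- match.arg(algorithm, .algorithms)
    hp <- defaultHyperparameters(algorithm)
    over <- list(...)
    unknown <- setdiff(names(over), names(hp))
    if (length(unknown))
        stop(sprintf("unknown hyperparameter(s) for %s: %s", algorithm,
                     paste(unknown, collapse = ", ")))
    hp[names(over)] <- over
    new("ModelSpec", algorithm = algorithm, hyperparameters = hp,
        seed = as.integer(seed))
}

#' The six default model specs
#' @param seed shared training seed.
#' @return named list of [ModelSpec-class].
#' @export
defaultModelSpecs <- function(seed = 1L) {
    specs <- lapply(.algorithms, modelSpec, seed = seed)
    names(specs) <- .algorithms
    specs
}

#' Split a feature matrix into train and test sets
#'
#' Disjoint loop (column) partition; with `stratified = TRUE` the class
#' ratio is preserved within rounding. Deterministic per seed.
#'
#' @param fm a [LoopFeatureMatrix-class] with labels.
#' @param split a [SplitSpec-class].
#' @return list with [LoopFeatureMatrix-class] elements `train` and `test`.
#' @export
splitTrainTest <- function(fm, split = SplitSpec()) {
    validObject(split)
    y <- colData(fm)$label
    if (anyNA(y)) stop("labels required for splitting")
    set.seed(split@seed)
    if (split@stratified) {
        byClass <- split(seq_along(y), y)
        if (any(vapply(byClass, length, integer(1)) < 2L))
            stop("each class needs >= 2 rows for a stratified split")
        trainIdx <- unlist(lapply(byClass, function(ix)
            sample(ix, round(split@trainFraction * length(ix)))))
    } else {
        trainIdx <- sample(seq_along(y),
                           round(split@trainFraction * length(y)))
    }
    trainIdx <- sort(trainIdx)
    list(train = fm[, trainIdx],
         test = fm[, setdiff(seq_along(y), trainIdx)])
}

.standardizeFit <- function(x) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    list(center = ctr, scale = scl)
}

.standardizeApply <- function(x, std) {
    if (is.null(std)) return(x)
    sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

.mlValues <- function(fm) {
    x <- t(assay(fm))
    y <- colData(fm)$label
    list(x = x, y = y)
}

#' Train a classifier on a feature matrix
#'
#' Fits the algorithm named by the spec with its hyperparameters, records
#' the feature-schema fingerprint (ordered feature names) of the training
#' matrix, and — for the scale-sensitive learners (SVM, MLP, deep net) —
#' standardizes inputs on the training data and stores the transformation
#' for prediction. All stochastic learners are seeded from the spec.
#'
#' @param spec a [ModelSpec-class].
#' @param fm training [LoopFeatureMatrix-class] (both classes present).
#' @return a [TrainedLoopModel-class].
#' @export
trainModel <- function(spec, fm) {
    stopifnot(is(spec, "ModelSpec"))
    v <- .mlValues(fm)
    x <- v$x; y <- v$y
    if (nrow(x) == 0L) stop("empty training matrix")
    if (anyNA(y)) stop("training matrix must carry labels")
    if (length(unique(y)) < 2L)
        stop("training set contains a single class")
    hp <- spec@hyperparameters
    std <- NULL
    if (isTRUE(hp$standardize)) {
        std <- .standardizeFit(x)
        x <- .standardizeApply(x, std)
    }
    set.seed(spec@seed)
    fit <- switch(spec@algorithm,
        decision_tree = {
            df <- data.frame(x, check.names = FALSE)
            df$.label <- factor(y, levels = c(0L, 1L))
            rpart::rpart(.label ~ ., data = df, method = "class",
                parms = list(split = if (hp$criterion == "entropy")
                                 "information" else "gini"),
                control = rpart::rpart.control(maxdepth = hp$max_depth,
                    minsplit = hp$min_split, cp = hp$cp, xval = 0L))
        },
        random_forest = ranger::ranger(x = x,
            y = factor(y, levels = c(0L, 1L)),
            num.trees = hp$n_estimators, max.depth = hp$max_depth,
            mtry = hp$mtry, seed = spec@seed, num.threads = 1L,
            importance = "impurity"),
        xgboost = xgboost::xgb.train(
            params = list(objective = "binary:logistic",
                          eta = hp$learning_rate, max_depth = hp$max_depth,
                          nthread = 1L, seed = spec@seed),
            data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
            nrounds = hp$n_estimators, verbose = 0L),
        svm_rbf = e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)),
            kernel = "radial", cost = hp$C,
            gamma = if (is.null(hp$gamma)) 1 / ncol(x) else hp$gamma,
            scale = FALSE),
        mlp = denseNetTrain(x, y, hidden = hp$hidden, dropout = 0,
            epochs = hp$epochs, batchSize = hp$batch_size,
            lr = hp$lr_init, alpha = hp$alpha,
            adaptive = identical(hp$learning_rate, "adaptive"),
            seed = spec@seed),
        deep_ann = denseNetTrain(x, y, hidden = hp$hidden,
            dropout = hp$dropout, epochs = hp$epochs,
            batchSize = hp$batch_size, lr = hp$lr, alpha = hp$alpha,
            adaptive = TRUE, seed = spec@seed))
    new("TrainedLoopModel", spec = spec, fit = fit,
        fingerprint = rownames(fm), standardization = std,
        meta = list(nTrain = ncol(fm), nBins = metadata(fm)$nBins,
                    classBalance = unname(table(y)["1"] / length(y)),
                    category = metadata(fm)$category,
                    dataset = metadata(fm)$dataset,
                    timestamp = format(Sys.time(), tz = "UTC")))
}

.checkFingerprint <- function(model, fm) {
    fp <- rownames(fm)
    if (length(fp) != length(model@fingerprint) ||
        any(fp != model@fingerprint)) {
        diff <- which(fp[seq_len(min(length(fp),
                                     length(model@fingerprint)))] !=
                      model@fingerprint[seq_len(min(length(fp),
                                                    length(model@fingerprint)))])
        first <- if (length(diff)) model@fingerprint[diff[1L]]
                 else "(length mismatch)"
        stop(sprintf("feature schema fingerprint mismatch; first difference: %s",
                     first))
    }
    invisible(TRUE)
}

#' Predicted 0/1 labels for the loops of a feature matrix
#' @param model a [TrainedLoopModel-class]; @param fm a matching
#'   [LoopFeatureMatrix-class].
#' @return integer vector of 0/1 predictions.
#' @export
predictLabels <- function(model, fm) {
    .checkFingerprint(model, fm)
    x <- t(assay(fm))
    x <- .standardizeApply(x, model@standardization)
    fit <- model@fit
    out <- switch(model@spec@algorithm,
        decision_tree = as.integer(as.character(
            stats::predict(fit, data.frame(x, check.names = FALSE),
                           type = "class"))),
        random_forest = as.integer(as.character(
            stats::predict(fit, data = x,
                           num.threads = 1L)$predictions)),
        xgboost = as.integer(stats::predict(
            fit, xgboost::xgb.DMatrix(x, nthread = 1L)) > 0.5),
        svm_rbf = as.integer(as.character(stats::predict(fit, x))),
        mlp = as.integer(predict.denseNet(fit, x) > 0.5),
        deep_ann = as.integer(predict.denseNet(fit, x) > 0.5))
    out
}

#' Tally confusion counts
#'
#' @param truth,pred 0/1 vectors of equal length; class 1 is the designated
#'   positive class.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(truth, pred) {
    stopifnot(length(truth) == length(pred))
    ConfusionCounts(tp = sum(truth == 1L & pred == 1L),
                    fp = sum(truth == 0L & pred == 1L),
                    fn = sum(truth == 1L & pred == 0L),
                    tn = sum(truth == 0L & pred == 0L))
}

.classMetrics <- function(tp, fp, fn) {
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall /
              (precision + recall) else 0
    c(precision = precision, recall = recall, f1 = f1)
}

#' Compute the metric suite from confusion counts
#'
#' Accuracy `(TP+TN)/total`; precision, recall and F1 for each class with
#' the zero-denominator convention (0). `positive_class` reports the
#' class-1 values; `macro` averages the two classes; `weighted` (the
#' headline default) weights them by class support.
#'
#' @param counts a [ConfusionCounts-class].
#' @param averaging `weighted`, `macro` or `positive_class`.
#' @param tags optional named character annotations carried in the report.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(counts, averaging = c("weighted", "macro",
                                                 "positive_class"),
                           tags = character()) {
    averaging <- match.arg(averaging)
    validObject(counts)
    tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
    total <- tp + fp + fn + tn
    if (total == 0L) stop("no evaluated rows")
    pos <- .classMetrics(tp, fp, fn)
    neg <- .classMetrics(tn, fn, fp)  # negative class as its own positive
    support <- c(`1` = tp + fn, `0` = tn + fp)
    perClass <- data.frame(class = c(1L, 0L), support = as.integer(support),
                           precision = c(pos["precision"], neg["precision"]),
                           recall = c(pos["recall"], neg["recall"]),
                           f1 = c(pos["f1"], neg["f1"]), row.names = NULL)
    agg <- switch(averaging,
        positive_class = pos,
        macro = (pos + neg) / 2,
        weighted = (pos * support["1"] + neg * support["0"]) / total)
    new("MetricsReport", accuracy = (tp + tn) / total,
        precision = unname(agg["precision"]), recall = unname(agg["recall"]),
        f1 = unname(agg["f1"]), averaging = averaging, perClass = perClass,
        counts = counts, tags = tags)
}

#' Evaluate a trained model on a test matrix
#'
#' Predicts the test loops (the schema fingerprint must match exactly),
#' tallies confusion counts and computes the metric suite.
#'
#' @param model a [TrainedLoopModel-class].
#' @param fm test [LoopFeatureMatrix-class].
#' @param averaging see [computeMetrics()].
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, fm, averaging = "weighted") {
    y <- colData(fm)$label
    if (anyNA(y)) stop("test matrix must carry labels")
    pred <- predictLabels(model, fm)
    computeMetrics(confusionCounts(y, pred), averaging = averaging,
                   tags = c(algorithm = model@spec@algorithm,
                            category = as.character(metadata(fm)$category)))
}

#' Train and evaluate a set of model specs on one split
#'
#' All specs share the identical train/test partition. A failing algorithm
#' yields a row with NA metrics and the error message in `status`, not an
#' abort.
#'
#' @param fm labeled [LoopFeatureMatrix-class].
#' @param specs list of [ModelSpec-class] (default: all six).
#' @param split a [SplitSpec-class].
#' @param averaging see [computeMetrics()].
#' @return data.frame with columns algorithm, category, accuracy, precision,
#'   recall, f1, status; the fitted models and reports are attached as
#'   attributes `models` and `reports`.
#' @export
runComparison <- function(fm, specs = defaultModelSpecs(),
                          split = SplitSpec(), averaging = "weighted") {
    stopifnot(length(specs) > 0L)
    parts <- splitTrainTest(fm, split)
    rows <- list(); models <- list(); reports <- list()
    for (k in seq_along(specs)) {
        spec <- specs[[k]]
        res <- tryCatch({
            m <- trainModel(spec, parts$train)
            r <- evaluateModel(m, parts$test, averaging = averaging)
            models[[spec@algorithm]] <- m
            reports[[spec@algorithm]] <- r
            data.frame(algorithm = spec@algorithm,
                       category = as.character(metadata(fm)$category),
                       accuracy = r@accuracy, precision = r@precision,
                       recall = r@recall, f1 = r@f1, status = "ok")
        }, error = function(e)
            data.frame(algorithm = spec@algorithm,
                       category = as.character(metadata(fm)$category),
                       accuracy = NA_real_, precision = NA_real_,
                       recall = NA_real_, f1 = NA_real_,
                       status = paste0("failed: ", conditionMessage(e))))
        rows[[k]] <- res
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "models") <- models
    attr(out, "reports") <- reports
    out
}

#' Apply a trained model to another dataset's matrix
#'
#' Evaluation without refitting, for cross-cell-line application. The
#' feature schema fingerprints must be identical (same tracks, bin count and
#' category), which prevents silent column misalignment.
#'
#' @param model a [TrainedLoopModel-class].
#' @param fm the other dataset's [LoopFeatureMatrix-class].
#' @param source,target free-text dataset tags recorded in the report.
#' @param averaging see [computeMetrics()].
#' @return a [MetricsReport-class] tagged with source and target.
#' @export
crossApply <- function(model, fm, source = "source", target = "target",
                       averaging = "weighted") {
    y <- colData(fm)$label
    if (anyNA(y)) stop("target matrix must carry labels")
    pred <- predictLabels(model, fm)
    computeMetrics(confusionCounts(y, pred), averaging = averaging,
                   tags = c(algorithm = model@spec@algorithm,
                            category = as.character(metadata(fm)$category),
                            source = source, target = target))
}
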