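#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Compact dense feed-forward network (relu hidden layers, sigmoid output,
## binary cross-entropy + L2, inverted dropout, Adam, mini-batches, and an
## adaptive learning-rate schedule that halves the rate when the epoch loss
## stops improving). Backend for the mlp and deep_ann model specs; written
## in-package because no installed R package provides multi-hidden-layer
## networks with dropout.
## ---------------------------------------------------------------------------

.reluF <- function(z) pmax(z, 0)
.sigmoidF <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

#' Train a dense feed-forward binary classifier
#'
#' @param x numeric matrix, rows = samples, columns = features (expected to
#'   be standardized by the caller).
#' @param y 0/1 integer labels.
#' @param hidden integer vector of hidden-layer sizes.
#' @param dropout per-hidden-layer dropout rates (recycled; 0 disables).
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param lr initial Adam learning rate.
#' @param alpha L2 regularization strength on the weights.
#' @param adaptive halve the learning rate when the epoch loss fails to
#'   improve by at least `tol` (sklearn-style "adaptive" schedule).
#' @param tol improvement tolerance for the adaptive schedule.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return an object of class `denseNet` with `$predict`-able weights.
#' @keywords internal
denseNetTrain <- function(x, y, hidden = c(120L, 30L, 10L),
                          dropout = c(0.2, 0.2, 0), epochs = 30L,
                          batchSize = 32L, lr = 0.001, alpha = 0,
                          adaptive = TRUE, tol = 1e-4, seed = 1L) {
    stopifnot(is.matrix(x), nrow(x) == length(y))
    set.seed(seed)
    y <- as.numeric(y)
    sizes <- c(ncol(x), as.integer(hidden), 1L)
    dropout <- rep_len(dropout, length(hidden))
    nL <- length(sizes) - 1L
    W <- vector("list", nL); b <- vector("list", nL)
    for (l in seq_len(nL)) {  # He initialization for relu stacks
        W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                      sd = sqrt(2 / sizes[l])),
                         sizes[l], sizes[l + 1L])
        b[[l]] <- rep(0, sizes[l + 1L])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mB <- lapply(b, function(v) v * 0); vB <- mB
    beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
    step <- 0L
    n <- nrow(x)
    bestLoss <- Inf
    for (epoch in seq_len(epochs)) {
        ord <- sample.int(n)
        epochLoss <- 0
        for (bs in split(ord, ceiling(seq_along(ord) / batchSize))) {
            xb <- x[bs, , drop = FALSE]; yb <- y[bs]
            m <- length(bs)
            ## forward with inverted dropout on hidden activations
            acts <- vector("list", nL + 1L); acts[[1L]] <- xb
            masks <- vector("list", nL)
            for (l in seq_len(nL)) {
                z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], "+")
                if (l < nL) {
                    a <- .reluF(z)
                    if (dropout[l] > 0) {
                        keep <- 1 - dropout[l]
                        msk <- matrix(stats::runif(length(a)) < keep,
                                      nrow(a), ncol(a)) / keep
                        a <- a * msk
                        masks[[l]] <- msk
                    }
                    acts[[l + 1L]] <- a
                } else {
                    acts[[l + 1L]] <- .sigmoidF(z)
                }
            }
            p <- as.numeric(acts[[nL + 1L]])
            eps <- 1e-12
            epochLoss <- epochLoss -
                sum(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))
            ## backward: d(BCE)/dz_out = p - y for sigmoid output
            delta <- matrix(p - yb, m, 1L)
            step <- step + 1L
            lrT <- lr * sqrt(1 - beta2^step) / (1 - beta1^step)
            for (l in rev(seq_len(nL))) {
                gW <- crossprod(acts[[l]], delta) / m + alpha * W[[l]]
                gB <- colSums(delta) / m
                if (l > 1L) {
                    delta <- delta %*% t(W[[l]])
                    delta <- delta * (acts[[l]] > 0)
                    if (!is.null(masks[[l - 1L]]))
                        delta <- delta * masks[[l - 1L]]
                }
                mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
                vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
                W[[l]] <- W[[l]] - lrT * mW[[l]] / (sqrt(vW[[l]]) + epsAdam)
                mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
                vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB^2
                b[[l]] <- b[[l]] - lrT * mB[[l]] / (sqrt(vB[[l]]) + epsAdam)
            }
        }
        epochLoss <- epochLoss / n
        if (adaptive && epochLoss > bestLoss - tol) lr <- lr / 2
        bestLoss <- min(bestLoss, epochLoss)
        if (lr < 1e-7) break
    }
    structure(list(W = W, b = b, hidden = hidden, loss = bestLoss),
              class = "denseNet")
}

#' Predicted positive-class probabilities of a dense network
#' @param object a `denseNet`; @param x sample-by-feature matrix;
#' @param ... unused.
#' @keywords internal
#' @export
predict.denseNet <- function(object, x, ...) {
    a <- x
    nL <- length(object$W)
    for (l in seq_len(nL)) {
        z <- sweep(a %*% object$W[[l]], 2L, object$b[[l]], "+")
        a <- if (l < nL) .reluF(z) else .sigmoidF(z)
    }
    as.numeric(a)
}

#' Named hidden-layer presets for the mlp spec
#'
#' Two readings of a layered-perceptron architecture are shipped:
#' `"two-layer"` (hidden sizes 40 then 10; the default, trains reliably
#' under plain backpropagation) and `"stacked"` (forty hidden layers of 10
#' units).
#'
#' @param name preset name.
#' @return integer vector of hidden-layer sizes.
#' @export
mlpHiddenPreset <- function(name = c("two-layer", "stacked")) {
    name <- match.arg(name)
    switch(name, "two-layer" = c(40L, 10L), "stacked" = rep(10L, 40L))
}
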