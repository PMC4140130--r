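#' @include AllClasses.R accessors.R synthetic.R
NULL

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SP = TN/(TN+FP), SN = TP/(TP+FN), and
#' the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP)).
#' Any metric whose denominator is zero is reported as 0 (documented
#' convention for degenerate confusion tables).
#'
#' @param TP,TN,FP,FN non-negative integer confusion counts.
#' @return named numeric vector with elements `ACC`, `SP`, `SN`,
#'   `MCC`.
#' @examples
#' confusionMetrics(TP = 39, TN = 195, FP = 0, FN = 0)
#' @export
confusionMetrics <- function(TP, TN, FP, FN) {
    stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
    total <- TP + TN + FP + FN
    safeDiv <- function(num, den) if (den == 0) 0 else num / den
    ## products kept in double; counts are far below 2^53
    mccDen <- sqrt((TN + FN) * (TN + FP)) * sqrt((TP + FN) * (TP + FP))
    mcc <- safeDiv(TP * TN - FP * FN, mccDen)
    c(ACC = safeDiv(TP + TN, total),
      SP = safeDiv(TN, TN + FP),
      SN = safeDiv(TP, TP + FN),
      MCC = min(1, max(-1, mcc)))   # guard rounding at the extremes
}

#' Train the margin classifier on a labeled feature matrix
#'
#' A soft-margin support-vector classifier solved by an SMO-family
#' decomposition method (libsvm via \pkg{e1071}), with features
#' standardized using statistics of the supplied training data only.
#' Defaults follow the reference configuration: linear (degree-1
#' polynomial) kernel with cost C = 1; polynomial degree and Gaussian
#' gamma are configurable.
#'
#' @param train numeric matrix, samples by features.
#' @param labels binary labels (1 positive, 0 negative) parallel to
#'   rows of `train`; both classes must be present.
#' @param kernel `"linear"`, `"polynomial"` or `"radial"`.
#' @param cost soft-margin cost C.
#' @param degree polynomial degree (polynomial kernel).
#' @param gamma kernel coefficient (polynomial/radial kernels);
#'   default 1/ncol.
#' @return a classifier handle; pass to [predictClassifier()].
#' @export
trainClassifier <- function(train, labels, kernel = "linear",
                            cost = 1, degree = 3L, gamma = NULL) {
    train <- as.matrix(train)
    y <- factor(labels, levels = c(0L, 1L))
    if (any(table(y) == 0L))
        stop("both classes must be present in the training data")
    mu <- colMeans(train)
    sg <- apply(train, 2L, stats::sd)
    sg[!is.finite(sg) | sg == 0] <- 1
    xs <- sweep(sweep(train, 2L, mu), 2L, sg, "/")
    if (is.null(gamma)) gamma <- 1 / ncol(train)
    fit <- e1071::svm(xs, y, type = "C-classification",
                      kernel = kernel, cost = cost, degree = degree,
                      gamma = gamma, scale = FALSE)
    structure(list(fit = fit, center = mu, scale = sg),
              class = "enrichClassifier")
}

#' Predict labels with a trained classifier
#'
#' @param object an `enrichClassifier` from [trainClassifier()].
#' @param newdata numeric matrix, samples by the same features.
#' @return integer vector of predicted labels (1/0).
#' @export
predictClassifier <- function(object, newdata) {
    stopifnot(inherits(object, "enrichClassifier"))
    newdata <- as.matrix(newdata)
    xs <- sweep(sweep(newdata, 2L, object$center), 2L,
                object$scale, "/")
    as.integer(as.character(stats::predict(object$fit, xs)))
}

## Deterministic stratified fold assignment: each class is permuted
## under the seed and dealt across folds; per-class remainders go to
## the currently least-loaded folds (ties by fold index), so total
## fold sizes also differ by at most one.
stratifiedFolds <- function(labels, folds, seed) {
    assign <- integer(length(labels))
    loads <- integer(folds)
    withSeed(seed, {
        for (cls in sort(unique(labels))) {
            idx <- which(labels == cls)
            perm <- sample(idx)
            base <- length(idx) %/% folds
            rem <- length(idx) %% folds
            counts <- rep.int(base, folds)
            if (rem > 0)
                counts[order(loads, seq_len(folds))[seq_len(rem)]] <-
                    base + 1L
            assign[perm] <- rep.int(seq_len(folds), counts)
            loads <- loads + counts
        }
    })
    assign
}

#' Stratified cross-validation with pooled confusion counts
#'
#' Samples are dealt into `folds` stratified portions (every fold
#' receives a near-equal share of each class); each portion serves
#' once as test data for a classifier trained on the remaining
#' portions, and the predictions of all folds are pooled into a single
#' confusion table — each sample is tested exactly once.
#'
#' @param x an [EnrichmentMatrix-class] with binary labels.
#' @param features character vector of term ids to use.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param ... classifier settings passed to [trainClassifier()].
#' @return named numeric vector `TP, TN, FP, FN`.
#' @export
crossValidate <- function(x, features, folds = 10L, seed = 1L, ...) {
    stopifnot(is(x, "EnrichmentMatrix"))
    lab <- geneLabels(x)
    if (any(is.na(lab))) stop("all genes must carry a binary label")
    if (any(table(factor(lab, c(0L, 1L))) < folds))
        stop("need at least one sample of each class per fold")
    m <- scoreMatrix(x)[, features, drop = FALSE]
    foldId <- stratifiedFolds(lab, folds, seed)
    pred <- integer(length(lab))
    for (f in seq_len(folds)) {
        te <- foldId == f
        clf <- trainClassifier(m[!te, , drop = FALSE], lab[!te], ...)
        pred[te] <- predictClassifier(clf, m[te, , drop = FALSE])
    }
    c(TP = sum(pred == 1L & lab == 1L),
      TN = sum(pred == 0L & lab == 0L),
      FP = sum(pred == 1L & lab == 0L),
      FN = sum(pred == 0L & lab == 1L))
}

#' Incremental feature selection over a ranked list
#'
#' For every prefix length i of the mRMR feature list, the classifier
#' is evaluated by stratified cross-validation restricted to the first
#' i features and the pooled confusion metrics are recorded, giving
#' the IFS curve (MCC against i). The optimal feature set is the
#' shortest prefix attaining the maximum MCC. The fold assignment is
#' fixed once per call, so the curve is bit-reproducible under a seed
#' and prefixes are compared on identical partitions.
#'
#' @param x an [EnrichmentMatrix-class] with binary labels.
#' @param rankedList character vector: the mRMR feature list.
#' @param folds cross-validation folds (default 10).
#' @param seed integer seed.
#' @param ... classifier settings passed to [trainClassifier()].
#' @return an [IFSResult-class].
#' @export
runIFS <- function(x, rankedList, folds = 10L, seed = 1L, ...) {
    stopifnot(is(x, "EnrichmentMatrix"))
    if (!length(rankedList)) stop("ranked feature list is empty")
    lab <- geneLabels(x)
    if (any(is.na(lab))) stop("all genes must carry a binary label")
    m <- scoreMatrix(x)[, rankedList, drop = FALSE]
    foldId <- stratifiedFolds(lab, folds, seed)
    L <- length(rankedList)
    curve <- data.frame(i = seq_len(L), TP = 0L, TN = 0L, FP = 0L,
                        FN = 0L, ACC = 0, SP = 0, SN = 0, MCC = 0)
    for (i in seq_len(L)) {
        pred <- integer(length(lab))
        xi <- m[, seq_len(i), drop = FALSE]
        for (f in seq_len(folds)) {
            te <- foldId == f
            clf <- trainClassifier(xi[!te, , drop = FALSE],
                                   lab[!te], ...)
            pred[te] <- predictClassifier(clf, xi[te, , drop = FALSE])
        }
        cc <- c(TP = sum(pred == 1L & lab == 1L),
                TN = sum(pred == 0L & lab == 0L),
                FP = sum(pred == 1L & lab == 0L),
                FN = sum(pred == 0L & lab == 1L))
        curve[i, c("TP", "TN", "FP", "FN")] <- as.list(cc)
        curve[i, c("ACC", "SP", "SN", "MCC")] <-
            as.list(confusionMetrics(cc[["TP"]], cc[["TN"]],
                                     cc[["FP"]], cc[["FN"]]))
    }
    best <- which.max(curve$MCC)   # first maximum = smallest prefix
    new("IFSResult", curve = curve, optimalSize = curve$i[[best]],
        optimalFeatures = rankedList[seq_len(curve$i[[best]])],
        maxMCC = curve$MCC[[best]])
}

#' Plot an IFS curve
#'
#' MCC (y-axis) against the number of top-ranked features in the
#' classifier (x-axis), with the optimal prefix marked.
#'
#' @param x an [IFSResult-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plotIFSCurve <- function(x, ...) {
    stopifnot(is(x, "IFSResult"))
    cv <- ifsCurve(x)
    graphics::plot(cv$i, cv$MCC, type = "l",
                   xlab = "number of features",
                   ylab = "MCC", ...)
    graphics::abline(v = optimalSize(x), lty = 2, col = "grey40")
    graphics::points(optimalSize(x), maxMCC(x), pch = 19,
                     col = "red3")
    invisible(x)
}
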