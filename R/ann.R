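## The 24-32-5 feed-forward classifier, trained by full-batch backpropagation.

sigmoid <- function(x) 1 / (1 + exp(-x))

annForward <- function(model, X) {
  w <- model@weights
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  H <- sigmoid(sweep(Xs %*% w$W1, 2, w$b1, "+"))
  O <- sigmoid(sweep(H %*% w$W2, 2, w$b2, "+"))
  list(H = H, O = O, Xs = Xs)
}

#' Train the motion classifier
#'
#' Full-batch gradient descent on the mean squared error between the logistic
#' network outputs and one-hot class targets (loss averaged over samples,
#' summed over the five output nodes). Inputs are standardized column-wise
#' with statistics stored in the returned model. Training is deterministic
#' given the model seed; the per-pass loss trace is retained and is
#' non-increasing under the default learning rate.
#'
#' @param features Numeric matrix, one row per epoch, \code{layerSizes[1]}
#'   columns (see [traceFeatures()]).
#' @param labels Factor or character vector of motion labels, one per row;
#'   every class in [motionLabels()] must be present.
#' @param model An untrained [AnnModel] carrying the hyperparameters.
#' @return The trained [AnnModel].
#' @export
trainAnn <- function(features, labels, model = AnnModel()) {
  stopifnot(is(model, "AnnModel"))
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = motionLabels())
  if (anyNA(labels)) stop("labels must be motion labels")
  if (nrow(features) != length(labels)) stop("one label per feature row required")
  missing <- setdiff(motionLabels(), unique(as.character(labels)))
  if (length(missing))
    stop("missing class(es) in training data: ", paste(missing, collapse = ", "))
  p <- model@trainParams
  sizes <- model@layerSizes
  if (ncol(features) != sizes[1]) stop("feature dimension does not match the input layer")

  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(features, 2, center), 2, scale, "/")
  n <- nrow(Xs)
  Tm <- matrix(0, n, sizes[3])
  Tm[cbind(seq_len(n), as.integer(labels))] <- 1

  set.seed(p$seed)
  W1 <- matrix(stats::runif(sizes[1] * sizes[2], -p$initRange, p$initRange), sizes[1])
  b1 <- stats::runif(sizes[2], -p$initRange, p$initRange)
  W2 <- matrix(stats::runif(sizes[2] * sizes[3], -p$initRange, p$initRange), sizes[2])
  b2 <- stats::runif(sizes[3], -p$initRange, p$initRange)

  lr <- p$learningRate
  loss <- numeric(p$epochs)
  for (e in seq_len(p$epochs)) {
    H <- sigmoid(sweep(Xs %*% W1, 2, b1, "+"))
    O <- sigmoid(sweep(H %*% W2, 2, b2, "+"))
    E <- O - Tm
    loss[e] <- sum(E^2) / n
    if (!is.finite(loss[e])) stop("training diverged: non-finite loss at pass ", e)
    dO <- 2 * E * O * (1 - O) / n
    dH <- (dO %*% t(W2)) * H * (1 - H)
    W2 <- W2 - lr * t(H) %*% dO
    b2 <- b2 - lr * colSums(dO)
    W1 <- W1 - lr * t(Xs) %*% dH
    b1 <- b1 - lr * colSums(dH)
  }
  model@weights <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  model@center <- center
  model@scale <- scale
  model@lossTrace <- loss
  model@trained <- TRUE
  validObject(model)
  model
}

#' Classify feature vectors
#'
#' Forward pass through the trained network; the predicted class is the
#' arg-max output node. Exact ties resolve to the lowest-index class (the
#' canonical order of [motionLabels()]).
#'
#' @param model A trained [AnnModel].
#' @param features A feature matrix (rows = epochs) or a single feature
#'   vector.
#' @return For \code{classifyFeatures}, a factor of predicted labels; for
#'   \code{classifyEpoch}, a single label (character).
#' @export
classifyFeatures <- function(model, features) {
  stopifnot(is(model, "AnnModel"))
  if (!model@trained) stop("model has not been trained")
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  O <- annForward(model, features)$O
  idx <- apply(O, 1, which.max)   # which.max: first maximum, lowest index on ties
  factor(motionLabels()[idx], levels = motionLabels())
}

#' @rdname classifyFeatures
#' @param fv A single 24-value feature vector.
#' @export
classifyEpoch <- function(model, fv) as.character(classifyFeatures(model, fv))

#' Run a classification session and tabulate accuracy
#'
#' Classifies one trace per task and reports the per-task recognition
#' accuracy: correct decisions over total decisions, in percent, plus an
#' unweighted mean row. With the streaming convention and a 2 s segment per
#' task, each task contributes exactly 200 decisions.
#'
#' @param taskTraces Named list of [MeasurementTrace] objects; names must be
#'   motion labels (the commanded task of each segment).
#' @param model A trained [AnnModel].
#' @param spec A [FeatureSpec].
#' @param cfg An [EpochConfig].
#' @param streaming Use the streaming epoch convention (default TRUE).
#' @return A data.frame with columns \code{task}, \code{nDecisions},
#'   \code{nCorrect}, \code{accuracy} (percent), final row \code{"mean"}.
#' @export
runSession <- function(taskTraces, model, spec = FeatureSpec(),
                       cfg = EpochConfig(), streaming = TRUE) {
  if (is.null(names(taskTraces)) || !all(names(taskTraces) %in% motionLabels()))
    stop("taskTraces must be named by motion label")
  rows <- lapply(names(taskTraces), function(task) {
    trace <- taskTraces[[task]]
    if (nSamples(trace) == 0) stop("empty segment for task ", task)
    feats <- traceFeatures(trace, spec, cfg, streaming = streaming)
    pred <- classifyFeatures(model, feats)
    data.frame(task = task, nDecisions = length(pred),
               nCorrect = sum(pred == task),
               accuracy = 100 * mean(pred == task))
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(task = "mean", nDecisions = sum(tab$nDecisions),
                        nCorrect = sum(tab$nCorrect),
                        accuracy = mean(tab$accuracy)))
}
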