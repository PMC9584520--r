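## Random-forest analysis of which parameters and initial conditions
## separate oscillatory from chaotic input vectors.

#' Assemble a label-balanced classification dataset
#'
#' Subsamples the larger class so both classes are equally represented,
#' then assigns a random train/test split.
#'
#' @param oscillatory data frame / matrix of oscillatory input vectors
#'   (one row per vector, one column per free parameter).
#' @param chaotic data frame / matrix of chaotic input vectors with the
#'   same columns.
#' @param seed RNG seed (balancing and splitting are deterministic given it).
#' @param split_ratio fraction of rows assigned to the training set.
#' @return list with `features`, `labels` (factor `oscillatory`/`chaotic`)
#'   and logical `train` split assignment.
#' @export
build_dataset <- function(oscillatory, chaotic, seed = 1, split_ratio = 0.5) {
  oscillatory <- as.data.frame(oscillatory)
  chaotic <- as.data.frame(chaotic)
  if (!nrow(oscillatory) || !nrow(chaotic)) stop("both classes must be non-empty")
  if (!identical(sort(names(oscillatory)), sort(names(chaotic))))
    stop("feature columns differ between classes")
  chaotic <- chaotic[, names(oscillatory), drop = FALSE]
  set.seed(seed)
  n <- min(nrow(oscillatory), nrow(chaotic))
  o <- oscillatory[sample(nrow(oscillatory), n), , drop = FALSE]
  c_ <- chaotic[sample(nrow(chaotic), n), , drop = FALSE]
  features <- rbind(o, c_)
  labels <- factor(rep(c("oscillatory", "chaotic"), each = n),
                   levels = c("oscillatory", "chaotic"))
  train <- rep(FALSE, 2 * n)
  train[sample(2 * n, round(split_ratio * 2 * n))] <- TRUE
  rownames(features) <- NULL
  list(features = features, labels = labels, train = train)
}

#' Train a random-forest classifier of dynamical regime
#'
#' Fits a random forest on the training split and evaluates accuracy and
#' the confusion matrix on the held-out split. Importance is computed from
#' permutation accuracy decrease (with its standard deviation across
#' trees) and Gini impurity decrease.
#'
#' @param dataset from [build_dataset()].
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @return list with `model`, `accuracy`, `confusion` (2 x 2, test split),
#'   and `importance` (see [feature_importance()]).
#' @export
train_classifier <- function(dataset, n_trees = 2000, seed = 1) {
  tr <- dataset$train
  if (length(unique(dataset$labels[tr])) < 2)
    stop("training split is single-class")
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = dataset$features[tr, , drop = FALSE], y = dataset$labels[tr],
    ntree = n_trees, importance = TRUE)
  pred <- stats::predict(fit, dataset$features[!tr, , drop = FALSE])
  truth <- dataset$labels[!tr]
  confusion <- table(truth = truth, predicted = pred)
  list(model = fit,
       accuracy = mean(pred == truth),
       confusion = confusion,
       importance = feature_importance(fit))
}

#' Per-feature importance with across-tree spread
#'
#' @param model a fitted `randomForest` classifier (trained with
#'   `importance = TRUE`).
#' @return data frame sorted by decreasing importance: permutation
#'   importance (`mean_decrease_accuracy`) with its standard deviation
#'   across trees, Gini decrease, and a normalised column summing to 1.
#' @export
feature_importance <- function(model) {
  imp <- randomForest::importance(model)
  sdv <- model$importanceSD
  sd_acc <- if (is.matrix(sdv)) sdv[, "MeanDecreaseAccuracy"] else sdv
  out <- data.frame(
    feature = rownames(imp),
    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
    sd_across_trees = sd_acc,
    gini_decrease = imp[, "MeanDecreaseGini"])
  tot <- sum(pmax(out$gini_decrease, 0))
  out$normalised <- if (tot > 0) pmax(out$gini_decrease, 0) / tot else 0
  out <- out[order(-out$mean_decrease_accuracy), ]
  rownames(out) <- NULL
  out
}
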