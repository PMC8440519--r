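#' Enumerate cross-dataset train/test splits
#'
#' With four SZ-bearing datasets and two ASD-bearing datasets, a split
#' trains on two SZ datasets plus one ASD dataset and tests on the
#' remaining two SZ datasets plus the other ASD dataset, giving
#' choose(4,2) x 2 = 12 experiments.
#'
#' @param sz_datasets character vector of SZ-bearing dataset ids.
#' @param asd_datasets character vector of ASD-bearing dataset ids.
#' @return list of splits, each a list with `train_sz`, `train_asd`,
#'   `test_sz`, `test_asd`.
#' @export
split_plan <- function(sz_datasets, asd_datasets) {
  stopifnot(length(sz_datasets) >= 2, length(asd_datasets) >= 2)
  plans <- list()
  for (cb in asplit(combn(sz_datasets, 2), 2)) {
    for (a in asd_datasets) {
      plans[[length(plans) + 1L]] <- list(
        train_sz = as.character(cb),
        train_asd = a,
        test_sz = setdiff(sz_datasets, cb),
        test_asd = setdiff(asd_datasets, a))
    }
  }
  plans
}

#' Select classification features from the change categorization
#'
#' Runs the full ANOVA-gated categorization engine on the training
#' subjects only (HCs participate in the categorization, not in the
#' classifier) and returns the union of the disorder-unique features
#' and the ASD-weaker features within the disorder-common changes.
#'
#' @param values subjects x features matrix.
#' @param covariates roster with `group` and `dataset`.
#' @param train_datasets dataset ids forming the training pool.
#' @param family,config passed to [run_group_contrast()].
#' @return character vector of selected feature ids.
#' @export
select_features <- function(values, covariates, train_datasets,
                            family = "fnc", config = NULL) {
  sel <- covariates$dataset %in% train_datasets
  gc <- run_group_contrast(values[sel, , drop = FALSE],
                           covariates$group[sel], family, config)
  unique_feats <- gc$anova$feature[
    gc$categories %in% c("SZ_UNIQUE_DECREASE", "ASD_UNIQUE_DECREASE")]
  weaker_feats <- gc$anova$feature[
    !is.na(gc$weaker) & gc$weaker == "ASD_WEAKER"]
  feats <- union(unique_feats, weaker_feats)
  if (!length(feats))
    stop("empty feature set: no unique or ASD-weaker changes found; ",
         "consider lowering the significance gates")
  feats
}

#' Train and evaluate one cross-dataset split
#'
#' Fits a linear support vector machine on the training datasets' SZ
#' and ASD subjects using the selected features, with the cost
#' parameter tuned by Bayesian optimization of internal k-fold
#' cross-validation accuracy over a log-spaced range. Test metrics are
#' computed with ASD as the positive class: sensitivity = correctly
#' classified ASD, specificity = correctly classified SZ.
#'
#' @param values subjects x features matrix.
#' @param covariates roster with `group`, `dataset`.
#' @param split one element of [split_plan()].
#' @param features selected feature ids.
#' @param positive_class label treated as positive (default `"ASD"`).
#' @param n_folds internal CV folds for tuning.
#' @param bo_init,bo_iter Bayesian-optimization budget (initial +
#'   acquisition evaluations).
#' @param seed RNG seed for fold assignment and tuning.
#' @return list: `accuracy`, `sensitivity`, `specificity` (percent, 1
#'   decimal), `cost`, confusion counts, `features`.
#' @export
train_and_evaluate <- function(values, covariates, split, features,
                               positive_class = "ASD", n_folds = 5,
                               bo_init = 6, bo_iter = 24, seed = 1L) {
  stopifnot(length(features) >= 1)
  values <- as.matrix(values)
  train_ds <- c(split$train_sz, split$train_asd)
  test_ds <- c(split$test_sz, split$test_asd)
  pat <- covariates$group %in% c("SZ", "ASD")
  tr <- pat & covariates$dataset %in% train_ds
  te <- pat & covariates$dataset %in% test_ds
  if (length(unique(covariates$group[tr])) < 2L)
    stop("training set lacks one of the two classes")
  Xtr <- values[tr, features, drop = FALSE]
  Xte <- values[te, features, drop = FALSE]
  ytr <- factor(covariates$group[tr], levels = c("SZ", "ASD"))
  yte <- factor(covariates$group[te], levels = c("SZ", "ASD"))
  # train-set standardization applied to both sets
  mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
  Xtr <- scale(Xtr, mu, sg); Xte <- scale(Xte, mu, sg)

  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), nrow(Xtr))))
  cv_acc <- function(log10c) {
    cost <- 10^log10c
    acc <- vapply(seq_len(n_folds), function(f) {
      hold <- folds == f
      if (length(unique(ytr[!hold])) < 2L) return(NA_real_)
      fit <- e1071::svm(Xtr[!hold, , drop = FALSE], ytr[!hold],
                        kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(fit, Xtr[hold, , drop = FALSE]) == ytr[hold])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }
  bo <- bayes_opt_1d(cv_acc, lower = -3, upper = 3,
                     n_init = bo_init, n_iter = bo_iter, seed = seed)
  cost <- 10^bo$x_best
  fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  pred <- predict(fit, Xte)
  pos <- yte == positive_class
  met <- confusion_metrics(tp = sum(pred == positive_class & pos),
                           fn = sum(pred != positive_class & pos),
                           tn = sum(pred != positive_class & !pos),
                           fp = sum(pred == positive_class & !pos))
  c(met, list(cost = cost, features = features))
}

# percent metrics (1 decimal) from confusion counts; sensitivity is the
# positive-class recall, specificity the negative-class recall
confusion_metrics <- function(tp, fn, tn, fp) {
  list(accuracy = round(100 * (tp + tn) / (tp + fn + tn + fp), 1),
       sensitivity = round(100 * tp / (tp + fn), 1),
       specificity = round(100 * tn / (tn + fp), 1),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Run all cross-dataset classification experiments
#'
#' For every split: feature selection on the training datasets (full
#' categorization engine, HCs included), SVM training on the training
#' patients, evaluation on the held-out datasets.
#'
#' @param values,covariates cohort measures and roster.
#' @param sz_datasets,asd_datasets dataset ids (defaults: datasets
#'   containing each patient group).
#' @param family,config categorization settings for selection.
#' @param ... passed to [train_and_evaluate()].
#' @return a `classifier_result` list: per-split data.frame `splits`
#'   and the [summarize_splits()] means.
#' @export
classify_datasets <- function(values, covariates,
                              sz_datasets = NULL, asd_datasets = NULL,
                              family = "fnc", config = NULL, ...) {
  if (is.null(sz_datasets))
    sz_datasets <- sort(unique(covariates$dataset[covariates$group == "SZ"]))
  if (is.null(asd_datasets))
    asd_datasets <- sort(unique(covariates$dataset[covariates$group == "ASD"]))
  plans <- split_plan(sz_datasets, asd_datasets)
  rows <- lapply(seq_along(plans), function(i) {
    sp <- plans[[i]]
    feats <- select_features(values, covariates,
                             c(sp$train_sz, sp$train_asd), family, config)
    res <- train_and_evaluate(values, covariates, sp, feats, ...)
    data.frame(split = i,
               train_sz = paste(sp$train_sz, collapse = "+"),
               train_asd = sp$train_asd,
               test_sz = paste(sp$test_sz, collapse = "+"),
               test_asd = paste(sp$test_asd, collapse = "+"),
               n_features = length(feats),
               accuracy = res$accuracy, sensitivity = res$sensitivity,
               specificity = res$specificity, stringsAsFactors = FALSE)
  })
  splits <- do.call(rbind, rows)
  structure(list(splits = splits, summary = summarize_splits(splits)),
            class = "classifier_result")
}

#' Aggregate split metrics
#'
#' Arithmetic means of accuracy, sensitivity and specificity across
#' splits, rounded to whole percent for the summary line, plus the
#' best (maximum) per-split values at one decimal.
#'
#' @param splits data.frame with `accuracy`, `sensitivity`,
#'   `specificity` columns (percent).
#' @return list: `mean_accuracy`, `mean_sensitivity`,
#'   `mean_specificity` (integer percent), `max_accuracy`,
#'   `max_sensitivity`, `max_specificity` (1 decimal).
#' @export
summarize_splits <- function(splits) {
  stopifnot(nrow(splits) >= 1)
  list(mean_accuracy = round(mean(splits$accuracy)),
       mean_sensitivity = round(mean(splits$sensitivity)),
       mean_specificity = round(mean(splits$specificity)),
       max_accuracy = round(max(splits$accuracy), 1),
       max_sensitivity = round(max(splits$sensitivity), 1),
       max_specificity = round(max(splits$specificity), 1))
}
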