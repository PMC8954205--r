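#' Confusion counts for the two-class problem (AD = positive)
#'
#' @param pred_labels,true_labels character vectors of `"control"` / `"ad"`,
#'   equal length.
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop("prediction and truth vectors differ in length")
  ok <- c("control", "ad")
  stopifnot(all(pred_labels %in% ok), all(true_labels %in% ok))
  list(tp = sum(pred_labels == "ad" & true_labels == "ad"),
       fp = sum(pred_labels == "ad" & true_labels == "control"),
       tn = sum(pred_labels == "control" & true_labels == "control"),
       fn = sum(pred_labels == "control" & true_labels == "ad"))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity (true positive rate), specificity (true negative rate),
#' accuracy, F1 score and Matthews correlation coefficient. Any metric whose
#' denominator is zero is defined as 0, which only affects degenerate
#' predictors.
#'
#' @param counts output of [confusion_counts()] (or a list with tp/fp/tn/fn).
#' @return named numeric vector.
#' @examples
#' classification_metrics(list(tp = 6, tn = 3, fp = 1, fn = 2))["mcc"]
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion counts")
  safe <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    accuracy = (tp + tn) / total,
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

#' Stratified train/test split
#'
#' @param manifest data.frame with `id` and `label` columns.
#' @param frac_train fraction assigned to training, stratified by class.
#' @param seed split seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_train_test <- function(manifest, frac_train = 0.7, seed = 1L) {
  stopifnot(frac_train > 0, frac_train < 1)
  for (cl in unique(manifest$label))
    if (sum(manifest$label == cl) < 2)
      stop(sprintf("class '%s' has fewer than 2 subjects", cl))
  with_seed(derive_seed(seed, 301L), {
    train <- unlist(lapply(split(manifest$id, manifest$label), function(ids) {
      # round half up so a .5 class share favours the training side
      n <- max(1L, floor(length(ids) * frac_train + 0.5))
      sample(ids, n)
    }), use.names = FALSE)
    list(train = sort(train),
         test = sort(setdiff(manifest$id, train)))
  })
}

#' Stratified k-fold assignment
#'
#' Folds partition the subjects; within each class the fold sizes differ by
#' at most one.
#'
#' @param manifest data.frame with `id` and `label`.
#' @param k number of folds.
#' @param seed fold seed.
#' @return named integer vector: fold index per subject id.
#' @export
make_folds <- function(manifest, k = 3L, seed = 1L) {
  for (cl in unique(manifest$label))
    if (sum(manifest$label == cl) < k)
      stop(sprintf("class '%s' has fewer than %d subjects", cl, k))
  with_seed(derive_seed(seed, 302L), {
    fold <- integer(nrow(manifest))
    names(fold) <- manifest$id
    for (cl in unique(manifest$label)) {
      ids <- sample(manifest$id[manifest$label == cl])
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
    fold
  })
}

#' k-fold cross-validation of an arbitrary classifier
#'
#' For each fold, `fit` is trained on the remaining folds and evaluated on
#' the held-out subjects; per-fold metric sets are aggregated as mean and
#' across-fold standard deviation.
#'
#' @param manifest data.frame with `id` and `label`.
#' @param k number of folds (default 3).
#' @param fit function(train_ids, fold) returning a fitted object.
#' @param predict_fn function(fitted, test_ids) returning predicted labels
#'   (`"control"` / `"ad"`) in the order of `test_ids`.
#' @param seed controls the stratified fold assignment.
#' @return list with `per_fold` (data.frame of fold metrics), `mean`, `sd`,
#'   `folds` (the assignment) and `extras` (whatever `fit` attached as
#'   attribute `"extras"` per fold).
#' @export
cross_validate <- function(manifest, k = 3L, fit, predict_fn, seed = 1L) {
  fold <- make_folds(manifest, k, seed)
  per <- NULL
  extras <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- manifest$id[fold[manifest$id] != f]
    test_ids <- manifest$id[fold[manifest$id] == f]
    fitted <- fit(train_ids, f)
    pred <- predict_fn(fitted, test_ids)
    truth <- manifest$label[match(test_ids, manifest$id)]
    met <- classification_metrics(confusion_counts(pred, truth))
    per <- rbind(per, data.frame(fold = f, t(met)))
    extras[[f]] <- attr(fitted, "extras")
  }
  mcols <- setdiff(names(per), "fold")
  list(per_fold = per,
       mean = vapply(per[mcols], mean, numeric(1)),
       sd = vapply(per[mcols], sd, numeric(1)),
       folds = fold, extras = extras)
}
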