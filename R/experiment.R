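#' Labelled collection of molecular graphs
#'
#' @param graphs List of `mol_graph` objects.
#' @param labels Class label per graph (factor or character); every graph
#'   must be labelled.
#' @return An object of class `graph_dataset`.
#' @export
graph_dataset <- function(graphs, labels = NULL) {
  if (is.null(labels)) {
    labels <- vapply(
      graphs,
      function(g) if (is.null(g$label)) NA_character_ else as.character(g$label),
      character(1)
    )
  }
  if (anyNA(labels)) {
    rlang::abort("every graph needs a class label", class = "hb_data_error")
  }
  stopifnot(length(graphs) == length(labels))
  structure(
    list(graphs = graphs, labels = factor(labels)),
    class = "graph_dataset"
  )
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat(sprintf(
    "<graph_dataset> %d graphs, %d classes (%s)\n",
    length(x$graphs), nlevels(x$labels),
    paste(sprintf("%s: %d", levels(x$labels), table(x$labels)), collapse = ", ")
  ))
  invisible(x)
}

subset_dataset <- function(d, idx) {
  graph_dataset(d$graphs[idx], droplevels(d$labels[idx]))
}

#' Stratified train/test split
#'
#' Splits each class independently at the given train fraction (4:1 by
#' default), rounding the test count to the nearest integer but keeping at
#' least one test member per class. Disjoint and exhaustive; deterministic
#' per seed.
#'
#' @param d A [graph_dataset()].
#' @param ratio Train fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(d, ratio = 0.8, seed = 1L) {
  labels <- d$labels
  if (any(table(labels) < 2L)) {
    rlang::abort("every class needs at least 2 members to split",
      class = "hb_data_error"
    )
  }
  with_local_seed(seed, {
    test <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_test <- max(1L, round(length(idx) * (1 - ratio)))
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

## Stratified k-fold assignment; returns an integer fold id per observation.
stratified_folds <- function(labels, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

## ---- metrics ---------------------------------------------------------------

confusion_counts <- function(truth, pred) {
  table(truth = truth, pred = factor(pred, levels = levels(truth)))
}

accuracy_from_confusion <- function(conf) {
  sum(diag(conf)) / sum(conf)
}

macro_f1 <- function(conf) {
  f1 <- vapply(seq_len(nrow(conf)), function(c) {
    tp <- conf[c, c]
    fp <- sum(conf[, c]) - tp
    fn <- sum(conf[c, ]) - tp
    if (tp == 0) {
      return(0)
    }
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

## One-vs-rest macro AUC-ROC; for two classes this reduces to the standard
## binary AUC. Classes absent from the truth vector are skipped.
macro_auc <- function(truth, probs) {
  aucs <- c()
  for (cl in colnames(probs)) {
    is_cl <- truth == cl
    if (!any(is_cl) || all(is_cl)) next
    r <- pROC::roc(
      response = factor(is_cl, levels = c(FALSE, TRUE)),
      predictor = probs[, cl], quiet = TRUE, direction = "<"
    )
    aucs <- c(aucs, as.numeric(pROC::auc(r)))
  }
  mean(aucs)
}

## ---- hyperparameter tuning -------------------------------------------------

#' Grid-search hyperparameters by stratified cross-validation
#'
#' Evaluates every grid point with stratified k-fold (default 5-fold)
#' cross-validation on the training data only. Selection follows the
#' highest-single-fold-accuracy rule by default (`select = "best_fold"`);
#' `select = "mean"` picks the best mean-across-folds instead. Ties break to
#' the higher mean accuracy, then to grid order. Classes smaller than `k`
#' reduce the fold count with a warning.
#'
#' @param d Training [graph_dataset()] (the test partition must not be in
#'   here).
#' @param grid Named list of vectors over `lr`, `batch_size`, `n_layers`
#'   (missing entries use the [hb_hyperparams()] default).
#' @param seed Integer seed.
#' @param k Fold count (default 5).
#' @param epochs Training epochs per fold.
#' @param select `"best_fold"` or `"mean"`.
#' @param concat Layer-concatenation mode passed to [train_gcn()].
#' @return The selected [hb_hyperparams()], with the full results tibble in
#'   attribute `"cv_results"`.
#' @export
tune_hyperparams <- function(d, grid = list(), seed = 1L, k = 5L,
                             epochs = 50L, select = c("best_fold", "mean"),
                             concat = TRUE) {
  select <- match.arg(select)
  defaults <- hb_hyperparams()
  grid$lr <- grid$lr %||% defaults$lr
  grid$batch_size <- grid$batch_size %||% defaults$batch_size
  grid$n_layers <- grid$n_layers %||% defaults$n_layers
  combos <- expand.grid(
    lr = grid$lr, batch_size = grid$batch_size, n_layers = grid$n_layers,
    KEEP.OUT.ATTRS = FALSE
  )

  min_class <- min(table(d$labels))
  if (min_class < k) {
    rlang::warn(sprintf(
      "smallest class has %d members; reducing folds from %d to %d",
      min_class, k, min_class
    ))
    k <- min_class
  }
  fold <- stratified_folds(d$labels, k, derive_seed(seed, 11L))

  rows <- vector("list", nrow(combos) * k)
  for (ci in seq_len(nrow(combos))) {
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      va <- which(fold == f)
      h <- hb_hyperparams(
        lr = combos$lr[ci], batch_size = combos$batch_size[ci],
        n_layers = combos$n_layers[ci], epochs = epochs,
        seed = derive_seed(seed, 100L + f)
      )
      m <- train_gcn(d$graphs[tr], d$labels[tr], h, concat = concat)
      pred <- predict(m, d$graphs[va])
      acc <- mean(as.character(pred$.pred_class) == as.character(d$labels[va]))
      rows[[(ci - 1L) * k + f]] <- tibble::tibble(
        combo = ci, lr = combos$lr[ci], batch_size = combos$batch_size[ci],
        n_layers = combos$n_layers[ci], fold = f, accuracy = acc
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  by_combo <- res |>
    dplyr::group_by(.data$combo) |>
    dplyr::summarise(
      best_fold = max(.data$accuracy), mean_acc = mean(.data$accuracy),
      .groups = "drop"
    )
  key <- if (select == "best_fold") by_combo$best_fold else by_combo$mean_acc
  ord <- order(-key, -by_combo$mean_acc, by_combo$combo)
  best <- by_combo$combo[ord[1]]
  out <- hb_hyperparams(
    lr = combos$lr[best], batch_size = combos$batch_size[best],
    n_layers = combos$n_layers[best], epochs = epochs, seed = seed
  )
  attr(out, "cv_results") <- res
  out
}

## ---- repeated-split evaluation ---------------------------------------------

#' Evaluate classification over repeated stratified splits
#'
#' For each of `n_splits` seeded 4:1 stratified splits: optionally tune on
#' the training partition, train the GCN + logistic-regression head, score
#' the held-out test partition, and record accuracy (correct / total), macro
#' F1 and one-vs-rest macro AUC-ROC. Test indices never reach tuning or
#' training; the split indices are stored on the result so leakage is
#' checkable.
#'
#' @param d A [graph_dataset()].
#' @param hyper Base [hb_hyperparams()].
#' @param n_splits Number of repeated splits (default 10).
#' @param ratio Train fraction per split.
#' @param tune Run [tune_hyperparams()] on each training partition.
#' @param grid Grid for tuning (see [tune_hyperparams()]).
#' @param concat Layer-concatenation mode.
#' @param seed Master seed; per-split seeds are derived from it.
#' @return An object of class `hb_eval`: per-split metric tibble, summary
#'   (mean and sd per metric), stored confusion matrices and split indices.
#' @export
evaluate <- function(d, hyper = hb_hyperparams(), n_splits = 10L, ratio = 0.8,
                     tune = FALSE, grid = list(), concat = TRUE, seed = 1L) {
  stopifnot(n_splits >= 1L)
  rows <- vector("list", n_splits)
  confusions <- vector("list", n_splits)
  splits <- vector("list", n_splits)
  for (sp in seq_len(n_splits)) {
    spl <- stratified_split(d, ratio = ratio, seed = derive_seed(seed, sp))
    splits[[sp]] <- spl
    train_d <- subset_dataset(d, spl$train)
    h <- if (tune) {
      tune_hyperparams(train_d,
        grid = grid, seed = derive_seed(seed, 1000L + sp),
        epochs = hyper$epochs, concat = concat
      )
    } else {
      hyper
    }
    h$seed <- derive_seed(seed, 2000L + sp)
    model <- train_gcn(train_d$graphs, train_d$labels, h, concat = concat)
    pred <- predict(model, d$graphs[spl$test])
    truth <- factor(as.character(d$labels[spl$test]), levels = model$classes)
    conf <- confusion_counts(truth, as.character(pred$.pred_class))
    probs <- as.matrix(pred[, paste0(".prob_", model$classes)])
    colnames(probs) <- model$classes
    confusions[[sp]] <- conf
    rows[[sp]] <- tibble::tibble(
      split = sp,
      accuracy = accuracy_from_confusion(conf),
      f1 = macro_f1(conf),
      auc = macro_auc(truth, probs),
      n_train = length(spl$train), n_test = length(spl$test)
    )
  }
  per_split <- dplyr::bind_rows(rows)
  summary <- per_split |>
    tidyr::pivot_longer(c("accuracy", "f1", "auc"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop"
    )
  structure(
    list(
      per_split = per_split, summary = summary, confusions = confusions,
      splits = splits, hyper = hyper, concat = concat, n_splits = n_splits,
      seed = seed
    ),
    class = "hb_eval"
  )
}

#' @export
print.hb_eval <- function(x, ...) {
  cat(sprintf(
    "<hb_eval> %d splits, %s\n", x$n_splits,
    if (x$concat) "layer concatenation" else "last layer only"
  ))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
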