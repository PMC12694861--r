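# Cross-validated evaluation: stratified k-fold splits, classification
# metrics, and confidence-interval reporting in the mean +/- margin format.

#' Deterministic k-fold split
#'
#' Partitions `1..n` into `k` disjoint folds whose sizes differ by at most
#' one. When `labels` are supplied the split is stratified: each fold gets
#' a near-proportional share of every class.
#'
#' @param n Number of samples, `n >= k`.
#' @param k Number of folds, `>= 2`.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param labels Optional label vector of length `n` for stratification.
#' @return A list of `k` integer index vectors.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L, labels = NULL) {
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  local_seed(seed, {
    folds <- vector("list", k)
    if (is.null(labels)) {
      ord <- sample.int(n)
      assign_fold <- rep_len(seq_len(k), n)
      for (f in seq_len(k)) folds[[f]] <- sort(ord[assign_fold == f])
    } else {
      stopifnot(length(labels) == n)
      for (cls in unique(labels)) {
        idx <- sample(which(labels == cls))
        assign_fold <- rep_len(seq_len(k), length(idx))
        for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_fold == f])
      }
      folds <- lapply(folds, sort)
    }
    folds
  })
}

#' Classification metrics
#'
#' Per-class precision (`TP/(TP+FP)`), recall (`TP/(TP+FN)`) and F1, plus
#' support-weighted and macro aggregates and overall accuracy. A class with
#' an empty denominator scores 0 (and still counts in the aggregates), with
#' a warning.
#'
#' @param y_true,y_pred Integer label vectors of equal length, values in
#'   `0..n_classes-1`.
#' @param n_classes Number of classes.
#' @return A list with `accuracy`, `per_class` (data frame), `weighted`
#'   and `macro` (named vectors: precision, recall, f1).
#' @export
classification_metrics <- function(y_true, y_pred, n_classes) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes)) {
    stop("labels out of range")
  }
  lev <- 0:(n_classes - 1L)
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b, what) {
    out <- ifelse(b > 0, a / pmax(b, 1), 0)
    if (any(b == 0)) warning("zero denominator in ", what, "; scoring 0 for that class")
    out
  }
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm)
  w <- support / sum(support)
  per_class <- data.frame(class = lev, precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          support = as.integer(support))
  list(accuracy = sum(tp) / length(y_true),
       per_class = per_class,
       weighted = c(precision = sum(w * prec), recall = sum(w * rec),
                    f1 = sum(w * f1)),
       macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)))
}

#' Cross-validation confidence summary
#'
#' Mean fold accuracy with a dispersion margin, reported as
#' `mean +/- margin` with interval `(mean - margin, mean + margin)` - the
#' printed convention of the accompanying report tables. The margin
#' estimator is configurable: sample standard deviation (default),
#' standard error, or a t-based 95% half-width.
#'
#' @param fold_accuracies Numeric vector of `>= 2` fold accuracies.
#' @param estimator `"std"`, `"se"`, or `"t95"`.
#' @return A list: `mean`, `margin`, `ci_low`, `ci_high`, `estimator`.
#' @export
cv_confidence <- function(fold_accuracies, estimator = c("std", "se", "t95")) {
  estimator <- match.arg(estimator)
  k <- length(fold_accuracies)
  if (k < 2L) stop("need at least 2 folds")
  m <- mean(fold_accuracies)
  s <- stats::sd(fold_accuracies)
  margin <- switch(estimator,
    std = s,
    se = s / sqrt(k),
    t95 = stats::qt(0.975, df = k - 1L) * s / sqrt(k))
  list(mean = m, margin = margin, ci_low = m - margin, ci_high = m + margin,
       estimator = estimator)
}

#' Run a k-fold cross-validated experiment
#'
#' Trains one hybrid model per fold (identical architecture and derived
#' seeds), evaluates it on the held-out fold, and aggregates fold
#' accuracies, pooled out-of-fold metrics, and the confidence summary into
#' a `cv_report`.
#'
#' @param images `n x H x W` image array (or list of matrices).
#' @param labels Integer labels, 0-based.
#' @param entangler `"CNOT"` or `"CZ"`.
#' @param n_layers Variational layers, 1..5.
#' @param config A [classifier_config()].
#' @param k Number of folds.
#' @param seed Split seed (also fans out to per-fold training seeds).
#' @param folds Optional pre-computed fold list, e.g. to force identical
#'   splits across compared models.
#' @param stratified Stratify folds by label (default `TRUE`).
#' @param ci_estimator Margin estimator for [cv_confidence()].
#' @return A `cv_report` object.
#' @export
run_cv_experiment <- function(images, labels, entangler = c("CZ", "CNOT"),
                              n_layers = 1L, config = classifier_config(),
                              k = 5L, seed = 1L, folds = NULL,
                              stratified = TRUE,
                              ci_estimator = c("std", "se", "t95")) {
  entangler <- match.arg(entangler)
  ci_estimator <- match.arg(ci_estimator)
  images <- as_image_array(images)
  labels <- as.integer(labels)
  n <- dim(images)[1L]
  if (is.null(folds)) {
    folds <- kfold_split(n, k, seed = derive_seed(seed, 23L),
                         labels = if (stratified) labels else NULL)
  }
  k <- length(folds)
  fold_acc <- numeric(k)
  train_acc <- numeric(k)
  oof_pred <- integer(n)
  for (f in seq_len(k)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    cfg <- config
    cfg$seed <- derive_seed(seed, 100L + f)
    mod <- hybrid_model(dim(images)[2L], entangler, n_layers, cfg)
    fit <- train_hybrid(mod, images[tr, , , drop = FALSE], labels[tr])
    pred <- predict_labels(fit$model, images[te, , , drop = FALSE])
    oof_pred[te] <- pred
    fold_acc[f] <- mean(pred == labels[te])
    train_acc[f] <- utils::tail(fit$history$accuracy, 1L)
  }
  conf <- cv_confidence(fold_acc, ci_estimator)
  metrics <- classification_metrics(labels, oof_pred, config$n_classes)
  structure(list(
    model = sprintf("%s (%s, L=%d)",
                    if (entangler == "CNOT") "NNQEv1" else "NNQEv2",
                    entangler, n_layers),
    entangler = entangler, n_layers = as.integer(n_layers),
    optimizer = config$optimizer, k = k, seed = seed,
    fold_accuracies = fold_acc,
    mean = conf$mean, margin = conf$margin,
    ci_low = conf$ci_low, ci_high = conf$ci_high,
    ci_estimator = conf$estimator,
    train_accuracy = mean(train_acc),
    test_accuracy = metrics$accuracy,
    per_class = metrics$per_class,
    weighted = metrics$weighted, macro = metrics$macro,
    folds = folds
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$model, " [", x$optimizer, "]\n", sep = "")
  cat(sprintf("  folds: %s\n", paste(sprintf("%.4f", x$fold_accuracies), collapse = " ")))
  cat(sprintf("  mean CV acc: %.4f +/- %.4f  CI (%.4f, %.4f)  [%s]\n",
              x$mean, x$margin, x$ci_low, x$ci_high, x$ci_estimator))
  cat(sprintf("  train acc %.4f | pooled test acc %.4f | weighted P/R/F1 %.4f/%.4f/%.4f\n",
              x$train_accuracy, x$test_accuracy,
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Serialise / restore a CV report
#'
#' JSON round trip for `cv_report` objects; `cv_report_from_json()` is the
#' exact inverse of `cv_report_json()` up to numeric printing precision
#' (digits are not truncated).
#'
#' @param report A `cv_report`.
#' @param path Optional file to write.
#' @return JSON string, or a `cv_report` for the reader.
#' @export
cv_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname cv_report_json
#' @param json JSON string or file path produced by `cv_report_json()`.
#' @export
cv_report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$per_class <- as.data.frame(x$per_class)
  x$weighted <- unlist(x$weighted)
  x$macro <- unlist(x$macro)
  x$folds <- lapply(x$folds, as.integer)
  class(x) <- "cv_report"
  x
}

#' One-row table summary of a CV report
#'
#' The report-table shape: model, train/test accuracy, weighted precision,
#' recall, F1, mean CV accuracy with margin, and the CI bounds.
#'
#' @param report A `cv_report`.
#' @return A one-row data frame.
#' @export
report_row <- function(report) {
  data.frame(model = report$model, optimizer = report$optimizer,
             train_acc = report$train_accuracy, test_acc = report$test_accuracy,
             precision = unname(report$weighted["precision"]),
             recall = unname(report$weighted["recall"]),
             f1 = unname(report$weighted["f1"]),
             mean_cv_acc = report$mean, margin = report$margin,
             ci_low = report$ci_low, ci_high = report$ci_high)
}

#' Paired CNOT-vs-CZ comparison
#'
#' Runs [run_cv_experiment()] for both entanglers with identical fold
#' splits and identical per-fold initialisation seeds, so any difference in
#' accuracy or dispersion is attributable to the entangler alone.
#'
#' @inheritParams run_cv_experiment
#' @return A list with `cnot`, `cz` (both `cv_report`s) and `table` (two
#'   report rows).
#' @export
compare_entanglers <- function(images, labels, n_layers = 1L,
                               config = classifier_config(), k = 5L, seed = 1L,
                               ci_estimator = "std") {
  images <- as_image_array(images)
  folds <- kfold_split(dim(images)[1L], k, seed = derive_seed(seed, 23L),
                       labels = as.integer(labels))
  rep_cnot <- run_cv_experiment(images, labels, "CNOT", n_layers, config,
                                seed = seed, folds = folds,
                                ci_estimator = ci_estimator)
  rep_cz <- run_cv_experiment(images, labels, "CZ", n_layers, config,
                              seed = seed, folds = folds,
                              ci_estimator = ci_estimator)
  list(cnot = rep_cnot, cz = rep_cz,
       table = rbind(report_row(rep_cnot), report_row(rep_cz)))
}

#' Final-accuracy stability across seeds
#'
#' Trains each entangler on a fixed train/validation split under several
#' seeds and reports the per-entangler mean and standard deviation of the
#' final validation accuracy - the stability comparison as a measurable,
#' with no assertion about which entangler wins.
#'
#' @param images,labels Dataset.
#' @param n_layers Variational layers.
#' @param config A [classifier_config()].
#' @param seeds Integer vector of training seeds.
#' @param val_frac Validation fraction of the data.
#' @return A data frame with one row per entangler: mean and sd of final
#'   validation accuracy, plus the per-seed values as an attribute.
#' @export
entangler_stability <- function(images, labels, n_layers = 1L,
                                config = classifier_config(),
                                seeds = 1:10, val_frac = 0.3) {
  images <- as_image_array(images)
  labels <- as.integer(labels)
  n <- dim(images)[1L]
  idx <- local_seed(derive_seed(seeds[[1L]], 31L), sample.int(n))
  nval <- max(1L, floor(val_frac * n))
  va <- idx[seq_len(nval)]; tr <- idx[(nval + 1L):n]
  acc <- sapply(c("CNOT", "CZ"), function(ent) {
    vapply(seeds, function(s) {
      cfg <- config; cfg$seed <- as.integer(s)
      mod <- hybrid_model(dim(images)[2L], ent, n_layers, cfg)
      fit <- train_hybrid(mod, images[tr, , , drop = FALSE], labels[tr],
                          val_images = images[va, , , drop = FALSE],
                          val_labels = labels[va])
      utils::tail(fit$history$val_accuracy, 1L)
    }, numeric(1L))
  })
  out <- data.frame(entangler = colnames(acc),
                    mean_val_accuracy = colMeans(acc),
                    sd_val_accuracy = apply(acc, 2L, stats::sd))
  attr(out, "per_seed") <- acc
  out
}
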