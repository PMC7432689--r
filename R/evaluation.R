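## Confusion counts, ACC/Sn/Sp/MCC, stratified k-fold cross-validation,
## and McNemar's paired-classifier test. lncRNA is the positive class
## (label 1), so Sn tracks lncRNA recovery and Sp protein-coding recovery.

as_pred_labels <- function(preds) {
  if (is.data.frame(preds)) preds$label else as.integer(preds)
}

#' Confusion counts for binary predictions
#'
#' @param preds predicted labels: an integer vector in \{0,1\} or a
#'   prediction data.frame with a `label` column.
#' @param labels true labels, parallel to `preds` (1 = lncRNA).
#' @return object of class `confusion`: list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(preds, labels) {
  p <- as_pred_labels(preds)
  y <- as.integer(labels)
  if (length(p) != length(y)) stop("predictions and labels differ in length")
  if (length(y) && !all(y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  structure(list(TP = sum(p == 1L & y == 1L),
                 TN = sum(p == 0L & y == 0L),
                 FP = sum(p == 1L & y == 0L),
                 FN = sum(p == 0L & y == 1L)),
            class = "confusion")
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/total`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' common convention `MCC = 0` when any denominator factor is zero.
#'
#' @param c a `confusion` object (or list with TP/TN/FP/FN).
#' @return object of class `metric_set`: list with `ACC`, `Sn`, `Sp`,
#'   `MCC`. `Sn`/`Sp` are `NA` when their class is absent.
#' @export
metrics <- function(c) {
  tp <- c$TP; tn <- c$TN; fp <- c$FP; fn <- c$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts")
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  structure(list(
    ACC = (tp + tn) / total,
    Sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    MCC = if (denom > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) /
      sqrt(denom) else 0
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("ACC %.4f  Sn %.4f  Sp %.4f  MCC %.4f\n",
              x$ACC, x$Sn, x$Sp, x$MCC))
  invisible(x)
}

#' McNemar's test for two paired classifiers
#'
#' Builds the discordance counts `b` (A correct, B wrong) and `c` (A
#' wrong, B correct) over the same examples. When `b + c < 25` the exact
#' two-sided binomial p-value `min(1, 2 * P(X <= min(b,c)))` with
#' `X ~ Bin(b+c, 1/2)` is used; otherwise the chi-square form with
#' continuity correction `(|b-c|-1)^2 / (b+c)` on 1 degree of freedom.
#'
#' @param preds_a,preds_b predicted labels of the two classifiers
#'   (vectors or prediction data.frames).
#' @param labels true labels.
#' @return list with `b`, `c`, `statistic` (`NA` for the exact branch),
#'   `p`, `method`, and `degenerate` (`TRUE` when `b + c == 0`, in which
#'   case `p = 1`).
#' @export
mcnemar <- function(preds_a, preds_b, labels) {
  a <- as_pred_labels(preds_a)
  b_ <- as_pred_labels(preds_b)
  y <- as.integer(labels)
  if (length(a) != length(y) || length(b_) != length(y)) {
    stop("prediction and label vectors must be parallel")
  }
  ca <- a == y
  cb <- b_ == y
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  n <- b + cc
  if (n == 0) {
    return(list(b = b, c = cc, statistic = NA_real_, p = 1.0,
                method = "degenerate", degenerate = TRUE))
  }
  if (n < 25) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    list(b = b, c = cc, statistic = NA_real_, p = p,
         method = "exact-binomial", degenerate = FALSE)
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    list(b = b, c = cc, statistic = stat,
         p = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chi-square", degenerate = FALSE)
  }
}

## ---- Cross-validation -----------------------------------------------------

#' Stratified fold assignment
#'
#' @param labels binary labels.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..folds) parallel to `labels`.
#' @export
stratified_folds <- function(labels, folds, seed) {
  y <- as.integer(labels)
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of the multimodal classifier
#'
#' For each fold, the model is trained on the remaining folds with the
#' full two-step schedule and evaluated on the held-out fold. The hexamer
#' table (and the OFH standardization) is re-estimated from each fold's
#' training partition only, so no information leaks from the test fold
#' into the features.
#'
#' @param data an `lnc_dataset`.
#' @param config an `lnc_model_config`.
#' @param folds number of folds (default 10); each class must have at
#'   least `folds` members.
#' @param seed fold-assignment seed.
#' @param modalities modality subset to train (default: all three).
#' @param lookup a `fickett_lookup`.
#' @param verbose print progress.
#' @return object of class `cv_report`: per-fold metrics data.frame,
#'   `mean` and `sd` per metric, the fold assignment, and one hexamer
#'   table fingerprint per fold (leakage guard).
#' @export
cross_validate <- function(data, config, folds = 10, seed = 1,
                           modalities = MODALITIES,
                           lookup = fickett_lookup(), verbose = FALSE) {
  stopifnot(inherits(data, "lnc_dataset"), folds >= 2)
  y <- data$labels
  if (min(table(y)) < folds) {
    stop("each class must have at least `folds` transcripts")
  }
  assign <- stratified_folds(y, folds, seed)
  rows <- vector("list", folds)
  fingerprints <- numeric(folds)
  for (f in seq_len(folds)) {
    if (verbose) message("fold ", f, "/", folds)
    test_i <- which(assign == f)
    train_i <- which(assign != f)
    model <- train_lnc_model(data[train_i], config,
                             modalities = modalities, lookup = lookup)
    preds <- predict(model, data$seqs[test_i])
    ms <- metrics(confusion(preds, y[test_i]))
    rows[[f]] <- data.frame(fold = f, ACC = ms$ACC, Sn = ms$Sn,
                            Sp = ms$Sp, MCC = ms$MCC)
    fingerprints[f] <- sum(model$table$f_c * seq_along(model$table$f_c))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, -1]),
                 sd = apply(per_fold[, -1], 2, sd),
                 folds = folds, seed = seed, assignment = assign,
                 table_fingerprints = fingerprints),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV\n", x$folds))
  for (m in names(x$mean)) {
    cat(sprintf("  %-4s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus a `mean +/- sd` summary row.
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  df <- report$per_fold
  summary_row <- data.frame(
    fold = "mean±sd",
    ACC = sprintf("%.4f ± %.4f", report$mean[["ACC"]], report$sd[["ACC"]]),
    Sn = sprintf("%.4f ± %.4f", report$mean[["Sn"]], report$sd[["Sn"]]),
    Sp = sprintf("%.4f ± %.4f", report$mean[["Sp"]], report$sd[["Sp"]]),
    MCC = sprintf("%.4f ± %.4f", report$mean[["MCC"]], report$sd[["MCC"]]))
  out <- rbind(data.frame(lapply(df, as.character),
                          stringsAsFactors = FALSE), summary_row)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
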