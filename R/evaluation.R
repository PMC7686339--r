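#' Confusion-matrix performance metrics
#'
#' The four standard site-prediction metrics:
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP),}
#' \deqn{Acc = (TP+TN)/(TP+FP+TN+FN),}
#' \deqn{MCC = \frac{TP \cdot TN - FN \cdot FP}
#'   {\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}.}
#' MCC is defined as 0 (with attribute \code{"degenerate"}) when any factor
#' of the denominator is 0.
#'
#' @param TP,FN,TN,FP Non-negative integer counts, total > 0.
#' @return Named list \code{Sn}, \code{Sp}, \code{Acc}, \code{MCC}.
#' @export
#' @examples
#' confusion_metrics(40, 10, 30, 20)  # Sn 0.8, Sp 0.6, Acc 0.7, MCC ~0.408
confusion_metrics <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  Sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  Sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  Acc <- (TP + TN) / sum(counts)
  denom2 <- as.numeric(TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  degenerate <- denom2 == 0
  MCC <- if (degenerate) 0 else
    (as.numeric(TP) * TN - as.numeric(FN) * FP) / sqrt(denom2)
  out <- list(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC)
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (ties grouped), and
#' integrates the ROC by the trapezoid rule — numerically equal to the
#' concordance probability with tied score pairs counted 1/2.
#'
#' @param scores Numeric decision values or positive-class probabilities.
#' @param labels Class labels; both classes must be present.
#' @return List with \code{auc} and \code{roc} (data.frame \code{FPR},
#'   \code{TPR}, from (0,0) to (1,1)).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$auc  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as_kcr_label(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == "positive")
  N <- sum(labels == "negative")
  if (P == 0L || N == 0L) stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == "positive"
  # group tied scores so ROC vertices sit between tie blocks
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- which(!duplicated(grp, fromLast = TRUE))
  roc <- data.frame(FPR = c(0, fp[last] / N), TPR = c(0, tp[last] / P))
  auc <- sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) +
                              utils::tail(roc$TPR, -1)) / 2)
  list(auc = auc, roc = roc)
}

# build a kcr_eval report from out-of-sample scores
evaluate_scores <- function(scores, labels, threshold, folds = NULL,
                            kind = "single") {
  labels <- as_kcr_label(labels)
  pred_pos <- scores > threshold
  is_pos <- labels == "positive"
  TP <- sum(pred_pos & is_pos); FN <- sum(!pred_pos & is_pos)
  TN <- sum(!pred_pos & !is_pos); FP <- sum(pred_pos & !is_pos)
  m <- confusion_metrics(TP, FN, TN, FP)
  ra <- roc_auc(scores, labels)
  structure(
    list(TP = TP, FN = FN, TN = TN, FP = FP,
         Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC,
         AUC = ra$auc, roc = ra$roc, threshold = threshold,
         folds = folds, kind = kind),
    class = "kcr_eval"
  )
}

#' @export
print.kcr_eval <- function(x, ...) {
  cat(sprintf("<kcr_eval> (%s)  TP=%d FN=%d TN=%d FP=%d\n",
              x$kind, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  Sn=%.3f Sp=%.3f Acc=%.3f MCC=%.3f AUC=%.3f\n",
              x$Sn, x$Sp, x$Acc, x$MCC, x$AUC))
  if (!is.null(x$folds)) {
    cat(sprintf("  per-fold mean AUC=%.3f over %d folds\n",
                mean(x$folds$AUC), nrow(x$folds)))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified k-fold CV of a model spec: each fold's model is
#' trained (including any grid search) on the remaining folds and scored on
#' the held-out fold. Confusion counts are pooled over folds; AUC is
#' computed both from the pooled out-of-fold scores (reported as
#' \code{AUC}) and as the mean of per-fold AUCs (in the \code{folds}
#' table).
#'
#' @param spec A \code{kcr_model_spec}.
#' @param x Feature matrix or \code{kcr_features} object.
#' @param labels Class labels (taken from \code{x} if \code{kcr_features}).
#' @param k Number of folds, default 10; every class must have at least k
#'   samples.
#' @param seed Integer seed for the fold assignment.
#' @return A \code{kcr_eval} with per-fold breakdown in \code{$folds} and
#'   pooled out-of-fold scores in \code{$scores}.
#' @export
cross_validate <- function(spec, x, labels = NULL, k = 10L, seed = 1) {
  inp <- fs_inputs(x, labels)
  x <- inp$x
  y <- inp$labels
  if (min(table(y)) < k) {
    stop("each class needs at least k = ", k, " samples", call. = FALSE)
  }
  fold <- stratified_folds(y, k, kcr_stage_seed(seed, "cvfolds"))
  scores <- numeric(length(y))
  fold_rows <- vector("list", k)
  thr <- if (spec$kind == "svm_rbf") 0 else 0.5
  for (f in seq_len(k)) {
    tr <- fold != f
    fspec <- spec
    fspec$seed <- kcr_stage_seed(seed, paste0("cv", f))
    model <- kcr_train(fspec, x[tr, , drop = FALSE], y[tr])
    s <- predict(model, x[!tr, , drop = FALSE])
    scores[!tr] <- s
    ev <- evaluate_scores(s, y[!tr], thr, kind = "fold")
    fold_rows[[f]] <- data.frame(fold = f, TP = ev$TP, FN = ev$FN,
                                 TN = ev$TN, FP = ev$FP, Sn = ev$Sn,
                                 Sp = ev$Sp, Acc = ev$Acc, MCC = ev$MCC,
                                 AUC = ev$AUC)
  }
  out <- evaluate_scores(scores, y, thr, folds = do.call(rbind, fold_rows),
                         kind = "cv")
  out$scores <- scores
  out$fold <- fold
  out$AUC_mean_folds <- mean(out$folds$AUC)
  out
}

#' Independent-test evaluation of a trained model
#'
#' Single-pass evaluation of held-out windows at the model's decision
#' threshold (0 for SVM decision values, 0.5 for RF probabilities). Test
#' columns must match the training columns exactly.
#'
#' @param model A \code{kcr_model}.
#' @param x Test feature matrix or \code{kcr_features}.
#' @param labels Test labels.
#' @return A \code{kcr_eval}.
#' @export
independent_test <- function(model, x, labels = NULL) {
  if (inherits(x, "kcr_features")) {
    labels <- x$labels
    x <- x$x
  }
  if (nrow(x) == 0L) stop("empty test set", call. = FALSE)
  s <- predict(model, x)
  out <- evaluate_scores(s, labels, model$threshold, kind = "independent")
  out$scores <- s
  out
}

#' Cross-species transfer evaluation
#'
#' Trains on dataset A (after undersampling its negatives to balance, as in
#' within-species training) and evaluates on the whole of dataset B. Both
#' feature matrices must share column names and order, i.e. the same
#' encoder configuration. Degraded AUC relative to within-species CV
#' indicates divergent site motifs between the species.
#'
#' @param spec A \code{kcr_model_spec}.
#' @param train,test \code{kcr_features} objects (or matrices with
#'   \code{train_labels} / \code{test_labels} supplied).
#' @param train_labels,test_labels Labels when matrices are passed.
#' @param balance Undersample the training negatives first (default TRUE).
#' @param seed Integer seed (undersampling draw).
#' @return A \code{kcr_eval} with \code{kind = "cross_species"}.
#' @export
cross_species_eval <- function(spec, train, test, train_labels = NULL,
                               test_labels = NULL, balance = TRUE,
                               seed = 1) {
  tr <- fs_inputs(train, train_labels)
  te <- fs_inputs(test, test_labels)
  if (!identical(colnames(tr$x), colnames(te$x))) {
    stop("train and test sets must share encoder configuration (columns)",
         call. = FALSE)
  }
  x <- tr$x; y <- tr$labels
  if (balance) {
    pos <- which(y == "positive"); neg <- which(y == "negative")
    if (length(neg) > length(pos)) {
      keep <- sort(c(pos, with_seed(kcr_stage_seed(seed, "xsp-under"),
                                    sample(neg, length(pos)))))
      x <- x[keep, , drop = FALSE]; y <- y[keep]
    }
  }
  sspec <- spec
  sspec$seed <- kcr_stage_seed(seed, "xsp-train")
  model <- kcr_train(sspec, x, y)
  out <- independent_test(model, te$x, te$labels)
  out$kind <- "cross_species"
  out
}

#' Write an evaluation report / ROC curve to disk
#'
#' The report goes out as JSON (counts, metrics, per-fold table, threshold)
#' and the ROC points as CSV \code{FPR,TPR}.
#'
#' @param report A \code{kcr_eval}.
#' @param path JSON output path.
#' @param roc_path Optional CSV path for the ROC points.
#' @return Invisibly, \code{path}.
#' @export
kcr_write_eval <- function(report, path, roc_path = NULL) {
  stopifnot(inherits(report, "kcr_eval"))
  obj <- report[c("kind", "TP", "FN", "TN", "FP", "Sn", "Sp", "Acc", "MCC",
                  "AUC", "threshold")]
  if (!is.null(report$AUC_mean_folds)) {
    obj$AUC_mean_folds <- report$AUC_mean_folds
  }
  if (!is.null(report$folds)) obj$folds <- report$folds
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(roc_path)) {
    utils::write.csv(report$roc, roc_path, row.names = FALSE)
  }
  invisible(path)
}
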