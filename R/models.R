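#' Model specification with the standard hyperparameter grids
#'
#' Defines the classifier kind and its search grid: for the RBF-kernel SVM,
#' penalty \eqn{C \in \{2^0, ..., 2^{10}\}} and kernel width
#' \eqn{\gamma \in \{2^{-10}, ..., 2^0\}} (121 combinations); for the
#' random forest, tree counts \{1400, 1600, ..., 2400\}. Grid search uses
#' internal stratified 5-fold CV accuracy; ties are broken towards smaller
#' C, then larger gamma (SVM) or fewer trees (RF). Pass scalar values to
#' fix hyperparameters and skip the search.
#'
#' @param kind \code{"random_forest"} (default) or \code{"svm_rbf"}.
#' @param cost,gamma SVM grids (defaults as above).
#' @param trees RF tree-count grid (default \code{seq(1400, 2400, 200)}).
#' @param tune Run the grid search (default TRUE when the grid has more
#'   than one point).
#' @param inner_k Folds of the internal selection CV, default 5.
#' @param seed Integer seed for fold assignment and tree growing.
#' @return A \code{kcr_model_spec}.
#' @export
#' @examples
#' nrow(kcr_grid(kcr_model_spec("svm_rbf")))  # 121
kcr_model_spec <- function(kind = c("random_forest", "svm_rbf"),
                           cost = 2^(0:10), gamma = 2^(-10:0),
                           trees = seq(1400L, 2400L, by = 200L),
                           tune = NULL, inner_k = 5L, seed = 1) {
  kind <- match.arg(kind)
  spec <- structure(
    list(kind = kind, cost = cost, gamma = gamma, trees = as.integer(trees),
         inner_k = as.integer(inner_k), seed = seed),
    class = "kcr_model_spec"
  )
  grid <- kcr_grid(spec)
  spec$tune <- if (is.null(tune)) nrow(grid) > 1L else isTRUE(tune)
  spec
}

#' Enumerate a model spec's hyperparameter grid
#'
#' Rows are ordered by the tie-break preference (first row wins ties):
#' SVM by ascending C then descending gamma; RF by ascending tree count.
#'
#' @param spec A \code{kcr_model_spec}.
#' @return data.frame with columns \code{cost}, \code{gamma} (SVM) or
#'   \code{trees} (RF).
#' @export
kcr_grid <- function(spec) {
  stopifnot(inherits(spec, "kcr_model_spec"))
  if (spec$kind == "svm_rbf") {
    g <- expand.grid(gamma = sort(spec$gamma, decreasing = TRUE),
                     cost = sort(spec$cost))[, c("cost", "gamma")]
    rownames(g) <- NULL
    g
  } else {
    data.frame(trees = sort(spec$trees))
  }
}

# fit one classifier at fixed hyperparameters
fit_one <- function(kind, x, y, pars, seed) {
  if (kind == "svm_rbf") {
    e1071::svm(x = x, y = y, kernel = "radial",
               cost = pars$cost, gamma = pars$gamma, scale = FALSE)
  } else {
    ranger::ranger(x = x, y = y, num.trees = pars$trees,
                   probability = TRUE, seed = seed, num.threads = 1)
  }
}

# positive-class score: SVM decision value (oriented so that larger means
# more positive) or RF positive-class probability
score_one <- function(fit, kind, x) {
  if (kind == "svm_rbf") {
    pr <- stats::predict(fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    if (startsWith(colnames(dv)[1], "positive")) dv[, 1] else -dv[, 1]
  } else {
    stats::predict(fit, data = x, num.threads = 1)$predictions[, "positive"]
  }
}

#' Train a Kcr classifier
#'
#' Selects hyperparameters from the spec's grid by stratified internal
#' cross-validation accuracy (deterministic tie-breaks, see
#' [kcr_model_spec()]), then refits on all training data.
#'
#' @param spec A \code{kcr_model_spec}.
#' @param x Numeric feature matrix (windows x dimensions) or a
#'   \code{kcr_features} object.
#' @param labels Class labels (taken from \code{x} if it is
#'   \code{kcr_features}).
#' @return A \code{kcr_model}: list with the fitted backend model
#'   (\code{fit}), \code{chosen} hyperparameters, \code{tuning} table,
#'   \code{columns} and decision \code{threshold} (0 for SVM decision
#'   values, 0.5 for RF probabilities).
#' @export
kcr_train <- function(spec, x, labels = NULL) {
  stopifnot(inherits(spec, "kcr_model_spec"))
  inp <- fs_inputs(x, labels)
  x <- inp$x
  y <- inp$labels
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (length(unique(y)) < 2L) stop("labels contain a single class",
                                   call. = FALSE)
  grid <- kcr_grid(spec)
  tuning <- NULL
  if (isTRUE(spec$tune) && nrow(grid) > 1L) {
    fold <- stratified_folds(y, spec$inner_k,
                             kcr_stage_seed(spec$seed, "tune"))
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(spec$inner_k), function(f) {
        tr <- fold != f
        fit <- fit_one(spec$kind, x[tr, , drop = FALSE], y[tr],
                       grid[g, , drop = FALSE],
                       kcr_stage_seed(spec$seed, paste0("fit", f)))
        s <- score_one(fit, spec$kind, x[!tr, , drop = FALSE])
        thr <- if (spec$kind == "svm_rbf") 0 else 0.5
        mean((s > thr) == (y[!tr] == "positive"))
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(acc)  # first max = preferred tie-break order
    tuning <- cbind(grid, accuracy = acc)
    chosen <- grid[best, , drop = FALSE]
  } else {
    chosen <- grid[1L, , drop = FALSE]
  }
  fit <- fit_one(spec$kind, x, y, chosen, kcr_stage_seed(spec$seed, "final"))
  structure(
    list(spec = spec, kind = spec$kind, fit = fit,
         chosen = as.list(chosen), tuning = tuning,
         columns = colnames(x),
         threshold = if (spec$kind == "svm_rbf") 0 else 0.5,
         levels = levels(y), seed = spec$seed),
    class = "kcr_model"
  )
}

#' @export
print.kcr_model <- function(x, ...) {
  cat(sprintf("<kcr_model> %s, %d features\n", x$kind, length(x$columns)))
  cat("  chosen:", paste(names(x$chosen), unlist(x$chosen), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.kcr_model <- function(object, ...) {
  print(object)
  if (!is.null(object$tuning)) {
    cat("  grid search (internal CV accuracy), top 5:\n")
    t5 <- object$tuning[order(-object$tuning$accuracy), , drop = FALSE]
    print(utils::head(t5, 5), row.names = FALSE)
  }
  invisible(object)
}

# check that new data carries exactly the training columns
check_columns <- function(model, x) {
  cn <- colnames(x)
  if (is.null(cn) || length(cn) != length(model$columns)) {
    stop("test columns do not match training columns (count or names)",
         call. = FALSE)
  }
  if (!identical(cn, model$columns)) {
    mism <- which(cn != model$columns)[1]
    stop("test column ", mism, " is '", cn[mism],
         "', expected '", model$columns[mism], "'", call. = FALSE)
  }
}

#' Predict Kcr scores or classes
#'
#' @param object A \code{kcr_model}.
#' @param newdata Feature matrix with exactly the training columns (names
#'   and order), or a \code{kcr_features} object.
#' @param type \code{"score"} (SVM decision value / RF positive-class
#'   probability) or \code{"class"}.
#' @param ... Unused.
#' @return Numeric scores or a factor of class labels.
#' @export
predict.kcr_model <- function(object, newdata, type = c("score", "class"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "kcr_features")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) stop("empty test set", call. = FALSE)
  check_columns(object, newdata)
  s <- score_one(object$fit, object$kind, newdata)
  if (type == "score") unname(s) else
    factor(ifelse(s > object$threshold, "positive", "negative"),
           levels = c("negative", "positive"))
}

#' Save / load a trained model with metadata
#'
#' Persists the model, its encoder configuration and column names as a
#' single-file archive.
#'
#' @param model A \code{kcr_model}.
#' @param path File path.
#' @param encoder_config Optional list recorded alongside the model (e.g.
#'   the encoder set used to build its features).
#' @return \code{kcr_save_model}: invisibly \code{path};
#'   \code{kcr_load_model}: the \code{kcr_model} (encoder config in
#'   attribute \code{"encoder_config"}).
#' @export
kcr_save_model <- function(model, path, encoder_config = NULL) {
  stopifnot(inherits(model, "kcr_model"))
  saveRDS(list(model = model, encoder_config = encoder_config,
               package_version = as.character(utils::packageVersion("kcrpred"))),
          path)
  invisible(path)
}

#' @rdname kcr_save_model
#' @export
kcr_load_model <- function(path) {
  obj <- readRDS(path)
  model <- obj$model
  attr(model, "encoder_config") <- obj$encoder_config
  model
}
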