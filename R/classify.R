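#' Train an SVM colony-quality classifier
#'
#' Standardises each feature by the training-set mean and sd, then fits a
#' support vector machine (via libsvm through \pkg{e1071}). The returned
#' model stores the support vectors, dual coefficients and scaler, so it
#' predicts identically after a JSON round trip ([save_model()] /
#' [load_model()]) without any external state.
#'
#' @param x numeric feature matrix (rows = patterns) or feature table.
#' @param labels character/factor class labels (two classes, each with at
#'   least two samples); taken from the table's `label` column if omitted.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost regularisation parameter C.
#' @param gamma RBF kernel width; default `1 / ncol(x)`.
#' @return An object of class `colony_svm` with elements `sv`, `coefs`,
#'   `rho`, `kernel`, `cost`, `gamma`, `mu`, `sigma`, `positive_class`,
#'   `negative_class`, `classes`, `feature_ids`, `training_accuracy`.
#' @export
train_classifier <- function(x, labels = NULL,
                             kernel = c("linear", "radial"),
                             cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  fm <- feature_matrix(x)
  X <- fm$x
  labels <- labels %||% fm$labels
  if (is.null(labels)) stop("`labels` are required", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("`labels` length must match the number of rows", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop("training requires exactly two classes, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  if (min(table(labels)) < 2)
    stop("each class needs at least two training samples", call. = FALSE)

  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  Xs <- scale(X, center = mu, scale = sigma)
  gamma <- gamma %||% 1 / ncol(X)

  fit <- e1071::svm(Xs, factor(labels, levels = classes), kernel = kernel,
                    cost = cost, gamma = gamma, scale = FALSE)

  # decision-value sign convention: colnames are "<positive>/<negative>"
  dv <- attr(predict(fit, Xs, decision.values = TRUE), "decision.values")
  pn <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]

  model <- structure(list(
    kernel = kernel, cost = cost, gamma = gamma,
    sv = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    mu = unname(mu), sigma = unname(sigma),
    positive_class = pn[1], negative_class = pn[2], classes = classes,
    feature_ids = colnames(X) %||% sprintf("f%03d", seq_len(ncol(X))),
    training_accuracy = NA_real_
  ), class = "colony_svm")
  model$training_accuracy <-
    mean(predict(model, X) == labels)
  model
}

# kernel matrix between raw-space rows of A and stored (scaled) SVs
svm_kernel <- function(model, A) {
  As <- scale(A, center = model$mu, scale = model$sigma)
  if (model$kernel == "linear") {
    As %*% t(model$sv)
  } else {
    d2 <- outer(rowSums(As^2), rowSums(model$sv^2), "+") -
      2 * As %*% t(model$sv)
    exp(-model$gamma * pmax(d2, 0))
  }
}

#' Decision values of a colony SVM
#'
#' `f(x) = sum_j coefs_j K(sv_j, x) - rho`; positive values vote for
#' `positive_class`.
#'
#' @param model a `colony_svm`.
#' @param x feature matrix or table with the model's feature dimension.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, x) {
  fm <- feature_matrix(x)
  A <- fm$x
  if (ncol(A) != length(model$mu))
    stop(sprintf("feature dimension %d does not match the model (%d)",
                 ncol(A), length(model$mu)), call. = FALSE)
  as.numeric(svm_kernel(model, A) %*% model$coefs - model$rho)
}

#' Predict colony classes
#'
#' @param object a `colony_svm`.
#' @param newdata feature matrix or feature table.
#' @param ... unused.
#' @return Character vector of predicted labels, one per row; deterministic
#'   given the model (ties at decision value 0 go to the positive class).
#' @export
predict.colony_svm <- function(object, newdata, ...) {
  dv <- decision_values(object, newdata)
  ifelse(dv >= 0, object$positive_class, object$negative_class)
}

#' @export
print.colony_svm <- function(x, ...) {
  cat(sprintf(
    "<colony_svm> %s kernel, C = %g, %d support vectors, %d features, training accuracy %.1f%%\n",
    x$kernel, x$cost, nrow(x$sv), length(x$mu), 100 * x$training_accuracy))
  invisible(x)
}

#' Confusion table and per-class distinguish rates
#'
#' Builds the 2x2 confusion matrix (rows = human-assigned class, columns =
#' system-assigned class) and the row-normalised percentages ("distinguish
#' rates", one decimal place) in the conventional good-first ordering.
#'
#' @param true,pred character vectors of true and predicted labels.
#' @return An object of class `eval_report`: `confusion` (counts), `rates`
#'   (row percentages), `n_test`, `recall` (named per-class fractions).
#' @export
confusion_report <- function(true, pred) {
  true <- as.character(true); pred <- as.character(pred)
  if (length(true) != length(pred) || length(true) == 0)
    stop("`true` and `pred` must be equal-length, non-empty", call. = FALSE)
  seen <- union(true, pred)
  classes <- c(intersect(c("good", "bad"), seen),
               sort(setdiff(seen, c("good", "bad"))))
  cm <- unclass(table(factor(true, levels = classes),
                      factor(pred, levels = classes)))
  rates <- round(100 * cm / pmax(rowSums(cm), 1), 1)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  structure(list(confusion = cm, rates = rates, n_test = length(true),
                 recall = recall),
            class = "eval_report")
}

#' Evaluate a trained classifier on a labelled test set
#'
#' @param model a `colony_svm`.
#' @param x labelled feature table, or feature matrix with `labels` supplied.
#' @param labels true labels (if `x` is a bare matrix).
#' @return An `eval_report`; see [confusion_report()].
#' @export
evaluate_classifier <- function(model, x, labels = NULL) {
  fm <- feature_matrix(x)
  labels <- labels %||% fm$labels
  if (is.null(labels) || all(is.na(labels)))
    stop("evaluation requires true labels", call. = FALSE)
  confusion_report(labels, predict(model, fm$x))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Distinguish rate (%) by human-assigned class\n")
  hdr <- colnames(x$rates)
  cat(sprintf("  %-18s %s\n", "", paste(sprintf("%8s", hdr), collapse = "")))
  for (i in seq_len(nrow(x$rates))) {
    cat(sprintf("  %-18s %s\n", rownames(x$rates)[i],
                paste(sprintf("%7.1f%%", x$rates[i, ]), collapse = "")))
  }
  cat(sprintf("  n_test = %d\n", x$n_test))
  invisible(x)
}

#' Stratified k-fold cross-validation of the SVM stage
#'
#' Deterministic, stratified fold assignment given `seed`; each fold holds
#' out roughly `1/k` of every class, the classifier is refit on the rest
#' (scaler and all), and per-class recalls are pooled.
#'
#' @param x labelled feature table, or matrix with `labels`.
#' @param labels true labels (if `x` is a bare matrix).
#' @param k_folds number of folds (>= 2, at most the smaller class count).
#' @param seed fold-assignment seed.
#' @param ... passed to [train_classifier()].
#' @return A list: `per_fold` data.frame (fold, recall per class, accuracy),
#'   `mean_rates`, `sd_rates` (per-class recall summaries, %), `accuracy`
#'   (pooled), `folds` (the assignment vector).
#' @export
cross_validate <- function(x, labels = NULL, k_folds = 5, seed = NULL, ...) {
  fm <- feature_matrix(x)
  X <- fm$x
  labels <- as.character(labels %||% fm$labels)
  if (k_folds < 2) stop("`k_folds` must be at least 2", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("cross-validation requires both classes", call. = FALSE)
  if (min(table(labels)) < k_folds)
    stop("each class needs at least `k_folds` samples for stratified folds",
         call. = FALSE)
  folds <- integer(length(labels))
  with_seed_if(seed, {
    for (cl in classes) {
      i <- which(labels == cl)
      folds[i] <- sample(rep_len(seq_len(k_folds), length(i)))
    }
  })
  pred <- character(length(labels))
  rows <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    model <- train_classifier(X[tr, , drop = FALSE], labels[tr], ...)
    pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
    rep_f <- confusion_report(labels[!tr], pred[!tr])
    rows[[f]] <- data.frame(fold = f,
                            t(rep_f$recall * 100),
                            accuracy = 100 * mean(pred[!tr] == labels[!tr]),
                            check.names = FALSE)
  }
  per_fold <- do.call(rbind, rows)
  rec_cols <- setdiff(names(per_fold), c("fold", "accuracy"))
  list(per_fold = per_fold,
       mean_rates = colMeans(per_fold[rec_cols]),
       sd_rates = apply(per_fold[rec_cols], 2, sd),
       accuracy = 100 * mean(pred == labels),
       folds = folds)
}
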