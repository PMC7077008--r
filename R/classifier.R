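#' Three-level feature discretization at mean +/- SD
#'
#' Each column is binned into levels 0 (below mu - sigma), 1 (within one
#' SD), 2 (above mu + sigma), with sigma the population (1/n) standard
#' deviation — the discretization feeding the mutual information terms of
#' mRMR. Constant columns collapse to level 1.
#'
#' @param X numeric matrix or data.frame of features (>= 2 rows).
#' @return list: `levels` (integer matrix), `edges` (2 x p matrix of cut
#'   points, reusable via [apply_discretization()]).
#' @export
discretize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_domain("discretize needs >= 2 rows")
  n <- nrow(X)
  edges <- vapply(seq_len(ncol(X)), function(j) {
    mu <- mean(X[, j])
    s <- sd(X[, j]) * sqrt((n - 1) / n)   # population SD
    c(mu - s, mu + s)
  }, numeric(2))
  colnames(edges) <- colnames(X)
  list(levels = apply_discretization(X, edges), edges = edges)
}

#' Re-apply stored discretization edges
#'
#' @param X numeric matrix or data.frame.
#' @param edges 2 x p matrix from [discretize()].
#' @return integer matrix of levels in {0, 1, 2}.
#' @export
apply_discretization <- function(X, edges) {
  X <- as.matrix(X)
  out <- matrix(1L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    lo <- edges[1, j]; hi <- edges[2, j]
    if (hi > lo) {
      out[X[, j] < lo, j] <- 0L
      out[X[, j] > hi, j] <- 2L
    }
  }
  out
}

#' Plug-in mutual information of two discrete vectors, in bits
#'
#' @param a,b equal-length vectors of discrete values.
#' @return mutual information estimate (>= 0).
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop_domain("length mismatch")
  if (length(a) < 1) stop_domain("empty vectors")
  pj <- table(a, b) / length(a)
  pa <- rowSums(pj); pb <- colSums(pj)
  pe <- outer(pa, pb)
  nz <- pj > 0
  max(0, sum(pj[nz] * log2(pj[nz] / pe[nz])))
}

#' Minimum-redundancy-maximum-relevance feature selection (MID scheme)
#'
#' Greedy forward selection: the first feature maximizes relevance
#' `I(f; y)`; each later step maximizes
#' `I(f; y) - mean over selected s of I(f; s)`. Ties break by column order.
#' Expects discretized features (see [discretize()]).
#'
#' @param X integer matrix/data.frame of discrete features (named columns).
#' @param y class labels (>= 2 classes).
#' @param m number of features to select.
#' @return list of class `mrmr_result`: `selected` (names), `scores`
#'   (per-step objective values).
#' @export
mrmr_select <- function(X, y, m) {
  X <- as.matrix(X)
  if (m < 1) stop_domain("m must be >= 1")
  if (length(unique(y)) < 2) stop_domain("y needs >= 2 classes")
  p <- ncol(X)
  if (m > p) {
    warning(sprintf("m = %d exceeds %d features; truncating", m, p))
    m <- p
  }
  nm <- colnames(X) %||% paste0("f", seq_len(p))
  rel <- vapply(seq_len(p), function(j) mutual_information(X[, j], y), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)   # running sum of I(f; s) over selected s
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(p), selected)
    obj <- if (step == 1) rel[cand] else
      rel[cand] - red_sum[cand] / length(selected)
    pick <- cand[which.max(obj)]   # which.max takes the first => column order
    selected <- c(selected, pick)
    scores <- c(scores, max(obj))
    if (step < m) {
      for (j in setdiff(seq_len(p), selected))
        red_sum[j] <- red_sum[j] + mutual_information(X[, j], X[, pick])
    }
  }
  structure(list(selected = nm[selected], scores = scores),
            class = "mrmr_result")
}

class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

fit_one <- function(X, y, model_type, weights) {
  y <- factor(y, levels = c(0, 1))
  switch(model_type,
    svm = e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE,
                     class.weights = weights),
    rf = randomForest::randomForest(X, y, ntree = 500,
                                    classwt = weights),
    dac = MASS::lda(X, grouping = y, prior = c(0.5, 0.5)))
}

predict_one <- function(fit, model_type, X) {
  if (model_type == "dac") {
    as.integer(as.character(predict(fit, X)$class))
  } else {
    as.integer(as.character(predict(fit, X)))
  }
}

#' Train a recurrence classifier under stratified five-fold cross-validation
#'
#' Folds are stratified by class and drawn from the seed; per-fold held-out
#' accuracy is recorded and the final model is refit on all rows. Features
#' are standardized by training-fold statistics (the full-data scaler is
#' stored for prediction). Class weighting (inverse frequency for SVM/RF,
#' flat priors for the discriminant) counters the low recurrence prevalence
#' typical of early-stage cohorts.
#'
#' @param X numeric matrix/data.frame of the selected features.
#' @param y binary labels (0 = non-recurrence, 1 = recurrence).
#' @param model_type "svm" (linear kernel, C = 1), "rf" (500 trees), or
#'   "dac" (linear discriminant).
#' @param folds number of CV folds (default 5); each class needs >= folds
#'   members.
#' @param seed RNG seed for fold assignment and the forest.
#' @return list of class `fitted_classifier`: model_type,
#'   selected_features, fit, scaler, cv_metrics (per-fold accuracy),
#'   locked (FALSE), seed.
#' @export
crossval_train <- function(X, y, model_type = c("svm", "rf", "dac"),
                           folds = 5L, seed = 1L) {
  model_type <- match.arg(model_type)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  if (any(table(y) < folds))
    stop_domain("stratification error: a class has fewer than %d members", folds)
  withr::with_seed(seed, {
    fold_of <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      Xtr <- scale(X[tr, , drop = FALSE], mu, sg)
      Xte <- scale(X[!tr, , drop = FALSE], mu, sg)
      fit <- fit_one(Xtr, y[tr], model_type, class_weights(y[tr]))
      acc[f] <- mean(predict_one(fit, model_type, Xte) == y[!tr])
    }
    mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
    fit <- fit_one(scale(X, mu, sg), y, model_type, class_weights(y))
  })
  structure(list(model_type = model_type, selected_features = colnames(X),
                 fit = fit, scaler = list(center = mu, scale = sg),
                 cv_metrics = acc, locked = FALSE, seed = as.integer(seed),
                 fold_assignment = fold_of),
            class = "fitted_classifier")
}

#' Lock down the best classifier
#'
#' Picks the candidate with the highest mean cross-validated accuracy; exact
#' ties break in the order svm > rf > dac. The returned model is flagged
#' locked and is the one [predict_risk()] will accept.
#'
#' @param candidates non-empty list of [crossval_train()] results.
#' @return the winning `fitted_classifier` with `locked = TRUE`.
#' @export
lock_down <- function(candidates) {
  if (!length(candidates)) stop_domain("no candidate classifiers")
  prio <- c(svm = 1, rf = 2, dac = 3)
  accs <- vapply(candidates, function(m) mean(m$cv_metrics), numeric(1))
  ord <- order(-accs, prio[vapply(candidates, function(m) m$model_type,
                                  character(1))])
  best <- candidates[[ord[1]]]
  best$locked <- TRUE
  best
}

#' Predict recurrence risk group
#'
#' Binds feature columns by name, applies the stored scaler, and returns
#' the binary risk call per row.
#'
#' @param model a locked [crossval_train()] model (see [lock_down()]).
#' @param X feature table containing all of `model$selected_features`.
#' @return character vector of "ECAHBC-positive" / "ECAHBC-negative".
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "fitted_classifier"))
  if (!isTRUE(model$locked)) stop_domain("model is not locked")
  X <- as.data.frame(X)
  if (nrow(X) == 0) return(character(0))
  missing_cols <- setdiff(model$selected_features, names(X))
  if (length(missing_cols))
    stop_domain("missing feature column(s): %s",
                paste(missing_cols, collapse = ", "))
  Xs <- scale(as.matrix(X[, model$selected_features, drop = FALSE]),
              model$scaler$center, model$scaler$scale)
  pred <- predict_one(model$fit, model$model_type, Xs)
  ifelse(pred == 1, "ECAHBC-positive", "ECAHBC-negative")
}

#' Confusion-matrix metrics of a binary prediction
#'
#' Accepts 0/1 vectors, logicals, or "ECAHBC-positive"/"ECAHBC-negative"
#' labels. PPV/NPV are `NA` (flagged via `undefined`) when their denominator
#' is zero.
#'
#' @param pred,truth equal-length binary vectors.
#' @return list of class `confusion_metrics`: tp, fp, tn, fn, accuracy,
#'   ppv, npv, sensitivity, specificity, undefined (character vector of
#'   undefined metrics).
#' @export
confusion_metrics <- function(pred, truth) {
  to01 <- function(v) {
    if (is.character(v) || is.factor(v)) as.integer(as.character(v) == "ECAHBC-positive")
    else as.integer(v)
  }
  pred <- to01(pred); truth <- to01(truth)
  if (length(pred) != length(truth)) stop_domain("length mismatch")
  if (!length(pred)) stop_domain("empty vectors")
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); NA_real_ } else num / den
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    ppv = ratio(tp, tp + fp, "ppv"),
    npv = ratio(tn, tn + fn, "npv"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    undefined = undef
  ), class = "confusion_metrics")
}

#' Confusion metrics from the four counts
#'
#' Convenience wrapper for worked examples quoted as counts (e.g. published
#' validation tables): expands the counts into vectors and calls
#' [confusion_metrics()].
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return A `confusion_metrics` object.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp + fp), rep(0, tn + fn))
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  confusion_metrics(pred, truth)
}
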