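#' Class-weighted (balanced) accuracy
#'
#' With `n1` examples of the positive class and `n-1` of the other, and
#' `c1`, `c-1` correct in each, returns `(n_-1 c_1 + n_1 c_-1) / (2 n_1
#' n_-1)` — the unweighted mean of the two per-class recalls, so each class
#' contributes equally regardless of imbalance.
#'
#' @param truth,pred vectors of two-class labels (any common coding).
#' @return Scalar in `[0, 1]`.
#' @export
weighted_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  classes <- unique(truth)
  if (length(classes) != 2L)
    stop("weighted accuracy needs both classes present in truth")
  recalls <- vapply(classes, function(cl)
    mean(pred[truth == cl] == cl), numeric(1))
  mean(recalls)
}

#' Classifier specification
#'
#' One of three class-weighted models: a linear-margin classifier (linear
#' SVM), L2-regularised logistic regression, or Gaussian naive Bayes. For
#' the margin and logistic models the penalty `C` is chosen per outer fold
#' by nested stratified threefold cross-validation over a log-spaced grid
#' (powers of two over `[2^-4, 2^6]` and `[2^-5, 2^5]` respectively),
#' maximising weighted accuracy with ties going to the smallest (most
#' regularised) value. For naive Bayes the posterior probability of the
#' typical class is compared against a cut chosen by nested leave-one-out
#' within the training fold over a `[0.05, 0.95]` grid.
#'
#' @param kind `"svm"`, `"logistic"` or `"nb"`.
#' @param C_grid penalty grid (ignored for `"nb"`).
#' @param inner_folds nested folds for penalty selection.
#' @param class_weighting weight examples inversely to class frequency.
#' @param nb_threshold_grid probability cuts searched for naive Bayes.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("svm", "logistic", "nb"),
                            C_grid = NULL, inner_folds = 3,
                            class_weighting = TRUE,
                            nb_threshold_grid = seq(0.05, 0.95, by = 0.05)) {
  kind <- match.arg(kind)
  if (is.null(C_grid))
    C_grid <- switch(kind, svm = 2^(-4:6), logistic = 2^(-5:5), nb = numeric(0))
  if (kind != "nb" && !length(C_grid)) stop("C_grid must be non-empty")
  if (inner_folds < 2) stop("inner_folds must be >= 2")
  structure(list(kind = kind, C_grid = C_grid, inner_folds = inner_folds,
                 class_weighting = class_weighting,
                 nb_threshold_grid = nb_threshold_grid),
            class = "classifier_spec")
}

class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

# ---- model fitting primitives -------------------------------------------

fit_svm <- function(X, y, C, class_weighting = TRUE) {
  cw <- if (class_weighting) class_weights(y) else NULL
  e1071::svm(X, y, kernel = "linear", cost = C, class.weights = cw,
             scale = FALSE)
}

predict_svm <- function(fit, X) predict(fit, X)

# glmnet penalised objective (1/n) sum loss + lambda/2 ||b||^2 matches the
# C-parameterised form ||b||^2/2 + C sum loss at lambda = 1/(n C).
fit_logistic <- function(X, y, C, class_weighting = TRUE) {
  n <- nrow(X)
  lambda <- 1 / (n * C)
  w <- if (class_weighting) class_weights(y)[as.character(y)] else rep(1, n)
  # glmnet warns whenever a class has < 8 observations, which is routine in
  # the inner folds of a small cohort; muffle that advisory only
  withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lambda * c(16, 8, 4, 2, 1),
                   weights = as.numeric(w), standardize = TRUE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

predict_logistic <- function(fit, X, C) {
  lambda <- fit$lambda[length(fit$lambda)]
  factor(as.character(predict(fit, X, s = lambda, type = "class")),
         levels = fit$classnames)
}

# Gaussian naive Bayes tables; variance floored (with a warning) when a
# feature is constant within a class.
nb_fit <- function(X, y) {
  classes <- levels(droplevels(factor(y)))
  mu <- s2 <- matrix(NA_real_, length(classes), ncol(X),
                     dimnames = list(classes, colnames(X)))
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(Xi)
    s2[cl, ] <- apply(Xi, 2, var)
  }
  # single-row classes have undefined variance; fall back to the floor
  degenerate <- any(s2 == 0, na.rm = TRUE)
  s2[!is.finite(s2)] <- 0
  floor_v <- 1e-9 * max(s2, 1e-12)
  if (any(s2 < floor_v)) {
    if (degenerate) warning("zero-variance feature(s); variance floor applied")
    s2 <- pmax(s2, floor_v)
  }
  prior <- as.numeric(table(factor(y, classes)) / length(y))
  list(classes = classes, mu = mu, s2 = s2, prior = prior)
}

# Posterior probability of each class; columns ordered as model$classes.
nb_posterior <- function(model, X) {
  X <- as.matrix(X)
  ll <- vapply(seq_along(model$classes), function(i) {
    rowSums(dnorm(X, rep(model$mu[i, ], each = nrow(X)),
                  rep(sqrt(model$s2[i, ]), each = nrow(X)), log = TRUE)) +
      log(model$prior[i])
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow(X), length(model$classes))
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  p <- p / rowSums(p)
  colnames(p) <- model$classes
  p
}

#' Gaussian naive Bayes with a tuned decision threshold
#'
#' Fits an independent-Gaussian class-conditional model on the training
#' data and converts the posterior probability of the typical (`TD`) class
#' into hard labels by comparing it against a cut chosen by leave-one-out
#' within the training set to maximise weighted accuracy (ties resolved
#' toward 0.5, then to the smaller cut) — the imbalance-aware alternative
#' to thresholding at one half.
#'
#' @param X_train,y_train training features and labels (`ASD`/`TD`).
#' @param X_test feature rows to classify.
#' @param threshold_grid candidate cuts on the typical-class posterior.
#' @return Factor of predicted labels with the chosen cut in attribute
#'   `"threshold"`.
#' @export
fit_predict_nb <- function(X_train, y_train, X_test,
                           threshold_grid = seq(0.05, 0.95, by = 0.05)) {
  X_train <- as.matrix(X_train)
  y_train <- factor(as.character(y_train), levels = c("ASD", "TD"))
  n <- nrow(X_train)
  p_loo <- numeric(n)
  for (i in seq_len(n)) {
    m <- nb_fit(X_train[-i, , drop = FALSE], droplevels(y_train[-i]))
    # leaving subject i out can empty a class in very small folds; the
    # typical-class posterior is then degenerate
    p_loo[i] <- if (!"TD" %in% m$classes) 0
                else if (length(m$classes) == 1L) 1
                else nb_posterior(m, X_train[i, , drop = FALSE])[, "TD"]
  }
  acc <- vapply(threshold_grid, function(th) {
    pred <- ifelse(p_loo > th, "TD", "ASD")
    if (length(unique(y_train)) < 2) return(NA_real_)
    weighted_accuracy(y_train, pred)
  }, numeric(1))
  best <- which(acc == max(acc))
  best <- best[order(abs(threshold_grid[best] - 0.5), threshold_grid[best])][1]
  th <- threshold_grid[best]
  model <- nb_fit(X_train, y_train)
  p <- nb_posterior(model, as.matrix(X_test))[, "TD"]
  structure(factor(ifelse(p > th, "TD", "ASD"), levels = c("ASD", "TD")),
            threshold = th, posterior_td = p)
}

# ---- nested selection and LOOCV -----------------------------------------

# Stratified k folds assigned round-robin within class, ordered by subject
# id so fold membership depends on identity, not row position.
inner_fold_ids <- function(ids, y, k) {
  fold <- integer(length(y))
  for (cl in unique(as.character(y))) {
    idx <- which(as.character(y) == cl)
    if (length(idx) < k)
      stop("cannot stratify ", k, " folds: class ", cl, " has only ",
           length(idx), " training subjects")
    idx <- idx[order(ids[idx])]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_once <- function(spec, X, y, C) {
  switch(spec$kind,
         svm = fit_svm(X, y, C, spec$class_weighting),
         logistic = fit_logistic(X, y, C, spec$class_weighting))
}

predict_once <- function(spec, fit, X, C) {
  switch(spec$kind,
         svm = predict_svm(fit, X),
         logistic = predict_logistic(fit, X, C))
}

#' Nested threefold penalty selection
#'
#' Splits the training fold into class-stratified thirds; each grid value
#' is scored by training on two parts and evaluating weighted accuracy on
#' the third, rotating through all assignments and averaging. The value
#' with the highest average wins; ties go to the smallest (most
#' regularised) value.
#'
#' @param spec a [classifier_spec] (`svm` or `logistic`).
#' @param X_train,y_train training fold.
#' @return The chosen penalty, with the grid-average accuracies in
#'   attribute `"mean_accuracy"`.
#' @export
nested_select <- function(spec, X_train, y_train) {
  ids <- rownames(X_train)
  if (is.null(ids)) ids <- sprintf("row%05d", seq_len(nrow(X_train)))
  fold <- inner_fold_ids(ids, y_train, spec$inner_folds)
  acc <- matrix(NA_real_, spec$inner_folds, length(spec$C_grid))
  for (f in seq_len(spec$inner_folds)) {
    tr <- fold != f; te <- !tr
    for (j in seq_along(spec$C_grid)) {
      fit <- fit_once(spec, X_train[tr, , drop = FALSE],
                      droplevels(factor(y_train[tr])), spec$C_grid[j])
      pred <- predict_once(spec, fit, X_train[te, , drop = FALSE],
                           spec$C_grid[j])
      acc[f, j] <- weighted_accuracy(y_train[te], pred)
    }
  }
  mean_acc <- colMeans(acc)
  best <- which(mean_acc == max(mean_acc))
  best <- best[which.min(spec$C_grid[best])]
  structure(spec$C_grid[best], mean_accuracy = mean_acc)
}

#' Leave-one-out cross-validated predictions
#'
#' For each subject: select the hyperparameter on the remaining subjects
#' (nested threefold for the penalised models, nested leave-one-out for the
#' naive Bayes threshold), fit on all of them, and predict the held-out
#' subject. Fold assignment depends only on subject identity (row names),
#' so predictions are equivariant to row permutation.
#'
#' @param spec a [classifier_spec].
#' @param X `n x p` feature matrix (row names = subject ids).
#' @param y labels (`ASD`/`TD`), length `n`.
#' @return Factor of out-of-fold predictions (named by subject), with the
#'   per-fold chosen hyperparameters in attribute `"chosen"`.
#' @export
loocv <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("ASD", "TD"))
  if (any(table(y) < 2)) stop("need at least 2 subjects per class")
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("row%05d", seq_len(n))
  pred <- character(n)
  chosen <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) stop("a class is absent from a training fold")
    if (spec$kind == "nb") {
      p <- fit_predict_nb(Xtr, ytr, X[i, , drop = FALSE],
                          spec$nb_threshold_grid)
      pred[i] <- as.character(p)
      chosen[i] <- attr(p, "threshold")
    } else {
      C <- nested_select(spec, Xtr, ytr)
      fit <- fit_once(spec, Xtr, ytr, C)
      pred[i] <- as.character(predict_once(spec, fit, X[i, , drop = FALSE], C))
      chosen[i] <- C
    }
  }
  structure(factor(pred, levels = c("ASD", "TD"),
                   labels = c("ASD", "TD")),
            names = rownames(X), chosen = chosen)
}

#' Stack an entropy-based prediction onto the selected features
#'
#' Trains a linear-margin model (penalty `C = 0.1`, inverse-frequency class
#' weights) on the high-dimensional multiscale-entropy block, evaluates it
#' by leave-one-out cross-validation, and appends each subject's
#' out-of-fold hard prediction (ASD = 1, TD = 0) as a 24th feature — a
#' stacking step that lets the low-dimensional model consume the entropy
#' information without being swamped by its dimensionality.
#'
#' @param selected `n x 23` selected-feature matrix.
#' @param mmse `n x p` multiscale-entropy matrix (same row order).
#' @param y labels (`ASD`/`TD`).
#' @param C margin penalty for the inner model.
#' @return `n x 24` matrix with the stacked column `mmse_pred` appended.
#' @export
stack_mmse <- function(selected, mmse, y, C = 0.1) {
  selected <- as.matrix(selected); mmse <- as.matrix(mmse)
  if (nrow(selected) != nrow(mmse))
    stop("selected and mmse feature blocks must cover the same subjects")
  y <- factor(as.character(y), levels = c("ASD", "TD"))
  n <- nrow(mmse)
  if (is.null(rownames(mmse))) rownames(mmse) <- rownames(selected)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_svm(mmse[-i, , drop = FALSE], droplevels(y[-i]), C)
    pred[i] <- as.character(predict_svm(fit, mmse[i, , drop = FALSE]))
  }
  out <- cbind(selected, mmse_pred = as.numeric(pred == "ASD"))
  rownames(out) <- rownames(selected)
  out
}

#' Permutation test of classification accuracy
#'
#' Re-runs the full cross-validated pipeline on `n_perm` label
#' permutations and reports `p = (#{permuted accuracy >= observed} + 1) /
#' (n_perm + 1)`.
#'
#' @param spec a [classifier_spec].
#' @param X,y features and labels.
#' @param n_perm number of permutations (> 0).
#' @param seed seed for the permutation draws.
#' @return List: `p_value`, `observed`, `permuted` (accuracy per draw).
#' @export
permutation_test <- function(spec, X, y, n_perm = 100, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  y <- factor(as.character(y), levels = c("ASD", "TD"))
  observed <- weighted_accuracy(y, loocv(spec, X, y))
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      weighted_accuracy(yp, loocv(spec, X, yp))
    }, numeric(1))
  })
  list(p_value = (sum(permuted >= observed) + 1) / (n_perm + 1),
       observed = observed, permuted = permuted)
}

classification_metrics <- function(truth, pred) {
  truth <- factor(as.character(truth), c("ASD", "TD"))
  pred <- factor(as.character(pred), c("ASD", "TD"))
  list(weighted_accuracy = weighted_accuracy(truth, pred),
       sensitivity = mean(pred[truth == "ASD"] == "ASD"),
       specificity = mean(pred[truth == "TD"] == "TD"))
}

#' Evaluate classifiers over feature sets
#'
#' Runs each classifier on each feature set under leave-one-out
#' cross-validation and reports weighted accuracy, sensitivity (ASD
#' recall) and specificity (TD recall); optionally reruns everything on the
#' male subjects only to check for sex-driven shortcuts.
#'
#' @param features named list of `n x p` feature matrices.
#' @param y labels (`ASD`/`TD`).
#' @param specs named list of [classifier_spec]s.
#' @param sex optional per-subject sex for the males-only rerun.
#' @param males_only also evaluate on the male subset.
#' @return List of class `classification_report`: `results` (one row per
#'   feature set x classifier), `predictions`, and optionally
#'   `males_only` (a nested report).
#' @export
evaluate <- function(features, y, specs = list(nb = classifier_spec("nb")),
                     sex = NULL, males_only = FALSE) {
  y <- factor(as.character(y), levels = c("ASD", "TD"))
  rows <- list(); preds <- list()
  for (fname in names(features)) {
    for (sname in names(specs)) {
      pred <- loocv(specs[[sname]], features[[fname]], y)
      m <- classification_metrics(y, pred)
      rows[[length(rows) + 1L]] <- data.frame(
        features = fname, classifier = sname,
        weighted_accuracy = m$weighted_accuracy,
        sensitivity = m$sensitivity, specificity = m$specificity)
      preds[[paste(fname, sname, sep = ".")]] <- pred
    }
  }
  out <- list(results = do.call(rbind, rows), predictions = preds, truth = y)
  if (males_only) {
    if (is.null(sex)) stop("males-only evaluation requires sex metadata")
    keep <- sex == "M"
    ym <- droplevels(y[keep])
    if (nlevels(ym) < 2) {
      warning("males-only subgroup has a single class; skipped")
    } else {
      fm <- lapply(features, function(f) f[keep, , drop = FALSE])
      out$males_only <- evaluate(fm, y[keep], specs)
    }
  }
  class(out) <- "classification_report"
  out
}

#' @exportS3Method print classification_report
print.classification_report <- function(x, ...) {
  cat("<classification_report> weighted accuracy (rows = classifiers):\n")
  wide <- stats::reshape(x$results[, c("features", "classifier",
                                       "weighted_accuracy")],
                         idvar = "classifier", timevar = "features",
                         direction = "wide")
  names(wide) <- sub("^weighted_accuracy\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  if (!is.null(x$males_only)) {
    cat("males-only rerun:\n")
    print(x$males_only)
  }
  invisible(x)
}
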