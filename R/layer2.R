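# Layer 2: univariate F-regression feature ranking, top-k selection, linear
# classifiers (squared-hinge margin, ridge, logistic) with Platt-calibrated
# probabilities, stratified 10-fold cross-validation scored by MCC.

#' Univariate F-regression feature ranking
#'
#' For each feature, F = r^2 (n - 2) / (1 - r^2) where r is the Pearson
#' correlation with the binary labels; p from the F(1, n-2) distribution.
#' Constant features get F = 0 and rank last; perfectly correlated features
#' (|r| = 1, infinite F) rank above all finite scores. Ties break by
#' ascending index.
#'
#' @param X numeric matrix (n >= 3 rows).
#' @param y binary labels (0/1, logical, or two-level factor).
#' @return data.frame `index`, `F`, `p` sorted by descending F.
#' @export
f_regression_rank <- function(X, y) {
  X <- as.matrix(X); y <- as_binary(y)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  if (length(unique(y)) < 2)
    ab_stop("ab_single_class", "labels contain a single class")
  yc <- y - mean(y)
  xc <- sweep(X, 2, colMeans(X))
  num <- as.vector(crossprod(xc, yc))
  den <- sqrt(colSums(xc^2) * sum(yc^2))
  r <- ifelse(den > 0, num / den, 0)
  r2 <- pmin(r^2, 1)
  f <- ifelse(r2 >= 1, Inf, r2 * (n - 2) / (1 - r2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  out <- data.frame(index = seq_len(ncol(X)), F = f, p = p)
  out[order(-out$F, out$index), , drop = FALSE]
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  stopifnot(all(y %in% c(0, 1)))
  as.numeric(y)
}

#' Select the top-k ranked features
#'
#' @param ranked output of [f_regression_rank()].
#' @param k number of features to keep (default 2500); values above the
#'   feature count keep everything.
#' @return a `feature_selection`: `indices` (in rank order), `k`, `scores`.
#' @export
select_k <- function(ranked, k = 2500L) {
  stopifnot(k >= 1)
  kept <- utils::head(ranked, min(k, nrow(ranked)))
  structure(list(indices = kept$index, k = as.integer(k), scores = kept),
            class = "feature_selection")
}

# classifiers -------------------------------------------------------------

#' Train a linear Layer-2 classifier with calibrated probabilities
#'
#' Kinds: `"linear_margin"` (L2-regularised squared-hinge, the LinearSVC
#' analogue; default), `"ridge"` (closed-form ridge regression on +/-1
#' targets), `"logistic"`. Features are standardised internally. Decision
#' scores are mapped to probabilities with Platt's sigmoid (smoothed targets),
#' fitted on the training scores, so 0.5/0.8 thresholds have consistent
#' semantics for all kinds.
#'
#' @param X numeric matrix of selected features.
#' @param y binary labels; positive class = 1 ("approved").
#' @param kind classifier kind.
#' @param seed integer (recorded; all kinds are deterministic).
#' @param lambda L2 regularisation strength.
#' @param threshold default decision threshold in (0, 1).
#' @return an `ab_layer2_model`.
#' @export
train_classifier <- function(X, y, kind = c("linear_margin", "ridge", "logistic"),
                             seed = 1L, lambda = 1, threshold = 0.5) {
  kind <- match.arg(kind)
  X <- as.matrix(X); y <- as_binary(y)
  stopifnot(nrow(X) == length(y), threshold > 0, threshold < 1)
  if (length(unique(y)) < 2)
    ab_stop("ab_single_class", "training labels contain a single class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ypm <- 2 * y - 1
  n <- nrow(Xs); d <- ncol(Xs)
  wb <- switch(kind,
    linear_margin = {
      obj <- function(th) {
        w <- th[1:d]; b <- th[d + 1]
        m <- 1 - ypm * (Xs %*% w + b)
        sum(pmax(m, 0)^2) + lambda * sum(w^2) / 2
      }
      grd <- function(th) {
        w <- th[1:d]; b <- th[d + 1]
        m <- as.vector(1 - ypm * (Xs %*% w + b))
        act <- pmax(m, 0)
        gw <- -2 * as.vector(crossprod(Xs, act * ypm)) + lambda * w
        c(gw, -2 * sum(act * ypm))
      }
      fit <- stats::optim(rep(0, d + 1), obj, grd, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (fit$convergence != 0 && fit$value > obj(rep(0, d + 1)))
        ab_stop("ab_nonconvergence", "squared-hinge optimisation failed")
      fit$par
    },
    ridge = {
      A <- crossprod(cbind(Xs, 1))
      diag(A)[1:d] <- diag(A)[1:d] + lambda
      as.vector(solve(A, crossprod(cbind(Xs, 1), ypm)))
    },
    logistic = {
      fit <- suppressWarnings(stats::glm.fit(cbind(Xs, 1), y,
        family = stats::binomial(), control = list(maxit = 100)))
      as.vector(fit$coefficients)
    })
  w <- wb[1:d]; b <- wb[d + 1]
  scores <- as.vector(Xs %*% w + b)
  structure(list(kind = kind, w = w, b = b, center = ctr, scale = scl,
                 platt = platt_fit(scores, y), threshold = threshold,
                 n_features = d, seed = as.integer(seed)),
            class = "ab_layer2_model")
}

# Platt (1999) sigmoid calibration with smoothed targets; deterministic.
platt_fit <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(ab) {
    z <- ab[1] * scores + ab[2]
    p <- 1 / (1 + exp(z))          # Platt: P(y=1) = 1/(1+exp(A s + B))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  c(A = fit$par[1], B = fit$par[2])
}

platt_prob <- function(platt, scores)
  1 / (1 + exp(platt[["A"]] * scores + platt[["B"]]))

#' Predict with a Layer-2 model
#'
#' @param object an `ab_layer2_model`.
#' @param newdata matrix with the model's selected-feature count (0 rows ok).
#' @param threshold probability threshold (default: the model's); the positive
#'   set at a higher threshold is a subset of that at a lower one.
#' @param ... unused.
#' @return data.frame `probability`, `label` (`"approved"`/`"discontinued"`).
#' @export
predict.ab_layer2_model <- function(object, newdata,
                                    threshold = object$threshold, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L)
    return(data.frame(probability = numeric(0), label = character(0)))
  if (ncol(newdata) != object$n_features)
    ab_stop("ab_dimension_mismatch", sprintf(
      "model expects %d features, got %d", object$n_features, ncol(newdata)))
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p <- platt_prob(object$platt, as.vector(Xs %*% object$w + object$b))
  data.frame(probability = p,
             label = ifelse(p >= threshold, "approved", "discontinued"))
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); returns 0 when any
#' denominator factor is 0 (documented convention for one-class predictions).
#'
#' @param tp,fp,tn,fn nonnegative confusion counts.
#' @return value in [-1, 1].
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

confusion <- function(truth, pred) {
  c(tp = sum(truth == 1 & pred == 1), fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0), fn = sum(truth == 1 & pred == 0))
}

#' Stratified k-fold cross-validation with in-fold feature selection
#'
#' Feature ranking and top-k selection are refit inside every training fold
#' (no selection leakage); set `select_within_folds = FALSE` only to
#' demonstrate the leakage pitfall. Folds are stratified by class and seeded.
#'
#' @param X feature matrix; `y` binary labels.
#' @param k features to select per fold.
#' @param kind classifier kind (see [train_classifier()]).
#' @param folds fold count (default 10).
#' @param seed fold-assignment seed.
#' @param threshold probability threshold for the fold predictions.
#' @param select_within_folds logical (default TRUE).
#' @param y binary labels.
#' @return list: `per_fold` data.frame (mcc, sensitivity, specificity and
#'   confusion counts), `mean`, `sd`.
#' @export
cross_validate <- function(X, y, k = 2500L, kind = "linear_margin",
                           folds = 10L, seed = 1L, threshold = 0.5,
                           select_within_folds = TRUE) {
  X <- as.matrix(X); y <- as_binary(y)
  n <- nrow(X)
  if (n < folds) ab_stop("ab_too_few_samples", "need n >= folds")
  if (length(unique(y)) < 2)
    ab_stop("ab_single_class", "labels contain a single class")
  fold_id <- integer(n)
  with_seed(seed, for (cls in unique(y)) {
    i <- which(y == cls)
    fold_id[i] <- sample(rep(seq_len(folds), length.out = length(i)))
  })
  sel_global <- if (!select_within_folds) select_k(f_regression_rank(X, y), k)
  rows <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f; te <- !tr
    if (!any(te)) return(NULL)
    if (length(unique(y[tr])) < 2)
      ab_stop("ab_single_class", sprintf("fold %d training split lost a class", f))
    sel <- if (select_within_folds)
      select_k(f_regression_rank(X[tr, , drop = FALSE], y[tr]), k)
    else sel_global
    m <- train_classifier(X[tr, sel$indices, drop = FALSE], y[tr],
                          kind = kind, seed = seed, threshold = threshold)
    pr <- predict(m, X[te, sel$indices, drop = FALSE], threshold = threshold)
    cm <- confusion(y[te], as.integer(pr$label == "approved"))
    data.frame(fold = f, t(cm),
               mcc = mcc(cm["tp"], cm["fp"], cm["tn"], cm["fn"]),
               sensitivity = if (cm["tp"] + cm["fn"] > 0)
                 cm["tp"] / (cm["tp"] + cm["fn"]) else NA_real_,
               specificity = if (cm["tn"] + cm["fp"] > 0)
                 cm["tn"] / (cm["tn"] + cm["fp"]) else NA_real_)
  })
  per_fold <- do.call(rbind, rows)
  mets <- c("mcc", "sensitivity", "specificity")
  list(per_fold = per_fold,
       mean = vapply(per_fold[mets], mean, numeric(1), na.rm = TRUE),
       sd = vapply(per_fold[mets], stats::sd, numeric(1), na.rm = TRUE))
}

#' Map selected feature indices to chain/grid-slot counts
#'
#' The histogram behind feature-location plots: how many selected features
#' fall on each (chain, Chothia slot). Counts sum to the selection size.
#'
#' @param selection a [select_k()] result (or integer indices).
#' @param layout a [layout_map()] data.frame.
#' @return data.frame `chain`, `slot`, `count` (only slots with count > 0).
#' @export
feature_positions <- function(selection, layout) {
  idx <- if (inherits(selection, "feature_selection")) selection$indices
         else as.integer(selection)
  pos <- match(idx, layout$index)
  if (anyNA(pos))
    ab_stop("ab_unknown_index", "selected index outside the layout map")
  key <- paste(layout$chain[pos], layout$slot[pos], sep = ":")
  tab <- table(key)
  out <- data.frame(chain = sub(":.*", "", names(tab)),
                    slot = sub(".*:", "", names(tab)),
                    count = as.integer(tab), row.names = NULL)
  stopifnot(sum(out$count) == length(idx))
  out
}
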