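# Machine-learning stage: z-score normalization with stored training
# moments, Fisher-discriminant-ratio feature scoring, NIPALS PLS2, the
# univariate-significance feature filter, SVM/KNN model search, the
# cross-validated 1,000-iteration AUC confidence loop, and external-cohort
# application.

#' Z-score normalization with retained training moments
#'
#' `zscore_fit()` standardizes each training column to mean 0 and (sample)
#' SD 1 and retains the per-feature mean and SD; `zscore_apply()` re-applies
#' those training moments verbatim to held-out or external rows.
#'
#' @param X numeric feature matrix (rows = subjects).
#' @return `zscore_fit()`: list with `center`, `scale` and the normalized
#'   matrix `X`; `zscore_apply()`: normalized matrix.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0))
    stop("constant feature(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  list(center = ctr, scale = scl,
       X = sweep(sweep(X, 2, ctr), 2, scl, "/"))
}

#' @rdname zscore_fit
#' @param fit a `zscore_fit()` result.
#' @param newX matrix to transform with the stored training moments.
#' @export
zscore_apply <- function(fit, newX) {
  newX <- as.matrix(newX)
  sweep(sweep(newX[, names(fit$center), drop = FALSE], 2, fit$center), 2,
        fit$scale, "/")
}

#' Fisher discriminant ratio per feature
#'
#' Univariate class-separability score `(mu1 - mu2)^2 / (var1 + var2)`
#' (summed class variances). The score is zero iff the class means are
#' equal, and invariant under a common affine transform of both classes.
#' Features are returned ranked by descending score; a feature whose two
#' class variances are both zero while the means differ has infinite
#' separation and is flagged.
#'
#' @param X numeric feature matrix.
#' @param y binary class labels.
#' @return data frame (one row per feature, ranked): `feature`, `mu1`,
#'   `mu2`, `var1`, `var2`, `score`, `infinite`.
#' @export
fdr_scores <- function(X, y) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  X <- as.matrix(X)
  a <- y == levels(y)[1]
  mu1 <- colMeans(X[a, , drop = FALSE]); mu2 <- colMeans(X[!a, , drop = FALSE])
  v1 <- apply(X[a, , drop = FALSE], 2, var)
  v2 <- apply(X[!a, , drop = FALSE], 2, var)
  denom <- v1 + v2
  score <- ifelse(denom == 0, ifelse(mu1 == mu2, 0, Inf),
                  (mu1 - mu2)^2 / denom)
  out <- data.frame(feature = colnames(X), mu1 = mu1, mu2 = mu2,
                    var1 = v1, var2 = v2, score = score,
                    infinite = is.infinite(score), row.names = NULL)
  out[order(-out$score), ]
}

#' NIPALS PLS2 decomposition
#'
#' Iterative-deflation partial least squares of paired blocks `X` (n x N)
#' and `Y` (n x M): `X = T P' + E`, `Y = U Q' + F`, with mutually orthogonal
#' X-score columns. `C` holds the Y-regression loadings (`Y ~ T C' +
#' residual`), used for projection-based prediction; `Q` the normalized
#' Y-block loadings of the printed decomposition.
#'
#' @param X,Y numeric matrices with the same row count (normalized
#'   upstream).
#' @param ncomp number of components `p <= min(n - 1, N)`.
#' @param tol,max_iter inner NIPALS convergence controls.
#' @return object of class `pls2_model` with `T`, `U`, `P`, `Q`, `C`, `W`,
#'   `E`, `F` (`Y - T C'`), `ncomp`.
#' @export
pls2_fit <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (ncomp > min(n - 1, ncol(X)))
    stop("ncomp must be <= min(n - 1, ncol(X))")
  Xd <- X; Yd <- Y
  Tm <- matrix(0, n, ncomp); Um <- matrix(0, n, ncomp)
  Pm <- matrix(0, ncol(X), ncomp); Qm <- matrix(0, ncol(Y), ncomp)
  Cm <- matrix(0, ncol(Y), ncomp); Wm <- matrix(0, ncol(X), ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2, var)), drop = TRUE]
    if (all(u == 0)) u <- Yd[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt); qn <- sqrt(sum(q^2))
      if (qn == 0) break
      q <- q / qn
      u <- Yd %*% q
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    tss <- sum(tt^2)
    if (tss < 1e-30) { ncomp <- a - 1; break }
    p <- crossprod(Xd, tt) / tss
    cc <- crossprod(Yd, tt) / tss
    Xd <- Xd - tcrossprod(tt, p)
    Yd <- Yd - tcrossprod(tt, cc)
    Tm[, a] <- tt; Um[, a] <- u; Pm[, a] <- p; Qm[, a] <- q
    Cm[, a] <- cc; Wm[, a] <- w
  }
  keep <- seq_len(ncomp)
  Tm <- Tm[, keep, drop = FALSE]; Um <- Um[, keep, drop = FALSE]
  Pm <- Pm[, keep, drop = FALSE]; Qm <- Qm[, keep, drop = FALSE]
  Cm <- Cm[, keep, drop = FALSE]; Wm <- Wm[, keep, drop = FALSE]
  structure(list(T = Tm, U = Um, P = Pm, Q = Qm, C = Cm, W = Wm,
                 E = Xd, F = Y - Tm %*% t(Cm), ncomp = ncomp,
                 X = X, Y = Y),
            class = "pls2_model")
}

#' Project new observations onto PLS2 scores
#'
#' Uses the standard direct projection `T_new = X_new W (P' W)^{-1}`;
#' projecting the training block reproduces the training scores.
#'
#' @param model a `pls2_model`.
#' @param X_new matrix in the training feature space (already normalized
#'   with the training moments).
#' @return score matrix (rows x ncomp).
#' @export
pls2_project <- function(model, X_new) {
  R <- model$W %*% solve(crossprod(model$P, model$W))
  as.matrix(X_new) %*% R
}

#' Select classifier training features
#'
#' Retains features whose pairwise pooled-t p-value is below `alpha`
#' (default 0.001); features with any missing value across subjects are
#' excluded beforehand. An empty selection is an error advising threshold
#' relaxation (the cross-validation loop instead falls back to the
#' top-ranked FDR feature so that every iteration can produce a model; see
#' the methods vignette).
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param alpha significance threshold (default 0.001).
#' @return character vector of selected feature names, ordered by
#'   descending FDR score.
#' @export
select_training_features <- function(X, y, alpha = 0.001) {
  X <- as.matrix(X)
  complete <- colnames(X)[!apply(X, 2, anyNA)]
  p <- pairwise_p(X[, complete, drop = FALSE], y)
  sel <- names(p)[!is.na(p) & p < alpha]
  if (!length(sel))
    stop("no feature passed the P < ", alpha,
         " univariate screen; consider relaxing the threshold")
  fd <- fdr_scores(X[, sel, drop = FALSE], y)
  as.character(fd$feature)
}

.select_with_fallback <- function(X, y, alpha) {
  tryCatch(select_training_features(X, y, alpha), error = function(e) {
    complete <- colnames(X)[!apply(X, 2, anyNA)]
    fd <- fdr_scores(X[, complete, drop = FALSE], y)
    as.character(fd$feature[1])
  })
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic: the probability that a random positive
#' scores above a random negative (ties counted half).
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels binary labels; `positive` names the positive class.
#' @param positive positive class label (default: second factor level).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Train one candidate classifier; returns a closure scoring new rows
# (higher = positive class) together with hard class predictions.
train_classifier <- function(X, y, method = "svm_linear", k = 5, cost = 1) {
  y <- factor(y)
  positive <- levels(y)[2]
  if (method %in% c("svm_linear", "svm_rbf")) {
    fit <- e1071::svm(x = X, y = y,
                      kernel = if (method == "svm_linear") "linear" else "radial",
                      cost = cost, scale = FALSE)
    predictor <- function(newX) {
      pr <- predict(fit, newX, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision values are oriented "level1/level2": positive favours level1
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      sc <- if (first == positive) dv[, 1] else -dv[, 1]
      list(scores = as.numeric(sc), class = as.character(pr))
    }
  } else if (method == "knn") {
    predictor <- function(newX) {
      pr <- class::knn(X, newX, y, k = k, prob = TRUE)
      pv <- attr(pr, "prob")
      sc <- ifelse(pr == positive, pv, 1 - pv)
      list(scores = as.numeric(sc), class = as.character(pr))
    }
  } else stop("unknown classifier method: ", method)
  list(method = method, k = k, cost = cost, positive = positive,
       predict = predictor)
}

#' Default classifier candidate grid
#'
#' Linear and RBF support-vector machines (unit cost) and k-nearest
#' neighbours with k in {1, 3, 5, 7}. Linear-discriminant and logistic
#' baselines can be appended by the caller.
#' @return list of candidate descriptors.
#' @export
default_candidates <- function() {
  c(list(list(method = "svm_linear", cost = 1),
         list(method = "svm_rbf", cost = 1)),
    lapply(c(1, 3, 5, 7), function(k) list(method = "knn", k = k)))
}

# Stratified train/test split indices: ~test_frac of each class, at least
# one test subject per class.
stratified_split <- function(y, test_frac = 0.2) {
  test <- integer(0)
  for (lv in levels(factor(y))) {
    idx <- which(y == lv)
    n_test <- max(1, round(length(idx) * test_frac))
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' Search the classifier grid for the best algorithm
#'
#' Evaluates every candidate by repeated stratified cross-validated AUC on
#' the training data and returns the argmax. Ties (within `tie_tol`) break
#' toward the simpler model: linear kernel before RBF before KNN, then
#' larger k.
#'
#' @param X normalized feature matrix.
#' @param y binary labels.
#' @param candidates candidate list ([default_candidates()]).
#' @param seed RNG seed (fixed seed gives an identical winner).
#' @param repeats number of random 80/20 evaluation splits per candidate.
#' @param tie_tol AUC margin treated as a tie.
#' @return list with `best` (winning candidate) and `table` (mean AUC per
#'   candidate).
#' @export
search_models <- function(X, y, candidates = default_candidates(), seed = 1,
                          repeats = 50, tie_tol = 1e-8) {
  set.seed(seed)
  y <- factor(y)
  res <- vapply(candidates, function(cand) {
    aucs <- replicate(repeats, {
      sp <- stratified_split(y, 0.2)
      if (length(unique(y[sp$train])) < 2) return(NA_real_)
      clf <- train_classifier(X[sp$train, , drop = FALSE], y[sp$train],
                              cand$method, k = cand$k %||% 5,
                              cost = cand$cost %||% 1)
      pr <- clf$predict(X[sp$test, , drop = FALSE])
      auc_score(pr$scores, y[sp$test], positive = clf$positive)
    })
    mean(aucs, na.rm = TRUE)
  }, 0)
  simplicity <- vapply(candidates, function(cand)
    switch(cand$method, svm_linear = 0, svm_rbf = 1, knn = 2 - (cand$k %||% 5) / 100,
           3), 0)
  best_auc <- max(res)
  tied <- which(res >= best_auc - tie_tol)
  best <- tied[order(simplicity[tied])][1]
  labels <- vapply(candidates, function(cand)
    paste0(cand$method, if (cand$method == "knn") paste0("_k", cand$k) else ""), "")
  list(best = candidates[[best]],
       table = data.frame(candidate = labels, mean_auc = res))
}

#' Cross-validated AUC confidence loop
#'
#' Repeats, for `iterations` (default 1,000) iterations: a re-randomized
#' stratified 80/20 split (the 20% test subset mirrors one fold of a
#' five-fold partition), feature normalization fitted on the 80% and applied
#' to the 20%, optional in-fold univariate `P < alpha` selection with FDR
#' ranking, classifier fit, and ROC-AUC plus accuracy on the held-out 20%.
#' Reports best, worst and mean AUC/accuracy over the loop.
#'
#' @param X raw (unnormalized) feature matrix.
#' @param y binary labels (at least 5 subjects per class).
#' @param method `"svm_linear"`, `"svm_rbf"` or `"knn"`.
#' @param iterations number of loop iterations.
#' @param seed RNG seed; the full loop is deterministic given the seed.
#' @param selection `"none"` (use all columns of `X`) or `"filter"`
#'   (univariate P < `alpha` screen inside each training split, falling back
#'   to the top-FDR feature when empty).
#' @param alpha selection threshold.
#' @param k,cost classifier hyperparameters.
#' @param test_frac held-out fraction per iteration (default 0.2).
#' @param max_features optional cap on the number of (FDR-ranked) selected
#'   features.
#' @param pair optional label for the report.
#' @return object of class `cv_report`.
#' @export
cv_confidence_loop <- function(X, y, method = "svm_linear", iterations = 1000,
                               seed = 1, selection = c("none", "filter"),
                               alpha = 0.001, k = 5, cost = 1,
                               test_frac = 0.2, max_features = Inf,
                               pair = NULL) {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2 || any(table(y) < 5))
    stop("need two classes with at least 5 subjects per class")
  set.seed(seed)
  aucs <- accs <- numeric(iterations)
  for (i in seq_len(iterations)) {
    repeat {
      sp <- stratified_split(y, test_frac)
      if (length(unique(y[sp$train])) == 2) break
    }
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    feats <- colnames(X)
    if (selection == "filter") {
      feats <- .select_with_fallback(Xtr, ytr, alpha)
      if (length(feats) > max_features) feats <- feats[seq_len(max_features)]
    }
    nz <- zscore_fit(Xtr[, feats, drop = FALSE])
    clf <- train_classifier(nz$X, ytr, method, k = k, cost = cost)
    Xte <- zscore_apply(nz, X[sp$test, feats, drop = FALSE])
    pr <- clf$predict(Xte)
    aucs[i] <- auc_score(pr$scores, y[sp$test], positive = clf$positive)
    accs[i] <- mean(pr$class == as.character(y[sp$test]))
  }
  structure(list(pair = pair %||% paste(levels(y), collapse = " vs "),
                 method = method, iterations = iterations, seed = seed,
                 best_auc = max(aucs), worst_auc = min(aucs),
                 mean_auc = mean(aucs), best_acc = max(accs),
                 worst_acc = min(accs), mean_acc = mean(accs)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s [%s, %d iterations, seed %d]\n", x$pair,
              x$method, x$iterations, x$seed))
  cat(sprintf("  AUC      best %.4f  worst %.4f  mean %.4f\n",
              x$best_auc, x$worst_auc, x$mean_auc))
  cat(sprintf("  accuracy best %.4f  worst %.4f  mean %.4f\n",
              x$best_acc, x$worst_acc, x$mean_acc))
  invisible(x)
}

#' Fit the full classification pipeline on one group pair
#'
#' Normalization, univariate selection with FDR ranking, and classifier fit
#' on the whole training sample; the fitted object retains the training
#' moments and selected features so it can be applied without refitting to
#' an external cohort ([external_validate()]).
#'
#' @param X raw feature matrix.
#' @param y binary labels.
#' @param method classifier method.
#' @param selection `"filter"` (P < `alpha` screen, default) or `"none"`.
#' @param alpha selection threshold.
#' @param k,cost classifier hyperparameters.
#' @return object of class `oculo_classifier`.
#' @export
fit_pipeline <- function(X, y, method = "svm_linear",
                         selection = c("filter", "none"), alpha = 0.001,
                         k = 5, cost = 1) {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  y <- factor(y)
  feats <- if (selection == "filter") .select_with_fallback(X, y, alpha)
           else colnames(X)
  nz <- zscore_fit(X[, feats, drop = FALSE])
  clf <- train_classifier(nz$X, y, method, k = k, cost = cost)
  resub <- clf$predict(nz$X)
  structure(list(features = feats, normalization = nz[c("center", "scale")],
                 classifier = clf, method = method, levels = levels(y),
                 resubstitution_auc = auc_score(resub$scores, y,
                                                positive = clf$positive)),
            class = "oculo_classifier")
}

#' Apply a fitted pipeline to an external cohort
#'
#' No refitting: external rows are transformed with the stored training mean
#' and SD and scored by the trained classifier.
#'
#' @param fit an `oculo_classifier` from [fit_pipeline()].
#' @param X_ext external feature matrix (same units as training).
#' @param y_ext external labels.
#' @return list with `auc` (NA when the external cohort contains a single
#'   class), per-subject `calls`, `scores` and the confusion table.
#' @export
external_validate <- function(fit, X_ext, y_ext) {
  X_ext <- as.matrix(X_ext)
  missing <- setdiff(fit$features, colnames(X_ext))
  if (length(missing))
    stop("external cohort lacks required feature(s): ",
         paste(missing, collapse = ", "))
  Xn <- sweep(sweep(X_ext[, fit$features, drop = FALSE], 2,
                    fit$normalization$center), 2, fit$normalization$scale, "/")
  pr <- fit$classifier$predict(Xn)
  auc <- if (length(unique(y_ext)) == 2)
    auc_score(pr$scores, y_ext, positive = fit$classifier$positive)
  else NA_real_  # single-class cohort: only per-subject calls are meaningful
  list(auc = auc, calls = pr$class, scores = pr$scores,
       confusion = table(truth = y_ext, call = pr$class))
}

#' Run the confidence loop for one group pair of a feature table
#'
#' Convenience wrapper reproducing the reported classifier evaluation:
#' restricts a feature table to two groups and the classifier-eligible
#' features, optionally performs the univariate selection once on the full
#' sample (`selection = "full"`, the publication-style flow) or inside every
#' training split (`selection = "fold"`, the leakage-guarded default), and
#' runs [cv_confidence_loop()].
#'
#' @param features feature data frame (with `group` column).
#' @param pair character vector of two group labels; the first is the
#'   positive (patient) class.
#' @param method classifier method.
#' @param iterations,seed loop controls.
#' @param selection `"fold"`, `"full"` or `"none"`.
#' @param alpha univariate threshold.
#' @param k,cost classifier hyperparameters.
#' @param feature_names candidate features (default:
#'   [classifier_features()] of the packaged profiles, intersected with the
#'   table); features with missing values are dropped.
#' @return a `cv_report` (with the selected feature set attached when
#'   `selection = "full"`).
#' @export
classify_pair <- function(features, pair, method = "svm_linear",
                          iterations = 1000, seed = 1,
                          selection = c("fold", "full", "none"),
                          alpha = 0.001, k = 5, cost = 1,
                          feature_names = NULL) {
  selection <- match.arg(selection)
  stopifnot(length(pair) == 2)
  if (is.null(feature_names))
    feature_names <- intersect(classifier_features(load_group_profiles()),
                               names(features))
  d <- features[features$group %in% pair, , drop = FALSE]
  X <- as.matrix(d[, feature_names, drop = FALSE])
  X <- X[, !apply(X, 2, anyNA), drop = FALSE]
  y <- factor(d$group, levels = rev(pair))  # second level = positive class
  sel_full <- NULL
  if (selection == "full") {
    sel_full <- .select_with_fallback(X, y, alpha)
    X <- X[, sel_full, drop = FALSE]
  }
  rep <- cv_confidence_loop(X, y, method = method, iterations = iterations,
                            seed = seed,
                            selection = if (selection == "fold") "filter" else "none",
                            alpha = alpha, k = k, cost = cost,
                            pair = paste(pair, collapse = " vs "))
  rep$selected_features <- sel_full
  rep
}
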