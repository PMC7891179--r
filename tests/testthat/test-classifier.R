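test_that("z-score normalization stores and re-applies the training moments", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  nz <- zscore_fit(X)
  expect_equal(unname(nz$X[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(nz$X), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(nz$X, 2, sd), c(a = 1, b = 1))
  # held-out rows use the training moments, not their own
  held <- zscore_apply(nz, cbind(a = 5, b = 10))
  expect_equal(unname(held[1, "a"]), (5 - 2) / 1)
  expect_error(zscore_fit(cbind(a = c(1, 1, 1))), "constant feature.*a")
})

test_that("Fisher discriminant ratio uses summed class variances and its invariances hold", {
  # mu1 = 1, mu2 = 0, var = 0.5 each -> (1-0)^2 / (0.5+0.5) = 1
  x1 <- c(0, 1, 2); x2 <- c(-1, 0, 1)   # var 1 each
  X <- cbind(f = c(x1 / sqrt(2) + 1 - mean(x1 / sqrt(2)),
                   x2 / sqrt(2) - mean(x2 / sqrt(2))))
  y <- rep(c("a", "b"), each = 3)
  sc <- fdr_scores(X, y)
  expect_equal(sc$score, 1, tolerance = 1e-12)

  # identical class distributions -> 0
  X0 <- cbind(f = c(1, 2, 3, 1, 2, 3))
  expect_equal(fdr_scores(X0, y)$score, 0)

  # invariance under a common affine transform
  set.seed(5)
  Xr <- cbind(f = rnorm(40, rep(c(0, 1), each = 20)))
  yr <- rep(c("a", "b"), each = 20)
  s1 <- fdr_scores(Xr, yr)$score
  s2 <- fdr_scores(3.7 * Xr - 11, yr)$score
  expect_equal(s1, s2, tolerance = 1e-10)

  # zero variances with distinct means: infinite separation is flagged
  Xi <- cbind(f = rep(c(0, 1), each = 3))
  sci <- fdr_scores(Xi, rep(c("a", "b"), each = 3))
  expect_true(sci$infinite)
})

test_that("PLS2 satisfies its decomposition identities and matches the SVD rank oracle", {
  set.seed(8)
  n <- 12; N <- 5
  X <- scale(matrix(rnorm(n * N), n, N))
  # identity target at full rank (rank from an SVD oracle): X and Y
  # residuals vanish
  r <- sum(svd(X)$d > 1e-8)
  m <- pls2_fit(X, X, ncomp = r)
  expect_lt(norm(m$E, "F") / norm(X, "F"), 1e-8)
  expect_lt(norm(m$F, "F") / norm(X, "F"), 1e-8)
  # decomposition identity X = T P' + E at any depth
  m2 <- pls2_fit(X, scale(matrix(rnorm(n * 2), n, 2)), ncomp = 3)
  expect_equal(m2$X, m2$T %*% t(m2$P) + m2$E, tolerance = 1e-10)
  # successive X-scores mutually orthogonal
  G <- crossprod(m2$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  # projecting the training block reproduces the scores
  expect_equal(pls2_project(m2, m2$X), m2$T, tolerance = 1e-8)
  expect_error(pls2_fit(X, X, ncomp = 40), "ncomp")

  # single component on exactly collinear data recovers the direction
  w_true <- c(3, -1, 2); w_true <- w_true / sqrt(sum(w_true^2))
  t_true <- rnorm(n)
  Xc <- outer(t_true, w_true)
  mc <- pls2_fit(Xc, cbind(t_true), ncomp = 1)
  expect_equal(abs(sum(mc$W[, 1] * w_true)), 1, tolerance = 1e-8)
})

test_that("PLS2 scores agree with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(9)
  X <- scale(matrix(rnorm(20 * 6), 20, 6))
  Y <- scale(matrix(rnorm(20 * 2), 20, 2))
  ours <- pls2_fit(X, Y, ncomp = 2)
  ref <- mixOmics::pls(X, Y, ncomp = 2, scale = FALSE, mode = "regression")
  expect_gt(abs(cor(ours$T[, 1], ref$variates$X[, 1])), 1 - 1e-6)
})

test_that("AUC is the Mann-Whitney statistic and flipping scores flips it", {
  sc <- c(0.9, 0.8, 0.4, 0.3, 0.2)
  y <- c("p", "p", "n", "p", "n")
  a <- auc_score(sc, y, positive = "p")
  expect_equal(a + auc_score(-sc, y, positive = "p"), 1)
  expect_equal(auc_score(c(1, 2, 3, 4), c("n", "n", "p", "p"), "p"), 1)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(a, ref)
})

test_that("the univariate screen keeps strong features, drops weak and missing ones", {
  set.seed(10)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(strong = rnorm(n, ifelse(y == "a", 0, 3)),
             weak = rnorm(n, ifelse(y == "a", 0, 0.4)),
             holey = rnorm(n))
  X[3, "holey"] <- NA
  sel <- select_training_features(X, y)
  expect_true("strong" %in% sel)
  expect_false("weak" %in% sel)     # p ~ 0.01-scale effect is excluded
  expect_false("holey" %in% sel)    # missing value -> excluded
  Xw <- X[, "weak", drop = FALSE]
  expect_error(select_training_features(Xw, y), "relaxing")
})

test_that("model search picks a perfect classifier on separable clouds, deterministically", {
  set.seed(12)
  n <- 30
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(x1 = rnorm(n, ifelse(y == "a", 0, 8)), x2 = rnorm(n))
  Xn <- zscore_fit(X)$X
  s1 <- search_models(Xn, y, seed = 99)
  s2 <- search_models(Xn, y, seed = 99)
  expect_identical(s1$best, s2$best)
  expect_equal(max(s1$table$mean_auc), 1)
  # label permutation: a single permuted data set retains a chance-level
  # empirical association, so the null is averaged over fresh permutations
  # (drawn up front: the loop reseeds the global RNG)
  set.seed(13)
  perms <- lapply(1:15, function(i) sample(y))
  null_aucs <- vapply(seq_along(perms), function(i)
    cv_confidence_loop(X, perms[[i]], method = "svm_linear",
                       iterations = 40, seed = i,
                       selection = "filter")$mean_auc, 0)
  expect_gt(mean(null_aucs), 0.42)   # wider band: x1 is strongly bimodal,
  expect_lt(mean(null_aucs), 0.58)   # so per-permutation AUCs spread more
})

test_that("the confidence loop reports ordered statistics and is seed-deterministic", {
  set.seed(14)
  n <- 30
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(x1 = rnorm(n, ifelse(y == "a", 0, 10)), x2 = rnorm(n))
  r <- cv_confidence_loop(X, y, iterations = 100, seed = 5)
  expect_lte(r$worst_auc, r$mean_auc)
  expect_lte(r$mean_auc, r$best_auc)
  expect_equal(c(r$best_auc, r$worst_auc, r$mean_auc), c(1, 1, 1))
  r2 <- cv_confidence_loop(X, y, iterations = 100, seed = 5)
  expect_identical(unclass(r)[c("best_auc", "worst_auc", "mean_auc",
                                "mean_acc")],
                   unclass(r2)[c("best_auc", "worst_auc", "mean_auc",
                                 "mean_acc")])
  expect_error(cv_confidence_loop(X[1:8, ], y[1:8]), "at least 5")
  expect_error(cv_confidence_loop(X[c(1:4, 16:19), ], y[c(1:4, 16:19)]),
               "at least 5")
})

test_that("external validation reuses training moments and degrades off-distribution", {
  pf <- load_group_profiles()
  d <- marginal_features(pf, c("AD", "control"), 18, 29, seed = 31)
  Xf <- as.matrix(d[, setdiff(names(d), "group")])
  fit <- fit_pipeline(Xf, factor(d$group, levels = c("control", "AD")),
                      method = "svm_linear")
  # external cohort = training cohort: AUC equals resubstitution AUC
  ext <- external_validate(fit, Xf, d$group)
  expect_equal(ext$auc, fit$resubstitution_auc)
  expect_error(external_validate(fit, Xf[, -1, drop = FALSE], d$group),
               "lacks required feature")

  # independent 15-subject patient sample: 15 calls
  ext_ad <- marginal_features(pf, c("AD", "control"), 15, 15, seed = 32)
  Xe <- as.matrix(ext_ad[, setdiff(names(ext_ad), "group")])
  out <- external_validate(fit, Xe[ext_ad$group == "AD", , drop = FALSE],
                           rep("AD", 15))
  expect_length(out$calls, 15)

  # a shifted (older, milder) external profile scores worse than an
  # in-distribution draw
  indist <- marginal_features(pf, c("AD", "control"), 18, 29, seed = 33)
  Xi <- as.matrix(indist[, setdiff(names(indist), "group")])
  auc_in <- external_validate(fit, Xi, indist$group)$auc
  shifted <- indist
  sel <- fit$features
  patients <- shifted$group == "AD"
  ctrl_mean <- colMeans(Xi[!patients, sel, drop = FALSE])
  # pull patients 90% of the way toward the control centroid: the decision
  # scores must shrink and the AUC must not improve
  Xs <- Xi
  Xs[patients, sel] <- sweep(0.1 * Xi[patients, sel, drop = FALSE], 2,
                             0.9 * ctrl_mean, "+")
  out_in <- external_validate(fit, Xi, indist$group)
  out_shift <- external_validate(fit, Xs, shifted$group)
  expect_lt(mean(out_shift$scores[patients]), mean(out_in$scores[patients]))
  expect_lte(out_shift$auc, auc_in)
})
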