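# Group-level univariate statistics: four-group ANOVA with Tukey post hoc
# contrasts, covariate-adjusted linear models, the sedative-intake screen,
# printed-table contrasts, and Spearman correlation panels.

#' One-way ANOVA with Tukey HSD pairwise contrasts
#'
#' @param values numeric outcome.
#' @param groups group labels (coerced to factor).
#' @return list with `F`, `p` (group effect), `means`, `sds`, `n`, and
#'   `pairwise`: data frame of group pairs with `mean_diff` (A minus B) and
#'   Tukey-adjusted `p`.
#' @export
anova_tukey <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("anova_tukey: need >= 2 groups with >= 2 observations each")
  if (all(tapply(values, groups, var) == 0) &&
      length(unique(tapply(values, groups, mean))) == 1)
    stop("anova_tukey: zero variance everywhere, F undefined")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(A = vapply(pairs, `[`, "", 1),
                   B = vapply(pairs, `[`, "", 2),
                   mean_diff = tk[, "diff"], p = tk[, "p adj"],
                   row.names = NULL)
  list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
       means = c(tapply(values, groups, mean)),
       sds = c(tapply(values, groups, sd)),
       n = as.vector(tab), pairwise = pw)
}

#' Covariate-adjusted group contrasts
#'
#' Linear model with the oculomotor parameter as dependent variable and age
#' and sex (optionally sedative count) as covariates; pairwise
#' covariate-adjusted p-values come from model-based contrasts of the
#' estimated marginal group means, without multiplicity adjustment (the
#' "adjusted" of the reported tables is covariate adjustment).
#'
#' @param values numeric outcome.
#' @param groups group labels.
#' @param age,sex covariates; `sex` is coded as a binary indicator.
#' @param sedatives optional sedative counts, included when the
#'   [sedative_screen()] flags the parameter.
#' @return list with the fitted `model` and `pairwise` data frame
#'   (`A`, `B`, `estimate` = adjusted mean difference A minus B, `p`).
#' @export
adjusted_model <- function(values, groups, age, sex, sedatives = NULL) {
  d <- data.frame(y = values, group = factor(groups), age = age,
                  sex = as.integer(factor(sex)) - 1L)
  form <- y ~ group + age + sex
  if (!is.null(sedatives)) {
    d$sedatives <- sedatives
    form <- y ~ group + age + sex + sedatives
  }
  d <- d[complete.cases(d), ]
  fit <- lm(form, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("adjusted_model: rank-deficient design, collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  em <- emmeans::emmeans(fit, "group")
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  pairs <- strsplit(as.character(ct$contrast), " - ", fixed = TRUE)
  list(model = fit,
       pairwise = data.frame(A = vapply(pairs, `[`, "", 1),
                             B = vapply(pairs, `[`, "", 2),
                             estimate = ct$estimate, p = ct$p.value))
}

#' Sedative-intake screen
#'
#' Spearman correlation between a parameter and the number of sedative drugs
#' taken; the count is included as a covariate in the adjusted model iff the
#' correlation is significant below `alpha` (default 0.1). Constant counts
#' make the correlation undefined and exclude the covariate.
#'
#' @param values numeric parameter values.
#' @param counts sedative counts (non-negative integers).
#' @param alpha screening level (default 0.1).
#' @return list with `include` (logical), `rho` and `p`.
#' @export
sedative_screen <- function(values, counts, alpha = 0.1) {
  stopifnot(all(counts >= 0, na.rm = TRUE))
  keep <- is.finite(values) & is.finite(counts)
  if (sum(keep) < 3 || length(unique(counts[keep])) < 2)
    return(list(include = FALSE, rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(cor.test(values[keep], counts[keep],
                                  method = "spearman", exact = FALSE))
  list(include = ct$p.value < alpha, rho = unname(ct$estimate),
       p = ct$p.value)
}

#' Mean difference between two groups
#'
#' `mean(A) - mean(B)` for a parameter, either from a feature table (one row
#' per subject) or directly from the packaged group-profile means, in which
#' case it reproduces the printed between-group contrasts.
#'
#' @param x a feature data frame with a `group` column, or a
#'   `group_profiles` object.
#' @param parameter parameter name.
#' @param A,B group labels (contrast is A minus B).
#' @return numeric mean difference on the parameter's scale.
#' @examples
#' pf <- load_group_profiles()
#' group_contrast(pf, "pursuit_error_h", "AD", "control")  # 2.92 deg
#' @export
group_contrast <- function(x, parameter, A, B) {
  if (inherits(x, "group_profiles"))
    return(unname(profile_param(x, A, parameter)[1] -
                  profile_param(x, B, parameter)[1]))
  stopifnot(is.data.frame(x), "group" %in% names(x), parameter %in% names(x))
  for (g in c(A, B)) if (!any(x$group == g)) stop("missing group: ", g)
  mean(x[[parameter]][x$group == A], na.rm = TRUE) -
    mean(x[[parameter]][x$group == B], na.rm = TRUE)
}

#' Spearman panel of oculomotor-neuropsychology correlations
#'
#' Spearman's rho and p per (feature, score) cell within each group, plus an
#' age-adjusted p from a linear model on the rank scale (documented choice:
#' rank-transformed feature and score with raw age as covariate).
#'
#' @param features feature data frame (with `group` and `age` columns).
#' @param feature_names oculomotor features to correlate.
#' @param score_names neuropsychological score columns.
#' @param min_pairs minimum paired observations per cell (default 5).
#' @return data frame with `group`, `feature`, `score`, `n`, `rho`, `p`,
#'   `p_adjusted`; cells with too few pairs are marked unavailable (NA).
#' @export
spearman_panel <- function(features, feature_names, score_names,
                           min_pairs = 5) {
  out <- list()
  for (g in unique(features$group)) {
    fg <- features[features$group == g, ]
    for (f in feature_names) for (s in score_names) {
      keep <- is.finite(fg[[f]]) & is.finite(fg[[s]]) & is.finite(fg$age)
      n <- sum(keep)
      row <- data.frame(group = g, feature = f, score = s, n = n,
                        rho = NA_real_, p = NA_real_, p_adjusted = NA_real_)
      if (n >= min_pairs) {
        ct <- suppressWarnings(cor.test(fg[[f]][keep], fg[[s]][keep],
                                        method = "spearman", exact = FALSE))
        row$rho <- unname(ct$estimate)
        row$p <- ct$p.value
        fit <- lm(rank(fg[[s]][keep]) ~ rank(fg[[f]][keep]) + fg$age[keep])
        row$p_adjusted <- summary(fit)$coefficients[2, 4]
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Full univariate statistics table
#'
#' For every oculomotor parameter: the four-group ANOVA with Tukey pairwise
#' contrasts (crude p), the sedative screen, and the age/sex(/sedative)
#' covariate-adjusted pairwise p-values — the analysis layout of the
#' published group-comparison tables.
#'
#' @param features feature data frame from [extract_features()] (must carry
#'   `group`, `age`, `sex`, `sedatives`).
#' @param parameters parameter columns to analyse (default: all oculomotor
#'   features present).
#' @return named list per parameter: `anova` ([anova_tukey()] result),
#'   `sedative_screen`, and `adjusted` ([adjusted_model()] pairwise frame).
#' @export
group_stat_table <- function(features, parameters = NULL) {
  if (is.null(parameters))
    parameters <- intersect(profile_params(load_group_profiles()),
                            names(features))
  out <- list()
  for (p in parameters) {
    v <- features[[p]]
    res <- list()
    res$anova <- tryCatch(anova_tukey(v, features$group), error = function(e) NULL)
    scr <- sedative_screen(v, features$sedatives)
    res$sedative_screen <- scr
    res$adjusted <- tryCatch(
      adjusted_model(v, features$group, features$age, features$sex,
                     sedatives = if (isTRUE(scr$include)) features$sedatives)$pairwise,
      error = function(e) NULL)
    out[[p]] <- res
  }
  out
}

#' Pairwise p-values for one two-group comparison
#'
#' Pooled-variance two-sample t-test per feature; the univariate screen used
#' to admit features into the classifier at significance `P < 0.001`.
#'
#' @param X numeric feature matrix (rows = subjects).
#' @param y binary class labels.
#' @return named numeric vector of p-values (NA for features with missing
#'   values or no variance).
#' @export
pairwise_p <- function(X, y) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  apply(X, 2, function(v) {
    if (anyNA(v)) return(NA_real_)
    a <- v[y == levels(y)[1]]; b <- v[y == levels(y)[2]]
    if (var(a) + var(b) == 0) return(NA_real_)
    t.test(a, b, var.equal = TRUE)$p.value
  })
}
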