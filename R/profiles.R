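# Group profiles: the packaged fixture of published group-level oculomotor
# distributions, name-based parameter lookup, and direct feature-vector
# sampling from the marginal truncated normals.

#' Load a packaged group-profile fixture
#'
#' Profiles bundle, for each diagnostic group (`control`, `AD`, `bvFTD`,
#' `svPPA`), the mean and SD of every reported oculomotor parameter, the
#' group size, demographics (age, sex, sedative intake, disease duration) and
#' neuropsychological summaries. They parameterize both the synthetic-trace
#' generator ([generate_cohort()]) and direct feature-vector sampling
#' ([sample_feature_matrix()]).
#'
#' @param fixture fixture name (currently `"default"`) or a path to a profile
#'   JSON file with the same schema.
#' @return object of class `group_profiles`.
#' @examples
#' pf <- load_group_profiles()
#' profile_param(pf, "control", "pro_latency_h")
#' @export
load_group_profiles <- function(fixture = "default") {
  path <- if (file.exists(fixture)) fixture else
    system.file("extdata", paste0("group_profiles", if (fixture == "default") ""
                                  else paste0("_", fixture), ".json"),
                package = "oculomark")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown profile fixture: ", fixture)
  pf <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_profiles(pf)
  structure(pf, class = "group_profiles")
}

# Success-probability parameters may be degenerate (SD 0, e.g. a group whose
# members all corrected every erroneous antisaccade); all other SDs must be
# positive.
validate_profiles <- function(pf) {
  stopifnot(is.list(pf$groups), length(pf$groups) >= 1)
  for (g in names(pf$groups)) {
    gr <- pf$groups[[g]]
    if (is.null(gr$n) || gr$n < 1) stop("profile ", g, ": n must be >= 1")
    for (p in names(gr$params)) {
      ms <- gr$params[[p]]
      if (length(ms) != 2 || !all(is.finite(ms)))
        stop("profile ", g, "/", p, ": expected [mean, sd]")
      degenerate_ok <- startsWith(p, "pct_")
      if (ms[2] < 0 || (!degenerate_ok && ms[2] <= 0))
        stop("profile ", g, "/", p, ": sd must be > 0")
    }
    pr <- group_probs(gr)
    if (any(pr < 0 | pr > 1)) stop("profile ", g, ": probabilities outside [0,1]")
  }
  invisible(pf)
}

group_probs <- function(gr) {
  c(p_correct_anti = gr$params$pct_correct_anti[1] / 100,
    p_corrected_anti = gr$params$pct_corrected_anti[1] / 100,
    p_correct_memory = gr$params$pct_correct_memory[1] / 100)
}

#' @export
print.group_profiles <- function(x, ...) {
  ns <- vapply(x$groups, function(g) g$n, 0)
  cat("<group_profiles> ", x$name, ": ",
      paste(sprintf("%s (n=%d)", names(ns), ns), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Look up one (group, parameter) cell of a profile
#'
#' @param profiles a `group_profiles` object.
#' @param group group label.
#' @param param parameter name; demographics (`"age"`, `"sedatives"`,
#'   `"disease_duration"`) and neuropsychological summaries (`"mmse"`, ...)
#'   are also resolvable. `"n"` returns the group size.
#' @return numeric `c(mean, sd)` (or a scalar for `"n"` / `"pct_female"`).
#' @export
profile_param <- function(profiles, group, param) {
  gr <- profiles$groups[[group]]
  if (is.null(gr)) stop("unknown group: ", group)
  if (param == "n") return(gr$n)
  if (param == "pct_female") return(gr$demographics$pct_female)
  for (block in list(gr$params, gr$demographics, gr$neuropsych)) {
    v <- block[[param]]
    if (!is.null(v)) return(c(mean = v[1], sd = v[2]))
  }
  stop("unknown parameter: ", param)
}

#' Parameter names of a profile fixture
#' @param profiles a `group_profiles` object.
#' @return character vector of oculomotor parameter names.
#' @export
profile_params <- function(profiles) names(profiles$groups[[1]]$params)

#' Classifier feature set
#'
#' Parameters eligible as classifier inputs. Parameters measured on
#' conditional trial subsets that can be empty for an impaired subject
#' (corrected-antisaccade latency, memory-saccade latency and endpoint
#' errors) are excluded up front because missing values cannot enter the
#' normalization; any remaining feature with a missing value is additionally
#' dropped at training time.
#'
#' @param profiles a `group_profiles` object.
#' @return character vector of feature names.
#' @export
classifier_features <- function(profiles) profiles$classifier_features

#' Truncation bounds for a parameter
#'
#' Physiological plausibility bounds used whenever a parameter is drawn from
#' its marginal truncated normal: percentages lie in \[0, 100\], latencies are
#' at least 80 ms (the anticipatory floor), pursuit gain lies in \[0, 1.5\],
#' signed endpoint errors keep their sign, and pursuit error is non-negative.
#'
#' @param param parameter name.
#' @return numeric `c(lower, upper)`.
#' @export
feature_bounds <- function(param) {
  if (startsWith(param, "pct_")) return(c(0, 100))
  if (grepl("latency", param)) return(c(80, Inf))
  if (grepl("gain", param)) return(c(0, 1.5))
  if (grepl("pos_error", param) || grepl("pursuit_error", param)) return(c(0, Inf))
  if (grepl("neg_error", param)) return(c(-Inf, 0))
  c(-Inf, Inf)
}

#' Sample feature vectors directly from a group's marginal distributions
#'
#' Draws each feature independently from a truncated normal with the group's
#' published mean and SD (bounds from [feature_bounds()]). This is the
#' marginal generative model used to exercise the classification stage; it
#' ignores between-feature correlation, an idealization discussed in the
#' methods vignette.
#'
#' @param profiles a `group_profiles` object.
#' @param group group label.
#' @param n number of subjects to draw.
#' @param features feature names (default: [classifier_features()]).
#' @return numeric matrix `n x length(features)`.
#' @export
sample_feature_matrix <- function(profiles, group, n,
                                  features = classifier_features(profiles)) {
  gr <- profiles$groups[[group]]
  if (is.null(gr)) stop("unknown group: ", group)
  out <- vapply(features, function(p) {
    ms <- gr$params[[p]]
    if (is.null(ms)) stop("feature not in profile: ", p)
    b <- feature_bounds(p)
    rtnorm(n, ms[1], ms[2], b[1], b[2])
  }, numeric(n))
  if (n == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, features))
  out
}
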