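# Shared helpers: independent oracles and lazily-built fixtures.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  v <- .fixture_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    .fixture_cache[[key]] <- v
  }
  v
}

# Brute-force saccade oracle: exhaustive threshold scan on unsmoothed
# finite differences. Independent of the package's smoothed detector; valid
# on noise-free traces only.
brute_saccades <- function(pos, fs, threshold = 30, min_amp = 1) {
  v <- diff(pos) * fs
  above <- abs(v) >= threshold
  if (!any(above)) return(data.frame(onset_ms = numeric(0),
                                     amplitude = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  out <- lapply(seq_len(nrow(runs)), function(k) {
    i1 <- runs[k, 1]; i2 <- runs[k, 2]
    # extend run to the flat flanks
    while (i1 > 1 && abs(v[i1 - 1]) > 1e-9) i1 <- i1 - 1
    while (i2 < length(v) && abs(v[i2 + 1]) > 1e-9) i2 <- i2 + 1
    amp <- pos[i2 + 1] - pos[i1]
    if (abs(amp) < min_amp) return(NULL)
    data.frame(onset_ms = (i1 - 1) * 1000 / fs, amplitude = amp)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) data.frame(onset_ms = numeric(0), amplitude = numeric(0))
  else out
}

# Analytic pursuit trial whose retained samples (after the detector's edge
# trimming) cover whole periods of the target sinusoid, so sample means of
# |eye - target| equal the continuous-time closed forms to quadrature
# accuracy.
make_pursuit_trial <- function(fs, A, f, eye_fun, cycles = 2) {
  nw <- max(3, round(50 * fs / 1000) + !(round(50 * fs / 1000) %% 2))
  half <- (nw - 1) / 2
  N <- 2 * (half + 1) + cycles * fs / f
  t <- (0:(N - 1)) * 1000 / fs
  target <- A * sin(2 * pi * f * t / 1000)
  structure(list(paradigm = "pursuit", plane = "horizontal",
                 eccentricity = A, fs = fs, end_ms = max(t), go_ms = 0,
                 go2_ms = NA, amp = A, freq = f,
                 trace = data.frame(t_ms = t, x_deg = eye_fun(target),
                                    y_deg = 0, valid = TRUE),
                 target = data.frame(t_ms = t, pos_deg = target)),
            class = "gaze_trial")
}

# Subject truth with hand-set latents (bypasses the profile sampler) for
# construction-level tests of synthesize_trial().
manual_truth <- function(latents, p_correct_anti = 1, p_corrected_anti = 1,
                         p_correct_memory = 1, early_rate = 0) {
  base <- c(pro_latency_h = 250, pro_latency_v = 250,
            return_latency_h = 250, return_latency_v = 250,
            anti_corrected_latency_h = 600, anti_corrected_latency_v = 600,
            mem_latency_h = 400, mem_latency_v = 400,
            pro_pos_error_h = 0.5, pro_pos_error_v = 0.5,
            pro_neg_error_h = -0.5, pro_neg_error_v = -0.5,
            anti_pos_error_h = 1, anti_pos_error_v = 1,
            anti_neg_error_h = -1, anti_neg_error_v = -1,
            mem_pos_error_h = 1, mem_pos_error_v = 1,
            mem_neg_error_h = -1, mem_neg_error_v = -1,
            pursuit_gain_h = 0.9, pursuit_gain_v = 0.9,
            pursuit_error_h = 2, pursuit_error_v = 2)
  base[names(latents)] <- latents
  list(latents = base, p_correct_anti = p_correct_anti,
       p_corrected_anti = p_corrected_anti,
       p_correct_memory = p_correct_memory, early_rate = early_rate)
}

# Marginal feature table for a two-group classifier run (the independent
# truncated-normal generative model of the published group distributions).
marginal_features <- function(profiles, pair, n1, n2, seed) {
  with_seed(seed, {
    X1 <- sample_feature_matrix(profiles, pair[1], n1)
    X2 <- sample_feature_matrix(profiles, pair[2], n2)
    d <- as.data.frame(rbind(X1, X2))
    d$group <- rep(pair, c(n1, n2))
    d
  })
}

# 200-subject-per-group synthetic cohort with its extracted features and
# generating truth; built once and shared by the acceptance tests.
recovery_cohort <- function() {
  cached("recovery", function() {
    pf <- load_group_profiles()
    coh <- generate_cohort(pf, sizes = c(control = 200, AD = 200,
                                         bvFTD = 200, svPPA = 200), seed = 1)
    list(features = extract_features(coh), truth = truth_features(coh))
  })
}
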