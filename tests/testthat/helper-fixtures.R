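# shared fixtures, computed once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# profile with all stochastic session inputs disabled
zero_noise_profile <- function(id = "z", status = "Healthy", ...) {
  subject_profile(
    id, status,
    base_styles = driving_styles(normal = list(turn_jitter_cv = 0),
                                 aggressive = list(turn_jitter_cv = 0)),
    noise = noise_params(0, 0, 0), ...
  )
}

default_cohort <- function() {
  cached("default_cohort", generate_cohort(cohort_config(), seed = 17))
}

default_features <- function() {
  cached("default_features", extract_feature_table(default_cohort()))
}

default_cv <- function() {
  cached("default_cv",
         suppressWarnings(cross_validate(default_features(), k = 4, seed = 17)))
}

highsep_cv <- function() {
  cached("highsep_cv", {
    coh <- generate_cohort(cohort_config(effect_size = 3,
                                         n_healthy = 20, n_mci = 20),
                           seed = 42)
    suppressWarnings(cross_validate(extract_feature_table(coh),
                                    k = 4, seed = 42))
  })
}

zeroeffect_cv <- function() {
  cached("zeroeffect_cv", {
    coh <- generate_cohort(cohort_config(effect_size = 0,
                                         n_healthy = 20, n_mci = 20),
                           seed = 42)
    suppressWarnings(cross_validate(extract_feature_table(coh),
                                    k = 4, seed = 42))
  })
}

# bare synced trace for detector unit tests
make_trace <- function(t, gz, speed = rep(0, length(t))) {
  structure(list(t = t, gz = gz, speed = speed), class = "synced_trace")
}

# bare session for io/sync unit tests
make_session <- function(imu, gps, subject_id = "x", condition = "normal") {
  structure(list(subject_id = subject_id, condition = condition,
                 imu = imu, gps = gps, truth = NULL, trajectory = NULL,
                 seed = NA),
            class = "sensor_session")
}
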