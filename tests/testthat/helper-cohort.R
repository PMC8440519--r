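# shared fixture builders

# an effect plan cycling through the four categories
make_effect_plan <- function(n, magnitude = 0.8) {
  cats <- change_categories()
  lapply(seq_len(n), function(i)
    planted_effect(i, cats[(i - 1) %% 4 + 1], magnitude))
}

# cohort spec with all confounds switched off (pure planted structure)
clean_spec <- function(..., seed = 1L) {
  cohort_spec(..., site_shift_sd = 0, age_slope_sd = 0, gender_shift_sd = 0,
              motion_outlier_fraction = 0, seed = seed)
}

# two-group toy matrix with a shift on selected features
two_group_matrix <- function(n_per_group, n_features, shift_features = integer(),
                             shift = 0, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(2 * n_per_group * n_features), 2 * n_per_group, n_features)
  m[seq_len(n_per_group), shift_features] <-
    m[seq_len(n_per_group), shift_features] + shift
  list(values = m, groups = rep(c("A", "B"), each = n_per_group))
}
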