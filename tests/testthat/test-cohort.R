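test_that("planted effects reproduce their standardized magnitudes", {
  plan <- list(planted_effect(1, "COMMON_DECREASE", 1.0),
               planted_effect(2, "SZ_UNIQUE_DECREASE", 0.8),
               planted_effect(3, "ASD_UNIQUE_DECREASE", 0.6))
  spec <- clean_spec(n_per_group_per_dataset = 250, n_features = 5,
                     dataset_types = c("sz", "sz", "asd", "asd"),
                     effect_plan = plan, asd_scale = 1, seed = 21)
  ch <- generate_cohort(spec)
  gm <- function(g, j) mean(ch$measures[ch$covariates$group == g, j])
  n_sz <- sum(ch$covariates$group == "SZ")
  n_hc <- sum(ch$covariates$group == "HC")
  se <- sqrt(1 / n_sz + 1 / n_hc)
  # lambda = 1 common decrease: both disorders sit one sd below HC
  expect_lt(abs(gm("HC", 1) - gm("SZ", 1) - 1.0), 3 * se)
  expect_lt(abs(gm("HC", 1) - gm("ASD", 1) - 1.0), 3 * se)
  # unique categories flip sign between the disorders
  expect_lt(abs(gm("HC", 2) - gm("SZ", 2) - 0.8), 3 * se)
  expect_lt(abs(gm("HC", 2) - gm("ASD", 2) + 0.8), 3 * se)
  expect_lt(abs(gm("HC", 3) - gm("ASD", 3) - 0.6), 3 * se)
  expect_lt(abs(gm("HC", 3) - gm("SZ", 3) + 0.6), 3 * se)
  # null features show no group separation beyond sampling error
  expect_lt(abs(gm("HC", 5) - gm("SZ", 5)), 3 * se)
})

test_that("asd_scale scales the ASD shift within common categories", {
  plan <- list(planted_effect(1, "COMMON_INCREASE", 1.0))
  spec <- clean_spec(n_per_group_per_dataset = 250, n_features = 2,
                     dataset_types = c("sz", "sz", "asd", "asd"),
                     effect_plan = plan, asd_scale = 0.5, seed = 8)
  ch <- generate_cohort(spec)
  gm <- function(g) mean(ch$measures[ch$covariates$group == g, 1])
  expect_lt(abs(gm("SZ") - gm("HC") - 1.0), 0.2)
  expect_lt(abs(gm("ASD") - gm("HC") - 0.5), 0.2)
})

test_that("the generator is deterministic in the seed", {
  spec <- cohort_spec(n_per_group_per_dataset = 20, n_features = 10,
                      effect_plan = make_effect_plan(4), seed = 77)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$measures, b$measures)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_cohort(cohort_spec(n_per_group_per_dataset = 20,
                                    n_features = 10,
                                    effect_plan = make_effect_plan(4),
                                    seed = 78))
  expect_false(identical(a$measures, c2$measures))
})

test_that("age and dataset confounds are recoverable when planted", {
  spec <- cohort_spec(n_per_group_per_dataset = 100, n_features = 30,
                      dataset_types = c("sz", "asd"),
                      site_shift_sd = 1, age_slope_sd = 0.1,
                      noise_sd = 0.5, seed = 31)
  ch <- generate_cohort(spec)
  slopes <- attr(ch$truth, "age_slopes")
  # regressing each feature on age within one dataset recovers the slope
  d1 <- ch$covariates$dataset == "ds01"
  est <- apply(ch$measures[d1, ], 2, function(y)
    coef(lm(y ~ ch$covariates$age[d1]))[2])
  expect_gt(cor(est, slopes), 0.8)
  # dataset offsets show up as mean differences once the age confound
  # (datasets differ in mean age by design) is accounted for
  offs <- attr(ch$truth, "dataset_offsets")
  age_gap <- mean(ch$covariates$age[d1]) - mean(ch$covariates$age[!d1])
  dmeans <- apply(ch$measures, 2, function(y) mean(y[d1]) - mean(y[!d1])) -
    age_gap * slopes
  expect_gt(cor(dmeans, offs[1, ] - offs[2, ]), 0.8)
})

test_that("spec validation rejects bad inputs", {
  expect_error(cohort_spec(n_per_group_per_dataset = 0), "n_per_group")
  expect_error(cohort_spec(asd_scale = 0), "asd_scale")
  expect_error(cohort_spec(asd_scale = 1.5), "asd_scale")
  expect_error(cohort_spec(dataset_types = c("sz", "sz")), "asd")
  expect_error(cohort_spec(effect_plan = list(
    planted_effect(1, "COMMON_DECREASE", 1),
    planted_effect(1, "COMMON_INCREASE", 1))), "distinct")
  expect_error(cohort_spec(n_features = 5, effect_plan = list(
    planted_effect(9, "COMMON_DECREASE", 1))), "exceeds")
  expect_error(cohort_spec(symptom_coupling = list(
    panss_positive = c(f9999 = 1)), n_features = 5), "missing features")
  expect_error(planted_effect(1, "SOMETHING_ELSE", 1))
})

test_that("network time series realize planted latent correlations", {
  plan <- data.frame(i = 1, j = 2, r_hc = 0.5, r_sz = 0.1, r_asd = 0.3)
  spec <- clean_spec(n_per_group_per_dataset = 75, n_features = 2,
                     dataset_types = c("sz", "sz", "asd", "asd"),
                     n_networks = 6, n_timepoints = 150,
                     fnc_edge_plan = plan, seed = 5)
  ts <- generate_network_timeseries(spec)
  edge_r <- function(g) {
    ids <- ts$covariates$subject_id[ts$covariates$group == g]
    mean(vapply(ids, function(s)
      cor(ts$subjects[[s]]$series[1, ], ts$subjects[[s]]$series[2, ]),
      numeric(1)))
  }
  expect_lt(abs(edge_r("HC") - 0.5), 0.05)
  expect_lt(abs(edge_r("SZ") - 0.1), 0.05)
  expect_lt(abs(edge_r("ASD") - 0.3), 0.05)
  # unplanted edges stay near zero
  ids <- head(ts$covariates$subject_id, 50)
  off <- mean(vapply(ids, function(s)
    cor(ts$subjects[[s]]$series[3, ], ts$subjects[[s]]$series[4, ]),
    numeric(1)))
  expect_lt(abs(off), 0.05)
})

test_that("motion outliers carry a >3 mm transition in their traces", {
  spec <- cohort_spec(n_per_group_per_dataset = 10, n_features = 2,
                      dataset_types = c("sz", "asd"), n_networks = 3,
                      n_timepoints = 130, motion_outlier_fraction = 0.2,
                      seed = 13)
  ts <- generate_network_timeseries(spec)
  out_ids <- ts$covariates$subject_id[ts$covariates$motion_trans_mm > 3]
  expect_gt(length(out_ids), 0)
  for (s in out_ids) {
    m <- ts$subjects[[s]]$motion["trans_x", ]
    expect_gt(max(abs(diff(m))), 3)
  }
})

test_that("degenerate time-series requests error", {
  spec <- cohort_spec(n_per_group_per_dataset = 4, dataset_types = c("sz", "asd"))
  spec$n_timepoints <- 2L
  expect_error(generate_network_timeseries(spec), "timepoints")
})

test_that("qc volume fixtures match their truth labels", {
  qv <- generate_qc_volumes(15, 1, seed = 3)
  rep <- qc_fmri_pipeline(qv$volumes)
  expect_identical(rep$report$pass, qv$truth)
  # a half-grid translation destroys the whole-mask correlation
  good <- individual_mask_fmri(qv$volumes[[1]])
  dims <- dim(qv$volumes[[1]])
  shifted <- array(0, dims)
  shifted[, , seq_len(dims[3] / 2)] <- qv$volumes[[1]][, , dims[3] / 2 + seq_len(dims[3] / 2)]
  shifted[shifted == 0] <- 0.01
  bad <- individual_mask_fmri(shifted)
  expect_lt(slab_correlations(bad, good)$r_whole, 0.8)
  # identical volumes correlate perfectly everywhere
  sc <- slab_correlations(good, good)
  expect_equal(c(sc$r_top, sc$r_bottom, sc$r_whole), c(1, 1, 1))
  expect_error(generate_qc_volumes(0, 0), "at least one")
})

test_that("symptom scores follow their planted couplings", {
  spec <- clean_spec(n_per_group_per_dataset = 200, n_features = 4,
                     dataset_types = c("sz", "asd"), seed = 17)
  ch <- generate_cohort(spec)
  # negative coupling recovered with the right sign and significance
  sym <- generate_symptoms(ch$measures, ch$covariates,
                           coupling = list(panss_positive = c(f0001 = -0.5)),
                           noise_sd = 1, seed = 2)
  sz <- sym[sym$group == "SZ", ]
  ct <- cor.test(ch$measures[sz$subject_id, "f0001"], sz$panss_positive)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # zero coupling: scores uncorrelated with any feature
  sym0 <- generate_symptoms(ch$measures, ch$covariates,
                            coupling = list(ados_total = c(f0002 = 0)),
                            noise_sd = 1, seed = 3)
  asd <- sym0[sym0$group == "ASD", ]
  expect_gt(cor.test(ch$measures[asd$subject_id, "f0002"],
                     asd$ados_total)$p.value, 0.01)
  # vanishing noise drives |r| toward 1
  sym1 <- generate_symptoms(ch$measures, ch$covariates,
                            coupling = list(srs = c(f0003 = 1)),
                            noise_sd = 1e-6, seed = 4)
  asd1 <- sym1[sym1$group == "ASD", ]
  expect_gt(abs(cor(ch$measures[asd1$subject_id, "f0003"], asd1$srs)), 0.999)
  expect_error(generate_symptoms(ch$measures, ch$covariates,
                                 coupling = list(panss_positive = c(f9999 = 1))),
               "absent")
})

test_that("cohort TSV round-trips through disk", {
  spec <- clean_spec(n_per_group_per_dataset = 5, n_features = 3,
                     dataset_types = c("sz", "asd"), seed = 2)
  ch <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort_tsv(ch, dir)
  back <- read_cohort_tsv(file.path(dir, "measures.tsv"))
  expect_equal(unname(back$measures), unname(ch$measures), tolerance = 1e-8)
  expect_identical(back$covariates$group, ch$covariates$group)
})
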