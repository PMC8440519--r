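#' Planted group-difference effect
#'
#' Describes one feature carrying a true group difference. `magnitude`
#' is the standardized shift applied to the SZ group relative to HC;
#' the ASD shift is `asd_scale * magnitude` with the same sign for the
#' common categories and the opposite sign for the unique categories.
#'
#' @param feature_id 1-based feature index.
#' @param category one of `"COMMON_DECREASE"`, `"COMMON_INCREASE"`,
#'   `"SZ_UNIQUE_DECREASE"`, `"ASD_UNIQUE_DECREASE"`.
#' @param magnitude positive standardized effect size in the SZ group.
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(feature_id, category, magnitude) {
  category <- match.arg(category, change_categories())
  stopifnot(is.numeric(feature_id), feature_id >= 1,
            is.numeric(magnitude), magnitude >= 0)
  structure(list(feature_id = as.integer(feature_id),
                 category = category,
                 magnitude = as.numeric(magnitude)),
            class = "planted_effect")
}

#' The four change categories
#' @return character vector of the four category names.
#' @export
change_categories <- function() {
  c("COMMON_DECREASE", "COMMON_INCREASE",
    "SZ_UNIQUE_DECREASE", "ASD_UNIQUE_DECREASE")
}

#' Synthetic cohort specification
#'
#' Full parameterization of the synthetic multi-dataset cohort
#' generator. The default layout mirrors the study design the
#' statistical pipeline targets: four datasets contributing HC and SZ
#' subjects and two datasets contributing HC and ASD subjects, sites
#' nested within dataset, and confounds (dataset offsets, age slopes,
#' gender shifts) acting additively on standard-Gaussian baseline
#' features.
#'
#' @param n_per_group_per_dataset subjects per group per dataset.
#' @param n_features number of features (e.g. FNC edges).
#' @param dataset_types character vector, one of `"sz"`/`"asd"` per
#'   dataset: an `"sz"` dataset holds HC+SZ, an `"asd"` dataset HC+ASD.
#' @param n_networks number of networks for the time-series generator.
#' @param n_timepoints timepoints per scan.
#' @param tr sampling interval in seconds.
#' @param effect_plan list of [planted_effect()] objects; feature ids
#'   must be distinct.
#' @param asd_scale lambda in (0, 1]: ASD effect = lambda x SZ effect,
#'   encoding overall weaker changes in ASD.
#' @param site_shift_sd sd of per-(dataset, feature) additive offsets.
#' @param age_slope_sd sd of per-feature age slopes (per year of
#'   centered age).
#' @param gender_shift_sd sd of per-feature additive shifts for the
#'   gender = 1 code.
#' @param noise_sd residual sd of the baseline Gaussian.
#' @param sites_per_dataset number of sites nested in each dataset.
#' @param symptom_coupling named list: score name -> named numeric
#'   vector of feature coefficients (names are feature ids).
#' @param motion_outlier_fraction fraction of subjects given head
#'   motion exceeding the 3 mm screening limit.
#' @param fnc_edge_plan optional data.frame with columns `i`, `j`,
#'   `r_hc`, `r_sz`, `r_asd`: latent correlations planted on network
#'   pairs for the time-series generator.
#' @param seed integer RNG seed; identical specs give identical cohorts.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group_per_dataset = 150,
                        n_features = 200,
                        dataset_types = c("sz", "sz", "sz", "sz", "asd", "asd"),
                        n_networks = 53,
                        n_timepoints = 150,
                        tr = 2,
                        effect_plan = list(),
                        asd_scale = 0.5,
                        site_shift_sd = 0.3,
                        age_slope_sd = 0.02,
                        gender_shift_sd = 0.1,
                        noise_sd = 1,
                        sites_per_dataset = 2,
                        symptom_coupling = list(),
                        motion_outlier_fraction = 0,
                        fnc_edge_plan = NULL,
                        seed = 1L) {
  stopifnot(n_per_group_per_dataset >= 1, n_features >= 1,
            length(dataset_types) >= 2,
            all(dataset_types %in% c("sz", "asd")),
            n_networks >= 1, n_timepoints > 2, tr > 0,
            asd_scale > 0, asd_scale <= 1,
            site_shift_sd >= 0, age_slope_sd >= 0, gender_shift_sd >= 0,
            noise_sd > 0, sites_per_dataset >= 1,
            motion_outlier_fraction >= 0, motion_outlier_fraction < 1)
  if (!any(dataset_types == "sz") || !any(dataset_types == "asd"))
    stop("need at least one 'sz' and one 'asd' dataset to cover all three groups")
  ids <- vapply(effect_plan, function(e) e$feature_id, integer(1))
  if (anyDuplicated(ids)) stop("effect features must be distinct")
  if (length(ids) && max(ids) > n_features)
    stop("effect feature id exceeds n_features")
  for (sc in symptom_coupling) {
    if (is.null(names(sc)) || !all(feature_index(names(sc)) <= n_features))
      stop("symptom_coupling references missing features")
  }
  structure(list(
    n_per_group_per_dataset = as.integer(n_per_group_per_dataset),
    n_features = as.integer(n_features),
    dataset_types = dataset_types,
    n_networks = as.integer(n_networks),
    n_timepoints = as.integer(n_timepoints),
    tr = tr,
    effect_plan = effect_plan,
    asd_scale = asd_scale,
    site_shift_sd = site_shift_sd,
    age_slope_sd = age_slope_sd,
    gender_shift_sd = gender_shift_sd,
    noise_sd = noise_sd,
    sites_per_dataset = as.integer(sites_per_dataset),
    symptom_coupling = symptom_coupling,
    motion_outlier_fraction = motion_outlier_fraction,
    fnc_edge_plan = fnc_edge_plan,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

feature_name <- function(i) sprintf("f%04d", i)
feature_index <- function(nm) as.integer(sub("^f", "", nm))

# SZ/ASD additive shifts implied by a planted effect under scale lambda
effect_shifts <- function(effect, lambda) {
  m <- effect$magnitude
  switch(effect$category,
    COMMON_DECREASE    = c(sz = -m, asd = -lambda * m),
    COMMON_INCREASE    = c(sz = +m, asd = +lambda * m),
    SZ_UNIQUE_DECREASE = c(sz = -m, asd = +lambda * m),
    ASD_UNIQUE_DECREASE = c(sz = +m, asd = -lambda * m))
}
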