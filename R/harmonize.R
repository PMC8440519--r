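#' Step 1: regress covariates within each dataset
#'
#' Per dataset, each feature is regressed by OLS on age (z-scored
#' within the dataset), gender, site dummies, and the age x site and
#' gender x site interactions; the residuals are returned with the
#' dataset-wise intercept retained, so dataset offsets remain for the
#' dataset-effect steps. Aliased design columns are dropped
#' deterministically (rank-deficient fits keep the first columns in
#' declaration order); a dataset with a single site loses its site
#' terms.
#'
#' @param values subjects x features matrix.
#' @param covariates data.frame with `dataset`, `site`, `age`,
#'   `gender`, row-aligned with `values`.
#' @return matrix of the same shape.
#' @export
regress_within_dataset <- function(values, covariates) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(covariates))
  out <- values
  for (d in unique(covariates$dataset)) {
    idx <- which(covariates$dataset == d)
    if (length(idx) < 2L) stop("dataset ", d, " has fewer than 2 subjects")
    cv <- covariates[idx, , drop = FALSE]
    age_sd <- sd(cv$age)
    age_z <- if (is.na(age_sd) || age_sd == 0) rep(0, length(idx))
             else (cv$age - mean(cv$age)) / age_sd
    gender <- as.numeric(cv$gender)
    site <- factor(cv$site)
    X <- if (nlevels(site) >= 2L)
      model.matrix(~ age_z * site + gender * site,
                   data = data.frame(age_z = age_z, gender = gender, site = site))
    else
      model.matrix(~ age_z + gender,
                   data = data.frame(age_z = age_z, gender = gender))
    fit <- lm.fit(X, values[idx, , drop = FALSE])
    coefs <- fit$coefficients
    if (!is.matrix(coefs))
      coefs <- matrix(coefs, ncol = 1, dimnames = list(names(coefs), NULL))
    intercept <- coefs["(Intercept)", ]
    intercept[is.na(intercept)] <- 0
    # residuals + intercept term: remove covariate effects, keep level
    out[idx, ] <- fit$residuals + rep(intercept, each = length(idx))
  }
  out
}

#' Step 2: estimate dataset effects from healthy controls
#'
#' The dataset effect of a feature is the mean of the step-1 residuals
#' over that dataset's HC subjects, minus the grand mean over all HC
#' subjects pooled. Estimating on HCs only keeps patient-vs-control
#' contrasts unbiased when case/control composition differs by dataset.
#'
#' @param values step-1 output matrix.
#' @param covariates data.frame with `dataset` and `group`.
#' @return datasets x features offset matrix (rownames = dataset ids).
#' @export
estimate_dataset_effects <- function(values, covariates) {
  values <- as.matrix(values)
  hc <- covariates$group == "HC"
  datasets <- unique(covariates$dataset)
  for (d in datasets)
    if (!any(hc & covariates$dataset == d))
      stop("dataset ", d, " has no HC subjects")
  grand <- colMeans(values[hc, , drop = FALSE])
  off <- matrix(NA_real_, length(datasets), ncol(values),
                dimnames = list(datasets, colnames(values)))
  for (d in datasets)
    off[d, ] <- colMeans(values[hc & covariates$dataset == d, ,
                                drop = FALSE]) - grand
  off
}

#' Step 3: remove dataset effects from every subject
#'
#' Subtracts each subject's dataset offset (HC-derived) from all
#' features, for patients and controls alike.
#'
#' @param values matrix; `covariates` must carry `dataset`.
#' @param offsets matrix from [estimate_dataset_effects()].
#' @param covariates subject roster.
#' @return corrected matrix.
#' @export
remove_dataset_effects <- function(values, offsets, covariates) {
  values <- as.matrix(values)
  idx <- match(covariates$dataset, rownames(offsets))
  if (anyNA(idx)) stop("unknown dataset id in covariates")
  out <- values - offsets[idx, , drop = FALSE]
  dimnames(out) <- dimnames(values)
  out
}

#' Three-step harmonization
#'
#' Runs within-dataset covariate regression, HC-based dataset-effect
#' estimation, and dataset-effect removal in sequence.
#'
#' @param values subjects x features matrix.
#' @param covariates roster with `dataset`, `site`, `age`, `gender`,
#'   `group`.
#' @return harmonized matrix.
#' @export
harmonize_measures <- function(values, covariates) {
  step1 <- regress_within_dataset(values, covariates)
  offs <- estimate_dataset_effects(step1, covariates)
  remove_dataset_effects(step1, offs, covariates)
}
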