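#' Generate a synthetic multi-dataset cohort
#'
#' Draws a subjects x features measure matrix from a standard Gaussian
#' baseline plus planted group shifts, per-(dataset, feature) offsets,
#' age and gender effects, and residual noise. SZ-style datasets hold
#' HC and SZ subjects; ASD-style datasets hold HC and ASD subjects,
#' mirroring a multi-site case-control design where the two disorders
#' are never scanned at the same site. ASD subjects are drawn younger
#' than SZ subjects so that an age confound is present by default.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort` list with elements:
#'   \describe{
#'     \item{measures}{numeric matrix, subjects x features.}
#'     \item{covariates}{data.frame: subject_id, group, dataset, site,
#'       age, gender, motion_trans_mm, motion_rot_deg, n_timepoints.}
#'     \item{truth}{data.frame of per-feature true category and the
#'       SZ/ASD shifts actually applied (category `"NONE"` for null
#'       features); attributes carry dataset offsets, age slopes and
#'       gender shifts.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    cov <- cohort_covariates(spec)
    n <- nrow(cov)
    p <- spec$n_features

    values <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p,
                     dimnames = list(cov$subject_id, feature_name(seq_len(p))))

    truth <- data.frame(feature = feature_name(seq_len(p)),
                        category = "NONE", magnitude = 0,
                        sz_shift = 0, asd_shift = 0,
                        stringsAsFactors = FALSE)
    for (e in spec$effect_plan) {
      sh <- effect_shifts(e, spec$asd_scale)
      j <- e$feature_id
      values[cov$group == "SZ", j] <- values[cov$group == "SZ", j] + sh["sz"]
      values[cov$group == "ASD", j] <- values[cov$group == "ASD", j] + sh["asd"]
      truth[j, c("category", "magnitude", "sz_shift", "asd_shift")] <-
        list(e$category, e$magnitude, sh[["sz"]], sh[["asd"]])
    }

    n_ds <- length(spec$dataset_types)
    ds_offsets <- matrix(rnorm(n_ds * p, sd = spec$site_shift_sd), n_ds, p,
                         dimnames = list(dataset_name(seq_len(n_ds)), NULL))
    age_slopes <- rnorm(p, sd = spec$age_slope_sd)
    gender_shifts <- rnorm(p, sd = spec$gender_shift_sd)

    ds_idx <- match(cov$dataset, rownames(ds_offsets))
    values <- values + ds_offsets[ds_idx, , drop = FALSE]
    age_c <- cov$age - mean(cov$age)
    values <- values + outer(age_c, age_slopes)
    values <- values + outer(cov$gender, gender_shifts)

    attr(truth, "dataset_offsets") <- ds_offsets
    attr(truth, "age_slopes") <- age_slopes
    attr(truth, "gender_shifts") <- gender_shifts

    structure(list(measures = values, covariates = cov, truth = truth,
                   spec = spec),
              class = "cohort")
  })
}

dataset_name <- function(i) sprintf("ds%02d", i)

# subject roster with demographics and motion summaries
cohort_covariates <- function(spec) {
  rows <- list()
  npg <- spec$n_per_group_per_dataset
  for (d in seq_along(spec$dataset_types)) {
    groups <- c("HC", if (spec$dataset_types[d] == "sz") "SZ" else "ASD")
    for (g in groups) {
      young <- spec$dataset_types[d] == "asd"
      age <- if (young) pmax(6, rnorm(npg, 15, 5)) else pmax(18, rnorm(npg, 35, 10))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g,
        dataset = dataset_name(d),
        site = paste0(dataset_name(d), "_s",
                      sample.int(spec$sites_per_dataset, npg, replace = TRUE)),
        age = age,
        gender = rbinom(npg, 1, 0.5),
        stringsAsFactors = FALSE)
    }
  }
  cov <- do.call(rbind, rows)
  n <- nrow(cov)
  cov$subject_id <- sprintf("sub%05d", seq_len(n))
  # benign motion by default; flagged outliers exceed the 3 mm limit
  cov$motion_trans_mm <- runif(n, 0.1, 1.5)
  cov$motion_rot_deg <- runif(n, 0.1, 1.5)
  n_out <- floor(spec$motion_outlier_fraction * n)
  if (n_out > 0) {
    out <- sample.int(n, n_out)
    cov$motion_trans_mm[out] <- runif(n_out, 3.5, 6)
  }
  cov$n_timepoints <- rep(spec$n_timepoints, n)
  cov[, c("subject_id", "group", "dataset", "site", "age", "gender",
          "motion_trans_mm", "motion_rot_deg", "n_timepoints")]
}

# evaluate expr with a local RNG seed, restoring caller state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate per-subject network time series
#'
#' Draws each subject's K x T network time series from a group-specific
#' latent covariance: identity plus the correlations planted on network
#' pairs by `spec$fnc_edge_plan`. Six motion regressor traces are
#' attached per subject; subjects flagged as motion outliers carry a
#' translation excursion above 3 mm.
#'
#' @param spec a [cohort_spec()]; `n_timepoints` must exceed 2.
#' @param covariates optional subject roster (defaults to the roster
#'   `generate_cohort(spec)` would produce, drawn under the same seed).
#' @return list with `subjects` (list of per-subject lists holding
#'   `series` (K x T), `motion` (6 x T), `tr`), and `covariates`.
#' @export
generate_network_timeseries <- function(spec, covariates = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_timepoints <= 2) stop("need more than 2 timepoints")
  with_seed(spec$seed + 1L, {
    cov <- if (is.null(covariates)) cohort_covariates(spec) else covariates
    K <- spec$n_networks
    Tn <- spec$n_timepoints
    plan <- spec$fnc_edge_plan
    sigma <- list()
    for (g in c("HC", "SZ", "ASD")) {
      S <- diag(K)
      if (!is.null(plan)) {
        r <- plan[[paste0("r_", tolower(g))]]
        for (k in seq_len(nrow(plan)))
          S[plan$i[k], plan$j[k]] <- S[plan$j[k], plan$i[k]] <- r[k]
      }
      ch <- tryCatch(chol(S), error = function(e)
        stop("planted edge correlations do not form a positive-definite covariance"))
      sigma[[g]] <- ch
    }
    subjects <- lapply(seq_len(nrow(cov)), function(s) {
      ch <- sigma[[cov$group[s]]]
      series <- crossprod(ch, matrix(rnorm(K * Tn), K, Tn))
      motion <- motion_traces(Tn, outlier = cov$motion_trans_mm[s] > 3)
      list(series = series, motion = motion, tr = spec$tr,
           subject_id = cov$subject_id[s])
    })
    names(subjects) <- cov$subject_id
    list(subjects = subjects, covariates = cov)
  })
}

# slow random-walk motion traces (3 translations mm, 3 rotations deg);
# outliers get a step transition > 3 mm in the first translation
motion_traces <- function(Tn, outlier = FALSE) {
  m <- t(apply(matrix(rnorm(6 * Tn, sd = 0.02), 6, Tn), 1, cumsum))
  if (outlier) m[1, seq(floor(Tn / 2), Tn)] <- m[1, seq(floor(Tn / 2), Tn)] + 4
  rownames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Generate synthetic volumes for normalization QC
#'
#' "Good" volumes share a common ellipsoidal brain support with small
#' center jitter; "bad" volumes are translated along the slice axis by
#' a third of the grid so their mask disagrees with the group mask in
#' the top/bottom slabs and overall. Intended as ground-truth fixtures
#' for the mask-correlation screening.
#'
#' @param n_good,n_bad volume counts.
#' @param seed RNG seed.
#' @param dim 3-element grid size; at least 20 slices along axis 3.
#' @return list with `volumes` (list of 3-D arrays) and `truth`
#'   (logical vector, TRUE for volumes expected to pass screening).
#' @export
generate_qc_volumes <- function(n_good, n_bad, seed = 1L, dim = c(24, 24, 24)) {
  stopifnot(n_good >= 0, n_bad >= 0, length(dim) == 3)
  if (n_good + n_bad == 0) stop("need at least one volume")
  if (dim[3] < 20) stop("need at least 20 slices along the slice axis")
  with_seed(seed, {
    ctr0 <- dim / 2
    radii <- dim * 0.35
    mk <- function(shift, jitter) {
      ctr <- ctr0 + shift + jitter
      g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                       z = seq_len(dim[3]))
      d2 <- ((g$x - ctr[1]) / radii[1])^2 + ((g$y - ctr[2]) / radii[2])^2 +
            ((g$z - ctr[3]) / radii[3])^2
      vol <- array(abs(rnorm(prod(dim), 1, 0.2)), dim)  # background floor
      vol[d2 <= 1] <- 100 + rnorm(sum(d2 <= 1), sd = 2)
      vol
    }
    vols <- c(
      lapply(seq_len(n_good), function(i) mk(c(0, 0, 0), rnorm(3, sd = 0.3))),
      lapply(seq_len(n_bad), function(i) mk(c(0, 0, dim[3] / 3), rnorm(3, sd = 0.3)))
    )
    list(volumes = vols,
         truth = rep(c(TRUE, FALSE), c(n_good, n_bad)))
  })
}

#' Generate symptom scores coupled to measures
#'
#' Scores are linear combinations of selected features plus Gaussian
#' noise, produced for patient groups only: PANSS-positive/-negative
#' and a chlorpromazine-equivalent dose (CPZ, mg/day) for SZ; ADOS
#' total, SRS and a medicated flag for ASD.
#'
#' @param measures subjects x features matrix (rownames = subject ids).
#' @param covariates roster with `subject_id` and `group`.
#' @param coupling named list: score name (one of `panss_positive`,
#'   `panss_negative`, `ados_total`, `srs`) -> named numeric vector of
#'   feature coefficients.
#' @param noise_sd residual sd added to every coupled score.
#' @param seed RNG seed.
#' @return data.frame: subject_id, group, then score columns; scores
#'   undefined for the other group are NA.
#' @export
generate_symptoms <- function(measures, covariates, coupling = list(),
                              noise_sd = 1, seed = 1L) {
  score_group <- c(panss_positive = "SZ", panss_negative = "SZ",
                   ados_total = "ASD", srs = "ASD")
  bad <- setdiff(names(coupling), names(score_group))
  if (length(bad)) stop("unknown score(s): ", paste(bad, collapse = ", "))
  for (sc in coupling)
    if (!all(names(sc) %in% colnames(measures)))
      stop("coupling references features absent from the measure matrix")
  with_seed(seed, {
    pat <- covariates$group %in% c("SZ", "ASD")
    out <- data.frame(subject_id = covariates$subject_id[pat],
                      group = covariates$group[pat],
                      stringsAsFactors = FALSE)
    for (score in names(score_group)) {
      g <- score_group[score]
      sel <- out$group == g
      base <- rnorm(sum(sel), mean = 0, sd = 1)
      cp <- coupling[[score]]
      if (!is.null(cp)) {
        contrib <- as.matrix(measures[out$subject_id[sel],
                                      names(cp), drop = FALSE]) %*% cp
        base <- drop(contrib) + rnorm(sum(sel), sd = noise_sd)
      }
      out[[score]] <- NA_real_
      out[[score]][sel] <- base
    }
    sz <- out$group == "SZ"
    out$cpz <- NA_real_
    out$cpz[sz] <- rlnorm(sum(sz), meanlog = 5.5, sdlog = 0.5)
    asd <- out$group == "ASD"
    out$medicated <- NA
    out$medicated[asd] <- rbinom(sum(asd), 1, 0.4) == 1
    out
  })
}

#' Write a cohort's measures and covariates as TSV
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written (measures+covariates TSV and
#'   ground-truth JSON).
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(cohort$covariates,
               as.data.frame(cohort$measures, check.names = FALSE))
  p1 <- file.path(dir, "measures.tsv")
  write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(cohort$truth, p2, dataframe = "rows", digits = NA)
  invisible(c(p1, p2))
}

#' Read a cohort measures TSV written by [write_cohort_tsv()]
#'
#' @param path path to `measures.tsv`.
#' @return list with `measures` matrix and `covariates` data.frame.
#' @export
read_cohort_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  covcols <- c("subject_id", "group", "dataset", "site", "age", "gender",
               "motion_trans_mm", "motion_rot_deg", "n_timepoints")
  covcols <- intersect(covcols, names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), covcols), drop = FALSE])
  rownames(m) <- tab$subject_id
  list(measures = m, covariates = tab[, covcols, drop = FALSE])
}
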