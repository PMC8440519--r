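#' Correlate measures with symptom scores
#'
#' For each (measure, score) pair within one patient group, computes
#' pairwise-complete Pearson and Spearman correlations with two-sided
#' p-values. A finding is "reported" when both p-values fall below
#' `alpha` (the dual-significance rule, default 0.01).
#'
#' @param measures subjects x features matrix (rownames = subject ids).
#' @param symptoms data.frame with `subject_id`, `group` and score
#'   columns; NAs allowed.
#' @param group patient group (`"SZ"` or `"ASD"`).
#' @param scores score column names to test (defaults to the non-id
#'   numeric columns present for the group).
#' @param alpha dual significance level.
#' @return data.frame: measure, score, n, pearson_r, pearson_p,
#'   spearman_rho, spearman_p, reported.
#' @export
symptom_correlations <- function(measures, symptoms, group,
                                 scores = NULL, alpha = 0.01) {
  measures <- as.matrix(measures)
  sym <- symptoms[symptoms$group == group, , drop = FALSE]
  if (is.null(scores)) {
    cand <- setdiff(names(sym), c("subject_id", "group", "cpz", "medicated"))
    scores <- cand[vapply(cand, function(s) any(!is.na(sym[[s]])), logical(1))]
  }
  idx <- match(sym$subject_id, rownames(measures))
  sym <- sym[!is.na(idx), , drop = FALSE]
  mm <- measures[idx[!is.na(idx)], , drop = FALSE]
  rows <- list()
  for (score in scores) {
    y <- sym[[score]]
    for (j in seq_len(ncol(mm))) {
      ok <- complete.cases(mm[, j], y)
      n <- sum(ok)
      if (n < 3L) stop("fewer than 3 complete pairs for score ", score)
      if (sd(y[ok]) == 0) stop("constant score vector: ", score)
      pe <- cor.test(mm[ok, j], y[ok], method = "pearson")
      sp <- suppressWarnings(cor.test(mm[ok, j], y[ok], method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        measure = colnames(mm)[j] %||% j, score = score, n = n,
        pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
        spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
        reported = pe$p.value < alpha && sp$p.value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Antipsychotic dose (CPZ) association
#'
#' One linear regression per measure with the chlorpromazine-equivalent
#' dose as predictor; slopes are flagged at the Bonferroni-adjusted
#' level alpha / (number of measures).
#'
#' @param measures subjects x features matrix for SZ patients with
#'   dose data (rownames = subject ids).
#' @param cpz named numeric vector of CPZ equivalents (mg/day).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: measure, slope, p, sig.
#' @export
cpz_regression <- function(measures, cpz, alpha = 0.05) {
  measures <- as.matrix(measures)
  ids <- intersect(rownames(measures), names(cpz))
  if (length(ids) < 3L) stop("fewer than 3 SZ patients with CPZ data")
  x <- cpz[ids]
  if (sd(x) == 0) stop("all CPZ values identical")
  mm <- measures[ids, , drop = FALSE]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slopes <- drop(crossprod(xc, mm)) / sxx
  fitted_var <- slopes^2 * sxx
  rss <- colSums((mm - rep(colMeans(mm), each = nrow(mm)))^2) - fitted_var
  df <- length(ids) - 2L
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tt <- ifelse(se > 0, slopes / se, 0)
  p <- 2 * pt(-abs(tt), df)
  p[se == 0 & fitted_var > 0] <- 0       # perfect linear fit
  p[se == 0 & fitted_var == 0] <- 1
  data.frame(measure = colnames(mm) %||% seq_len(ncol(mm)),
             slope = slopes, p = p,
             sig = p * ncol(mm) < alpha,
             stringsAsFactors = FALSE)
}

#' Medicated vs unmedicated comparison
#'
#' Two-tailed pooled-variance t-test per measure between medicated and
#' unmedicated patients, Bonferroni-corrected.
#'
#' @param measures subjects x features matrix (rownames = subject ids).
#' @param medicated named logical vector per patient.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: measure, t, p, sig.
#' @export
medication_group_test <- function(measures, medicated, alpha = 0.05) {
  measures <- as.matrix(measures)
  ids <- intersect(rownames(measures), names(medicated))
  med <- medicated[ids]
  if (!any(med) || !any(!med)) stop("one medication group is empty")
  mm <- measures[ids, , drop = FALSE]
  tt <- col_ttest_pooled(mm[med, , drop = FALSE], mm[!med, , drop = FALSE])
  data.frame(measure = colnames(mm) %||% seq_len(ncol(mm)),
             t = tt$t, p = tt$p,
             sig = tt$p * ncol(mm) < alpha,
             stringsAsFactors = FALSE)
}
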