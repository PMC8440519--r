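#' Permutation-null two-sample test
#'
#' For each feature, subjects of the two groups are repeatedly
#' rearranged into two dummy groups of the original sizes; the
#' empirical p-value is the frequency with which the dummy-group
#' two-sample t-test p-value falls strictly below the observed one.
#' No +1 smoothing is applied, so an empirical p of exactly 0 is
#' possible. An exhaustive mode enumerates every distinct assignment
#' instead of sampling.
#'
#' @param values subjects x features matrix.
#' @param groups labels; `group_a` / `group_b` select the two groups.
#' @param group_a,group_b group labels to compare (positive T = first
#'   larger).
#' @param n_perm number of sampled permutations.
#' @param seed RNG seed.
#' @param exhaustive if TRUE, enumerate all `choose(n, nA)` splits
#'   (feasible only for small groups).
#' @param alpha,correction Bonferroni flagging of the empirical
#'   p-values (FNC default alpha 0.01).
#' @return a `permutation_result` list: data.frame `result` (feature,
#'   t_obs, p_obs, p_perm, sig), `n_perm` used, `seed`.
#' @export
permutation_test <- function(values, groups, group_a, group_b,
                             n_perm = 1000, seed = 1L, exhaustive = FALSE,
                             alpha = 0.01, correction = "BFN") {
  values <- as.matrix(values)
  g <- as.character(groups)
  sel <- g %in% c(group_a, group_b)
  v <- values[sel, , drop = FALSE]
  lab <- g[sel]
  nA <- sum(lab == group_a); nB <- sum(lab == group_b)
  if (nA < 2L || nB < 2L) stop("both groups need at least 2 subjects")
  ord <- order(lab != group_a)            # group A first
  v <- v[ord, , drop = FALSE]
  obs <- col_ttest_pooled(v[seq_len(nA), , drop = FALSE],
                          v[nA + seq_len(nB), , drop = FALSE])
  n <- nA + nB
  perm_p <- function(idxA) {
    b <- setdiff(seq_len(n), idxA)
    col_ttest_pooled(v[idxA, , drop = FALSE], v[b, , drop = FALSE])$p
  }
  if (exhaustive) {
    splits <- combn(n, nA)
    n_used <- ncol(splits)
    count <- numeric(ncol(v))
    for (k in seq_len(n_used))
      count <- count + (perm_p(splits[, k]) < obs$p)
  } else {
    if (n_perm < 1) stop("n_perm must be at least 1")
    n_used <- as.integer(n_perm)
    count <- with_seed(seed, {
      cnt <- numeric(ncol(v))
      for (k in seq_len(n_used))
        cnt <- cnt + (perm_p(sample.int(n, nA)) < obs$p)
      cnt
    })
  }
  p_emp <- count / n_used
  structure(list(
    result = data.frame(feature = colnames(values) %||% seq_len(ncol(values)),
                        t_obs = obs$t, p_obs = obs$p, p_perm = p_emp,
                        sig = correct_multiple(p_emp, correction, alpha),
                        stringsAsFactors = FALSE),
    n_perm = n_used, seed = seed, exhaustive = exhaustive),
    class = "permutation_result")
}

#' Combine per-dataset p-values with Fisher's method
#'
#' Per feature, the chi-square statistic is -2 sum(log p) over the k
#' dataset-level comparisons, referred to a chi-square distribution
#' with 2k degrees of freedom (upper tail). Combined p-values are
#' Bonferroni-flagged and the mean T across datasets is reported.
#'
#' @param pvals features x datasets matrix of p-values in (0, 1\];
#'   zeros are clipped to the smallest positive double with a warning.
#' @param tvals optional features x datasets matrix of T-values used
#'   for the mean-T report.
#' @param alpha,correction correction of the combined p (default
#'   Bonferroni at 0.01).
#' @return a `meta_result` data.frame: feature, chisq, df, p_combined,
#'   sig, mean_t.
#' @export
fisher_combine <- function(pvals, tvals = NULL, alpha = 0.01,
                           correction = "BFN") {
  pvals <- as.matrix(pvals)
  if (ncol(pvals) < 1L) stop("need at least one dataset column")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  if (any(pvals == 0, na.rm = TRUE)) {
    warning("p-values of 0 clipped to smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  k <- ncol(pvals)
  X2 <- -2 * rowSums(log(pvals))
  p_comb <- pchisq(X2, df = 2 * k, lower.tail = FALSE)
  structure(data.frame(
    feature = rownames(pvals) %||% seq_len(nrow(pvals)),
    chisq = X2, df = 2 * k, p_combined = p_comb,
    sig = correct_multiple(p_comb, correction, alpha),
    mean_t = if (is.null(tvals)) NA_real_ else rowMeans(as.matrix(tvals)),
    stringsAsFactors = FALSE), class = c("meta_result", "data.frame"))
}

#' Per-dataset contrasts feeding the meta-analysis
#'
#' Runs the two-sample contrast separately in each dataset that holds
#' both groups; for SZ vs ASD (never co-acquired), every pairing of an
#' SZ-bearing and an ASD-bearing dataset contributes one comparison.
#'
#' @param values subjects x features matrix.
#' @param covariates roster with `group`, `dataset`.
#' @param group_a,group_b groups to contrast.
#' @return list with matrices `p` and `t` (features x comparisons) and
#'   the comparison labels.
#' @export
dataset_contrasts <- function(values, covariates, group_a, group_b) {
  values <- as.matrix(values)
  ds <- unique(covariates$dataset)
  has <- function(d, g) any(covariates$dataset == d & covariates$group == g)
  combos <- list()
  if (group_a %in% c("SZ", "ASD") && group_b %in% c("SZ", "ASD") &&
      group_a != group_b) {
    da <- ds[vapply(ds, has, logical(1), g = group_a)]
    db <- ds[vapply(ds, has, logical(1), g = group_b)]
    for (a in da) for (b in db) combos[[length(combos) + 1L]] <- c(a, b)
  } else {
    for (d in ds[vapply(ds, function(d) has(d, group_a) && has(d, group_b),
                        logical(1))])
      combos[[length(combos) + 1L]] <- c(d, d)
  }
  if (!length(combos)) stop("no dataset holds both groups")
  pm <- tm <- matrix(NA_real_, ncol(values), length(combos),
                     dimnames = list(colnames(values), NULL))
  labels <- character(length(combos))
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    selA <- covariates$dataset == cb[1] & covariates$group == group_a
    selB <- covariates$dataset == cb[2] & covariates$group == group_b
    tt <- col_ttest_pooled(values[selA, , drop = FALSE],
                           values[selB, , drop = FALSE])
    pm[, i] <- tt$p; tm[, i] <- tt$t
    labels[i] <- if (cb[1] == cb[2]) cb[1] else paste(cb[1], cb[2], sep = "x")
  }
  colnames(pm) <- colnames(tm) <- labels
  list(p = pm, t = tm, comparisons = labels)
}
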