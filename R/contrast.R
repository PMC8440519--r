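#' One-sample positivity gate for network Z-maps
#'
#' Voxel-wise right-tailed one-sample t-test with Bonferroni
#' correction: a voxel is retained iff p x (number of voxels) < alpha,
#' keeping only voxels whose Z-scores are reliably positive before any
#' group comparison. Zero-variance voxels get p = 1 when the mean is
#' non-positive and p = 0 when positive.
#'
#' @param zmaps subjects x voxels matrix of network Z-scores.
#' @param alpha significance level (default 0.01).
#' @return list: logical `retained`, numeric `p` (raw one-sided).
#' @export
positivity_gate <- function(zmaps, alpha = 0.01) {
  zmaps <- as.matrix(zmaps)
  n <- nrow(zmaps)
  stopifnot(n >= 2)
  m <- colMeans(zmaps)
  s <- sqrt(colVars(zmaps))
  tt <- m / (s / sqrt(n))
  p <- pt(tt, df = n - 1, lower.tail = FALSE)
  degen <- s == 0
  p[degen] <- ifelse(m[degen] > 0, 0, 1)
  list(retained = p * ncol(zmaps) < alpha, p = p)
}

#' Multiple-comparison correction flags
#'
#' Bonferroni (`"BFN"`): flag iff p x m < alpha (strict). FDR
#' (`"FDR"`): Benjamini-Hochberg step-up at level alpha.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param method `"BFN"`, `"FDR"`, or `"none"`.
#' @param alpha significance level.
#' @return logical flags.
#' @export
correct_multiple <- function(pvals, method = c("BFN", "FDR", "none"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (!length(pvals)) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  switch(method,
         BFN = pvals * length(pvals) < alpha,
         FDR = p.adjust(pvals, "BH") <= alpha,
         none = pvals < alpha)
}

#' Per-family test configuration
#'
#' Significance settings for each measure family: network-voxel
#' Z-scores use ANOVA at p < 0.05 (after the positivity gate) with
#' FDR-corrected pairwise tests at 0.05; FNC and ROI-FC use
#' Bonferroni-corrected ANOVA and pairwise tests at 0.01; gray-matter
#' voxels use ANOVA at p < 0.05 with FDR-corrected pairwise tests
#' (default 0.05).
#'
#' @param family `"network"`, `"fnc"`, `"fc"`, or `"gm"`.
#' @return list of anova/pairwise alpha and correction settings.
#' @export
family_config <- function(family = c("fnc", "network", "fc", "gm")) {
  family <- match.arg(family)
  switch(family,
    network = list(anova_alpha = 0.05, anova_correction = "none",
                   pairwise_alpha = 0.05, pairwise_correction = "FDR"),
    fnc = list(anova_alpha = 0.01, anova_correction = "BFN",
               pairwise_alpha = 0.01, pairwise_correction = "BFN"),
    fc = list(anova_alpha = 0.01, anova_correction = "BFN",
              pairwise_alpha = 0.01, pairwise_correction = "BFN"),
    gm = list(anova_alpha = 0.05, anova_correction = "none",
              pairwise_alpha = 0.05, pairwise_correction = "FDR"))
}

#' Omnibus three-group ANOVA gate
#'
#' One-way fixed-effects ANOVA per feature across HC, SZ and ASD, with
#' the family's alpha and correction applied to decide which features
#' pass.
#'
#' @param values subjects x features matrix (harmonized).
#' @param groups group labels (must contain HC, SZ, ASD).
#' @param alpha significance level.
#' @param correction `"none"`, `"BFN"` or `"FDR"`.
#' @return data.frame: feature, F, p, pass.
#' @export
omnibus_anova <- function(values, groups, alpha = 0.05,
                          correction = c("none", "BFN", "FDR")) {
  correction <- match.arg(correction)
  a <- col_anova_oneway(values, groups)
  pass <- correct_multiple(a$p, if (correction == "none") "none" else correction,
                           alpha)
  data.frame(feature = colnames(values) %||% seq_along(a$p),
             F = a$F, p = a$p, pass = pass, stringsAsFactors = FALSE)
}

#' Pairwise two-sample t-tests for the three group contrasts
#'
#' Pooled-variance (Student) two-tailed t-tests for HC vs SZ, HC vs
#' ASD and SZ vs ASD. Positive T means the first-named group has the
#' larger mean (e.g. positive T in HC vs SZ = higher values in HC,
#' i.e. a decrease in SZ).
#'
#' @param values subjects x features matrix.
#' @param groups labels containing `"HC"`, `"SZ"`, `"ASD"`.
#' @return a `contrast_result` data.frame with columns `feature`,
#'   `t_hc_sz`, `p_hc_sz`, `t_hc_asd`, `p_hc_asd`, `t_sz_asd`,
#'   `p_sz_asd`.
#' @export
pairwise_ttests <- function(values, groups) {
  values <- as.matrix(values)
  g <- as.character(groups)
  pick <- function(lbl) values[g == lbl, , drop = FALSE]
  hc <- pick("HC"); sz <- pick("SZ"); asd <- pick("ASD")
  if (!nrow(hc) || !nrow(sz) || !nrow(asd)) stop("a group is empty")
  hs <- col_ttest_pooled(hc, sz)
  ha <- col_ttest_pooled(hc, asd)
  sa <- col_ttest_pooled(sz, asd)
  structure(data.frame(
    feature = colnames(values) %||% seq_len(ncol(values)),
    t_hc_sz = hs$t, p_hc_sz = hs$p,
    t_hc_asd = ha$t, p_hc_asd = ha$p,
    t_sz_asd = sa$t, p_sz_asd = sa$p,
    stringsAsFactors = FALSE), class = c("contrast_result", "data.frame"))
}

#' Categorize features into common and unique change types
#'
#' For features passing the ANOVA gate, the signs of T(HC vs SZ) and
#' T(HC vs ASD) define the category: both positive = common decrease
#' in the disorders; both negative = common increase; positive/negative
#' = SZ-unique decrease (ASD increase); negative/positive = ASD-unique
#' decrease (SZ increase). Any exact zero T, or a failed gate, maps to
#' `"NONE"`.
#'
#' @param contrasts a `contrast_result` from [pairwise_ttests()].
#' @param anova_pass logical vector, one per feature.
#' @return character vector of categories.
#' @export
categorize_changes <- function(contrasts, anova_pass) {
  stopifnot(nrow(contrasts) == length(anova_pass))
  ths <- contrasts$t_hc_sz
  tha <- contrasts$t_hc_asd
  cat <- rep("NONE", nrow(contrasts))
  cat[ths > 0 & tha > 0] <- "COMMON_DECREASE"
  cat[ths < 0 & tha < 0] <- "COMMON_INCREASE"
  cat[ths > 0 & tha < 0] <- "SZ_UNIQUE_DECREASE"
  cat[ths < 0 & tha > 0] <- "ASD_UNIQUE_DECREASE"
  cat[!anova_pass] <- "NONE"
  cat
}

#' Flag common changes that are weaker in ASD than SZ
#'
#' Within a common decrease, T(SZ vs ASD) < 0 means ASD sits closer to
#' HC (a weaker decrease); within a common increase, T(SZ vs ASD) > 0
#' means the same. Strict inequalities: T = 0 is `"NOT_WEAKER"`.
#' Non-common features get `NA`.
#'
#' @param contrasts a `contrast_result`.
#' @param categories categories from [categorize_changes()].
#' @return character vector: `"ASD_WEAKER"`, `"NOT_WEAKER"` or `NA`.
#' @export
asd_weaker_flags <- function(contrasts, categories) {
  stopifnot(nrow(contrasts) == length(categories))
  tsa <- contrasts$t_sz_asd
  out <- rep(NA_character_, length(categories))
  dec <- categories == "COMMON_DECREASE"
  inc <- categories == "COMMON_INCREASE"
  out[dec] <- ifelse(tsa[dec] < 0, "ASD_WEAKER", "NOT_WEAKER")
  out[inc] <- ifelse(tsa[inc] > 0, "ASD_WEAKER", "NOT_WEAKER")
  out
}

#' Summarize categorized changes
#'
#' Counts and one-decimal percentages of the four change types among
#' ANOVA-passing features, and of ASD-weaker changes within each common
#' category (percentages relative to that category's count).
#'
#' @param categories per-feature categories.
#' @param weaker per-feature weaker flags ([asd_weaker_flags()]).
#' @param total_anova number of features passing ANOVA (defaults to
#'   the number of non-`"NONE"` features plus `"NONE"`-categorized
#'   ANOVA passers if supplied explicitly).
#' @return a `change_summary` data.frame (one row) with count and
#'   percentage columns.
#' @export
summarize_table1 <- function(categories, weaker,
                             total_anova = sum(categories != "NONE")) {
  if (total_anova <= 0) stop("no features passing ANOVA")
  counts <- vapply(change_categories(), function(cc) sum(categories == cc),
                   integer(1))
  wk_dec <- sum(weaker == "ASD_WEAKER" & categories == "COMMON_DECREASE",
                na.rm = TRUE)
  wk_inc <- sum(weaker == "ASD_WEAKER" & categories == "COMMON_INCREASE",
                na.rm = TRUE)
  change_summary(counts["COMMON_DECREASE"], counts["COMMON_INCREASE"],
                 counts["SZ_UNIQUE_DECREASE"], counts["ASD_UNIQUE_DECREASE"],
                 wk_dec, wk_inc, total_anova)
}

#' Change summary from raw counts
#'
#' Computes the percentage table directly from category counts: each
#' category's percentage is 100 x count / (features passing ANOVA),
#' rounded to one decimal; ASD-weaker percentages are relative to the
#' corresponding common-category count.
#'
#' @param common_decrease,common_increase,sz_unique_decrease,asd_unique_decrease
#'   category counts.
#' @param weaker_decrease,weaker_increase ASD-weaker counts within the
#'   common decrease/increase.
#' @param total_anova features passing ANOVA.
#' @return one-row `change_summary` data.frame.
#' @export
change_summary <- function(common_decrease, common_increase,
                           sz_unique_decrease, asd_unique_decrease,
                           weaker_decrease, weaker_increase, total_anova) {
  if (total_anova <= 0) stop("total_anova must be positive")
  pct <- function(k, n) if (n > 0) round(100 * k / n, 1) else 0.0
  structure(data.frame(
    common_decrease_n = common_decrease,
    common_decrease_pct = pct(common_decrease, total_anova),
    common_increase_n = common_increase,
    common_increase_pct = pct(common_increase, total_anova),
    sz_unique_decrease_n = sz_unique_decrease,
    sz_unique_decrease_pct = pct(sz_unique_decrease, total_anova),
    asd_unique_decrease_n = asd_unique_decrease,
    asd_unique_decrease_pct = pct(asd_unique_decrease, total_anova),
    weaker_decrease_n = weaker_decrease,
    weaker_decrease_pct = pct(weaker_decrease, common_decrease),
    weaker_increase_n = weaker_increase,
    weaker_increase_pct = pct(weaker_increase, common_increase),
    total_anova = total_anova,
    row.names = NULL), class = c("change_summary", "data.frame"))
}

#' Run the full categorization engine on one measure family
#'
#' ANOVA gate, pairwise contrasts, pairwise corrected-significance
#' flags, sign-based categorization, ASD-weaker flags and the summary
#' table, using the family's significance configuration.
#'
#' @param values harmonized subjects x features matrix.
#' @param groups labels with HC, SZ, ASD.
#' @param family measure family for [family_config()].
#' @param config optional list overriding the family configuration.
#' @return list with `anova`, `contrasts` (including pairwise corrected
#'   flags `sig_hc_sz` etc.), `categories`, `weaker`, `summary`.
#' @export
run_group_contrast <- function(values, groups, family = "fnc",
                               config = NULL) {
  cfg <- utils::modifyList(family_config(family), config %||% list())
  an <- omnibus_anova(values, groups, cfg$anova_alpha, cfg$anova_correction)
  cr <- pairwise_ttests(values, groups)
  for (pair in c("hc_sz", "hc_asd", "sz_asd"))
    cr[[paste0("sig_", pair)]] <-
      correct_multiple(cr[[paste0("p_", pair)]],
                       if (cfg$pairwise_correction == "none") "none"
                       else cfg$pairwise_correction,
                       cfg$pairwise_alpha)
  categories <- categorize_changes(cr, an$pass)
  weaker <- asd_weaker_flags(cr, categories)
  list(anova = an, contrasts = cr, categories = categories,
       weaker = weaker,
       summary = if (any(an$pass))
         summarize_table1(categories, weaker, sum(an$pass)) else NULL)
}
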