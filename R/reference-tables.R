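#' Bundled example change counts per measure family
#'
#' Category counts, ASD-weaker counts and ANOVA totals for six measure
#' families of a large multi-site HC/SZ/ASD comparison, bundled to
#' exercise the summary arithmetic: the percentage of each change type
#' is its count divided by the number of measures passing ANOVA.
#'
#' @return data.frame with one row per family and columns
#'   `family`, `common_decrease`, `common_increase`,
#'   `sz_unique_decrease`, `asd_unique_decrease`, `weaker_decrease`,
#'   `weaker_increase`, `total_anova`.
#' @export
example_change_counts <- function() {
  data.frame(
    family = c("network_ica", "fnc_ica", "fc_aal", "fc_brainnetome",
               "gm_volume", "gm_density"),
    common_decrease     = c(2592L,  191L, 401L, 349L,  45898L, 185750L),
    common_increase     = c(2906L,  224L, 391L, 215L,   2205L,    155L),
    sz_unique_decrease  = c(1013L,   17L,  48L, 105L,  65957L,  20833L),
    asd_unique_decrease = c( 782L,   17L,  84L,  51L,      0L,      0L),
    weaker_decrease     = c(2212L,  172L, 361L, 321L,  45891L, 185724L),
    weaker_increase     = c(2744L,  204L, 377L, 201L,    903L,    150L),
    total_anova         = c(7293L,  449L, 924L, 720L, 114060L, 206738L),
    stringsAsFactors = FALSE)
}

#' Bundled example cross-dataset classification metrics
#'
#' Accuracy, sensitivity and specificity (percent) of twelve SZ-vs-ASD
#' classification experiments over cross-dataset train/test
#' assignments (four SZ-bearing and two ASD-bearing datasets), bundled
#' to exercise the split aggregation.
#'
#' @return data.frame with 12 rows and columns `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
example_split_metrics <- function() {
  data.frame(
    accuracy    = c(75.8, 73.9, 78.1, 67.4, 78.9, 80.0,
                    77.9, 77.2, 73.1, 70.4, 73.8, 71.7),
    sensitivity = c(84.2, 85.3, 80.5, 88.7, 84.7, 90.0,
                    80.2, 85.4, 76.4, 88.2, 78.1, 77.9),
    specificity = c(61.0, 58.9, 73.7, 43.1, 70.0, 68.0,
                    73.9, 65.9, 66.8, 49.1, 66.8, 63.9))
}

#' Summary table for all bundled families
#'
#' Applies [change_summary()] to every row of
#' [example_change_counts()].
#'
#' @return data.frame of one `change_summary` row per family.
#' @export
example_change_summaries <- function() {
  cc <- example_change_counts()
  out <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i)
    change_summary(cc$common_decrease[i], cc$common_increase[i],
                   cc$sz_unique_decrease[i], cc$asd_unique_decrease[i],
                   cc$weaker_decrease[i], cc$weaker_increase[i],
                   cc$total_anova[i])))
  cbind(family = cc$family, out)
}
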