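# Reference values from the thyroid-nodule study cohort (84 benign / 27
# malignant nodules). These ship as defaults and validation inputs: the
# clinical images themselves are not public, so the per-offset group summary
# statistics, the derived VI cut-offs and the reported rule performance are
# the anchors the package reproduces its cohort arithmetic against.

#' Study cohort group sizes
#'
#' @return named integer vector `c(benign = 84, malignant = 27)`.
#' @export
study_group_sizes <- function() c(benign = 84L, malignant = 27L)

#' Per-offset regional VI summary statistics of the study cohort
#'
#' Group mean and standard deviation of the peripheral and central vascular
#' index at each explored offset level (coarse 5% grid plus the 21–24%
#' refinement). One published row (23% offset) printed its four cells in a
#' scrambled order; it is restored here to the column order of every other
#' row, consistent with its neighbouring offsets and significance marks.
#'
#' @return data frame with columns `offset`, `region`, `group`, `n`, `mean`,
#'   `sd` (VI percentages).
#' @export
study_vi_summaries <- function() {
  # offset, periph benign (m, sd), periph malig, central benign, central malig
  rows <- list(
    c(5,  21.7, 20.3, 23.5, 19.3, 15.2, 15.3, 23.4, 17.7),
    c(10, 21.4, 19.6, 25.3, 18.7, 13.5, 14.6, 23.3, 18.0),
    c(15, 20.0, 18.4, 24.0, 16.6, 12.4, 14.5, 22.3, 19.3),
    c(20, 18.7, 17.1, 25.0, 17.0, 12.0, 14.7, 21.6, 20.1),
    c(21, 18.4, 16.9, 25.0, 17.1, 11.9, 14.9, 21.3, 20.1),
    c(22, 18.2, 16.7, 26.5, 16.2, 11.9, 15.1, 21.7, 19.6),
    c(23, 17.9, 16.5, 24.9, 17.1, 11.9, 15.4, 20.9, 20.3),
    c(24, 17.8, 16.4, 24.9, 17.2, 11.9, 15.6, 20.6, 20.1),
    c(25, 17.7, 16.3, 26.6, 18.7, 11.9, 16.0, 20.4, 20.1))
  n <- study_group_sizes()
  do.call(rbind, lapply(rows, function(r) data.frame(
    offset = r[1],
    region = rep(c("peripheral", "central"), each = 2),
    group  = rep(c("benign", "malignant"), 2),
    n      = as.integer(n[c("benign", "malignant")]),
    mean   = r[c(2, 4, 6, 8)],
    sd     = r[c(3, 5, 7, 9)],
    stringsAsFactors = FALSE)))
}

#' Overall VI summary statistics of the study cohort
#'
#' @return data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
study_overall_summaries <- function() {
  n <- study_group_sizes()
  data.frame(group = c("benign", "malignant"),
             n = as.integer(n), mean = c(16.6, 23.8), sd = c(1.8, 4.6),
             stringsAsFactors = FALSE)
}

#' Study-derived optimum VI cut-offs
#'
#' ROC-derived cut-offs at the 22% optimum offset. These are study-derived
#' defaults for the rule-based classifiers; override them for other cohorts.
#'
#' @return a [cutoff_set()] with peripheral 19.7, central 9.1, overall 20.2.
#' @export
study_cutoffs <- function() cutoff_set(19.7, 9.1, 20.2)

#' Grey-scale ultrasound feature prevalence in the study cohort
#'
#' Fraction of nodules in each group presenting each suspicious feature:
#' microcalcification, hypoechogenicity, irregular margins, tall-to-width
#' ratio > 1.
#'
#' @return data frame with columns `feature`, `benign`, `malignant`
#'   (proportions in `[0, 1]`).
#' @export
study_gsu_prevalence <- function() {
  data.frame(feature = c("gsu_microcalc", "gsu_hypoechoic",
                         "gsu_irregular", "gsu_tall"),
             benign    = c(0.071, 0.333, 0.167, 0.131),
             malignant = c(0.778, 0.926, 0.556, 0.593),
             stringsAsFactors = FALSE)
}

#' Reported diagnostic performance of the study's classifiers
#'
#' Sensitivity/specificity/NPV/PPV/accuracy (percent) reported for the three
#' single-index ROC classifiers at the 22% offset and for the three decision
#' rules. Used by the validation suite to check arithmetic closure: the
#' confusion counts reconstructed from each row's sensitivity and specificity
#' (at n = 27 malignant / 84 benign) must reproduce the remaining columns.
#'
#' @return data frame with columns `rule`, `cutoff` (`NA` for composite
#'   rules), `sens`, `spec`, `npv`, `ppv`, `accuracy`.
#' @export
study_reported_performance <- function() {
  data.frame(
    rule = c("peripheral_vi", "central_vi", "overall_vi",
             "gsu", "combined_vi", "combined_vi_gsu"),
    cutoff = c(19.7, 9.1, 20.2, NA, NA, NA),
    sens = c(74.1, 74.1, 74.1, 96.3, 70.4, 66.7),
    spec = c(60.7, 60.7, 69.0, 46.4, 71.4, 83.3),
    npv  = c(87.9, 87.9, 89.2, 97.5, 88.2, 88.6),
    ppv  = c(37.7, 37.7, 43.5, 36.6, 44.2, 56.3),
    accuracy = c(64.0, 64.0, 70.3, 58.6, 71.2, 79.3),
    stringsAsFactors = FALSE)
}
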