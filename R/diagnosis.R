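#' VI cut-off set
#'
#' Cut-offs (percent) applied to the peripheral, central and overall vascular
#' index by the rule-based classifiers. Comparison is inclusive: a nodule at
#' exactly the cut-off is called positive.
#'
#' @param peripheral,central,overall cut-offs in `[0, 100]`.
#' @return an object of class `cutoff_set`.
#' @seealso [study_cutoffs()] for the study-derived defaults.
#' @export
cutoff_set <- function(peripheral, central, overall) {
  v <- c(peripheral = peripheral, central = central, overall = overall)
  if (anyNA(v) || any(v < 0 | v > 100))
    stop_vicad("cut-offs must lie in [0, 100]", "vicad_validation_error")
  structure(as.list(v), class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set> peripheral >= %g%%, central >= %g%%, overall >= %g%%\n",
              x$peripheral, x$central, x$overall))
  invisible(x)
}

gsu_feature_names <- function()
  c("gsu_microcalc", "gsu_hypoechoic", "gsu_irregular", "gsu_tall")

vi_columns <- function(cohort, offset_pct) {
  cols <- sprintf(c("peripheral_vi_%g", "central_vi_%g"), offset_pct)
  miss <- setdiff(c(cols, "overall_vi"), names(cohort))
  if (length(miss))
    stop_vicad(sprintf("cohort lacks VI columns: %s",
                       paste(miss, collapse = ", ")), "vicad_schema_error")
  cols
}

#' Grey-scale ultrasound rule
#'
#' A nodule is called malignant when it presents at least one suspicious
#' grey-scale feature: microcalcification, hypoechogenicity, irregular
#' margins, or tall-to-width ratio > 1.
#'
#' @param cohort cohort data frame (one or more rows) with the four
#'   `gsu_*` feature columns.
#' @return logical vector of predicted labels (`TRUE` = malignant).
#' @export
gsu_rule <- function(cohort) {
  feats <- gsu_feature_names()
  miss <- setdiff(feats, names(cohort))
  if (length(miss))
    stop_vicad(sprintf("missing GSU feature column(s): %s",
                       paste(miss, collapse = ", ")), "vicad_schema_error")
  f <- as.matrix(cohort[feats]) != 0
  if (anyNA(f))
    stop_vicad("GSU features must not be missing", "vicad_validation_error")
  rowSums(f) >= 1
}

#' Combined vascular-index rule
#'
#' A nodule is called malignant when all three vascular indices are at or
#' above their cut-offs: peripheral and central VI at the chosen offset and
#' the overall VI of the representative image. A nodule whose central region
#' is empty (missing central VI) is conservatively called benign: the rule
#' requires all three indices to reach their cut-offs and an absent index
#' cannot.
#'
#' @param cohort cohort data frame with `overall_vi` and the per-offset VI
#'   columns.
#' @param cutoffs a [cutoff_set()]; default [study_cutoffs()].
#' @param offset_pct which offset level's regional VIs to use (default 22,
#'   the study optimum).
#' @return logical vector of predicted labels.
#' @export
combined_vi_rule <- function(cohort, cutoffs = study_cutoffs(),
                             offset_pct = 22) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  cols <- vi_columns(cohort, offset_pct)
  p <- cohort[[cols[1]]]; ce <- cohort[[cols[2]]]; ov <- cohort$overall_vi
  if (anyNA(p) || anyNA(ov))
    stop_vicad("peripheral and overall VI must not be missing",
               "vicad_validation_error")
  call <- p >= cutoffs$peripheral & ov >= cutoffs$overall &
          !is.na(ce) & ce >= cutoffs$central
  call
}

#' Combined vascular-index + grey-scale rule
#'
#' Conjunction of [gsu_rule()] and [combined_vi_rule()]: malignant only when
#' at least one suspicious grey-scale feature is present *and* all three VIs
#' reach their cut-offs.
#'
#' @inheritParams combined_vi_rule
#' @return logical vector of predicted labels.
#' @export
combined_vi_gsu_rule <- function(cohort, cutoffs = study_cutoffs(),
                                 offset_pct = 22) {
  gsu_rule(cohort) & combined_vi_rule(cohort, cutoffs, offset_pct)
}

#' Score a decision rule against cohort ground truth
#'
#' Applies a rule to every nodule, tallies the confusion counts against the
#' `malignant` labels and derives the five diagnostic metrics.
#'
#' @param cohort cohort data frame with ground-truth `malignant` labels.
#' @param rule `"gsu"`, `"combined_vi"`, `"combined_vi_gsu"`, or a function
#'   `function(cohort) -> logical` of predicted labels.
#' @param cutoffs a [cutoff_set()] (ignored by the pure GSU rule).
#' @param offset_pct offset level for the regional VIs.
#' @return an object of class `diagnostic_report`: list with `rule_name`,
#'   `counts` ([confusion_counts()]), `metrics` (percent vector) and `calls`
#'   (per-nodule predicted labels, named by `nodule_id` when present).
#' @export
score_rule <- function(cohort, rule = c("combined_vi_gsu", "combined_vi", "gsu"),
                       cutoffs = study_cutoffs(), offset_pct = 22) {
  if (nrow(cohort) == 0)
    stop_vicad("cohort is empty", "vicad_validation_error")
  if (is.null(cohort$malignant) || anyNA(cohort$malignant))
    stop_vicad("cohort must carry complete `malignant` labels",
               "vicad_validation_error")
  if (is.function(rule)) {
    pred <- rule(cohort); rule_name <- "custom"
  } else {
    rule_name <- match.arg(rule)
    pred <- switch(rule_name,
      gsu = gsu_rule(cohort),
      combined_vi = combined_vi_rule(cohort, cutoffs, offset_pct),
      combined_vi_gsu = combined_vi_gsu_rule(cohort, cutoffs, offset_pct))
  }
  truth <- cohort$malignant != 0
  counts <- confusion_counts(tp = sum(pred & truth), fp = sum(pred & !truth),
                             tn = sum(!pred & !truth), fn = sum(!pred & truth))
  if (!is.null(cohort$nodule_id)) names(pred) <- cohort$nodule_id
  structure(list(rule_name = rule_name, counts = counts,
                 metrics = diagnostic_metrics(counts), calls = pred),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  m <- round_half_up(x$metrics, 1)
  cat(sprintf("<diagnostic_report> rule '%s' on %d nodules\n",
              x$rule_name, length(x$calls)))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  cat(sprintf(paste0("  sensitivity %.1f%%  specificity %.1f%%  ",
                     "NPV %.1f%%  PPV %.1f%%  accuracy %.1f%%\n"),
              m["sensitivity"], m["specificity"], m["npv"], m["ppv"],
              m["accuracy"]))
  invisible(x)
}

#' Diagnostic report as a one-row data frame
#'
#' Percentages formatted to one decimal (half-up), as in printed tables.
#'
#' @param report a `diagnostic_report`.
#' @return one-row data frame.
#' @export
report_row <- function(report) {
  m <- round_half_up(report$metrics, 1)
  data.frame(rule = report$rule_name,
             tp = report$counts$tp, fp = report$counts$fp,
             tn = report$counts$tn, fn = report$counts$fn,
             sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
             npv = m[["npv"]], ppv = m[["ppv"]], accuracy = m[["accuracy"]],
             stringsAsFactors = FALSE)
}
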