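#' Group summary statistics
#'
#' @param n group size (>= 2).
#' @param mean group mean VI in percent.
#' @param sd group standard deviation (>= 0).
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (!is.numeric(n) || n < 2)
    stop_vicad("group size must be >= 2", "vicad_validation_error")
  if (sd < 0)
    stop_vicad("standard deviation must be >= 0", "vicad_validation_error")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Two-sample t test from summary statistics
#'
#' Location test between two groups given only (n, mean, sd), as needed when
#' working from published summary tables. `variant = "welch"` (default) does
#' not assume equal variances and uses the Welch–Satterthwaite degrees of
#' freedom; `"pooled"` is the classical equal-variance Student test. P values
#' are two-tailed. If both groups are degenerate (sd = 0) the test returns
#' p = 1 for equal means and p = 0 otherwise.
#'
#' @param a,b `group_summary` objects (or lists with `n`, `mean`, `sd`).
#' @param variant `"welch"` or `"pooled"`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  a <- group_summary(a$n, a$mean, a$sd)
  b <- group_summary(b$n, b$mean, b$sd)
  if (a$sd == 0 && b$sd == 0) {
    equal <- isTRUE(all.equal(a$mean, b$mean))
    return(list(t = if (equal) 0 else Inf * sign(a$mean - b$mean),
                df = a$n + b$n - 2, p = if (equal) 1 else 0))
  }
  if (variant == "welch") {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Optimum offset level from per-offset group summaries
#'
#' The optimum offset for separating the peripheral and central regions is
#' the level at which the vascular index differs significantly (p < `alpha`)
#' between benign and malignant nodules in *both* regions. When several
#' offsets qualify the smallest is returned (all qualifying levels are kept
#' in the result); when none qualifies the optimum is `NA`.
#'
#' @param summaries data frame with columns `offset`, `region`
#'   (`"peripheral"`/`"central"`), `group` (`"benign"`/`"malignant"`), `n`,
#'   `mean`, `sd` — as produced by [study_vi_summaries()] or
#'   [summarize_cohort()].
#' @param alpha significance level in (0, 1).
#' @param variant t-test variant, see [two_sample_t()].
#' @return an object of class `offset_search`: list with `optimum` (offset
#'   percent, or `NA`), `qualifying` (all offsets meeting the rule) and
#'   `table` (per offset: t, df, p for each region).
#' @export
optimum_offset <- function(summaries, alpha = 0.05,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_vicad("`alpha` must lie in (0, 1)", "vicad_validation_error")
  need <- c("offset", "region", "group", "n", "mean", "sd")
  if (!all(need %in% names(summaries)))
    stop_vicad(sprintf("`summaries` needs columns: %s",
                       paste(need, collapse = ", ")), "vicad_schema_error")
  offsets <- sort(unique(summaries$offset))
  if (length(offsets) == 0)
    stop_vicad("no offsets in `summaries`", "vicad_validation_error")
  one <- function(off, reg) {
    s <- summaries[summaries$offset == off & summaries$region == reg, ]
    ben <- s[s$group == "benign", ]; mal <- s[s$group == "malignant", ]
    if (nrow(ben) != 1L || nrow(mal) != 1L)
      stop_vicad(sprintf("offset %g / %s: need one benign and one malignant row",
                         off, reg), "vicad_schema_error")
    two_sample_t(group_summary(ben$n, ben$mean, ben$sd),
                 group_summary(mal$n, mal$mean, mal$sd), variant)
  }
  tab <- do.call(rbind, lapply(offsets, function(off) {
    tp <- one(off, "peripheral"); tc <- one(off, "central")
    data.frame(offset = off,
               t_peripheral = tp$t, df_peripheral = tp$df, p_peripheral = tp$p,
               t_central = tc$t, df_central = tc$df, p_central = tc$p)
  }))
  qual <- tab$offset[tab$p_peripheral < alpha & tab$p_central < alpha]
  structure(list(optimum = if (length(qual)) min(qual) else NA_real_,
                 qualifying = qual, alpha = alpha, variant = variant,
                 table = tab),
            class = "offset_search")
}

#' @export
print.offset_search <- function(x, ...) {
  cat(sprintf("<offset_search> %s t-test, alpha = %g\n", x$variant, x$alpha))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %5g%%  p_peripheral = %-8.4g p_central = %-8.4g %s\n",
                tab$offset[i], tab$p_peripheral[i], tab$p_central[i],
                if (tab$offset[i] %in% x$qualifying) "*both*" else ""))
  cat(if (is.na(x$optimum)) "  no offset qualifies in both regions\n"
      else sprintf("  optimum offset: %g%%\n", x$optimum))
  invisible(x)
}

#' Two-stage optimum-offset search on a cohort
#'
#' Mirrors the exploration schedule of the original study: test a coarse
#' offset grid (default 5, 10, 15, 20, 25%), then refine at 1% steps between
#' the neighbours of the most promising coarse levels, and apply the
#' both-regions significance rule over all levels tested. "Most promising"
#' means the coarse levels where at least one region is significant; the
#' refinement spans the unit grid between their outermost neighbours.
#'
#' @param cohort cohort data frame (see [read_cohort()]) with per-offset VI
#'   columns `peripheral_vi_<n>` / `central_vi_<n>` for every requested level,
#'   or a function `function(offsets)` returning the summary data frame (used
#'   when VI can be recomputed from images at arbitrary offsets).
#' @param coarse coarse grid of offset percentages.
#' @param alpha,variant see [optimum_offset()].
#' @return an `offset_search` over all levels tested.
#' @export
search_optimum_offset <- function(cohort, coarse = c(5, 10, 15, 20, 25),
                                  alpha = 0.05,
                                  variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  available <- NULL
  if (!is.function(cohort)) {
    pcols <- grep("^peripheral_vi_", names(cohort), value = TRUE)
    available <- sort(as.numeric(sub("^peripheral_vi_", "", pcols)))
    coarse <- intersect(coarse, available)
    if (length(coarse) == 0)
      stop_vicad("cohort has no per-offset VI columns on the coarse grid",
                 "vicad_schema_error")
  }
  get_summ <- if (is.function(cohort)) cohort
              else function(offs) summarize_cohort(cohort, offs)
  s1 <- optimum_offset(get_summ(coarse), alpha, variant)
  hit <- s1$table$offset[s1$table$p_peripheral < alpha |
                         s1$table$p_central < alpha]
  levels <- coarse
  if (length(hit)) {
    lo <- max(min(coarse), min(hit) - 5); hi <- min(max(coarse), max(hit) + 5)
    levels <- sort(unique(c(coarse, seq(lo, hi, by = 1))))
    if (!is.null(available)) levels <- intersect(levels, available)
  }
  optimum_offset(get_summ(levels), alpha, variant)
}

#' Summarize a cohort's regional VI per offset
#'
#' Collapses per-nodule VI columns into per-group summary statistics in the
#' format [optimum_offset()] consumes. Missing VI values (e.g. empty central
#' regions) are dropped from that group's summary.
#'
#' @param cohort cohort data frame with `malignant` plus
#'   `peripheral_vi_<n>` / `central_vi_<n>` columns.
#' @param offsets offsets to summarize; default: every offset present.
#' @return data frame with columns `offset`, `region`, `group`, `n`, `mean`, `sd`.
#' @export
summarize_cohort <- function(cohort, offsets = NULL) {
  pcols <- grep("^peripheral_vi_", names(cohort), value = TRUE)
  found <- as.numeric(sub("^peripheral_vi_", "", pcols))
  if (is.null(offsets)) offsets <- sort(found)
  rows <- list()
  for (off in offsets) {
    for (reg in c("peripheral", "central")) {
      col <- sprintf("%s_vi_%g", reg, off)
      if (!col %in% names(cohort))
        stop_vicad(sprintf("cohort lacks column `%s`", col),
                   "vicad_schema_error")
      for (grp in c("benign", "malignant")) {
        v <- cohort[[col]][if (grp == "malignant") cohort$malignant
                           else !cohort$malignant]
        v <- v[!is.na(v)]
        rows[[length(rows) + 1L]] <- data.frame(
          offset = off, region = reg, group = grp, n = length(v),
          mean = mean(v), sd = stats::sd(v), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' ROC optimum cut-off by the Youden index
#'
#' Scans every observed score as a candidate cut-off under the decision rule
#' "positive iff score >= cutoff", and returns the cut-off maximizing the
#' Youden index J = sensitivity + specificity - 1 (ties broken toward the
#' lower cut-off). The AUC is the Mann–Whitney statistic (ties counted 1/2).
#'
#' @param scores numeric vector of VI values (percent).
#' @param labels logical vector, `TRUE` = malignant; both classes must occur.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`, `auc`
#'   and `points` (the full ROC table over candidate cut-offs).
#' @export
roc_cutoff <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0)
    stop_vicad("`scores` and `labels` must be equal-length and non-empty",
               "vicad_validation_error")
  labels <- as.logical(labels)
  if (anyNA(scores) || any(!is.finite(scores)) || anyNA(labels))
    stop_vicad("scores must be finite and labels complete",
               "vicad_validation_error")
  if (!any(labels) || all(labels))
    stop_vicad("both classes must be present", "vicad_validation_error")
  pos <- scores[labels]; neg <- scores[!labels]
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]        # candidates ascend: first = lowest
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  list(cutoff = cand[best], sensitivity = sens[best], specificity = spec[best],
       youden = j[best], auc = auc,
       points = data.frame(cutoff = cand, sensitivity = sens,
                           specificity = spec, youden = j))
}

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    stop_vicad("counts must be non-negative integers", "vicad_validation_error")
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "confusion_counts")
}

#' Diagnostic test metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp),
#' NPV tn/(tn+fn) and accuracy (tp+tn)/total, each in percent at full
#' precision (reports format them to one decimal, half-up). PPV/NPV are
#' `NA` when their denominator is zero.
#'
#' @param counts a [confusion_counts()].
#' @return named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (percent).
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (tp + fn < 1 || tn + fp < 1)
      stop_vicad("need at least one positive and one negative case",
                 "vicad_validation_error")
    c(sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp),
      ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
      accuracy = 100 * (tp + tn) / (tp + fp + tn + fn))
  })
}

#' Reconstruct confusion counts from published rates
#'
#' Inverts [diagnostic_metrics()] for validation against published tables:
#' given sensitivity and specificity in percent and the group sizes, the
#' counts are `tp = round(sens/100 * n_pos)` and `tn = round(spec/100 *
#' n_neg)` (half-up), with fn/fp by complement.
#'
#' @param sensitivity,specificity percentages in `[0, 100]`.
#' @param n_pos,n_neg group sizes (>= 1).
#' @return a [confusion_counts()].
#' @export
counts_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 100 || specificity < 0 ||
      specificity > 100 || n_pos < 1 || n_neg < 1)
    stop_vicad("rates must lie in [0,100] and group sizes be >= 1",
               "vicad_validation_error")
  tp <- round_half_up(sensitivity / 100 * n_pos)
  tn <- round_half_up(specificity / 100 * n_neg)
  confusion_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Chi-square test of a grey-scale ultrasound feature between groups
#'
#' 2x2 chi-square (no continuity correction by default, matching the study's
#' analysis; set `correct = TRUE` for Yates) of feature presence in benign
#' versus malignant nodules, plus the per-group prevalence.
#'
#' @param cohort cohort data frame with `malignant` and the feature column.
#' @param feature column name, e.g. `"gsu_microcalc"`.
#' @param correct apply Yates continuity correction?
#' @return list with `chi_square`, `df`, `p`, `prevalence` (named percent
#'   vector) and `table` (the 2x2 table).
#' @export
gsu_feature_test <- function(cohort, feature, correct = FALSE) {
  if (!feature %in% names(cohort))
    stop_vicad(sprintf("cohort lacks feature column `%s`", feature),
               "vicad_schema_error")
  grp <- factor(ifelse(cohort$malignant, "malignant", "benign"),
                levels = c("benign", "malignant"))
  feat <- factor(ifelse(cohort[[feature]] != 0, "present", "absent"),
                 levels = c("absent", "present"))
  if (any(table(grp) == 0))
    stop_vicad("both groups must be non-empty", "vicad_validation_error")
  tab <- table(grp, feat)
  prev <- 100 * tab[, "present"] / rowSums(tab)
  if (any(colSums(tab) == 0)) {           # constant feature: no association
    return(list(chi_square = 0, df = 1L, p = 1,
                prevalence = prev, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, prevalence = prev, table = tab)
}
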