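# Classification of Doppler reports against ASE guideline thresholds and
# sensitivity/specificity tables over the study grid.

#' ASE guideline thresholds for suspected valve dysfunction
#'
#' Named list of criteria; each has a metric, a direction and a threshold.
#' Comparisons are inclusive, matching the printed ">= 3 m/s" / "<= 0.35"
#' guideline notation.
#'
#' @return An object of class `ase_criteria`.
#' @export
ase_criteria <- function() {
  crit <- list(
    vpeak_ge_3  = list(metric = "v_peak",   dir = "ge", threshold = 3,
                       label = "Peak velocity >= 3 m/s"),
    vpeak_ge_4  = list(metric = "v_peak",   dir = "ge", threshold = 4,
                       label = "Peak velocity >= 4 m/s"),
    tpg_ge_20   = list(metric = "tpg_mean", dir = "ge", threshold = 20,
                       label = "TPGmean >= 20 mmHg"),
    tpg_ge_35   = list(metric = "tpg_mean", dir = "ge", threshold = 35,
                       label = "TPGmean >= 35 mmHg"),
    dvi_le_0.35 = list(metric = "dvi",      dir = "le", threshold = 0.35,
                       label = "DVI <= 0.35"),
    dvi_le_0.30 = list(metric = "dvi",      dir = "le", threshold = 0.30,
                       label = "DVI <= 0.30"),
    dvi_le_0.25 = list(metric = "dvi",      dir = "le", threshold = 0.25,
                       label = "DVI <= 0.25"),
    eoa_le_1.2  = list(metric = "eoa",      dir = "le", threshold = 1.2,
                       label = "EOA <= 1.2 cm2"),
    eoa_le_0.8  = list(metric = "eoa",      dir = "le", threshold = 0.8,
                       label = "EOA <= 0.8 cm2"))
  structure(crit, class = "ase_criteria")
}

#' Classify a Doppler report against the guideline criteria
#'
#' @param report A `doppler_report` (or any list/row with `v_peak`,
#'   `tpg_mean`, `dvi`, `eoa`).
#' @param criteria An [ase_criteria()] object.
#' @return Named logical vector, one flag per criterion; `TRUE` means the
#'   criterion suggests dysfunction. Boundary equality counts as positive.
#' @export
classify <- function(report, criteria = ase_criteria()) {
  vapply(criteria, function(cr) {
    val <- report[[cr$metric]]
    if (is.null(val) || length(val) != 1L || !is.finite(val))
      stop("missing metric for classification: ", cr$metric, call. = FALSE)
    if (cr$dir == "ge") val >= cr$threshold else val <= cr$threshold
  }, logical(1))
}

#' Ground-truth dysfunction label of a case
#'
#' Two groupings: `mild_to_severe` counts both 50% and 100% one-leaflet
#' dysfunction as positive; `moderate_to_severe` counts only 100%.
#'
#' @param case A [case_spec()] (or list/row with `dysfunction_pct`).
#' @param grouping `"mild_to_severe"` or `"moderate_to_severe"`.
#' @return Logical: `TRUE` if the case is a dysfunction positive.
#' @export
ground_truth <- function(case,
                         grouping = c("mild_to_severe",
                                      "moderate_to_severe")) {
  grouping <- match.arg(grouping)
  if (grouping == "mild_to_severe") case$dysfunction_pct %in% c(50, 100)
  else case$dysfunction_pct == 100
}

#' Sensitivity and specificity of a set of flags against labels
#'
#' Standard confusion-matrix arithmetic. Percentages are exact; use
#' [accuracy_table()] for integer-rounded presentation.
#'
#' @param flags Logical vector of classifier outputs.
#' @param labels Logical vector of ground-truth labels (same length; at
#'   least one positive and one negative).
#' @return List with `sensitivity_pct`, `specificity_pct`, and counts `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
#' @examples
#' sensitivity_specificity(c(TRUE, FALSE, TRUE, FALSE, FALSE),
#'                         c(TRUE, TRUE, FALSE, FALSE, FALSE))
sensitivity_specificity <- function(flags, labels) {
  stopifnot(is.logical(flags), is.logical(labels))
  if (length(flags) != length(labels))
    stop("flags and labels must have equal length", call. = FALSE)
  if (!any(labels))
    stop("degenerate labels: no positive cases", call. = FALSE)
  if (all(labels))
    stop("degenerate labels: no negative cases", call. = FALSE)
  tp <- sum(flags & labels)
  fn <- sum(!flags & labels)
  tn <- sum(!flags & !labels)
  fp <- sum(flags & !labels)
  list(sensitivity_pct = 100 * tp / (tp + fn),
       specificity_pct = 100 * tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Sensitivity/specificity table over both severity groupings
#'
#' One row per guideline criterion and grouping, mirroring the layout of a
#' clinical accuracy table: integer-rounded percentages for presentation
#' plus the exact fractions and confusion counts.
#'
#' @param reports_df Data.frame from [reports_to_df()] including a
#'   `dysfunction_pct` column.
#' @param criteria An [ase_criteria()] object.
#' @return Data.frame with columns `criterion`, `label`, `grouping`,
#'   `sensitivity`, `specificity` (integers), `sensitivity_exact`,
#'   `specificity_exact`, `tp`, `fp`, `tn`, `fn`.
#' @export
accuracy_table <- function(reports_df, criteria = ase_criteria()) {
  stopifnot("dysfunction_pct" %in% names(reports_df))
  rows <- list()
  for (cn in names(criteria)) {
    cr <- criteria[[cn]]
    flags <- vapply(seq_len(nrow(reports_df)), function(i)
      classify(as.list(reports_df[i, ]), criteria)[[cn]], logical(1))
    for (grp in c("mild_to_severe", "moderate_to_severe")) {
      labels <- vapply(seq_len(nrow(reports_df)), function(i)
        ground_truth(as.list(reports_df[i, ]), grp), logical(1))
      ss <- sensitivity_specificity(flags, labels)
      rows[[length(rows) + 1L]] <- data.frame(
        criterion = cn, label = cr$label, grouping = grp,
        sensitivity = round(ss$sensitivity_pct),
        specificity = round(ss$specificity_pct),
        sensitivity_exact = ss$sensitivity_pct,
        specificity_exact = ss$specificity_pct,
        tp = ss$tp, fp = ss$fp, tn = ss$tn, fn = ss$fn,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-diameter summary of the Doppler metrics
#'
#' Mean, sample standard deviation (n - 1) and range of each Doppler metric
#' grouped by LVOT diameter, ordered by diameter descending.
#'
#' @param reports_df Data.frame from [reports_to_df()] including an
#'   `lvot_diameter_mm` column; at least 2 reports per diameter.
#' @return Long-format data.frame with columns `lvot_diameter_mm`, `metric`,
#'   `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_by_lvot <- function(reports_df) {
  stopifnot("lvot_diameter_mm" %in% names(reports_df))
  metrics <- c("v_peak", "tpg_mean", "dvi", "eoa")
  diams <- sort(unique(reports_df$lvot_diameter_mm), decreasing = TRUE)
  rows <- list()
  for (d in diams) {
    sub <- reports_df[reports_df$lvot_diameter_mm == d, ]
    if (nrow(sub) < 2)
      stop("fewer than 2 reports for diameter ", d, " mm", call. = FALSE)
    for (m in metrics) {
      x <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        lvot_diameter_mm = d, metric = m, mean = mean(x), sd = sd(x),
        min = min(x), max = max(x), n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
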