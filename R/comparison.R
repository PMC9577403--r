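#' Cross-tabulate one method's signals against a reference
#'
#' Builds the four-fold table used to benchmark a disproportionality
#' method against a reference method: `tp` = both flag, `fp` = method
#' flags but reference does not, `fn` = reference flags but method does
#' not, `tn` = neither. When `min_cases` is given, only combinations with
#' at least that many cases enter the table.
#'
#' @param flags Logical vector: the method's signal per combination.
#' @param reference_flags Logical vector: the reference's signal.
#' @param case_counts Optional integer vector of case counts (required
#'   when `min_cases` is used).
#' @param min_cases Optional case-count floor for the comparison stratum.
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(flags, reference_flags, case_counts = NULL,
                      min_cases = NULL) {
  if (length(flags) != length(reference_flags)) {
    abort("flags and reference_flags must have equal length")
  }
  if (!is.null(min_cases)) {
    if (is.null(case_counts) || length(case_counts) != length(flags)) {
      abort("case_counts of matching length is required with min_cases")
    }
    keep <- case_counts >= min_cases
    flags <- flags[keep]
    reference_flags <- reference_flags[keep]
  }
  tibble(
    tp = sum(flags & reference_flags),
    fp = sum(flags & !reference_flags),
    fn = sum(!flags & reference_flags),
    tn = sum(!flags & !reference_flags)
  )
}

#' Diagnostic metrics of a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive and
#' negative predictive values, and the Youden index
#' (sensitivity + specificity - 1). Any 0/0 ratio is undefined and
#' reported as `NA`, never coerced to 0 — an empty stratum carries no
#' information and silently zeroing it would corrupt the Youden index.
#'
#' @param ct A one-row confusion tibble from [confusion()] (or any data
#'   frame with columns `tp`, `fp`, `fn`, `tn`).
#' @return `ct` with columns `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden` appended.
#' @export
confusion_metrics <- function(ct) {
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  ct %>% mutate(
    sensitivity = safe_ratio(.data$tp, .data$tp + .data$fn),
    specificity = safe_ratio(.data$tn, .data$fp + .data$tn),
    ppv = safe_ratio(.data$tp, .data$tp + .data$fp),
    npv = safe_ratio(.data$tn, .data$fn + .data$tn),
    youden = .data$sensitivity + .data$specificity - 1
  )
}

#' Compare methods against a reference across case-count thresholds
#'
#' For each method and each case-count threshold, restricts the screen to
#' combinations with at least that many cases, cross-tabulates the
#' method's signals against the reference method's, and computes the
#' diagnostic metrics. The default thresholds 3, 4, 5, 6, 7, 11 span the
#' case-count strata commonly examined in single-hospital screens.
#'
#' @param screen A `signal_screen` (from [detect_signals()] or
#'   [screen_from_printed()]).
#' @param reference Reference method (default `"BCPNN"`, the usual
#'   Bayesian reference standard).
#' @param thresholds Ascending integer case-count thresholds.
#' @param methods Methods to compare (default: all but the reference).
#' @return A `method_comparison` tibble: `method`, `min_cases`,
#'   `sample_size`, `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `youden`. Empty strata keep their row with `NA`
#'   metrics.
#' @seealso [roc_points()], [roc_auc()], [autoplot.method_comparison()]
#' @export
compare_methods <- function(screen, reference = "BCPNN",
                            thresholds = c(3L, 4L, 5L, 6L, 7L, 11L),
                            methods = NULL) {
  reference <- match.arg(reference, methods_all)
  if (length(thresholds) == 0L || is.unsorted(thresholds)) {
    abort("thresholds must be a nonempty ascending integer vector")
  }
  if (is.null(methods)) methods <- setdiff(methods_all, reference)
  fl <- signal_flags(screen)
  rows <- tidyr::crossing(method = methods, min_cases = as.integer(thresholds)) %>%
    mutate(method = factor(.data$method,
                           levels = intersect(methods_all, methods))) %>%
    arrange(.data$method, .data$min_cases)
  out <- purrr::pmap(rows, function(method, min_cases) {
    ct <- confusion(fl[[as.character(method)]], fl[[reference]],
                    case_counts = fl$n_cases, min_cases = min_cases)
    tibble(method = method, min_cases = min_cases,
           sample_size = sum(fl$n_cases >= min_cases)) %>%
      dplyr::bind_cols(confusion_metrics(ct))
  }) %>% bind_rows()
  attr(out, "reference") <- reference
  class(out) <- c("method_comparison", class(tibble()))
  out
}

#' ROC points of a threshold sweep
#'
#' Builds the receiver operating characteristic point set of one method
#' from its threshold-sweep rows: one point (1 - specificity,
#' sensitivity) per case-count threshold, deduplicated, anchored at
#' (0, 0) and (1, 1), and sorted by abscissa.
#'
#' @param comparison A `method_comparison` tibble.
#' @param method Method whose points to extract.
#' @return A tibble `fpr`, `tpr` defining the ROC polyline.
#' @export
roc_points <- function(comparison, method) {
  rows <- comparison %>%
    filter(.data$method == .env$method,
           !is.na(.data$sensitivity), !is.na(.data$specificity)) %>%
    mutate(fpr = 1 - .data$specificity, tpr = .data$sensitivity) %>%
    select("fpr", "tpr")
  if (nrow(rows) == 0L) abort("no defined (sensitivity, specificity) points")
  bind_rows(tibble(fpr = 0, tpr = 0), rows, tibble(fpr = 1, tpr = 1)) %>%
    distinct() %>%
    arrange(.data$fpr, .data$tpr)
}

#' Area under the threshold-sweep ROC curve
#'
#' Trapezoidal area under the anchored ROC polyline of [roc_points()],
#' computed per method. Note that a sweep in which a method's specificity
#' is 1 at every threshold contributes only points on the left edge, so
#' the anchored trapezoid construction yields 0.5 + sensitivity-dependent
#' area, not 1; a sweep-based AUC is a coarse summary of a handful of
#' operating points, not of a continuous score. For a score-based ROC use
#' [roc_scores()].
#'
#' @param comparison A `method_comparison` tibble.
#' @param methods Methods to evaluate (default: all present).
#' @return A tibble `method`, `auc`.
#' @export
roc_auc <- function(comparison, methods = NULL) {
  if (is.null(methods)) methods <- unique(as.character(comparison$method))
  purrr::map(methods, function(m) {
    pts <- tryCatch(roc_points(comparison, m), error = function(e) NULL)
    auc <- if (is.null(pts)) NA_real_ else trapezoid_area(pts$fpr, pts$tpr)
    tibble(method = m, auc = auc)
  }) %>% bind_rows()
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Score-based ROC against the reference labels
#'
#' An alternative ROC construction: each method's continuous statistic
#' (PRR, ROR, chi-square or IC point estimate) is used as a score for
#' predicting the reference method's signal labels, and the full ROC
#' curve over all score cutoffs is computed with \pkg{pROC}.
#'
#' @param screen A `signal_screen`.
#' @param method Method whose statistic provides the score.
#' @param reference Reference method providing the labels.
#' @return A `pROC::roc` object (use `pROC::auc()` on it).
#' @export
roc_scores <- function(screen, method, reference = "BCPNN") {
  method <- match.arg(method, methods_all)
  if (!requireNamespace("pROC", quietly = TRUE)) {
    abort("score-based ROC requires the 'pROC' package")
  }
  score <- switch(method, PRR = screen$prr, ROR = screen$ror,
                  MHRA = screen$chi2, BCPNN = screen$ic)
  labels <- signal_flags(screen)[[reference]]
  pROC::roc(response = labels, predictor = score, quiet = TRUE,
            direction = "<", levels = c(FALSE, TRUE))
}
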