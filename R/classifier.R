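#' ROC curve for stiffness as a binary marker
#'
#' Sweeps a stiffness threshold over all distinct observed values (plus
#' infinite endpoints); a ROI is called positive when its value is strictly
#' above the threshold. Tied values step simultaneously. The AUC is the
#' trapezoidal area under the (FPR, TPR) polyline, which equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg` (with midrank ties).
#'
#' @param values Numeric marker values (kPa).
#' @param labels Logical vector, `TRUE` for the positive (mutant) class.
#' @return An object of class `oce_roc`: `thresholds`, `tpr`, `fpr`
#'   (ordered by increasing threshold), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels) || anyNA(values) || anyNA(labels))
    stop("values and labels must be complete and of equal length", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  th <- c(-Inf, sort(unique(values)))
  tpr <- vapply(th, function(t) sum(labels & values > t) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(!labels & values > t) / n_neg, numeric(1))
  # trapezoid over the fpr-sorted polyline (fpr decreases with threshold)
  auc <- sum(-diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "oce_roc")
}

#' Youden-optimal threshold
#'
#' Maximizes the Youden index `J = TPR - FPR` over the ROC sweep, breaking
#' ties toward the smallest threshold. The reported threshold is the midpoint
#' between the optimal cut's flanking observed values (so the cut lies in the
#' open gap between classes rather than on an observation).
#'
#' @param roc An [roc_curve()] result.
#' @return A list: `threshold_kpa`, `j`. When every value is identical the
#'   Youden index is 0, the threshold is that value, and a degeneracy warning
#'   is raised.
#' @export
youden_threshold <- function(roc) {
  j <- roc$tpr - roc$fpr
  k <- which.max(j)                       # first maximum = smallest threshold
  obs <- roc$thresholds[is.finite(roc$thresholds)]
  if (length(obs) == 1L) {
    warning("degenerate ROC: all values identical", call. = FALSE)
    return(list(threshold_kpa = obs, j = 0))
  }
  t_star <- roc$thresholds[k]
  if (!is.finite(t_star)) {
    # all-positive cut: report just below the smallest observation
    return(list(threshold_kpa = min(obs), j = j[k]))
  }
  nxt <- obs[obs > t_star]
  thr <- if (length(nxt)) (t_star + min(nxt)) / 2 else t_star
  list(threshold_kpa = thr, j = j[k])
}

#' Confusion metrics at a fixed stiffness threshold
#'
#' Positive call = value strictly above the threshold (boundary equality is
#' negative). Sensitivity, specificity and diagnostic accuracy are derived
#' from the counts; with a single-class input the undefined rate is `NA` and
#' flagged.
#'
#' @param values Numeric marker values (kPa).
#' @param labels Logical vector, `TRUE` = positive class.
#' @param threshold Threshold (kPa), or a pattern label for pattern-based
#'   markers (see [pattern_marker_metrics()]).
#' @return An object of class `oce_confusion`: `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `accuracy`, `threshold`,
#'   `undefined_rates`.
#' @export
metrics_at_threshold <- function(values, labels, threshold) {
  labels <- as.logical(labels)
  call_pos <- values > threshold
  tp <- sum(call_pos & labels); fn <- sum(!call_pos & labels)
  fp <- sum(call_pos & !labels); tn <- sum(!call_pos & !labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / length(values),
                 threshold = threshold,
                 undefined_rates = is.na(sens) || is.na(spec)),
            class = "oce_confusion")
}

#' Morphological pattern as a mutation marker
#'
#' Baseline classifier: a ROI is called mutant when its morphological
#' pattern equals the marker pattern. Evaluated over all ROIs against the
#' any-driver mutation label.
#'
#' @param cohort An [sample_cohort()] table.
#' @param marker_pattern One of `"complex_tubular"`, `"mucinous"`, `"solid"`.
#' @return An `oce_confusion` object with `threshold` set to the pattern
#'   label.
#' @export
pattern_marker_metrics <- function(cohort, marker_pattern) {
  if (!marker_pattern %in% cohort$pattern)
    stop("pattern absent from cohort: ", marker_pattern, call. = FALSE)
  labels <- cohort$mutation != "wt"
  call_pos <- cohort$pattern == marker_pattern
  tp <- sum(call_pos & labels); fn <- sum(!call_pos & labels)
  fp <- sum(call_pos & !labels); tn <- sum(!call_pos & !labels)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / nrow(cohort),
                 threshold = marker_pattern, undefined_rates = FALSE),
            class = "oce_confusion")
}

#' Flag intratumorally heterogeneous cases
#'
#' For every case contributing more than one ROI, reports the per-ROI
#' stiffness-threshold calls against both the any-driver and the
#' KRAS-specific thresholds, and flags the case as discordant when its ROIs
#' receive different calls (the signature of intratumoral molecular
#' heterogeneity, as in the study's case #21 where a complex tubular ROI at
#' 937.7 kPa and a mucinous ROI at 840.8 kPa straddle the 850 kPa cut).
#'
#' @param cohort An [sample_cohort()] table.
#' @param cfg An [classifier_config()] object.
#' @return A `data.frame` with one row per multi-ROI case: `case_id`,
#'   `n_roi`, `calls_any_driver`, `calls_kras`, `discordant_any_driver`,
#'   `discordant_kras`. Single-ROI cases are not reported.
#' @export
flag_heterogeneous_cases <- function(cohort, cfg = classifier_config()) {
  sp <- split(cohort, cohort$case_id)
  sp <- sp[vapply(sp, nrow, integer(1)) > 1L]
  out <- lapply(sp, function(d) {
    any_call <- d$stiffness_kpa > cfg$threshold_any_driver_kpa
    kras_call <- d$stiffness_kpa > cfg$threshold_kras_kpa
    data.frame(case_id = d$case_id[1], n_roi = nrow(d),
               calls_any_driver = paste(ifelse(any_call, "pos", "neg"),
                                        collapse = ","),
               calls_kras = paste(ifelse(kras_call, "pos", "neg"),
                                  collapse = ","),
               discordant_any_driver = length(unique(any_call)) > 1L,
               discordant_kras = length(unique(kras_call)) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(case_id = integer(), n_roi = integer(),
                      calls_any_driver = character(), calls_kras = character(),
                      discordant_any_driver = logical(),
                      discordant_kras = logical()))
  rownames(out) <- NULL
  out[order(out$case_id), ]
}
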