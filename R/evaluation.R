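# The metric family used to compare the two arms: sensitivity,
# specificity and CCR (the mean of the two); conformal variants counting
# 'both' predictions as correct (_incl) or dropping those compounds
# (_excl); per-class and overall conformal validity; both/empty set
# fractions; cross-set Tanimoto similarity diagnostics; and family-level
# aggregation.

rate_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Sensitivity, specificity and CCR for single-class predictions
#'
#' Sensitivity = TP / (TP + FN) over true actives, specificity =
#' TN / (TN + FP) over true inactives, CCR = their mean.  A class absent
#' from the labels leaves its rate (and the CCR) missing.
#'
#' @param predicted predicted classes (`"active"`/`"inactive"`); missing
#'   predictions are dropped with their labels.
#' @param labels true classes.
#' @return named numeric vector `sensitivity`, `specificity`, `ccr`.
#' @export
qsar_metrics <- function(predicted, labels) {
  keep <- !is.na(predicted)
  predicted <- as.character(predicted)[keep]
  labels <- as.character(labels)[keep]
  sens <- rate_or_na(sum(predicted == "active" & labels == "active"),
                     sum(labels == "active"))
  spec <- rate_or_na(sum(predicted == "inactive" & labels == "inactive"),
                     sum(labels == "inactive"))
  c(sensitivity = sens, specificity = spec, ccr = (sens + spec) / 2)
}

#' Sensitivity, specificity and CCR for conformal prediction sets
#'
#' `"incl"` counts a compound as correct when its prediction set is the
#' correct single class *or* `"both"`; the denominator is every compound
#' of the class (so single-wrong and empty predictions are errors).
#' `"excl"` removes `"both"` compounds from numerator and denominator;
#' empty predictions still count as errors in the denominator.  If every
#' compound of a class is predicted `"both"`, the excl rate is undefined
#' and reported missing.
#'
#' @param sets prediction-set labels from [assign_prediction_set()].
#' @param labels true classes.
#' @param mode `"incl"` or `"excl"`.
#' @return named numeric vector `sensitivity`, `specificity`, `ccr`.
#' @export
mcp_metrics <- function(sets, labels, mode = c("incl", "excl")) {
  mode <- match.arg(mode)
  keep <- !is.na(sets)
  sets <- as.character(sets)[keep]
  labels <- as.character(labels)[keep]
  class_rate <- function(cls) {
    in_class <- labels == cls
    if (mode == "excl") in_class <- in_class & sets != "both"
    correct <- sets[in_class] == cls
    if (mode == "incl") correct <- correct | sets[in_class] == "both"
    rate_or_na(sum(correct), sum(in_class))
  }
  sens <- class_rate("active")
  spec <- class_rate("inactive")
  c(sensitivity = sens, specificity = spec, ccr = (sens + spec) / 2)
}

#' Conformal validity
#'
#' A conformal predictor is valid at significance epsilon when its error
#' rate does not exceed epsilon, where an error is a prediction set that
#' does not contain the true class (a single-wrong or empty prediction;
#' `"both"` always contains the truth).  Scope restricts the assessment
#' to compounds of one class.
#'
#' @param sets prediction-set labels.
#' @param labels true classes.
#' @param epsilon significance level.
#' @param scope `"overall"`, `"active"` or `"inactive"`.
#' @return list with `valid` (logical), `error_rate`, `n`.
#' @export
validity <- function(sets, labels, epsilon,
                     scope = c("overall", "active", "inactive")) {
  scope <- match.arg(scope)
  keep <- !is.na(sets)
  sets <- as.character(sets)[keep]
  labels <- as.character(labels)[keep]
  if (scope != "overall") {
    sets <- sets[labels == scope]
    labels <- labels[labels == scope]
  }
  errors <- !(sets == labels | sets == "both")
  rate <- rate_or_na(sum(errors), length(errors))
  list(valid = !is.na(rate) && rate <= epsilon, error_rate = rate,
       n = length(errors))
}

#' Fractions of 'both' and 'empty' prediction sets
#'
#' @param sets prediction-set labels.
#' @return named numeric vector `both`, `empty`, `single`; the three sum
#'   to 1.
#' @export
set_fractions <- function(sets) {
  sets <- as.character(sets[!is.na(sets)])
  n <- length(sets)
  both <- rate_or_na(sum(sets == "both"), n)
  empty <- rate_or_na(sum(sets == "empty"), n)
  c(both = both, empty = empty, single = 1 - both - empty)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over on-bits; a pair of all-zero fingerprints
#' has similarity 0 by convention.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) 0 else inter / union
}

#' Median cross-set Tanimoto similarity
#'
#' Diagnostic for conformal behaviour: the median Tanimoto coefficient
#' over all cross-set pairs between (for example) the test-set and
#' calibration-set compounds of one class.  Low values flag test
#' compounds too dissimilar from the calibration set for confident
#' single-class assignment.
#'
#' @param x,y 0/1 fingerprint matrices (rows = compounds, same number of
#'   columns).
#' @return median pairwise similarity.
#' @export
tanimoto_diagnostic <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) > 0, nrow(y) > 0, ncol(x) == ncol(y))
  inter <- x %*% t(y)
  on_x <- rowSums(x)
  on_y <- rowSums(y)
  union <- outer(on_x, on_y, "+") - inter
  sim <- ifelse(union == 0, 0, inter / union)
  stats::median(sim)
}

#' Per-target metrics for both arms
#'
#' Assembles the long-format metrics table for one target: one QSAR row
#' and, per epsilon, one incl and one excl conformal row with set
#' fractions and validity flags.
#'
#' @param qsar result of [run_qsar_protocol()] (or NULL to skip the arm).
#' @param mcp result of [run_mcp_protocol()] (or NULL).
#' @param target_id,family identifiers for the output rows.
#' @param n_active,n_inactive class counts for the output rows.
#' @return data.frame, one row per (arm, epsilon, mode).
#' @export
metrics_report <- function(qsar = NULL, mcp = NULL, target_id = NA_character_,
                           family = NA_character_, n_active = NA_integer_,
                           n_inactive = NA_integer_) {
  base <- function(arm, epsilon, mode, m, fb = NA_real_, fe = NA_real_,
                   vo = NA, va = NA, vi = NA, eo = NA_real_) {
    data.frame(target_id = target_id, family = family, arm = arm,
               epsilon = epsilon, mode = mode,
               sensitivity = unname(m[["sensitivity"]]),
               specificity = unname(m[["specificity"]]),
               ccr = unname(m[["ccr"]]),
               fraction_both = fb, fraction_empty = fe,
               valid_overall = vo, valid_active = va, valid_inactive = vi,
               error_rate_overall = eo,
               n_active = n_active, n_inactive = n_inactive,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (!is.null(qsar)) {
    rows[["qsar"]] <- base("qsar", NA_real_, NA_character_,
                           qsar_metrics(qsar$qsar_class, qsar$label))
  }
  if (!is.null(mcp)) {
    for (eps in attr(mcp, "epsilons")) {
      col <- sprintf("set_at_%d", as.integer(round(100 * (1 - eps))))
      sets <- mcp[[col]]
      fr <- set_fractions(sets)
      vo <- validity(sets, mcp$label, eps, "overall")
      va <- validity(sets, mcp$label, eps, "active")
      vi <- validity(sets, mcp$label, eps, "inactive")
      for (mode in c("incl", "excl")) {
        rows[[paste0("mcp_", eps, "_", mode)]] <- base(
          "mcp", eps, mode, mcp_metrics(sets, mcp$label, mode),
          fb = unname(fr[["both"]]), fe = unname(fr[["empty"]]),
          vo = vo$valid, va = va$valid, vi = vi$valid,
          eo = vo$error_rate)
      }
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' Aggregate per-target metrics by protein family
#'
#' Unweighted mean of each metric over the targets of a family, separately
#' per (arm, epsilon, mode); validity flags aggregate to the fraction of
#' valid models.
#'
#' @param metrics long-format table from [metrics_report()] /
#'   [run_benchmark()].
#' @return data.frame keyed by (family, arm, epsilon, mode) with mean
#'   metrics and `n_targets`.
#' @export
aggregate_by_family <- function(metrics) {
  key <- interaction(metrics$family, metrics$arm,
                     ifelse(is.na(metrics$epsilon), "-", metrics$epsilon),
                     ifelse(is.na(metrics$mode), "-", metrics$mode),
                     drop = TRUE)
  rows <- lapply(split(metrics, key), function(sub) {
    data.frame(
      family = sub$family[[1L]], arm = sub$arm[[1L]],
      epsilon = sub$epsilon[[1L]], mode = sub$mode[[1L]],
      n_targets = length(unique(sub$target_id)),
      sensitivity = mean(sub$sensitivity, na.rm = TRUE),
      specificity = mean(sub$specificity, na.rm = TRUE),
      ccr = mean(sub$ccr, na.rm = TRUE),
      fraction_both = mean(sub$fraction_both, na.rm = TRUE),
      fraction_empty = mean(sub$fraction_empty, na.rm = TRUE),
      fraction_valid_overall = mean(sub$valid_overall, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out[order(out$family, out$arm), , drop = FALSE]
}

#' Confusion-count table with an uncertain category
#'
#' Counts correct, incorrect and uncertain predictions per true class,
#' where for conformal sets "uncertain" regroups `"both"` and `"empty"`
#' predictions; single-class predictors have no uncertain column mass.
#'
#' @param predicted single-class predictions or prediction-set labels.
#' @param labels true classes.
#' @return data.frame with rows `active`/`inactive` and columns
#'   `correct`, `incorrect`, `uncertain`.
#' @export
confusion_counts <- function(predicted, labels) {
  keep <- !is.na(predicted)
  predicted <- as.character(predicted)[keep]
  labels <- as.character(labels)[keep]
  out <- t(vapply(c("active", "inactive"), function(cls) {
    p <- predicted[labels == cls]
    uncertain <- p %in% c("both", "empty")
    c(correct = sum(p == cls), incorrect = sum(!uncertain & p != cls),
      uncertain = sum(uncertain))
  }, numeric(3L)))
  as.data.frame(out)
}
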