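# Mondrian (class-conditional) conformal prediction over any probability
# model: per-class calibration score lists, p-values, and epsilon-level
# prediction sets with single/both/empty semantics.  The conformity score
# of a compound for a class is the model's predicted probability of that
# class; a class enters the prediction set when its p-value exceeds the
# significance level epsilon (confidence = 1 - epsilon).

#' Split a training set into proper-training and calibration sets
#'
#' Random split stratified on the activity class (so that both per-class
#' calibration lists are non-empty), taking `fraction` of each class into
#' the calibration set, rounded to the nearest compound with at least one
#' compound per class on each side.  Deterministic given the seed.
#'
#' @param labels `"active"`/`"inactive"` for the training set.
#' @param fraction calibration fraction (default 0.30).
#' @param seed integer seed.
#' @return list with integer index vectors `proper` and `calibration`
#'   (relative to the supplied training set).
#' @export
split_proper_calibration <- function(labels, fraction = 0.30, seed = 1L) {
  calibration <- stratified_indices(labels, fraction, seed)
  list(proper = setdiff(seq_along(labels), calibration),
       calibration = calibration)
}

#' Build per-class calibration score lists
#'
#' Applies a fitted model to the calibration set and records, separately
#' per class, the predicted probability of the *true* class of each
#' calibration compound, sorted ascending.  The Mondrian split into
#' per-class lists is what protects the minority class.
#'
#' @param model a `qsar_model` fitted on the proper training set.
#' @param x calibration feature matrix.
#' @param labels true classes of the calibration compounds.
#' @return object of class `mondrian_calibration` with sorted numeric
#'   vectors `scores_active` and `scores_inactive`.
#' @export
calibrate <- function(model, x, labels) {
  y <- as_label_factor(labels)
  if (any(table(y) == 0L)) {
    stop("calibration set must contain both classes", call. = FALSE)
  }
  p_active <- predict_prob_active(model, x)
  structure(list(
    scores_active = sort(p_active[y == "active"]),
    scores_inactive = sort(1 - p_active[y == "inactive"])
  ), class = "mondrian_calibration")
}

#' Conformal p-value from a calibration score list
#'
#' In `"literal"` mode the p-value is the fraction of calibration scores
#' strictly lower than the new compound's score, `#\{s < p\} / n` (ties
#' excluded).  In `"adjusted"` mode the standard finite-sample-corrected
#' definition `(#\{s <= p\} + 1) / (n + 1)` is used (ties included), which
#' carries the usual conformal coverage guarantee.
#'
#' @param scores calibration score list for one class (need not be
#'   sorted).
#' @param p_new numeric vector of new-compound scores for that class.
#' @param mode `"literal"` or `"adjusted"`.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
p_value <- function(scores, p_new, mode = c("literal", "adjusted")) {
  mode <- match.arg(mode)
  if (!length(scores)) {
    stop("calibration score list is empty", call. = FALSE)
  }
  n <- length(scores)
  vapply(p_new, function(q) {
    switch(mode,
           literal = sum(scores < q) / n,
           adjusted = (sum(scores <= q) + 1) / (n + 1))
  }, numeric(1L))
}

#' Per-class p-values for new compounds
#'
#' @param calibration a `mondrian_calibration`.
#' @param prob_active model probabilities `P(active)` of new compounds.
#' @param mode p-value mode, see [p_value()].
#' @return data.frame with columns `p_active`, `p_inactive`.
#' @export
mondrian_p_values <- function(calibration, prob_active,
                              mode = c("literal", "adjusted")) {
  stopifnot(inherits(calibration, "mondrian_calibration"))
  mode <- match.arg(mode)
  data.frame(
    p_active = p_value(calibration$scores_active, prob_active, mode),
    p_inactive = p_value(calibration$scores_inactive, 1 - prob_active, mode)
  )
}

#' Prediction set at a significance level
#'
#' A class belongs to the prediction set iff its p-value is strictly
#' greater than epsilon.  The result is one of `"active"` or
#' `"inactive"` (single-class predictions), `"both"`, or `"empty"`.
#' Prediction sets are nested: lowering epsilon can only add members.
#'
#' @param p_active,p_inactive p-value vectors.
#' @param epsilon significance level in (0, 1); confidence = 1 - epsilon.
#' @return character vector over
#'   `c("active", "inactive", "both", "empty")`.
#' @export
assign_prediction_set <- function(p_active, p_inactive, epsilon) {
  stopifnot(is_scalar_number(epsilon), epsilon > 0, epsilon < 1)
  in_active <- p_active > epsilon
  in_inactive <- p_inactive > epsilon
  ifelse(in_active & in_inactive, "both",
         ifelse(in_active, "active",
                ifelse(in_inactive, "inactive", "empty")))
}

#' Members of a prediction set label
#'
#' @param set character vector from [assign_prediction_set()].
#' @return list of character vectors (subsets of
#'   `c("active", "inactive")`).
#' @export
set_members <- function(set) {
  lapply(set, function(s) switch(s,
    active = "active",
    inactive = "inactive",
    both = c("active", "inactive"),
    empty = character(0L),
    stop("unknown prediction-set label: ", s, call. = FALSE)))
}

#' Run the repeated-split Mondrian conformal protocol for one target
#'
#' Shares the first 80/20 split (identical seeds, hence identical test
#' sets) with the QSAR arm; within each repeat the training set is further
#' divided 70/30 into proper-training and calibration sets, a forest is
#' fitted on the proper training set, per-class calibration lists built,
#' and test-compound p-values computed.  Per compound, the median
#' `p_active` and `p_inactive` over the repeats in which it was in the
#' test set are reported, and prediction sets are derived from those
#' median p-values at each epsilon.
#'
#' @param x feature matrix with rownames = compound ids.
#' @param labels `"active"`/`"inactive"` per row.
#' @param plan a [split_plan()] (same seeds as the QSAR arm).
#' @param config an [rf_config()].
#' @param epsilons significance levels; the defaults correspond to 70, 80
#'   and 90% confidence.
#' @param mode p-value mode, see [p_value()].
#' @return data.frame: `compound_id`, `label`, `p_active_median`,
#'   `p_inactive_median`, one `set_at_<confidence>` column per epsilon,
#'   `n_test_appearances`, `p_value_mode`; epsilons kept in attribute
#'   `"epsilons"`.
#' @export
run_mcp_protocol <- function(x, labels, plan = split_plan(),
                             config = rf_config(),
                             epsilons = c(0.30, 0.20, 0.10),
                             mode = c("literal", "adjusted")) {
  stopifnot(inherits(plan, "split_plan"), all(epsilons > 0 & epsilons < 1))
  mode <- match.arg(mode)
  n <- nrow(x)
  p_act <- vector("list", n)
  p_inact <- vector("list", n)
  appearances <- integer(n)
  for (r in seq_len(plan$n_repeats)) {
    sp <- stratified_split(labels, plan$test_fraction, plan$split_seeds[[r]])
    xs <- scale_physchem(x, sp$train)
    pc <- split_proper_calibration(labels[sp$train],
                                   plan$calibration_fraction,
                                   plan$calibration_seeds[[r]])
    proper <- sp$train[pc$proper]
    calib <- sp$train[pc$calibration]
    cfg <- config
    cfg$seed <- plan$rf_seeds[[r]]
    model <- train_rf(xs[proper, , drop = FALSE], labels[proper], cfg)
    mc <- calibrate(model, xs[calib, , drop = FALSE], labels[calib])
    pv <- mondrian_p_values(mc, predict_prob_active(model, xs[sp$test, , drop = FALSE]),
                            mode = mode)
    for (k in seq_along(sp$test)) {
      i <- sp$test[[k]]
      p_act[[i]] <- c(p_act[[i]], pv$p_active[[k]])
      p_inact[[i]] <- c(p_inact[[i]], pv$p_inactive[[k]])
      appearances[[i]] <- appearances[[i]] + 1L
    }
  }
  med <- function(lst) vapply(lst, function(p) {
    if (is.null(p)) NA_real_ else stats::median(p)
  }, numeric(1L))
  out <- data.frame(
    compound_id = rownames(x) %||% as.character(seq_len(n)),
    label = as.character(labels),
    p_active_median = med(p_act),
    p_inactive_median = med(p_inact),
    stringsAsFactors = FALSE
  )
  for (eps in epsilons) {
    col <- sprintf("set_at_%d", as.integer(round(100 * (1 - eps))))
    out[[col]] <- ifelse(
      is.na(out$p_active_median), NA_character_,
      assign_prediction_set(out$p_active_median, out$p_inactive_median, eps))
  }
  out$n_test_appearances <- appearances
  out$p_value_mode <- mode
  attr(out, "epsilons") <- epsilons
  out
}
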