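# Orchestration of the two modelling arms over curated targets: shared
# repeated splits, per-target predictions, long-format metrics, and the
# temporal-validation workflow across two releases.

features_for <- function(features, keys) {
  missing <- setdiff(keys, rownames(features))
  if (length(missing)) {
    stop("no features for structure key(s): ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  }
  x <- features[keys, , drop = FALSE]
  attr(x, "physchem_cols") <- physchem_cols(features)
  x
}

#' Run both modelling arms over curated targets
#'
#' For each retained target: the repeated-split QSAR protocol and the
#' Mondrian conformal protocol under the *same* first-split seeds, then
#' the per-target metrics table.  A failure in one target is logged and
#' skipped; the remaining targets still run (the benchmark builds many
#' independent models).
#'
#' @param datasets named list of `target_dataset` objects (from
#'   [curate_activity_table()]).
#' @param features feature matrix keyed by structure string (rownames
#'   matching the datasets' `smiles` column), physchem block raw.
#' @param plan a [split_plan()]; its seeds are shared by both arms.
#' @param config an [rf_config()].
#' @param epsilons significance levels for the conformal arm.
#' @param mode conformal p-value mode, see [p_value()].
#' @param arms which arms to run.
#' @return list: `predictions` (per target: `qsar`, `mcp` data.frames),
#'   `metrics` (long data.frame, one row per target x arm x epsilon x
#'   mode), `errors` (per-target error messages, if any).
#' @export
run_benchmark <- function(datasets, features, plan = split_plan(),
                          config = rf_config(),
                          epsilons = c(0.30, 0.20, 0.10),
                          mode = c("literal", "adjusted"),
                          arms = c("qsar", "mcp")) {
  mode <- match.arg(mode)
  arms <- match.arg(arms, several.ok = TRUE)
  predictions <- list()
  metrics <- list()
  errors <- character()
  for (ds in datasets) {
    tid <- ds$target_id
    res <- tryCatch({
      x <- features_for(features, ds$compounds$smiles)
      rownames(x) <- ds$compounds$compound_id
      labels <- ds$compounds$label
      qsar <- if ("qsar" %in% arms) {
        run_qsar_protocol(x, labels, plan, config)
      }
      mcp <- if ("mcp" %in% arms) {
        run_mcp_protocol(x, labels, plan, config, epsilons, mode)
      }
      list(qsar = qsar, mcp = mcp,
           metrics = metrics_report(qsar, mcp, target_id = tid,
                                    family = ds$family,
                                    n_active = ds$n_active,
                                    n_inactive = ds$n_inactive))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[tid]] <- conditionMessage(res)
      warning("target ", tid, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      predictions[[tid]] <- res[c("qsar", "mcp")]
      metrics[[tid]] <- res$metrics
    }
  }
  out_metrics <- do.call(rbind, unname(metrics)) %||% data.frame()
  rownames(out_metrics) <- NULL
  list(predictions = predictions, metrics = out_metrics, errors = errors)
}

#' Identify compounds new to the later release for one target
#'
#' @param dataset_a,dataset_b `target_dataset` objects for the same target
#'   curated from the earlier and later release.
#' @return subset of `dataset_b$compounds` whose structure key is absent
#'   from release A (by canonical nonstereo structure).
#' @export
new_compounds <- function(dataset_a, dataset_b) {
  stopifnot(inherits(dataset_a, "target_dataset"),
            inherits(dataset_b, "target_dataset"))
  keep <- !(dataset_b$compounds$smiles %in% dataset_a$compounds$smiles)
  dataset_b$compounds[keep, , drop = FALSE]
}

#' Temporal validation of models across two releases
#'
#' Restricts to targets modelled in the earlier release; keeps only the
#' later release's compounds whose structure is absent from the earlier
#' one for that target; relabels them with the *same* threshold the model
#' used; predicts them with both arms (each repeat trains on the earlier
#' release under the internal protocol's splits and predicts every new
#' compound; per-compound results are medians over repeats); pools the
#' predictions globally.  Per-target metrics are reported only for
#' targets with at least `min_per_target` new compounds — with a handful
#' of new compounds per target only the pooled numbers are meaningful.
#'
#' @param curated_a,curated_b results of [curate_activity_table()] on the
#'   earlier and later release tables.  Targets present in `curated_b`
#'   only are ignored.
#' @param features feature matrix covering both releases' structures.
#' @param plan,config,epsilons,mode as in [run_benchmark()].
#' @param min_per_target minimum new-compound count for a per-target row.
#' @return list: `pooled` (metrics data.frame over all new compounds,
#'   `target_id = "(pooled)"`), `per_target` (metrics for well-populated
#'   targets), `predictions` (pooled per-compound predictions with
#'   target ids), `n_new` (named per-target new-compound counts).
#' @export
temporal_validate <- function(curated_a, curated_b, features,
                              plan = split_plan(), config = rf_config(),
                              epsilons = c(0.30, 0.20, 0.10),
                              mode = c("literal", "adjusted"),
                              min_per_target = 10L) {
  mode <- match.arg(mode)
  shared <- intersect(names(curated_a$datasets), names(curated_b$datasets))
  if (!length(shared)) {
    warning("no targets shared between the two releases", call. = FALSE)
    return(list(pooled = data.frame(), per_target = data.frame(),
                predictions = data.frame(), n_new = integer()))
  }
  qsar_rows <- list(); mcp_rows <- list(); n_new <- integer()
  per_target <- list()
  for (tid in shared) {
    ds_a <- curated_a$datasets[[tid]]
    ds_b <- curated_b$datasets[[tid]]
    fresh <- new_compounds(ds_a, ds_b)
    n_new[[tid]] <- nrow(fresh)
    if (!nrow(fresh)) next
    # same threshold as the trained model, not a re-derived one
    fresh$label <- assign_activity_class(
      fresh$median_pchembl, fresh$censored, ds_a$family,
      threshold_override = ds_a$threshold_used)
    x_train <- features_for(features, ds_a$compounds$smiles)
    x_new <- features_for(features, fresh$smiles)
    labels_train <- ds_a$compounds$label
    pred <- predict_temporal(x_train, labels_train, x_new, plan, config,
                             epsilons, mode)
    pred$qsar$label <- pred$mcp$label <- fresh$label
    pred$qsar$compound_id <- pred$mcp$compound_id <- fresh$compound_id
    pred$qsar$target_id <- pred$mcp$target_id <- tid
    qsar_rows[[tid]] <- pred$qsar
    mcp_rows[[tid]] <- pred$mcp
    if (nrow(fresh) >= min_per_target) {
      per_target[[tid]] <- metrics_report(
        pred$qsar, pred$mcp, target_id = tid, family = ds_a$family,
        n_active = sum(fresh$label == "active"),
        n_inactive = sum(fresh$label == "inactive"))
    }
  }
  qsar_all <- do.call(rbind, unname(qsar_rows))
  mcp_all <- do.call(rbind, unname(mcp_rows))
  if (!is.null(mcp_all)) attr(mcp_all, "epsilons") <- epsilons
  pooled <- if (is.null(qsar_all) && is.null(mcp_all)) data.frame() else {
    metrics_report(qsar_all, mcp_all, target_id = "(pooled)",
                   family = "(all)",
                   n_active = sum(qsar_all$label == "active"),
                   n_inactive = sum(qsar_all$label == "inactive"))
  }
  per_target_df <- do.call(rbind, unname(per_target)) %||% data.frame()
  rownames(per_target_df) <- NULL
  list(pooled = pooled, per_target = per_target_df,
       predictions = data.frame(), n_new = n_new,
       qsar = qsar_all, mcp = mcp_all)
}

# One target's temporal predictions: every repeat trains on the earlier
# release's internal-protocol training portion and predicts all new
# compounds; medians over repeats.
predict_temporal <- function(x_train, labels_train, x_new, plan, config,
                             epsilons, mode) {
  n_new <- nrow(x_new)
  q_probs <- matrix(NA_real_, n_new, plan$n_repeats)
  p_act <- matrix(NA_real_, n_new, plan$n_repeats)
  p_inact <- matrix(NA_real_, n_new, plan$n_repeats)
  pc_cols <- physchem_cols(x_train)
  for (r in seq_len(plan$n_repeats)) {
    sp <- stratified_split(labels_train, plan$test_fraction,
                           plan$split_seeds[[r]])
    scaler <- fit_scaler(x_train[sp$train, pc_cols, drop = FALSE])
    xs_train <- x_train
    xs_train[, pc_cols] <- apply_scaler(x_train[, pc_cols, drop = FALSE], scaler)
    xs_new <- x_new
    xs_new[, pc_cols] <- apply_scaler(x_new[, pc_cols, drop = FALSE], scaler)
    cfg <- config
    cfg$seed <- plan$rf_seeds[[r]]
    # QSAR arm: forest on the full training portion
    model_q <- train_rf(xs_train[sp$train, , drop = FALSE],
                        labels_train[sp$train], cfg)
    q_probs[, r] <- predict_prob_active(model_q, xs_new)
    # conformal arm: proper-train / calibration split inside the repeat
    pc <- split_proper_calibration(labels_train[sp$train],
                                   plan$calibration_fraction,
                                   plan$calibration_seeds[[r]])
    proper <- sp$train[pc$proper]
    calib <- sp$train[pc$calibration]
    model_m <- train_rf(xs_train[proper, , drop = FALSE],
                        labels_train[proper], cfg)
    mc <- calibrate(model_m, xs_train[calib, , drop = FALSE],
                    labels_train[calib])
    pv <- mondrian_p_values(mc, predict_prob_active(model_m, xs_new), mode)
    p_act[, r] <- pv$p_active
    p_inact[, r] <- pv$p_inactive
  }
  q_med <- apply(q_probs, 1L, stats::median)
  qsar <- data.frame(
    compound_id = rownames(x_new) %||% as.character(seq_len(n_new)),
    label = NA_character_,
    qsar_median_prob = q_med,
    qsar_class = ifelse(q_med >= 0.5, "active", "inactive"),
    n_test_appearances = plan$n_repeats,
    stringsAsFactors = FALSE)
  mcp <- data.frame(
    compound_id = qsar$compound_id,
    label = NA_character_,
    p_active_median = apply(p_act, 1L, stats::median),
    p_inactive_median = apply(p_inact, 1L, stats::median),
    stringsAsFactors = FALSE)
  for (eps in epsilons) {
    col <- sprintf("set_at_%d", as.integer(round(100 * (1 - eps))))
    mcp[[col]] <- assign_prediction_set(mcp$p_active_median,
                                        mcp$p_inactive_median, eps)
  }
  mcp$n_test_appearances <- plan$n_repeats
  mcp$p_value_mode <- mode
  attr(mcp, "epsilons") <- epsilons
  list(qsar = qsar, mcp = mcp)
}
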