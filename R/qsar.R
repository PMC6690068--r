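# The QSAR arm: class-weighted probability Random Forest (300 trees,
# depth 20) trained per target under a repeated stratified-split protocol;
# per-compound results are medians of the active-class probability over
# the repeats in which the compound fell in the test set.

.label_levels <- c("inactive", "active")

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .label_levels)
  if (length(bad)) {
    stop("labels must be 'active'/'inactive'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(labels, levels = .label_levels)
}

#' Random-Forest configuration
#'
#' Defaults follow the benchmarking protocol: 300 trees, maximum depth 20,
#' inverse-class-frequency ("balanced") weighting; all other forest
#' parameters are left at the `ranger` defaults.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param class_weighting apply balanced class weights (`N / (2 n_class)`).
#' @param seed integer seed for the forest.
#' @param num_threads threads used by ranger (1 for bit-reproducibility).
#' @return object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 300L, max_depth = 20L,
                      class_weighting = TRUE, seed = 1L, num_threads = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed),
                 num_threads = as.integer(num_threads)),
            class = "rf_config")
}

#' Repeated-split plan shared by the QSAR and conformal arms
#'
#' Stratified 80/20 train/test splits repeated `n_repeats` times; the
#' conformal arm further divides each training set 70/30 into proper
#' training and calibration sets.  Both arms consume the *same* first-split
#' seeds, so their test sets are identical repeat by repeat; calibration
#' splits and forest seeds come from independent streams of the same
#' master seed.
#'
#' @param n_repeats number of random splits (the benchmark uses 100).
#' @param test_fraction test-set fraction of the full data.
#' @param calibration_fraction calibration fraction of the training set.
#' @param seed master seed from which the per-repeat seed streams are
#'   derived (see [derive_seeds()]).
#' @return object of class `split_plan` carrying `split_seeds`,
#'   `calibration_seeds` and `rf_seeds`.
#' @export
split_plan <- function(n_repeats = 100L, test_fraction = 0.20,
                       calibration_fraction = 0.30, seed = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be at least 1", call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1,
            calibration_fraction > 0, calibration_fraction < 1)
  seed <- as.integer(as.double(seed) %% 2147483647)
  structure(list(
    n_repeats = as.integer(n_repeats),
    test_fraction = test_fraction,
    calibration_fraction = calibration_fraction,
    seed = seed,
    split_seeds = derive_seeds(seed, n_repeats, stream = 1L),
    calibration_seeds = derive_seeds(seed, n_repeats, stream = 2L),
    rf_seeds = derive_seeds(seed, n_repeats, stream = 3L)
  ), class = "split_plan")
}

# Per-class index draw used by both stratified splits.
stratified_indices <- function(labels, fraction, seed) {
  y <- as_label_factor(labels)
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("cannot stratify: class '", names(counts)[which.min(counts)],
         "' has fewer than 2 members", call. = FALSE)
  }
  with_seed(seed, {
    held <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      n_held <- round(fraction * length(idx))
      n_held <- max(1L, min(length(idx) - 1L, n_held))
      sample(idx, n_held)
    }), use.names = FALSE)
  })
  sort(held)
}

#' Stratified train/test split
#'
#' Samples `test_fraction` of each activity class (rounded to the nearest
#' compound, always leaving at least one compound per class on each side),
#' so test class proportions match the dataset within one compound per
#' class.  Deterministic given the seed.
#'
#' @param labels character/factor vector of `"active"`/`"inactive"`.
#' @param test_fraction fraction held out.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_fraction = 0.20, seed = 1L) {
  test <- stratified_indices(labels, test_fraction, seed)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Balanced class weights
#'
#' Inverse-class-frequency weights `N / (2 n_class)`: a balanced set gets
#' weight 1 per class; the minority class is up-weighted.
#'
#' @param labels vector of `"active"`/`"inactive"`.
#' @return named numeric vector (one weight per class present).
#' @export
balanced_class_weights <- function(labels) {
  y <- as_label_factor(labels)
  counts <- table(y)
  n <- length(y)
  w <- n / (2 * as.numeric(counts))
  names(w) <- names(counts)
  w
}

#' Train a probability Random Forest
#'
#' @param x numeric feature matrix (rows = compounds).
#' @param labels `"active"`/`"inactive"` per row; both classes required.
#' @param config an [rf_config()].
#' @return object of class `qsar_model` wrapping the fitted forest.
#' @export
train_rf <- function(x, labels, config = rf_config()) {
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training set is single-class; cannot fit a classifier",
         call. = FALSE)
  }
  weights <- NULL
  case_weights <- NULL
  if (config$class_weighting) {
    w <- balanced_class_weights(labels)
    weights <- as.numeric(w[.label_levels])
    # per-observation weights: balancing must reach the bootstrap draws
    # and hence the leaf class frequencies, not just the split criterion
    case_weights <- as.numeric(w[as.character(y)])
  }
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    max.depth = config$max_depth,
    probability = TRUE,
    class.weights = weights,
    case.weights = case_weights,
    seed = config$seed,
    num.threads = config$num_threads,
    verbose = FALSE
  )
  structure(list(fit = fit, config = config,
                 class_weights = weights %||% c(1, 1)),
            class = "qsar_model")
}

#' Predicted probability of the active class
#'
#' @param model a `qsar_model`.
#' @param x feature matrix.
#' @return numeric vector of `P(active)` in `[0, 1]`.
#' @export
predict_prob_active <- function(model, x) {
  stopifnot(inherits(model, "qsar_model"))
  pred <- stats::predict(model$fit, data = x,
                         num.threads = model$config$num_threads)
  as.numeric(pred$predictions[, "active"])
}

# Scale the physchem block on the training rows only, apply everywhere.
scale_physchem <- function(x, train_idx) {
  pc <- physchem_cols(x)
  if (!length(pc)) return(x)
  scaler <- fit_scaler(x[train_idx, pc, drop = FALSE])
  x[, pc] <- apply_scaler(x[, pc, drop = FALSE], scaler)
  x
}

#' Run the repeated-split QSAR protocol for one target
#'
#' For each repeat: stratified 80/20 split, per-split min-max scaling of
#' the physicochemical block, class-weighted forest fit on the training
#' set, probability prediction on the test set.  Per compound, the median
#' `P(active)` over the repeats in which it was in the test set is
#' reported; the hard class is active iff the median probability is at
#' least 0.5.  A compound never sampled into a test set (vanishingly rare
#' under 100 repeats) is reported with missing values, not imputed.
#'
#' @param x feature matrix with rownames = compound ids.
#' @param labels `"active"`/`"inactive"` per row.
#' @param plan a [split_plan()].
#' @param config an [rf_config()].
#' @return data.frame: `compound_id`, `label`, `qsar_median_prob`,
#'   `qsar_class`, `n_test_appearances`.
#' @export
run_qsar_protocol <- function(x, labels, plan = split_plan(),
                              config = rf_config()) {
  stopifnot(inherits(plan, "split_plan"))
  n <- nrow(x)
  probs <- vector("list", n)
  appearances <- integer(n)
  for (r in seq_len(plan$n_repeats)) {
    sp <- stratified_split(labels, plan$test_fraction, plan$split_seeds[[r]])
    xs <- scale_physchem(x, sp$train)
    cfg <- config
    cfg$seed <- plan$rf_seeds[[r]]
    model <- train_rf(xs[sp$train, , drop = FALSE], labels[sp$train], cfg)
    p <- predict_prob_active(model, xs[sp$test, , drop = FALSE])
    for (k in seq_along(sp$test)) {
      i <- sp$test[[k]]
      probs[[i]] <- c(probs[[i]], p[[k]])
      appearances[[i]] <- appearances[[i]] + 1L
    }
  }
  med <- vapply(probs, function(p) {
    if (is.null(p)) NA_real_ else stats::median(p)
  }, numeric(1L))
  data.frame(
    compound_id = rownames(x) %||% as.character(seq_len(n)),
    label = as.character(labels),
    qsar_median_prob = med,
    qsar_class = ifelse(is.na(med), NA_character_,
                        ifelse(med >= 0.5, "active", "inactive")),
    n_test_appearances = appearances,
    stringsAsFactors = FALSE
  )
}
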