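# Synthetic ChEMBL-like study generator: per-target activity tables with
# controllable active:inactive ratio, fingerprint class separability,
# label noise, publication counts, censored records, curation-filter
# decoys, and a two-release temporal structure -- with known ground truth
# so every pipeline stage is testable offline.

.families <- c("kinase", "gpcr", "nuclear_receptor", "ion_channel", "other")

#' Configuration of the synthetic study
#'
#' Defaults emulate the modelling panel the pipeline targets: 400
#' compounds per target (the curated panel's median is a few hundred),
#' active fraction 0.45 (active:inactive ratio near the panel median of
#' 0.8), fingerprint separability 0.5 with 64 informative bits over a
#' 2048-bit fingerprint at background on-rate 0.1, 10% label noise as a
#' realistic assay/curation error floor, 3 publications per target, and
#' 30% of inactives reported as censored (`<`) records.
#'
#' @param n_targets number of protein targets.
#' @param n_compounds compounds per target.
#' @param family_weights sampling weights over the five family labels.
#' @param active_fraction fraction of compounds truly active.
#' @param separability s in `[0, 1]`: informative bits are Bernoulli(0.5 +
#'   s/2) for actives and Bernoulli(0.5 - s/2) for inactives; s = 0 means
#'   no signal, s = 1 perfectly separating bits.
#' @param label_noise fraction of compounds whose reported activity
#'   contradicts their feature-generating class.
#' @param n_informative_bits number of class-informative fingerprint bits.
#' @param n_bits fingerprint length.
#' @param background_rate on-rate of uninformative bits.
#' @param n_docs distinct publications per target.
#' @param censored_fraction fraction of inactives emitted as relation `<`.
#' @param margin minimum pChEMBL distance from the class threshold, in log
#'   units, so labelling is unambiguous.
#' @param dup_rate fraction of compounds with a replicate measurement.
#' @param flagged_dup_rate,inconclusive_rate,validity_comment_rate,gt_relation_rate
#'   rates of injected decoy records that the curation filters must drop
#'   (flagged duplicates, "inconclusive" comments, data-validity comments,
#'   relation `>` rows); decoys carry wrong-side values so that a filter
#'   failure corrupts labels detectably.
#' @param temporal_new_fraction fraction of additional new compounds per
#'   target in the later release of a temporal pair.
#' @param structure_mode `"feature"` (chemistry-free: structure strings
#'   are opaque keys with precomputed features) or `"smiles"` (structures
#'   drawn from the packaged fixture list of valid SMILES).
#' @param seed master seed; everything derives from it deterministically.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_targets = 10L, n_compounds = 400L,
                             family_weights = c(kinase = 0.25, gpcr = 0.30,
                                                nuclear_receptor = 0.10,
                                                ion_channel = 0.15,
                                                other = 0.20),
                             active_fraction = 0.45, separability = 0.5,
                             label_noise = 0.10, n_informative_bits = 64L,
                             n_bits = 2048L, background_rate = 0.10,
                             n_docs = 3L, censored_fraction = 0.30,
                             margin = 0.30, dup_rate = 0.05,
                             flagged_dup_rate = 0.02,
                             inconclusive_rate = 0.02,
                             validity_comment_rate = 0.02,
                             gt_relation_rate = 0.02,
                             temporal_new_fraction = 0.20,
                             structure_mode = c("feature", "smiles"),
                             seed = 1L) {
  structure_mode <- match.arg(structure_mode)
  fracs <- c(active_fraction = active_fraction, separability = separability,
             label_noise = label_noise, background_rate = background_rate,
             censored_fraction = censored_fraction, dup_rate = dup_rate,
             flagged_dup_rate = flagged_dup_rate,
             inconclusive_rate = inconclusive_rate,
             validity_comment_rate = validity_comment_rate,
             gt_relation_rate = gt_relation_rate,
             temporal_new_fraction = temporal_new_fraction)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad)) {
    stop("configuration fraction(s) outside [0, 1]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_informative_bits > n_bits) {
    stop("n_informative_bits cannot exceed n_bits", call. = FALSE)
  }
  stopifnot(n_targets >= 1L, n_compounds >= 2L, n_docs >= 1L, margin >= 0)
  if (!setequal(names(family_weights), .families)) {
    stop("family_weights must name exactly: ",
         paste(.families, collapse = ", "), call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# Plausible native-unit physicochemical draws with a class shift that
# scales with separability.
draw_physchem <- function(n, active, separability) {
  shift <- separability * c(MolWt = 20, NumHDonors = 0.4,
                            NumHAcceptors = 0.6, NumRotatableBonds = 0.6,
                            MolLogP = 0.4, TPSA = 8)
  a <- as.numeric(active)
  cbind(
    MolWt = stats::rnorm(n, 400 + a * shift[["MolWt"]], 75),
    NumHDonors = stats::rpois(n, 2 + a * shift[["NumHDonors"]]),
    NumHAcceptors = stats::rpois(n, 5 + a * shift[["NumHAcceptors"]]),
    NumRotatableBonds = stats::rpois(n, 5 + a * shift[["NumRotatableBonds"]]),
    MolLogP = stats::rnorm(n, 3 + a * shift[["MolLogP"]], 1.5),
    TPSA = stats::rnorm(n, 80 + a * shift[["TPSA"]], 30)
  )
}

#' Generate a labelled class-conditional feature matrix
#'
#' The first `n_informative_bits` fingerprint columns are drawn
#' Bernoulli(0.5 + s/2) for actives and Bernoulli(0.5 - s/2) for
#' inactives; remaining bits are background Bernoulli(`background_rate`).
#' Six pseudo-physicochemical descriptors are drawn from class-shifted
#' distributions on realistic native scales.  Class counts are exact;
#' labels are exact before noise, and `label_noise` flips a rounded
#' fraction of reported labels away from the feature-generating class.
#'
#' @param n number of compounds.
#' @param active_fraction exact fraction of truly active compounds.
#' @param separability s in `[0, 1]`.
#' @param n_informative_bits informative bit count.
#' @param seed integer seed.
#' @param n_bits fingerprint length.
#' @param background_rate background on-rate.
#' @param label_noise reported-label flip fraction (default 0).
#' @return list: `x` (feature matrix from [assemble_features()]),
#'   `labels` (reported), `true_labels` (feature-generating class).
#' @export
generate_features <- function(n, active_fraction, separability,
                              n_informative_bits, seed, n_bits = 2048L,
                              background_rate = 0.10, label_noise = 0) {
  n_active <- round(n * active_fraction)
  if (n_active < 1L || n_active > n - 1L) {
    stop("active_fraction yields an empty class (n_active = ", n_active,
         " of ", n, ")", call. = FALSE)
  }
  true_labels <- rep(c("active", "inactive"), c(n_active, n - n_active))
  with_seed(seed, {
    active <- true_labels == "active"
    p_info <- ifelse(active, 0.5 + separability / 2, 0.5 - separability / 2)
    info <- matrix(stats::rbinom(n * n_informative_bits, 1L,
                                 rep(p_info, n_informative_bits)),
                   nrow = n, ncol = n_informative_bits)
    n_bg <- n_bits - n_informative_bits
    bg <- matrix(stats::rbinom(n * n_bg, 1L, background_rate), n, n_bg)
    physchem <- draw_physchem(n, active, separability)
    labels <- true_labels
    n_flip <- round(label_noise * n)
    if (n_flip > 0L) {
      flip <- sample.int(n, n_flip)
      labels[flip] <- ifelse(labels[flip] == "active", "inactive", "active")
    }
    list(x = assemble_features(cbind(info, bg), physchem),
         labels = labels, true_labels = true_labels)
  })
}

# Records for one target's compounds, plus injected decoy rows.
make_target_records <- function(tid, family, keys, compound_ids, labels,
                                config, seed) {
  thr <- idg_threshold(family)
  n <- length(keys)
  with_seed(seed, {
    active <- labels == "active"
    pchembl <- ifelse(active,
                      thr + config$margin + stats::runif(n, 0, 1.5),
                      pmax(3, thr - config$margin - stats::runif(n, 0, 1.5)))
    relation <- rep("=", n)
    inact_idx <- which(!active)
    n_cens <- round(config$censored_fraction * length(inact_idx))
    if (n_cens > 0L) relation[sample(inact_idx, n_cens)] <- "<"
    docs <- sample(rep_len(paste0(tid, "_doc", seq_len(config$n_docs)), n))
    rec <- function(i, pch, rel = "=", dup = FALSE, validity = NA_character_,
                    comment = NA_character_) {
      data.frame(target_id = tid, family = family,
                 compound_id = compound_ids[i], smiles = keys[i],
                 relation = rel, pchembl = pch, doc_id = docs[i],
                 src_id = 1L, duplicate_flag = dup,
                 data_validity_comment = validity,
                 activity_comment = comment, stringsAsFactors = FALSE)
    }
    records <- rec(seq_len(n), pchembl, relation)
    n_of <- function(rate) round(rate * n)
    wrong_side <- function(i) {
      ifelse(active[i], pmax(3, thr - config$margin - stats::runif(length(i), 0, 1.5)),
             thr + config$margin + stats::runif(length(i), 0, 1.5))
    }
    extras <- list()
    n_dup <- n_of(config$dup_rate)
    if (n_dup > 0L) {
      # genuine replicate measurements: same side, small jitter, so the
      # aggregated median keeps the label
      i <- sample(which(relation == "="), min(n_dup, sum(relation == "=")))
      extras$dup <- rec(i, pchembl[i] + stats::runif(length(i), -0.2, 0.2))
    }
    n_fd <- n_of(config$flagged_dup_rate)
    if (n_fd > 0L) {
      i <- sample.int(n, n_fd)
      extras$flagged <- rec(i, wrong_side(i), dup = TRUE)
    }
    n_inc <- n_of(config$inconclusive_rate)
    if (n_inc > 0L) {
      i <- sample.int(n, n_inc)
      extras$inconclusive <- rec(i, wrong_side(i), comment = "inconclusive")
    }
    n_val <- n_of(config$validity_comment_rate)
    if (n_val > 0L) {
      i <- sample.int(n, n_val)
      extras$validity <- rec(i, wrong_side(i),
                             validity = "Potential transcription error")
    }
    n_gt <- n_of(config$gt_relation_rate)
    if (n_gt > 0L) {
      i <- sample.int(n, n_gt)
      extras$gt <- rec(i, wrong_side(i), rel = ">")
    }
    do.call(rbind, c(list(records), unname(extras)))
  })
}

target_ids <- function(n) sprintf("T%03d", seq_len(n))

#' Generate a raw ChEMBL-like activity table with hidden truth
#'
#' One call produces, per target: a feature matrix with known
#' class-conditional structure, clean measured/censored activity records
#' whose pChEMBL side of the family threshold encodes the reported label,
#' and decoy rows exercising every curation filter.  Curating the records
#' recovers the reported labels exactly (margins keep values away from
#' the threshold); with `label_noise = 0` the reported labels equal the
#' feature-generating truth.
#'
#' @param config a [synthetic_config()].
#' @return list: `records` (raw activity table), `truth` (per compound:
#'   `target_id`, `compound_id`, `smiles`, `true_label`, `label`),
#'   `features` (matrix keyed by structure string, raw physchem block),
#'   `families` (named per-target family vector).
#' @export
generate_activity_table <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  tids <- target_ids(config$n_targets)
  fam_seeds <- derive_seeds(config$seed, config$n_targets, stream = 10L)
  feat_seeds <- derive_seeds(config$seed, config$n_targets, stream = 11L)
  rec_seeds <- derive_seeds(config$seed, config$n_targets, stream = 12L)
  families <- with_seed(fam_seeds[[1L]], {
    sample(names(config$family_weights), config$n_targets, replace = TRUE,
           prob = config$family_weights)
  })
  names(families) <- tids
  all_records <- list(); all_truth <- list(); all_features <- list()
  for (t in seq_len(config$n_targets)) {
    tid <- tids[[t]]
    n <- config$n_compounds
    feats <- generate_features(n, config$active_fraction,
                               config$separability,
                               config$n_informative_bits, feat_seeds[[t]],
                               n_bits = config$n_bits,
                               background_rate = config$background_rate,
                               label_noise = config$label_noise)
    keys <- structure_keys(tid, n, config, feat_seeds[[t]])
    compound_ids <- sprintf("%s_M%04d", tid, seq_len(n))
    rownames(feats$x) <- keys
    all_features[[tid]] <- feats$x
    all_records[[tid]] <- make_target_records(
      tid, families[[tid]], keys, compound_ids, feats$labels, config,
      rec_seeds[[t]])
    all_truth[[tid]] <- data.frame(
      target_id = tid, compound_id = compound_ids, smiles = keys,
      true_label = feats$true_labels, label = feats$labels,
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, unname(all_features))
  attr(features, "physchem_cols") <- ncol(features) -
    length(.physchem_names) + seq_along(.physchem_names)
  list(records = do.call(rbind, c(unname(all_records),
                                  list(make.row.names = FALSE))),
       truth = do.call(rbind, c(unname(all_truth),
                                list(make.row.names = FALSE))),
       features = features, families = families)
}

structure_keys <- function(tid, n, config, seed, suffix = "") {
  if (config$structure_mode == "feature") {
    sprintf("%s_S%04d%s", tid, seq_len(n), suffix)
  } else {
    pool <- fixture_smiles()
    if (n > length(pool)) {
      stop("smiles structure_mode supports at most ", length(pool),
           " compounds per target (the packaged fixture list)",
           call. = FALSE)
    }
    with_seed(seed + 1L, sample(pool, n))
  }
}

#' Packaged fixture list of valid drug-like SMILES
#'
#' Small plain-text list shipped with the package, used by the `"smiles"`
#' structure mode so curation and canonicalization paths can be exercised
#' on real structures (including stereo variants) without generating
#' novel chemistry.
#'
#' @return character vector of SMILES strings.
#' @export
fixture_smiles <- function() {
  path <- system.file("extdata", "fixture_smiles.smi", package = "cpqsar",
                      mustWork = TRUE)
  readLines(path)
}

#' Generate a temporal release pair
#'
#' Release A is the plain synthetic study; release B contains every
#' record of A plus `temporal_new_fraction` new compounds per target
#' (new structure keys, absent from A) drawn from the same class
#' distribution, or from a shifted one when `new_separability` is given
#' (lower separability emulates new chemistry drifting away from the
#' trained model's space).
#'
#' @param config a [synthetic_config()].
#' @param new_separability optional separability for the new compounds.
#' @return list with `release_a` and `release_b`, each shaped like
#'   [generate_activity_table()] output; feature stores cover A and B.
#' @export
generate_temporal_pair <- function(config = synthetic_config(),
                                   new_separability = NULL) {
  release_a <- generate_activity_table(config)
  n_new <- round(config$temporal_new_fraction * config$n_compounds)
  if (n_new == 0L) {
    return(list(release_a = release_a, release_b = release_a))
  }
  s_new <- new_separability %||% config$separability
  tids <- target_ids(config$n_targets)
  feat_seeds <- derive_seeds(config$seed, config$n_targets, stream = 21L)
  rec_seeds <- derive_seeds(config$seed, config$n_targets, stream = 22L)
  new_records <- list(); new_truth <- list(); new_features <- list()
  for (t in seq_len(config$n_targets)) {
    tid <- tids[[t]]
    feats <- generate_features(n_new, config$active_fraction, s_new,
                               config$n_informative_bits, feat_seeds[[t]],
                               n_bits = config$n_bits,
                               background_rate = config$background_rate,
                               label_noise = config$label_noise)
    keys <- structure_keys(tid, n_new, config, feat_seeds[[t]],
                           suffix = "n")
    if (config$structure_mode == "smiles") {
      stop("temporal pairs require structure_mode = 'feature' ",
           "(the fixture list cannot supply disjoint new structures)",
           call. = FALSE)
    }
    compound_ids <- sprintf("%s_N%04d", tid, seq_len(n_new))
    rownames(feats$x) <- keys
    new_features[[tid]] <- feats$x
    new_records[[tid]] <- make_target_records(
      tid, release_a$families[[tid]], keys, compound_ids, feats$labels,
      config, rec_seeds[[t]])
    new_truth[[tid]] <- data.frame(
      target_id = tid, compound_id = compound_ids, smiles = keys,
      true_label = feats$true_labels, label = feats$labels,
      stringsAsFactors = FALSE)
  }
  features <- rbind(release_a$features, do.call(rbind, unname(new_features)))
  attr(features, "physchem_cols") <- attr(release_a$features, "physchem_cols")
  release_b <- list(
    records = rbind(release_a$records,
                    do.call(rbind, unname(new_records))),
    truth = rbind(release_a$truth, do.call(rbind, unname(new_truth))),
    features = features,
    families = release_a$families)
  release_a$features <- features
  list(release_a = release_a, release_b = release_b)
}
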