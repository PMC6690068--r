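# Curation of raw ChEMBL-style activity tables into per-target modelling
# sets: record-level filters, duplicate aggregation by nonstereo structure,
# family-threshold activity labelling with a 6.5 fallback, and the
# 40-active / 30-inactive / two-publication retention rules.

.record_columns <- c(
  "target_id", "family", "compound_id", "smiles", "relation", "pchembl",
  "doc_id", "src_id", "duplicate_flag", "data_validity_comment",
  "activity_comment"
)

.drop_comments <- c("inconclusive", "undetermined")

#' Family activity thresholds
#'
#' Potency cut-offs (pChEMBL units, "active" means value >= threshold) per
#' protein family as defined by the Illuminating the Druggable Genome
#' consortium: protein kinases 7.5, G protein-coupled receptors 7, nuclear
#' receptors 7, ion channels 5, and 6.5 for any other family.  An unknown
#' family string falls back to the non-IDG value of 6.5 with a message.
#'
#' @param family character vector of family labels
#'   (`"kinase"`, `"gpcr"`, `"nuclear_receptor"`, `"ion_channel"`, or any
#'   other label).
#' @param override if non-`NULL`, a single threshold used for every entry
#'   (the relabelling fallback uses 6.5).
#' @return numeric vector of thresholds in pChEMBL units.
#' @export
idg_threshold <- function(family, override = NULL) {
  if (!is.null(override)) {
    stopifnot(is_scalar_number(override))
    return(rep(override, length(family)))
  }
  table <- c(kinase = 7.5, gpcr = 7, nuclear_receptor = 7, ion_channel = 5)
  out <- unname(table[as.character(family)])
  unknown <- is.na(out)
  if (any(unknown)) {
    novel <- setdiff(unique(as.character(family)[unknown]),
                     c("other", NA_character_))
    if (length(novel)) {
      message("families without an IDG threshold use the default 6.5: ",
              paste(novel, collapse = ", "))
    }
    out[unknown] <- 6.5
  }
  out
}

check_record_schema <- function(records) {
  if (!is.data.frame(records)) {
    stop("activity records must be a data.frame", call. = FALSE)
  }
  missing <- setdiff(.record_columns, names(records))
  if (length(missing)) {
    stop("activity table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

# Normalise absent values and column types in place.
normalise_records <- function(records) {
  check_record_schema(records)
  for (col in c("data_validity_comment", "activity_comment", "relation",
                "smiles", "compound_id", "target_id", "doc_id", "family")) {
    records[[col]] <- blank_to_na(as.character(records[[col]]))
  }
  records$pchembl <- suppressWarnings(as.numeric(records$pchembl))
  records$src_id <- suppressWarnings(as.integer(records$src_id))
  flag <- records$duplicate_flag
  if (!is.logical(flag)) {
    flag <- tolower(trimws(as.character(flag))) %in% c("true", "t", "1", "yes")
  }
  records$duplicate_flag <- !is.na(flag) & flag
  records
}

#' Record-level quality filters
#'
#' Keeps only measured (`relation == "="`) and censored-inactive
#' (`relation == "<"`) records that carry a pChEMBL value, are not flagged
#' as potential duplicates, have no data-validity comment, whose activity
#' comment is neither "inconclusive" nor "undetermined", and whose source
#' is in the allow-list (default: scientific literature, src_id 1, and
#' DrugMatrix, src_id 15).  The operation is idempotent.
#'
#' @param records data.frame with the documented activity-table columns.
#' @param src_allow integer vector of admissible `src_id` codes.
#' @return the filtered data.frame.
#' @export
filter_records <- function(records, src_allow = c(1L, 15L)) {
  records <- normalise_records(records)
  keep <- records$relation %in% c("=", "<") &
    !is.na(records$pchembl) &
    !records$duplicate_flag &
    is.na(records$data_validity_comment) &
    (is.na(records$activity_comment) |
       !(tolower(records$activity_comment) %in% .drop_comments)) &
    records$src_id %in% as.integer(src_allow)
  records[keep, , drop = FALSE]
}

#' Resolve multiple activity types per measurement group
#'
#' When one (target, structure, source) group carries several activity
#' types (e.g. both Ki and IC50 from a pharmacology panel), only the
#' highest-priority type present is kept before median aggregation.  With
#' no `activity_type` column the table passes through unchanged.
#'
#' @param records filtered activity records, optionally with an
#'   `activity_type` column.
#' @param priority character vector, most preferred first.
#' @return data.frame with lower-priority duplicate types removed.
#' @export
select_activity_type <- function(records, priority = "IC50") {
  if (!"activity_type" %in% names(records) || !nrow(records)) {
    return(records)
  }
  type <- blank_to_na(as.character(records$activity_type))
  rank <- match(type, priority)
  rank[is.na(rank)] <- length(priority) + 1L
  grp <- paste(records$target_id, records$smiles, records$src_id, sep = "\r")
  best <- stats::ave(rank, grp, FUN = min)
  records[rank == best, , drop = FALSE]
}

#' Aggregate replicate measurements per target and structure
#'
#' Collapses filtered records to one row per (target, canonical nonstereo
#' structure).  If any measured (`=`) record exists, the median of its
#' pChEMBL values is taken and censored (`<`) records for the same
#' structure are discarded (the exact measurement carries more
#' information); a structure observed only through `<` records is carried
#' forward as censored-inactive with no numeric median.
#'
#' @param records filtered records whose `smiles` column is already
#'   canonical (see [canonicalize_structure()]).
#' @return data.frame with one row per (target_id, smiles): `compound_id`
#'   (first id seen for the structure), `median_pchembl` (`NA` when
#'   censored), `censored`, `n_records`.
#' @export
aggregate_duplicates <- function(records) {
  if (!nrow(records)) {
    return(data.frame(target_id = character(), compound_id = character(),
                      smiles = character(), median_pchembl = numeric(),
                      censored = logical(), n_records = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$target_id, records$smiles, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    sub <- records[i, , drop = FALSE]
    measured <- sub$pchembl[sub$relation == "="]
    data.frame(
      target_id = sub$target_id[[1L]],
      compound_id = sort(sub$compound_id)[[1L]],
      smiles = sub$smiles[[1L]],
      median_pchembl = if (length(measured)) stats::median(measured) else NA_real_,
      censored = !length(measured),
      n_records = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$target_id, out$compound_id), , drop = FALSE]
}

#' Assign active/inactive labels
#'
#' A censored-inactive compound is always inactive; a measured compound is
#' active iff its median pChEMBL is greater than or equal to the family
#' threshold (boundary counts as active).
#'
#' @param median_pchembl numeric vector (NA for censored compounds).
#' @param censored logical vector.
#' @param family family label(s), recycled.
#' @param threshold_override optional single threshold replacing the family
#'   value (the retention fallback uses 6.5).
#' @return character vector `"active"`/`"inactive"`.
#' @export
assign_activity_class <- function(median_pchembl, censored, family,
                                  threshold_override = NULL) {
  thr <- idg_threshold(rep_len(family, length(median_pchembl)),
                       override = threshold_override)
  ifelse(censored | is.na(median_pchembl), "inactive",
         ifelse(median_pchembl >= thr, "active", "inactive"))
}

#' Target retention decision
#'
#' Applies, in order: the two-publication rule; the 40-active/30-inactive
#' count screen under the family threshold; if that fails, relabelling of
#' the *same* compound set at the default threshold 6.5 and a second count
#' screen; otherwise the target is discarded.
#'
#' @param compounds aggregated per-structure table for one target (columns
#'   `compound_id`, `smiles`, `median_pchembl`, `censored`).
#' @param target_id,family identifiers carried into the result.
#' @param n_docs number of distinct publications backing the target.
#' @param min_active,min_inactive,min_docs retention cut-offs.
#' @param threshold_fallback default threshold used when the family
#'   threshold does not yield enough compounds per class.
#' @return a `target_dataset` object, or a `target_discard` decision
#'   object carrying the reason (`"too_few_publications"` or
#'   `"too_few_compounds"`).
#' @export
retain_target <- function(compounds, target_id, family, n_docs,
                          min_active = 40L, min_inactive = 30L,
                          min_docs = 2L, threshold_fallback = 6.5) {
  discard <- function(reason) {
    structure(list(target_id = target_id, reason = reason),
              class = "target_discard")
  }
  if (n_docs < min_docs) {
    return(discard("too_few_publications"))
  }
  try_threshold <- function(override) {
    labels <- assign_activity_class(compounds$median_pchembl,
                                    compounds$censored, family,
                                    threshold_override = override)
    n_act <- sum(labels == "active")
    n_inact <- sum(labels == "inactive")
    if (n_act >= min_active && n_inact >= min_inactive) {
      list(labels = labels, n_active = n_act, n_inactive = n_inact)
    } else {
      NULL
    }
  }
  fit <- try_threshold(NULL)
  used <- if (!is.null(fit)) idg_threshold(family) else {
    fit <- try_threshold(threshold_fallback)
    threshold_fallback
  }
  if (is.null(fit)) {
    return(discard("too_few_compounds"))
  }
  cmp <- compounds[, c("compound_id", "smiles", "median_pchembl", "censored")]
  cmp$label <- fit$labels
  rownames(cmp) <- NULL
  structure(
    list(target_id = target_id, family = family, threshold_used = used,
         compounds = cmp, n_active = fit$n_active,
         n_inactive = fit$n_inactive,
         ratio = fit$n_active / fit$n_inactive, n_docs = n_docs),
    class = "target_dataset"
  )
}

#' Ratio of active to inactive compounds
#'
#' @param dataset a `target_dataset`.
#' @return `n_active / n_inactive` (dimensionless).
#' @export
active_inactive_ratio <- function(dataset) {
  stopifnot(inherits(dataset, "target_dataset"))
  dataset$n_active / dataset$n_inactive
}

#' @export
print.target_dataset <- function(x, ...) {
  cat(sprintf(
    "<target_dataset> %s (%s)\n  %d active / %d inactive (ratio %.2f), threshold %.1f, %d publication(s)\n",
    x$target_id, x$family, x$n_active, x$n_inactive, x$ratio,
    x$threshold_used, x$n_docs))
  invisible(x)
}

#' Curate a raw activity table into per-target modelling sets
#'
#' End-to-end curation: record filters, activity-type priority, structure
#' canonicalization, duplicate aggregation, labelling and retention.
#' Unparsable structures are dropped with a warning rather than aborting
#' the run.
#'
#' @param records raw activity table with the documented columns.
#' @param src_allow admissible `src_id` codes.
#' @param canonicalize structure backend: `"identity"` treats the `smiles`
#'   column as already-canonical opaque keys (the chemistry-free default
#'   used with precomputed/synthetic features); `"openbabel"` computes
#'   canonical nonstereo SMILES via [canonicalize_structure()].
#' @param type_priority activity-type priority list, most preferred first.
#' @param min_active,min_inactive,min_docs,threshold_fallback retention
#'   parameters (see [retain_target()]).
#' @return list with `datasets` (named list of `target_dataset`) and
#'   `summary` (one row per input target: `target_id`, `retained`,
#'   `reason`, `threshold_used`, `n_active`, `n_inactive`, `ratio`,
#'   `n_docs`).
#' @export
curate_activity_table <- function(records, src_allow = c(1L, 15L),
                                  canonicalize = c("identity", "openbabel"),
                                  type_priority = "IC50",
                                  min_active = 40L, min_inactive = 30L,
                                  min_docs = 2L, threshold_fallback = 6.5) {
  canonicalize <- match.arg(canonicalize)
  kept <- filter_records(records, src_allow = src_allow)
  kept <- select_activity_type(kept, priority = type_priority)
  if (canonicalize == "openbabel" && nrow(kept)) {
    canon <- vapply(kept$smiles, function(s) {
      tryCatch(canonicalize_structure(s), cpqsar_parse_error = function(e) NA_character_)
    }, character(1L), USE.NAMES = FALSE)
    if (anyNA(canon)) {
      warning(sum(is.na(canon)), " record(s) dropped: unparsable structure(s) ",
              paste(utils::head(unique(kept$smiles[is.na(canon)]), 3L),
                    collapse = ", "), call. = FALSE)
      kept <- kept[!is.na(canon), , drop = FALSE]
      canon <- canon[!is.na(canon)]
    }
    kept$smiles <- canon
  }
  targets <- unique(records$target_id)
  targets <- targets[!is.na(targets)]
  datasets <- list()
  summary_rows <- list()
  for (tid in targets) {
    sub <- kept[kept$target_id == tid, , drop = FALSE]
    fam <- if (nrow(sub)) sub$family[[1L]] else
      records$family[records$target_id == tid][[1L]]
    fam <- fam %||% "other"
    if (is.na(fam)) fam <- "other"
    n_docs <- length(unique(sub$doc_id[!is.na(sub$doc_id)]))
    agg <- aggregate_duplicates(sub)
    ds <- retain_target(agg, target_id = tid, family = fam, n_docs = n_docs,
                        min_active = min_active, min_inactive = min_inactive,
                        min_docs = min_docs,
                        threshold_fallback = threshold_fallback)
    if (!inherits(ds, "target_dataset")) {
      summary_rows[[tid]] <- data.frame(
        target_id = tid, retained = FALSE,
        reason = ds$reason,
        threshold_used = NA_real_, n_active = NA_integer_,
        n_inactive = NA_integer_, ratio = NA_real_, n_docs = n_docs,
        stringsAsFactors = FALSE)
    } else {
      datasets[[tid]] <- ds
      summary_rows[[tid]] <- data.frame(
        target_id = tid, retained = TRUE, reason = "retained",
        threshold_used = ds$threshold_used, n_active = ds$n_active,
        n_inactive = ds$n_inactive, ratio = ds$ratio, n_docs = ds$n_docs,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, unname(summary_rows)) %||% data.frame()
  rownames(summary) <- NULL
  list(datasets = datasets, summary = summary)
}

#' Write curated datasets to CSV
#'
#' One `<target_id>.csv` per retained target (compound_id, smiles,
#' median_pchembl, label, threshold_used) plus `curation_summary.csv`.
#'
#' @param curated result of [curate_activity_table()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (ds in curated$datasets) {
    out <- ds$compounds[, c("compound_id", "smiles", "median_pchembl", "label")]
    out$threshold_used <- ds$threshold_used
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", ds$target_id), ".csv"))
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "curation_summary.csv")
  utils::write.csv(curated$summary, p, row.names = FALSE)
  invisible(c(paths, p))
}
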