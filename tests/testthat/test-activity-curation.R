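test_that("record filters keep measured and censored rows and drop everything else", {
  tbl <- records(
    record(compound_id = "keep_eq"),
    record(compound_id = "keep_lt", relation = "<", pchembl = 4.0),
    record(compound_id = "gt", relation = ">", pchembl = 5.0),
    record(compound_id = "no_pchembl", pchembl = NA),
    record(compound_id = "dup", duplicate_flag = TRUE),
    record(compound_id = "validity", data_validity_comment = "Outside typical range"),
    record(compound_id = "inconclusive", activity_comment = "inconclusive"),
    record(compound_id = "undetermined", activity_comment = "Undetermined"),
    record(compound_id = "active_comment_ok", activity_comment = "active"),
    record(compound_id = "bad_src", src_id = 7L),
    record(compound_id = "drugmatrix", src_id = 15L)
  )
  kept <- filter_records(tbl)
  expect_setequal(kept$compound_id,
                  c("keep_eq", "keep_lt", "active_comment_ok", "drugmatrix"))
})

test_that("filtering treats empty strings as absent and is idempotent", {
  tbl <- records(
    record(compound_id = "blank_comment", activity_comment = "",
           data_validity_comment = ""),
    record(compound_id = "real_comment", data_validity_comment = "x")
  )
  once <- filter_records(tbl)
  expect_equal(once$compound_id, "blank_comment")
  expect_equal(filter_records(once), once)
})

test_that("missing mandatory columns raise a schema error naming them", {
  tbl <- record()
  tbl$pchembl <- NULL
  tbl$doc_id <- NULL
  expect_error(filter_records(tbl), "pchembl")
  expect_error(filter_records(tbl), "doc_id")
})

test_that("source allow-list is configurable", {
  tbl <- records(record(compound_id = "lit", src_id = 1L),
                 record(compound_id = "dm", src_id = 15L))
  expect_equal(filter_records(tbl, src_allow = 15L)$compound_id, "dm")
})

test_that("activity-type priority keeps IC50 over Ki within a measurement group", {
  tbl <- records(
    record(compound_id = "C1", activity_type = "Ki", pchembl = 9.0),
    record(compound_id = "C1", activity_type = "IC50", pchembl = 7.2),
    record(compound_id = "C2", smiles = "S2", activity_type = "Ki", pchembl = 6.0)
  )
  out <- select_activity_type(tbl)
  expect_equal(out$pchembl[out$smiles == "S1"], 7.2)
  # a group with no prioritized type is untouched
  expect_equal(out$pchembl[out$smiles == "S2"], 6.0)
})

test_that("duplicate aggregation takes medians of measured values", {
  tbl <- records(
    record(compound_id = "C1", smiles = "S1", pchembl = 6.0),
    record(compound_id = "C1", smiles = "S1", pchembl = 7.0),
    record(compound_id = "C1", smiles = "S1", pchembl = 9.0),
    record(compound_id = "C2", smiles = "S2", pchembl = 6.0),
    record(compound_id = "C2", smiles = "S2", pchembl = 8.0)
  )
  agg <- aggregate_duplicates(filter_records(tbl))
  expect_equal(agg$median_pchembl[agg$smiles == "S1"], 7.0)
  expect_equal(agg$median_pchembl[agg$smiles == "S2"], 7.0)
  expect_false(any(agg$censored))
  expect_equal(nrow(agg), 2L)
})

test_that("measured records take precedence over censored ones; censored-only is carried", {
  tbl <- records(
    record(compound_id = "C1", smiles = "S1", pchembl = 7.4),
    record(compound_id = "C1", smiles = "S1", relation = "<", pchembl = 4.0),
    record(compound_id = "C2", smiles = "S2", relation = "<", pchembl = 4.5)
  )
  agg <- aggregate_duplicates(filter_records(tbl))
  expect_equal(agg$median_pchembl[agg$smiles == "S1"], 7.4)
  expect_false(agg$censored[agg$smiles == "S1"])
  expect_true(agg$censored[agg$smiles == "S2"])
  expect_true(is.na(agg$median_pchembl[agg$smiles == "S2"]))
})

test_that("aggregation is permutation-invariant", {
  tbl <- target_block(n_active = 10, n_inactive = 10)
  tbl <- rbind(tbl, tbl[1:5, ])  # real duplicates
  shuffled <- tbl[rev(seq_len(nrow(tbl))), ]
  a <- aggregate_duplicates(filter_records(tbl))
  b <- aggregate_duplicates(filter_records(shuffled))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("family thresholds and the >= boundary rule label correctly", {
  expect_equal(assign_activity_class(7.6, FALSE, "kinase"), "active")
  expect_equal(assign_activity_class(7.5, FALSE, "kinase"), "active")
  expect_equal(assign_activity_class(7.4, FALSE, "kinase"), "inactive")
  expect_equal(assign_activity_class(5.0, FALSE, "ion_channel"), "active")
  expect_equal(assign_activity_class(6.8, FALSE, "gpcr"), "inactive")
  expect_equal(assign_activity_class(6.8, FALSE, "other"), "active")
  expect_equal(assign_activity_class(9.9, TRUE, "gpcr"), "inactive")
  expect_equal(assign_activity_class(6.0, FALSE, "gpcr", threshold_override = 6.5),
               "inactive")
})

test_that("unknown families fall back to 6.5 with a note", {
  expect_message(thr <- idg_threshold("protease"), "6.5")
  expect_equal(thr, 6.5)
})

test_that("retention applies the publication rule, the count screen and the 6.5 rescue", {
  blk <- target_block(n_active = 45, n_inactive = 35, n_docs = 3)
  agg <- aggregate_duplicates(filter_records(blk))
  ds <- retain_target(agg, "T1", "gpcr", n_docs = 3)
  expect_s3_class(ds, "target_dataset")
  expect_equal(ds$threshold_used, idg_threshold("gpcr"))
  expect_equal(ds$n_active, 45L)
  expect_equal(active_inactive_ratio(ds), 45 / 35)

  # single publication: discarded before counting
  d1 <- retain_target(agg, "T1", "gpcr", n_docs = 1)
  expect_s3_class(d1, "target_discard")
  expect_equal(d1$reason, "too_few_publications")

  # kinase threshold leaves 39 actives; 6.5 rescues the target
  thr_k <- idg_threshold("kinase")
  rescue <- records(
    record(compound_id = sprintf("a%03d", 1:39), smiles = sprintf("a%03d", 1:39),
           family = "kinase", pchembl = thr_k + 0.2),
    record(compound_id = sprintf("m%03d", 1:21), smiles = sprintf("m%03d", 1:21),
           family = "kinase", pchembl = 7.0),   # active at 6.5, inactive at 7.5
    record(compound_id = sprintf("i%03d", 1:300), smiles = sprintf("i%03d", 1:300),
           family = "kinase", pchembl = 5.0)
  )
  agg_r <- aggregate_duplicates(filter_records(rescue))
  ds_r <- retain_target(agg_r, "T2", "kinase", n_docs = 5)
  expect_s3_class(ds_r, "target_dataset")
  expect_equal(ds_r$threshold_used, 6.5)
  expect_equal(ds_r$n_active, 60L)
  expect_equal(ds_r$n_inactive, 300L)

  # relabelling at 6.5 changes only labels, never the compound set
  ds_f <- retain_target(agg_r, "T2", "kinase", n_docs = 5, min_active = 1L)
  expect_equal(ds_f$threshold_used, idg_threshold("kinase"))
  expect_setequal(ds_r$compounds$compound_id, ds_f$compounds$compound_id)
})

test_that("retained datasets satisfy their invariants on randomized synthetic tables", {
  for (seed in 1:3) {
    cfg <- synthetic_config(n_targets = 2, n_compounds = 150, seed = seed)
    study <- generate_activity_table(cfg)
    cur <- curate_activity_table(study$records)
    expect_gt(length(cur$datasets), 0)
    for (ds in cur$datasets) {
      expect_gte(ds$n_active, 40L)
      expect_gte(ds$n_inactive, 30L)
      expect_gte(ds$n_docs, 2L)
      expect_false(any(duplicated(ds$compounds$compound_id)))
      expect_false(any(duplicated(ds$compounds$smiles)))
      expect_true(ds$threshold_used %in% c(idg_threshold(ds$family), 6.5))
      expect_equal(ds$n_active + ds$n_inactive, nrow(ds$compounds))
    }
  }
})

test_that("curation writes per-target CSVs and a run summary", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_targets = 2, n_compounds = 150, seed = 5)
  cur <- curate_activity_table(generate_activity_table(cfg)$records)
  write_curated(cur, dir)
  expect_true(file.exists(file.path(dir, "curation_summary.csv")))
  files <- list.files(dir, pattern = "^T\\d+\\.csv$")
  expect_length(files, sum(cur$summary$retained))
  back <- read.csv(file.path(dir, files[[1]]))
  expect_named(back, c("compound_id", "smiles", "median_pchembl", "label",
                       "threshold_used"))
})
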