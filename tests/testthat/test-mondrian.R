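test_that("proper-training/calibration split is stratified and deterministic", {
  labels <- rep(c("active", "inactive"), c(32, 48))
  pc <- split_proper_calibration(labels, 0.30, seed = 5)
  expect_length(pc$calibration, 24L)
  expect_equal(sum(labels[pc$calibration] == "active"), 10L)
  expect_setequal(c(pc$proper, pc$calibration), seq_along(labels))
  expect_identical(pc, split_proper_calibration(labels, 0.30, seed = 5))

  # degenerate minority: the single spare active is forced into one side,
  # both sides keep at least one
  tiny <- rep(c("active", "inactive"), c(2, 8))
  pc2 <- split_proper_calibration(tiny, 0.30, seed = 1)
  expect_gte(sum(tiny[pc2$calibration] == "active"), 1L)
  expect_gte(sum(tiny[pc2$proper] == "active"), 1L)
  expect_error(split_proper_calibration(c("active", rep("inactive", 5)), 0.3, 1),
               "fewer than 2")
})

test_that("calibration lists conserve per-class counts and are sorted", {
  g <- make_xy(n = 60, separability = 0.9, seed = 7, active_fraction = 10 / 24,
               bits = 64, informative = 16)
  pc <- split_proper_calibration(g$labels, 0.40, seed = 2)
  model <- train_rf(g$x[pc$proper, ], g$labels[pc$proper],
                    rf_config(n_trees = 50))
  calib_idx <- pc$calibration
  mc <- calibrate(model, g$x[calib_idx, ], g$labels[calib_idx])
  expect_s3_class(mc, "mondrian_calibration")
  expect_length(mc$scores_active, sum(g$labels[calib_idx] == "active"))
  expect_length(mc$scores_inactive, sum(g$labels[calib_idx] == "inactive"))
  expect_false(is.unsorted(mc$scores_active))
  expect_false(is.unsorted(mc$scores_inactive))
  expect_true(all(c(mc$scores_active, mc$scores_inactive) >= 0))
  expect_true(all(c(mc$scores_active, mc$scores_inactive) <= 1))
})

test_that("p-values follow the counting definitions including ties", {
  expect_equal(p_value(c(0.1, 0.3, 0.5, 0.9), 0.6, "literal"), 0.75)
  expect_equal(p_value(c(0.5, 0.6, 0.9), 0.05, "literal"), 0)
  # strict "lower than": ties are excluded in literal mode
  expect_equal(p_value(c(0.2, 0.5, 0.5, 0.8), 0.5, "literal"), 1 / 4)
  # adjusted mode includes ties and the +1 correction
  expect_equal(p_value(c(0.2, 0.5, 0.5, 0.8), 0.5, "adjusted"), 4 / 5)
  expect_equal(p_value(c(0.1, 0.3, 0.5, 0.9), 0.6, "adjusted"), 4 / 5)
  expect_error(p_value(numeric(0), 0.5), "empty")
})

test_that("p-values match brute-force counting on random instances", {
  set.seed(99)
  for (i in 1:300) {
    scores <- round(runif(sample(1:30, 1)), 2)
    q <- round(runif(1), 2)
    expect_identical(p_value(scores, q, "literal"),
                     sum(scores < q) / length(scores))
    expect_identical(p_value(scores, q, "adjusted"),
                     (sum(scores <= q) + 1) / (length(scores) + 1))
  }
})

test_that("prediction sets follow the p > epsilon rule", {
  expect_equal(assign_prediction_set(0.40, 0.10, 0.20), "active")
  expect_equal(assign_prediction_set(0.40, 0.10, 0.05), "both")
  expect_equal(assign_prediction_set(0.40, 0.10, 0.45), "empty")
  expect_equal(assign_prediction_set(0.10, 0.40, 0.20), "inactive")
  # boundary: p equal to epsilon excludes the class
  expect_equal(assign_prediction_set(0.20, 0.10, 0.20), "empty")
  expect_equal(set_members(c("both", "empty", "active")),
               list(c("active", "inactive"), character(0), "active"))
})

test_that("prediction sets are nested across significance levels", {
  set.seed(42)
  for (i in 1:200) {
    pa <- runif(1); pi <- runif(1)
    members <- lapply(c(0.10, 0.20, 0.30), function(eps) {
      set_members(assign_prediction_set(pa, pi, eps))[[1]]
    })
    expect_true(all(members[[2]] %in% members[[1]]))
    expect_true(all(members[[3]] %in% members[[2]]))
  }
})

test_that("the conformal protocol shares test sets with the QSAR arm and reports medians", {
  g <- make_xy(n = 100, separability = 0.7, seed = 23, bits = 64,
               informative = 16, noise = 0.1)
  plan <- split_plan(n_repeats = 8, seed = 77)
  out <- run_mcp_protocol(g$x, g$labels, plan, rf_config(n_trees = 60),
                          epsilons = c(0.30, 0.20, 0.10), mode = "adjusted")
  qsar <- run_qsar_protocol(g$x, g$labels, plan, rf_config(n_trees = 60))
  # identical first splits => identical per-compound appearance counts
  expect_equal(out$n_test_appearances, qsar$n_test_appearances)
  expect_named(out, c("compound_id", "label", "p_active_median",
                      "p_inactive_median", "set_at_70", "set_at_80",
                      "set_at_90", "n_test_appearances", "p_value_mode"))
  covered <- out$n_test_appearances > 0
  expect_true(all(out$p_active_median[covered] >= 0 &
                    out$p_active_median[covered] <= 1))
  # sets recomputed from the median p-values agree with the stored columns
  expect_equal(out$set_at_80[covered],
               assign_prediction_set(out$p_active_median[covered],
                                     out$p_inactive_median[covered], 0.20))
  # nesting per compound at the three levels
  m90 <- set_members(out$set_at_90[covered])
  m80 <- set_members(out$set_at_80[covered])
  m70 <- set_members(out$set_at_70[covered])
  for (i in seq_along(m90)) {
    expect_true(all(m80[[i]] %in% m90[[i]]))
    expect_true(all(m70[[i]] %in% m80[[i]]))
  }
})

test_that("median p-value aggregation and the spec micro-example behave as stated", {
  expect_equal(median(c(0.1, 0.4, 0.5)), 0.4)
  # medians (0.4, 0.1): single-active at all three confidence levels
  for (eps in c(0.30, 0.20, 0.10)) {
    expect_equal(assign_prediction_set(0.4, 0.1, eps), "active")
  }
  # medians (0.15, 0.12): both at 90%, empty at 70%
  expect_equal(assign_prediction_set(0.15, 0.12, 0.10), "both")
  expect_equal(assign_prediction_set(0.15, 0.12, 0.30), "empty")
})
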