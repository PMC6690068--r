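test_that("sensitivity, specificity and CCR follow their confusion-matrix definitions", {
  labels <- rep(c("active", "inactive"), c(10, 10))
  pred <- c(rep("active", 8), rep("inactive", 2),     # TP 8, FN 2
            rep("active", 4), rep("inactive", 6))     # FP 4, TN 6
  m <- qsar_metrics(pred, labels)
  expect_equal(unname(m), c(0.8, 0.6, 0.7))
  expect_equal(unname(qsar_metrics(labels, labels)), c(1, 1, 1))
  all_active <- rep("active", 20)
  expect_equal(unname(qsar_metrics(all_active, labels)), c(1, 0, 0.5))
  # absent class: rate and ccr reported missing
  m2 <- qsar_metrics(rep("active", 5), rep("active", 5))
  expect_equal(unname(m2["sensitivity"]), 1)
  expect_true(is.na(m2[["specificity"]]) && is.na(m2[["ccr"]]))
})

test_that("incl and excl conformal metrics treat 'both' and 'empty' as specified", {
  labels <- rep("active", 10)
  sets <- c(rep("active", 7), "inactive", "both", "empty")
  expect_equal(mcp_metrics(sets, labels, "incl")[["sensitivity"]], 0.8)
  expect_equal(mcp_metrics(sets, labels, "excl")[["sensitivity"]], 7 / 9)
  # all both: incl rates 1, excl rates missing
  allb <- rep("both", 6)
  lab2 <- rep(c("active", "inactive"), 3)
  expect_equal(unname(mcp_metrics(allb, lab2, "incl")), c(1, 1, 1))
  expect_true(all(is.na(mcp_metrics(allb, lab2, "excl"))))
  # no both/empty: incl == excl == plain rates
  single <- ifelse(runif(6) > 0.5, "active", "inactive")
  expect_equal(mcp_metrics(single, lab2, "incl"),
               mcp_metrics(single, lab2, "excl"))
  expect_equal(unname(mcp_metrics(single, lab2, "incl")),
               unname(qsar_metrics(single, lab2)))
})

test_that("validity counts errors as sets missing the true class", {
  labels <- rep(c("active", "inactive"), 50)
  sets <- labels
  sets[1:15] <- ifelse(labels[1:15] == "active", "inactive", "active")
  v <- validity(sets, labels, 0.20)
  expect_true(v$valid)
  expect_equal(v$error_rate, 0.15)
  sets[16:25] <- "empty"   # 25 errors now
  expect_false(validity(sets, labels, 0.20)$valid)
  expect_true(validity(rep("both", 100), labels, 0.01)$valid)
  # per-class scope restricts the denominator
  va <- validity(sets, labels, 0.20, scope = "active")
  expect_equal(va$n, 50L)
})

test_that("set fractions partition the outcomes", {
  sets <- c(rep("active", 70), rep("inactive", 18), rep("both", 8),
            rep("empty", 4))
  fr <- set_fractions(sets)
  expect_equal(unname(fr), c(0.08, 0.04, 0.88))
  expect_equal(unname(set_fractions(rep("active", 5))), c(0, 0, 1))
  expect_equal(unname(set_fractions(rep("empty", 5))[c("both", "empty")]),
               c(0, 1))
})

test_that("Tanimoto similarity matches the on-bit set formula", {
  a <- c(1, 1, 1, 0, 0); b <- c(0, 1, 1, 1, 0)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)
  expect_equal(tanimoto_diagnostic(matrix(a, 1), matrix(b, 1)), 0.5)
  expect_equal(tanimoto_diagnostic(matrix(a, 1), matrix(a, 1)), 1)
  # cross-set median over all pairs, against a brute-force loop
  set.seed(3)
  x <- matrix(rbinom(60, 1, 0.4), 6, 10)
  y <- matrix(rbinom(40, 1, 0.4), 4, 10)
  sims <- as.numeric(sapply(seq_len(nrow(y)), function(j)
    sapply(seq_len(nrow(x)), function(i) tanimoto(x[i, ], y[j, ]))))
  expect_equal(tanimoto_diagnostic(x, y), median(sims))
})

test_that("metric identities hold over randomized outcome tables", {
  for (seed in 1:25) {
    o <- random_outcomes(80, seed)
    for (mode in c("incl", "excl")) {
      m <- mcp_metrics(o$sets, o$labels, mode)
      if (!anyNA(m)) {
        expect_equal(m[["ccr"]], (m[["sensitivity"]] + m[["specificity"]]) / 2)
      }
    }
    mi <- mcp_metrics(o$sets, o$labels, "incl")
    me <- mcp_metrics(o$sets, o$labels, "excl")
    for (k in c("sensitivity", "specificity")) {
      if (!is.na(mi[[k]]) && !is.na(me[[k]])) expect_gte(mi[[k]], me[[k]])
    }
    fr <- set_fractions(o$sets)
    expect_equal(sum(fr), 1)
  }
})

test_that("family aggregation averages per-target metrics unweighted", {
  metrics <- rbind(
    data.frame(target_id = c("A", "B"), family = "kinase", arm = "qsar",
               epsilon = NA, mode = NA, sensitivity = c(0.6, 0.8),
               specificity = c(0.7, 0.9), ccr = c(0.65, 0.85),
               fraction_both = NA, fraction_empty = NA,
               valid_overall = NA, valid_active = NA, valid_inactive = NA,
               error_rate_overall = NA, n_active = 50, n_inactive = 50),
    data.frame(target_id = "C", family = "gpcr", arm = "qsar",
               epsilon = NA, mode = NA, sensitivity = 0.5,
               specificity = 0.5, ccr = 0.5,
               fraction_both = NA, fraction_empty = NA,
               valid_overall = NA, valid_active = NA, valid_inactive = NA,
               error_rate_overall = NA, n_active = 10, n_inactive = 90))
  agg <- aggregate_by_family(metrics)
  expect_equal(agg$ccr[agg$family == "kinase"], 0.75)
  expect_equal(agg$n_targets[agg$family == "kinase"], 2L)
  expect_equal(agg$ccr[agg$family == "gpcr"], 0.5)
})

test_that("confusion counts split into correct, incorrect and uncertain", {
  labels <- c(rep("active", 6), rep("inactive", 4))
  sets <- c("active", "active", "inactive", "both", "empty", "active",
            "inactive", "active", "both", "inactive")
  cc <- confusion_counts(sets, labels)
  expect_equal(cc["active", ], data.frame(correct = 3, incorrect = 1,
                                          uncertain = 2, row.names = "active"))
  expect_equal(cc["inactive", ], data.frame(correct = 2, incorrect = 1,
                                            uncertain = 1, row.names = "inactive"))
})
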