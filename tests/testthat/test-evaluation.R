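# Group equalization, cross-validation structure, wrapper selection.

# A synthetic feature table with one informative feature and pure noise:
# cheap to evaluate, with known structure.
toy_table <- function(n_part = 8, weeks = 8, informative = 1, n_feat = 5,
                      effect = 3, seed = 20) {
  withr::with_seed(seed, {
    rows <- tidyr::crossing(participant = sprintf("P%02d", seq_len(n_part)),
                            week = seq_len(weeks)) |>
      dplyr::mutate(week_start = MONDAY + (week - 1) * 7 * 86400,
                    depressed = runif(dplyr::n()) < 0.4,
                    score = ifelse(depressed, 16, 6))
    for (j in seq_len(n_feat)) {
      v <- rnorm(nrow(rows))
      if (j %in% informative) v <- v + effect * rows$depressed
      rows[[paste0("F", j)]] <- v
    }
  })
  list(table = dplyr::select(rows, -"depressed", -"score", -"week"),
       labels = dplyr::select(rows, "participant", "week_start", "score",
                              "depressed"))
}

test_that("group equalization balances classes without touching the minority", {
  df <- tibble::tibble(id = 1:40, depressed = rep(c(TRUE, FALSE), c(10, 30)))
  eq <- group_equalize(df, seed = 3)
  expect_equal(nrow(eq), 20)
  expect_equal(sum(eq$depressed), 10)
  expect_true(all(1:10 %in% eq$id)) # every minority row kept
  expect_identical(eq, group_equalize(df, seed = 3))
  balanced <- tibble::tibble(depressed = rep(c(TRUE, FALSE), 5))
  expect_identical(group_equalize(balanced, seed = 1), balanced)
  expect_error(group_equalize(tibble::tibble(depressed = rep(TRUE, 4))),
               "empty")
})

test_that("participant-wise folds never leak the held-out participant", {
  toy <- toy_table()
  df <- dplyr::inner_join(toy$table, toy$labels,
                          by = c("participant", "week_start"))
  for (scheme in c("lopo", "kfold")) {
    parts <- geomood:::make_partitions(df, scheme, k = 4, seed = 5)
    for (partition in parts) {
      expect_equal(sort(unlist(partition)), seq_len(nrow(df)))
      for (test_rows in partition) {
        held <- unique(df$participant[test_rows])
        train_rows <- setdiff(seq_len(nrow(df)), test_rows)
        expect_false(any(df$participant[train_rows] %in% held))
      }
    }
  }
})

test_that("lopo on two participants gives exactly two folds", {
  toy <- toy_table(n_part = 2)
  df <- dplyr::inner_join(toy$table, toy$labels,
                          by = c("participant", "week_start"))
  parts <- geomood:::make_partitions(df, "lopo")
  expect_equal(length(parts), 1)
  expect_equal(length(parts[[1]]), 2)
})

test_that("within-participant folds interleave each participant's weeks", {
  toy <- toy_table(n_part = 3, weeks = 9)
  df <- dplyr::inner_join(toy$table, toy$labels,
                          by = c("participant", "week_start"))
  parts <- geomood:::make_partitions(df, "within3")
  expect_equal(length(parts[[1]]), 3)
  for (p in unique(df$participant)) {
    rows <- which(df$participant == p)
    fold_sizes <- vapply(parts[[1]], function(f) sum(rows %in% f), integer(1))
    expect_equal(sort(fold_sizes), c(3, 3, 3))
  }
})

test_that("cross-validation detects a strong feature and reports balanced
           iterations", {
  toy <- toy_table(effect = 4)
  cv <- run_cv(toy$table, toy$labels, "F1", model = "qda", scheme = "lopo",
               M = 10, seed = 2)
  expect_s3_class(cv, "geomood_cv")
  expect_equal(nrow(cv$metrics), 10)
  f1 <- cv$summary$median[cv$summary$metric == "f1"]
  expect_gt(f1, 0.7)
  expect_true(all(cv$metrics$auc >= 0 & cv$metrics$auc <= 1))
  expect_equal(cv$mean_roc$fpr, seq(0, 1, by = 0.02))
  expect_true(all(diff(cv$mean_roc$tpr) > -1e-9))
})

test_that("cross-validated regression reports MAE against the baseline", {
  toy <- toy_table(effect = 4)
  cv <- run_cv(toy$table, toy$labels, "F1", model = "linear", scheme = "lopo",
               seed = 2)
  expect_equal(cv$task, "regression")
  expect_lt(cv$mae, cv$mae_baseline)
  expect_lt(cv$f_test$p, 0.01)
  expect_equal(nrow(cv$predictions), nrow(toy$table))
})

test_that("wrapper selection finds the informative feature first", {
  first_picks <- vapply(1:5, function(s) {
    toy <- toy_table(n_part = 6, weeks = 6, seed = 100 + s)
    w <- wrapper_select(toy$table, toy$labels, paste0("F", 1:5),
                        model = "qda", scheme = "lopo", M = 3, seed = 1,
                        max_features = 1)
    w$order[1]
  }, character(1))
  expect_true(all(first_picks == "F1"))
})

test_that("max_features = 1 reduces to the argmax of single-feature CV and
           greedy selection matches brute-force enumeration", {
  toy <- toy_table(n_part = 6, weeks = 6, n_feat = 3, seed = 33)
  cand <- paste0("F", 1:3)
  w <- wrapper_select(toy$table, toy$labels, cand, model = "qda",
                      scheme = "lopo", M = 3, seed = 4)
  # brute-force greedy with the same evaluation settings
  selected <- character(0)
  for (step in 1:3) {
    rem <- setdiff(cand, selected)
    crit <- vapply(rem, function(f) {
      cv <- run_cv(toy$table, toy$labels, c(selected, f), model = "qda",
                   scheme = "lopo", M = 3, seed = 4)
      cv$summary$median[cv$summary$metric == "f1"]
    }, numeric(1))
    selected <- c(selected, rem[which.max(crit)])
  }
  expect_equal(w$order, selected)
  w1 <- wrapper_select(toy$table, toy$labels, cand, model = "qda",
                       scheme = "lopo", M = 3, seed = 4, max_features = 1)
  expect_equal(w1$order, selected[1])
  expect_equal(nrow(w$trace), 3)
})

test_that("tidy, glance and autoplot work on CV results", {
  toy <- toy_table()
  cv <- run_cv(toy$table, toy$labels, "F1", model = "qda", M = 5, seed = 2)
  expect_s3_class(generics::tidy(cv), "tbl_df")
  g <- generics::glance(cv)
  expect_equal(g$scheme, "lopo")
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  expect_s3_class(plot_mean_roc(cv), "ggplot")
})
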