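## Cross-validation with class-balanced subsampling, plus greedy wrapper
## feature selection. Participant-wise schemes (leave-one-participant-out
## and k-fold over participants) never let a held-out participant's weeks
## into training; the within-participant 3-fold scheme deliberately does,
## to expose the non-independence of a participant's weeks over time.

#' Balance a training set by subsampling the majority class
#'
#' Keeps every minority-class week and draws an equal number of
#' majority-class weeks uniformly without replacement.
#'
#' @param train Tibble with a logical `depressed` column.
#' @param seed Integer seed.
#' @return Balanced tibble (`n_min` rows per class).
#' @export
group_equalize <- function(train, seed = 1L) {
  n1 <- sum(train$depressed)
  n2 <- sum(!train$depressed)
  if (n1 == 0 || n2 == 0) stop("a class is empty", call. = FALSE)
  if (n1 == n2) return(train)
  withr::with_seed(seed, {
    minority <- train$depressed == (n1 < n2)
    idx_min <- which(minority)
    idx_maj <- sample(which(!minority), min(n1, n2))
    train[sort(c(idx_min, idx_maj)), ]
  })
}

## Build the list of fold partitions for a scheme. Each partition is a list
## of integer row-index vectors (the test sets); folds of one partition are
## disjoint and cover all rows.
make_partitions <- function(df, scheme, k = 10, seed = 1L) {
  pids <- unique(df$participant)
  N <- length(pids)
  if (scheme == "lopo") {
    return(list(lapply(pids, function(p) which(df$participant == p))))
  }
  if (scheme == "kfold") {
    n_rep <- ceiling(N / k)
    return(withr::with_seed(seed, {
      lapply(seq_len(n_rep), function(r) {
        # stratify: spread participants with depressed weeks across folds
        has_dep <- vapply(pids, function(p)
          any(df$depressed[df$participant == p]), logical(1))
        fold_of <- integer(N)
        for (grp in list(which(has_dep), which(!has_dep))) {
          grp <- sample(grp)
          fold_of[grp] <- rep_len(sample(k), length(grp))
        }
        lapply(seq_len(k), function(f)
          which(df$participant %in% pids[fold_of == f]))
      })
    }))
  }
  if (scheme == "within3") {
    fold <- integer(nrow(df))
    for (p in pids) {
      rows <- which(df$participant == p)
      rows <- rows[order(df$week_start[rows])]
      fold[rows] <- rep_len(1:3, length(rows)) # interleave weeks 1,4,7.../2,5,8...
    }
    return(list(lapply(1:3, function(f) which(fold == f))))
  }
  stop("unknown scheme", call. = FALSE)
}

## Evaluate one partition x equalization iteration: pooled test predictions.
cv_iteration <- function(df, X, partition, seed) {
  pred <- rep(NA, nrow(df))
  score <- rep(NA_real_, nrow(df))
  skipped <- 0L
  for (fi in seq_along(partition)) {
    test <- partition[[fi]]
    if (length(test) == 0) next
    train <- setdiff(seq_len(nrow(df)), test)
    if (length(unique(df$depressed[train])) < 2) {
      skipped <- skipped + 1L
      next
    }
    tr <- df[train, c("participant", "depressed")]
    tr$.row <- train
    eq <- group_equalize(tr, seed = child_seed(seed, fi))
    rows <- eq$.row
    fit <- fit_qda(X[rows, , drop = FALSE], df$depressed[rows])
    pr <- predict(fit, X[test, , drop = FALSE])
    pred[test] <- pr$class == "TRUE"
    score[test] <- pr$score
  }
  list(pred = pred, score = score, skipped = skipped)
}

#' Cross-validated depression classification or score regression
#'
#' Joins the feature table with week labels, builds folds for the requested
#' scheme, and evaluates the model. For classification (`model = "qda"`),
#' each fold's training set is re-balanced by [group_equalize()] `M` times;
#' per equalization iteration the pooled test predictions over all folds
#' yield one set of metrics (Ac/Se/Sp/F1/AUC), and the result reports their
#' median and IQR. For regression models the folds are evaluated once and
#' the pooled mean absolute error is reported with an F-test against the
#' constant training-mean baseline.
#'
#' @param table Feature table from [extract_feature_table()].
#' @param labels Week labels from [label_weeks()].
#' @param features Feature column names to use.
#' @param model `"qda"`, `"linear"` or `"qlglm"`.
#' @param scheme `"lopo"`, `"kfold"` (over participants) or `"within3"`
#'   (each participant's weeks interleaved over 3 folds).
#' @param k Fold count for `"kfold"`; the random partition is regenerated
#'   `ceiling(N/k)` times.
#' @param M Equalization iterations per fold (classification only).
#' @param seed Integer seed.
#' @param roc_grid FPR grid for the vertically averaged mean ROC curve.
#' @return Object of class `geomood_cv`.
#' @export
run_cv <- function(table, labels, features, model = c("qda", "linear", "qlglm"),
                   scheme = c("lopo", "kfold", "within3"), k = 10, M = 100,
                   seed = 1L, roc_grid = seq(0, 1, by = 0.02)) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  df <- dplyr::inner_join(table, labels, by = c("participant", "week_start"))
  df <- df[!is.na(df$score), ]
  df <- df[complete.cases(df[features]), ]
  rownames(df) <- NULL
  if (nrow(df) == 0) stop("no labeled complete weeks", call. = FALSE)
  partitions <- make_partitions(df, scheme, k = k, seed = child_seed(seed, 77))
  X <- as.matrix(df[features])
  if (model == "qda") {
    iters <- list()
    rocs <- list()
    skipped <- 0L
    for (p in seq_along(partitions)) {
      for (m in seq_len(M)) {
        it <- cv_iteration(df, X, partitions[[p]],
                           seed = child_seed(seed, p * 100000 + m))
        skipped <- skipped + it$skipped
        ok <- !is.na(it$pred)
        met <- classification_metrics(df$depressed[ok], it$pred[ok],
                                      it$score[ok])
        iters[[length(iters) + 1]] <- tibble::tibble(
          partition = p, iteration = m, ac = met$ac, se = met$se,
          sp = met$sp, f1 = met$f1, auc = met$auc)
        # vertical averaging on a common FPR grid: best TPR at FPR <= g
        dedup <- !duplicated(met$roc$fpr, fromLast = TRUE)
        fpr_u <- met$roc$fpr[dedup]
        tpr_u <- met$roc$tpr[dedup]
        rocs[[length(rocs) + 1]] <- tpr_u[findInterval(roc_grid, fpr_u)]
      }
    }
    metrics <- dplyr::bind_rows(iters)
    summary <- metrics |>
      tidyr::pivot_longer(c("ac", "se", "sp", "f1", "auc"),
                          names_to = "metric") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(median = median(.data$value),
                       iqr = quantile(.data$value, 0.75) -
                         quantile(.data$value, 0.25),
                       .groups = "drop")
    res <- list(task = "classification", model = model, scheme = scheme,
                features = features, M = M, n_weeks = nrow(df),
                metrics = metrics, summary = summary,
                mean_roc = tibble::tibble(
                  fpr = roc_grid,
                  tpr = colMeans(do.call(rbind, rocs))),
                n_skipped_folds = skipped)
  } else {
    pred <- rep(NA_real_, nrow(df))
    base_pred <- rep(NA_real_, nrow(df))
    for (p in seq_along(partitions)) {
      for (test in partitions[[p]]) {
        train <- setdiff(seq_len(nrow(df)), test)
        fit <- if (model == "linear") {
          fit_linear(df[train, ], features)
        } else {
          fit_quadratic_logistic_glm(df[train, ], features)
        }
        pred[test] <- predict(fit, df[test, ])
        base_pred[test] <- mean(df$score[train])
      }
    }
    ftest <- significance_vs_baseline(df$score - pred, df$score - base_pred,
                                      df_model = if (model == "linear")
                                        length(features) else 2 * length(features))
    res <- list(task = "regression", model = model, scheme = scheme,
                features = features, n_weeks = nrow(df),
                mae = mae(df$score, pred),
                mae_baseline = mae(df$score, base_pred),
                f_test = ftest,
                predictions = tibble::tibble(
                  participant = df$participant, week_start = df$week_start,
                  score = df$score, estimate = pred))
  }
  structure(res, class = "geomood_cv")
}

#' @export
print.geomood_cv <- function(x, ...) {
  cat(sprintf("<geomood_cv> %s | %s | %s | %d weeks\n",
              x$task, x$model, x$scheme, x$n_weeks))
  if (x$task == "classification") {
    s <- x$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-3s median %.3f  IQR %.3f\n",
                  s$metric[i], s$median[i], s$iqr[i]))
  } else {
    cat(sprintf("  MAE %.3f (baseline %.3f), F = %.2f, p = %.3g\n",
                x$mae, x$mae_baseline, x$f_test$F, x$f_test$p))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.geomood_cv <- function(x, ...) {
  if (x$task == "classification") x$summary
  else tibble::tibble(metric = c("mae", "mae_baseline"),
                      value = c(x$mae, x$mae_baseline))
}

#' @exportS3Method generics::glance
glance.geomood_cv <- function(x, ...) {
  if (x$task == "classification") {
    s <- setNames(x$summary$median, x$summary$metric)
    tibble::tibble(model = x$model, scheme = x$scheme, n_weeks = x$n_weeks,
                   f1 = s[["f1"]], ac = s[["ac"]], auc = s[["auc"]],
                   n_skipped_folds = x$n_skipped_folds)
  } else {
    tibble::tibble(model = x$model, scheme = x$scheme, n_weeks = x$n_weeks,
                   mae = x$mae, p = x$f_test$p)
  }
}

#' Plot a cross-validation result
#'
#' Classification results show the per-iteration metric distributions and
#' the vertically averaged ROC curve; regression results show estimated vs
#' true scores.
#'
#' @param object A `geomood_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.geomood_cv <- function(object, ...) {
  if (object$task == "classification") {
    long <- tidyr::pivot_longer(object$metrics,
                                c("ac", "se", "sp", "f1", "auc"),
                                names_to = "metric")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
      ggplot2::geom_boxplot(outlier.shape = 4) +
      ggplot2::labs(y = "value over equalization iterations", x = NULL,
                    title = sprintf("%s / %s cross-validation",
                                    object$model, object$scheme)) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$predictions,
                    ggplot2::aes(x = .data$score, y = .data$estimate)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::labs(x = "QIDS score", y = "estimated score") +
      ggplot2::theme_minimal()
  }
}

#' Plot the mean ROC curve of a classification CV result
#' @param object A classification `geomood_cv` result.
#' @return A ggplot object.
#' @export
plot_mean_roc <- function(object) {
  stopifnot(object$task == "classification")
  ggplot2::ggplot(object$mean_roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line(color = "red") +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "FPR", y = "TPR") +
    ggplot2::theme_minimal()
}

#' Greedy forward wrapper feature selection
#'
#' Incrementally grows a feature set: at each step every remaining
#' candidate is evaluated joined to the selected set under full
#' cross-validation, and the best by the criterion (median F1 for
#' classification, MAE for regression) is kept; ties go to the earliest
#' candidate in the supplied order.
#'
#' @param table,labels,model,scheme,k,M,seed As in [run_cv()].
#' @param candidates Candidate feature columns, in canonical order.
#' @param max_features Stop after this many selections.
#' @return List of class `geomood_wrapper`: `order` (selected features),
#'   `trace` (per-size criterion values), `results` (per-size
#'   `geomood_cv`).
#' @export
wrapper_select <- function(table, labels, candidates, model = "qda",
                           scheme = "lopo", k = 10, M = 10, seed = 1L,
                           max_features = length(candidates)) {
  selected <- character(0)
  trace <- list()
  results <- list()
  classify <- model == "qda"
  while (length(selected) < min(max_features, length(candidates))) {
    remaining <- setdiff(candidates, selected)
    crit <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      cv <- run_cv(table, labels, c(selected, remaining[i]), model = model,
                   scheme = scheme, k = k, M = M, seed = seed)
      fits[[i]] <- cv
      crit[i] <- if (classify)
        cv$summary$median[cv$summary$metric == "f1"] else cv$mae
    }
    best <- if (classify) which.max(crit) else which.min(crit)
    selected <- c(selected, remaining[best])
    trace[[length(trace) + 1]] <- tibble::tibble(
      size = length(selected), feature = remaining[best],
      criterion = crit[best])
    results[[length(selected)]] <- fits[[best]]
  }
  structure(list(order = selected, trace = dplyr::bind_rows(trace),
                 results = results, criterion = if (classify) "median F1" else "MAE"),
            class = "geomood_wrapper")
}

#' @export
print.geomood_wrapper <- function(x, ...) {
  cat("<geomood_wrapper> greedy forward selection by", x$criterion, "\n")
  print(x$trace)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.geomood_wrapper <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$size, y = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$trace$size,
                                labels = paste0(object$trace$size, "\n",
                                                object$trace$feature)) +
    ggplot2::labs(x = "features (in selection order)", y = object$criterion) +
    ggplot2::theme_minimal()
}
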