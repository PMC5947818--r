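## Estimators and metrics: a linear QIDS-score model, a quadratic GLM with
## logistic link bounding the estimate in (0, a), a quadratic discriminant
## classifier with ridge fallback, the mean absolute error, the
## sensitivity/specificity F1, ROC/AUC and the F-test against a constant
## baseline model.

#' Fit the linear QIDS-score model
#'
#' Ordinary least squares `Q = b0 + b . f` on one or more feature columns.
#'
#' @param data Data frame holding the features and response.
#' @param features Character vector of feature column names.
#' @param response Response column name (default `"score"`).
#' @return Object of class `geomood_lm` wrapping the `lm` fit.
#' @export
fit_linear <- function(data, features, response = "score") {
  df <- data[c(features, response)]
  df <- df[complete.cases(df), ]
  if (nrow(df) < 2) stop("need at least 2 complete rows", call. = FALSE)
  if (any(vapply(df[features], function(f) var(f) == 0, logical(1))))
    stop("constant feature: linear fit undefined", call. = FALSE)
  fm <- stats::reformulate(sprintf("`%s`", features), response = sprintf("`%s`", response))
  structure(list(fit = lm(fm, data = df), features = features,
                 response = response),
            class = "geomood_lm")
}

#' @export
predict.geomood_lm <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata = newdata))
}

#' @exportS3Method generics::tidy
tidy.geomood_lm <- function(x, ...) {
  co <- coef(x$fit)
  tibble::tibble(term = names(co), estimate = unname(co))
}

#' @exportS3Method generics::glance
glance.geomood_lm <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = length(stats::residuals(x$fit)))
}

## Quadratic-logistic mean function: a / (1 + exp(-(b0 + B1.f + B2.f^2)))
qlglm_mean <- function(beta, X, a) {
  p <- ncol(X)
  eta <- beta[1] + X %*% beta[2:(p + 1)] + X^2 %*% beta[(p + 2):(2 * p + 1)]
  out <- as.vector(a / (1 + exp(-eta)))
  # keep the open interval (0, a) where exp() saturates in floating point
  pmin(pmax(out, a * 1e-12), a * (1 - 1e-12))
}

#' Fit the quadratic GLM with logistic link
#'
#' Minimizes the sum of squared errors of
#' `Q = a / (1 + exp(-(b0 + b1 f + b2 f^2)))` (per-feature linear and
#' quadratic terms for multivariate fits) by nonlinear least squares from
#' five deterministic multi-starts. The logistic link bounds every
#' prediction smoothly in (0, a).
#'
#' @param data Data frame holding features and response.
#' @param features Feature column names.
#' @param response Response column name.
#' @param a Output ceiling (default 27, the QIDS maximum).
#' @return Object of class `geomood_qlglm` with coefficients `beta`
#'   (intercept, linear terms, quadratic terms).
#' @export
fit_quadratic_logistic_glm <- function(data, features, response = "score",
                                       a = 27) {
  df <- data[c(features, response)]
  df <- df[complete.cases(df), ]
  if (nrow(df) < 4) stop("need at least 4 complete rows", call. = FALSE)
  Q <- df[[response]]
  if (any(Q < 0 | Q > a)) stop("responses must lie in [0, a]", call. = FALSE)
  # standardize features internally for a well-conditioned search
  mu <- vapply(df[features], mean, numeric(1))
  sg <- pmax(vapply(df[features], sd, numeric(1)), 1e-12)
  X <- scale(as.matrix(df[features]), center = mu, scale = sg)
  p <- length(features)
  sse <- function(beta) sum((Q - qlglm_mean(beta, X, a))^2)
  starts <- list(rep(0, 2 * p + 1),
                 c(0, rep(1, p), rep(0, p)),
                 c(0, rep(-1, p), rep(0, p)),
                 c(-1, rep(1, p), rep(-0.5, p)),
                 c(1, rep(-1, p), rep(0.5, p)))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, sse, method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("quadratic logistic GLM did not converge from any start", call. = FALSE)
  structure(list(beta = best$par, a = a, features = features, center = mu,
                 scale = sg, sse = best$value, nobs = nrow(df)),
            class = "geomood_qlglm")
}

#' @export
predict.geomood_qlglm <- function(object, newdata, ...) {
  X <- scale(as.matrix(newdata[object$features]),
             center = object$center, scale = object$scale)
  qlglm_mean(object$beta, X, object$a)
}

#' @exportS3Method generics::tidy
tidy.geomood_qlglm <- function(x, ...) {
  p <- length(x$features)
  tibble::tibble(
    term = c("(Intercept)", x$features, paste0(x$features, "^2")),
    estimate = x$beta,
    scale = c(NA, x$scale, x$scale^2)
  )
}

#' @exportS3Method generics::glance
glance.geomood_qlglm <- function(x, ...) {
  tibble::tibble(sse = x$sse, nobs = x$nobs, ceiling = x$a)
}

#' Fit a quadratic discriminant classifier
#'
#' Class-conditional multivariate Gaussians with per-class covariance;
#' ill-conditioned covariances receive a ridge of `1e-6 * trace / d` on the
#' diagonal. Priors default to equal (training sets are class-balanced by
#' group equalization upstream).
#'
#' @param X Numeric matrix / data frame of feature columns.
#' @param y Logical or two-level vector of class labels.
#' @param priors Named numeric priors (default equal).
#' @return Object of class `geomood_qda`.
#' @export
fit_qda <- function(X, y, priors = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required", call. = FALSE)
  if (any(table(y) < 2)) stop("need >= 2 samples per class", call. = FALSE)
  if (is.null(priors)) priors <- setNames(c(0.5, 0.5), levels(y))
  d <- ncol(X)
  cls <- lapply(levels(y), function(lv) {
    Xl <- X[y == lv, , drop = FALSE]
    S <- stats::cov(Xl)
    if (rcond(S) < 1e-10) {
      S <- S + diag(1e-6 * sum(diag(S)) / d + 1e-12, d)
      if (rcond(S) < 1e-14)
        stop("singular class covariance after ridge", call. = FALSE)
    }
    ch <- chol(S)
    list(mean = colMeans(Xl), chol_inv = backsolve(ch, diag(d)),
         logdet = 2 * sum(log(diag(ch))))
  })
  names(cls) <- levels(y)
  structure(list(classes = cls, levels = levels(y),
                 priors = priors[levels(y)], d = d),
            class = "geomood_qda")
}

#' Predict classes and scores from a QDA fit
#'
#' @param object A `geomood_qda` fit.
#' @param newdata Matrix/data frame with the training feature columns.
#' @param ... Unused.
#' @return Tibble with `class` (predicted label), `score` (posterior
#'   probability of the second factor level, the positive class) and per-class
#'   discriminants.
#' @export
predict.geomood_qda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  disc <- vapply(object$levels, function(lv) {
    cl <- object$classes[[lv]]
    Z <- sweep(X, 2, cl$mean) %*% cl$chol_inv
    log(object$priors[[lv]]) - 0.5 * cl$logdet - 0.5 * rowSums(Z^2)
  }, numeric(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X),
                 dimnames = list(NULL, object$levels))
  m <- apply(disc, 1, max)
  post <- exp(disc - m)
  post <- post / rowSums(post)
  tibble::tibble(
    class = object$levels[max.col(disc, ties.method = "first")],
    score = post[, 2],
    d1 = disc[, 1], d2 = disc[, 2]
  )
}

#' @exportS3Method generics::tidy
tidy.geomood_qda <- function(x, ...) {
  purrr::map_dfr(x$levels, function(lv) {
    tibble::tibble(class = lv, term = names(x$classes[[lv]]$mean),
                   mean = unname(x$classes[[lv]]$mean),
                   prior = unname(x$priors[[lv]]))
  })
}

#' Mean absolute error
#'
#' @param q True scores.
#' @param q_hat Estimates (same length).
#' @return `mean(|q - q_hat|)`.
#' @export
mae <- function(q, q_hat) {
  if (length(q) == 0) stop("empty input", call. = FALSE)
  if (length(q) != length(q_hat)) stop("length mismatch", call. = FALSE)
  mean(abs(q - q_hat))
}

#' Sensitivity/specificity F1
#'
#' The harmonic mean of sensitivity and specificity,
#' `2 Se Sp / (Se + Sp)` (0 when both are 0) — deliberately distinct from
#' precision-recall F1.
#'
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_sesp <- function(se, sp) {
  ifelse(se + sp == 0, 0, 2 * se * sp / (se + sp))
}

#' ROC curve by threshold sweep
#'
#' @param y Logical true labels.
#' @param scores Classifier scores (larger = more positive).
#' @return Tibble of `fpr`, `tpr`, monotone from (0,0) to (1,1).
#' @export
roc_curve <- function(y, scores) {
  o <- order(scores, decreasing = TRUE)
  y <- as.logical(y)[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # collapse tied scores to one operating point
  keep <- c(diff(scores[o]) < 0, TRUE)
  tibble::tibble(
    fpr = c(0, fp[keep] / sum(!y)),
    tpr = c(0, tp[keep] / sum(y))
  )
}

#' Trapezoid area under an ROC curve
#' @param roc Tibble from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity, specificity, the Se/Sp F1, and (when scores are
#' supplied) the ROC curve and its trapezoid AUC.
#'
#' @param y Logical true labels (both classes present).
#' @param y_hat Logical predictions.
#' @param scores Optional classifier scores for ROC/AUC.
#' @return List with `ac`, `se`, `sp`, `f1`, and optionally `roc`, `auc`.
#' @export
classification_metrics <- function(y, y_hat, scores = NULL) {
  y <- as.logical(y); y_hat <- as.logical(y_hat)
  if (length(unique(y)) < 2)
    stop("both classes must be present in y", call. = FALSE)
  tp <- sum(y & y_hat); tn <- sum(!y & !y_hat)
  fp <- sum(!y & y_hat); fn <- sum(y & !y_hat)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  out <- list(ac = (tp + tn) / length(y), se = se, sp = sp,
              f1 = f1_sesp(se, sp),
              confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
  if (!is.null(scores)) {
    out$roc <- roc_curve(y, scores)
    out$auc <- auc_trapezoid(out$roc)
  }
  out
}

#' F-test of a fitted model against the constant baseline
#'
#' Standard nested-model F statistic from residual sums of squares:
#' `F = ((RSS0 - RSS1) / df_extra) / (RSS1 / (n - p1))`, with the p-value
#' from the F distribution.
#'
#' @param resid_model Residuals of the fitted model.
#' @param resid_baseline Residuals of the constant-mean baseline.
#' @param df_model Number of parameters the model adds over the baseline.
#' @return List with `F`, `p`, degrees of freedom.
#' @export
significance_vs_baseline <- function(resid_model, resid_baseline, df_model) {
  n <- length(resid_model)
  if (df_model <= 0) stop("df_model must be positive", call. = FALSE)
  df2 <- n - df_model - 1
  if (df2 <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  rss1 <- sum(resid_model^2)
  rss0 <- sum(resid_baseline^2)
  Fstat <- max(0, (rss0 - rss1) / df_model) / (rss1 / df2)
  list(F = Fstat, p = pf(Fstat, df_model, df2, lower.tail = FALSE),
       df1 = df_model, df2 = df2)
}
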