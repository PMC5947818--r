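# Estimators and metrics.

test_that("the linear model recovers exact lines and shifts with the response", {
  df <- tibble::tibble(f = c(0, 1, 2), score = c(1, 3, 5))
  fit <- fit_linear(df, "f")
  expect_equal(unname(coef(fit$fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(predict(fit, df), df$score, tolerance = 1e-12)
  fit2 <- fit_linear(dplyr::mutate(df, score = score + 7), "f")
  expect_equal(unname(coef(fit2$fit)), c(8, 2), tolerance = 1e-12)
  expect_error(fit_linear(tibble::tibble(f = c(1, 1, 1), score = 1:3), "f"),
               "constant")
})

test_that("the quadratic logistic GLM fits the midpoint exactly and bounds
           its predictions", {
  df <- tibble::tibble(f = seq(-3, 3, length.out = 12), score = 13.5)
  fit <- fit_quadratic_logistic_glm(df, "f")
  expect_equal(predict(fit, df), rep(13.5, 12), tolerance = 1e-6)
  wild <- tibble::tibble(f = c(-1e4, -5, 0, 5, 1e4))
  withr::with_seed(6, {
    df2 <- tibble::tibble(f = rnorm(20), score = runif(20, 0, 27))
  })
  p <- predict(fit_quadratic_logistic_glm(df2, "f"), wild)
  expect_true(all(p > 0 & p < 27))
})

test_that("the quadratic logistic GLM recovers generating coefficients", {
  beta <- c(-1, 2, -0.5)
  a <- 27
  f <- seq(-2, 4, length.out = 50)
  q <- a / (1 + exp(-(beta[1] + beta[2] * f + beta[3] * f^2)))
  fit <- fit_quadratic_logistic_glm(tibble::tibble(f = f, score = q), "f")
  # undo the internal standardization to compare on the raw-feature scale
  mu <- fit$center[[1]]; sg <- fit$scale[[1]]
  b <- fit$beta
  raw <- c(b[1] - b[2] * mu / sg + b[3] * mu^2 / sg^2,
           b[2] / sg - 2 * b[3] * mu / sg^2,
           b[3] / sg^2)
  expect_equal(raw, beta, tolerance = 1e-4)
  expect_equal(predict(fit, tibble::tibble(f = f)), q, tolerance = 1e-6)
})

test_that("QDA separates well-separated Gaussians and is chance on identical
           ones", {
  withr::with_seed(8, {
    X1 <- cbind(rnorm(200), rnorm(200))
    X2 <- cbind(rnorm(200, 6), rnorm(200, 6))
    Xtest1 <- cbind(rnorm(500), rnorm(500))
    Xtest2 <- cbind(rnorm(500, 6), rnorm(500, 6))
  })
  fit <- fit_qda(rbind(X1, X2), rep(c(FALSE, TRUE), each = 200))
  pred <- predict(fit, rbind(Xtest1, Xtest2))
  acc <- mean((pred$class == "TRUE") == rep(c(FALSE, TRUE), each = 500))
  expect_gt(acc, 0.99)
  withr::with_seed(9, {
    Xa <- cbind(rnorm(300), rnorm(300))
    Xb <- cbind(rnorm(300), rnorm(300))
    Xt <- cbind(rnorm(1000), rnorm(1000))
  })
  fit0 <- fit_qda(rbind(Xa, Xb), rep(c(FALSE, TRUE), each = 300))
  p0 <- predict(fit0, Xt)
  expect_lt(abs(mean(p0$class == "TRUE") - 0.5), 0.1) # no preferred class
})

test_that("QDA matches the reference implementation's posteriors", {
  skip_if_not_installed("MASS")
  withr::with_seed(10, {
    X <- rbind(cbind(rnorm(60), rnorm(60)),
               cbind(rnorm(60, 2, 1.5), rnorm(60, 1, 0.7)))
  })
  y <- rep(c(FALSE, TRUE), each = 60)
  ours <- predict(fit_qda(X, y), X)
  ref <- MASS::qda(X, grouping = factor(y), prior = c(0.5, 0.5))
  ref_post <- predict(ref, X)$posterior[, "TRUE"]
  expect_equal(ours$score, unname(ref_post), tolerance = 1e-8)
  expect_equal(ours$class == "TRUE",
               unname(predict(ref, X)$class == "TRUE"))
})

test_that("QDA recovers generating means and covariances at n = 1000", {
  withr::with_seed(11, {
    S <- matrix(c(2, 0.6, 0.6, 1), 2)
    L <- chol(S)
    X1 <- matrix(rnorm(2000), ncol = 2) %*% L
    X2 <- sweep(matrix(rnorm(2000), ncol = 2), 2, c(-3, 2), "+")
  })
  fit <- fit_qda(rbind(X1, X2), rep(c("a", "b"), each = 1000))
  expect_equal(unname(fit$classes$a$mean), c(0, 0), tolerance = 0.15)
  expect_equal(unname(fit$classes$b$mean), c(-3, 2), tolerance = 0.15)
  R <- solve(fit$classes$a$chol_inv) # chol factor of the fitted covariance
  expect_equal(t(R) %*% R, S, tolerance = 0.25, ignore_attr = TRUE)
})

test_that("MAE matches hand computation and ignores order", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(5, 5, 5), c(4, 3, 2)), 2)
  expect_equal(mae(c(5, 5, 5), c(2, 4, 3)), 2)
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mae(1:3, 1:2), "length")
})

test_that("classification metrics follow their closed forms", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  m <- classification_metrics(y, y, scores = c(1, 1, 0, 0))
  expect_equal(unlist(m[c("ac", "se", "sp", "f1", "auc")]),
               c(ac = 1, se = 1, sp = 1, f1 = 1, auc = 1))
  expect_equal(f1_sesp(0.8, 0.6), 2 * 0.8 * 0.6 / 1.4, tolerance = 1e-12)
  expect_equal(f1_sesp(0, 0), 0)
  expect_error(classification_metrics(c(TRUE, TRUE), c(TRUE, FALSE)), "class")
})

test_that("AUC equals Mann-Whitney pair counting on a swapped pair", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  scores <- c(1, 0, 1, 0) # one positive and one negative swapped
  # pair enumeration: (1>0) + (1~1)/2 + (0~0)/2 + (0<1) = 2 / 4
  pairs <- outer(scores[y], scores[!y],
                 function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc_trapezoid(roc_curve(y, scores)), mean(pairs))
  expect_equal(mean(pairs), 0.5)
})

test_that("AUC agrees with the reference implementation on random scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    y <- runif(60) > 0.4
    s <- runif(60) + y * 0.3
  })
  ours <- auc_trapezoid(roc_curve(y, s))
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("the F1 harmonic mean is bounded by min and arithmetic mean", {
  withr::with_seed(14, {
    se <- runif(200)
    sp <- runif(200)
  })
  f1 <- f1_sesp(se, sp)
  expect_true(all(f1 <= (se + sp) / 2 + 1e-12))
  expect_true(all(f1 >= pmin(se, sp) * (se + sp > 0) - 1e-12))
})

test_that("the baseline F-test matches its textbook form", {
  n <- 20
  resid0 <- sqrt(rep(100 / n, n)) # RSS0 = 100
  resid1 <- sqrt(rep(50 / n, n)) # RSS1 = 50
  ft <- significance_vs_baseline(resid1, resid0, df_model = 1)
  expect_equal(ft$F, 18, tolerance = 1e-12)
  expect_equal(ft$p, pf(18, 1, 18, lower.tail = FALSE), tolerance = 1e-12)
  same <- significance_vs_baseline(resid0, resid0, df_model = 1)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # p decreases as the model RSS shrinks at fixed df
  ps <- vapply(c(90, 70, 50, 30), function(rss1) {
    significance_vs_baseline(sqrt(rep(rss1 / n, n)), resid0, 1)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})
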