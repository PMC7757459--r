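test_that("one-component PLS coefficients align with X'y of autoscaled data", {
  lm_ <- random_label_matrix(12, 8, seed = 20)
  m <- fit_plsda(lm_$x, lm_$labels, n_components = 1)
  xs <- scale(lm_$x)
  y0 <- ifelse(lm_$labels == "responder", 1, -1)
  xty <- as.vector(crossprod(xs, y0 - mean(y0)))
  b_scaled <- m$coefficients * attr(xs, "scaled:scale")
  expect_gt(abs(cor(b_scaled, xty)), 1 - 1e-10)
  # proportionality, not just correlation
  ratio <- b_scaled / xty
  expect_lt(diff(range(ratio)), 1e-8 * abs(mean(ratio)))
})

test_that("a perfect predictor peptide reproduces class signs in training", {
  lm_ <- random_label_matrix(10, 5, seed = 21)
  x <- cbind(lm_$x, marker = ifelse(lm_$labels == "responder", 1, -1))
  m <- fit_plsda(x, lm_$labels, n_components = 2)
  idx <- predict_index(m, x)
  expect_identical(idx$predicted, lm_$labels)
})

test_that("duplicating every training sample leaves the model unchanged", {
  lm_ <- random_label_matrix(10, 6, seed = 22)
  m1 <- fit_plsda(lm_$x, lm_$labels, n_components = 2)
  dup <- lm_$x[rep(1:10, 2), ]
  rownames(dup) <- sprintf("S%02d", 1:20)
  m2 <- fit_plsda(dup, rep(lm_$labels, 2), n_components = 2)
  # the raw-scale linear map is duplication-invariant: scale factors from
  # the sd denominator cancel between autoscaling and coefficient fold-back
  expect_equal(m2$coefficients, m1$coefficients, tolerance = 1e-6)
  expect_equal(m2$offset, m1$offset, tolerance = 1e-6)
  p1 <- predict_index(m1, lm_$x)$prediction_index
  p2 <- predict_index(m2, lm_$x)$prediction_index
  expect_equal(p2, p1, tolerance = 1e-6)
})

test_that("prediction follows the strict >0 responder rule", {
  model <- structure(list(coefficients = setNames(rep(0, 3), c("a", "b", "c")),
                          offset = 0.3, n_components = 1,
                          center = rep(0, 3), scale = rep(1, 3)),
                     class = "pls_model")
  x <- matrix(0, 1, 3, dimnames = list("s", c("a", "b", "c")))
  expect_identical(predict_index(model, x)$predicted, "responder")
  model$offset <- -0.3
  expect_identical(predict_index(model, x)$predicted, "nonresponder")
  model$offset <- 0
  expect_identical(predict_index(model, x)$predicted, "nonresponder")
  expect_error(predict_index(model, matrix(0, 1, 2)), "expects")
})

test_that("full-component PLS1 reproduces least-squares predictions", {
  set.seed(23)
  n <- 12; p <- 5
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%d", 1:n), sprintf("P%d", 1:p)))
  labels <- rep(c("responder", "nonresponder"), 6)
  y <- ifelse(labels == "responder", 1, -1)
  m <- fit_plsda(x, labels, n_components = p)
  pls_pred <- predict_index(m, x)$prediction_index
  ols <- lm(y ~ x)
  expect_equal(pls_pred, unname(fitted(ols)), tolerance = 1e-6)
})

test_that("single-class training sets are rejected", {
  lm_ <- random_label_matrix(6, 4, seed = 24)
  expect_error(fit_plsda(lm_$x, rep("responder", 6)), "both classes")
})

test_that("LOO cross-validation separates a strong synthetic cohort", {
  cm <- cohort_matrix(synthetic_config(5, 5, effect_size = 0.84,
                                       noise_sd_log2 = 0.2, seed = 25))
  rep_ <- crossvalidate(cm$mat, cm$labels)
  expect_equal(rep_$ccr, 1.0)
  expect_equal(rep_$n_total, 10)
  expect_equal(rep_$ci_lower, 0.741134449107, tolerance = 1e-8)
  expect_equal(rep_$ci_upper, 1)
  expect_identical(rep_$cv_scheme, "loo")
})

test_that("CCR counts correct held-out predictions", {
  # one marker peptide separates the classes except for one contrarian
  # nonresponder placed firmly on the responder side
  x <- matrix(3, 8, 5,
              dimnames = list(sprintf("S%d", 1:8), sprintf("P%02d", 1:5)))
  labels <- rep(c("responder", "nonresponder"), each = 4)
  x[, 1] <- c(1, 1, 1, 1, -1, -1, -1, 1)  # S8 is the contrarian
  rep_ <- crossvalidate(x, labels, n_components = 1)
  expect_equal(rep_$ccr, rep_$n_correct / rep_$n_total)
  expect_equal(rep_$n_correct, 7)
  expect_equal(rep_$ccr, 0.875)
  expect_identical(rep_$per_sample$predicted[8], "responder")
})

test_that("a held-out sample's label cannot influence its own index", {
  lm_ <- random_label_matrix(10, 15, seed = 27)
  r1 <- crossvalidate(lm_$x, lm_$labels, n_components = 2)
  flipped <- lm_$labels
  flipped[4] <- setdiff(c("responder", "nonresponder"), flipped[4])
  r2 <- crossvalidate(lm_$x, flipped, n_components = 2)
  expect_equal(r2$per_sample$prediction_index[4],
               r1$per_sample$prediction_index[4], tolerance = 1e-12)
})

test_that("permuted labels keep the cross-validated CCR near chance", {
  cm <- cohort_matrix(synthetic_config(10, 10, seed = 1))
  set.seed(42)
  ccrs <- replicate(60, crossvalidate(cm$mat, sample(cm$labels),
                                      n_components = 2)$ccr)
  expect_gt(mean(ccrs), 0.35)
  expect_lt(mean(ccrs), 0.62)
})

test_that("exact binomial intervals reproduce the printed study bounds", {
  ci <- clopper_pearson(10, 10, 0.90)
  expect_equal(unname(round(100 * ci)), c(74, 100))
  expect_equal(ci[["lower"]], 0.741134449107, tolerance = 1e-10)
  ci2 <- clopper_pearson(27, 29, 0.90)
  expect_equal(unname(round(100 * ci2)), c(80, 99))
  ci0 <- clopper_pearson(0, 10, 0.90)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - clopper_pearson(10, 10, 0.90)[["lower"]],
               tolerance = 1e-10)
  expect_error(clopper_pearson(11, 10), "0 <= x <= n")
  expect_error(clopper_pearson(5, 10, level = 1.2), "level")
})

test_that("beta-quantile and root-finding interval routes agree", {
  for (n in c(1, 7, 29, 60)) {
    for (x in unique(c(0, 1, n %/% 2, n))) {
      a <- clopper_pearson(x, n, method = "beta")
      b <- clopper_pearson(x, n, method = "root")
      expect_equal(a, b, tolerance = 1e-10, info = sprintf("x=%d n=%d", x, n))
    }
  }
})

test_that("interval coverage at p = 0.7, n = 29 meets the nominal level", {
  cis <- vapply(0:29, function(x) clopper_pearson(x, 29, 0.90), numeric(2))
  set.seed(28)
  draws <- rbinom(5000, 29, 0.7)
  covered <- cis[1, draws + 1] <= 0.7 & 0.7 <= cis[2, draws + 1]
  expect_gte(mean(covered), 0.90)
})
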