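label_code <- function(labels) {
  if (!all(labels %in% c("responder", "nonresponder")))
    stop("labels must be 'responder' or 'nonresponder'")
  ifelse(labels == "responder", 1, -1)
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' Responders are coded +1, non-responders -1. Predictors are autoscaled
#' (zero mean, unit SD) with statistics of the supplied training data only;
#' zero-variance peptides get scale 1 so they contribute a centered-but-flat
#' term. NIPALS extracts `n_components` latent components on the scaled
#' data; the regression vector is folded back to the original peptide scale
#' so the model is exactly a set of per-peptide coefficients plus an offset,
#' and `prediction index = sum(coef * x) + offset`.
#'
#' @param x training samples x peptides matrix.
#' @param labels training labels (both classes required).
#' @param n_components number of latent components
#'   (`<= min(n_train - 1, n_peptides)`).
#' @return `pls_model` list with `coefficients`, `offset`, `n_components`,
#'   and the training scaling (`center`, `scale`).
#' @export
fit_plsda <- function(x, labels, n_components = 2) {
  x <- unclass(x)
  y <- label_code(labels)
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")
  if (nrow(x) != length(y)) stop("x and labels differ in length")
  kmax <- min(nrow(x) - 1, ncol(x))
  if (n_components < 1 || n_components > kmax)
    stop("n_components must be in 1..", kmax)
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  flat <- sdev == 0
  sdev[flat] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  y0 <- y - mean(y)

  p <- ncol(x)
  w_mat <- matrix(0, p, n_components)
  p_mat <- matrix(0, p, n_components)
  q_vec <- numeric(n_components)
  e <- xs
  f <- y0
  for (a in seq_len(n_components)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # residual orthogonal to response: stop early
      w_mat <- w_mat[, seq_len(a - 1), drop = FALSE]
      p_mat <- p_mat[, seq_len(a - 1), drop = FALSE]
      q_vec <- q_vec[seq_len(a - 1)]
      n_components <- a - 1
      break
    }
    w <- w / nw
    t_sc <- as.vector(e %*% w)
    tt <- sum(t_sc^2)
    p_load <- crossprod(e, t_sc) / tt
    q_load <- sum(f * t_sc) / tt
    e <- e - tcrossprod(t_sc, p_load)
    f <- f - q_load * t_sc
    w_mat[, a] <- w
    p_mat[, a] <- p_load
    q_vec[a] <- q_load
  }
  if (n_components == 0) {
    b_scaled <- rep(0, p)
  } else {
    b_scaled <- as.vector(w_mat %*% solve(crossprod(p_mat, w_mat), q_vec))
  }
  coef <- b_scaled / sdev
  offset <- mean(y) - sum(coef * mu)
  structure(list(coefficients = setNames(coef, colnames(x)),
                 offset = offset, n_components = n_components,
                 center = mu, scale = sdev, flat_peptides = names(which(flat))),
            class = "pls_model")
}

#' Prediction index and label for new profiles
#'
#' Index = sum of coefficients times peptide values plus the offset; a
#' strictly positive index predicts a responder (an index of exactly 0
#' predicts non-responder, the documented tie rule).
#'
#' @param model `pls_model` from [fit_plsda()].
#' @param x numeric vector (one profile) or samples x peptides matrix.
#' @return `data.frame` with `prediction_index` and `predicted`.
#' @export
predict_index <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- unclass(x)
  if (ncol(x) != length(model$coefficients))
    stop("profile has ", ncol(x), " peptides; model expects ",
         length(model$coefficients))
  idx <- as.vector(x %*% model$coefficients) + model$offset
  data.frame(prediction_index = idx,
             predicted = ifelse(idx > 0, "responder", "nonresponder"),
             stringsAsFactors = FALSE)
}

select_components <- function(x, labels, candidates) {
  # inner leave-one-out over the training partition; ties -> fewest
  n <- nrow(x)
  kmax <- min(n - 2, ncol(x))  # inner folds have n - 1 samples
  candidates <- candidates[candidates <= kmax]
  if (!length(candidates)) return(1L)
  acc <- vapply(candidates, function(a) {
    correct <- 0L
    for (i in seq_len(n)) {
      tr_lab <- labels[-i]
      if (length(unique(tr_lab)) < 2) next
      m <- fit_plsda(x[-i, , drop = FALSE], tr_lab, n_components = a)
      pred <- predict_index(m, x[i, ])$predicted
      correct <- correct + (pred == labels[i])
    }
    correct / n
  }, numeric(1))
  candidates[which.max(acc)]  # which.max takes the first (fewest) on ties
}

#' Cross-validated PLS-DA classification report
#'
#' For each outer fold the model (including the autoscaling statistics) is
#' fit on the training partition only, and prediction indices are computed
#' for the held-out samples. The correct classification rate (CCR) is the
#' fraction of cross-validated predictions matching the clinical label, with
#' an exact Clopper-Pearson binomial confidence interval.
#'
#' @param mat `activity_matrix` (samples x peptides).
#' @param labels sample labels (`responder`/`nonresponder`).
#' @param scheme `"loo"` (default, seed-free) or `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param n_components fixed component count, or `NULL` (default) to select
#'   from `component_candidates` by inner leave-one-out on each training
#'   partition (ties resolved toward fewer components).
#' @param component_candidates candidate component counts for the inner
#'   selection (default `1:3`).
#' @param ci_level confidence level of the exact interval (default 0.90).
#' @param seed integer seed for the k-fold assignment (ignored for LOO).
#' @return `classification_report` list: per-sample `data.frame`
#'   (`sample_id`, `prediction_index`, `predicted`, `actual`, `fold`,
#'   `n_components`), `ccr`, `n_correct`, `n_total`, `ci_level`,
#'   `ci_lower`, `ci_upper`, `cv_scheme`.
#' @export
crossvalidate <- function(mat, labels, scheme = c("loo", "kfold"), k = 5,
                          n_components = NULL, component_candidates = 1:3,
                          ci_level = 0.90, seed = 1L) {
  scheme <- match.arg(scheme)
  v <- unclass(mat)
  n <- nrow(v)
  if (length(labels) != n) stop("labels must match the number of samples")
  if (sum(labels == "responder") < 2 || sum(labels == "nonresponder") < 2)
    stop("cross-validation needs at least 2 samples per class")
  folds <- if (scheme == "loo") seq_len(n) else {
    set.seed(seed)
    f <- sample(rep_len(seq_len(k), n))
    f
  }
  per_sample <- data.frame(sample_id = rownames(v),
                           prediction_index = NA_real_,
                           predicted = NA_character_,
                           actual = labels, fold = folds,
                           n_components = NA_integer_,
                           stringsAsFactors = FALSE)
  for (fold in sort(unique(folds))) {
    test_i <- which(folds == fold)
    train_i <- setdiff(seq_len(n), test_i)
    tr_lab <- labels[train_i]
    if (length(unique(tr_lab)) < 2)
      stop("fold ", fold, " leaves a single-class training partition; ",
           "use scheme = 'loo'")
    a <- if (is.null(n_components))
      select_components(v[train_i, , drop = FALSE], tr_lab,
                        component_candidates)
    else n_components
    model <- fit_plsda(v[train_i, , drop = FALSE], tr_lab, n_components = a)
    pred <- predict_index(model, v[test_i, , drop = FALSE])
    per_sample$prediction_index[test_i] <- pred$prediction_index
    per_sample$predicted[test_i] <- pred$predicted
    per_sample$n_components[test_i] <- model$n_components
  }
  n_correct <- sum(per_sample$predicted == per_sample$actual)
  ci <- clopper_pearson(n_correct, n, level = ci_level)
  structure(list(per_sample = per_sample,
                 ccr = n_correct / n, n_correct = n_correct, n_total = n,
                 ci_level = ci_level, ci_lower = ci[["lower"]],
                 ci_upper = ci[["upper"]],
                 cv_scheme = if (scheme == "loo") "loo" else sprintf("%d-fold", k)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("PLS-DA %s cross-validation: CCR %.0f%% (%d/%d), %.0f%% CI %.0f%%-%.0f%%\n",
              x$cv_scheme, 100 * x$ccr, x$n_correct, x$n_total,
              100 * x$ci_level, 100 * x$ci_lower, 100 * x$ci_upper))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, by the beta-quantile
#' identity (`method = "beta"`, default) or by direct root-finding on the
#' binomial tail probabilities (`method = "root"`); the two routes agree to
#' 1e-10. The lower bound solves `P(X >= x | p) = (1 - level) / 2` (0 when
#' `x = 0`); the upper solves `P(X <= x | p) = (1 - level) / 2` (1 when
#' `x = n`).
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.90).
#' @param method `"beta"` or `"root"`.
#' @return named numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, level = 0.90, method = c("beta", "root")) {
  method <- match.arg(method)
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integers 0 <= x <= n with n >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- (1 - level) / 2
  if (method == "beta") {
    lower <- if (x == 0) 0 else qbeta(alpha, x, n - x + 1)
    upper <- if (x == n) 1 else qbeta(1 - alpha, x + 1, n - x)
  } else {
    lower <- if (x == 0) 0 else
      uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - alpha,
              c(1e-15, 1 - 1e-15), tol = 1e-14)$root
    upper <- if (x == n) 1 else
      uniroot(function(p) pbinom(x, n, p) - alpha,
              c(1e-15, 1 - 1e-15), tol = 1e-14)$root
  }
  c(lower = lower, upper = upper)
}
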