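# exact homogeneous batch-effect construction: per-peptide residual vectors
# share one multiset, so the EB estimates collapse to direct standardization
homogeneous_batches <- function(n_per = 10, p = 50, offset = 2, seed = 3) {
  set.seed(seed)
  e <- scale(rnorm(n_per), scale = FALSE)[, 1]
  b1 <- vapply(1:p, function(g) 5 + g * 0.1 + sample(e), numeric(n_per))
  x <- rbind(b1, b1 + offset)
  dimnames(x) <- list(sprintf("S%02d", 1:(2 * n_per)), sprintf("P%03d", 1:p))
  list(x = activity_matrix(x, "log2"),
       batch = rep(c("A", "B"), each = n_per))
}

test_that("PCA scores satisfy rank, reconstruction and symmetry contracts", {
  u <- matrix(rnorm(6), 6, 1)
  v <- matrix(rnorm(5), 1, 5)
  rank1 <- u %*% v
  dimnames(rank1) <- list(sprintf("S%d", 1:6), sprintf("P%d", 1:5))
  res <- pca_scores(rank1, k = 1)
  expect_equal(res$explained[1], 1.0, tolerance = 1e-10)

  lm_ <- random_label_matrix(6, 5, seed = 8)
  full <- pca_scores(lm_$x, k = 5)
  centered <- scale(lm_$x, scale = FALSE)
  expect_equal(full$scores %*% t(full$loadings), centered,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(full$explained) <= 1e-12))

  dup <- lm_$x[c(1, 1, 2:6), ]
  rownames(dup) <- sprintf("S%d", 1:7)
  sc <- pca_scores(dup, k = 2)$scores
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-10)
  expect_error(pca_scores(lm_$x, k = 6), "between 1 and")
})

test_that("outlier flagging catches generator-attenuated samples", {
  cfg <- synthetic_config(6, 6, effect_size = 0, seed = 12,
                          n_outlier_samples = 1)
  cm <- cohort_matrix(cfg)
  fl <- flag_outlier_samples(cm$mat)
  expect_identical(fl$flagged, cm$truth$sample_id[cm$truth$is_outlier])
  expect_match(fl$reasons, "low overall activity")
})

test_that("homogeneous cohorts yield no flags, invariantly to row order", {
  cm <- cohort_matrix(synthetic_config(5, 5, effect_size = 0, seed = 33))
  fl <- flag_outlier_samples(cm$mat)
  expect_length(fl$flagged, 0)
  v <- unclass(cm$mat)
  perm <- v[rev(seq_len(nrow(v))), ]
  expect_setequal(flag_outlier_samples(activity_matrix(perm, "log2"))$flagged,
                  fl$flagged)
})

test_that("flagging never exceeds a quarter of null-cohort samples", {
  fracs <- vapply(1:10, function(s) {
    cm <- cohort_matrix(synthetic_config(5, 5, effect_size = 0,
                                         seed = 300 + s))
    length(flag_outlier_samples(cm$mat)$flagged) / nrow(cm$mat)
  }, numeric(1))
  expect_true(all(fracs <= 0.25))
})

test_that("single-batch correction is the identity", {
  lm_ <- random_label_matrix(6, 10, seed = 9)
  mat <- activity_matrix(lm_$x, "log2")
  out <- combat_correct(mat, rep("B1", 6))
  expect_equal(unclass(out), unclass(mat), tolerance = 1e-15,
               ignore_attr = TRUE)
})

test_that("pure per-batch offsets are removed exactly in the homogeneous limit", {
  hb <- homogeneous_batches()
  pre <- colMeans(unclass(hb$x)[hb$batch == "B", ]) -
    colMeans(unclass(hb$x)[hb$batch == "A", ])
  out <- combat_correct(hb$x, hb$batch)
  post <- colMeans(unclass(out)[hb$batch == "B", ]) -
    colMeans(unclass(out)[hb$batch == "A", ])
  expect_lt(max(abs(post)), 1e-6 * max(abs(pre)))
  # grand means preserved by the de-standardization
  expect_lt(max(abs(colMeans(unclass(out)) - colMeans(unclass(hb$x)))), 1e-8)
})

test_that("batch correction is idempotent in the homogeneous limit", {
  hb <- homogeneous_batches(seed = 5)
  once <- combat_correct(hb$x, hb$batch)
  twice <- combat_correct(once, hb$batch)
  expect_lt(max(abs(unclass(twice) - unclass(once))), 1e-6)
})

test_that("correction reduces the batch-separation ratio at least tenfold", {
  cfg <- synthetic_config(8, 8, effect_size = 0, seed = 44,
                          batch_assignment = c("B1", "B2"),
                          batch_offsets = c(B1 = 0, B2 = 1.2))
  cm <- cohort_matrix(cfg)
  sep <- function(m, b) {
    mean(vapply(seq_len(ncol(m)), function(j) {
      bm <- tapply(m[, j], b, mean)
      wv <- mean(tapply(m[, j], b, var))
      var(bm) / wv
    }, numeric(1)))
  }
  b <- cm$truth$batch
  before <- sep(unclass(cm$mat), b)
  after <- sep(unclass(combat_correct(cm$mat, b)), b)
  expect_gt(before / after, 10)
})

test_that("empirical-Bayes correction tracks the reference implementation", {
  set.seed(10)
  y <- matrix(rnorm(40 * 60, 6, 1), 40, 60,
              dimnames = list(sprintf("S%02d", 1:40), sprintf("P%03d", 1:60)))
  b <- rep(c("A", "B"), each = 20)
  y[b == "B", ] <- y[b == "B", ] + 1.2
  mine <- unclass(combat_correct(activity_matrix(y, "log2"), b))
  ref <- t(suppressMessages(sva::ComBat(t(y), batch = b)))
  # conventions differ in variance denominators; agreement is approximate
  expect_lt(max(abs(mine - ref)), 0.1)
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.999)
})

test_that("undersized batches are rejected", {
  lm_ <- random_label_matrix(5, 8, seed = 11)
  mat <- activity_matrix(lm_$x, "log2")
  expect_error(combat_correct(mat, c("A", "A", "A", "A", "B")),
               "fewer than 2 samples")
})
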