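test_that("background subtraction is exact, linear, and preserves negatives", {
  expect_equal(subtract_background(c(10, 20, 30), c(5, 5, 5)), c(5, 15, 25))
  expect_equal(subtract_background(c(1, 1), c(1, 1)), c(0, 0))
  expect_equal(subtract_background(c(1, 1), c(2, 3)), c(-1, -2))
  expect_error(subtract_background(1:3, 1:2), "length")
})

test_that("trend detection resolves monotone, constant and decreasing series", {
  up <- detect_positive_trend(1:60)
  expect_true(up$trend_positive)
  expect_equal(up$trend_p, 0)
  flat <- detect_positive_trend(rep(3, 10))
  expect_false(flat$trend_positive)
  down <- detect_positive_trend(60:1)
  expect_false(down$trend_positive)
  expect_equal(down$trend_p, 1)
  expect_error(detect_positive_trend(c(1, 2)), "at least 3")
})

test_that("trend test type-I error matches its level on pure noise", {
  set.seed(42)
  hits <- vapply(1:1000, function(i)
    detect_positive_trend(rnorm(30))$trend_positive, logical(1))
  # binomial(1000, 0.05): 3 sd band is about +/- 0.021
  expect_gt(mean(hits), 0.028)
  expect_lt(mean(hits), 0.072)
})

test_that("spot signal statistics reduce kinetic curves as documented", {
  tc <- data.frame(sample_id = "s", peptide_id = "p", replicate_id = 1,
                   cycle = 1:60, foreground = (1:60) + 7, background = 7)
  end <- quantify_spots(tc, statistic = "end_level")
  expect_equal(end$signal, 53)          # median of corrected cycles 46..60
  sl <- quantify_spots(tc, statistic = "slope")
  expect_equal(sl$signal, 60)           # unit slope times 60 cycles
  const <- transform(tc, foreground = 12, background = 7)
  expect_equal(quantify_spots(const)$signal, 5)
  expect_false(quantify_spots(const)$trend_positive)
})

test_that("replicate QC drops aberrant replicates and keeps consistent ones", {
  set.seed(1)
  base <- rnorm(30, 100, 20)
  good <- rbind(r1 = base, r2 = base + rnorm(30, 0, 2),
                r3 = base + rnorm(30, 0, 2))
  res <- qc_replicates(good)
  expect_setequal(res$retained, c("r1", "r2", "r3"))
  withzero <- rbind(good, r4 = rep(0, 30))
  res2 <- qc_replicates(withzero)
  expect_identical(res2$dropped, "r4")
  two <- good[1:2, ]
  expect_setequal(qc_replicates(two)$retained, c("r1", "r2"))
})

test_that("replicate QC is invariant to replicate order and never empties", {
  set.seed(2)
  base <- rnorm(25, 100, 20)
  reps <- rbind(r1 = base + rnorm(25, 0, 2), r2 = base + rnorm(25, 0, 2),
                r3 = -base)  # anti-correlated replicate
  res <- qc_replicates(reps)
  perm <- qc_replicates(reps[c(3, 1, 2), ])
  expect_setequal(res$retained, perm$retained)
  # all mutually inconsistent: fallback keeps exactly one, flagged
  bad <- rbind(r1 = rnorm(25), r2 = rnorm(25), r3 = rnorm(25)) * 1000
  res3 <- qc_replicates(bad, min_cor = 0.999)
  expect_length(res3$retained, 1)
  expect_true(res3$flagged)
})

test_that("replicate averaging takes means and majority trend votes", {
  sig <- data.frame(sample_id = "s", peptide_id = "p",
                    replicate_id = 1:2, signal = c(2, 4),
                    trend_positive = c(TRUE, FALSE), trend_p = 0.5)
  avg <- average_replicates(sig)
  expect_equal(unname(avg$values["s", "p"]), 3)
  expect_true(avg$trend_detected["s", "p"])  # tie counts as detected
  one <- sig[1, ]
  expect_equal(unname(average_replicates(one)$values["s", "p"]), 2)
  three <- data.frame(sample_id = "s", peptide_id = "p", replicate_id = 1:3,
                      signal = 1, trend_positive = c(TRUE, FALSE, TRUE),
                      trend_p = 0.5)
  expect_true(average_replicates(three)$trend_detected["s", "p"])
})

test_that("cohort-level replicate QC removes an injected dead replicate", {
  co <- generate_cohort(small_config(2, 2, seed = 21))
  sig <- quantify_spots(co$timecourses)
  kill <- sig$sample_id == "S01" & sig$replicate_id == 2
  sig$signal[kill] <- 0
  res <- apply_replicate_qc(sig)
  expect_false(any(res$signals$sample_id == "S01" &
                     res$signals$replicate_id == 2))
  expect_match(res$log, "S01.*dropped replicate 2", all = FALSE)
})
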