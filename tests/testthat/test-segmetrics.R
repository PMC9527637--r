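test_that("confusion counts and ratio metrics match closed forms", {
  tr <- label_volume(array(c(rep(1L, 3), rep(0L, 13)), c(1, 4, 4)))
  ## prediction with TP = 2, FP = 1, FN = 1, TN = 12
  pr_arr <- array(0L, c(1, 4, 4))
  pr_arr[1, 1, 1] <- 1L  # TP
  pr_arr[1, 2, 1] <- 1L  # TP
  pr_arr[1, 1, 2] <- 1L  # FP (truth is 0 there)
  tr_arr <- array(0L, c(1, 4, 4))
  tr_arr[1, 1:3, 1] <- 1L
  cc <- confusion_counts(pr_arr, tr_arr, 1L)
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(2L, 1L, 1L, 12L))
  m <- basic_metrics(cc)
  expect_equal(unname(m["ppv"]), 2 / 3)
  expect_equal(unname(m["npv"]), 12 / 13)
  expect_equal(unname(m["accuracy"]), 14 / 16)
  expect_equal(unname(m["specificity"]), 12 / 13)
  expect_equal(unname(m["recall"]), 2 / 3)
  expect_equal(unname(m["jaccard"]), 2 / 4)
  ## perfect prediction scores 1 on all six metrics
  perf <- basic_metrics(confusion_counts(tr, tr, 1L))
  expect_equal(unname(perf), rep(1, 6))
  ## all-background prediction: no true positives, perfect specificity
  bg <- confusion_counts(array(0L, c(1, 4, 4)), tr_arr, 1L)
  expect_identical(bg$tp, 0L)
  expect_equal(suppressWarnings(basic_metrics(bg)[["specificity"]]), 1)
  ## zero-denominator metrics surface as NaN with a warning, never as 0
  empty <- confusion_counts(array(0L, c(1, 2, 2)), array(0L, c(1, 2, 2)), 1L)
  w <- testthat::capture_warnings(m0 <- basic_metrics(empty))
  expect_true(any(grepl("PPV undefined", w)))
  expect_true(is.nan(m0[["ppv"]]))
  expect_error(confusion_counts(array(0L, c(1, 2, 2)), tr, 1L), "shape")
})

test_that("thinned V-scores are exact on perfect predictions and toy merges", {
  ## truth: two touching segments on a 6x6 grid; prediction merges them
  tr <- matrix(0L, 6, 6)
  tr[2:5, 2:3] <- 1L
  tr[2:5, 4:5] <- 2L
  pr <- matrix(0L, 6, 6)
  pr[2:5, 2:5] <- 1L
  expect_equal(v_rand_thinned(tr, tr, 0), 1)
  expect_equal(v_info_thinned(tr, tr, 0), 1)
  ## radius-1 thinning keeps the interiors of thick segments
  big <- matrix(0L, 10, 10)
  big[2:9, 2:5] <- 1L
  big[2:9, 6:9] <- 2L
  expect_true(any(cardioEM:::thinned_eval_mask(big, 1)))
  expect_equal(v_rand_thinned(big, big, 1), 1)
  expect_equal(v_info_thinned(big, big, 1), 1)
  mask <- cardioEM:::thinned_eval_mask(tr, 0)
  expect_equal(v_rand_thinned(pr, tr, 0), rand_fscore_oracle(pr, tr, mask))
  expect_equal(v_info_thinned(pr, tr, 0), info_fscore_oracle(pr, tr, mask))
  ## a radius that swallows the whole image leaves nothing to evaluate
  expect_warning(vr <- v_rand_thinned(pr, tr, 10), "undefined")
  expect_true(is.nan(vr))
})

test_that("V-scores equal their oracles on random small grids", {
  set.seed(14)
  for (rep in 1:8) {
    tr <- matrix(sample(0:2, 64, TRUE, prob = c(0.3, 0.4, 0.3)), 8, 8)
    pr <- matrix(sample(0:2, 64, TRUE), 8, 8)
    for (radius in 0:1) {
      mask <- cardioEM:::thinned_eval_mask(tr, radius)
      if (!any(mask)) next
      expect_equal(v_rand_thinned(pr, tr, radius),
                   rand_fscore_oracle(pr, tr, mask), tolerance = 1e-12)
      expect_equal(v_info_thinned(pr, tr, radius),
                   info_fscore_oracle(pr, tr, mask), tolerance = 1e-12)
      expect_gte(v_rand_thinned(pr, tr, radius), 0)
      expect_lte(v_rand_thinned(pr, tr, radius), 1)
    }
  }
})

test_that("V-scores are invariant to permuting segment ids", {
  set.seed(5)
  tr <- matrix(sample(0:3, 100, TRUE), 10, 10)
  pr <- matrix(sample(0:3, 100, TRUE), 10, 10)
  ## permute prediction ids 1..3 -> 3,1,2 (0 stays foreground-irrelevant)
  prm <- pr
  prm[pr == 1L] <- 3L
  prm[pr == 2L] <- 1L
  prm[pr == 3L] <- 2L
  expect_equal(v_rand_thinned(prm, tr, 0), v_rand_thinned(pr, tr, 0))
  expect_equal(v_info_thinned(prm, tr, 0), v_info_thinned(pr, tr, 0))
})

test_that("the full report covers every class and both V-scores", {
  ph <- generate_phantom(training_phantom_config(31, c(6L, 96L, 96L), mito_count = 0L))
  noisy <- degrade_labels(ph$labels, 0.05, seed = 1)
  rep <- suppressWarnings(segmentation_report(noisy, ph$labels))
  expect_identical(rep$class, 0:3)
  num <- rep[, c("accuracy", "specificity", "ppv", "npv", "recall", "jaccard")]
  expect_true(all(is.nan(as.matrix(num)) | (num >= 0 & num <= 1)))
  expect_true(all(rep$v_rand_thinned >= 0 & rep$v_rand_thinned <= 1))
})
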