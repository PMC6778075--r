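# Label-noise planting, per-class entropy thresholds, candidate
# identification and the planted-noise evaluation.

test_that("label planting flips exactly the requested fraction, never in place", {
  ds <- dummy_dataset(4, 25)
  res0 <- plant_label_noise(ds, 0, seed = 1)
  expect_identical(patch_labels(res0$dataset), patch_labels(ds))
  expect_length(res0$planted, 0L)

  res <- plant_label_noise(ds, 10, seed = 2)
  expect_length(res$planted, 10L)
  old <- patch_labels(ds)
  new <- patch_labels(res$dataset)
  changed <- patch_ids(ds)[old != new]
  expect_setequal(changed, res$planted)
  expect_true(all(new[old != new] != old[old != new]))
  expect_true(all(new %in% 1:4))
  expect_error(plant_label_noise(ds, 101, seed = 1), "percentage")
  # reproducible
  res2 <- plant_label_noise(ds, 10, seed = 2)
  expect_identical(res2$planted, res$planted)
})

test_that("relabels spread uniformly over the other classes", {
  ds <- dummy_dataset(8, 125)  # N = 1000
  received <- matrix(0, 3, 8)
  for (s in 1:3) {
    res <- plant_label_noise(ds, 50, seed = 100 + s)
    old <- patch_labels(ds)
    new <- patch_labels(res$dataset)
    received[s, ] <- tabulate(new[old != new], nbins = 8)
  }
  # 500 flips spread over receiving classes: roughly 500/7 each originates
  # from every donor class; per-class received counts stay near 500/8 * 8/7
  expect_true(all(abs(colMeans(received) - 500 / 7) < 25))
})

test_that("per-class thresholds equal the interpolated percentile oracle", {
  vals <- seq(0.1, 1.0, by = 0.1)
  recs <- data.frame(id = sprintf("r%02d", 1:10), true_label = 1L,
                     predicted = 1L, H = vals, stringsAsFactors = FALSE)
  expect_equal(per_class_thresholds(recs, 0)[["1"]], 0.1, tolerance = 1e-12)
  expect_equal(per_class_thresholds(recs, 100)[["1"]], 1.0, tolerance = 1e-12)
  expect_equal(per_class_thresholds(recs, 25)[["1"]], 0.325,
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    h <- runif(sample(2:30, 1))
    p <- runif(1, 0, 100)
    r <- data.frame(id = as.character(seq_along(h)), true_label = 1L,
                    predicted = 1L, H = h)
    expect_lt(abs(per_class_thresholds(r, p)[["1"]] - bf_percentile(h, p)),
              1e-12)
  }
})

test_that("candidates are confidently misclassified records, unioned by class", {
  recs <- data.frame(
    id = c("a", "b", "c", "d", "e", "f"),
    true_label = c(1L, 1L, 1L, 2L, 2L, 2L),
    predicted = c(2L, 1L, 1L, 2L, 1L, 2L),
    H = c(0.05, 0.5, 0.9, 0.2, 0.1, 0.8), stringsAsFactors = FALSE)
  # class 1 H values (0.05, 0.5, 0.9), p_m = 50 -> threshold 0.5; only the
  # misclassified 0.05 record falls below it
  rep50 <- identify_mislabelled(recs, 50)
  expect_identical(rep50$candidates, c("a", "e"))
  expect_equal(rep50$thresholds[["1"]], 0.5, tolerance = 1e-12)

  none <- recs
  none$predicted <- none$true_label
  expect_length(identify_mislabelled(none, 100)$candidates, 0L)

  # p_m = 100: every misclassified record below the class maximum
  rep100 <- identify_mislabelled(recs, 100)
  expect_setequal(rep100$candidates, c("a", "e"))
})

test_that("candidate sets nest as p_m grows and stay within misclassifications", {
  set.seed(8)
  recs <- data.frame(id = sprintf("r%03d", 1:120),
                     true_label = rep(1:4, each = 30),
                     predicted = sample(1:4, 120, replace = TRUE),
                     H = runif(120, 0, log(4)), stringsAsFactors = FALSE)
  mis <- recs$id[recs$predicted != recs$true_label]
  prev <- character(0)
  for (pm in c(0, 5, 20, 40, 60, 80, 100)) {
    cand <- identify_mislabelled(recs, pm)$candidates
    expect_true(all(prev %in% cand))
    expect_true(all(cand %in% mis))
    prev <- cand
  }
  thr <- vapply(c(10, 40, 70), function(pm) {
    per_class_thresholds(recs, pm)[["2"]]
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("identification scoring follows the positives-based convention", {
  all_ids <- sprintf("i%03d", 1:100)
  planted <- all_ids[1:10]
  cand <- c(all_ids[1:8], all_ids[11:12])  # 8 planted + 2 clean
  ev <- evaluate_identification(cand, planted, all_ids)
  expect_equal(ev$sensitivity, 0.8)
  expect_equal(ev$specificity, 88 / 90)
  expect_equal(ev$recall, 0.8)

  perfect <- evaluate_identification(planted, planted, all_ids)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  disjoint <- evaluate_identification(all_ids[11:15], planted, all_ids)
  expect_equal(disjoint$sensitivity, 0)
  expect_warning(ev0 <- evaluate_identification(character(0), planted,
                                                all_ids), "undefined")
  expect_true(is.na(ev0$sensitivity))
})

test_that("planted noise is recovered and accuracy degrades gracefully", {
  bench <- get_mislabel_bench()
  sens10 <- mean(bench$sensitivity[bench$p_m == 10])
  expect_gte(sens10, 0.7)
  acc <- tapply(bench$test_accuracy, bench$p_m, mean)
  expect_true(all(diff(acc) <= 1e-12))
  # early noise hurts less than heavy noise
  expect_lte(acc[["0"]] - acc[["10"]], acc[["30"]] - acc[["50"]] + 1e-12)
})
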