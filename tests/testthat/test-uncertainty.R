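# Predictive posterior, entropy H, BALD and dataset scoring.

test_that("posteriors validate their sample rows and expose the row mean", {
  s <- rbind(c(0.7, 0.3), c(0.5, 0.5))
  post <- predictive_posterior(s)
  expect_equal(post$mean, c(0.6, 0.4))
  expect_identical(post$T, 2L)
  expect_error(predictive_posterior(rbind(c(0.7, 0.7))), "summing to 1")
  expect_error(predictive_posterior(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("entropy and BALD reproduce their closed-form identities", {
  expect_equal(entropy_H(rep(1 / 8, 8)), log(8), tolerance = 1e-10)
  expect_equal(entropy_H(c(1, 0, 0)), 0, tolerance = 1e-10)
  expect_equal(entropy_H(c(0.5, 0.5)), log(2), tolerance = 1e-10)

  # identical rows: mutual information vanishes
  same <- predictive_posterior(matrix(rep(c(0.3, 0.7), 5), 5, 2, byrow = TRUE))
  expect_equal(bald(same), 0, tolerance = 1e-10)
  # two opposing one-hot rows: pure epistemic disagreement
  opp <- predictive_posterior(rbind(c(1, 0), c(0, 1)))
  expect_equal(bald(opp), log(2), tolerance = 1e-10)
  expect_equal(entropy_H(opp), log(2), tolerance = 1e-10)
  # flat but identical rows: aleatoric only - H large, BALD zero
  flat <- predictive_posterior(rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(bald(flat), 0, tolerance = 1e-10)
  expect_equal(entropy_H(flat), log(2), tolerance = 1e-10)
})

test_that("entropy and BALD match brute-force oracles on random posteriors", {
  set.seed(77)
  for (i in 1:200) {
    T <- sample(1:200, 1)
    M <- sample(2:16, 1)
    post <- predictive_posterior(random_posterior(T, M))
    expect_lt(abs(entropy_H(post) - bf_entropy(post$mean)), 1e-10)
    expect_lt(abs(bald(post) - max(bf_bald(post$samples), 0)), 1e-10)
    expect_gte(bald(post), 0)
    expect_lte(bald(post), entropy_H(post) + 1e-12)
    expect_lte(entropy_H(post), log(M) + 1e-12)
  }
})

test_that("classification takes the argmax with lowest-index tie-break", {
  expect_identical(classify(predictive_posterior(rbind(c(0.1, 0.7, 0.2)))), 2L)
  expect_identical(classify(predictive_posterior(rbind(c(0, 1, 0)))), 2L)
  expect_identical(classify(predictive_posterior(rbind(c(0.5, 0.5)))), 1L)
})

test_that("mc_predict averages T seeded passes", {
  fit <- get_toy_fit()
  patch <- fit$test$patches[[1]]
  p1 <- mc_predict(fit$model, patch, T = 1, seed = 3)
  expect_identical(p1$T, 1L)
  expect_equal(p1$mean, drop(p1$samples))
  p <- mc_predict(fit$model, patch, T = 10, seed = 3)
  expect_equal(sum(p$mean), 1, tolerance = 1e-6)
  q <- mc_predict(fit$model, patch, T = 10, seed = 3)
  expect_identical(p$samples, q$samples)
  r <- mc_predict(fit$model, patch, T = 10, seed = 4)
  expect_false(identical(p$samples, r$samples))
  expect_error(mc_predict(fit$model, patch, T = 0), "T")
})

test_that("score_dataset returns ordered, reproducible, bounded records", {
  fit <- get_toy_fit()
  sub <- dataset_subset(fit$test, patch_ids(fit$test)[1:40])
  recs <- score_dataset(fit$model, sub, T = 12, seed = 5, eval_batch = 16)
  expect_identical(recs$id, patch_ids(sub))
  expect_true(all(recs$BALD >= 0))
  expect_true(all(recs$BALD <= recs$H + 1e-12))
  expect_true(all(recs$H <= log(4) + 1e-12))
  expect_equal(recs$H_normalized, recs$H / log(4))
  expect_true(all(recs$predicted %in% 1:4))
  # deterministic under the seed, including across batch boundaries
  recs2 <- score_dataset(fit$model, sub, T = 12, seed = 5, eval_batch = 7)
  expect_equal(recs, recs2, tolerance = 1e-12)
  # identical tiles receive identical records (one weight sample per pass)
  twin <- patch_dataset(list(
    image_patch(sub$patches[[1]]$pixels, "a", 1L),
    image_patch(sub$patches[[1]]$pixels, "b", 1L)), fit$test$catalog)
  tr <- score_dataset(fit$model, twin, T = 8, seed = 6)
  expect_equal(tr$H[1], tr$H[2], tolerance = 1e-12)
  expect_identical(tr$predicted[1], tr$predicted[2])

  empty <- patch_dataset(list(), fit$test$catalog)
  expect_identical(nrow(score_dataset(fit$model, empty, T = 2)), 0L)
})

test_that("records survive a CSV round trip", {
  fit <- get_toy_fit()
  sub <- dataset_subset(fit$test, patch_ids(fit$test)[1:10])
  recs <- score_dataset(fit$model, sub, T = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_uncertainty_records(recs, path)
  back <- read_uncertainty_records(path)
  expect_equal(back$H, recs$H, tolerance = 1e-12)
  expect_identical(back$id, recs$id)
})

test_that("confusable classes carry higher mean entropy than easy ones", {
  fit <- get_confusable_fit()
  recs <- score_dataset(fit$model, fit$test, T = 25, seed = 9)
  h_confusable <- mean(recs$H[recs$true_label %in% c(1, 2)])
  h_easy <- mean(recs$H[recs$true_label %in% c(3, 4)])
  expect_gt(h_confusable, h_easy)
})
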