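# FAR/FRR/accuracy counting, the EER sweep against a dense brute-force
# oracle, and the cross-validation bookkeeping.

test_that("rates at a threshold match hand counting", {
  scores <- c(0.9, 0.8, 0.1, 0.2)
  labels <- c("genuine", "genuine", "impostor", "impostor")
  r <- rates_at(scores, labels, 0.5)
  expect_equal(unname(r), c(0, 0, 100))
  # degenerate threshold: every impostor accepted
  r0 <- rates_at(scores, labels, 0)
  expect_equal(r0[["far"]], 100)
  expect_equal(r0[["frr"]], 0)
  expect_error(rates_at(c(0.1), c("genuine"), 0.5), "both")
})

test_that("rates agree with an exhaustive per-item count on random sets", {
  set.seed(81)
  for (rep in 1:5) {
    scores <- runif(40)
    labels <- sample(c("genuine", "impostor"), 40, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    tau <- runif(1)
    r <- rates_at(scores, labels, tau)
    far_o <- 0; frr_o <- 0; correct <- 0
    for (i in seq_along(scores)) {
      acc <- scores[i] >= tau
      if (labels[i] == "impostor" && acc) far_o <- far_o + 1
      if (labels[i] == "genuine" && !acc) frr_o <- frr_o + 1
      if ((labels[i] == "genuine") == acc) correct <- correct + 1
    }
    expect_equal(r[["far"]], 100 * far_o / sum(labels == "impostor"))
    expect_equal(r[["frr"]], 100 * frr_o / sum(labels == "genuine"))
    expect_equal(r[["accuracy"]], 100 * correct / 40)
  }
})

test_that("EER is zero for perfectly separated classes", {
  scores <- c(0.8, 0.9, 0.95, 0.1, 0.2, 0.3)
  labels <- rep(c("genuine", "impostor"), each = 3)
  e <- eer(scores, labels)
  expect_equal(e$eer, 0)
  expect_false(e$degenerate)
})

test_that("EER matches a dense brute-force sweep on random score sets", {
  set.seed(82)
  for (rep in 1:10) {
    scores <- runif(30)
    labels <- sample(rep(c("genuine", "impostor"), c(15, 15)))
    e <- eer(scores, labels)
    expect_lt(abs(e$eer - dense_eer(scores, labels)), 0.1)
  }
})

test_that("label-shuffled scores give chance-level EER and a tight crossing", {
  set.seed(83)
  scores <- runif(2000)
  labels <- sample(rep(c("genuine", "impostor"), 1000))
  e <- eer(scores, labels)
  expect_lt(abs(e$eer - 50), 3)
  # empirical rates recomputed at the returned threshold nearly cross
  r <- rates_at(scores, labels, e$threshold)
  expect_lte(abs(r[["far"]] - r[["frr"]]), 0.5)
})

test_that("FAR is non-increasing and FRR non-decreasing along the sweep", {
  set.seed(84)
  scores <- runif(300)
  labels <- sample(rep(c("genuine", "impostor"), 150))
  det <- eer(scores, labels)$det
  expect_true(all(diff(det$far) <= 0))
  expect_true(all(diff(det$frr) >= 0))
})

test_that("EER is invariant under strictly monotone score transforms", {
  set.seed(85)
  scores <- runif(100)
  labels <- sample(rep(c("genuine", "impostor"), 50))
  e0 <- eer(scores, labels)$eer
  expect_equal(eer(scores^3, labels)$eer, e0, tolerance = 1e-9)
  expect_equal(eer(plogis(5 * scores - 2), labels)$eer, e0, tolerance = 1e-9)
})

test_that("identical scores are flagged as degenerate", {
  e <- eer(rep(0.5, 10), rep(c("genuine", "impostor"), 5))
  expect_true(e$degenerate)
  expect_equal(e$eer, 50)
})

test_that("cross-validation bookkeeping: k rows, means of folds, JSON roundtrip", {
  task <- separable_task()
  bundles <- task$bundles[c(1:30, 101:130)]
  folds <- kfold(bundles, k = 2, seed = 3)
  report <- crossval(bundles, folds, esn_config(epochs = 2, seed = 21))
  expect_identical(nrow(report$per_fold), 2L)
  expect_equal(report$mean[["accuracy"]], mean(report$per_fold$accuracy))
  expect_equal(report$mean[["eer"]], mean(report$per_fold$eer))
  expect_identical(sum(report$per_fold$n_test), length(bundles))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(report, path)
  back <- read_eval_report(path)
  expect_equal(back$per_fold, report$per_fold)
  expect_equal(back$mean, report$mean)
  det_path <- withr::local_tempfile(fileext = ".csv")
  write_det_csv(report, det_path)
  det <- read.csv(det_path)
  expect_identical(names(det), c("threshold", "far", "frr"))
})

test_that("two-fold cross-validation solves the separable task", {
  task <- separable_task()
  folds <- kfold(task$bundles, k = 2, seed = 5)
  report <- crossval(task$bundles, folds, esn_config(epochs = 8, seed = 31))
  expect_gte(report$mean[["accuracy"]], 95)
  expect_lte(report$mean[["eer"]], 5)
})
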