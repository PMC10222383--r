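# Contracts of the shared-weight encoder, the similarity head, ensemble
# scoring and the training loop.

test_that("encoding is deterministic and yields 512-dimensional embeddings", {
  w <- small_weights()
  set.seed(61)
  fm <- random_fm()
  e1 <- encode(w, fm)
  e2 <- encode(w, fm)
  expect_identical(e1, e2)
  expect_length(e1, 512L)
  expect_true(all(is.finite(e1)))
  expect_error(encode(w, random_fm(L = 128L)), "L=64")
})

test_that("both presets flatten to a 256-dimensional pre-dense vector", {
  cfg <- esn_config(seed = 1)
  for (L in c(200L, 256L)) {
    w <- esn_init(cfg, L = L)
    expect_identical(w$flat_dim, 256L)
    expect_identical(w$pooled[length(w$pooled)], 1L)
    # instrumented probe: a forward pass works end to end at this length
    set.seed(L)
    expect_length(encode(w, random_fm(L)), 512L)
  }
  # the pooling stack halves in ceil mode: 200,100,50,25,13,7,4,2,1
  expect_identical(esn_init(cfg, 200L)$pooled,
                   c(200L, 100L, 50L, 25L, 13L, 7L, 4L, 2L, 1L))
})

test_that("similarity is symmetric, self-constant and matches exported weights", {
  w <- small_weights()
  set.seed(62)
  for (i in 1:20) {
    a <- rnorm(512)
    b <- rnorm(512)
    s_ab <- similarity(a, b, w)
    expect_identical(s_ab, similarity(b, a, w))
    expect_gt(s_ab, 0)
    expect_lt(s_ab, 1)
    # independent recomputation from the exported head parameters
    oracle <- 1 / (1 + exp(-(sum(w$params$hw * abs(a - b)) + w$params$hb)))
    expect_equal(s_ab, oracle, tolerance = 1e-6)
  }
  # zero-difference collapse: one constant value for every a
  s_self <- vapply(1:5, function(i) {
    v <- rnorm(512)
    similarity(v, v, w)
  }, numeric(1))
  expect_true(all(s_self == 1 / (1 + exp(-w$params$hb))))
  expect_error(similarity(rnorm(512), rnorm(511), w), "dimension")
})

test_that("bundle score is the permutation-invariant mean of pairwise similarities", {
  w <- small_weights()
  set.seed(63)
  refs <- lapply(1:4, function(i) random_fm())
  probe <- random_fm()
  bu <- ecg_bundle(refs, probe, "positive", "A", "A")
  s <- bundle_score(w, bu)
  # equals the mean of individually computed similarities
  ep <- encode(w, probe)
  sims <- vapply(refs, function(r) similarity(encode(w, r), ep, w), numeric(1))
  expect_equal(s, mean(sims), tolerance = 1e-9)
  # shuffling the references leaves the score unchanged
  bu_shuf <- ecg_bundle(refs[c(3, 1, 4, 2)], probe, "positive", "A", "A")
  expect_equal(bundle_score(w, bu_shuf), s, tolerance = 1e-12)
  # one reference: reduces to plain pairwise similarity
  bu1 <- ecg_bundle(refs[1], probe, "positive", "A", "A")
  expect_equal(bundle_score(w, bu1), sims[1], tolerance = 1e-12)
})

test_that("zero-epoch training returns the initialization fingerprint", {
  set.seed(64)
  bundles <- c(list(ecg_bundle(list(random_fm()), random_fm(), "positive", "A", "A")),
               list(ecg_bundle(list(random_fm()), random_fm(), "negative", "A", "B")))
  cfg <- esn_config(epochs = 0L, seed = 9)
  fit <- esn_train(bundles, cfg)
  expect_identical(esn_fingerprint(fit$weights),
                   esn_fingerprint(esn_init(cfg, 64L)))
  expect_length(fit$loss_trace, 0L)
})

test_that("training rejects degenerate inputs", {
  set.seed(65)
  pos_only <- list(ecg_bundle(list(random_fm()), random_fm(), "positive", "A", "A"))
  expect_error(esn_train(pos_only, esn_config(epochs = 1)), "both")
  expect_error(esn_train(list(), esn_config(epochs = 1)), "non-empty")
})

test_that("an uninformative scorer has binary cross-entropy ln 2", {
  y <- c(1, 0, 1, 1, 0)
  expect_equal(ecgverify:::esn_bce(rep(0.5, 5), y), log(2), tolerance = 1e-12)
})

test_that("training separates a two-subject zero-noise task", {
  task <- separable_task()
  fit <- task$fit
  scores <- vapply(task$bundles, function(b) bundle_score(fit$weights, b),
                   numeric(1))
  labels <- ifelse(vapply(task$bundles, `[[`, character(1), "label") ==
                     "positive", "genuine", "impostor")
  acc <- rates_at(scores, labels, 0.5)[["accuracy"]]
  expect_gte(acc, 95)
  # loss trace is non-increasing up to small transient upticks
  trace <- fit$loss_trace
  upticks <- diff(trace)[diff(trace) > 0]
  expect_true(all(upticks <= 0.05 * trace[-length(trace)][diff(trace) > 0]))
  expect_lt(trace[length(trace)], trace[1])
})

test_that("training is reproducible under the config seed", {
  task <- separable_task()
  cfg <- esn_config(epochs = 1, seed = 77)
  f1 <- esn_train(task$bundles[c(1:10, 101:110)], cfg)
  f2 <- esn_train(task$bundles[c(1:10, 101:110)], cfg)
  expect_identical(esn_fingerprint(f1$weights), esn_fingerprint(f2$weights))
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("weights roundtrip through a checkpoint file", {
  w <- small_weights()
  path <- withr::local_tempfile(fileext = ".rds")
  esn_save_weights(w, path)
  expect_identical(esn_fingerprint(esn_load_weights(path)), esn_fingerprint(w))
})
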