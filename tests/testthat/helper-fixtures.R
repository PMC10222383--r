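# Shared fixtures, all built in code at test time.

# z-scored random segment of length L, through the package constructor
random_segment <- function(L = 64L, subject_id = "X") {
  v <- stats::rnorm(L)
  ecg_segment((v - mean(v)) / stats::sd(v), subject_id, floor(0.4 * L) + 1L)
}

random_fm <- function(L = 64L, subject_id = "X") {
  featurize(random_segment(L, subject_id))
}

# lightweight bundles for fold/bookkeeping tests (no training involved)
dummy_bundles <- function(n_pos, n_neg, L = 8L) {
  mk <- function(lab, i) {
    fm <- matrix(stats::rnorm(2 * L), L, 2)
    ecg_bundle(list(fm), fm * (if (lab == "positive") 1 else -1),
               lab, "A", ifelse(lab == "positive", "A", "B"))
  }
  c(lapply(seq_len(n_pos), mk, lab = "positive"),
    lapply(seq_len(n_neg), mk, lab = "negative"))
}

# memoised expensive fixtures: built once per test run
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# zero-noise two-subject dataset + balanced bundles + a short training run:
# the clearly separable sanity task
separable_task <- function() {
  memo("separable_task", {
    ds <- synth_segment_dataset(seed = 42, n_subjects = 2,
                                beats_per_subject = 12, noise_sd = 0,
                                rr_jitter_sd = 0.02, baseline_amp = 0)
    bundles <- build_bundles(ds, n_ref = 3, n_pos = 100, n_neg = 100, seed = 1)
    fit <- esn_train(bundles, esn_config(epochs = 8, seed = 11))
    list(dataset = ds, bundles = bundles, fit = fit)
  })
}

# small untrained encoder shared by contract tests (init is cheap but not free)
small_weights <- function(L = 64L, seed = 5L) {
  memo(paste0("w_", L, "_", seed), esn_init(esn_config(seed = seed), L = L))
}

# naive O(N^2) discrete Fourier transform: the independent oracle
naive_dft <- function(x) {
  N <- length(x)
  ks <- 0:(N - 1)
  vapply(ks, function(k) {
    sum(x * exp(-2i * pi * k * ks / N))
  }, complex(1))
}

# dense brute-force EER oracle: uniform threshold grid, same crossing rule,
# implemented independently of the package sweep
dense_eer <- function(scores, labels, n_grid = 1e5) {
  gen <- scores[labels == "genuine"]
  imp <- scores[labels == "impostor"]
  d <- max(diff(range(scores)), 1e-6) * 1e-3
  taus <- seq(min(scores) - d, max(scores) + d, length.out = n_grid)
  far <- vapply(taus, function(t) 100 * mean(imp >= t), numeric(1))
  frr <- vapply(taus, function(t) 100 * mean(gen < t), numeric(1))
  diffs <- far - frr
  hit <- which(diffs == 0)
  if (length(hit)) return(far[hit[1]])
  i2 <- which(diffs < 0)[1]
  i1 <- i2 - 1
  t <- diffs[i1] / (diffs[i1] - diffs[i2])
  far[i1] + t * (far[i2] - far[i1])
}
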