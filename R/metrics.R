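# Biometric evaluation: FAR (impostor attempts accepted), FRR (genuine
# attempts rejected), accuracy, and the equal error rate found by sweeping
# the decision threshold over the observed scores. The accept convention is
# score >= threshold everywhere, matching authentication.

#' Error rates and accuracy at a fixed threshold
#'
#' FAR is the percentage of impostor scores at or above the threshold, FRR
#' the percentage of genuine scores below it, accuracy the percentage of
#' correct decisions overall.
#'
#' @param scores Numeric similarity scores in \[0, 1\].
#' @param labels Parallel character vector, `"genuine"` or `"impostor"`.
#' @param tau Decision threshold.
#' @return Named numeric vector `c(far, frr, accuracy)`, each in percent.
#' @export
rates_at <- function(scores, labels, tau) {
  check_scored(scores, labels)
  gen <- scores[labels == "genuine"]
  imp <- scores[labels == "impostor"]
  far <- 100 * sum(imp >= tau) / length(imp)
  frr <- 100 * sum(gen < tau) / length(gen)
  acc <- 100 * (sum(gen >= tau) + sum(imp < tau)) / length(scores)
  c(far = far, frr = frr, accuracy = acc)
}

check_scored <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort_invalid("scores and labels must have equal length")
  }
  if (!all(labels %in% c("genuine", "impostor"))) {
    abort_invalid("labels must be 'genuine' or 'impostor'")
  }
  if (!any(labels == "genuine") || !any(labels == "impostor")) {
    abort_invalid("both genuine and impostor scores are required")
  }
  invisible(NULL)
}

sweep_rates <- function(scores, labels, taus) {
  gen <- sort(scores[labels == "genuine"])
  imp <- sort(scores[labels == "impostor"])
  # #x >= tau via binary search on the sorted vector
  n_ge <- function(sorted, tau) length(sorted) - findInterval(tau, sorted, left.open = TRUE)
  far <- vapply(taus, function(t) 100 * n_ge(imp, t) / length(imp), numeric(1))
  frr <- vapply(taus, function(t) 100 * (1 - n_ge(gen, t) / length(gen)), numeric(1))
  data.frame(threshold = taus, far = far, frr = frr)
}

#' Equal error rate
#'
#' Sweeps the threshold over every distinct score, the midpoints between
#' adjacent distinct scores, and sentinels below and above the score range.
#' FAR is non-increasing and FRR non-decreasing along the sweep; the EER is
#' read at their crossing, linearly interpolated between the adjacent sweep
#' points when no sweep point hits FAR = FRR exactly. The returned
#' threshold is the sweep point adjacent to the crossing with the smaller
#' |FAR - FRR|, so empirical rates recomputed at it stay within one
#' score-step of each other.
#'
#' @inheritParams rates_at
#' @return List with `eer` (percent), `threshold`, `degenerate` (`TRUE`
#'   when all scores are identical) and `det` (the sweep as a data frame
#'   with columns `threshold`, `far`, `frr` — the detection error
#'   trade-off curve).
#' @export
eer <- function(scores, labels) {
  check_scored(scores, labels)
  u <- sort(unique(scores))
  degenerate <- length(u) == 1L
  d <- max(diff(range(u)), 1e-6) * 1e-3
  taus <- sort(unique(c(u[1] - d, u, u[-length(u)] + diff(u) / 2,
                        u[length(u)] + d)))
  sw <- sweep_rates(scores, labels, taus)
  diffs <- sw$far - sw$frr
  hit <- which(diffs == 0)
  if (length(hit)) {
    i <- hit[1]
    return(list(eer = sw$far[i], threshold = sw$threshold[i],
                degenerate = degenerate, det = sw))
  }
  i2 <- which(diffs < 0)[1]  # first sweep point with FAR < FRR
  i1 <- i2 - 1L
  d1 <- diffs[i1]
  d2 <- diffs[i2]
  t <- d1 / (d1 - d2)
  eer_val <- sw$far[i1] + t * (sw$far[i2] - sw$far[i1])
  thr <- if (abs(d1) <= abs(d2)) sw$threshold[i1] else sw$threshold[i2]
  list(eer = eer_val, threshold = thr, degenerate = degenerate, det = sw)
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each fold: train the model on the remaining folds, score the held-out
#' bundles, and compute accuracy at the 0.5 classification cutoff, the same
#' at the authentication policy threshold, FAR/FRR at both, and the EER of
#' the held-out score set. Per-fold results and their means are reported.
#' Fold `f` trains with seed `config$seed + f`, so the whole protocol is
#' deterministic.
#'
#' @param bundles List of [ecg_bundle()] objects.
#' @param folds A [kfold()] assignment over `bundles`.
#' @param config An [esn_config()].
#' @param policy_threshold Authentication policy threshold (default 0.7).
#' @param verbose Print per-fold progress.
#' @return An object of class `eval_report`: list with `per_fold` (data
#'   frame), `mean` (named numeric vector), `policy_threshold`, `k` and
#'   `det` (the DET sweep of the pooled held-out scores).
#' @export
crossval <- function(bundles, folds, config = esn_config(),
                     policy_threshold = 0.7, verbose = FALSE) {
  stopifnot(inherits(folds, "fold_assignment"),
            length(folds$assignment) == length(bundles))
  rows <- vector("list", folds$k)
  all_scores <- numeric(0)
  all_labels <- character(0)
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$assignment == f)
    train_idx <- which(folds$assignment != f)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- esn_train(bundles[train_idx], cfg)
    scores <- vapply(bundles[test_idx], function(b) bundle_score(fit$weights, b),
                     numeric(1))
    labels <- ifelse(vapply(bundles[test_idx], `[[`, character(1), "label") ==
                       "positive", "genuine", "impostor")
    r05 <- rates_at(scores, labels, 0.5)
    rpol <- rates_at(scores, labels, policy_threshold)
    e <- eer(scores, labels)
    rows[[f]] <- data.frame(
      fold = f, n_test = length(test_idx),
      accuracy = r05[["accuracy"]], far = r05[["far"]], frr = r05[["frr"]],
      accuracy_policy = rpol[["accuracy"]], far_policy = rpol[["far"]],
      frr_policy = rpol[["frr"]],
      eer = e$eer, eer_threshold = e$threshold,
      final_loss = fit$loss_trace[length(fit$loss_trace)]
    )
    all_scores <- c(all_scores, scores)
    all_labels <- c(all_labels, labels)
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.1f%%, EER %.2f%%",
                      f, folds$k, r05[["accuracy"]], e$eer))
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), c("fold", "n_test"))
  means <- colMeans(per_fold[metric_cols])
  pooled <- eer(all_scores, all_labels)
  structure(list(per_fold = per_fold, mean = means, k = folds$k,
                 policy_threshold = policy_threshold, det = pooled$det),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold cross-validation\n", x$k))
  cat(sprintf("  mean accuracy %.2f%% | FAR %.2f%% | FRR %.2f%% | EER %.2f%%\n",
              x$mean[["accuracy"]], x$mean[["far"]], x$mean[["frr"]],
              x$mean[["eer"]]))
  cat(sprintf("  at policy threshold %.2f: accuracy %.2f%% | FAR %.2f%% | FRR %.2f%%\n",
              x$policy_threshold, x$mean[["accuracy_policy"]],
              x$mean[["far_policy"]], x$mean[["frr_policy"]]))
  invisible(x)
}

#' Write / read an evaluation report
#'
#' JSON roundtrip of the per-fold table and summary; the DET sweep can also
#' be written as CSV with columns threshold, far, frr.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `read_eval_report` returns the report.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(k = report$k, policy_threshold = report$policy_threshold,
              mean = as.list(report$mean), per_fold = report$per_fold,
              det = report$det)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_fold = as.data.frame(obj$per_fold),
                 mean = unlist(obj$mean), k = obj$k,
                 policy_threshold = obj$policy_threshold,
                 det = as.data.frame(obj$det)),
            class = "eval_report")
}

#' @rdname write_eval_report
#' @export
write_det_csv <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  utils::write.csv(report$det, path, row.names = FALSE)
  invisible(path)
}
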