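# Balanced training bundles: n_ref reference feature matrices from one
# subject plus one probe, labelled positive when the probe is the same
# subject. Because pairs are sampled, the builder produces exactly balanced
# labels regardless of per-subject segment counts in the source data.

#' Reference/probe bundle
#'
#' @param refs List of exactly `n_ref` feature matrices, all one subject.
#' @param probe One feature matrix.
#' @param label `"positive"` or `"negative"`.
#' @param ref_subject,probe_subject Subject labels; the label must be
#'   positive iff they are equal.
#' @param ref_ids,probe_id Integer segment indices within the source
#'   dataset (bookkeeping for manifests and validity scans).
#' @return An object of class `ecg_bundle`.
#' @export
ecg_bundle <- function(refs, probe, label, ref_subject, probe_subject,
                       ref_ids = NULL, probe_id = NULL) {
  label <- match.arg(label, c("positive", "negative"))
  if ((label == "positive") != identical(ref_subject, probe_subject)) {
    abort_invalid("label must be positive iff probe_subject equals ref_subject")
  }
  structure(list(refs = refs, probe = probe, label = label,
                 ref_subject = ref_subject, probe_subject = probe_subject,
                 ref_ids = ref_ids, probe_id = probe_id),
            class = "ecg_bundle")
}

#' Build balanced positive/negative bundles
#'
#' Each positive bundle draws `n_ref + 1` distinct segments from one
#' uniformly chosen subject (`n_ref` references plus a matching probe);
#' each negative bundle draws `n_ref` references from one subject and a
#' probe from a different, uniformly chosen subject. Segments may be reused
#' across bundles; within a positive bundle all `n_ref + 1` segments are
#' distinct.
#'
#' @param dataset Named list mapping subject id to a list of feature
#'   matrices (see [preprocess_record()]).
#' @param n_ref References per bundle.
#' @param n_pos,n_neg Number of positive / negative bundles.
#' @param seed Integer seed; identical arguments reproduce identical
#'   bundles.
#' @return List of [ecg_bundle()] objects: `n_pos` positives followed by
#'   `n_neg` negatives.
#' @export
build_bundles <- function(dataset, n_ref = 3L, n_pos, n_neg, seed = 1L) {
  if (!is.list(dataset) || is.null(names(dataset)) || any(!nzchar(names(dataset)))) {
    abort_invalid("dataset must be a named list of per-subject segment lists")
  }
  if (!is_count(n_ref) || n_ref < 1) abort_invalid("n_ref must be a positive integer")
  if (!is_count(n_pos) || n_pos < 0 || !is_count(n_neg) || n_neg < 0) {
    abort_invalid("n_pos and n_neg must be non-negative integers")
  }
  counts <- lengths(dataset)
  subjects <- names(dataset)
  if (n_pos + n_neg == 0L) return(list())
  if (n_pos > 0L) {
    short <- subjects[counts < n_ref + 1L]
    if (length(short)) {
      abort_invalid("insufficient segments for positive bundles: subject ",
                    short[1], " has ", counts[short[1]], ", need ", n_ref + 1L)
    }
  }
  if (n_neg > 0L) {
    if (length(subjects) < 2L) abort_invalid("negative bundles need at least 2 subjects")
    short <- subjects[counts < n_ref]
    if (length(short)) {
      abort_invalid("insufficient segments for reference sets: subject ",
                    short[1], " has ", counts[short[1]], ", need ", n_ref)
    }
  }
  with_seed(seed, {
    bundles <- vector("list", n_pos + n_neg)
    for (j in seq_len(n_pos)) {
      s <- sample(subjects, 1L)
      idx <- sample(counts[[s]], n_ref + 1L)
      bundles[[j]] <- ecg_bundle(dataset[[s]][idx[seq_len(n_ref)]],
                                 dataset[[s]][[idx[n_ref + 1L]]],
                                 "positive", s, s,
                                 ref_ids = idx[seq_len(n_ref)],
                                 probe_id = idx[n_ref + 1L])
    }
    for (j in seq_len(n_neg)) {
      rs <- sample(subjects, 1L)
      ps <- sample(setdiff(subjects, rs), 1L)
      ridx <- sample(counts[[rs]], n_ref)
      pidx <- sample(counts[[ps]], 1L)
      bundles[[n_pos + j]] <- ecg_bundle(dataset[[rs]][ridx],
                                         dataset[[ps]][[pidx]],
                                         "negative", rs, ps,
                                         ref_ids = ridx, probe_id = pidx)
    }
    bundles
  })
}

#' Stratified k-fold assignment over bundles
#'
#' Bundles are shuffled within each label class and dealt round-robin over
#' the `k` folds, so fold sizes differ by at most one and the per-fold label
#' balance matches the global balance to within one bundle per class.
#'
#' @param bundles List of [ecg_bundle()] objects.
#' @param k Number of folds (2 <= k <= number of bundles).
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: list with `k` and
#'   `assignment`, an integer vector mapping bundle index to fold.
#' @export
kfold <- function(bundles, k, seed = 1L) {
  n <- length(bundles)
  if (!is_count(k) || k < 2 || k > n) {
    abort_invalid("k must be an integer in [2, number of bundles]")
  }
  labels <- vapply(bundles, `[[`, character(1), "label")
  with_seed(seed, {
    order_pos <- sample(which(labels == "positive"))
    order_neg <- sample(which(labels == "negative"))
    dealt <- c(order_pos, order_neg)
    assignment <- integer(n)
    assignment[dealt] <- ((seq_len(n) - 1L) %% k) + 1L
    structure(list(k = as.integer(k), assignment = assignment),
              class = "fold_assignment")
  })
}
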