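# Test-phase protocol: register a user by storing n_ref encoder embeddings
# in the repository (no retraining, no raw signals), then verify a claimed
# identity by comparing a probe embedding against the stored templates.

#' Authentication policy
#'
#' @param threshold Similarity cutoff in (0, 1); a probe is accepted when
#'   its ensemble score is greater than or equal to the threshold. Default
#'   0.7.
#' @return An object of class `auth_policy`.
#' @export
auth_policy <- function(threshold = 0.7) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort_invalid("threshold must lie strictly inside (0, 1)")
  }
  structure(list(threshold = threshold), class = "auth_policy")
}

#' Enroll a user into the repository
#'
#' Featurizes the user's segments, encodes the first `n_ref` of them with
#' the trained shared encoder, and stores the embeddings. The model is
#' never retrained (its parameter fingerprint is unchanged) and raw
#' segments are never stored. Selecting the first `n_ref` segments is
#' deterministic, so re-enrollment from the same data reproduces the same
#' repository.
#'
#' @param repo A [new_repository()] object.
#' @param user_id New user label; enrolling an existing user is an error.
#' @param segments List of at least `n_ref` [ecg_segment()] objects of the
#'   trained window length.
#' @param weights Trained [esn_init()]/[esn_train()] weights.
#' @return The updated repository.
#' @export
enroll <- function(repo, user_id, segments, weights) {
  stopifnot(inherits(repo, "template_repository"),
            inherits(weights, "esn_weights"))
  if (user_id %in% names(repo$users)) {
    abort_invalid("user already enrolled: ", user_id)
  }
  if (length(segments) < repo$n_ref) {
    abort_invalid("enrollment needs at least ", repo$n_ref,
                  " segments, got ", length(segments))
  }
  fms <- lapply(segments[seq_len(repo$n_ref)], featurize)
  E <- encode_batch(weights, fms)
  if (is.na(repo$embed_dim)) {
    repo$embed_dim <- ncol(E)
  } else if (repo$embed_dim != ncol(E)) {
    abort_invalid("embedding dimension ", ncol(E),
                  " does not match repository dimension ", repo$embed_dim)
  }
  repo$users[[user_id]] <- list(
    embeddings = lapply(seq_len(nrow(E)), function(i) as.numeric(E[i, ])),
    enrolled_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    preset = repo$preset
  )
  repo
}

#' Authenticate a probe against a claimed identity
#'
#' Encodes the probe segment and scores it against the claimed user's
#' stored templates (mean pairwise similarity by default). The probe is
#' accepted iff the score is greater than or equal to the policy threshold
#' — a score exactly at the threshold is accepted. An unknown claimed
#' identity raises an error, distinct from a reject decision: rejection
#' asserts a mismatch against known templates, which is unverifiable for an
#' identity that has none.
#'
#' @param repo Repository containing the claimed user.
#' @param claimed_user User label being claimed.
#' @param probe An [ecg_segment()] of the trained window length.
#' @param weights Trained weights.
#' @param policy An [auth_policy()].
#' @return An object of class `auth_decision`: list with `claimed_user`,
#'   `score`, `accepted` and `threshold_used`.
#' @export
authenticate <- function(repo, claimed_user, probe, weights,
                         policy = auth_policy()) {
  stopifnot(inherits(repo, "template_repository"),
            inherits(weights, "esn_weights"),
            inherits(policy, "auth_policy"))
  if (!claimed_user %in% names(repo$users)) {
    abort_invalid("identity not found: ", claimed_user)
  }
  emb <- encode(weights, featurize(probe))
  refs <- do.call(rbind, repo$users[[claimed_user]]$embeddings)
  score <- score_from_embeddings(weights, emb, refs)
  structure(list(claimed_user = claimed_user, score = score,
                 accepted = score >= policy$threshold,
                 threshold_used = policy$threshold),
            class = "auth_decision")
}

#' @export
print.auth_decision <- function(x, ...) {
  cat(sprintf("<auth_decision> claimed=%s score=%.4f threshold=%.2f -> %s\n",
              x$claimed_user, x$score, x$threshold_used,
              if (x$accepted) "ACCEPT" else "REJECT"))
  invisible(x)
}
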