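# The shared-weight Siamese encoder and its similarity head. One encoder —
# one parameter set — serves every branch: a probe and its n_ref reference
# segments are all encoded by the same function, pairwise similarity is a
# sigmoid over a learned weighting of the elementwise absolute difference
# of two embeddings, and a bundle's score is the mean pairwise similarity
# of the probe against the references. Training minimizes binary
# cross-entropy of the bundle score against the match label, with L2
# weight decay, using Adam.

#' Encoder and training configuration
#'
#' The architecture is eight 1D convolutional layers (ReLU, kernel 3, "same"
#' zero padding) with filter counts 32, 32, 64, 64, 128, 128, 256, 256, each
#' followed by width-2 stride-2 max pooling in ceil mode (an odd trailing
#' element pools alone, so a 200-sample input survives the stack:
#' 200, 100, 50, 25, 13, 7, 4, 2, 1). The pooled output is flattened and
#' projected by a dense layer to a 512-dimensional embedding.
#'
#' @param conv_filters Integer vector of 8 filter counts.
#' @param kernel_size Odd convolution kernel width (default 3).
#' @param embed_dim Embedding dimension (default 512).
#' @param l2_coeff L2 weight-decay coefficient (default 1e-4).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs Training epochs (default 50).
#' @param batch_size Bundles per minibatch (default 32).
#' @param seed Integer seed for initialization and batch shuffling.
#' @param aggregate How a bundle aggregates its reference comparisons:
#'   `"mean_similarity"` (default; mean of the pairwise similarities) or
#'   `"similarity_to_mean"` (similarity of the probe to the mean reference
#'   embedding).
#' @return An object of class `esn_config`.
#' @export
esn_config <- function(conv_filters = c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L),
                       kernel_size = 3L, embed_dim = 512L, l2_coeff = 1e-4,
                       learning_rate = 1e-3, epochs = 50L, batch_size = 32L,
                       seed = 1L,
                       aggregate = c("mean_similarity", "similarity_to_mean")) {
  aggregate <- match.arg(aggregate)
  if (length(conv_filters) != 8L || any(conv_filters < 1)) {
    abort_invalid("conv_filters must be 8 positive filter counts")
  }
  if (!is_count(kernel_size) || kernel_size %% 2L != 1L) {
    abort_invalid("kernel_size must be an odd integer")
  }
  if (!is_count(embed_dim) || embed_dim < 1) abort_invalid("embed_dim must be >= 1")
  if (l2_coeff < 0) abort_invalid("l2_coeff must be non-negative")
  if (learning_rate <= 0) abort_invalid("learning_rate must be positive")
  if (!is_count(epochs) || epochs < 0) abort_invalid("epochs must be a non-negative integer")
  if (!is_count(batch_size) || batch_size < 1) abort_invalid("batch_size must be positive")
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 embed_dim = as.integer(embed_dim), l2_coeff = l2_coeff,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 aggregate = aggregate),
            class = "esn_config")
}

#' Initialize encoder weights
#'
#' He-normal initialization for the convolutional and dense weights, small
#' Gaussian for the similarity-head weighting, deterministic under the
#' config seed.
#'
#' @param config An [esn_config()].
#' @param L Input segment length the encoder is built for (e.g. 256 for the
#'   ecgid-like preset, 200 for ptb-like).
#' @return An object of class `esn_weights` holding the parameter list, the
#'   config and `L`.
#' @export
esn_init <- function(config, L) {
  stopifnot(inherits(config, "esn_config"))
  if (!is_count(L) || L < 2) abort_invalid("L must be an integer >= 2")
  L <- as.integer(L)
  nb <- length(config$conv_filters)
  lens <- pooled_lengths(L, nb)
  flat_dim <- lens[nb + 1L] * config$conv_filters[nb]
  with_seed(config$seed, {
    params <- list()
    c_in <- 2L
    for (i in seq_len(nb)) {
      c_out <- config$conv_filters[i]
      fan_in <- config$kernel_size * c_in
      params[[paste0("cW", i)]] <- matrix(
        stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
      params[[paste0("cb", i)]] <- numeric(c_out)
      c_in <- c_out
    }
    params$dW <- matrix(stats::rnorm(flat_dim * config$embed_dim, 0,
                                     sqrt(1 / flat_dim)),
                        flat_dim, config$embed_dim)
    params$db <- numeric(config$embed_dim)
    params$hw <- stats::rnorm(config$embed_dim, 0, 0.1)
    params$hb <- 0
    structure(list(params = params, config = config, L = L,
                   pooled = lens, flat_dim = flat_dim),
              class = "esn_weights")
  })
}

#' @export
print.esn_weights <- function(x, ...) {
  cat(sprintf(
    "<esn_weights> L=%d -> %s -> flat %d -> embed %d; fingerprint %s\n",
    x$L, paste(x$pooled[-1], collapse = ","), x$flat_dim,
    x$config$embed_dim, substr(esn_fingerprint(x), 1, 12)))
  invisible(x)
}

check_fm <- function(weights, fm) {
  if (!is.matrix(fm) || ncol(fm) != 2L) {
    abort_invalid("feature matrix must have 2 channels")
  }
  if (nrow(fm) != weights$L) {
    abort_invalid("feature matrix has L=", nrow(fm),
                  " but the encoder expects L=", weights$L)
  }
  invisible(fm)
}

#' Encode feature matrices into embeddings
#'
#' The single shared encoder: deterministic in inference, the same function
#' regardless of which Siamese "branch" an input nominally belongs to.
#'
#' @param weights An [esn_init()] / [esn_train()] weight object.
#' @param fm One L x 2 feature matrix ([featurize()]).
#' @param fms A list of feature matrices (batched variant).
#' @return `encode`: numeric embedding of length `embed_dim`;
#'   `encode_batch`: a matrix with one embedding per row.
#' @export
encode <- function(weights, fm) {
  stopifnot(inherits(weights, "esn_weights"))
  check_fm(weights, fm)
  as.numeric(encoder_forward(weights$params, weights$config,
                             unclass(fm), B = 1L))
}

#' @rdname encode
#' @export
encode_batch <- function(weights, fms) {
  stopifnot(inherits(weights, "esn_weights"), length(fms) >= 1L)
  for (fm in fms) check_fm(weights, fm)
  x <- do.call(rbind, fms)
  encoder_forward(weights$params, weights$config, x, B = length(fms))
}

#' Pairwise similarity of two embeddings
#'
#' `sigmoid(hw . |a - b| + hb)`: a learned weighting of the elementwise
#' absolute difference (L1-style comparison) squashed to (0, 1). Symmetric
#' in its arguments; identical embeddings always score `sigmoid(hb)`.
#'
#' @param a,b Numeric embeddings of equal length `embed_dim`.
#' @param weights Weight object providing the head parameters.
#' @return A similarity score strictly inside (0, 1).
#' @export
similarity <- function(a, b, weights) {
  stopifnot(inherits(weights, "esn_weights"))
  if (length(a) != length(b)) {
    abort_invalid("embedding dimensions differ: ", length(a), " vs ", length(b))
  }
  if (length(a) != weights$config$embed_dim) {
    abort_invalid("embeddings must have length ", weights$config$embed_dim)
  }
  sigmoid(sum(weights$params$hw * abs(a - b)) + weights$params$hb)
}

#' Ensemble score of a bundle
#'
#' Encodes the probe and the `n_ref` references with the shared encoder and
#' aggregates the pairwise similarities — by default their arithmetic mean,
#' which is invariant under any permutation of the references.
#'
#' @param weights Weight object.
#' @param bundle An [ecg_bundle()].
#' @return A score in (0, 1).
#' @export
bundle_score <- function(weights, bundle) {
  stopifnot(inherits(bundle, "ecg_bundle"))
  E <- encode_batch(weights, c(list(bundle$probe), bundle$refs))
  score_from_embeddings(weights, E[1, ], E[-1, , drop = FALSE])
}

# Probe embedding vs a matrix of reference embeddings (one per row),
# honoring the configured aggregation rule.
score_from_embeddings <- function(weights, probe_emb, ref_embs) {
  if (weights$config$aggregate == "similarity_to_mean") {
    return(similarity(probe_emb, colMeans(ref_embs), weights))
  }
  mean(apply(ref_embs, 1L, similarity, b = probe_emb, weights = weights))
}

# Binary cross-entropy of scores in (0,1) against 0/1 labels, with scores
# clamped away from the boundary for numerical safety.
esn_bce <- function(scores, y, eps = 1e-7) {
  s <- pmin(pmax(scores, eps), 1 - eps)
  mean(-(y * log(s) + (1 - y) * log(1 - s)))
}

l2_penalty <- function(params, l2_coeff) {
  if (l2_coeff == 0) return(0)
  wnames <- grep("^cW|^dW$|^hw$", names(params), value = TRUE)
  l2_coeff * sum(vapply(params[wnames], function(w) sum(w * w), numeric(1)))
}

#' Stable fingerprint of the model parameters
#'
#' MD5 of the XDR serialization of the parameter list in canonical order;
#' changes iff any parameter value changes. Used to assert that enrollment
#' and authentication never retrain the model.
#'
#' @param weights Weight object.
#' @return A hex string.
#' @export
esn_fingerprint <- function(weights) {
  stopifnot(inherits(weights, "esn_weights"))
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  writeBin(serialize(weights$params[sort(names(weights$params))], NULL), f)
  unname(tools::md5sum(f))
}

#' Save / load encoder weights
#'
#' Checkpoint containing the parameters, config, input length and seed.
#'
#' @param weights Weight object.
#' @param path Checkpoint file path.
#' @return `esn_load_weights` returns the weight object.
#' @export
esn_save_weights <- function(weights, path) {
  stopifnot(inherits(weights, "esn_weights"))
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname esn_save_weights
#' @export
esn_load_weights <- function(path) {
  w <- readRDS(path)
  stopifnot(inherits(w, "esn_weights"))
  w
}

#' Train the Siamese model on labelled bundles
#'
#' Minimizes `BCE(bundle_score, label) + l2_coeff * ||W||^2` with Adam.
#' Every segment of every bundle in a minibatch passes through the one
#' shared encoder in a single batched forward pass; the gradient of the
#' aggregated bundle score is backpropagated through the head and the
#' encoder. Deterministic for a fixed config seed.
#'
#' @param train_bundles Non-empty list of [ecg_bundle()] with both labels
#'   present.
#' @param config An [esn_config()].
#' @param verbose Print per-epoch loss.
#' @return A list with `weights` (class `esn_weights`) and `loss_trace`
#'   (mean training loss per epoch, length `config$epochs`).
#' @export
esn_train <- function(train_bundles, config = esn_config(), verbose = FALSE) {
  stopifnot(inherits(config, "esn_config"))
  if (length(train_bundles) == 0L) abort_invalid("train_bundles must be non-empty")
  labels <- vapply(train_bundles, `[[`, character(1), "label")
  if (length(unique(labels)) < 2L) {
    abort_invalid("training requires both positive and negative bundles")
  }
  n_ref <- length(train_bundles[[1]]$refs)
  L <- nrow(train_bundles[[1]]$probe)
  weights <- esn_init(config, L)
  y_all <- as.numeric(labels == "positive")
  loss_trace <- numeric(config$epochs)
  if (config$epochs == 0L) {
    return(list(weights = weights, loss_trace = loss_trace))
  }
  n <- length(train_bundles)
  with_seed(config$seed + 1L, {
    state <- adam_init(weights$params)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        step <- esn_train_step(weights$params, config, train_bundles[idx],
                               y_all[idx], n_ref)
        grads <- step$grads
        # L2 weight decay on convolution, dense and head weights
        if (config$l2_coeff > 0) {
          for (nm in grep("^cW|^dW$|^hw$", names(weights$params), value = TRUE)) {
            grads[[nm]] <- grads[[nm]] + 2 * config$l2_coeff * weights$params[[nm]]
          }
        }
        upd <- adam_step(weights$params, grads, state, config$learning_rate)
        weights$params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + step$loss * length(idx)
      }
      loss_trace[epoch] <- epoch_loss / n +
        l2_penalty(weights$params, config$l2_coeff)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f", epoch, loss_trace[epoch]))
      }
    }
  })
  list(weights = weights, loss_trace = loss_trace)
}

# One minibatch: forward all (n_ref + 1) * B segments through the shared
# encoder, score bundles, and return the BCE loss plus parameter gradients.
esn_train_step <- function(params, config, bundles, y, n_ref) {
  B <- length(bundles)
  m <- n_ref + 1L
  fms <- vector("list", B * m)
  for (j in seq_len(B)) {
    fms[[(j - 1L) * m + 1L]] <- bundles[[j]]$probe
    for (r in seq_len(n_ref)) fms[[(j - 1L) * m + 1L + r]] <- bundles[[j]]$refs[[r]]
  }
  x <- do.call(rbind, fms)
  fwd <- encoder_forward(params, config, x, B = B * m, cache = TRUE)
  E <- fwd$E

  ip <- (seq_len(B) - 1L) * m + 1L                  # probe rows
  ir <- rep(ip, each = n_ref) + seq_len(n_ref)      # reference rows
  pi <- rep(ip, each = n_ref)
  Dif <- E[pi, , drop = FALSE] - E[ir, , drop = FALSE]
  D <- abs(Dif)
  z <- as.numeric(D %*% params$hw) + params$hb
  s <- sigmoid(z)
  S <- rowMeans(matrix(s, nrow = B, byrow = TRUE))

  eps <- 1e-7
  Sc <- pmin(pmax(S, eps), 1 - eps)
  loss <- mean(-(y * log(Sc) + (1 - y) * log(1 - Sc)))

  dS <- (Sc - y) / (Sc * (1 - Sc)) / B
  g <- rep(dS, each = n_ref) * s * (1 - s) / n_ref  # per-pair dLoss/dz
  grads <- list(hw = as.numeric(crossprod(D, g)), hb = sum(g))

  Tm <- (sign(Dif) * g) * rep(params$hw, each = length(g))
  dE <- matrix(0, nrow(E), ncol(E))
  dEp <- rowsum(Tm, group = pi)
  dE[sort(unique(pi)), ] <- dEp
  dE[ir, ] <- -Tm
  list(loss = loss,
       grads = c(grads, encoder_backward(params, config, fwd, dE, B = B * m)))
}
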