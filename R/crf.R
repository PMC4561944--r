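# Linear-chain conditional random field over sentence sequences, trained by
# penalized maximum likelihood (forward-backward gradients + L-BFGS).
# Feature functions are indicator features given as strings per position;
# emission weights are (feature, label) pairs, plus a dense (label, label)
# transition block and a BOS->label start block.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Train a linear-chain CRF
#'
#' @param x List of sequences; each sequence is a list of character vectors
#'   (the active indicator features at each position).
#' @param y List of label vectors (character), parallel to `x`.
#' @param labels Label set in fixed order (determines tie-breaking and the
#'   parameter layout). Defaults to the sorted unique labels in `y`.
#' @param lambda L2 regularization strength.
#' @param maxit Maximum L-BFGS iterations.
#' @param seed Integer recorded in the model for provenance; training
#'   itself is deterministic (zero initialization).
#' @return An object of class `crf_model`.
#' @export
crf_train <- function(x, y, labels = sort(unique(unlist(y))),
                      lambda = 0.1, maxit = 200L, seed = 0L) {
  stopifnot(length(x) == length(y), length(x) > 0L)
  present <- unique(unlist(y))
  miss <- setdiff(labels, present)
  if (length(miss) > 0L) {
    stop("training data is missing label class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  K <- length(labels)
  feats <- sort(unique(unlist(x)))
  fid <- stats::setNames(seq_along(feats), feats)
  # integer-encode once
  xs <- lapply(x, function(seq) lapply(seq, function(fs) unname(fid[fs])))
  ys <- lapply(y, function(lab) match(lab, labels))
  nf <- length(feats)
  n_emit <- nf * K
  n_par <- n_emit + K * K + K   # emissions, transitions, start
  eidx <- function(f, k) (f - 1L) * K + k
  tidx <- function(kp, k) n_emit + (kp - 1L) * K + k
  sidx <- function(k) n_emit + K * K + k

  obj <- function(w) {
    nll <- 0
    g <- numeric(n_par)
    for (s in seq_along(xs)) {
      seq_f <- xs[[s]]; seq_y <- ys[[s]]; Tn <- length(seq_f)
      emit <- matrix(0, Tn, K)
      for (t in seq_len(Tn)) {
        fs <- seq_f[[t]]
        if (length(fs) > 0L)
          for (k in seq_len(K)) emit[t, k] <- sum(w[eidx(fs, k)])
      }
      trans <- matrix(w[(n_emit + 1L):(n_emit + K * K)], K, K, byrow = TRUE)
      start <- w[(n_emit + K * K + 1L):n_par]
      # forward
      alpha <- matrix(-Inf, Tn, K)
      alpha[1L, ] <- start + emit[1L, ]
      if (Tn > 1L) for (t in 2L:Tn) for (k in seq_len(K))
        alpha[t, k] <- .logsumexp(alpha[t - 1L, ] + trans[, k]) + emit[t, k]
      logZ <- .logsumexp(alpha[Tn, ])
      # backward
      beta <- matrix(0, Tn, K)
      if (Tn > 1L) for (t in (Tn - 1L):1L) for (k in seq_len(K))
        beta[t, k] <- .logsumexp(trans[k, ] + emit[t + 1L, ] + beta[t + 1L, ])
      # gold score
      gold <- start[seq_y[1L]] + sum(emit[cbind(seq_len(Tn), seq_y)])
      if (Tn > 1L) gold <- gold +
        sum(trans[cbind(seq_y[-Tn], seq_y[-1L])])
      nll <- nll + logZ - gold
      # gradients: model expectations minus observed
      post <- exp(alpha + beta - logZ)     # Tn x K marginals
      for (t in seq_len(Tn)) {
        fs <- seq_f[[t]]
        if (length(fs) > 0L) {
          for (k in seq_len(K)) g[eidx(fs, k)] <- g[eidx(fs, k)] + post[t, k]
          g[eidx(fs, seq_y[t])] <- g[eidx(fs, seq_y[t])] - 1
        }
      }
      g[sidx(seq_len(K))] <- g[sidx(seq_len(K))] + post[1L, ]
      g[sidx(seq_y[1L])] <- g[sidx(seq_y[1L])] - 1
      if (Tn > 1L) for (t in 2L:Tn) {
        pm <- outer(alpha[t - 1L, ], emit[t, ] + beta[t, ], "+") + trans
        pm <- exp(pm - logZ)
        for (kp in seq_len(K))
          g[tidx(kp, seq_len(K))] <- g[tidx(kp, seq_len(K))] + pm[kp, ]
        g[tidx(seq_y[t - 1L], seq_y[t])] <- g[tidx(seq_y[t - 1L], seq_y[t])] - 1
      }
    }
    list(value = nll + lambda * sum(w^2), gradient = g + 2 * lambda * w)
  }

  fn <- function(w) obj(w)$value
  gr <- function(w) obj(w)$gradient
  fit <- stats::optim(numeric(n_par), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  structure(list(weights = fit$par, labels = labels, features = feats,
                 lambda = lambda, seed = seed,
                 converged = fit$convergence == 0L,
                 template_hash = hash_object(feats)),
            class = "crf_model")
}

#' Viterbi decoding with a trained CRF
#'
#' @param model A [crf_train()] result.
#' @param x One sequence: a list of character vectors of active features.
#' @return Character vector of predicted labels. Ties break toward the
#'   earlier label in the model's fixed label order.
#' @export
crf_predict <- function(model, x) {
  K <- length(model$labels)
  Tn <- length(x)
  if (Tn == 0L) return(character())
  nf <- length(model$features)
  fid <- stats::setNames(seq_len(nf), model$features)
  n_emit <- nf * K
  w <- model$weights
  trans <- matrix(w[(n_emit + 1L):(n_emit + K * K)], K, K, byrow = TRUE)
  start <- w[(n_emit + K * K + 1L):(n_emit + K * K + K)]
  emit <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) {
    fs <- unname(fid[x[[t]]]); fs <- fs[!is.na(fs)]
    if (length(fs) > 0L)
      for (k in seq_len(K)) emit[t, k] <- sum(w[(fs - 1L) * K + k])
  }
  delta <- matrix(-Inf, Tn, K); back <- matrix(0L, Tn, K)
  delta[1L, ] <- start + emit[1L, ]
  if (Tn > 1L) for (t in 2L:Tn) for (k in seq_len(K)) {
    sc <- delta[t - 1L, ] + trans[, k]
    back[t, k] <- which.max(sc)
    delta[t, k] <- sc[back[t, k]] + emit[t, k]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1L) for (t in (Tn - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  model$labels[path]
}

#' Stable hash of an R object
#'
#' MD5 of the object's canonical serialization; used to fingerprint models
#' and corpora for determinism checks.
#' @param obj Any R object.
#' @return Hex digest string.
#' @export
hash_object <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}
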