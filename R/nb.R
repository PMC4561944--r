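# Multinomial Naive Bayes over token bags with additive (Laplace)
# smoothing; the event model used by the smoking-status and time-attribute
# classifiers.

#' Train a multinomial Naive Bayes classifier
#'
#' @param bags List of character vectors (token multisets, one per
#'   instance).
#' @param labels Character vector of class labels, parallel to `bags`.
#' @param classes Class set in fixed order; determines deterministic
#'   tie-breaking at prediction. Defaults to sorted unique labels.
#' @param alpha Additive smoothing pseudo-count.
#' @param min_count Features seen fewer times than this across the corpus
#'   are dropped (a simple frequency-based feature selection; 1 keeps all).
#' @param seed Integer recorded for provenance; training is deterministic.
#' @return An object of class `nb_model`.
#' @export
nb_train <- function(bags, labels, classes = sort(unique(labels)),
                     alpha = 1, min_count = 1L, seed = 0L) {
  stopifnot(length(bags) == length(labels), length(bags) > 0L)
  miss <- setdiff(classes, unique(labels))
  if (length(miss) > 0L) {
    stop("training data is missing class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  all_tok <- unlist(bags, use.names = FALSE)
  tab <- table(all_tok)
  vocab <- sort(names(tab)[tab >= min_count])
  V <- length(vocab)
  K <- length(classes)
  counts <- matrix(0, K, V, dimnames = list(classes, vocab))
  prior <- numeric(K); names(prior) <- classes
  for (i in seq_along(bags)) {
    k <- labels[i]
    prior[k] <- prior[k] + 1
    tk <- bags[[i]][bags[[i]] %in% vocab]
    if (length(tk) > 0L) {
      tt <- table(tk)
      counts[k, names(tt)] <- counts[k, names(tt)] + as.numeric(tt)
    }
  }
  log_prior <- log(prior) - log(sum(prior))
  log_lik <- log(counts + alpha) - log(rowSums(counts) + alpha * V)
  structure(list(classes = classes, vocab = vocab,
                 log_prior = log_prior, log_lik = log_lik,
                 alpha = alpha,
                 default_ll = log(alpha) - log(rowSums(counts) + alpha * V),
                 seed = seed),
            class = "nb_model")
}

#' Class log-posteriors for a token bag
#' @param model An [nb_train()] result.
#' @param bag Character vector of tokens.
#' @return Named numeric vector of unnormalized log-posteriors, in the
#'   model's class order.
#' @export
nb_scores <- function(model, bag) {
  sc <- model$log_prior
  known <- bag[bag %in% model$vocab]
  if (length(known) > 0L) {
    tt <- table(known)
    sc <- sc + as.numeric(model$log_lik[, names(tt), drop = FALSE] %*% as.numeric(tt))
  }
  # out-of-vocabulary tokens contribute the smoothed unseen likelihood
  n_unk <- length(bag) - length(known)
  if (n_unk > 0L) sc <- sc + n_unk * model$default_ll
  sc
}

#' Predict the class of a token bag
#'
#' Argmax of the posterior; ties break toward the earlier class in the
#' model's fixed class order.
#' @inheritParams nb_scores
#' @return A single class label.
#' @export
nb_predict <- function(model, bag) {
  model$classes[which.max(nb_scores(model, bag))]
}
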