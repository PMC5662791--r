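#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet Allocation with symmetric Dirichlet priors: `alpha` on
#' the document–topic mixtures, `beta` on the topic–word distributions.
#' Token topic assignments are initialized uniformly at random and updated by
#' collapsed Gibbs sweeps in a fixed order (documents in index order, tokens
#' left to right). Point estimates are read off the final sweep's counts:
#' \deqn{\hat\phi_{tw} = (n_{tw} + \beta) / (n_t + V\beta), \quad
#'       \hat\theta_{dt} = (n_{dt} + \alpha) / (n_d + K\alpha).}
#' Results are bit-reproducible given the same corpus, hyperparameters,
#' iteration count and seed.
#'
#' Defaults follow common collapsed-Gibbs practice: `alpha = 50/K`,
#' `beta = 0.1`, 1000 sweeps.
#'
#' @param corpus a `Corpus` (tokenized with the configuration the model
#'   should use).
#' @param K number of topics (>= 1, at most the total token count).
#' @param alpha,beta symmetric Dirichlet hyperparameters (> 0).
#' @param n_iter number of full Gibbs sweeps (>= 1).
#' @param seed integer seed controlling initialization and sampling.
#' @return object of class `LdaModel`: `K`, `alpha`, `beta`, `phi` (K x V,
#'   columns named by word), `theta` (D x K, rows named by doc_id),
#'   `assignments` (list of per-token topic vectors, 1-based), `vocab`,
#'   `doc_ids`, `seed`, `n_iter`.
#' @export
fit_lda <- function(corpus, K, alpha = 50 / K, beta = 0.1,
                    n_iter = 1000L, seed = 1L) {
  stopifnot(inherits(corpus, "Corpus"), K >= 1, alpha > 0, beta > 0,
            n_iter >= 1)
  vocab <- corpus$vocabulary
  if (length(vocab) == 0L) stop("vocabulary empty after tokenization")
  lens <- vapply(corpus$tokens, length, 0L)
  N <- sum(lens)
  if (K > N) stop("K (", K, ") exceeds total token count (", N, ")")
  D <- length(corpus$doc_ids); V <- length(vocab)
  doc <- rep.int(seq_len(D), lens) - 1L
  word <- match(unlist(corpus$tokens), vocab) - 1L

  set.seed(as.integer(seed))
  res <- lda_gibbs_fit_cpp(doc, word, D, V, as.integer(K),
                           alpha, beta, as.integer(n_iter))

  phi <- (res$nkw + beta) / (res$nk + V * beta)
  theta <- (res$ndk + alpha) / (res$nd + K * alpha)
  colnames(phi) <- vocab
  rownames(theta) <- corpus$doc_ids
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 phi = phi, theta = theta,
                 assignments = split(res$z + 1L, doc + 1L),
                 nkw = res$nkw, nk = res$nk,
                 vocab = vocab, doc_ids = corpus$doc_ids,
                 seed = as.integer(seed), n_iter = as.integer(n_iter)),
            class = "LdaModel")
}

#' @export
print.LdaModel <- function(x, ...) {
  cat(sprintf("<LdaModel: K = %d, V = %d, D = %d, alpha = %.3g, beta = %.3g, %d sweeps, seed %d>\n",
              x$K, length(x$vocab), length(x$doc_ids), x$alpha, x$beta,
              x$n_iter, x$seed))
  invisible(x)
}

#' Infer topic proportions for an unseen document (fold-in)
#'
#' Gibbs sampling over the query's token assignments only, with the trained
#' topic–word counts held fixed, so new text never alters the model. The
#' returned proportions \eqn{(n_{qt} + \alpha)/(n_q + K\alpha)} are averaged
#' over the final quarter of sweeps. Out-of-vocabulary tokens are dropped
#' (their number is reported via the `n_oov` attribute); a query with no
#' in-vocabulary tokens returns the uniform prior `1/K`.
#'
#' @param model a fitted `LdaModel`.
#' @param tokens character vector of query tokens.
#' @param n_iter number of fold-in sweeps.
#' @param seed integer seed.
#' @return numeric topic-proportion vector of length `K` (sums to 1), with
#'   attribute `n_oov`.
#' @export
fold_in <- function(model, tokens, n_iter = 100L, seed = 1L) {
  stopifnot(inherits(model, "LdaModel"), n_iter >= 1)
  idx <- match(tokens, model$vocab)
  n_oov <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L)
    return(structure(rep(1 / model$K, model$K), n_oov = n_oov))
  if (is.null(model$nkw)) {
    # deserialized model: reconstruct counts from phi and the topic totals
    V <- length(model$vocab)
    nk <- as.integer(round(model$nk))
    nkw <- round(model$phi * (nk + V * model$beta) - model$beta)
    storage.mode(nkw) <- "integer"
  } else {
    nkw <- model$nkw
    nk <- model$nk
  }
  set.seed(as.integer(seed))
  theta <- lda_fold_in_cpp(idx - 1L, nkw, as.integer(nk),
                           model$alpha, model$beta, as.integer(n_iter))
  structure(as.numeric(theta), n_oov = n_oov)
}

#' Top-weighted words of a topic
#'
#' @param model a fitted `LdaModel`.
#' @param topic_id topic index in `1..K`.
#' @param n number of words (capped at the vocabulary size).
#' @return data frame `word`, `weight` sorted by topic–word probability
#'   descending, ties broken alphabetically.
#' @export
topic_top_words <- function(model, topic_id, n = 20L) {
  stopifnot(inherits(model, "LdaModel"))
  if (topic_id < 1L || topic_id > model$K)
    stop("topic_id out of range [1, ", model$K, "]: ", topic_id)
  w <- model$phi[topic_id, ]
  ord <- order(-w, names(w), method = "radix")
  df <- data.frame(word = names(w)[ord], weight = as.numeric(w[ord]),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  head(df, min(as.integer(n), nrow(df)))
}

#' Dominant topic of a training document
#'
#' The topic with the largest estimated proportion for the document; ties go
#' to the lowest topic index.
#'
#' @param model a fitted `LdaModel`.
#' @param doc_index document position in `1..D`, or a `doc_id` string.
#' @return topic index in `1..K`.
#' @export
dominant_topic <- function(model, doc_index) {
  stopifnot(inherits(model, "LdaModel"))
  if (is.character(doc_index)) doc_index <- match(doc_index, model$doc_ids)
  if (is.na(doc_index) || doc_index < 1L || doc_index > nrow(model$theta))
    stop("invalid document index")
  which.max(model$theta[doc_index, ])
}

#' Corpus log likelihood under a fitted model
#'
#' \eqn{\sum_{d}\sum_{i} \log \sum_t \theta_{dt}\phi_{t,w_{di}}}, the token
#' log likelihood under the point estimates; a convergence diagnostic for
#' the sampler. The corpus must have the same documents as the training
#' corpus (theta is per training document); tokens outside the model
#' vocabulary are ignored.
#'
#' @param model a fitted `LdaModel`.
#' @param corpus a `Corpus` with the model's documents (defaults to
#'   evaluating the model against its own assignments is not possible, so
#'   the training corpus must be passed).
#' @return finite scalar log likelihood.
#' @export
log_likelihood <- function(model, corpus) {
  stopifnot(inherits(model, "LdaModel"), inherits(corpus, "Corpus"))
  if (!identical(corpus$doc_ids, model$doc_ids))
    stop("corpus documents do not match the model's training documents")
  ll <- 0
  for (d in seq_along(corpus$tokens)) {
    idx <- match(corpus$tokens[[d]], model$vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx))
      ll <- ll + sum(log(as.numeric(model$theta[d, ] %*% model$phi[, idx, drop = FALSE])))
  }
  ll
}

#' Serialize a fitted LDA model to a directory
#'
#' Plain-text layout: `vocab.txt` (one word per line), `phi.tsv` and
#' `theta.tsv` (dense matrices), `params.yaml` (K, alpha, beta, n_iter,
#' seed).
#'
#' @param model a fitted `LdaModel`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "LdaModel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(model$vocab, file.path(path, "vocab.txt"))
  write.table(model$phi, file.path(path, "phi.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(model$theta, file.path(path, "theta.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  yaml::write_yaml(list(K = model$K, alpha = model$alpha, beta = model$beta,
                        n_iter = model$n_iter, seed = model$seed,
                        nk = as.integer(model$nk),
                        doc_ids = model$doc_ids),
                   file.path(path, "params.yaml"))
  invisible(path)
}

#' Read a serialized LDA model
#'
#' Counterpart of [write_lda_model()]. Token-level assignments are not
#' serialized; fold-in on a restored model reconstructs the topic totals it
#' needs from `phi` and `theta`.
#'
#' @param path directory written by [write_lda_model()].
#' @return an `LdaModel` (without `assignments`).
#' @export
read_lda_model <- function(path) {
  params <- yaml::read_yaml(file.path(path, "params.yaml"))
  vocab <- readLines(file.path(path, "vocab.txt"))
  phi <- as.matrix(read.delim(file.path(path, "phi.tsv"), row.names = 1,
                              check.names = FALSE))
  rownames(phi) <- NULL
  theta <- as.matrix(read.delim(file.path(path, "theta.tsv"), row.names = 1,
                                check.names = FALSE))
  colnames(phi) <- vocab
  structure(list(K = params$K, alpha = params$alpha, beta = params$beta,
                 phi = phi, theta = theta, assignments = NULL,
                 nkw = NULL, nk = as.integer(params$nk),
                 vocab = vocab, doc_ids = params$doc_ids,
                 seed = params$seed, n_iter = params$n_iter),
            class = "LdaModel")
}
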