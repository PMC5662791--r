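ranked_list <- function(doc_ids, scores, query_id) {
  ord <- order(-scores, doc_ids, method = "radix")
  structure(data.frame(rank = seq_along(ord),
                       doc_id = doc_ids[ord],
                       score = scores[ord],
                       stringsAsFactors = FALSE),
            query_id = query_id, class = c("RankedList", "data.frame"))
}

#' @export
print.RankedList <- function(x, ...) {
  cat(sprintf("<RankedList for query '%s', %d documents>\n",
              attr(x, "query_id"), nrow(x)))
  print.data.frame(head(x, 10L))
  invisible(x)
}

cosine_rows <- function(M, v) {
  # cosine of each row of M against v; zero rows / zero v give 0
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(numeric(nrow(M)))
  num <- as.numeric(M %*% v)
  nr <- sqrt(Matrix::rowSums(M^2))
  out <- numeric(nrow(M))
  ok <- nr > 0
  out[ok] <- num[ok] / (nr[ok] * nv)
  out
}

#' Build a TF-IDF vector space index
#'
#' Term frequency is the raw in-document count; inverse document frequency
#' uses the smoothed convention \eqn{idf(w) = \ln((1+N)/(1+df(w))) + 1}, so a
#' term present in every document gets idf 1 and an unseen term gets the
#' maximum \eqn{\ln(1+N)+1}. Document vectors are TF x IDF, L2-normalized.
#'
#' @param materials a `Corpus` of candidate documents.
#' @return object of class `VsmIndex`: `vocab`, `idf` (named), `doc_vectors`
#'   (sparse docs x terms matrix of unit rows), `doc_ids`, `n_docs`.
#' @export
build_vsm_index <- function(materials) {
  stopifnot(inherits(materials, "Corpus"))
  vocab <- materials$vocabulary
  N <- length(materials$doc_ids)
  lens <- vapply(materials$tokens, length, 0L)
  i <- rep.int(seq_len(N), lens)
  j <- match(unlist(materials$tokens), vocab)
  tf <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                             dims = c(N, length(vocab)),
                             dimnames = list(materials$doc_ids, vocab))
  df <- Matrix::colSums(tf > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  W <- tf %*% Matrix::Diagonal(x = idf)
  nr <- sqrt(Matrix::rowSums(W^2))
  nr[nr == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / nr) %*% W
  dimnames(W) <- list(materials$doc_ids, vocab)
  structure(list(vocab = vocab, idf = stats::setNames(idf, vocab),
                 doc_vectors = W, doc_ids = materials$doc_ids, n_docs = N),
            class = "VsmIndex")
}

#' Score a query against a vector space index
#'
#' The query vector is built with the index's idf table (raw query term
#' counts times idf, L2-normalized; out-of-vocabulary terms are ignored) and
#' compared with every document by cosine similarity. Ties are broken by
#' ascending `doc_id`; a query sharing no terms with the collection scores 0
#' everywhere.
#'
#' @param query_tokens character vector of query tokens.
#' @param index a `VsmIndex`.
#' @param query_id identifier recorded on the ranking.
#' @return a `RankedList` over all indexed documents.
#' @export
score_vsm <- function(query_tokens, index, query_id = NA_character_) {
  stopifnot(inherits(index, "VsmIndex"))
  idx <- match(query_tokens, index$vocab)
  idx <- idx[!is.na(idx)]
  q <- numeric(length(index$vocab))
  if (length(idx)) {
    counts <- tabulate(idx, length(index$vocab))
    q <- counts * index$idf
  }
  scores <- cosine_rows(index$doc_vectors, q)
  ranked_list(index$doc_ids, scores, query_id)
}

#' Topic frequency profile of a query
#'
#' For each in-vocabulary query token \eqn{w} the posterior topic probability
#' under a uniform topic prior, \eqn{P(t|w) = \phi_{tw} / \sum_{t'}
#' \phi_{t'w}}, is accumulated, so `frequencies[t]` is the expected number of
#' query tokens attributable to topic `t`. The entries sum to the number of
#' in-vocabulary tokens and are generally non-integer.
#'
#' @param query_tokens character vector of query tokens.
#' @param model a fitted `LdaModel`.
#' @param query_id identifier recorded on the profile.
#' @return object of class `QueryTopicProfile`: `query_id`, `frequencies`
#'   (length K), `n_oov`.
#' @export
query_topic_frequency <- function(query_tokens, model,
                                  query_id = NA_character_) {
  stopifnot(inherits(model, "LdaModel"))
  idx <- match(query_tokens, model$vocab)
  n_oov <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  freq <- numeric(model$K)
  if (length(idx)) {
    cols <- model$phi[, idx, drop = FALSE]
    p_tw <- sweep(cols, 2L, colSums(cols), "/")
    freq <- rowSums(p_tw)
  }
  structure(list(query_id = query_id, frequencies = freq, n_oov = n_oov),
            class = "QueryTopicProfile")
}

#' Rank documents with the topic modeling-based (TMB) model
#'
#' Cosine similarity between the L1-normalized query topic profile and each
#' training document's topic mixture `theta`. A zero profile (all query
#' tokens out of vocabulary) scores 0 everywhere.
#'
#' @param profile a `QueryTopicProfile` (see [query_topic_frequency()]).
#' @param model the fitted `LdaModel` whose `theta` covers the candidates.
#' @return a `RankedList` over the model's training documents.
#' @export
score_tmb <- function(profile, model) {
  stopifnot(inherits(profile, "QueryTopicProfile"), inherits(model, "LdaModel"))
  s <- sum(profile$frequencies)
  scores <- if (s > 0) cosine_rows(model$theta, profile$frequencies / s)
            else numeric(nrow(model$theta))
  ranked_list(model$doc_ids, scores, profile$query_id)
}

#' Per-concept inverse document frequency table
#'
#' Document frequency of each concept over an annotated collection, turned
#' into the same smoothed idf used by [build_vsm_index()]. Concepts never
#' seen in the collection take the maximum idf \eqn{\ln(1+N)+1}.
#'
#' @param annotations annotation data frame over the collection
#'   (see [annotate_corpus()]).
#' @param n_docs number of documents in the collection.
#' @return named numeric vector of idf values with attribute `n_docs`.
#' @export
concept_idf <- function(annotations, n_docs) {
  stopifnot(n_docs >= 1)
  df <- tapply(annotations$doc_id, annotations$concept_id,
               function(d) length(unique(d)))
  idf <- log((1 + n_docs) / (1 + as.numeric(df))) + 1
  structure(stats::setNames(idf, names(df)), n_docs = n_docs)
}

#' Semantic group frequency profile
#'
#' Aggregates a document's (or question's) concept annotations into a
#' weighted frequency per semantic group: each annotation contributes the
#' idf of its concept, so common concepts count less. With all idf equal to
#' 1 this reduces to raw per-group annotation counts.
#'
#' @param annotations annotation data frame for one owner (see [annotate()]).
#' @param idf_table per-concept idf from [concept_idf()].
#' @param owner_id identifier recorded on the profile.
#' @param groups configured group set.
#' @return object of class `SemanticGroupProfile`: `owner_id`, `frequencies`
#'   (named over `groups`), `n_unknown_concepts` (annotations whose concept
#'   is absent from the idf table; they receive the maximum idf).
#' @export
group_profile <- function(annotations, idf_table, owner_id = NA_character_,
                          groups = semantic_groups()) {
  freq <- stats::setNames(numeric(length(groups)), groups)
  n_unknown <- 0L
  if (nrow(annotations)) {
    w <- unname(idf_table[annotations$concept_id])
    missing <- is.na(w)
    n_unknown <- sum(missing)
    if (n_unknown)
      w[missing] <- log(1 + attr(idf_table, "n_docs")) + 1
    agg <- tapply(w, factor(annotations$semantic_group, levels = groups), sum)
    agg[is.na(agg)] <- 0
    freq[] <- agg
  }
  structure(list(owner_id = owner_id, frequencies = freq,
                 n_unknown_concepts = n_unknown),
            class = "SemanticGroupProfile")
}

#' Rank documents with the semantic group-based (SGB) model
#'
#' Cosine similarity between the query's and each document's semantic group
#' frequency vectors; each semantic group plays the role of a topic.
#'
#' @param query_profile a `SemanticGroupProfile` for the query.
#' @param doc_profiles list of `SemanticGroupProfile`, one per candidate
#'   document (sharing the query's group set).
#' @return a `RankedList` over the candidate documents.
#' @export
score_sgb <- function(query_profile, doc_profiles) {
  stopifnot(inherits(query_profile, "SemanticGroupProfile"))
  groups <- names(query_profile$frequencies)
  M <- do.call(rbind, lapply(doc_profiles, function(p) {
    stopifnot(inherits(p, "SemanticGroupProfile"))
    if (!identical(names(p$frequencies), groups))
      stop("document profile group set differs from the query's")
    p$frequencies
  }))
  doc_ids <- vapply(doc_profiles, function(p) p$owner_id, "")
  scores <- cosine_rows(M, query_profile$frequencies)
  ranked_list(doc_ids, scores, query_profile$owner_id)
}

#' Recommend education materials for a question
#'
#' Dispatch to one of the three matching models and truncate to the top `k`.
#' `resources` bundles the fitted artifacts each model needs:
#' \describe{
#'   \item{vsm}{`index` — a `VsmIndex`.}
#'   \item{tmb}{`lda` — a fitted `LdaModel`.}
#'   \item{sgb}{`lexicon`, `concept_idf`, `doc_profiles`.}
#' }
#'
#' @param query a `Corpus` document given as a list with `doc_id` and `text`,
#'   or a character vector of pre-tokenized query tokens with a `query_id`
#'   attribute.
#' @param model_choice `"vsm"`, `"tmb"`, or `"sgb"`.
#' @param resources named list of fitted resources (see Details).
#' @param k number of materials to return.
#' @param tokenizer tokenizer applied when `query` carries raw text.
#' @return a `RankedList` truncated to `k` rows.
#' @export
recommend <- function(query, model_choice = c("vsm", "tmb", "sgb"),
                      resources, k = 10L,
                      tokenizer = tokenizer_config()) {
  model_choice <- match.arg(model_choice)
  if (is.list(query)) {
    query_id <- query$doc_id
    tokens <- tokenize(query$text, tokenizer)
  } else {
    tokens <- query
    query_id <- attr(query, "query_id")
    if (is.null(query_id)) query_id <- NA_character_
  }
  need <- function(name) {
    if (is.null(resources[[name]]))
      stop("model '", model_choice, "' requires resource '", name, "'")
    resources[[name]]
  }
  ranked <- switch(model_choice,
    vsm = score_vsm(tokens, need("index"), query_id),
    tmb = score_tmb(query_topic_frequency(tokens, need("lda"), query_id),
                    need("lda")),
    sgb = {
      ann <- annotate(tokens, need("lexicon"), doc_id = query_id)
      qp <- group_profile(ann, need("concept_idf"), owner_id = query_id,
                          groups = names(need("doc_profiles")[[1]]$frequencies))
      score_sgb(qp, need("doc_profiles"))
    })
  out <- head(ranked, min(as.integer(k), nrow(ranked)))
  attr(out, "query_id") <- attr(ranked, "query_id")
  class(out) <- class(ranked)
  out
}

#' Write rankings as a TSV run table or TREC-style run file
#'
#' @param runs named list of `RankedList` objects (names are query ids, used
#'   when a list's own `query_id` is missing).
#' @param path output file.
#' @param format `"tsv"` (`query_id`, `rank`, `doc_id`, `score`) or `"trec"`
#'   (`query_id Q0 doc_id rank score tag`).
#' @param tag run tag written in TREC format.
#' @return `path`, invisibly.
#' @export
write_run <- function(runs, path, format = c("tsv", "trec"), tag = "edurec") {
  format <- match.arg(format)
  rows <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    qid <- attr(r, "query_id")
    if (is.null(qid) || is.na(qid)) qid <- names(runs)[i]
    data.frame(query_id = qid, rank = r$rank, doc_id = r$doc_id,
               score = r$score, stringsAsFactors = FALSE)
  }))
  if (format == "tsv") {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(sprintf("%s Q0 %s %d %.6f %s", rows$query_id, rows$doc_id,
                       rows$rank, rows$score, tag), path)
  }
  invisible(path)
}
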