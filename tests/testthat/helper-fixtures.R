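# Small in-code fixtures shared across test files.

toy_corpus <- function(texts, label = "toy", ids = NULL, categories = NULL,
                       tokenizer = tokenizer_config()) {
  df <- data.frame(doc_id = if (is.null(ids)) sprintf("d%02d", seq_along(texts)) else ids,
                   text = texts, stringsAsFactors = FALSE)
  if (!is.null(categories)) df$category <- categories
  corpus(df, label = label, tokenizer = tokenizer)
}

toy_lexicon <- function(rows = NULL) {
  if (is.null(rows))
    rows <- data.frame(
      term = c("blood sugar", "blood", "insulin", "pump", "insulin pump"),
      concept_id = c("C001", "C002", "C003", "C004", "C005"),
      semantic_type = c("PHEN_T1", "ANAT_T1", "CHEM_T1", "DEVI_T1", "DEVI_T2"),
      semantic_group = c("PHEN", "ANAT", "CHEM", "DEVI", "DEVI"),
      stringsAsFactors = FALSE)
  lexicon(rows)
}

# Three disjoint 10-word vocabulary blocks; each document drawn purely from
# one block. The generating block is the oracle topic label.
make_block_corpus <- function(seed = 42, D = 60, len = 40) {
  set.seed(seed)
  words <- matrix(paste0("b", rep(letters[1:3], each = 10), letters[1:10], "x"),
                  nrow = 3, byrow = TRUE)
  block <- rep(1:3, length.out = D)
  text <- vapply(seq_len(D), function(d)
    paste(sample(words[block[d], ], len, replace = TRUE), collapse = " "), "")
  list(corpus = toy_corpus(text, "block", ids = sprintf("d%03d", seq_len(D))),
       block = block, words = words)
}

# Which fitted topic corresponds to vocabulary block b (by top-10 word overlap).
block_topic <- function(model, words, b) {
  which.max(vapply(seq_len(model$K), function(t)
    sum(topic_top_words(model, t, 10)$word %in% words[b, ]), 0))
}

# Build a RankedList directly (bypassing the scorers) for evaluation tests.
fake_ranking <- function(doc_ids, scores, query_id) {
  ord <- order(-scores, doc_ids, method = "radix")
  structure(data.frame(rank = seq_along(ord), doc_id = doc_ids[ord],
                       score = scores[ord], stringsAsFactors = FALSE),
            query_id = query_id, class = c("RankedList", "data.frame"))
}

# Independent dense TF-IDF oracle: plain loops, no shared code with the
# sparse production path.
dense_tfidf <- function(token_lists) {
  vocab <- sort(unique(unlist(token_lists)))
  N <- length(token_lists)
  tf <- matrix(0, N, length(vocab), dimnames = list(NULL, vocab))
  for (d in seq_len(N))
    for (w in token_lists[[d]]) tf[d, w] <- tf[d, w] + 1
  df <- numeric(length(vocab))
  for (j in seq_along(vocab)) df[j] <- sum(tf[, j] > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  W <- tf
  for (d in seq_len(N)) {
    for (j in seq_along(vocab)) W[d, j] <- tf[d, j] * idf[j]
    nrm <- sqrt(sum(W[d, ]^2))
    if (nrm > 0) W[d, ] <- W[d, ] / nrm
  }
  list(W = W, idf = idf, vocab = vocab)
}

# Hand-constructed LdaModel with a prescribed phi/theta (for scoring tests
# that need exact topic-word columns).
fake_lda <- function(phi, theta, doc_ids = NULL, alpha = 0.1, beta = 0.01) {
  if (is.null(doc_ids)) doc_ids <- sprintf("m%02d", seq_len(nrow(theta)))
  rownames(theta) <- doc_ids
  structure(list(K = nrow(phi), alpha = alpha, beta = beta, phi = phi,
                 theta = theta, assignments = NULL, nkw = NULL,
                 nk = rep(100L, nrow(phi)), vocab = colnames(phi),
                 doc_ids = doc_ids, seed = 1L, n_iter = 0L),
            class = "LdaModel")
}
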