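test_that("vector space index matches the smoothed TF-IDF closed forms", {
  one <- build_vsm_index(toy_corpus("aa bb aa"))
  expect_equal(sum(one$doc_vectors[1, ]^2), 1)          # unit L2 norm

  all3 <- build_vsm_index(toy_corpus(c("aa xx", "aa yy", "aa zz")))
  expect_equal(unname(all3$idf["aa"]), 1)               # ln(1) + 1
  expect_equal(unname(all3$idf["xx"]), log(4 / 2) + 1)
})

test_that("the 3-document worked example reproduces hand-computed weights
           and cosines", {
  co <- toy_corpus(c("aa bb", "aa cc", "cc cc"), ids = c("d1", "d2", "d3"))
  idx <- build_vsm_index(co)
  ia <- log(4 / 3) + 1; ib <- log(4 / 2) + 1; ic <- log(4 / 3) + 1
  # d1 = (ia, ib, 0)/||.||, d2 = (ia, 0, ic)/||.||, d3 = (0, 0, 2 ic)/||.||
  n1 <- sqrt(ia^2 + ib^2); n2 <- sqrt(ia^2 + ic^2)
  expect_equal(as.numeric(idx$doc_vectors["d1", c("aa", "bb", "cc")]),
               c(ia / n1, ib / n1, 0), tolerance = 1e-12)
  expect_equal(as.numeric(idx$doc_vectors["d3", c("aa", "bb", "cc")]),
               c(0, 0, 1), tolerance = 1e-12)
  r <- score_vsm("aa", idx, "q")
  expect_equal(r$doc_id, c("d2", "d1", "d3"))           # ia/n2 > ia/n1 > 0
  expect_equal(r$score, c(ia / n2, ia / n1, 0), tolerance = 1e-12)
})

test_that("sparse index equals the independent dense oracle on random corpora", {
  set.seed(31)
  vocab <- paste0(letters[1:12], letters[1:12])
  for (i in 1:25) {
    n <- sample(2:6, 1)
    toks <- lapply(seq_len(n), function(d)
      sample(vocab, sample(3:15, 1), replace = TRUE))
    co <- toy_corpus(vapply(toks, paste, "", collapse = " "))
    idx <- build_vsm_index(co)
    ora <- dense_tfidf(co$tokens)
    expect_equal(unname(as.matrix(idx$doc_vectors[, ora$vocab])),
                 unname(ora$W), tolerance = 1e-9)
    expect_equal(unname(idx$idf[ora$vocab]), ora$idf, tolerance = 1e-9)
  }
})

test_that("VSM scoring gives cosine identity, orthogonality and doc_id ties", {
  co <- toy_corpus(c("aa bb cc", "dd ee ff"), ids = c("d1", "d2"))
  idx <- build_vsm_index(co)
  r <- score_vsm(c("aa", "bb", "cc"), idx, "q")
  expect_equal(r$score[r$doc_id == "d1"], 1.0, tolerance = 1e-12)
  expect_equal(r$score[r$doc_id == "d2"], 0.0)
  # all-OOV query: zero scores in doc_id order
  r0 <- score_vsm("zz", idx, "q")
  expect_equal(r0$score, c(0, 0))
  expect_equal(r0$doc_id, c("d1", "d2"))
})

test_that("query topic frequencies decompose tokens linearly over P(t|w)", {
  # phi column for "aa" proportional to (0.5, 0.3, 0.2); "bb" concentrated
  phi <- rbind(c(0.50, 1e-9), c(0.30, 1e-9), c(0.20, 0.999))
  colnames(phi) <- c("aa", "bb")
  m <- fake_lda(phi, theta = matrix(1 / 3, 2, 3))
  p1 <- query_topic_frequency("bb", m, "q")
  expect_equal(sum(p1$frequencies), 1, tolerance = 1e-9)
  expect_gt(p1$frequencies[3], 0.99)

  p10 <- query_topic_frequency(rep("aa", 10), m, "q")
  expect_equal(p10$frequencies, c(5, 3, 2), tolerance = 1e-9)
  # conservation: totals equal the in-vocabulary token count
  pm <- query_topic_frequency(c(rep("aa", 4), "bb", "oovword"), m, "q")
  expect_equal(sum(pm$frequencies), 5, tolerance = 1e-9)
  expect_equal(pm$n_oov, 1L)
  p0 <- query_topic_frequency("oovword", m, "q")
  expect_equal(sum(p0$frequencies), 0)
})

test_that("TMB scoring is cosine against theta with deterministic ties", {
  phi <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                dimnames = list(NULL, c("aa", "bb")))
  theta <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.2, 0.8))
  m <- fake_lda(phi, theta)
  prof <- structure(list(query_id = "q", frequencies = c(0.8, 0.2), n_oov = 0L),
                    class = "QueryTopicProfile")
  r <- score_tmb(prof, m)
  expect_equal(r$doc_id[1], "m01")
  expect_equal(r$score[1], 1.0, tolerance = 1e-12)
  # alpha -> 0 limit: disjoint support scores 0
  prof2 <- structure(list(query_id = "q", frequencies = c(1, 0), n_oov = 0L),
                     class = "QueryTopicProfile")
  r2 <- score_tmb(prof2, fake_lda(phi, rbind(c(0, 1))))
  expect_equal(r2$score, 0)
  # zero profile scores 0 everywhere
  r3 <- score_tmb(structure(list(query_id = "q", frequencies = c(0, 0),
                                 n_oov = 3L), class = "QueryTopicProfile"), m)
  expect_equal(r3$score, rep(0, 3))
})

test_that("block corpus: single-block queries retrieve block documents first", {
  bc <- make_block_corpus()
  m <- fit_lda(bc$corpus, K = 3, alpha = 0.1, n_iter = 200, seed = 1)
  set.seed(99)
  hits <- vapply(1:20, function(i) {
    b <- sample(1:3, 1)
    q <- sample(bc$words[b, ], 15, replace = TRUE)
    r <- score_tmb(query_topic_frequency(q, m, "q"), m)
    top_doc <- match(r$doc_id[1], bc$corpus$doc_ids)
    bc$block[top_doc] == b
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("semantic group profiles aggregate concept idf additively", {
  idf <- structure(c(C1 = 1.0, C2 = 2.0), n_docs = 10)
  ann <- data.frame(doc_id = "q", start_token = 0:1, end_token = 1:2,
                    concept_id = c("C1", "C1"), semantic_group = "CHEM")
  p <- group_profile(ann, idf, "q")
  expect_equal(unname(p$frequencies["CHEM"]), 2.0)
  expect_equal(sum(p$frequencies), 2.0)

  # all idf = 1 reduces to raw per-group counts
  idf1 <- structure(c(C1 = 1, C2 = 1, C3 = 1), n_docs = 10)
  ann2 <- data.frame(doc_id = "q", start_token = 0:2, end_token = 1:3,
                     concept_id = c("C1", "C2", "C3"),
                     semantic_group = c("DISO", "DISO", "PROC"))
  p2 <- group_profile(ann2, idf1, "q")
  expect_equal(unname(p2$frequencies[c("DISO", "PROC")]), c(2, 1))

  # unknown concept: maximum idf ln(1 + N) + 1, counted and reported
  ann3 <- data.frame(doc_id = "q", start_token = 0, end_token = 1,
                     concept_id = "C99", semantic_group = "PHYS")
  p3 <- group_profile(ann3, idf, "q")
  expect_equal(unname(p3$frequencies["PHYS"]), log(11) + 1)
  expect_equal(p3$n_unknown_concepts, 1L)

  empty <- group_profile(ann3[0, ], idf, "q")
  expect_equal(sum(empty$frequencies), 0)
})

test_that("SGB scoring is scale-invariant cosine over group vectors", {
  mk <- function(id, v) structure(list(owner_id = id,
                                       frequencies = stats::setNames(v, semantic_groups()),
                                       n_unknown_concepts = 0L),
                                  class = "SemanticGroupProfile")
  qv <- c(2, 1, rep(0, 8))
  q <- mk("q", qv)
  docs <- list(mk("d1", 3 * qv), mk("d2", c(0, 0, 5, rep(0, 7))))
  r <- score_sgb(q, docs)
  expect_equal(r$score[r$doc_id == "d1"], 1.0, tolerance = 1e-12)
  expect_equal(r$score[r$doc_id == "d2"], 0.0)     # orthogonal groups
})

test_that("SGB beats a random ranker when relevance is planted in group
           composition", {
  set.seed(41)
  groups <- semantic_groups()
  mk <- function(id, v) structure(list(owner_id = id,
                                       frequencies = stats::setNames(v, groups),
                                       n_unknown_concepts = 0L),
                                  class = "SemanticGroupProfile")
  n_docs <- 20
  hits <- replicate(50, {
    # materials dominated by one group each; query shares one material's group
    dom <- sample(seq_along(groups), n_docs, replace = TRUE)
    docs <- lapply(seq_len(n_docs), function(d) {
      v <- stats::runif(10, 0, 0.3); v[dom[d]] <- 3 + stats::runif(1)
      mk(sprintf("m%02d", d), v)
    })
    g <- sample(unique(dom), 1)
    qv <- stats::runif(10, 0, 0.3); qv[g] <- 2 + stats::runif(1)
    r <- score_sgb(mk("q", qv), docs)
    dom[match(r$doc_id[1], sprintf("m%02d", seq_len(n_docs)))] == g
  })
  # random ranking would hit the planted group in roughly 1/10 of trials
  expect_gt(mean(hits), 0.5)
})

test_that("recommend dispatches, truncates, and is deterministic", {
  gp <- generate_paired_corpora(K = 3, overlap = 0.5, n_questions = 10,
                                n_materials = 8, seed = 21)
  lda <- fit_lda(gp$materials, K = 3, n_iter = 100, seed = 1)
  vsm <- build_vsm_index(gp$materials)
  lex <- generate_lexicon(gp$materials, gp$questions, 0.9, 0.9, seed = 2)
  ann_m <- annotate_corpus(gp$materials, lex)
  cidf <- concept_idf(ann_m, n_docs(gp$materials))
  profs <- lapply(split(ann_m, ann_m$doc_id), function(a)
    group_profile(a, cidf, a$doc_id[1]))
  res <- list(index = vsm, lda = lda, lexicon = lex, concept_idf = cidf,
              doc_profiles = profs)
  q <- list(doc_id = "q0001",
            text = gp$questions$texts[[1]])
  for (mc in c("vsm", "tmb", "sgb")) {
    r1 <- recommend(q, mc, res, k = 1)
    expect_equal(nrow(r1), 1)
    rall <- recommend(q, mc, res, k = 100)
    expect_equal(nrow(rall), 8)                     # k >= corpus size
    expect_identical(recommend(q, mc, res, k = 5), recommend(q, mc, res, k = 5))
    expect_true(all(diff(rall$score) <= 0))
    expect_false(any(is.na(rall$score)))
  }
  expect_error(recommend(q, "bm25", res, k = 1))
  expect_error(recommend(q, "tmb", list(index = vsm), k = 1), "lda")
})

test_that("all three scorers are invariant to duplicating the query text", {
  gp <- generate_paired_corpora(K = 3, overlap = 0.5, n_questions = 5,
                                n_materials = 6, seed = 33)
  lda <- fit_lda(gp$materials, K = 3, n_iter = 100, seed = 1)
  vsm <- build_vsm_index(gp$materials)
  toks <- gp$questions$tokens[[1]]
  twice <- c(toks, toks)
  expect_equal(score_vsm(toks, vsm, "q")$doc_id,
               score_vsm(twice, vsm, "q")$doc_id)
  expect_equal(score_tmb(query_topic_frequency(toks, lda, "q"), lda)$doc_id,
               score_tmb(query_topic_frequency(twice, lda, "q"), lda)$doc_id)
})

test_that("run files are written in TSV and TREC formats", {
  r <- fake_ranking(c("d1", "d2"), c(0.9, 0.4), "q1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_run(list(q1 = r), f, "tsv")
  df <- read.delim(f)
  expect_equal(df$doc_id, c("d1", "d2"))
  f2 <- withr::local_tempfile(fileext = ".run")
  write_run(list(q1 = r), f2, "trec")
  expect_match(readLines(f2)[1], "^q1 Q0 d1 1 0\\.9")
})
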