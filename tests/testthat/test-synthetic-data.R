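test_that("generators are deterministic under a fixed seed", {
  g1 <- generate_lda_corpus(K = 2, V = 15, D = 20, mean_len = 20, seed = 5)
  g2 <- generate_lda_corpus(K = 2, V = 15, D = 20, mean_len = 20, seed = 5)
  expect_identical(g1$corpus$texts, g2$corpus$texts)
  expect_identical(g1$truth$true_phi, g2$truth$true_phi)

  p1 <- generate_paired_corpora(K = 2, overlap = 0.4, n_questions = 10,
                                n_materials = 5, seed = 8)
  p2 <- generate_paired_corpora(K = 2, overlap = 0.4, n_questions = 10,
                                n_materials = 5, seed = 8)
  expect_identical(p1$questions$texts, p2$questions$texts)
  expect_identical(p1$materials$texts, p2$materials$texts)

  l1 <- generate_lexicon(p1$materials, p1$questions, 0.8, 0.8, seed = 3)
  l2 <- generate_lexicon(p2$materials, p2$questions, 0.8, 0.8, seed = 3)
  expect_identical(l1$entries, l2$entries)
})

test_that("K = 1 corpus converges to its topic-word distribution", {
  g <- generate_lda_corpus(K = 1, V = 25, D = 200, mean_len = 50, seed = 2)
  counts <- table(factor(unlist(g$corpus$tokens),
                         levels = colnames(g$truth$true_phi)))
  emp <- as.numeric(counts) / sum(counts)
  tv <- 0.5 * sum(abs(emp - g$truth$true_phi[1, ]))
  expect_lt(tv, 0.05)               # 10,000 tokens, law of large numbers
})

test_that("corpus shapes track their length targets within 3 standard errors", {
  gp <- generate_paired_corpora(K = 4, overlap = 0.3, n_questions = 150,
                                n_materials = 40, seed = 4)
  sq <- corpus_stats(gp$questions); sm <- corpus_stats(gp$materials)
  expect_lt(abs(sq$mean_len - 110), 3 * 36 / sqrt(150))
  expect_lt(abs(sm$mean_len - 968), 3 * 115 / sqrt(40))
  expect_gt(sq$sd_len, 20); expect_lt(sq$sd_len, 50)
})

test_that("the overlap knob controls the cross-corpus vocabulary gap", {
  p0 <- generate_paired_corpora(K = 3, overlap = 0, n_questions = 30,
                                n_materials = 10, seed = 6)
  expect_equal(vocabulary_overlap(p0$questions, p0$materials)$shared, 0)
  # and VSM cross scores vanish by construction
  idx <- build_vsm_index(p0$materials)
  r <- score_vsm(p0$questions$tokens[[1]], idx, "q")
  expect_true(all(r$score == 0))

  p1 <- generate_paired_corpora(K = 3, overlap = 1, n_questions = 30,
                                n_materials = 10, seed = 6)
  # full overlap: the question topic blocks reuse the material blocks
  expect_true(all(p1$questions$vocabulary %in%
                    colnames(p1$truth$phi_materials)))

  pm <- generate_paired_corpora(K = 3, overlap = 0.3, n_questions = 60,
                                n_materials = 20, seed = 6,
                                terms_per_topic = 40)
  # realized shared fraction of each topic block is the planted 0.3
  expect_equal(lengths(pm$truth$shared_terms), rep(12L, 3))
})

test_that("generated lexicons reach their coverage targets and induce
           distinguishable group distributions", {
  gp <- generate_paired_corpora(K = 3, overlap = 0.3, n_questions = 80,
                                n_materials = 20, seed = 7)
  lex <- generate_lexicon(gp$materials, gp$questions, 0.93, 0.91, seed = 1)
  expect_gte(attr(lex, "achieved_coverage_m"), 0.93)
  expect_gte(attr(lex, "achieved_coverage_q"), 0.91)
  # realized mapping rates land near the targets
  st_m <- corpus_stats(gp$materials, annotate_corpus(gp$materials, lex))
  st_q <- corpus_stats(gp$questions, annotate_corpus(gp$questions, lex))
  expect_equal(st_m$mapping_rate, 0.93, tolerance = 0.05)
  expect_equal(st_q$mapping_rate, 0.91, tolerance = 0.05)

  # full coverage maps every token
  full <- generate_lexicon(gp$materials, gp$questions, 1, 1, seed = 1)
  expect_equal(corpus_stats(gp$materials,
                            annotate_corpus(gp$materials, full))$mapping_rate, 1)

  # skewed group mixes emulate differing corpus group distributions
  mixq <- c(DEVI = 0.9, PROC = 0.1); mixm <- c(DEVI = 0.1, PROC = 0.9)
  lex2 <- generate_lexicon(gp$materials, gp$questions, 0.9, 0.9, seed = 2,
                           group_mix_m = mixm, group_mix_q = mixq)
  gd_m <- group_distribution(annotate_corpus(gp$materials, lex2))
  gd_q <- group_distribution(annotate_corpus(gp$questions, lex2))
  tab <- rbind(gd_m$counts[c("DEVI", "PROC")] + 1,
               gd_q$counts[c("DEVI", "PROC")] + 1)
  expect_lt(chi_square_test(tab)$p_value, 0.05)

  expect_error(generate_lexicon(gp$materials, gp$questions, 0.9, 0.9,
                                group_mix_q = c(NOPE = 1), seed = 1),
               "group")
})

test_that("planted gold grades follow latent-topic overlap and admit a
           relevant material for every question", {
  gp <- generate_paired_corpora(K = 5, overlap = 0.3, n_questions = 50,
                                n_materials = 40, seed = 11)
  # all K topics must be some material's dominant topic for the pigeonhole
  expect_setequal(unique(gp$truth$dominant_materials), 1:5)
  gold <- generate_gold(gp$truth, gp$questions$doc_ids, gp$materials$doc_ids)
  twos <- gold[gold$score == 2, ]
  expect_setequal(unique(twos$query_id), gp$questions$doc_ids)

  # grade 2 iff dominant topics match
  for (i in sample(nrow(twos), 10)) {
    q <- twos$query_id[i]; d <- twos$doc_id[i]
    expect_equal(gp$truth$dominant_questions[[q]],
                 gp$truth$dominant_materials[[d]])
  }

  # grade-2 pairs have higher true topic cosine than grade-0 pairs per query
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (q in sample(gp$questions$doc_ids, 10)) {
    tq <- gp$truth$theta_questions[q, ]
    grades <- gold_score(gold, rep(q, n_docs(gp$materials)),
                         gp$materials$doc_ids)
    sims <- apply(gp$truth$theta_materials, 1, cos, a = tq)
    if (any(grades == 2) && any(grades == 0))
      expect_gt(mean(sims[grades == 2]), mean(sims[grades == 0]))
  }

  expect_error(generate_gold(gp$truth, "not-a-question",
                             gp$materials$doc_ids), "unknown")
})

test_that("generator outputs round-trip through the package's own loaders", {
  gp <- generate_paired_corpora(K = 2, overlap = 0.5, n_questions = 6,
                                n_materials = 4, seed = 13)
  dir <- withr::local_tempdir()
  jl <- file.path(dir, "qs.jsonl")
  writeLines(vapply(seq_along(gp$questions$doc_ids), function(i)
    jsonlite::toJSON(list(doc_id = gp$questions$doc_ids[i],
                          text = gp$questions$texts[i],
                          category = gp$questions$categories[i]),
                     auto_unbox = TRUE), ""), jl)
  rt <- load_corpus(jl, "jsonl", label = "questions")
  expect_identical(rt$tokens, gp$questions$tokens)
  expect_identical(rt$categories, gp$questions$categories)
})
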