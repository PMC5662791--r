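rdirichlet <- function(n, alpha) {
  # one Dirichlet draw per row via normalized gammas
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

alpha_word <- function(i, width = 3L) {
  # purely alphabetic word ids ("waaa", "waab", ...) that survive the
  # alphabetic tokenizer unchanged
  out <- character(length(i))
  for (j in seq_along(i)) {
    v <- i[j] - 1L
    s <- character(width)
    for (p in width:1) { s[p] <- letters[v %% 26L + 1L]; v <- v %/% 26L }
    out[j] <- paste0("w", paste(s, collapse = ""))
  }
  out
}

rtrunc_pois <- function(n, lambda, lower) {
  x <- rpois(n, lambda)
  while (any(bad <- x < lower)) x[bad] <- rpois(sum(bad), lambda)
  x
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- round(rnorm(n, mean, sd))
  while (any(bad <- x < lower)) x[bad] <- round(rnorm(sum(bad), mean, sd))
  as.integer(x)
}

sample_doc_tokens <- function(len, theta_d, phi, words) {
  z <- sample.int(nrow(phi), len, replace = TRUE, prob = theta_d)
  w <- integer(len)
  for (t in unique(z)) {
    sel <- z == t
    w[sel] <- sample.int(ncol(phi), sum(sel), replace = TRUE, prob = phi[t, ])
  }
  list(tokens = words[w], z = z)
}

#' Generate a synthetic corpus from the LDA generative process
#'
#' Topics \eqn{\phi_t \sim Dirichlet(\beta)}, document mixtures
#' \eqn{\theta_d \sim Dirichlet(\alpha)}, lengths Poisson(`mean_len`)
#' truncated at 5 tokens, tokens drawn \eqn{z \sim \theta_d}, \eqn{w \sim
#' \phi_z}. The returned truth (true parameters and token assignments) is
#' the oracle for parameter-recovery tests.
#'
#' @param K,V,D topic, vocabulary and document counts.
#' @param mean_len mean document length in tokens.
#' @param alpha,beta symmetric Dirichlet concentrations for the document and
#'   topic distributions.
#' @param seed integer seed; everything is deterministic given it.
#' @return list with `corpus` (a `Corpus`) and `truth` (class
#'   `GeneratorTruth`: `true_phi` with word column names, `true_theta`,
#'   `assignments`, `dominant_topic` named by doc_id).
#' @export
generate_lda_corpus <- function(K, V, D, mean_len = 50, alpha = 0.3,
                                beta = 0.1, seed = 1L) {
  stopifnot(K >= 1, K <= V, D >= 1)
  set.seed(as.integer(seed))
  words <- alpha_word(seq_len(V))
  phi <- rdirichlet(K, rep(beta, V))
  theta <- rdirichlet(D, rep(alpha, K))
  lens <- rtrunc_pois(D, mean_len, 5L)
  docs <- vector("list", D)
  zs <- vector("list", D)
  for (d in seq_len(D)) {
    s <- sample_doc_tokens(lens[d], theta[d, ], phi, words)
    docs[[d]] <- s$tokens
    zs[[d]] <- s$z
  }
  ids <- sprintf("d%04d", seq_len(D))
  corp <- corpus(data.frame(doc_id = ids,
                            text = vapply(docs, paste, "", collapse = " "),
                            stringsAsFactors = FALSE),
                 label = "synthetic-lda")
  colnames(phi) <- words
  rownames(theta) <- ids
  truth <- structure(list(true_phi = phi, true_theta = theta,
                          assignments = stats::setNames(zs, ids),
                          dominant_topic = stats::setNames(
                            apply(theta, 1L, which.max), ids)),
                     class = "GeneratorTruth")
  list(corpus = corp, truth = truth)
}

#' Generate paired question/material corpora with a controllable
#' vocabulary gap
#'
#' Emulates the two-corpus structure of a consumer-question collection and
#' an education-material collection that share latent topics but diverge in
#' surface vocabulary. Each of the `K` topics owns a block of
#' `terms_per_topic` material terms and a block of question terms that
#' shares a fraction `overlap` of them (the rest are question-only words).
#' Documents draw a topic mixture from Dirichlet(`doc_topic_alpha`), then
#' tokens from their corpus's per-topic word distribution
#' (Dirichlet(`word_conc`) within the block). Lengths are truncated-normal:
#' questions mean 110 (SD 36, floor 10), materials mean 968 (SD 115, floor
#' 100) — the corpus shape of a forum-question vs education-material pairing.
#'
#' @param K number of shared latent topics.
#' @param overlap fraction of each topic's material block reused by its
#'   question block (0 = fully disjoint vocabularies, 1 = one shared
#'   vocabulary).
#' @param n_questions,n_materials corpus sizes.
#' @param seed integer seed.
#' @param q_len_mean,q_len_sd,m_len_mean,m_len_sd length distribution
#'   parameters.
#' @param terms_per_topic block size per topic per corpus.
#' @param doc_topic_alpha,word_conc Dirichlet concentrations.
#' @param categories optional: label each question with its dominant topic
#'   (`"cat<k>"`), giving a categorized question corpus (default TRUE).
#' @return list with `questions`, `materials` (Corpus objects) and `truth`
#'   (class `GeneratorTruth`: per-corpus true theta and dominant topics,
#'   per-corpus topic-word matrices, shared-term list).
#' @export
generate_paired_corpora <- function(K, overlap = 0.3, n_questions = 200L,
                                    n_materials = 40L, seed = 1L,
                                    q_len_mean = 110, q_len_sd = 36,
                                    m_len_mean = 968, m_len_sd = 115,
                                    terms_per_topic = 30L,
                                    doc_topic_alpha = 0.3, word_conc = 0.2,
                                    categories = TRUE) {
  stopifnot(K >= 1, overlap >= 0, overlap <= 1, n_questions >= 1,
            n_materials >= 1)
  set.seed(as.integer(seed))
  B <- as.integer(terms_per_topic)
  n_shared <- as.integer(round(overlap * B))

  all_words <- alpha_word(seq_len(K * (2L * B)))  # generous pool
  ptr <- 0L
  m_blocks <- vector("list", K); q_blocks <- vector("list", K)
  shared_terms <- vector("list", K)
  for (t in seq_len(K)) {
    m_blocks[[t]] <- all_words[ptr + seq_len(B)]; ptr <- ptr + B
    sh <- if (n_shared > 0) sample(m_blocks[[t]], n_shared) else character(0)
    extra <- if (B - n_shared > 0) {
      w <- all_words[ptr + seq_len(B - n_shared)]; ptr <- ptr + B - n_shared; w
    } else character(0)
    q_blocks[[t]] <- c(sh, extra)
    shared_terms[[t]] <- sh
  }

  block_phi <- function(blocks) {
    vocab <- unlist(blocks)
    phi <- matrix(0, K, length(vocab))
    colnames(phi) <- vocab
    for (t in seq_len(K)) {
      p <- rdirichlet(1L, rep(word_conc, length(blocks[[t]])))
      phi[t, blocks[[t]]] <- p
    }
    phi
  }
  phi_m <- block_phi(m_blocks)
  phi_q <- block_phi(q_blocks)

  gen_side <- function(n, prefix, phi, len_mean, len_sd, len_floor) {
    theta <- rdirichlet(n, rep(doc_topic_alpha, K))
    lens <- rtrunc_norm(n, len_mean, len_sd, len_floor)
    words <- colnames(phi)
    texts <- character(n)
    for (d in seq_len(n)) {
      s <- sample_doc_tokens(lens[d], theta[d, ], phi, words)
      texts[d] <- paste(s$tokens, collapse = " ")
    }
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    rownames(theta) <- ids
    list(ids = ids, texts = texts, theta = theta,
         dominant = stats::setNames(apply(theta, 1L, which.max), ids))
  }
  m <- gen_side(n_materials, "m", phi_m, m_len_mean, m_len_sd, 100L)
  q <- gen_side(n_questions, "q", phi_q, q_len_mean, q_len_sd, 10L)

  materials <- corpus(data.frame(doc_id = m$ids, text = m$texts,
                                 stringsAsFactors = FALSE),
                      label = "materials")
  qdf <- data.frame(doc_id = q$ids, text = q$texts, stringsAsFactors = FALSE)
  if (categories) qdf$category <- sprintf("cat%d", q$dominant)
  questions <- corpus(qdf, label = "questions")

  truth <- structure(list(phi_questions = phi_q, phi_materials = phi_m,
                          theta_questions = q$theta,
                          theta_materials = m$theta,
                          dominant_questions = q$dominant,
                          dominant_materials = m$dominant,
                          shared_terms = shared_terms,
                          overlap = overlap, K = K),
                     class = "GeneratorTruth")
  list(questions = questions, materials = materials, truth = truth)
}

#' Generate a synthetic concept lexicon hitting target mapping rates
#'
#' Samples vocabulary terms (in seeded random order) into the lexicon until
#' the expected fraction of word tokens covered in each corpus reaches its
#' target: first terms carrying material tokens until `coverage_m` is
#' reached, then further terms carrying question tokens until `coverage_q`.
#' Each selected term becomes a single-token entry with a synthetic concept
#' id and a semantic group drawn from a per-corpus group mix, so the two
#' corpora end up with distinguishable group distributions.
#'
#' @param materials,questions `Corpus` objects.
#' @param coverage_m,coverage_q target token coverage fractions in (0, 1].
#' @param groups configured group set.
#' @param seed integer seed.
#' @param group_mix_m,group_mix_q named probability vectors over `groups`;
#'   defaults emphasize procedures/disorders for materials and chemicals &
#'   drugs/physiology/devices for questions.
#' @return a `Lexicon` with attributes `achieved_coverage_m`,
#'   `achieved_coverage_q` (expected coverages realized by the selection).
#' @export
generate_lexicon <- function(materials, questions, coverage_m = 0.9331,
                             coverage_q = 0.9118,
                             groups = semantic_groups(), seed = 1L,
                             group_mix_m = NULL, group_mix_q = NULL) {
  stopifnot(inherits(materials, "Corpus"), inherits(questions, "Corpus"),
            coverage_m > 0, coverage_m <= 1, coverage_q > 0, coverage_q <= 1)
  if (is.null(group_mix_m))
    group_mix_m <- c(ANAT = 0.12, CHEM = 0.07, DEVI = 0.03, DISO = 0.20,
                     GENE = 0.01, LIVB = 0.12, OBJC = 0.10, PHEN = 0.09,
                     PHYS = 0.06, PROC = 0.20)
  if (is.null(group_mix_q))
    group_mix_q <- c(ANAT = 0.07, CHEM = 0.18, DEVI = 0.11, DISO = 0.14,
                     GENE = 0.04, LIVB = 0.08, OBJC = 0.06, PHEN = 0.06,
                     PHYS = 0.16, PROC = 0.10)
  if (!all(names(group_mix_m) %in% groups) ||
      !all(names(group_mix_q) %in% groups))
    stop("group mix names must lie in the configured group set")

  set.seed(as.integer(seed))
  cnt_m <- table(unlist(materials$tokens))
  cnt_q <- table(unlist(questions$tokens))
  tot_m <- sum(cnt_m); tot_q <- sum(cnt_q)
  pool <- sample(union(names(cnt_m), names(cnt_q)))
  freq_m <- stats::setNames(rep(0, length(pool)), pool)
  freq_m[names(cnt_m)[names(cnt_m) %in% pool]] <- as.numeric(cnt_m[names(cnt_m) %in% pool])
  freq_q <- stats::setNames(rep(0, length(pool)), pool)
  freq_q[names(cnt_q)[names(cnt_q) %in% pool]] <- as.numeric(cnt_q[names(cnt_q) %in% pool])

  taken <- logical(length(pool))
  origin_v <- character(length(pool))
  cum_m <- 0; cum_q <- 0
  for (i in seq_along(pool)) {              # pass 1: material coverage
    if (cum_m / tot_m >= coverage_m) break
    if (freq_m[i] == 0) next
    taken[i] <- TRUE; origin_v[i] <- "m"
    cum_m <- cum_m + freq_m[i]
    cum_q <- cum_q + freq_q[i]
  }
  for (i in seq_along(pool)) {              # pass 2: question coverage
    if (cum_q / tot_q >= coverage_q) break
    if (taken[i] || freq_q[i] == 0) next
    taken[i] <- TRUE; origin_v[i] <- "q"
    cum_m <- cum_m + freq_m[i]
    cum_q <- cum_q + freq_q[i]
  }
  selected <- pool[taken]
  origin <- origin_v[taken]
  if (cum_m / tot_m < coverage_m || cum_q / tot_q < coverage_q)
    stop(sprintf("coverage targets unreachable: achieved %.4f / %.4f",
                 cum_m / tot_m, cum_q / tot_q))

  grp <- character(length(selected))
  is_m <- origin == "m"
  if (any(is_m))
    grp[is_m] <- sample(names(group_mix_m), sum(is_m), replace = TRUE,
                        prob = group_mix_m)
  if (any(!is_m))
    grp[!is_m] <- sample(names(group_mix_q), sum(!is_m), replace = TRUE,
                         prob = group_mix_q)

  lex <- lexicon(data.frame(term = selected,
                            concept_id = sprintf("C%07d", seq_along(selected)),
                            semantic_type = paste0(grp, "_T1"),
                            semantic_group = grp, stringsAsFactors = FALSE),
                 groups = groups, tokenizer = materials$tokenizer)
  attr(lex, "achieved_coverage_m") <- unname(cum_m / tot_m)
  attr(lex, "achieved_coverage_q") <- unname(cum_q / tot_q)
  lex
}

#' Plant a graded gold standard from generator truth
#'
#' Relevance is induced by latent-topic overlap: a material whose dominant
#' topic equals the question's dominant topic is fully relevant (grade 2); a
#' material whose dominant topic carries question weight in
#' `[partial_lo, partial_hi)` is partially relevant (grade 1); anything else
#' is not relevant (grade 0, omitted from the table).
#'
#' @param truth a `GeneratorTruth` from [generate_paired_corpora()].
#' @param query_ids question ids to judge.
#' @param doc_ids material ids to judge against.
#' @param partial_lo,partial_hi grade-1 window on the question's topic
#'   weight (defaults 0.2 and 0.5).
#' @return a `GoldStandard` listing all grade-1 and grade-2 pairs.
#' @export
generate_gold <- function(truth, query_ids, doc_ids,
                          partial_lo = 0.2, partial_hi = 0.5) {
  stopifnot(inherits(truth, "GeneratorTruth"))
  if (!all(query_ids %in% rownames(truth$theta_questions)))
    stop("unknown query ids in truth")
  if (!all(doc_ids %in% rownames(truth$theta_materials)))
    stop("unknown material ids in truth")
  rows <- list()
  for (q in query_ids) {
    tq <- truth$theta_questions[q, ]
    dq <- truth$dominant_questions[q]
    for (d in doc_ids) {
      dd <- truth$dominant_materials[d]
      score <- if (dd == dq) 2L
               else if (tq[dd] >= partial_lo && tq[dd] < partial_hi) 1L
               else 0L
      if (score > 0L)
        rows[[length(rows) + 1L]] <- data.frame(query_id = q, doc_id = d,
                                                score = score,
                                                stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(gold_standard(data.frame(query_id = character(0),
                                    doc_id = character(0),
                                    score = integer(0))))
  gold_standard(do.call(rbind, rows))
}

#' Greedy/exact topic matching and total-variation distance
#'
#' Aligns estimated topics with true topics by the permutation minimizing
#' the mean total-variation distance between matched topic-word rows (exact
#' search for K <= 8, greedy otherwise) over the shared vocabulary.
#'
#' @param true_phi,est_phi K x V topic-word matrices with word column names.
#' @return list with `permutation` (est topic for each true topic) and
#'   `mean_tv` (mean matched total-variation distance).
#' @export
match_topics <- function(true_phi, est_phi) {
  stopifnot(nrow(true_phi) == nrow(est_phi))
  vocab <- union(colnames(true_phi), colnames(est_phi))
  pad <- function(phi) {
    M <- matrix(0, nrow(phi), length(vocab))
    colnames(M) <- vocab
    M[, colnames(phi)] <- phi
    M
  }
  tp <- pad(true_phi); ep <- pad(est_phi)
  K <- nrow(tp)
  tv <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    tv[i, j] <- 0.5 * sum(abs(tp[i, ] - ep[j, ]))
  if (K <= 8L) {
    perms <- permutations_of(K)
    costs <- vapply(perms, function(p) mean(tv[cbind(seq_len(K), p)]), 0)
    best <- perms[[which.min(costs)]]
  } else {
    best <- integer(K); used <- logical(K)
    for (i in seq_len(K)) {
      cand <- order(tv[i, ])
      best[i] <- cand[!used[cand]][1L]
      used[best[i]] <- TRUE
    }
  }
  list(permutation = best, mean_tv = mean(tv[cbind(seq_len(K), best)]))
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}
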