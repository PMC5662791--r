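#' Relevance judgment table constructor / validator
#'
#' Graded judgments on question–material pairs: 0 = not relevant, 1 =
#' partially relevant, 2 = most relevant. One row per (query, document,
#' annotator).
#'
#' @param query_id,doc_id,annotator character vectors.
#' @param score integer vector with values in \{0, 1, 2\}.
#' @return data frame of class `RelevanceJudgments`.
#' @export
judgments <- function(query_id, doc_id, annotator, score) {
  score <- as.integer(score)
  if (!all(score %in% 0:2)) stop("scores must be in {0, 1, 2}")
  df <- data.frame(query_id = as.character(query_id),
                   doc_id = as.character(doc_id),
                   annotator = as.character(annotator),
                   score = score, stringsAsFactors = FALSE)
  key <- paste(df$query_id, df$doc_id, df$annotator, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (query_id, doc_id, annotator) judgment")
  class(df) <- c("RelevanceJudgments", "data.frame")
  df
}

#' Read a judgments TSV (query_id, doc_id, annotator, score)
#' @param path TSV file with those four header columns.
#' @return a `RelevanceJudgments` data frame.
#' @export
read_judgments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  judgments(df$query_id, df$doc_id, df$annotator, df$score)
}

align_judgments <- function(a, b) {
  # align two annotators on identical (query_id, doc_id) pair sets
  if (is.numeric(a) && is.numeric(b)) {
    if (length(a) != length(b)) stop("judgment vectors differ in length")
    return(cbind(as.integer(a), as.integer(b)))
  }
  ka <- paste(a$query_id, a$doc_id, sep = "\r")
  kb <- paste(b$query_id, b$doc_id, sep = "\r")
  if (!setequal(ka, kb) || length(ka) != length(kb))
    stop("the two annotators do not judge the same (query, document) pairs")
  cbind(a$score, b$score[match(ka, kb)])
}

#' Weighted Cohen kappa for ordinal relevance judgments
#'
#' Chance-corrected agreement \eqn{\kappa = 1 - \sum w_{ij} O_{ij} / \sum
#' w_{ij} E_{ij}} over the 3 x 3 table of the grades \{0,1,2\}, with
#' disagreement weights \eqn{w_{ij} = |i-j|/(c-1)} (linear, default) or
#' \eqn{(i-j)^2/(c-1)^2} (quadratic). `O` holds observed pair proportions
#' and `E` the outer product of the two annotators' marginals. Two identical
#' gradings give kappa 1 by convention even when constant.
#'
#' @param a,b either `RelevanceJudgments` data frames over the same pair set
#'   or two aligned integer vectors of grades.
#' @param weighting `"linear"` or `"quadratic"`.
#' @return object of class `AgreementResult` with `kappa`, `weighting`,
#'   `n_pairs`.
#' @export
weighted_kappa <- function(a, b, weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  m <- align_judgments(a, b)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 judged pairs")
  if (!all(m %in% 0:2)) stop("scores must be in {0, 1, 2}")
  lev <- 0:2
  O <- table(factor(m[, 1], lev), factor(m[, 2], lev)) / n
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(lev, lev, "-")) / (length(lev) - 1)
  W <- if (weighting == "linear") d else d^2
  denom <- sum(W * E)
  kappa <- if (denom == 0) {
    if (sum(W * O) == 0) 1 else stop("kappa undefined: disjoint constant annotations")
  } else 1 - sum(W * O) / denom
  structure(list(kappa = kappa, weighting = weighting, n_pairs = n),
            class = "AgreementResult")
}

#' @export
print.AgreementResult <- function(x, ...) {
  cat(sprintf("<weighted kappa (%s) = %.4f over %d pairs>\n",
              x$weighting, x$kappa, x$n_pairs))
  invisible(x)
}

#' Consensus gold standard from two annotators
#'
#' Pairs where the annotators agree take the shared grade; every
#' disagreement must be adjudicated via `resolved`, otherwise the full list
#' of unresolved pairs is reported as an error.
#'
#' @param a,b `RelevanceJudgments` over the same pair set.
#' @param resolved optional data frame `query_id`, `doc_id`, `score` of
#'   adjudicated grades for disagreeing pairs.
#' @return object of class `GoldStandard`: data frame `query_id`, `doc_id`,
#'   `score`; unjudged pairs implicitly score 0 (see [gold_score()]).
#' @export
consensus <- function(a, b, resolved = NULL) {
  m <- align_judgments(a, b)
  key_a <- paste(a$query_id, a$doc_id, sep = "\r")
  out <- data.frame(query_id = a$query_id, doc_id = a$doc_id,
                    score = m[, 1], stringsAsFactors = FALSE)
  disagree <- m[, 1] != m[, 2]
  if (any(disagree)) {
    if (is.null(resolved))
      stop("unresolved disagreements: ",
           paste(paste0("(", out$query_id[disagree], ", ",
                        out$doc_id[disagree], ")"), collapse = ", "))
    rkey <- paste(resolved$query_id, resolved$doc_id, sep = "\r")
    hit <- match(key_a[disagree], rkey)
    if (anyNA(hit))
      stop("unresolved disagreements: ",
           paste(paste0("(", out$query_id[disagree][is.na(hit)], ", ",
                        out$doc_id[disagree][is.na(hit)], ")"),
                 collapse = ", "))
    out$score[disagree] <- as.integer(resolved$score[hit])
  }
  gold_standard(out)
}

#' Construct a gold standard from consensus scores
#'
#' @param df data frame `query_id`, `doc_id`, `score` (grades 0/1/2); rows
#'   with grade 0 may be omitted — unlisted pairs default to 0.
#' @return object of class `GoldStandard`.
#' @export
gold_standard <- function(df) {
  stopifnot(all(c("query_id", "doc_id", "score") %in% names(df)))
  score <- as.integer(df$score)
  if (!all(score %in% 0:2)) stop("scores must be in {0, 1, 2}")
  out <- data.frame(query_id = as.character(df$query_id),
                    doc_id = as.character(df$doc_id),
                    score = score, stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$query_id, out$doc_id, sep = "\r")))
    stop("duplicate (query_id, doc_id) in gold standard")
  class(out) <- c("GoldStandard", "data.frame")
  out
}

#' Look up gold grades for (query, document) pairs
#'
#' @param gold a `GoldStandard`.
#' @param query_id,doc_id equal-length character vectors.
#' @return integer grades; pairs absent from the gold table score 0.
#' @export
gold_score <- function(gold, query_id, doc_id) {
  stopifnot(inherits(gold, "GoldStandard"))
  key <- paste(gold$query_id, gold$doc_id, sep = "\r")
  hit <- match(paste(query_id, doc_id, sep = "\r"), key)
  ifelse(is.na(hit), 0L, gold$score[hit])
}

#' Precision at rank k with graded partial credit
#'
#' \deqn{P(k) = (\textrm{number of relevant documents in the top } k) / k}
#' where a fully relevant document (grade 2) counts 1, a partially relevant
#' one (grade 1) counts 0.5, and unjudged or grade-0 documents count 0.
#' When the ranking is shorter than `k`, `k` is capped at the list length.
#'
#' @param ranked a `RankedList`.
#' @param gold a `GoldStandard`.
#' @param k rank cutoff (>= 1).
#' @return precision in `[0, 1]`.
#' @export
precision_at_k <- function(ranked, gold, k) {
  stopifnot(inherits(ranked, "RankedList"), k >= 1)
  kk <- min(as.integer(k), nrow(ranked))
  grades <- gold_score(gold, rep(attr(ranked, "query_id"), kk),
                       ranked$doc_id[seq_len(kk)])
  credit <- c(0, 0.5, 1)[grades + 1L]
  sum(credit) / kk
}

#' Mean precision curve over a query set
#'
#' Mean of [precision_at_k()] over all queries of a run, at each requested
#' cutoff — one row per k.
#'
#' @param runs named list of `RankedList` objects, one per query.
#' @param gold a `GoldStandard` covering every query in `runs`.
#' @param ks rank cutoffs (default `c(1:5, 10, 20)`).
#' @param label model label attached to the curve.
#' @return data frame of class `PrecisionCurve` with columns `k`,
#'   `precision`, and attribute `label`.
#' @export
precision_curve <- function(runs, gold, ks = c(1:5, 10L, 20L),
                            label = "model") {
  stopifnot(inherits(gold, "GoldStandard"), length(runs) >= 1)
  qids <- vapply(runs, function(r) attr(r, "query_id"), "")
  missing <- setdiff(qids, unique(gold$query_id))
  if (length(missing))
    stop("queries missing from the gold standard: ",
         paste(missing, collapse = ", "))
  prec <- vapply(ks, function(k)
    mean(vapply(runs, precision_at_k, 0, gold = gold, k = k)), 0)
  structure(data.frame(k = as.integer(ks), precision = prec),
            label = label, class = c("PrecisionCurve", "data.frame"))
}

#' Random query sample for gold-standard construction
#'
#' Uniform sample of `n` document ids without replacement, deterministic
#' under `seed`.
#'
#' @param corpus a `Corpus`.
#' @param n sample size (<= corpus size).
#' @param seed integer seed.
#' @return character vector of sampled doc_ids.
#' @export
sample_queries <- function(corpus, n, seed = 1L) {
  stopifnot(inherits(corpus, "Corpus"))
  if (n > length(corpus$doc_ids))
    stop("n (", n, ") exceeds corpus size (", length(corpus$doc_ids), ")")
  set.seed(as.integer(seed))
  sample(corpus$doc_ids, n)
}

#' Write a gold standard as a qrels-style file
#'
#' Lines `query_id 0 doc_id grade`, the conventional interchange format for
#' graded relevance judgments, preceded by `#`-comment provenance headers.
#'
#' @param gold a `GoldStandard`.
#' @param path output file.
#' @param provenance optional named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(gold, path, provenance = NULL) {
  stopifnot(inherits(gold, "GoldStandard"))
  hdr <- c("# qrels: query_id 0 doc_id grade",
           if (!is.null(provenance))
             sprintf("# %s: %s", names(provenance),
                     vapply(provenance, function(v) paste(v, collapse = " "), "")))
  writeLines(c(hdr, sprintf("%s 0 %s %d", gold$query_id, gold$doc_id,
                            gold$score)), path)
  invisible(path)
}
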