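#' Default clinical semantic groups
#'
#' The ten coarse semantic groups used throughout the package: anatomy
#' (ANAT), chemicals & drugs (CHEM), devices (DEVI), disorders (DISO), genes
#' & molecular sequences (GENE), living beings (LIVB), objects (OBJC),
#' phenomena (PHEN), physiology (PHYS) and procedures (PROC). Pass
#' `extra = "CONC"` (concepts & ideas) or any other group codes to extend
#' the configured set.
#'
#' @param extra additional group codes to append.
#' @return character vector of group codes.
#' @export
semantic_groups <- function(extra = character(0)) {
  c("ANAT", "CHEM", "DEVI", "DISO", "GENE", "LIVB", "OBJC", "PHEN",
    "PHYS", "PROC", extra)
}

new_lexicon <- function(entries, groups) {
  # hash from normalized term to its entry rows for O(1) span lookup
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (term in unique(entries$term))
    assign(term, which(entries$term == term), envir = index)
  structure(list(entries = entries,
                 groups = groups,
                 index = index,
                 max_term_tokens = max(entries$n_tokens)),
            class = "Lexicon")
}

#' @export
print.Lexicon <- function(x, ...) {
  cat(sprintf("<Lexicon: %d entries, %d distinct terms, groups {%s}>\n",
              nrow(x$entries), length(unique(x$entries$term)),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Build a concept lexicon from a data frame
#'
#' The lexicon is a deterministic stand-in for a licensed terminology plus
#' concept mapper: each entry maps a term (1–5 tokens after normalization)
#' to a concept identifier, a semantic type, and one semantic group from the
#' configured group set. Terms are normalized with the supplied tokenizer;
#' duplicate (term, concept_id) rows are collapsed.
#'
#' @param entries data frame with columns `term`, `concept_id`,
#'   `semantic_type`, `semantic_group`.
#' @param groups configured group set (default [semantic_groups()]).
#' @param tokenizer tokenizer used to normalize terms.
#' @return object of class `Lexicon`.
#' @export
lexicon <- function(entries, groups = semantic_groups(),
                    tokenizer = tokenizer_config()) {
  req <- c("term", "concept_id", "semantic_type", "semantic_group")
  if (!all(req %in% names(entries)))
    stop("lexicon requires columns: ", paste(req, collapse = ", "))
  if (nrow(entries) == 0L) stop("empty lexicon")
  bad <- setdiff(unique(entries$semantic_group), groups)
  if (length(bad))
    stop("unknown semantic_group: ", paste(bad, collapse = ", "))
  norm <- lapply(as.character(entries$term), tokenize, config = tokenizer)
  n_tok <- vapply(norm, length, 0L)
  if (any(n_tok == 0L))
    stop("lexicon term empty after normalization: ",
         paste(entries$term[n_tok == 0L], collapse = ", "))
  if (any(n_tok > 5L))
    stop("lexicon term longer than 5 tokens: ",
         paste(entries$term[n_tok > 5L], collapse = ", "))
  df <- data.frame(term = vapply(norm, paste, "", collapse = " "),
                   concept_id = as.character(entries$concept_id),
                   semantic_type = as.character(entries$semantic_type),
                   semantic_group = as.character(entries$semantic_group),
                   n_tokens = n_tok, stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("term", "concept_id")]), , drop = FALSE]
  rownames(df) <- NULL
  new_lexicon(df, groups)
}

#' Load a concept lexicon from a TSV file
#'
#' @param path TSV file with header columns `term`, `concept_id`,
#'   `semantic_type`, `semantic_group`.
#' @inheritParams lexicon
#' @return a `Lexicon`.
#' @export
load_lexicon <- function(path, groups = semantic_groups(),
                         tokenizer = tokenizer_config()) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                   comment.char = "#")
  lexicon(df, groups = groups, tokenizer = tokenizer)
}

#' Annotate a token sequence with lexicon concepts
#'
#' Greedy left-to-right longest-match scan: at each position the longest
#' matching lexicon term (up to 5 tokens) is taken, the covered span is
#' consumed, and scanning resumes after it, so spans never overlap. A term
#' mapped to several concepts emits one annotation per concept on the same
#' span. No word-sense disambiguation is attempted; the mapping is fully
#' deterministic.
#'
#' @param tokens character vector of tokens (from the configured tokenizer).
#' @param lex a `Lexicon`.
#' @param doc_id document identifier recorded on each annotation.
#' @return data frame with columns `doc_id`, `start_token` (0-based),
#'   `end_token` (exclusive), `concept_id`, `semantic_group`; zero rows when
#'   nothing matches.
#' @export
annotate <- function(tokens, lex, doc_id = NA_character_) {
  stopifnot(inherits(lex, "Lexicon"))
  n <- length(tokens)
  starts <- integer(0); ends <- integer(0); rows <- integer(0)
  i <- 1L
  maxlen <- lex$max_term_tokens
  while (i <= n) {
    hit <- 0L
    for (L in seq.int(min(maxlen, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      idx <- get0(key, envir = lex$index, inherits = FALSE)
      if (!is.null(idx)) {
        starts <- c(starts, rep(i - 1L, length(idx)))
        ends <- c(ends, rep(i - 1L + L, length(idx)))
        rows <- c(rows, idx)
        hit <- L
        break
      }
    }
    i <- i + max(hit, 1L)
  }
  data.frame(doc_id = rep(doc_id, length(rows)),
             start_token = starts,
             end_token = ends,
             concept_id = lex$entries$concept_id[rows],
             semantic_group = lex$entries$semantic_group[rows],
             stringsAsFactors = FALSE)
}

#' Annotate every document of a corpus
#'
#' @param corpus a `Corpus`.
#' @param lex a `Lexicon`.
#' @return one annotation data frame (see [annotate()]) covering all
#'   documents, in corpus order.
#' @export
annotate_corpus <- function(corpus, lex) {
  stopifnot(inherits(corpus, "Corpus"))
  out <- mapply(annotate, corpus$tokens, corpus$doc_ids,
                MoreArgs = list(lex = lex), SIMPLIFY = FALSE)
  do.call(rbind, out)
}

#' Semantic group distribution of an annotation set
#'
#' @param annotations annotation data frame (see [annotate()]).
#' @param groups configured group set.
#' @return object of class `GroupDistribution` with named `counts` and
#'   `proportions` over `groups`; with no annotations the proportions are
#'   all `NA` and the result carries attribute `empty = TRUE`.
#' @export
group_distribution <- function(annotations, groups = semantic_groups()) {
  counts <- table(factor(annotations$semantic_group, levels = groups))
  counts <- stats::setNames(as.integer(counts), groups)
  total <- sum(counts)
  props <- if (total > 0) counts / total else stats::setNames(rep(NA_real_, length(groups)), groups)
  structure(list(counts = counts, proportions = props),
            class = "GroupDistribution", empty = total == 0)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Computes the Pearson statistic \eqn{\sum (O - E)^2 / E} with expected
#' counts from the row/column marginals, degrees of freedom
#' \eqn{(r-1)(c-1)}, and the upper-tail p-value of the chi-square
#' distribution. No continuity correction is applied.
#'
#' @param observed numeric matrix of counts, at least 2 x 2.
#' @return object of class `ChiSquareResult` with `statistic`, `df`,
#'   `p_value`, `expected`.
#' @export
chi_square_test <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(observed < 0)) stop("counts must be non-negative")
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal row or column in contingency table")
  expected <- outer(rs, cs) / sum(observed)
  statistic <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  structure(list(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected),
            class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf("<chi-square: X2 = %.4f, df = %d, p = %.3g>\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Chi-square comparison of two concept mapping rates
#'
#' Builds the 2 x 2 table of mapped vs unmapped token counts for the two
#' corpora and applies [chi_square_test()].
#'
#' @param mapped_a,total_a mapped and total token counts of corpus A.
#' @param mapped_b,total_b mapped and total token counts of corpus B.
#' @return a `ChiSquareResult`.
#' @export
mapping_rate_test <- function(mapped_a, total_a, mapped_b, total_b) {
  if (mapped_a > total_a || mapped_b > total_b)
    stop("mapped count exceeds total count")
  chi_square_test(rbind(c(mapped_a, total_a - mapped_a),
                        c(mapped_b, total_b - mapped_b)))
}
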