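#' Construct a corpus from a data frame of documents
#'
#' The corpus is the unit of retrieval and statistics: an ordered collection
#' of identified documents together with their tokenization. Documents are
#' sorted lexicographically by `doc_id` so corpus construction is stable
#' regardless of input order. When both a title and a body are present they
#' are concatenated (title first, single space) into the searchable text;
#' category labels are kept as metadata, never as text.
#'
#' @param docs data frame with columns `doc_id`, `text` (or `content`), and
#'   optionally `title`, `category`.
#' @param label corpus label, e.g. `"questions"` or `"materials"`.
#' @param tokenizer a [tokenizer_config()].
#' @return object of class `Corpus`: list with `label`, `doc_ids`,
#'   `categories`, `titles`, `texts`, `tokens` (list of token vectors) and
#'   `vocabulary` (sorted union of token sets).
#' @export
corpus <- function(docs, label, tokenizer = tokenizer_config()) {
  stopifnot(is.data.frame(docs), is.character(label), length(label) == 1L)
  if (!"text" %in% names(docs) && "content" %in% names(docs))
    names(docs)[names(docs) == "content"] <- "text"
  if (!all(c("doc_id", "text") %in% names(docs)))
    stop("corpus requires 'doc_id' and 'text' (or 'content') columns")
  if (nrow(docs) == 0L) stop("empty corpus: no documents")
  ids <- as.character(docs$doc_id)
  if (anyNA(ids) || any(!nzchar(ids))) stop("doc_id must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate doc_id: ", paste(unique(dup), collapse = ", "))

  title <- if ("title" %in% names(docs)) as.character(docs$title) else rep(NA_character_, nrow(docs))
  body <- as.character(docs$text)
  text <- ifelse(is.na(title) | !nzchar(title), body, paste(title, body))
  if (any(is.na(text) | !nzchar(trimws(text))))
    stop("document text empty after whitespace normalization: ",
         paste(ids[is.na(text) | !nzchar(trimws(text))], collapse = ", "))

  ord <- order(ids, method = "radix")
  cat_col <- if ("category" %in% names(docs)) as.character(docs$category) else rep(NA_character_, nrow(docs))
  tokens <- tokenize_all(text[ord], tokenizer)
  structure(list(label = label,
                 doc_ids = ids[ord],
                 categories = cat_col[ord],
                 titles = title[ord],
                 texts = text[ord],
                 tokens = tokens,
                 vocabulary = sort(unique(unlist(tokens))),
                 tokenizer = tokenizer),
            class = "Corpus")
}

#' @export
print.Corpus <- function(x, ...) {
  cat(sprintf("<Corpus '%s': %d documents, %d unique words>\n",
              x$label, length(x$doc_ids), length(x$vocabulary)))
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus a `Corpus`.
#' @return integer document count.
#' @export
n_docs <- function(corpus) length(corpus$doc_ids)

#' Load a corpus from disk
#'
#' Three plain-text layouts are supported:
#' \describe{
#'   \item{`txt_dir`}{a directory of UTF-8 `.txt` files; the file name
#'     (without extension) is the `doc_id`.}
#'   \item{`jsonl`}{one JSON object per line with keys `doc_id`, `text`
#'     (or `content`), optional `title`, `category`.}
#'   \item{`tsv`}{tab-separated with a header carrying the same columns.}
#' }
#'
#' @param path file or directory path.
#' @param format one of `"txt_dir"`, `"jsonl"`, `"tsv"`.
#' @param label corpus label.
#' @param tokenizer a [tokenizer_config()].
#' @return a `Corpus`.
#' @export
load_corpus <- function(path, format = c("txt_dir", "jsonl", "tsv"),
                        label, tokenizer = tokenizer_config()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  docs <- switch(format,
    txt_dir = {
      files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
      if (!length(files)) stop("empty corpus: no .txt files in ", path)
      data.frame(doc_id = sub("\\.txt$", "", basename(files)),
                 text = vapply(files, function(f)
                   paste(readLines(f, warn = FALSE), collapse = "\n"), ""),
                 stringsAsFactors = FALSE)
    },
    jsonl = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines)) stop("empty corpus: ", path)
      recs <- lapply(lines, jsonlite::fromJSON)
      as.data.frame(do.call(rbind, lapply(recs, function(r) {
        if (is.null(r$doc_id)) stop("jsonl record missing doc_id")
        txt <- if (!is.null(r$text)) r$text else r$content
        if (is.null(txt)) stop("jsonl record ", r$doc_id, " missing text")
        data.frame(doc_id = as.character(r$doc_id), text = as.character(txt),
                   title = if (is.null(r$title)) NA_character_ else as.character(r$title),
                   category = if (is.null(r$category)) NA_character_ else as.character(r$category),
                   stringsAsFactors = FALSE)
      })))
    },
    tsv = {
      df <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                       comment.char = "")
      if (nrow(df) == 0L) stop("empty corpus: ", path)
      df
    })
  corpus(docs, label = label, tokenizer = tokenizer)
}

#' Descriptive corpus statistics
#'
#' Per-corpus summary: document count, total token count, mean and standard
#' deviation of document lengths (sample SD, n-1 denominator), unique word
#' count, and — when concept annotations are supplied — the concept mapping
#' rate (fraction of word tokens covered by at least one annotation span,
#' each token counted once) and the number of distinct concepts.
#'
#' @param corpus a `Corpus`.
#' @param annotations optional annotation data frame as returned by
#'   [annotate_corpus()]; must reference only documents of `corpus`.
#' @return object of class `CorpusStats` (a list).
#' @export
corpus_stats <- function(corpus, annotations = NULL) {
  stopifnot(inherits(corpus, "Corpus"))
  lens <- vapply(corpus$tokens, length, 0L)
  out <- list(label = corpus$label,
              n_docs = length(lens),
              total_words = sum(lens),
              mean_len = mean(lens),
              sd_len = if (length(lens) > 1L) sd(lens) else NA_real_,
              unique_words = length(corpus$vocabulary),
              mapping_rate = NA_real_,
              unique_concepts = NA_integer_)
  if (!is.null(annotations) && nrow(annotations)) {
    unknown <- setdiff(unique(annotations$doc_id), corpus$doc_ids)
    if (length(unknown))
      stop("annotations reference unknown doc_id: ",
           paste(unknown, collapse = ", "))
    covered <- 0L
    by_doc <- split(annotations, annotations$doc_id)
    for (id in names(by_doc)) {
      len <- lens[match(id, corpus$doc_ids)]
      mask <- logical(len)
      a <- by_doc[[id]]
      for (r in seq_len(nrow(a)))
        mask[seq(a$start_token[r] + 1L, a$end_token[r])] <- TRUE
      covered <- covered + sum(mask)
    }
    out$mapping_rate <- covered / out$total_words
    out$unique_concepts <- length(unique(annotations$concept_id))
  }
  structure(out, class = "CorpusStats")
}

#' @export
print.CorpusStats <- function(x, ...) {
  cat(sprintf("<CorpusStats '%s': %d docs, %d tokens, mean length %.1f (SD %.1f), %d unique words",
              x$label, x$n_docs, x$total_words, x$mean_len, x$sd_len,
              x$unique_words))
  if (!is.na(x$mapping_rate))
    cat(sprintf(", mapping rate %.2f%%, %d concepts",
                100 * x$mapping_rate, x$unique_concepts))
  cat(">\n")
  invisible(x)
}

#' Vocabulary overlap between two corpora
#'
#' Venn-diagram counts of the two vocabularies (both corpora must have been
#' tokenized under the same configuration for the comparison to be
#' meaningful). Fractions are relative to each corpus's own vocabulary size.
#'
#' @param a,b `Corpus` objects.
#' @return object of class `OverlapSummary` with `shared`, `only_a`,
#'   `only_b`, `frac_only_a`, `frac_only_b`.
#' @export
vocabulary_overlap <- function(a, b) {
  stopifnot(inherits(a, "Corpus"), inherits(b, "Corpus"))
  va <- a$vocabulary; vb <- b$vocabulary
  shared <- length(intersect(va, vb))
  structure(list(shared = shared,
                 only_a = length(va) - shared,
                 only_b = length(vb) - shared,
                 frac_only_a = (length(va) - shared) / length(va),
                 frac_only_b = (length(vb) - shared) / length(vb)),
            class = "OverlapSummary")
}

#' Most frequent words in a corpus
#'
#' @param corpus a `Corpus`.
#' @param n number of words to return; capped at the vocabulary size.
#' @return data frame with `word` and `frequency`, sorted by frequency
#'   descending, ties broken alphabetically.
#' @export
top_words <- function(corpus, n = 20L) {
  stopifnot(inherits(corpus, "Corpus"), n >= 1)
  counts <- table(unlist(corpus$tokens))
  df <- data.frame(word = names(counts), frequency = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$word, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  head(df, min(as.integer(n), nrow(df)))
}
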