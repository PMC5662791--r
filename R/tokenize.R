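#' Tokenizer configuration
#'
#' Settings for the deterministic tokenizer used throughout the package:
#' lowercase, split on runs of non-alphabetic characters, drop short tokens,
#' optionally remove stop-words. The same configuration object must be used
#' for every corpus that is compared or modelled jointly, so that word counts,
#' vocabulary overlap and model vocabularies are commensurable.
#'
#' The stop-list is off by default so that raw descriptive word counts are
#' reproducible; topic modelling typically benefits from turning it on via
#' `stopwords = english_stopwords()`.
#'
#' @param lowercase fold text to lower case before splitting (default TRUE).
#' @param min_length minimum token length in characters; shorter tokens are
#'   dropped (default 2, which removes single-letter fragments).
#' @param stopwords character vector of tokens to remove after case folding
#'   (default none).
#' @return an object of class `tokenizer_config`.
#' @seealso [tokenize()], [english_stopwords()]
#' @export
tokenizer_config <- function(lowercase = TRUE, min_length = 2L,
                             stopwords = character(0)) {
  stopifnot(is.logical(lowercase), length(lowercase) == 1L,
            is.numeric(min_length), min_length >= 1,
            is.character(stopwords))
  structure(list(lowercase = lowercase,
                 min_length = as.integer(min_length),
                 stopwords = tolower(stopwords)),
            class = "tokenizer_config")
}

#' Packaged English stop-list
#'
#' A small general-English stop-list (function words only, no domain terms).
#'
#' @return character vector of stop-words.
#' @export
english_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "edurec")
  readLines(path, warn = FALSE)
}

#' Tokenize a text string
#'
#' Deterministic: the same `text` and `config` always yield the same token
#' sequence. Tokens are maximal runs of alphabetic characters, case folded
#' when configured, filtered by minimum length and stop-list.
#'
#' @param text a single character string (NA or empty gives no tokens).
#' @param config a [tokenizer_config()].
#' @return character vector of tokens in text order (possibly empty).
#' @examples
#' tokenize("Blood sugar, blood Sugar!")
#' @export
tokenize <- function(text, config = tokenizer_config()) {
  stopifnot(inherits(config, "tokenizer_config"))
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(character(0))
  if (config$lowercase) text <- tolower(text)
  toks <- strsplit(text, "[^A-Za-z]+")[[1]]
  toks <- toks[nzchar(toks) & nchar(toks) >= config$min_length]
  if (length(config$stopwords)) toks <- toks[!(toks %in% config$stopwords)]
  toks
}

tokenize_all <- function(texts, config) {
  lapply(texts, tokenize, config = config)
}
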