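# Lexicon-based sentiment and lexical-diversity features for short emotional
# narratives: Polarity, Subjectivity, Average Word Length, Token Count,
# Unique Tokens, Type-Token Ratio.

.lexicon_cache <- new.env(parent = emptyenv())

#' Default negator word set
#'
#' A matched lexicon word immediately preceded by one of these has its
#' polarity weight multiplied by the lexicon's `negation_factor`.
#' @export
default_negators <- function() {
  c("not", "no", "never", "neither", "nor", "cannot", "cant", "dont",
    "doesnt", "didnt", "isnt", "wasnt", "werent", "wont", "wouldnt",
    "shouldnt", "couldnt", "hardly", "barely", "without")
}

#' Load a sentiment lexicon
#'
#' Reads a two-weight lexicon (word, polarity in [-1,1], subjectivity in
#' [0,1]). The packaged default is a transparent ~250-entry affect lexicon
#' shipped as a plain TSV, so every score is reproducible and auditable.
#'
#' @param path TSV file with columns `word`, `polarity`, `subjectivity`;
#'   default: the packaged lexicon.
#' @param negators words that flip/damp a following word's polarity.
#' @param negation_factor multiplier applied to a negated word's polarity.
#' @return an object of class `sentiment_lexicon`.
#' @export
sentiment_lexicon <- function(path = NULL, negators = default_negators(),
                              negation_factor = -0.5) {
  if (is.null(path)) {
    path <- system.file("extdata", "affect_lexicon.tsv", package = "createlab")
    key <- paste0("default:", negation_factor)
    if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  } else {
    key <- NULL
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "polarity", "subjectivity") %in% names(tab)))
  if (any(tab$polarity < -1 | tab$polarity > 1) ||
      any(tab$subjectivity < 0 | tab$subjectivity > 1)) {
    stop_validation("lexicon weights out of range")
  }
  if (anyDuplicated(tab$word)) stop_validation("duplicate lexicon words")
  if (length(intersect(tab$word, negators))) {
    stop_validation("negators must be disjoint from lexicon entries")
  }
  lex <- structure(list(
    words = tab$word,
    polarity = stats::setNames(tab$polarity, tab$word),
    subjectivity = stats::setNames(tab$subjectivity, tab$word),
    negators = negators,
    negation_factor = negation_factor
  ), class = "sentiment_lexicon")
  if (!is.null(key)) .lexicon_cache[[key]] <- lex
  lex
}

#' Tokenize free text
#'
#' Lowercases, splits on any run of non-alphanumeric characters, and drops
#' empty tokens; order is preserved. Hyphens and apostrophes are separators,
#' so "Awe-struck" yields `c("awe", "struck")`.
#'
#' @param text a character string (possibly empty).
#' @return character vector of tokens.
#' @export
tokenize <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop_validation("`text` must be a single character string")
  }
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Lexical features of a token list
#'
#' Token Count, Unique Tokens, Type-Token Ratio (unique/total) and Average
#' Word Length (mean characters per token, after punctuation stripping by
#' [tokenize()]). For an empty token list all four are `NA` (missing, not
#' zero), since TTR and AWL are undefined.
#'
#' @param tokens character vector from [tokenize()].
#' @return list with `token_count`, `unique_tokens`, `type_token_ratio`,
#'   `avg_word_length`.
#' @export
lexical_features <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) {
    return(list(token_count = NA_integer_, unique_tokens = NA_integer_,
                type_token_ratio = NA_real_, avg_word_length = NA_real_))
  }
  u <- length(unique(tokens))
  list(token_count = n,
       unique_tokens = u,
       type_token_ratio = u / n,
       avg_word_length = mean(nchar(tokens)))
}

#' Polarity and subjectivity of a token list
#'
#' Polarity is the mean polarity weight of lexicon-matched tokens after
#' negation adjustment (a matched token immediately preceded by a negator has
#' its polarity multiplied by the lexicon's `negation_factor`); subjectivity
#' is the mean subjectivity weight of matched tokens. With zero matches both
#' are 0 (neutral default).
#'
#' @param tokens character vector from [tokenize()].
#' @param lexicon a [sentiment_lexicon()].
#' @return list with `polarity` and `subjectivity`.
#' @export
polarity_subjectivity <- function(tokens, lexicon = sentiment_lexicon()) {
  hit <- tokens %in% lexicon$words
  if (!any(hit)) return(list(polarity = 0.0, subjectivity = 0.0))
  idx <- which(hit)
  pol <- unname(lexicon$polarity[tokens[idx]])
  negated <- idx > 1L & tokens[pmax(idx - 1L, 1L)] %in% lexicon$negators
  pol[negated] <- pol[negated] * lexicon$negation_factor
  sub <- unname(lexicon$subjectivity[tokens[idx]])
  list(polarity = mean(pol), subjectivity = mean(sub))
}

#' All six narrative features of one comment
#'
#' @param text a character string.
#' @param lexicon a [sentiment_lexicon()].
#' @return one-row `data.frame` with columns `polarity`, `subjectivity`,
#'   `avg_word_length`, `token_count`, `unique_tokens`, `type_token_ratio`.
#' @export
text_features <- function(text, lexicon = sentiment_lexicon()) {
  toks <- tokenize(text)
  lex <- lexical_features(toks)
  ps <- polarity_subjectivity(toks, lexicon)
  data.frame(polarity = ps$polarity, subjectivity = ps$subjectivity,
             avg_word_length = lex$avg_word_length,
             token_count = lex$token_count,
             unique_tokens = lex$unique_tokens,
             type_token_ratio = lex$type_token_ratio)
}
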