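## Abstract cleaning into a stemmed document-term matrix.
##
## The cleaning recipe is fixed in order: lowercase; delete search-term
## phrases; hyphens and forward slashes to spaces; strip all other
## punctuation; tokenize on whitespace; drop number-words, stop-words and
## publisher boilerplate terms; Porter-stem each surviving token.  Search
## phrases are deleted again at the stem level (prefix and bigram patterns)
## as a safety net, because hyphenated variants ("climate-change") only
## become visible after punctuation handling.

#' Cleaning configuration
#'
#' @param searchTerms phrases to delete from abstracts before tokenisation.
#'   A trailing \code{*} makes a single word a prefix pattern
#'   (\code{"phenolog*"} removes phenology, phenological, ...).  Multi-word
#'   phrases are removed as phrases; their stemmed bigrams are removed again
#'   after stemming.
#' @param stopWords,numberWords,publisherTerms word lists (lowercase);
#'   defaults ship with the package and are fully configurable.
#' @param minDocFrequency minimum number of documents a stem must occur in
#'   to stay in the vocabulary.  The default 6 removes terms appearing in
#'   five or fewer abstracts.
#' @return list of class \code{littopics_cleaning_config}.
#' @export
cleaningConfig <- function(searchTerms = c("phenolog*", "climate change",
                                           "global change", "global warming"),
                           stopWords = NULL,
                           numberWords = NULL,
                           publisherTerms = NULL,
                           minDocFrequency = 6L) {
  stopifnot(minDocFrequency >= 1L)
  cfg <- list(
    searchTerms = tolower(searchTerms),
    stopWords = tolower(stopWords %||%
                          readWordList(extdataPath("stopwords_en.txt"))),
    numberWords = tolower(numberWords %||%
                            readWordList(extdataPath("number_words.txt"))),
    publisherTerms = tolower(publisherTerms %||%
                               readWordList(extdataPath("publisher_terms.txt"))),
    minDocFrequency = as.integer(minDocFrequency)
  )
  cfg$stemPatterns <- compileStemPatterns(cfg$searchTerms)
  class(cfg) <- "littopics_cleaning_config"
  cfg
}

## Stem-level deletion patterns derived from the search terms: single words
## (optionally prefix) and stemmed bigrams.
compileStemPatterns <- function(searchTerms) {
  prefixes <- character(); words <- character(); bigrams <- list()
  for (term in searchTerms) {
    parts <- strsplit(trimws(term), "\\s+")[[1]]
    if (length(parts) == 1L) {
      if (endsWith(parts, "*")) {
        prefixes <- c(prefixes, sub("\\*$", "", parts))
      } else {
        words <- c(words, porterStem(parts))
      }
    } else if (length(parts) == 2L) {
      bigrams[[length(bigrams) + 1L]] <-
        porterStem(sub("\\*$", "", parts))
    } else {
      bigrams[[length(bigrams) + 1L]] <-
        porterStem(sub("\\*$", "", parts))  # general n-gram
    }
  }
  list(prefixes = unique(prefixes), words = unique(words),
       ngrams = bigrams)
}

deleteSearchPhrases <- function(text, searchTerms) {
  for (term in searchTerms) {
    if (grepl("\\s", term)) {
      re <- paste0("\\b", gsub("\\s+", "\\\\s+", term), "\\b")
    } else if (endsWith(term, "*")) {
      re <- paste0("\\b", sub("\\*$", "", term), "[a-z]*\\b")
    } else {
      re <- paste0("\\b", term, "\\b")
    }
    text <- gsub(re, " ", text, perl = TRUE)
  }
  text
}

dropStemPatterns <- function(stems, pat) {
  if (!length(stems)) return(stems)
  drop <- rep(FALSE, length(stems))
  for (p in pat$prefixes) drop <- drop | startsWith(stems, p)
  drop <- drop | stems %in% pat$words
  for (ng in pat$ngrams) {
    L <- length(ng)
    if (length(stems) < L) next
    for (i in seq_len(length(stems) - L + 1L)) {
      if (!any(drop[i:(i + L - 1L)]) && all(stems[i:(i + L - 1L)] == ng))
        drop[i:(i + L - 1L)] <- TRUE
    }
  }
  stems[!drop]
}

#' Clean and tokenise abstract text
#'
#' Applies the fixed cleaning pipeline (see package vignette) and returns
#' stemmed tokens; possibly empty.
#'
#' @param text character vector of abstracts.
#' @param config a \code{\link{cleaningConfig}}.
#' @return for a single abstract, a character vector of stems; for several,
#'   a list of such vectors.
#' @examples
#' cfg <- cleaningConfig()
#' cleanText("Climate-change effects on phenology of twenty plants", cfg)
#' @export
cleanText <- function(text, config = cleaningConfig()) {
  stopifnot(is.character(text))
  res <- lapply(text, cleanTextOne, config = config)
  if (length(text) == 1L) res[[1]] else res
}

cleanTextOne <- function(text, config) {
  t <- tolower(text)
  t <- deleteSearchPhrases(t, config$searchTerms)
  t <- gsub("[-/]", " ", t)
  ## remaining punctuation is deleted outright (word-internal apostrophes
  ## etc. close up rather than splitting the word)
  t <- gsub("[^a-z0-9\\s]", "", t, perl = TRUE)
  tokens <- strsplit(trimws(gsub("\\s+", " ", t)), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  remove <- c(config$numberWords, config$stopWords, config$publisherTerms)
  tokens <- tokens[!(tokens %in% remove)]
  stems <- porterStem(tokens)
  dropStemPatterns(stems, config$stemPatterns)
}

#' Build the document-term matrix
#'
#' Counts stems per document and removes terms whose document frequency is
#' below \code{minDocFrequency} (default: terms in five or fewer abstracts
#' vanish).  Documents emptied by the filter are kept as all-zero rows,
#' flagged via \code{\link{emptyDocs}}, and excluded from LDA fitting.
#' The vocabulary is sorted lexicographically (C locale) so all downstream
#' output is deterministic.
#'
#' @param tokenLists list of stem vectors, one per document (output of
#'   \code{\link{cleanText}}).
#' @param ids character record ids, one per document.
#' @param config a \code{\link{cleaningConfig}} (only
#'   \code{minDocFrequency} is used here).
#' @return a \code{\linkS4class{DocTermMatrix}}.
#' @export
buildDtm <- function(tokenLists, ids, config = cleaningConfig()) {
  if (is.character(tokenLists)) tokenLists <- list(tokenLists)
  stopifnot(length(tokenLists) >= 1L, length(ids) == length(tokenLists))
  if (anyDuplicated(ids)) stop("document ids must be unique")
  ids <- as.character(ids)

  df <- table(unlist(lapply(tokenLists, unique)))
  keep <- csort(names(df)[df >= config$minDocFrequency])
  if (!length(keep))
    stop("cleaning pipeline error: no term reaches the document-frequency ",
         "threshold (", config$minDocFrequency, "); all documents empty")

  triples <- lapply(seq_along(tokenLists), function(d) {
    tk <- tokenLists[[d]]
    tk <- tk[tk %in% keep]
    if (!length(tk)) return(NULL)
    tab <- table(tk)
    cbind(d, match(names(tab), keep), as.integer(tab))
  })
  triples <- do.call(rbind, triples)
  if (is.null(triples))
    stop("cleaning pipeline error: all documents empty after filtering")
  counts <- Matrix::sparseMatrix(
    i = triples[, 1], j = triples[, 2], x = triples[, 3],
    dims = c(length(ids), length(keep)),
    dimnames = list(ids, keep)
  )
  empty <- Matrix::rowSums(counts) == 0
  if (any(empty))
    message(sum(empty), " document(s) emptied by term filtering; ",
            "flagged and excluded from fitting")
  new("DocTermMatrix",
      counts = counts, terms = keep, docIds = ids,
      docFrequency = as.integer(df[keep]),
      emptyDocs = as.logical(empty),
      minDocFrequency = config$minDocFrequency)
}

#' Serialise a DocTermMatrix
#'
#' Writes MatrixMarket counts plus sidecar term and document-id text files
#' and a small YAML metadata file into \code{dir}.
#'
#' @param dtm a \code{DocTermMatrix}.
#' @param dir output directory (created if needed).
#' @export
writeDtm <- function(dtm, dir) {
  stopifnot(is(dtm, "DocTermMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(dtm@counts, "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(dtm@terms, file.path(dir, "terms.txt"))
  writeLines(dtm@docIds, file.path(dir, "docs.txt"))
  yaml::write_yaml(list(min_doc_frequency = dtm@minDocFrequency),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname writeDtm
#' @export
readDtm <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "counts.mtx"))
  terms <- readLines(file.path(dir, "terms.txt"), encoding = "UTF-8")
  ids <- readLines(file.path(dir, "docs.txt"), encoding = "UTF-8")
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(ids, terms)
  df <- as.integer(Matrix::colSums(counts > 0))
  new("DocTermMatrix",
      counts = counts, terms = terms, docIds = ids,
      docFrequency = df,
      emptyDocs = as.logical(Matrix::rowSums(counts) == 0),
      minDocFrequency = as.integer(meta$min_doc_frequency))
}
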