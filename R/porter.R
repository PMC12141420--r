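## Classic Porter (1980) suffix-stripping stemmer, implemented directly from
## the algorithm's rule tables.  Operates on lowercase words; words of length
## <= 2 and tokens containing digits pass through unchanged (pseudo-word
## vocabularies such as "w0001" must survive intact).
##
## Conventions: a "consonant" is any letter other than a,e,i,o,u, with y
## counting as a consonant only when not preceded by a consonant; m is the
## number of VC sequences in the [C](VC)^m[V] decomposition of a stem.

porterConsMask <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cons <- logical(n)
  for (i in seq_len(n)) {
    c <- ch[i]
    if (c %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (c == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

porterMeasure <- function(word) {
  if (!nzchar(word)) return(0L)
  cons <- porterConsMask(word)
  ## collapse runs, count V->C transitions
  runs <- rle(cons)$values
  sum(runs[-1] & !runs[-length(runs)])
}

porterHasVowel <- function(word) {
  nzchar(word) && any(!porterConsMask(word))
}

porterEndsDouble <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L); b <- substr(word, n, n)
  a == b && porterConsMask(word)[n]
}

## *o: stem ends consonant-vowel-consonant where the final consonant is not
## w, x or y.
porterEndsCvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- porterConsMask(word)
  last <- substr(word, n, n)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(last %in% c("w", "x", "y"))
}

endsWith1 <- function(word, suf) {
  n <- nchar(word); m <- nchar(suf)
  n > m && substr(word, n - m + 1L, n) == suf
}

chopSuffix <- function(word, suf) substr(word, 1L, nchar(word) - nchar(suf))

porterStep1a <- function(w) {
  if (endsWith1(w, "sses")) return(paste0(chopSuffix(w, "sses"), "ss"))
  if (endsWith1(w, "ies"))  return(paste0(chopSuffix(w, "ies"), "i"))
  if (endsWith1(w, "ss"))   return(w)
  if (endsWith1(w, "s"))    return(chopSuffix(w, "s"))
  w
}

porterStep1b <- function(w) {
  if (endsWith1(w, "eed")) {
    stem <- chopSuffix(w, "eed")
    if (porterMeasure(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  stripped <- FALSE
  if (endsWith1(w, "ed") && porterHasVowel(chopSuffix(w, "ed"))) {
    w <- chopSuffix(w, "ed"); stripped <- TRUE
  } else if (endsWith1(w, "ing") && porterHasVowel(chopSuffix(w, "ing"))) {
    w <- chopSuffix(w, "ing"); stripped <- TRUE
  }
  if (stripped) {
    if (endsWith1(w, "at") || endsWith1(w, "bl") || endsWith1(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porterEndsDouble(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (porterMeasure(w) == 1L && porterEndsCvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

porterStep1c <- function(w) {
  if (endsWith1(w, "y") && porterHasVowel(chopSuffix(w, "y")))
    return(paste0(chopSuffix(w, "y"), "i"))
  w
}

## Rule tables for steps 2-4: first suffix that matches ends the step;
## the replacement applies only if the stem condition holds.
.porterStep2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"),
  c("alli", "al"), c("entli", "ent"), c("eli", "e"), c("ousli", "ous"),
  c("ization", "ize"), c("ation", "ate"), c("ator", "ate"),
  c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"),
  c("biliti", "ble")
)

.porterStep3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.porterStep4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                  "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                  "ous", "ive", "ize")

porterRuleStep <- function(w, rules, minMeasure) {
  for (r in rules) {
    if (endsWith1(w, r[1])) {
      stem <- chopSuffix(w, r[1])
      if (porterMeasure(stem) > minMeasure - 1L)
        return(paste0(stem, r[2]))
      return(w)
    }
  }
  w
}

porterStep4 <- function(w) {
  ## longest-match within each suffix family: 'ement' precedes 'ment'
  ## precedes 'ent' in the table.
  for (suf in .porterStep4) {
    if (endsWith1(w, suf)) {
      stem <- chopSuffix(w, suf)
      if (porterMeasure(stem) > 1L) {
        if (suf == "ion" &&
            !(substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")))
          return(w)
        return(stem)
      }
      return(w)
    }
  }
  w
}

porterStep5a <- function(w) {
  if (endsWith1(w, "e")) {
    stem <- chopSuffix(w, "e")
    m <- porterMeasure(stem)
    if (m > 1L || (m == 1L && !porterEndsCvc(stem))) return(stem)
  }
  w
}

porterStep5b <- function(w) {
  if (porterMeasure(w) > 1L && porterEndsDouble(w) &&
      endsWith(w, "l"))
    return(substr(w, 1L, nchar(w) - 1L))
  w
}

porterStemOne <- function(w) {
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)
  w <- porterStep1a(w)
  w <- porterStep1b(w)
  w <- porterStep1c(w)
  w <- porterRuleStep(w, .porterStep2, 1L)
  w <- porterRuleStep(w, .porterStep3, 1L)
  w <- porterStep4(w)
  w <- porterStep5a(w)
  porterStep5b(w)
}

#' Porter suffix-stripping stemmer
#'
#' Reduces English words to a common root by the classic Porter (1980)
#' suffix-stripping algorithm, e.g. \code{"precipitation"} to
#' \code{"precipit"}, \code{"vegetation"} to \code{"veget"},
#' \code{"studied"} to \code{"studi"}.  Words of one or two letters and
#' tokens containing non-letter characters are returned unchanged.  Input is
#' expected lowercase.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length.
#' @examples
#' porterStem(c("effects", "plants", "vegetation"))
#' @export
porterStem <- function(words) {
  if (!length(words)) return(character())
  u <- unique(words)
  stems <- vapply(u, porterStemOne, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}
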