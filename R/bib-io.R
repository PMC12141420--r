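## Bibliographic record ingestion, deduplication, screening bookkeeping and
## dual-reviewer agreement.
##
## A record collection is a data.frame with columns
##   record_id, title, abstract, year, journal, source_db, included
## (record_id unique; abstract possibly empty; year integer or NA; included
## a logical screening flag, NA until screened).

.bibColumns <- c("record_id", "title", "abstract", "year", "journal",
                 "source_db", "included")

validateRecords <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(setdiff(.bibColumns, "included"), names(records))
  if (length(missing))
    stop("record collection lacks columns: ", paste(missing, collapse = ", "))
  if (!"included" %in% names(records)) records$included <- NA
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup))
    stop("duplicate record_id in collection: ",
         paste(unique(dup), collapse = ", "))
  records$year <- suppressWarnings(as.integer(records$year))
  bad <- !is.na(records$year) & (records$year < 1900L | records$year > 2100L)
  if (any(bad))
    stop("year outside [1900, 2100] for record(s): ",
         paste(records$record_id[bad], collapse = ", "))
  records$abstract[is.na(records$abstract)] <- ""
  records$source_db <- ifelse(records$source_db %in% c("wos", "scopus"),
                              records$source_db, "other")
  rownames(records) <- NULL
  records[, .bibColumns]
}

#' Read bibliographic records
#'
#' Ingests RIS, BibTeX or CSV bibliographies into the standard record
#' collection layout.  Missing abstracts are stored as empty strings (the
#' decision to drop them belongs to \code{\link{dropMissingAbstracts}});
#' records without a parseable year are kept with \code{NA} year and a
#' warning, since year is only needed by the trend analyses.
#'
#' @param path file path.
#' @param format one of \code{"ris"}, \code{"bibtex"}, \code{"csv"}.  CSV
#'   files must carry the header
#'   \code{id,title,abstract,year,journal,source_db}.
#' @return data.frame with columns record_id, title, abstract, year,
#'   journal, source_db, included.
#' @export
readRecords <- function(path, format = c("csv", "ris", "bibtex")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- switch(format,
    csv = readRecordsCsv(path),
    ris = readRecordsRis(path),
    bibtex = readRecordsBibtex(path)
  )
  if (any(is.na(recs$year)))
    warning(sum(is.na(recs$year)), " record(s) lack a year; kept with NA")
  validateRecords(recs)
}

readRecordsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "title", "abstract", "year", "journal", "source_db")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CSV format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  data.frame(
    record_id = df$id, title = df$title, abstract = df$abstract,
    year = suppressWarnings(as.integer(df$year)),
    journal = df$journal, source_db = df$source_db, included = NA,
    stringsAsFactors = FALSE
  )
}

## Minimal RIS reader: tag lines "XX  - value"; records delimited by
## "ER  -".  TI/T1 title, AB/N2 abstract, PY/Y1 year, JO/JF/T2 journal,
## ID record id (generated when absent).
readRecordsRis <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tagRe <- "^([A-Z][A-Z0-9])  ?- ?(.*)$"
  recs <- list(); cur <- list(); lastTag <- NULL
  flush <- function(cur, n) {
    if (!length(cur)) return(NULL)
    year <- suppressWarnings(as.integer(
      sub("^([0-9]{4}).*$", "\\1", cur$PY %||% cur$Y1 %||% "")))
    list(
      record_id = cur$ID %||% sprintf("ris_%04d", n),
      title = cur$TI %||% cur$T1 %||% "",
      abstract = cur$AB %||% cur$N2 %||% "",
      year = year,
      journal = cur$JO %||% cur$JF %||% cur$T2 %||% "",
      source_db = "other"
    )
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (grepl(tagRe, ln)) {
      tag <- sub(tagRe, "\\1", ln)
      val <- sub(tagRe, "\\2", ln)
      if (tag == "ER") {
        r <- flush(cur, length(recs) + 1L)
        if (!is.null(r)) recs[[length(recs) + 1L]] <- r
        cur <- list(); lastTag <- NULL
      } else {
        cur[[tag]] <- if (is.null(cur[[tag]])) val else
          paste(cur[[tag]], val)
        lastTag <- tag
      }
    } else if (!is.null(lastTag)) {
      ## continuation line of the previous tag
      cur[[lastTag]] <- paste(cur[[lastTag]], trimws(ln))
    } else {
      stop("RIS format error at line ", i, ": ", ln)
    }
  }
  if (length(cur))
    recs[[length(recs) + 1L]] <- flush(cur, length(recs) + 1L)
  if (!length(recs)) stop("RIS format error: no records in ", path)
  do.call(rbind.data.frame,
          c(recs, list(stringsAsFactors = FALSE, make.row.names = FALSE)))
}

## Minimal BibTeX reader for @article{key, field = {value}|"value", ...}.
readRecordsBibtex <- function(path) {
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  starts <- gregexpr("@[A-Za-z]+\\s*\\{", txt)[[1]]
  if (starts[1] == -1) stop("BibTeX format error: no entries in ", path)
  entries <- list()
  for (s in starts) {
    ## walk braces to find the matching close
    open <- regexpr("\\{", substr(txt, s, nchar(txt)))[1] + s - 1L
    depth <- 0L; e <- NA_integer_
    for (i in open:nchar(txt)) {
      c <- substr(txt, i, i)
      if (c == "{") depth <- depth + 1L
      if (c == "}") {
        depth <- depth - 1L
        if (depth == 0L) { e <- i; break }
      }
    }
    if (is.na(e)) stop("BibTeX format error: unbalanced braces in entry ",
                       "starting at character ", s)
    entries[[length(entries) + 1L]] <- substr(txt, open + 1L, e - 1L)
  }
  recs <- lapply(seq_along(entries), function(n) {
    body <- entries[[n]]
    key <- trimws(sub(",.*$", "", body))
    fields <- list()
    fieldRe <- "([A-Za-z]+)\\s*=\\s*"
    rest <- sub("^[^,]*,", "", body)
    while (grepl(fieldRe, rest)) {
      m <- regexpr(fieldRe, rest)
      name <- tolower(gsub("[=\\s]", "", regmatches(rest, m), perl = TRUE))
      rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
      first <- substr(rest, 1L, 1L)
      if (first == "{") {
        depth <- 0L; e <- NA_integer_
        for (i in seq_len(nchar(rest))) {
          c <- substr(rest, i, i)
          if (c == "{") depth <- depth + 1L
          if (c == "}") { depth <- depth - 1L
            if (depth == 0L) { e <- i; break } }
        }
        val <- substr(rest, 2L, e - 1L)
        rest <- substr(rest, e + 1L, nchar(rest))
      } else if (first == "\"") {
        e <- regexpr("\"", substr(rest, 2L, nchar(rest)))[1] + 1L
        val <- substr(rest, 2L, e - 1L)
        rest <- substr(rest, e + 1L, nchar(rest))
      } else {
        e <- regexpr("[,}]|$", rest)[1]
        val <- trimws(substr(rest, 1L, e - 1L))
        rest <- substr(rest, e, nchar(rest))
      }
      fields[[name]] <- gsub("\\s+", " ", trimws(val))
      rest <- sub("^\\s*,", "", rest)
    }
    list(
      record_id = if (nzchar(key)) key else sprintf("bib_%04d", n),
      title = fields$title %||% "",
      abstract = fields$abstract %||% "",
      year = suppressWarnings(as.integer(fields$year %||% NA)),
      journal = fields$journal %||% "",
      source_db = "other"
    )
  })
  do.call(rbind.data.frame,
          c(recs, list(stringsAsFactors = FALSE, make.row.names = FALSE)))
}

#' Write records as CSV
#'
#' @param records a record collection.
#' @param path output path.
#' @export
writeRecords <- function(records, path) {
  records <- validateRecords(records)
  out <- data.frame(id = records$record_id, title = records$title,
                    abstract = records$abstract, year = records$year,
                    journal = records$journal, source_db = records$source_db,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

normaliseTitle <- function(title) {
  t <- tolower(title)
  t <- gsub("[[:punct:]]", " ", t)
  gsub("\\s+", " ", trimws(t))
}

#' Deduplicate a record collection
#'
#' Two records are duplicates when their normalised titles (casefolded,
#' punctuation stripped, whitespace collapsed) and years both match; the
#' first occurrence is kept.  Optional fuzzy matching (edit distance on the
#' normalised title, same year) is off by default: silently merging
#' near-matches is riskier than missing the odd duplicate.
#'
#' @param records record collection.
#' @param fuzzy enable edit-distance matching.
#' @param maxDist maximum edit distance treated as a duplicate when
#'   \code{fuzzy} is on.
#' @return list with \code{records} (deduplicated) and \code{removed}
#'   (data.frame: removed record_id and the record_id it duplicated).
#' @export
deduplicateRecords <- function(records, fuzzy = FALSE, maxDist = 3L) {
  records <- validateRecords(records)
  if (!nrow(records))
    return(list(records = records,
                removed = data.frame(record_id = character(),
                                     duplicate_of = character())))
  norm <- normaliseTitle(records$title)
  key <- paste(norm, records$year, sep = "\r")
  dup <- duplicated(key)
  dupOf <- records$record_id[match(key, key)]
  if (fuzzy && any(!dup)) {
    keepIdx <- which(!dup)
    for (i in keepIdx) {
      if (dup[i]) next
      earlier <- keepIdx[keepIdx < i & !dup[keepIdx]]
      if (!length(earlier)) next
      sameYear <- earlier[
        (is.na(records$year[earlier]) & is.na(records$year[i])) |
        (!is.na(records$year[earlier]) & !is.na(records$year[i]) &
           records$year[earlier] == records$year[i])]
      if (!length(sameYear)) next
      d <- utils::adist(norm[i], norm[sameYear])[1, ]
      hit <- sameYear[d <= maxDist]
      if (length(hit)) {
        dup[i] <- TRUE
        dupOf[i] <- records$record_id[hit[1]]
      }
    }
  }
  removed <- data.frame(record_id = records$record_id[dup],
                        duplicate_of = dupOf[dup],
                        stringsAsFactors = FALSE)
  list(records = records[!dup, , drop = FALSE], removed = removed)
}

#' Drop records with no abstract
#'
#' @param records record collection.
#' @return the records whose abstract is non-empty; warns when everything is
#'   dropped.
#' @export
dropMissingAbstracts <- function(records) {
  records <- validateRecords(records)
  keep <- nzchar(trimws(records$abstract))
  if (!any(keep) && nrow(records))
    warning("all records have empty abstracts; returning empty collection")
  records[keep, , drop = FALSE]
}

#' Sample the double-screening subset
#'
#' Draws a seeded random subset of records (default 20\%) for a second
#' reviewer to screen, mirroring the usual dual-screening protocol.
#'
#' @param records record collection.
#' @param fraction proportion to sample.
#' @param seed RNG seed.
#' @return character vector of sampled record_ids.
#' @export
sampleScreeningSubset <- function(records, fraction = 0.2, seed = 1L) {
  records <- validateRecords(records)
  stopifnot(fraction > 0, fraction <= 1)
  n <- max(1L, round(fraction * nrow(records)))
  ids <- records$record_id
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restoreSeed(old), add = TRUE)
  csort(sample(ids, n))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cohen's kappa for dual-reviewer screening agreement
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with p_o the
#' observed proportion of agreeing pairs and p_e the agreement expected from
#' the raters' marginal rates.
#'
#' @param pairs either a data.frame with logical columns \code{rating_a} and
#'   \code{rating_b} (one row per double-screened record) or a 2 x 2
#'   contingency table/matrix (rows rater A yes/no, columns rater B yes/no).
#' @return kappa in [-1, 1].  When both raters are constant and identical
#'   (p_e = 1) kappa is undefined and an error of class
#'   \code{littopics_kappa_undefined} is signalled.
#' @examples
#' cohenKappa(matrix(c(20, 10, 5, 15), 2))  # 0.4
#' @export
cohenKappa <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("rating_a", "rating_b") %in% names(pairs)))
    if (nrow(pairs) < 2L)
      stop("at least 2 screening pairs are required")
    a <- factor(as.logical(pairs$rating_a), levels = c(TRUE, FALSE))
    b <- factor(as.logical(pairs$rating_b), levels = c(TRUE, FALSE))
    tab <- table(a, b)
  } else if (is.matrix(pairs) || is.table(pairs)) {
    tab <- as.matrix(pairs)
    stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
    if (sum(tab) < 2L) stop("at least 2 screening pairs are required")
  } else stop("pairs must be a data.frame or a square contingency table")
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    cond <- simpleError(
      "Cohen's kappa undefined: expected agreement p_e = 1 (both raters constant and identical)")
    class(cond) <- c("littopics_kappa_undefined", class(cond))
    stop(cond)
  }
  (po - pe) / (1 - pe)
}
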