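## Country-mention extraction from raw abstract text.
##
## Matching is literal, token-boundary anchored and case-insensitive,
## except for aliases that double as ordinary English words or personal
## names ("Georgia", "Jordan", "Turkey", "US", ...), which are matched only
## as capitalised in the source text.  Each article contributes at most one
## count per country (set semantics), however often it repeats the name.

#' Load a country alias map
#'
#' Reads a YAML map of canonical country name to alias list (see the
#' shipped \code{country_aliases.yaml} for the format), validating that no
#' alias resolves to two different countries.
#'
#' @param path YAML file; default is the alias file shipped with the
#'   package (ISO-style country list plus common variants such as UK /
#'   Britain, USA / America).
#' @return list with \code{aliases} (data.frame: alias, country,
#'   ambiguous) ready for \code{\link{extractCountries}}.
#' @export
loadCountryAliases <- function(path = extdataPath("country_aliases.yaml")) {
  raw <- yaml::read_yaml(path)
  stopifnot(is.list(raw$countries))
  ambiguous <- as.character(raw$ambiguous %||% character())
  rows <- list()
  for (country in names(raw$countries)) {
    al <- unique(c(country, as.character(raw$countries[[country]])))
    al <- al[nzchar(al)]
    if (!length(al)) stop("country with no usable alias: ", country)
    rows[[country]] <- data.frame(alias = al, country = country,
                                  stringsAsFactors = FALSE)
  }
  aliases <- do.call(rbind, rows)
  rownames(aliases) <- NULL
  key <- tolower(aliases$alias)
  dup <- key[duplicated(key)]
  conflict <- unique(aliases$alias[key %in% dup &
                                     ave(aliases$country, key,
                                         FUN = function(x)
                                           length(unique(x))) > 1])
  if (length(conflict))
    stop("alias maps to two canonical names: ",
         paste(conflict, collapse = ", "))
  aliases <- aliases[!duplicated(key), , drop = FALSE]
  aliases$ambiguous <- aliases$alias %in% ambiguous
  list(aliases = aliases)
}

aliasRegex <- function(alias) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", alias)
  esc <- gsub("\\s+", "\\\\s+", esc)
  ## token-boundary anchors: "Nigeria" must not count for Niger
  paste0("(?<![A-Za-z])", esc, "(?![A-Za-z])")
}

#' Count country mentions in abstracts
#'
#' Searches each raw (pre-cleaning) abstract for every country name and
#' alias.  An article mentioning several aliases of one country ("the UK
#' and Britain") counts once for that country; articles can count for
#' several different countries.
#'
#' @param records record collection (raw abstracts).
#' @param aliasMap from \code{\link{loadCountryAliases}}.
#' @param matchAmbiguousLowercase if TRUE, aliases flagged ambiguous are
#'   matched case-insensitively like the rest (default FALSE: capitalised
#'   occurrences only).
#' @return list with \code{counts} (data.frame country, n; countries with
#'   zero mentions omitted; sorted by decreasing n then name) and
#'   \code{perArticle} (named list: record_id -> character vector of
#'   countries mentioned).
#' @export
extractCountries <- function(records, aliasMap = loadCountryAliases(),
                             matchAmbiguousLowercase = FALSE) {
  records <- validateRecords(records)
  al <- aliasMap$aliases
  regex <- vapply(al$alias, aliasRegex, character(1))
  ci <- !al$ambiguous | matchAmbiguousLowercase
  perArticle <- vector("list", nrow(records))
  names(perArticle) <- records$record_id
  for (i in seq_len(nrow(records))) {
    text <- records$abstract[i]
    if (!nzchar(text)) { perArticle[[i]] <- character(); next }
    hit <- vapply(seq_len(nrow(al)), function(j) {
      grepl(regex[j], text, perl = TRUE, ignore.case = ci[j])
    }, logical(1))
    perArticle[[i]] <- csort(unique(al$country[hit]))
  }
  tab <- table(unlist(perArticle))
  if (length(tab)) {
    ord <- order(-as.integer(tab), names(tab), method = "radix")
    counts <- data.frame(country = names(tab)[ord],
                         n = as.integer(tab)[ord],
                         stringsAsFactors = FALSE)
  } else {
    counts <- data.frame(country = character(), n = integer(),
                         stringsAsFactors = FALSE)
  }
  list(counts = counts, perArticle = perArticle)
}

#' Serialise a country alias map
#'
#' Writes the alias map back to YAML in the same format
#' \code{\link{loadCountryAliases}} reads, so that edited maps round-trip.
#'
#' @param aliasMap from \code{\link{loadCountryAliases}}.
#' @param path output YAML path.
#' @export
writeCountryAliases <- function(aliasMap, path) {
  al <- aliasMap$aliases
  countries <- lapply(split(al, al$country), function(d) {
    as.list(setdiff(d$alias, d$country[1]))
  })
  yaml::write_yaml(list(
    countries = countries[csort(names(countries))],
    ambiguous = al$alias[al$ambiguous]
  ), path)
  invisible(path)
}
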