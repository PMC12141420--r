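# Fixture builders shared across test files; everything is constructed in
# code so the suite has no binary or downloaded inputs.

makeRecords <- function(ids, titles = sprintf("Title %s", ids),
                        abstracts = sprintf("Abstract for %s", ids),
                        years = rep(2005L, length(ids)),
                        journals = rep("Journal A", length(ids)),
                        source = rep("other", length(ids))) {
  data.frame(record_id = ids, title = titles, abstract = abstracts,
             year = years, journal = journals, source_db = source,
             included = rep(NA, length(ids)), stringsAsFactors = FALSE)
}

writeTempCsv <- function(records, path = tempfile(fileext = ".csv")) {
  df <- data.frame(id = records$record_id, title = records$title,
                   abstract = records$abstract, year = records$year,
                   journal = records$journal, source_db = records$source_db)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Independent Dirichlet-multinomial evaluation of the collapsed LDA joint
# p(w, z) for a tiny corpus; used to enumerate conditionals by brute force.
collapsedJointLogProb <- function(z, docOfToken, wordOfToken, D, V, K,
                                  alpha, beta) {
  ndk <- matrix(0L, D, K); nkv <- matrix(0L, K, V)
  for (i in seq_along(z)) {
    ndk[docOfToken[i], z[i]] <- ndk[docOfToken[i], z[i]] + 1L
    nkv[z[i], wordOfToken[i]] <- nkv[z[i], wordOfToken[i]] + 1L
  }
  nk <- rowSums(nkv); nd <- rowSums(ndk)
  ll <- K * (lgamma(V * beta) - V * lgamma(beta)) +
    sum(lgamma(nkv + beta)) - sum(lgamma(nk + V * beta)) +
    D * (lgamma(K * alpha) - K * lgamma(alpha)) +
    sum(lgamma(ndk + alpha)) - sum(lgamma(nd + K * alpha))
  ll
}

# A small deterministic theta matrix with strictly positive entries.
toyTheta <- function(D, K, seed = 42) {
  set.seed(seed)
  m <- matrix(rgamma(D * K, shape = 0.5) + 1e-4, D, K)
  m / rowSums(m)
}

# Build a DocTermMatrix straight from a synthetic corpus with default
# cleaning.
corpusDtm <- function(corpus, config = cleaningConfig()) {
  toks <- cleanText(corpusRecords(corpus)$abstract, config)
  buildDtm(toks, corpusRecords(corpus)$record_id, config)
}
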