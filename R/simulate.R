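## Synthetic corpus generator with known LDA ground truth: pseudo-word
## abstracts drawn from an LDA generative model, per-year topic-prevalence
## trends via prior tilting, journal labels and injected country mentions.
## Every pipeline stage is testable against the stored truth without any
## external data.

.simCountryPool <- c("Australia", "Brazil", "Canada", "China", "Finland",
                     "Germany", "Japan", "Kenya", "Norway", "Spain")

#' Simulation configuration
#'
#' Defaults describe a mid-sized abstract corpus with a handful of
#' well-separated topics: 500 documents of mean length 100 tokens over a
#' 500-term vocabulary, 5 topics, sparse topic-word distributions
#' (betaTrue = 0.01) and concentrated document-topic mixtures
#' (alphaTrue = 0.1), published 1989-2019 across 25 journals whose
#' contributions follow a Zipf profile, with a modest fraction of abstracts
#' naming a study country.
#'
#' @param kTrue number of generating topics.
#' @param V vocabulary size (pseudo-words \code{w0001}, ...).
#' @param D number of documents.
#' @param meanDocLength Poisson mean token count per document.
#' @param alphaTrue,betaTrue generating Dirichlet concentrations.
#' @param yearRange integer vector of publication years.
#' @param trendIntercepts,trendSlopes per-topic coefficients of the
#'   year-dependent softmax prior tilt (on the year standardised to
#'   [-1, 1]); zero slopes give a stationary corpus.  Default slopes spread
#'   evenly over [-1, 1], so early topics decline while late topics rise.
#' @param yearGrowth exponential growth rate of yearly publication volume
#'   (default 0.08, i.e. about 8\% more articles per year, the familiar
#'   expansion of a research field).
#' @param journalCount,journalZipf number of journals and the Zipf exponent
#'   of their article shares.
#' @param countryRate fraction of abstracts that mention a study country.
#' @param seed RNG seed.
#' @return validated config list (class \code{littopics_sim_config}).
#' @export
simulationConfig <- function(kTrue = 5L, V = 500L, D = 500L,
                             meanDocLength = 100,
                             alphaTrue = 0.1, betaTrue = 0.01,
                             yearRange = 1989:2019,
                             trendIntercepts = rep(0, kTrue),
                             trendSlopes = seq(-1, 1, length.out = kTrue),
                             yearGrowth = 0.08,
                             journalCount = 25L, journalZipf = 1,
                             countryRate = 0.2, seed = 1L) {
  cfg <- list(kTrue = as.integer(kTrue), V = as.integer(V),
              D = as.integer(D), meanDocLength = meanDocLength,
              alphaTrue = alphaTrue, betaTrue = betaTrue,
              yearRange = as.integer(yearRange),
              trendIntercepts = as.numeric(trendIntercepts),
              trendSlopes = as.numeric(trendSlopes),
              yearGrowth = yearGrowth,
              journalCount = as.integer(journalCount),
              journalZipf = journalZipf,
              countryRate = countryRate, seed = as.integer(seed))
  if (cfg$V < 2L) stop("infeasible config: V must be >= 2")
  if (cfg$kTrue < 1L || cfg$D < 1L) stop("infeasible config: kTrue, D >= 1")
  if (cfg$meanDocLength <= 0 || cfg$alphaTrue <= 0 || cfg$betaTrue <= 0)
    stop("infeasible config: lengths and concentrations must be positive")
  if (!length(cfg$yearRange)) stop("infeasible config: empty year range")
  if (length(cfg$trendIntercepts) != cfg$kTrue ||
      length(cfg$trendSlopes) != cfg$kTrue)
    stop("infeasible config: one trend coefficient pair per topic")
  if (cfg$countryRate < 0 || cfg$countryRate > 1)
    stop("infeasible config: countryRate in [0, 1]")
  class(cfg) <- "littopics_sim_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic corpus with known truth
#'
#' Per document: a year is drawn (volume growing over the window), the
#' document-topic prior is tilted by the year-dependent softmax trend,
#' theta_d ~ Dirichlet(alpha_d), tokens via z ~ theta_d, w ~ phi_z with
#' phi_k ~ Dirichlet(betaTrue) fixed across years (topics are fixed;
#' only prevalence shifts).  Tokens are rendered as stem-like pseudo-words
#' so preprocessing is a near no-op; \code{\link{injectNoise}} adds decoys
#' that exercise the cleaning pipeline.  The same (config, seed) yields
#' byte-identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\linkS4class{SyntheticCorpus}}.
#' @export
generateCorpus <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "littopics_sim_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(restoreSeed(old), add = TRUE)

  K <- config$kTrue; V <- config$V; D <- config$D
  vocab <- sprintf("w%04d", seq_len(V))
  phi <- t(vapply(seq_len(K),
                  function(k) rdirichlet1(rep(config$betaTrue, V)),
                  numeric(V)))
  colnames(phi) <- vocab

  yrs <- config$yearRange
  yw <- exp(config$yearGrowth * (yrs - min(yrs)))
  years <- sample(yrs, D, replace = TRUE, prob = yw / sum(yw))
  span <- max(yrs) - min(yrs)
  tstd <- if (span == 0) rep(0, D) else
    2 * (years - mean(range(yrs))) / span

  theta <- matrix(0, D, K)
  tokens <- vector("list", D)
  for (d in seq_len(D)) {
    u <- config$trendIntercepts + config$trendSlopes * tstd[d]
    w <- exp(u - max(u))
    alphaD <- config$alphaTrue * K * w / sum(w)
    theta[d, ] <- rdirichlet1(alphaD)
    nd <- max(1L, stats::rpois(1, config$meanDocLength))
    z <- sample.int(K, nd, replace = TRUE, prob = theta[d, ])
    tokens[[d]] <- vapply(z, function(k)
      sample.int(V, 1L, prob = phi[k, ]), integer(1))
  }

  jw <- (seq_len(config$journalCount))^(-config$journalZipf)
  journals <- sprintf("Journal %02d", sample.int(config$journalCount, D,
                                                 replace = TRUE,
                                                 prob = jw / sum(jw)))
  countries <- vector("list", D)
  for (d in seq_len(D)) {
    countries[[d]] <- if (stats::runif(1) < config$countryRate)
      sample(.simCountryPool, sample(1:2, 1)) else character()
  }

  ids <- sprintf("doc%04d", seq_len(D))
  rownames(theta) <- ids
  abstracts <- vapply(seq_len(D), function(d) {
    txt <- paste(vocab[tokens[[d]]], collapse = " ")
    if (length(countries[[d]]))
      txt <- paste0(txt, " Field sites in ",
                    paste(countries[[d]], collapse = " and "), ".")
    txt
  }, character(1))
  records <- data.frame(
    record_id = ids,
    title = sprintf("Synthetic article %04d", seq_len(D)),
    abstract = abstracts,
    year = years,
    journal = journals,
    source_db = "other",
    included = TRUE,
    stringsAsFactors = FALSE
  )
  new("SyntheticCorpus",
      records = records, phiTrue = phi, thetaTrue = theta,
      tokens = tokens, vocabulary = vocab,
      years = as.integer(years), journals = journals,
      countries = countries,
      noiseLog = data.frame(record_id = character(), type = character(),
                            token = character(),
                            stringsAsFactors = FALSE),
      config = unclass(config), seed = config$seed)
}

#' Inject cleaning decoys into a synthetic corpus
#'
#' Adds tokens the cleaning pipeline is contractually required to remove —
#' stop-words, spelled-out numbers, hyphenated search-term variants
#' ("climate-change") and a publisher boilerplate sentence — at seeded
#' random positions, plus optionally a custom rare decoy term in chosen
#' documents (for document-frequency boundary checks).  Everything injected
#' is recorded in the corpus noise log so tests can assert exact removal.
#'
#' @param corpus a \code{\linkS4class{SyntheticCorpus}}.
#' @param stopWordsPerDoc,numberWordsPerDoc,hyphenatedPerDoc decoy tokens
#'   per document.
#' @param publisherBoilerplate append a copyright sentence to each
#'   abstract.
#' @param decoyTerm,decoyDocs inject \code{decoyTerm} once into each of the
#'   documents indexed by \code{decoyDocs}.
#' @param seed RNG seed for injection positions.
#' @return the corpus with modified abstracts and a populated
#'   \code{noiseLog}.
#' @export
injectNoise <- function(corpus, stopWordsPerDoc = 5L, numberWordsPerDoc = 3L,
                        hyphenatedPerDoc = 2L, publisherBoilerplate = TRUE,
                        decoyTerm = NULL, decoyDocs = integer(),
                        seed = corpus@seed + 1L) {
  stopifnot(is(corpus, "SyntheticCorpus"))
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restoreSeed(old), add = TRUE)

  stopPool <- c("the", "and", "of", "with", "from", "these", "very")
  numberPool <- c("twenty", "five", "hundred", "third", "ninety")
  hyphenPool <- c("climate-change", "global-warming", "global-change")
  boiler <- "Copyright Elsevier all rights reserved."

  records <- corpus@records
  log <- list()
  for (d in seq_len(nrow(records))) {
    words <- strsplit(records$abstract[d], " ", fixed = TRUE)[[1]]
    add <- character(); addType <- character()
    if (stopWordsPerDoc > 0) {
      add <- c(add, sample(stopPool, stopWordsPerDoc, replace = TRUE))
      addType <- c(addType, rep("stopword", stopWordsPerDoc))
    }
    if (numberWordsPerDoc > 0) {
      add <- c(add, sample(numberPool, numberWordsPerDoc, replace = TRUE))
      addType <- c(addType, rep("numberword", numberWordsPerDoc))
    }
    if (hyphenatedPerDoc > 0) {
      add <- c(add, sample(hyphenPool, hyphenatedPerDoc, replace = TRUE))
      addType <- c(addType, rep("hyphenated", hyphenatedPerDoc))
    }
    if (!is.null(decoyTerm) && d %in% decoyDocs) {
      add <- c(add, decoyTerm)
      addType <- c(addType, "decoy")
    }
    for (tok in add) {
      pos <- sample.int(length(words) + 1L, 1L) - 1L
      words <- append(words, tok, after = pos)
    }
    txt <- paste(words, collapse = " ")
    if (publisherBoilerplate) txt <- paste(txt, boiler)
    records$abstract[d] <- txt
    if (length(add))
      log[[length(log) + 1L]] <- data.frame(
        record_id = records$record_id[d], type = addType,
        token = add, stringsAsFactors = FALSE)
  }
  corpus@records <- records
  corpus@noiseLog <- if (length(log)) do.call(rbind, log) else
    corpus@noiseLog
  corpus
}

#' Simulate per-topic yearly counts from the popularity GLMM
#'
#' Draws counts y_kt ~ Poisson(lambda_kt) with
#' log lambda_kt = mu + gamma t + b0_k + b1_k t, where t is the centred
#' calendar year (in years) and (b0_k, b1_k) are independent normal with
#' standard deviations sigma0 and sigma1.  Ground truth is returned for
#' recovery tests of \code{\link{fitPopularityGLMM}}.
#'
#' @param K number of topics.
#' @param years integer vector of calendar years.
#' @param mu,gamma fixed intercept and per-year fixed slope.
#' @param sigma0,sigma1 random-effect standard deviations (per-year units
#'   for the slope).
#' @param seed RNG seed.
#' @return list with \code{counts} (data.frame topic, year, count),
#'   \code{b0}, \code{b1} (true per-topic effects).
#' @export
simulateTopicYearCounts <- function(K = 40L, years = 1990:2019,
                                    mu = 2, gamma = 0.05,
                                    sigma0 = 0.5, sigma1 = 0.1,
                                    seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restoreSeed(old), add = TRUE)
  tc <- years - mean(years)
  b0 <- stats::rnorm(K, 0, sigma0)
  b1 <- stats::rnorm(K, 0, sigma1)
  g <- expand.grid(topic = seq_len(K), year = years,
                   KEEP.OUT.ATTRS = FALSE)
  t <- tc[match(g$year, years)]
  lambda <- exp(mu + gamma * t + b0[g$topic] + b1[g$topic] * t)
  g$count <- stats::rpois(nrow(g), lambda)
  list(counts = g, b0 = b0, b1 = b1)
}
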