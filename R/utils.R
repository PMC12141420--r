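## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic C-locale sort so vocabulary and document order never depend
## on the session locale.
csort <- function(x) sort(x, method = "radix")

corderIdx <- function(x) order(x, method = "radix")

cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match fitted topics to reference topics
#'
#' Finds the one-to-one assignment of fitted topic-word rows to reference
#' rows that maximises total cosine similarity.  For up to 9 topics the
#' assignment is solved exactly by enumerating permutations; beyond that a
#' greedy best-pair heuristic is used.
#'
#' @param phiFit fitted K x V topic-word matrix.
#' @param phiRef reference K x V topic-word matrix (same column order).
#' @return list with \code{assignment} (integer: reference row matched to
#'   each fitted row), \code{cosines} (per matched pair) and
#'   \code{meanCosine}.
#' @export
matchTopics <- function(phiFit, phiRef) {
  stopifnot(is.matrix(phiFit), is.matrix(phiRef),
            nrow(phiFit) == nrow(phiRef), ncol(phiFit) == ncol(phiRef))
  K <- nrow(phiFit)
  sim <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    sim[i, j] <- cosineSim(phiFit[i, ], phiRef[j, ])
  if (K <= 9L) {
    perms <- permutationsOf(K)
    best <- NULL; bestVal <- -Inf
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      v <- sum(sim[cbind(seq_len(K), p)])
      if (v > bestVal) { bestVal <- v; best <- p }
    }
    assignment <- best
  } else {
    assignment <- integer(K)
    simw <- sim
    for (step in seq_len(K)) {
      ij <- arrayInd(which.max(simw), dim(simw))
      assignment[ij[1]] <- ij[2]
      simw[ij[1], ] <- -Inf
      simw[, ij[2]] <- -Inf
    }
  }
  cosines <- sim[cbind(seq_len(K), assignment)]
  list(assignment = assignment, cosines = cosines,
       meanCosine = mean(cosines))
}

permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(i, rest[sub[s, ]])
    }
  }
  out
}

## Resolve a file shipped under inst/extdata.
extdataPath <- function(name) {
  p <- system.file("extdata", name, package = "littopics")
  if (p == "") stop("extdata file not found: ", name)
  p
}

readWordList <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

## Write a data.frame as deterministic TSV (no quoting surprises, C locale
## untouched ordering left to the caller).
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
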