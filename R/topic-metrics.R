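## Derived statistics over a fitted topic model: decadal prevalence,
## co-occurrence, generality vs. specificity, per-topic article frequency,
## journal contribution.

thetaMatrix <- function(theta) {
  if (is(theta, "LDAModel")) theta <- docTopicDist(theta)
  stopifnot(is.matrix(theta), all(is.finite(theta)))
  theta
}

## Argmax per row with ties broken by lowest topic index (max.col would
## randomise); ties are reported via the "ties" attribute.
argmaxTopics <- function(theta) {
  rowMax <- apply(theta, 1, max)
  sel <- apply(theta, 1, which.max)  # which.max takes the first maximum
  ties <- rowSums(theta == rowMax) > 1L
  structure(as.integer(sel), ties = which(ties))
}

#' Decadal topic prevalence
#'
#' Sums each topic's per-article weight (theta) over the articles published
#' within each decade.  Articles outside the configured decades (for the
#' default window, anything before 1990 or after 2019 — e.g. a lone 1989
#' article) are excluded and their number reported via the
#' \code{"nExcluded"} attribute.  Since theta rows sum to one, each decade
#' column sums to the number of articles in that decade.
#'
#' @param theta D x K document-topic matrix (or an \code{LDAModel}).
#' @param years integer calendar year per document (NA allowed; excluded).
#' @param decadeStarts first years of the decades to tabulate
#'   (default \code{c(1990, 2000, 2010)}).
#' @return list with \code{weights} (K x decades summed-weight matrix),
#'   \code{ranks} (K x decades rank table, 1 = highest weight, ties by
#'   topic index) and \code{articles} (articles per decade); attribute
#'   \code{"nExcluded"} counts excluded articles.
#' @export
decadalPrevalence <- function(theta, years,
                              decadeStarts = c(1990L, 2000L, 2010L)) {
  theta <- thetaMatrix(theta)
  stopifnot(length(years) == nrow(theta))
  decadeStarts <- sort(as.integer(decadeStarts))
  decade <- ifelse(is.na(years), NA_integer_,
                   as.integer(floor(years / 10) * 10))
  inWindow <- !is.na(decade) & decade %in% decadeStarts
  nExcluded <- sum(!inWindow)
  if (nExcluded)
    message(nExcluded, " article(s) outside configured decades excluded ",
            "from prevalence")
  K <- ncol(theta)
  labels <- paste0(decadeStarts, "s")
  W <- matrix(0, K, length(decadeStarts),
              dimnames = list(paste0("topic", seq_len(K)), labels))
  nArt <- integer(length(decadeStarts))
  for (j in seq_along(decadeStarts)) {
    rows <- inWindow & decade == decadeStarts[j]
    nArt[j] <- sum(rows)
    if (nArt[j]) W[, j] <- colSums(theta[rows, , drop = FALSE])
  }
  ranks <- apply(W, 2, function(w) rank(-w, ties.method = "first"))
  structure(list(weights = W, ranks = ranks,
                 articles = stats::setNames(nArt, labels)),
            nExcluded = nExcluded)
}

#' Topic co-occurrence matrix
#'
#' Topic weights are log10-transformed per article and the Euclidean
#' distance between each pair of topic weight profiles (columns of log10
#' theta over articles) is computed.  Distances are mapped to a 0-1
#' co-occurrence scale by \code{1 - d/dmax} (\code{rescale = "max"},
#' default, with dmax the largest off-diagonal distance) or by min-max
#' rescaling: 1 means the pair always co-occurs (identical profiles), 0
#' marks the most dissociated pair.  The raw distance matrix is returned
#' alongside, since the rescaling convention is a declared choice.
#'
#' @param theta strictly positive D x K document-topic matrix (Dirichlet
#'   smoothing guarantees positivity) or an \code{LDAModel}.
#' @param rescale \code{"max"} or \code{"minmax"}.
#' @return list with \code{cooccurrence} (K x K, symmetric, unit diagonal)
#'   and \code{distance} (raw Euclidean distances).
#' @export
topicCooccurrence <- function(theta, rescale = c("max", "minmax")) {
  rescale <- match.arg(rescale)
  theta <- thetaMatrix(theta)
  if (nrow(theta) < 2L) stop("at least 2 documents are required")
  if (any(theta <= 0))
    stop("theta contains zero weights; use smoothed (Dirichlet posterior ",
         "mean) estimates")
  lt <- log10(theta)
  d <- as.matrix(stats::dist(t(lt)))
  off <- d[upper.tri(d)]
  dmax <- max(off)
  dmin <- if (rescale == "minmax") min(off) else 0
  if (dmax - dmin <= 0) {
    C <- matrix(1, ncol(theta), ncol(theta))
  } else {
    C <- 1 - (d - dmin) / (dmax - dmin)
  }
  diag(C) <- 1
  dimnames(C) <- dimnames(d) <-
    list(paste0("topic", seq_len(ncol(theta))),
         paste0("topic", seq_len(ncol(theta))))
  list(cooccurrence = C, distance = d)
}

#' Topic generality vs. specificity
#'
#' For each article the highest-weighted topic is "selected" (ties broken
#' by lowest topic index).  A topic's generality contrasts its mean weight
#' in articles where it was selected against its mean weight elsewhere:
#' general topics keep substantial weight even when not selected, specific
#' topics concentrate in the articles they dominate.  Topics never selected
#' get \code{n_selected = 0} and a missing (NA) selected mean.
#'
#' @param theta D x K document-topic matrix or an \code{LDAModel}.
#' @return data.frame with columns topic, n_selected, mean_weight_selected,
#'   mean_weight_unselected.
#' @export
topicGenerality <- function(theta) {
  theta <- thetaMatrix(theta)
  sel <- argmaxTopics(theta)
  if (length(attr(sel, "ties")))
    message(length(attr(sel, "ties")),
            " article(s) with tied top weight; lowest topic index selected")
  K <- ncol(theta)
  out <- data.frame(
    topic = seq_len(K),
    n_selected = integer(K),
    mean_weight_selected = NA_real_,
    mean_weight_unselected = NA_real_
  )
  for (k in seq_len(K)) {
    isSel <- sel == k
    out$n_selected[k] <- sum(isSel)
    if (any(isSel))
      out$mean_weight_selected[k] <- mean(theta[isSel, k])
    if (any(!isSel))
      out$mean_weight_unselected[k] <- mean(theta[!isSel, k])
  }
  out
}

#' Per-topic article frequency
#'
#' Emits both readings of "frequency of topics across articles, given the
#' topic weight": (a) the number of articles in which each topic carries
#' the highest weight, and (b) the histogram of each topic's weights across
#' all articles, binned on [0, 1].
#'
#' @param theta D x K document-topic matrix or an \code{LDAModel}.
#' @param breaks histogram bin boundaries on [0, 1].
#' @return list with \code{argmaxCounts} (length K; sums to D) and
#'   \code{weightHistogram} (K x bins matrix of article counts; each row
#'   sums to D).
#' @export
articleTopicFrequency <- function(theta, breaks = seq(0, 1, by = 0.05)) {
  theta <- thetaMatrix(theta)
  sel <- argmaxTopics(theta)
  K <- ncol(theta)
  counts <- tabulate(sel, nbins = K)
  hist <- t(apply(theta, 2, function(w)
    tabulate(findInterval(w, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(breaks) - 1L)))
  colnames(hist) <- paste0("[", utils::head(breaks, -1), ",",
                           utils::tail(breaks, -1), ")")
  rownames(hist) <- paste0("topic", seq_len(K))
  list(argmaxCounts = stats::setNames(counts, rownames(hist)),
       weightHistogram = hist)
}

#' Journal publication contribution
#'
#' Ranks journals by article count (ties lexicographic), reports the
#' cumulative share contributed by the top-N journals, and profiles each
#' journal's topics by the mean theta over its articles and by argmax
#' counts.
#'
#' @param records record collection aligned with \code{theta} rows (same
#'   order, or matched by record_id when theta carries row names).
#' @param theta D x K document-topic matrix or an \code{LDAModel}.
#' @return list with \code{counts} (data.frame journal, n, share,
#'   cumulative_share, sorted), \code{topShare(n)} convenience function,
#'   \code{meanTheta} (journal x K) and \code{argmaxCounts} (journal x K).
#' @export
journalContribution <- function(records, theta) {
  theta <- thetaMatrix(theta)
  records <- validateRecords(records)
  if (!is.null(rownames(theta))) {
    idx <- match(rownames(theta), records$record_id)
    if (anyNA(idx))
      stop("theta row names not found among record ids")
    records <- records[idx, , drop = FALSE]
  }
  stopifnot(nrow(records) == nrow(theta))
  journal <- records$journal
  tab <- table(journal)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  counts <- data.frame(
    journal = names(tab)[ord],
    n = as.integer(tab)[ord],
    stringsAsFactors = FALSE
  )
  counts$share <- 100 * counts$n / sum(counts$n)
  counts$cumulative_share <- cumsum(counts$share)
  sel <- argmaxTopics(theta)
  K <- ncol(theta)
  meanTheta <- matrix(NA_real_, nrow(counts), K,
                      dimnames = list(counts$journal,
                                      paste0("topic", seq_len(K))))
  argmaxCounts <- matrix(0L, nrow(counts), K,
                         dimnames = dimnames(meanTheta))
  for (j in seq_len(nrow(counts))) {
    rows <- journal == counts$journal[j]
    meanTheta[j, ] <- colMeans(theta[rows, , drop = FALSE])
    argmaxCounts[j, ] <- tabulate(sel[rows], nbins = K)
  }
  topShare <- function(n) sum(counts$n[seq_len(min(n, nrow(counts)))]) /
    sum(counts$n) * 100
  list(counts = counts, topShare = topShare,
       meanTheta = meanTheta, argmaxCounts = argmaxCounts)
}

#' Write metric tables as TSV
#'
#' Serialises the outputs of the derived-statistic functions into a
#' directory of TSV files (matrices with a leading id column), giving a
#' deterministic on-disk record of an analysis.
#'
#' @param metrics named list; entries may be matrices, data.frames or the
#'   list outputs of the metric functions (flattened one level).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeMetricTables <- function(metrics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  flat <- list()
  for (nm in names(metrics)) {
    x <- metrics[[nm]]
    if (is.list(x) && !is.data.frame(x)) {
      for (sub in names(x)) {
        if (is.function(x[[sub]])) next
        flat[[paste0(nm, "_", sub)]] <- x[[sub]]
      }
    } else flat[[nm]] <- x
  }
  for (nm in names(flat)) {
    x <- flat[[nm]]
    if (is.matrix(x)) {
      df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), x,
                       check.names = FALSE, stringsAsFactors = FALSE)
    } else if (is.data.frame(x)) {
      df <- x
    } else {
      df <- data.frame(id = names(x) %||% seq_along(x), value = as.vector(x),
                       stringsAsFactors = FALSE)
    }
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeTsv(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
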