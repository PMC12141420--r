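test_that("CSV ingestion maps all rows and fields", {
  recs <- makeRecords(c("a1", "a2", "a3"), years = c(1995L, 2003L, 2011L))
  path <- writeTempCsv(recs)
  got <- readRecords(path, "csv")
  expect_equal(nrow(got), 3L)
  expect_equal(got$record_id, recs$record_id)
  expect_equal(got$year, recs$year)
  expect_equal(got$abstract, recs$abstract)
})

test_that("RIS entries parse, with empty abstract when AB is absent", {
  path <- tempfile(fileext = ".ris")
  writeLines(c(
    "TY  - JOUR",
    "ID  - r1",
    "TI  - Spring arrival of migratory birds",
    "AB  - Long-term records show earlier arrival.",
    "PY  - 2004",
    "JO  - Journal of Avian Biology",
    "ER  - ",
    "TY  - JOUR",
    "ID  - r2",
    "TI  - A study without abstract",
    "PY  - 2010",
    "JO  - Oikos",
    "ER  - "
  ), path)
  got <- readRecords(path, "ris")
  expect_equal(nrow(got), 2L)
  expect_match(got$abstract[1], "earlier arrival")
  expect_identical(got$abstract[2], "")
  expect_equal(got$year, c(2004L, 2010L))
})

test_that("RIS continuation lines are folded into the open tag", {
  path <- tempfile(fileext = ".ris")
  writeLines(c(
    "TY  - JOUR",
    "ID  - r1",
    "TI  - Title line one",
    "  continued over two lines",
    "PY  - 1999",
    "ER  - "
  ), path)
  got <- readRecords(path, "ris")
  expect_match(got$title, "continued over two lines")
})

test_that("BibTeX entries parse with braced and quoted values", {
  path <- tempfile(fileext = ".bib")
  writeLines(c(
    "@article{smith2001,",
    "  title = {Budburst timing in {Betula}},",
    "  abstract = \"Warming advances budburst.\",",
    "  year = {2001},",
    "  journal = {Global Change Biology}",
    "}",
    "@article{jones2015,",
    "  title = {No abstract here},",
    "  year = {2015},",
    "  journal = {Ecology Letters}",
    "}"
  ), path)
  got <- readRecords(path, "bibtex")
  expect_equal(got$record_id, c("smith2001", "jones2015"))
  expect_match(got$title[1], "Budburst timing")
  expect_identical(got$abstract[2], "")
  expect_equal(got$year, c(2001L, 2015L))
})

test_that("duplicate record ids and missing years are handled as contracted", {
  recs <- makeRecords(c("x", "x"))
  path <- writeTempCsv(recs)
  expect_error(readRecords(path, "csv"), "duplicate record_id")

  recs2 <- makeRecords(c("a", "b"))
  recs2$year[2] <- NA
  path2 <- writeTempCsv(recs2)
  expect_warning(got <- readRecords(path2, "csv"), "lack a year")
  expect_equal(nrow(got), 2L)
  expect_true(is.na(got$year[2]))
})

test_that("deduplication uses normalised title + year and keeps the first", {
  recs <- makeRecords(
    c("a", "b", "c", "d"),
    titles = c("Phenology of oaks.", "phenology of OAKS",
               "Phenology of oaks", "Something else"),
    years = c(2005L, 2005L, 2006L, 2005L)
  )
  out <- deduplicateRecords(recs)
  # b duplicates a (case + trailing period); c differs by year and stays
  expect_equal(out$records$record_id, c("a", "c", "d"))
  expect_equal(out$removed$record_id, "b")
  expect_equal(out$removed$duplicate_of, "a")
})

test_that("deduplication is idempotent and safe on empty input", {
  recs <- makeRecords(c("a", "b"), titles = c("One Title", "one title!"),
                      years = c(2000L, 2000L))
  once <- deduplicateRecords(recs)
  twice <- deduplicateRecords(once$records)
  expect_equal(once$records, twice$records)
  expect_equal(nrow(twice$removed), 0L)

  empty <- deduplicateRecords(makeRecords(character()))
  expect_equal(nrow(empty$records), 0L)
})

test_that("fuzzy deduplication only engages behind its flag", {
  recs <- makeRecords(c("a", "b"),
                      titles = c("Phenology of alpine plants",
                                 "Phenology of alpine plant"),
                      years = c(2002L, 2002L))
  expect_equal(nrow(deduplicateRecords(recs)$records), 2L)
  expect_equal(nrow(deduplicateRecords(recs, fuzzy = TRUE)$records), 1L)
})

test_that("records without abstracts are dropped, with warning when all go", {
  recs <- makeRecords(c("a", "b", "c"))
  recs$abstract[2] <- ""
  out <- dropMissingAbstracts(recs)
  expect_equal(out$record_id, c("a", "c"))

  expect_equal(nrow(dropMissingAbstracts(recs)), 2L)
  allEmpty <- makeRecords(c("a", "b"))
  allEmpty$abstract <- ""
  expect_warning(out2 <- dropMissingAbstracts(allEmpty), "empty abstracts")
  expect_equal(nrow(out2), 0L)
})

test_that("screening subset sampling is seeded and sized correctly", {
  recs <- makeRecords(sprintf("r%02d", 1:50))
  s1 <- sampleScreeningSubset(recs, 0.2, seed = 9L)
  s2 <- sampleScreeningSubset(recs, 0.2, seed = 9L)
  s3 <- sampleScreeningSubset(recs, 0.2, seed = 10L)
  expect_equal(length(s1), 10L)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_true(all(s1 %in% recs$record_id))
})

test_that("Cohen's kappa matches hand-derived values", {
  # perfect agreement on a 50/50 split
  expect_equal(cohenKappa(matrix(c(25, 0, 0, 25), 2)), 1.0)
  # worked 2x2 example: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(cohenKappa(matrix(c(20, 10, 5, 15), 2)), 0.4)
  # data.frame interface agrees with the table interface
  pairs <- data.frame(
    record_id = sprintf("p%02d", 1:50),
    rating_a = rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 10, 15)),
    rating_b = rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 10, 15))
  )
  expect_equal(cohenKappa(pairs), 0.4)
})

test_that("kappa is symmetric in raters and zero under independence", {
  set.seed(3)
  for (i in 1:10) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    expect_equal(cohenKappa(tab), cohenKappa(t(tab)), tolerance = 1e-12)
  }
  # joint table equal to the outer product of its marginals
  for (pa in c(0.3, 0.5, 0.8)) {
    for (pb in c(0.2, 0.6)) {
      n <- 1000
      tab <- n * outer(c(pa, 1 - pa), c(pb, 1 - pb))
      expect_equal(cohenKappa(tab), 0, tolerance = 1e-12)
    }
  }
})

test_that("kappa against brute-force recomputation on random tables", {
  set.seed(17)
  for (i in 1:20) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (sum(tab) < 2) next
    n <- sum(tab)
    po <- (tab[1, 1] + tab[2, 2]) / n
    pe <- (sum(tab[1, ]) * sum(tab[, 1]) +
             sum(tab[2, ]) * sum(tab[, 2])) / n^2
    if (abs(1 - pe) < 1e-12) next
    expect_equal(cohenKappa(tab), (po - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("kappa signals explicitly when expected agreement is 1", {
  tab <- matrix(c(10, 0, 0, 0), 2)  # both raters always say yes
  expect_error(cohenKappa(tab), class = "littopics_kappa_undefined")
  expect_error(cohenKappa(matrix(c(1, 0, 0, 0), 2)), "at least 2")
})
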