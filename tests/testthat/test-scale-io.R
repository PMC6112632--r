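test_that("CSV responses round-trip and missing cells propagate", {
  spec <- cvss17_spec()
  set.seed(7)
  m <- sapply(spec$item_ids, function(it)
    sample.int(spec$n_categories[[it]], 2L, replace = TRUE))
  rownames(m) <- c("a", "b")
  rm <- response_matrix(m, spec, gender = c("F", "M"), age = c(30, 45))

  f <- tempfile(fileext = ".csv")
  write_responses(rm, f)
  back <- read_responses(f, spec)
  expect_identical(back$responses, rm$responses)
  expect_identical(sum(is.na(back$responses)), 0L)
  expect_equal(back$age, c(30, 45))

  # blank a single cell -> exactly one missing cell
  df <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
  df[1, "A21"] <- ""
  utils::write.csv(df, f, row.names = FALSE, na = "")
  back2 <- read_responses(f, spec)
  expect_identical(sum(is.na(back2$responses)), 1L)
  expect_true(is.na(back2$responses["a", "A21"]))

  # unparseable cell becomes missing with a warning
  df[2, "A9"] <- "x"
  utils::write.csv(df, f, row.names = FALSE, na = "")
  expect_warning(back3 <- read_responses(f, spec), "unparseable")
  expect_identical(sum(is.na(back3$responses)), 2L)
})

test_that("malformed response files are rejected with informative errors", {
  spec <- toy_spec3()
  f <- tempfile(fileext = ".csv")
  writeLines(c("person,i1,i2,i3,zz", "a,1,1,1,1"), f)
  expect_error(read_responses(f, spec), "zz")
  writeLines(c("person,i1,i2,i3", "a,1,1,1", "a,2,2,2"), f)
  expect_error(read_responses(f, spec), "duplicate person id")
  m <- matrix(1L, 1, 3)
  expect_error(rm_from(matrix(5L, 1, 3), spec), "invalid category")
})

test_that("raw scores follow the score chart, with the published range", {
  spec <- cvss17_spec()
  lo <- vapply(spec$item_ids, function(it) 1L, 0L)
  hi <- spec$n_categories
  m <- rbind(lo, hi)
  rm <- rm_from(m, spec)
  s <- raw_score(rm, "total")
  expect_equal(unname(s), c(17, 53))
  expect_equal(score_range(spec, "total"), c(17, 53))

  # hand-summed oracle on a 3-item toy with a custom chart
  chart <- list(total = list(i1 = c(0, 2, 5), i2 = c(1, 1, 4), i3 = c(0, 3, 6)),
                S = list(i1 = c(0, 2, 5), i2 = c(1, 1, 4), i3 = c(0, 3, 6)))
  sp <- scale_spec(c("i1", "i2", "i3"), 3L, "S", chart = chart)
  rm2 <- rm_from(matrix(c(2L, 3L, 1L), 1), sp)
  expect_equal(unname(raw_score(rm2, "total")), 2 + 4 + 0)

  # a missing item makes the score undefined unless prorated
  m3 <- matrix(c(1L, NA, 2L), 1)
  rm3 <- rm_from(m3, toy_spec3())
  expect_true(is.na(raw_score(rm3, "total")))
  expect_equal(unname(raw_score(rm3, "total", prorate = TRUE)), (1 + 2) / 2 * 3)
})

test_that("subscale charts are independent of the total chart", {
  spec <- cvss17_spec()
  expect_equal(sum(spec$subscale == "ESF"), 11L)
  expect_equal(sum(spec$subscale == "ISF"), 6L)
  sub <- subscale_spec(spec, "ISF")
  expect_equal(length(sub$item_ids), 6L)
  m <- matrix(1L, 1, 6)
  expect_equal(unname(raw_score(rm_from(m, sub), "total")), 6)
})

test_that("person filters apply the answered and outfit rules", {
  spec <- cvss17_spec()
  full <- vapply(spec$item_ids, function(it) 1L, 0L)
  m <- rbind(full, full, full)
  m[2, 1:6] <- NA    # answers 11 of 17 items
  rownames(m) <- c("p1", "p2", "p3")
  rm <- response_matrix(m, spec)

  out <- filter_persons(rm, min_answered = 12L)
  expect_identical(out$persons, c("p1", "p3"))
  expect_equal(attr(out, "exclusions")[["too_few_answered"]], 1)

  # outfit exactly at the cap is retained (the rule is strictly over)
  of <- c(p1 = 2.5, p3 = 2.51)
  out2 <- filter_persons(out, person_outfit = of, min_answered = 12L,
                         outfit_cap = 2.5)
  expect_identical(out2$persons, "p1")

  # no-op when everyone conforms, and the filter is idempotent
  ok <- filter_persons(rm, person_outfit = c(p1 = 1, p2 = 1, p3 = 1),
                       min_answered = 11L)
  expect_identical(ok$persons, rm$persons)
  again <- filter_persons(ok, person_outfit = c(p1 = 1, p2 = 1, p3 = 1),
                          min_answered = 11L)
  expect_identical(again$responses, ok$responses)

  expect_error(filter_persons(rm, min_answered = 18L), "exceeds")
})

test_that("the shipped synthetic example data load and score cleanly", {
  f <- system.file("extdata", "synthetic_responses.csv",
                   package = "cvssrasch")
  spec <- cvss17_spec()
  rm <- read_responses(f, spec)
  expect_equal(length(rm$persons), 60L)
  s <- raw_score(rm, "total")
  expect_true(all(s[!is.na(s)] >= 17 & s[!is.na(s)] <= 53))

  chart <- read_score_chart(system.file(
    "extdata", "score_chart_default.json", package = "cvssrasch"))
  sp2 <- cvss17_spec(chart = chart)
  expect_equal(raw_score(response_matrix(rm$responses, sp2,
                                         person_ids = rm$persons), "total"), s)
})

test_that("gender by presbyopia groups partition persons at age > 39", {
  spec <- toy_spec3()
  m <- matrix(1L, 5, 3)
  rm <- rm_from(m, spec,
                gender = c("F", "M", "F", "M", NA),
                age = c(40, 39, 25, 64, 30))
  g <- assign_groups(rm)
  expect_equal(as.character(g[1:4]), c("PW", "NPM", "NPW", "PM"))
  expect_true(is.na(g[5]))
  expect_equal(attr(g, "n_ungrouped"), 1L)
  expect_equal(sum(table(g)), 4L)  # grouped persons partition
})
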