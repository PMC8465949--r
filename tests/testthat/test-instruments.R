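test_that("SNOT-20 subscores follow the block formulas and normalization", {
  z <- snot20_scores(rep(0, 20))
  expect_equal(unlist(z), c(primary_nasal = 0, secondary_nasal = 0,
                            general_qol = 0, sum_score = 0))
  m <- snot20_scores(rep(5, 20))
  expect_equal(unlist(m), c(primary_nasal = 100, secondary_nasal = 100,
                            general_qol = 100, sum_score = 100))

  r <- rep(0, 20); r[c(1, 2, 3, 5, 10)] <- 1
  s <- snot20_scores(r)
  expect_equal(s$primary_nasal, 20)   # 5 items * 1 / 25 * 100
  expect_equal(s$secondary_nasal, 0)
  expect_equal(s$general_qol, 0)
  expect_equal(s$sum_score, 5)

  # subscores stay in [0, 100] for arbitrary valid ratings
  set.seed(1)
  for (i in 1:25) {
    s <- snot20_scores(sample(0:5, 20, replace = TRUE))
    expect_true(all(unlist(s[1:3]) >= 0 & unlist(s[1:3]) <= 100))
  }

  expect_error(snot20_scores(rep(1, 19)), "20")
  expect_error(snot20_scores(c(rep(1, 19), 6)), "0..5")
  expect_error(snot20_scores(c(rep(1, 19), NA)), "issing")
})

test_that("SNOT-20 symptom freedom uses strict cutoffs 12/14/12/10.5", {
  near <- list(primary_nasal = 11.9, secondary_nasal = 10.4,
               general_qol = 13.9, sum_score = 11)
  expect_true(all(snot20_symptom_free(near)))

  at <- list(primary_nasal = 12, secondary_nasal = 10.4,
             general_qol = 13.9, sum_score = 11)
  flags <- snot20_symptom_free(at)
  expect_false(flags[["primary"]])
  expect_true(all(flags[c("total", "general", "secondary")]))

  zero <- list(primary_nasal = 0, secondary_nasal = 0, general_qol = 0,
               sum_score = 0)
  expect_true(all(snot20_symptom_free(zero)))
})

test_that("TDI diagnosis partitions [0, 48] with hyposmia closed at both ends", {
  expect_equal(as.character(olfactory_diagnosis(16.4)), "anosmia")
  expect_equal(as.character(olfactory_diagnosis(16.5)), "hyposmia")
  expect_equal(as.character(olfactory_diagnosis(30.5)), "hyposmia")
  expect_equal(as.character(olfactory_diagnosis(35)), "normosmia")
  # exhaustive and mutually exclusive over a fine grid
  g <- olfactory_diagnosis(seq(0, 48, by = 0.1))
  expect_false(anyNA(g))
  expect_equal(sort(unique(as.character(g))),
               c("anosmia", "hyposmia", "normosmia"))
  expect_error(olfactory_diagnosis(-1), "non-negative")
})

test_that("perceptible olfactory improvement is a >= 5.5 point TDI gain", {
  expect_true(perceptible_improvement(20, 25.5))
  expect_false(perceptible_improvement(20, 25.4))
  expect_false(perceptible_improvement(20, 14))
})

test_that("endoscopic totals sum per-side grades and flag LK < 2", {
  top <- endoscopic_totals(c(3, 3), rep(2, 10))
  expect_equal(top$lildholdt, 6)
  expect_equal(top$lund_kennedy, 20)
  expect_false(top$lk_no_findings)

  none <- endoscopic_totals(c(0, 0), rep(0, 10))
  expect_equal(none$lildholdt, 0)
  expect_equal(none$lund_kennedy, 0)
  expect_true(none$lk_no_findings)

  mid <- endoscopic_totals(c(1, 2), c(1, rep(0, 4), 1, rep(0, 4)))
  expect_equal(mid$lildholdt, 3)
  expect_equal(mid$lund_kennedy, 2)
  expect_false(mid$lk_no_findings)  # 2 is not < 2

  expect_error(endoscopic_totals(c(4, 0), rep(0, 10)), "0..3")
  expect_error(endoscopic_totals(c(1, 1), rep(3, 10)), "0..2")
})

test_that("default schema has 37 variables split 3/8/14/12 over categories", {
  s <- default_schema()
  expect_equal(nrow(s), 37)
  expect_equal(as.integer(table(s$category)[c("anatomy", "olfactory", "qol",
                                              "demographic")]),
               c(3L, 8L, 14L, 12L))
  expect_false(anyDuplicated(s$name) > 0)
})

test_that("schema round-trips through YAML and JSON", {
  s <- default_schema()
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_schema(s, f)
    s2 <- read_schema(f)
    expect_equal(as.data.frame(s2), as.data.frame(s))
    unlink(f)
  }
})

test_that("cohort CSV I/O round-trips losslessly and rejects bad input", {
  sch <- toy_schema()
  tab <- toy_cohort()
  expect_equal(nrow(tab), 4)
  f <- tempfile(fileext = ".csv")
  write_cohort(tab, f)
  back <- read_cohort(f, sch)
  expect_equal(back, tab)  # missing values preserved

  dup <- rbind(tab, tab[1, ])
  write_cohort(dup, f)
  expect_error(read_cohort(f, sch), "duplicated")

  bad <- tab; bad$extra_var <- 1
  write_cohort(bad, f)
  expect_error(read_cohort(f, sch), "unknown")

  txt <- readLines({ write_cohort(tab, f); f })
  txt[2] <- sub("40", "forty", txt[2])
  writeLines(txt, f)
  expect_error(read_cohort(f, sch), "unparseable")
  unlink(f)
})

test_that("cohort validation enforces schema support", {
  sch <- toy_schema()
  tab <- toy_cohort()
  tab$gradeC[1] <- 9  # outside 0..5
  expect_error(validate_cohort(tab, sch), "support")
})
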