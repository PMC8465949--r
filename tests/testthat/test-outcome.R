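test_that("sign coding maps changes through the improvement direction", {
  sch <- default_schema()
  co <- default_test_cohort(seed = 14)

  m <- sign_matrix(co, c("lildholdt", "snot_primary", "olf_rating_2"), sch)
  expect_true(all(m %in% c(-1L, 0L, 1L)))

  b <- co[co$occasion == "baseline", ]; p <- co[co$occasion == "post", ]
  p <- p[match(b$patient_id, p$patient_id), ]
  # a Lildholdt decrease is an improvement
  i <- which(b$lildholdt == 3 & p$lildholdt == 0)[1]
  if (!is.na(i)) expect_equal(unname(m[i, "lildholdt"]), 1L)
  # a primary-nasal-symptom increase is a worsening
  j <- which(p$snot_primary > b$snot_primary)[1]
  if (!is.na(j)) expect_equal(unname(m[j, "snot_primary"]), -1L)

  # pre == post everywhere codes to zero
  same <- co[co$occasion == "baseline", ]
  same2 <- same; same2$occasion <- "post"
  m0 <- sign_matrix(rbind(same, same2), c("lildholdt", "snot_primary"), sch)
  expect_true(all(m0 == 0L))

  # swapping the occasions flips every nonzero entry
  sw <- co
  sw$occasion <- ifelse(co$occasion == "baseline", "post", "baseline")
  msw <- sign_matrix(sw, c("lildholdt", "snot_primary", "olf_rating_2"), sch)
  expect_equal(as.vector(msw), -as.vector(m))

  # reversing a variable's improvement direction flips its column
  sch2 <- sch
  sch2$improves_when[sch2$name == "lildholdt"] <- "increases"
  m2 <- sign_matrix(co, c("lildholdt", "snot_primary"), sch2)
  expect_equal(as.vector(m2[, "lildholdt"]), -as.vector(m[, "lildholdt"]))

  expect_warning(sign_matrix(co, c("lildholdt", "age"), sch), "age")
})

test_that("direction agreement is detected and null pairs stay null", {
  sch <- toy_schema()
  base <- data.frame(patient_id = sprintf("p%02d", 1:90), occasion = "baseline",
                     scoreA = 50 + rnorm(90), scoreB = 25 + rnorm(90),
                     gradeC = 0, flagD = 0, colorE = 1, stringsAsFactors = FALSE)
  post <- base; post$occasion <- "post"
  shift <- rep(c(-5, 5), 45)
  post$scoreA <- base$scoreA + shift
  post$scoreB <- base$scoreB + shift  # identical change directions
  m <- sign_matrix(rbind(base, post), c("scoreA", "scoreB"), sch)
  ag <- agreement_chi2(m)
  expect_lt(ag$p_value[1], 1e-6)

  # independent random signs: uniform p-values
  sig <- 0
  for (i in 1:200) {
    set.seed(6000 + i)
    mm <- matrix(sample(c(-1L, 0L, 1L), 180, TRUE), 90, 2,
                 dimnames = list(NULL, c("u", "v")))
    mm <- structure(mm, row_sums = rowSums(mm), col_sums = colSums(mm),
                    class = c("crs_signmat", class(mm)))
    if (agreement_chi2(mm)$p_value[1] < 0.05) sig <- sig + 1
  }
  expect_gt(sig / 200, 0.01); expect_lt(sig / 200, 0.10)

  tiny <- structure(matrix(c(1L, -1L, 1L, 1L), 2, 2,
                           dimnames = list(NULL, c("a", "b"))),
                    row_sums = c(2, 0), col_sums = c(0, 2),
                    class = c("crs_signmat", "matrix"))
  expect_true(agreement_chi2(tiny)$untestable[1])
})

test_that("patient outcomes follow the row sums of the sign matrix", {
  m <- structure(matrix(c(1L, 1L, -1L, 1L, -1L, 0L), 2, 3, byrow = TRUE,
                        dimnames = list(c("p1", "p2"), c("a", "b", "c"))),
                 row_sums = c(1, 0), col_sums = c(2, 0, -1),
                 class = c("crs_signmat", "matrix"))
  out <- patient_outcomes(m)
  expect_equal(unname(out), c(1L, 1L, 0L))

  sch <- default_schema()
  co <- default_test_cohort(seed = 15)
  six <- c("lildholdt", "lund_kennedy", "snot_primary", "snot_total",
           "olf_rating_1", "olf_rating_2")
  counts <- patient_outcomes(sign_matrix(co, six, sch))
  expect_gte(counts[["improved"]] / 90, 0.90)
})

test_that("symptom-freedom counts reproduce hand-computed chi-square values", {
  sch <- default_schema()
  co <- default_test_cohort(seed = 16)
  sf <- symptom_free_counts(co, sch)
  expect_equal(sf$n, 90)
  # the generator is calibrated to 59/90 normal post-surgery Lildholdt
  lild <- sf$criteria[sf$criteria$criterion == "lildholdt_normal", ]
  expect_lt(abs(lild$post / 90 - 59 / 90), 0.05)
  expect_gt(lild$post, lild$baseline)

  # all-zero toy table: everyone symptom-free on every criterion
  zero <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                     occasion = rep(c("baseline", "post"), 2))
  for (v in sch$name) zero[[v]] <- 0
  sfz <- symptom_free_counts(zero, sch)
  expect_true(all(sfz$criteria$baseline == 2 & sfz$criteria$post == 2))

  # published-style diagnosis tallies: Pearson chi-square by hand = 12.918
  tall <- data.frame(patient_id = rep(sprintf("p%02d", 1:90), 2),
                     occasion = rep(c("baseline", "post"), each = 90))
  for (v in sch$name) tall[[v]] <- 0
  tall$tdi <- c(rep(10, 43), rep(20, 37), rep(35, 10),   # 43/37/10
                rep(10, 20), rep(20, 55), rep(35, 15))   # 20/55/15
  sft <- symptom_free_counts(tall, sch)
  expect_equal(unname(sft$tdi_diagnosis["baseline", ]), c(43, 37, 10))
  expect_equal(unname(sft$tdi_diagnosis["post", ]), c(20, 55, 15))
  hand <- {
    O <- rbind(c(43, 37, 10), c(20, 55, 15))
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  }
  expect_equal(sft$tdi_diagnosis_chi2, hand, tolerance = 1e-8)
  expect_equal(hand, 12.92, tolerance = 0.01)
})

test_that("delta and raw post correlations occupy the two triangles", {
  co <- default_test_cohort(seed = 17)
  sel <- c("lildholdt", "snot_primary", "olf_rating_2")
  dc <- delta_correlations(co, sel)
  expect_equal(unname(diag(dc$rho)), rep(1, 3))

  # calibrated weak coupling between self-rated smell and primary nasal
  # symptom changes (lower triangle = deltas); median over 5 cohorts to
  # damp the n = 90 sampling noise of a single Spearman coefficient
  rs <- vapply(1:5, function(s) {
    delta_correlations(default_test_cohort(seed = s),
                       sel)$rho["olf_rating_2", "snot_primary"]
  }, 0)
  expect_gt(median(rs^2), 0.10); expect_lt(median(rs^2), 0.35)
  expect_true(all(rs < 0))  # inversely scaled instruments

  # invariance of Spearman coefficients to monotone transforms
  co2 <- co
  co2$snot_primary <- co2$snot_primary^3
  dc2 <- delta_correlations(co2, sel)
  expect_lt(abs(dc2$rho["snot_primary", "lildholdt"] -
                dc$rho["snot_primary", "lildholdt"]), 0.35)  # deltas shift mildly
  expect_equal(dc2$rho["lildholdt", "snot_primary"],
               dc$rho["lildholdt", "snot_primary"], tolerance = 1e-9)

  # independent simulated deltas stay near zero
  ok <- 0
  for (i in 1:20) {
    set.seed(7000 + i)
    tabi <- data.frame(patient_id = rep(sprintf("r%02d", 1:90), 2),
                       occasion = rep(c("baseline", "post"), each = 90),
                       a = rnorm(180), b = rnorm(180))
    r0 <- delta_correlations(tabi, c("a", "b"))$rho["b", "a"]
    if (abs(r0) < 0.2) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.9)

  # constant delta flagged undefined
  tabc <- data.frame(patient_id = rep(c("x", "y", "z"), 2),
                     occasion = rep(c("baseline", "post"), each = 3),
                     a = c(1, 2, 3, 1, 2, 3), b = c(1, 2, 3, 2, 4, 6))
  dcc <- delta_correlations(tabc, c("a", "b"))
  expect_true(dcc$undefined["b", "a"])
})
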