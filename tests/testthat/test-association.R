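toy_assoc_cohort <- function() {
  # 6 patients, 4 treated with cisplatin: 2 in cluster 0 (both ADR),
  # 2 outside (one ADR); the 2 untreated are in cluster 0, one with ADR
  clinical <- tibble::tibble(
    patient_id = sprintf("P%d", 1:6),
    age = 60, sex = "male", stage = "IIIA",
    treatments = c("cisplatin", "cisplatin", "cisplatin", "cisplatin",
                   "other", "other"),
    adr_any = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    adr_categories = ifelse(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                            "hematologic", ""))
  labels <- stats::setNames(c(0L, 0L, 1L, 1L, 0L, 0L), clinical$patient_id)
  list(clinical = clinical, clustering = clustering_from_labels(labels))
}

test_that("contingency tables follow both orientation conventions", {
  co <- toy_assoc_cohort()
  ta <- build_contingency(co$clinical, co$clustering, "cisplatin", 0, "A")
  expect_equal(c(ta$a, ta$b, ta$c, ta$d), c(2, 0, 1, 1))
  # convention B: within cluster 0, treated vs untreated
  tb <- build_contingency(co$clinical, co$clustering, "cisplatin", 0, "B")
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(2, 0, 1, 1))
  tb1 <- build_contingency(co$clinical, co$clustering, "cisplatin", 1, "B")
  expect_equal(c(tb1$a, tb1$b, tb1$c, tb1$d), c(1, 1, 0, 0))

  expect_error(build_contingency(co$clinical, co$clustering, "pemetrexed", 0),
               "pemetrexed")
})

test_that("planted tables are reproduced cell for cell", {
  pt <- make_planted_table_cohort(contingency_table(7, 2, 2, 3), "cisplatin", 0)
  tab <- build_contingency(pt$clinical, pt$clustering, "cisplatin", 0)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(7, 2, 2, 3))

  ptb <- make_planted_table_cohort(contingency_table(3, 4, 2, 6), "carboplatin",
                                   1, convention = "B", n_patients = 20)
  tabb <- build_contingency(ptb$clinical, ptb$clustering, "carboplatin", 1, "B")
  expect_equal(c(tabb$a, tabb$b, tabb$c, tabb$d), c(3, 4, 2, 6))

  expect_error(make_planted_table_cohort(contingency_table(0, 0, 0, 0), "x", 0),
               "infeasible")
})

test_that("odds ratios match closed-form values, with Haldane on zero cells", {
  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1))$or_value, 1)

  est <- odds_ratio(contingency_table(7, 2, 2, 3))
  expect_equal(round_half_up(est$or_value), 5.25)
  expect_equal(round_half_up(est$ci_low), 0.49)
  expect_equal(round_half_up(est$ci_high), 56.80)
  expect_false(est$haldane_applied)

  esth <- odds_ratio(contingency_table(0, 5, 3, 10))
  expect_true(esth$haldane_applied)
  expect_equal(esth$or_value, (0.5 * 10.5) / (5.5 * 3.5), tolerance = 1e-12)

  expect_error(odds_ratio(contingency_table(0, 5, 3, 10), haldane = FALSE),
               "zero cell")
})

test_that("the chi-square is Pearson on the raw cells", {
  tab <- contingency_table(10, 5, 3, 12)
  est <- odds_ratio(tab)
  ref <- suppressWarnings(stats::chisq.test(matrix(c(10, 3, 5, 12), 2),
                                            correct = FALSE))
  expect_equal(est$chi2, unname(ref$statistic))
  expect_equal(est$p_chi2, unname(ref$p.value))
  est_y <- odds_ratio(tab, yates = TRUE)
  expect_lt(est_y$chi2, est$chi2)
  # zero margin: chi-square undefined, OR still estimable via Haldane
  est0 <- odds_ratio(contingency_table(0, 0, 3, 10))
  expect_true(is.na(est0$chi2))
})

test_that("odds-ratio symmetries and the Woolf identity hold", {
  set.seed(31)
  for (rep in 1:50) {
    cells <- sample(1:30, 4, replace = TRUE)  # no zeros: Haldane off
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    est <- odds_ratio(contingency_table(a, b, c, d))
    rec <- odds_ratio(contingency_table(b, a, d, c))
    expect_equal(est$or_value * rec$or_value, 1, tolerance = 1e-12)
    swapped <- odds_ratio(contingency_table(d, b, c, a))
    expect_equal(est$or_value, swapped$or_value, tolerance = 1e-12)
    # geometric-mean identity, pre-rounding
    expect_equal(exp((log(est$ci_low) + log(est$ci_high)) / 2), est$or_value,
                 tolerance = 1e-9)
  }
  # identity also holds on Haldane-corrected tables
  est <- odds_ratio(contingency_table(0, 4, 2, 9))
  expect_equal(exp((log(est$ci_low) + log(est$ci_high)) / 2), est$or_value,
               tolerance = 1e-9)
})

test_that("table recovery from printed values is exhaustive", {
  # planted round trip: table -> printed OR/CI -> recover must contain it
  set.seed(41)
  for (rep in 1:10) {
    cells <- sample(0:8, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    est <- odds_ratio(do.call(contingency_table, as.list(cells)))
    printed_ci <- c(round_half_up(est$ci_low), round_half_up(est$ci_high))
    rec <- recover_table(round_half_up(est$or_value), printed_ci,
                         n_max = sum(cells))
    expect_true(any(rec$a == cells[1] & rec$b == cells[2] &
                    rec$c == cells[3] & rec$d == cells[4]))
  }
  # an OR outside its own CI matches nothing
  rec0 <- recover_table(2.0, c(3.0, 4.0), n_max = 12)
  expect_equal(nrow(rec0), 0)
})

test_that("association scan covers treatments, aggregates and risk flags", {
  pt <- make_planted_table_cohort(contingency_table(7, 2, 2, 3), "cisplatin", 0,
                                  n_patients = 20)
  rows <- suppressWarnings(associate_all(pt$clinical, pt$clustering))
  r0 <- rows[rows$treatment == "cisplatin" & rows$cluster == 0, ]
  expect_equal(c(r0$a, r0$b, r0$c, r0$d), c(7, 2, 2, 3))
  expect_true(r0$risk)
  # nobody received pemetrexed: no such rows, warning on the way
  expect_false("pemetrexed" %in% rows$treatment)
  expect_warning(associate_all(pt$clinical, pt$clustering,
                               treatments = "pemetrexed"), "skipping")

  # aggregate platinum table total = |cisplatin u carboplatin| treated
  clin <- pt$clinical
  clin$treatments[15:18] <- "carboplatin"
  rows2 <- suppressWarnings(associate_all(clin, pt$clustering,
                                          treatments = "platinum_compounds"))
  expect_equal(rows2$a + rows2$b + rows2$c + rows2$d,
               rep(14 + 4, nrow(rows2)))
})

test_that("display rounding is half-up and only applied at serialization", {
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(2.675), 2.68)
  expect_equal(round_half_up(56.801, 2), 56.80)
  rows <- tibble::tibble(or = 1.005, ci_low = 0.4849, ci_high = 2.345)
  out <- format_association(rows)
  expect_equal(out$or, 1.01)
  expect_equal(out$ci_low, 0.48)
})
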