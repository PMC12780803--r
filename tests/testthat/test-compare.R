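test_that("Fisher exact test matches frozen enumeration values", {
  # equal row proportions: every table is at least as probable -> p = 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  # margins (4,4|4,4): support probs {1,16,36,16,1}/70, observed 16/70,
  # mass <= observed is 34/70
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p_value, 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  # the overall CAP-vs-non-CAP symbol table is decisively non-null
  expect_lt(fisher_exact_2x2(555, 191, 3352, 1752)$p_value, 0.001)
})

test_that("Fisher p agrees with an independent enumeration and with fisher.test", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4)))
    ours <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    expect_equal(ours, fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    m <- matrix(cells, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(ours, stats::fisher.test(m)$p.value, tolerance = 1e-10)
    }
  }
  # moderate totals against the reference implementation, tight tolerance
  for (i in 1:60) {
    n <- sample(41:200, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.1, 1)))
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value,
                 stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is symmetric under row and column swaps and in [0,1]", {
  set.seed(9)
  for (i in 1:100) {
    cells <- as.vector(stats::rmultinom(1, sample(1:60, 1), runif(4)))
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(p, fisher_exact_2x2(cells[3], cells[4], cells[1], cells[2])$p_value)
    expect_equal(p, fisher_exact_2x2(cells[2], cells[1], cells[4], cells[3])$p_value)
  }
})

test_that("degenerate margins give p = 1; bad counts error; OR sentinels documented", {
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p_value, 1)
  expect_equal(fisher_exact_2x2(2, 0, 3, 0)$p_value, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "non-negative integers")
  expect_equal(fisher_exact_2x2(2, 3, 4, 5)$odds_ratio, (2 * 5) / (3 * 4))
  expect_equal(fisher_exact_2x2(2, 0, 4, 5)$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(0, 3, 4, 0)$odds_ratio, 0)
  expect_true(is.na(fisher_exact_2x2(0, 3, 0, 4)$odds_ratio))
  td <- tidy(fisher_exact_2x2(3, 1, 1, 3))
  expect_equal(td$p.value, 34 / 70)
})

test_that("reported percentages round half-up to one decimal", {
  expect_equal(report_percent(555, 746), 74.4)
  expect_equal(report_percent(366, 746), 49.1)
  expect_equal(report_percent(0, 5), 0)
  expect_equal(report_percent(1, 16), 6.3)   # 6.25 rounds up, not to even
  expect_equal(report_percent(1, 8), 12.5)
  expect_equal(report_percent(74, 5104), 1.4)
  expect_error(report_percent(1, 0), "positive")
})

test_that("summarize_supply reproduces hand-tallied counts per stratum and overall", {
  supply <- make_products(
    8,
    tra_sub = rep(c("cereal", "candy"), each = 4),
    reference_amount_g = 100, serving_size_g = 100,
    # sugars %DV equals grams here; thresholds: general tier 15 %
    total_sugars_g = c(20, 2, 16, 1, 30, 30, 2, 2),
    sodium_mg = c(400, 10, 10, 10, 10, 350, 10, 10),
    saturated_fat_g = 0,
    exemptions = c(rep(list(character(0)), 3), list("health"),
                   rep(list(character(0)), 4)),
    techniques = list("fun_shape", "fun_shape", character(0), character(0),
                      "fun_shape", character(0), character(0), "game_activity")
  )
  run <- summarize_supply(supply, evaluate_products(supply), classify_cap(supply))
  ac <- run$arm_counts
  cereal_cap <- ac[ac$stratum == "cereal" & ac$arm == "CAP", ]
  expect_equal(cereal_cap$n, 2)
  expect_equal(cereal_cap$n_two, 1)      # sugars 20 + sodium 400 (17.4 %)
  expect_equal(cereal_cap$n_zero, 1)
  expect_equal(cereal_cap$n_displays, 1)
  cereal_non <- ac[ac$stratum == "cereal" & ac$arm == "non-CAP", ]
  expect_equal(cereal_non$n, 2)
  expect_equal(cereal_non$n_exempt, 1)
  expect_equal(cereal_non$n_one, 1)      # sugars 16
  overall <- ac[ac$stratum == "Overall", ]
  expect_equal(sum(overall$n), 8)
  # overall row equals the sum over strata for every count column
  for (col in grep("^n", names(ac), value = TRUE)) {
    expect_equal(sum(ac[[col]][ac$stratum != "Overall" & ac$arm == "CAP"]),
                 overall[[col]][overall$arm == "CAP"], info = col)
  }
  expect_true(all(run$tests$p_value >= 0 & run$tests$p_value <= 1))
})

test_that("summaries are invariant to product order and single products degrade", {
  supply <- generate_supply(test_generator(seed = 12, n = 200))
  fop <- evaluate_products(supply)
  cap <- classify_cap(supply)
  s1 <- summarize_supply(supply, fop, cap)
  perm <- sample(nrow(supply))
  s2 <- summarize_supply(supply[perm, ], fop[perm, ], cap[perm, ])
  expect_equal(s1$arm_counts, s2$arm_counts)
  expect_equal(s1$tests, s2$tests)

  one <- as_products(supply[1, ])
  s3 <- summarize_supply(one, evaluate_products(one), classify_cap(one))
  ov <- s3$arm_counts[s3$arm_counts$stratum == "Overall", ]
  st <- s3$arm_counts[s3$arm_counts$stratum != "Overall", ]
  expect_equal(dplyr::select(ov, -"stratum"), dplyr::select(st, -"stratum"))
})

test_that("mismatched product ids are rejected; Holm adjustment is opt-in", {
  supply <- generate_supply(test_generator(seed = 2, n = 100))
  fop <- evaluate_products(supply)
  cap <- classify_cap(supply)
  expect_error(summarize_supply(supply, fop[-1, ], cap), "must match")
  s <- summarize_supply(supply, fop, cap, p_adjust = "holm")
  expect_true("p_adjusted" %in% names(s$tests))
  expect_true(is.na(s$tests$p_adjusted[s$tests$stratum == "Overall"]))
})

test_that("tidy and glance expose the summary as tibbles", {
  supply <- generate_supply(test_generator(seed = 4, n = 300))
  s <- summarize_supply(supply, evaluate_products(supply), classify_cap(supply))
  g <- glance(s)
  expect_equal(g$n, 300)
  expect_equal(g$cap_prevalence_pct, report_percent(s$n_cap, 300))
  td <- tidy(s)
  expect_true(all(c("stratum", "arm", "n", "p_value", "displays_pct") %in% names(td)))
})
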