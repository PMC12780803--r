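test_that("exemption precedence is health > technical > practical over all subsets", {
  classes <- c("health", "technical", "practical")
  subsets <- unlist(lapply(0:3, function(k) combn(classes, k, simplify = FALSE)),
                    recursive = FALSE)
  expected <- vapply(subsets, function(s) {
    if (length(s) == 0) NA_character_ else classes[classes %in% s][1]
  }, character(1))
  expect_identical(check_exemption(subsets), expected)
  # precedence affects only the reported reason, never the exempt boolean
  res <- evaluate_products(make_products(
    length(subsets), exemptions = subsets, total_sugars_g = 80))
  expect_identical(res$exempt, lengths(subsets) > 0)
  expect_false(any(res$displays_symbol[res$exempt]))
})

test_that("scaling basis is the greater of serving size and reference amount", {
  expect_equal(compute_basis(30, 55), 55)
  expect_equal(compute_basis(30, 30), 30)
  expect_equal(compute_basis(250, NA), 250)
  expect_equal(compute_basis(NA, 40), 40)
  expect_error(compute_basis(NA, NA), "both")
})

test_that("tier boundaries are inclusive and follow the reference amount", {
  tier <- function(ra, ss = ra, md = FALSE, ag = "standard") {
    select_tier(ra, ss, md, ag, fop_policy())
  }
  expect_equal(tier(30), "small")            # <= 30 g is small
  expect_equal(tier(30.1), "general")
  expect_equal(tier(200, md = TRUE), "main_dish")  # >= 200 g main dish
  expect_equal(tier(199, md = TRUE), "general")    # below cutoff: falls through
  expect_equal(tier(25, md = TRUE), "small")
  expect_equal(tier(170, md = TRUE, ag = "young_child"), "main_dish")
  expect_equal(tier(170, md = TRUE, ag = "standard"), "general")
  # RA has primacy for the small-format test; serving used only when RA absent
  expect_equal(tier(ra = 40, ss = 25), "general")
  expect_equal(tier(ra = NA, ss = 25), "small")
})

test_that("percent daily value is plain unrounded arithmetic on the configured DVs", {
  expect_equal(percent_dv(15, "total_sugars_g"), 15)
  expect_equal(percent_dv(0, "sodium_mg"), 0)
  expect_equal(percent_dv(20, "saturated_fat_g"), 100)
  expect_equal(percent_dv(100, "sodium_mg"), 100 * 100 / 2300)
  expect_error(percent_dv(5, "total_sugars_g", "young_child"),
               "no daily values")
})

test_that("evaluate_products reproduces hand-computed decisions", {
  # small-format product below every 10 % threshold
  low <- make_products(1, reference_amount_g = 30, serving_size_g = 30,
                       total_sugars_g = 3, sodium_mg = 100, saturated_fat_g = 0.5)
  r <- evaluate_products(low)
  expect_equal(r$tier, "small")
  expect_equal(r$sugars_pct_dv, 3)
  expect_equal(r$sodium_pct_dv, 100 * 100 / 2300)
  expect_equal(r$saturated_fat_pct_dv, 2.5)
  expect_false(r$displays_symbol)
  expect_equal(r$n_high, 0L)

  # main dish at 30 %: 700 mg sodium = 30.43 %DV -> symbol for sodium only
  md <- make_products(1, is_main_dish = TRUE, reference_amount_g = 250,
                      serving_size_g = 250, sodium_mg = 700,
                      total_sugars_g = 1, saturated_fat_g = 0.5)
  r <- evaluate_products(md)
  expect_equal(r$tier, "main_dish")
  expect_equal(r$sodium_pct_dv, 100 * 700 / 2300)
  expect_true(r$high_in_sodium)
  expect_equal(r$n_high, 1L)
  expect_true(r$displays_symbol)

  # exemption screens first, regardless of nutrient levels
  ex <- make_products(1, exemptions = list("health"), total_sugars_g = 80)
  r <- evaluate_products(ex)
  expect_true(r$exempt)
  expect_equal(r$exemption_reason, "health")
  expect_true(is.na(r$tier))
  expect_false(r$displays_symbol)
  expect_equal(r$n_high, 0L)
})

test_that("per-serving amounts scale linearly to the basis", {
  # serving 25 g, RA 50 g: basis 50, amounts double; 8 g sugars -> 16 %DV >= 15
  p <- make_products(1, serving_size_g = 25, reference_amount_g = 50,
                     total_sugars_g = 8, sodium_mg = 10, saturated_fat_g = 0.1)
  r <- evaluate_products(p)
  expect_equal(r$basis_g, 50)
  expect_equal(r$sugars_pct_dv, 16)
  expect_true(r$high_in_sugars)
  # no stated serving: RA is the only basis and amounts stay unscaled
  p2 <- make_products(1, serving_size_g = NA_real_, reference_amount_g = 50,
                      total_sugars_g = 8)
  expect_equal(evaluate_products(p2)$sugars_pct_dv, 8)
})

test_that("a %DV exactly at the tier threshold is 'high in'", {
  for (case in list(list(ra = 50, sugars = 15, tier = "general"),
                    list(ra = 30, sugars = 10, tier = "small"))) {
    p <- make_products(1, reference_amount_g = case$ra,
                       serving_size_g = case$ra, total_sugars_g = case$sugars,
                       sodium_mg = 0, saturated_fat_g = 0)
    r <- evaluate_products(p)
    expect_equal(r$tier, case$tier)
    expect_true(r$high_in_sugars)
    expect_true(r$displays_symbol)
  }
})

test_that("missing nutrient amounts yield missing flags and never count", {
  p <- make_products(1, total_sugars_g = NA_real_, sodium_mg = 800,
                     saturated_fat_g = NA_real_, reference_amount_g = 100,
                     serving_size_g = 100)
  r <- evaluate_products(p)
  expect_true(is.na(r$high_in_sugars))
  expect_true(is.na(r$high_in_saturated_fat))
  expect_true(r$high_in_sodium)
  expect_equal(r$n_high, 1L)
  expect_true(r$displays_symbol)
})

test_that("raising any single nutrient never lowers flags or n_high", {
  set.seed(42)
  n <- 150
  base <- make_products(
    n,
    reference_amount_g = sample(c(20, 30, 50, 100, 250), n, TRUE),
    serving_size_g = round(runif(n, 15, 260), 1),
    is_main_dish = runif(n) < 0.2,
    saturated_fat_g = round(rlnorm(n, log(1.5), 1), 2),
    total_sugars_g = round(rlnorm(n, log(6), 1), 2),
    sodium_mg = round(rlnorm(n, log(200), 1), 1)
  )
  before <- evaluate_products(base)
  for (col in c("saturated_fat_g", "total_sugars_g", "sodium_mg")) {
    bumped <- base
    bumped[[col]] <- bumped[[col]] * (1 + runif(n, 0, 2))
    after <- evaluate_products(bumped)
    flag <- switch(col, saturated_fat_g = "high_in_saturated_fat",
                   total_sugars_g = "high_in_sugars", sodium_mg = "high_in_sodium")
    expect_false(any(before[[flag]] & !after[[flag]], na.rm = TRUE))
    expect_true(all(after$n_high >= before$n_high))
  }
})

test_that("M2K criteria: meets-or-exceeds at 6/5/10 %DV, exemptions not applied", {
  # exactly 5 %DV sugars -> restricted
  p <- make_products(1, total_sugars_g = 5, sodium_mg = 0, saturated_fat_g = 0,
                     reference_amount_g = 100, serving_size_g = 100)
  expect_true(evaluate_m2k(p)$m2k_restricted)
  # all zero -> not restricted
  p0 <- make_products(1, total_sugars_g = 0, sodium_mg = 0, saturated_fat_g = 0)
  expect_false(evaluate_m2k(p0)$m2k_restricted)
  # exempt product is still screened by M2K
  pe <- make_products(1, exemptions = list("health"), total_sugars_g = 40,
                      reference_amount_g = 100, serving_size_g = 100)
  expect_true(evaluate_m2k(pe)$m2k_restricted)
  # M2K is stricter: fails no FOP threshold (all < 15 %) yet sugars 6 %DV
  lenient_gap <- make_products(1, reference_amount_g = 100, serving_size_g = 100,
                               total_sugars_g = 6, sodium_mg = 100,
                               saturated_fat_g = 0.5)
  expect_false(evaluate_products(lenient_gap)$displays_symbol)
  expect_true(evaluate_m2k(lenient_gap)$m2k_restricted)
})

test_that("products unrestricted under M2K never display the FOP symbol", {
  set.seed(7)
  n <- 400
  pop <- make_products(
    n,
    reference_amount_g = sample(c(20, 30, 50, 100, 250), n, TRUE),
    serving_size_g = round(runif(n, 15, 260), 1),
    is_main_dish = runif(n) < 0.2,
    saturated_fat_g = round(rlnorm(n, log(1), 1.2), 2),
    total_sugars_g = round(rlnorm(n, log(4), 1.2), 2),
    sodium_mg = round(rlnorm(n, log(150), 1.2), 1)
  )
  fop <- evaluate_products(pop)
  m2k <- evaluate_m2k(pop)
  expect_false(any(!m2k$m2k_restricted & fop$displays_symbol))
})

test_that("policy files round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    kind = "fop", name = "custom",
    daily_values = list(standard = list(saturated_fat_g = 20, total_sugars_g = 100,
                                        sodium_mg = 2300),
                        young_child = list(saturated_fat_g = 10, total_sugars_g = 100,
                                           sodium_mg = 1500)),
    small_ra_cutoff_g = 30,
    main_dish_cutoff_g = list(standard = 200, young_child = 170),
    tier_thresholds_pct = list(small = 10, general = 15, main_dish = 30)
  ), path)
  pol <- read_policy(path)
  expect_s3_class(pol, "fop_policy")
  expect_equal(pol$daily_values$young_child[["sodium_mg"]], 1500)
  # young-child main dish at 170 g RA screens at 30 %
  p <- make_products(1, age_group = "young_child", is_main_dish = TRUE,
                     reference_amount_g = 170, serving_size_g = 170,
                     sodium_mg = 500, total_sugars_g = 0, saturated_fat_g = 0)
  r <- evaluate_products(p, pol)
  expect_equal(r$tier, "main_dish")
  expect_true(r$high_in_sodium)  # 500/1500 = 33.3 % >= 30 %
})
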