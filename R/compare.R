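#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test for association in a 2x2 contingency table (here, CAP status
#' by symbol status), computed by enumerating the hypergeometric
#' distribution of the first cell conditional on both margins. The
#' two-sided p-value follows the probability-mass rule: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table, with a relative tolerance of
#' `1e-7` for floating-point ties. Chosen over asymptotic chi-squared
#' because stratified food-category tables routinely have low expected
#' counts.
#'
#' Degenerate tables (an all-zero row or column margin) return `p = 1` by
#' convention. The odds ratio is the unconditional sample estimate
#' `(a d)/(b c)`, reported descriptively: `Inf` when `b c = 0` with
#' `a d > 0`, and `NA` when both products are zero.
#'
#' @param a,b,c,d Non-negative integer counts; rows are the two groups,
#'   columns the two outcomes. Alternatively pass a 2x2 matrix as `a`.
#' @return An object of class `fop_fisher`: a list with `p_value`,
#'   `odds_ratio` and `table`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2)
  }
  counts <- as.vector(m)
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  n <- r1 + r2
  if (n < 1) stop("table total must be at least 1", call. = FALSE)

  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    p <- 1
  } else {
    support <- max(0L, c1 - r2):min(c1, r1)
    probs <- stats::dhyper(support, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NA_real_
  structure(
    list(p_value = p, odds_ratio = or,
         table = matrix(c(a, c_, b, d), nrow = 2,
                        dimnames = list(group = c("row1", "row2"),
                                        outcome = c("col1", "col2")))),
    class = "fop_fisher"
  )
}

#' @export
print.fop_fisher <- function(x, ...) {
  cat("<Fisher exact 2x2>  p =", format(x$p_value, digits = 4),
      " OR =", format(x$odds_ratio, digits = 4), "\n")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fisher_exact_2x2
#' @param x An `fop_fisher` object.
#' @param ... Unused.
#' @method tidy fop_fisher
#' @export
tidy.fop_fisher <- function(x, ...) {
  tibble::tibble(
    estimate = x$odds_ratio,
    p.value = x$p_value,
    method = "Fisher's exact test (two-sided, probability-mass rule)",
    alternative = "two.sided"
  )
}

#' Percentage for reporting
#'
#' `100 * numerator / denominator`, rounded half-up (not banker's) to one
#' decimal — the convention used for every reported proportion.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @return Numeric percentage(s) with one decimal.
#' @export
report_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  p <- 100 * numerator / denominator
  # half-up at the first decimal; tiny epsilon guards binary representation
  floor(p * 10 + 0.5 + 1e-9) / 10
}

#' Summarize a supply: CAP-stratified symbol, threshold-count and nutrient
#' tallies
#'
#' Joins the per-product FOP and CAP results and aggregates, per TRA
#' subcategory and overall, the counts a surveillance report needs: sample
#' sizes, CAP counts, and within each arm (CAP / non-CAP) the number of
#' products exempt, meeting 0, 1, 2 or 3 nutrient thresholds, displaying
#' the symbol, and 'high in' each individual nutrient. For each stratum a
#' two-sided Fisher exact test compares the proportion displaying a symbol
#' between arms; per the reporting convention the "no symbol" column
#' includes exempt products, but an exempt-excluded p-value is also
#' reported. No multiple-testing adjustment is applied across strata by
#' default; set `p_adjust = "holm"` to add one.
#'
#' @param data A products table.
#' @param fop_results Output of [evaluate_products()] for `data`.
#' @param cap_results Output of [classify_cap()] for `data`.
#' @param p_adjust Method for [stats::p.adjust()] across category strata,
#'   or `"none"` (default).
#' @return An object of class `supply_summary`: a list of tibbles
#'   `arm_counts` (one row per stratum x arm, stratum `"Overall"`
#'   included), `tests` (one row per stratum with `p_value`,
#'   `p_value_excl_exempt`, `odds_ratio`), and `n` / `n_cap` scalars.
#' @export
summarize_supply <- function(data, fop_results, cap_results, p_adjust = "none") {
  data <- as_products(data)
  if (!setequal(data$product_id, fop_results$product_id) ||
      !setequal(data$product_id, cap_results$product_id)) {
    stop("product_id sets of data, fop_results and cap_results must match",
         call. = FALSE)
  }
  df <- dplyr::inner_join(
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(data), "product_id", "tra_sub"),
      dplyr::select(fop_results, "product_id", "exempt", "n_high",
                    "displays_symbol", dplyr::starts_with("high_in_")),
      by = "product_id"),
    dplyr::select(cap_results, "product_id", "is_cap"),
    by = "product_id")

  count_arms <- function(g, stratum) {
    g |>
      dplyr::mutate(arm = ifelse(.data$is_cap, "CAP", "non-CAP")) |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_exempt = sum(.data$exempt),
        n_zero = sum(!.data$exempt & .data$n_high == 0L),
        n_one = sum(.data$n_high == 1L),
        n_two = sum(.data$n_high == 2L),
        n_three = sum(.data$n_high == 3L),
        n_displays = sum(.data$displays_symbol),
        n_high_saturated_fat = sum(.data$high_in_saturated_fat, na.rm = TRUE),
        n_high_sugars = sum(.data$high_in_sugars, na.rm = TRUE),
        n_high_sodium = sum(.data$high_in_sodium, na.rm = TRUE),
        .groups = "drop") |>
      dplyr::mutate(stratum = stratum, .before = 1)
  }

  strata <- sort(unique(df$tra_sub))
  arm_counts <- dplyr::bind_rows(
    purrr::map(strata, function(s) count_arms(df[df$tra_sub == s, ], s)),
    count_arms(df, "Overall")
  ) |>
    tidyr::complete(
      stratum = c(strata, "Overall"), arm = c("CAP", "non-CAP"),
      fill = list(n = 0L, n_exempt = 0L, n_zero = 0L, n_one = 0L, n_two = 0L,
                  n_three = 0L, n_displays = 0L, n_high_saturated_fat = 0L,
                  n_high_sugars = 0L, n_high_sodium = 0L)) |>
    dplyr::mutate(stratum = factor(.data$stratum, levels = c(strata, "Overall"))) |>
    dplyr::arrange(.data$stratum, .data$arm) |>
    dplyr::mutate(stratum = as.character(.data$stratum))

  fisher_row <- function(counts) {
    cap <- counts[counts$arm == "CAP", ]
    non <- counts[counts$arm == "non-CAP", ]
    incl <- fisher_exact_2x2(cap$n_displays, cap$n - cap$n_displays,
                             non$n_displays, non$n - non$n_displays)
    excl <- fisher_exact_2x2(cap$n_displays, cap$n - cap$n_exempt - cap$n_displays,
                             non$n_displays, non$n - non$n_exempt - non$n_displays)
    tibble::tibble(p_value = incl$p_value,
                   p_value_excl_exempt = excl$p_value,
                   odds_ratio = incl$odds_ratio)
  }
  tests <- arm_counts |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_modify(~ fisher_row(.x)) |>
    dplyr::ungroup()
  if (!identical(p_adjust, "none")) {
    cat_rows <- tests$stratum != "Overall"
    tests$p_adjusted <- NA_real_
    tests$p_adjusted[cat_rows] <- stats::p.adjust(tests$p_value[cat_rows],
                                                  method = p_adjust)
  }

  structure(
    list(arm_counts = arm_counts, tests = tests,
         n = nrow(df), n_cap = sum(df$is_cap)),
    class = "supply_summary"
  )
}

#' @export
print.supply_summary <- function(x, ...) {
  ov <- x$arm_counts[x$arm_counts$stratum == "Overall", ]
  cat("<supply_summary> ", x$n, " products (", x$n_cap, " CAP, ",
      report_percent(x$n_cap, x$n), " %) across ",
      length(unique(x$arm_counts$stratum)) - 1, " categories\n", sep = "")
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-7s n=%d  displays symbol: %d (%.1f %%)\n", ov$arm[i],
                ov$n[i], ov$n_displays[i], report_percent(ov$n_displays[i], ov$n[i])))
  }
  p <- x$tests$p_value[x$tests$stratum == "Overall"]
  cat("  overall Fisher p =", format.pval(p, digits = 3, eps = 0.001), "\n")
  invisible(x)
}

#' @rdname summarize_supply
#' @param x A `supply_summary`.
#' @param ... Unused.
#' @method glance supply_summary
#' @export
glance.supply_summary <- function(x, ...) {
  ov <- x$arm_counts[x$arm_counts$stratum == "Overall", ]
  cap <- ov[ov$arm == "CAP", ]; non <- ov[ov$arm == "non-CAP", ]
  tibble::tibble(
    n = x$n,
    n_cap = x$n_cap,
    cap_prevalence_pct = report_percent(x$n_cap, x$n),
    cap_displays_pct = report_percent(cap$n_displays, cap$n),
    noncap_displays_pct = report_percent(non$n_displays, non$n),
    overall_displays_pct = report_percent(cap$n_displays + non$n_displays, x$n),
    p_value = x$tests$p_value[x$tests$stratum == "Overall"]
  )
}

#' @rdname summarize_supply
#' @method tidy supply_summary
#' @export
tidy.supply_summary <- function(x, ...) {
  dplyr::left_join(x$arm_counts, x$tests, by = "stratum") |>
    dplyr::mutate(displays_pct = ifelse(.data$n > 0,
                                        report_percent(.data$n_displays, pmax(.data$n, 1)),
                                        NA_real_))
}

#' Report tables from a supply summary
#'
#' Three presentation tables mirroring a surveillance report: the
#' symbol-prevalence comparison by category (`table_symbol`), the
#' exempt/0/1/2/3 threshold-count distribution by arm (`table_threshold_counts`),
#' and the per-nutrient 'high in' tallies by arm (`table_nutrients`).
#' Percentages are arm-relative, one decimal, half-up.
#'
#' @param summary A [summarize_supply()] result.
#' @return A tibble.
#' @export
table_symbol <- function(summary) {
  wide <- tidy(summary) |>
    dplyr::select("stratum", "arm", "n", "n_displays", "displays_pct") |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("n", "n_displays", "displays_pct"))
  dplyr::left_join(wide, summary$tests[, c("stratum", "p_value")], by = "stratum") |>
    dplyr::rename(n_cap = "n_CAP", n_noncap = "n_non-CAP",
                  cap_displays = "n_displays_CAP",
                  noncap_displays = "n_displays_non-CAP",
                  cap_displays_pct = "displays_pct_CAP",
                  noncap_displays_pct = "displays_pct_non-CAP") |>
    dplyr::mutate(n_total = .data$n_cap + .data$n_noncap, .after = "stratum")
}

#' @rdname table_symbol
#' @export
table_threshold_counts <- function(summary) {
  summary$arm_counts |>
    dplyr::select("stratum", "arm", "n", "n_exempt", "n_zero", "n_one",
                  "n_two", "n_three") |>
    dplyr::mutate(dplyr::across(
      c("n_exempt", "n_zero", "n_one", "n_two", "n_three"),
      ~ ifelse(.data$n > 0, report_percent(.x, pmax(.data$n, 1)), NA_real_),
      .names = "{.col}_pct"))
}

#' @rdname table_symbol
#' @export
table_nutrients <- function(summary) {
  summary$arm_counts |>
    dplyr::select("stratum", "arm", "n", "n_high_saturated_fat",
                  "n_high_sugars", "n_high_sodium") |>
    dplyr::mutate(dplyr::across(
      dplyr::starts_with("n_high_"),
      ~ ifelse(.data$n > 0, report_percent(.x, pmax(.data$n, 1)), NA_real_),
      .names = "{.col}_pct"))
}
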