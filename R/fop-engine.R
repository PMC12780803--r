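nutrients <- c("saturated_fat_g", "total_sugars_g", "sodium_mg")
nutrient_labels <- c(saturated_fat_g = "saturated_fat",
                     total_sugars_g = "sugars",
                     sodium_mg = "sodium")

#' Exemption reason for each product
#'
#' The regulation exempts three classes of foods from the symbol: health
#' exemptions (foods with shown health benefits, e.g. fruits and vegetables,
#' and dairy products that are good sources of calcium), technical
#' exemptions (foods not required to carry a Nutrition Facts table) and
#' practical exemptions (well-known sources of nutrients-of-concern such as
#' honey, butter and table salt). A product carrying any flag is exempt; when
#' several are present the reported reason follows the fixed precedence
#' health > technical > practical (the precedence affects only the reported
#' reason, never whether the product is exempt).
#'
#' @param exemptions A list-column of exemption-code character vectors (or a
#'   single character vector).
#' @return Character vector: the highest-precedence code, or `NA` when none.
#' @export
check_exemption <- function(exemptions) {
  if (!is.list(exemptions)) exemptions <- list(exemptions)
  vapply(exemptions, function(s) {
    hit <- exemption_levels()[exemption_levels() %in% s]
    if (length(hit) == 0) NA_character_ else hit[1]
  }, character(1))
}

#' Scaling basis in grams
#'
#' Thresholds are applied per stated serving size or per regulated reference
#' amount, whichever is greater; when only one is present it is used alone.
#'
#' @param reference_amount_g,serving_size_g Numeric vectors in grams
#'   (`NA` = missing).
#' @return Numeric vector of basis amounts in grams.
#' @export
compute_basis <- function(reference_amount_g, serving_size_g) {
  if (any(is.na(reference_amount_g) & is.na(serving_size_g))) {
    stop("compute_basis: both reference_amount_g and serving_size_g missing",
         call. = FALSE)
  }
  pmax(reference_amount_g, serving_size_g, na.rm = TRUE)
}

#' Threshold tier for each product
#'
#' Main dishes with a reference amount at or above the age-group cut point
#' (200 g standard, 170 g for foods intended for children one to under four
#' years) are screened at the main-dish threshold; otherwise products whose
#' tier-determining amount (reference amount when present, else serving
#' size) is at or below the small-format cut point (30 g) use the small
#' tier, and all remaining products the general tier. All boundaries are
#' inclusive.
#'
#' @param reference_amount_g,serving_size_g,is_main_dish,age_group Product
#'   fields, vectorized.
#' @param policy An [fop_policy()].
#' @return Character vector: `"small"`, `"general"` or `"main_dish"`.
#' @export
select_tier <- function(reference_amount_g, serving_size_g, is_main_dish,
                        age_group, policy = fop_policy()) {
  cutoff <- unname(policy$main_dish_cutoff_g[age_group])
  md <- is_main_dish & !is.na(reference_amount_g) & reference_amount_g >= cutoff
  small_basis <- ifelse(is.na(reference_amount_g), serving_size_g, reference_amount_g)
  ifelse(md, "main_dish",
         ifelse(small_basis <= policy$small_ra_cutoff_g, "small", "general"))
}

#' Percent daily value
#'
#' @param amount Nutrient amount at the scaling basis (grams, or milligrams
#'   for sodium).
#' @param nutrient One of `"saturated_fat_g"`, `"total_sugars_g"`,
#'   `"sodium_mg"`.
#' @param age_group Age group whose daily values apply.
#' @param policy An [fop_policy()] (or [m2k_policy()]) carrying the DVs.
#' @return `100 * amount / daily_value`, unrounded.
#' @export
percent_dv <- function(amount, nutrient, age_group = "standard",
                       policy = fop_policy()) {
  nutrient <- match.arg(nutrient, nutrients, several.ok = FALSE)
  groups <- unique(age_group)
  dv_by_group <- vapply(groups, function(ag) {
    dv <- policy$daily_values[[ag]]
    if (is.null(dv)) {
      stop("no daily values configured for age group '", ag, "'", call. = FALSE)
    }
    unname(dv[[nutrient]])
  }, numeric(1))
  100 * amount / unname(dv_by_group[age_group])
}

scale_to_basis <- function(amount_per_serving, serving_size_g, basis_g) {
  # per-serving NFt amounts scale linearly to the basis; with no stated
  # serving the reference amount is the only basis and amounts stay unscaled
  ifelse(is.na(serving_size_g), amount_per_serving,
         amount_per_serving * basis_g / serving_size_g)
}

#' Evaluate products against a 'high in' labelling policy
#'
#' Runs the full regulatory decision for every product: exemption screening
#' first (an exempt product never displays a symbol regardless of nutrient
#' levels), then scaling of per-serving nutrient amounts to the
#' greater-of-serving-and-reference-amount basis, tier selection, and the
#' per-nutrient %DV threshold test. A product whose %DV *meets or exceeds*
#' its tier threshold is 'high in' that nutrient; one or more 'high in'
#' flags require the FOP symbol. Missing nutrient amounts yield `NA` flags
#' and never count toward `n_high`.
#'
#' @param data A products table ([as_products()] schema).
#' @param policy An [fop_policy()].
#' @return A tibble with one row per product: `product_id`, `exempt`,
#'   `exemption_reason`, `tier` (`NA` for exempt products), `basis_g`,
#'   per-nutrient `*_pct_dv` and `high_in_*` columns, `n_high` (0–3) and
#'   `displays_symbol`.
#' @export
evaluate_products <- function(data, policy = fop_policy()) {
  data <- as_products(data)
  reason <- check_exemption(data$exemptions)
  exempt <- !is.na(reason)
  basis <- compute_basis(data$reference_amount_g, data$serving_size_g)
  tier <- select_tier(data$reference_amount_g, data$serving_size_g,
                      data$is_main_dish, data$age_group, policy)
  thr <- unname(policy$tier_thresholds_pct[tier])

  res <- tibble::tibble(
    product_id = data$product_id,
    exempt = exempt,
    exemption_reason = reason,
    tier = ifelse(exempt, NA_character_, tier),
    basis_g = basis
  )
  flags <- matrix(NA, nrow = nrow(data), ncol = length(nutrients),
                  dimnames = list(NULL, nutrients))
  for (nut in nutrients) {
    at_basis <- scale_to_basis(data[[nut]], data$serving_size_g, basis)
    pct <- percent_dv(at_basis, nut, data$age_group, policy)
    if (!is.null(policy$round_pct_dv)) pct <- round(pct, policy$round_pct_dv)
    hi <- pct >= thr
    hi[exempt] <- NA
    flags[, nut] <- hi
    res[[paste0(nutrient_labels[[nut]], "_pct_dv")]] <- pct
    res[[paste0("high_in_", nutrient_labels[[nut]])]] <- hi
  }
  res$n_high <- ifelse(exempt, 0L, as.integer(rowSums(flags, na.rm = TRUE)))
  res$displays_symbol <- !exempt & res$n_high >= 1L
  res
}

#' Evaluate products against the proposed M2K nutrient criteria
#'
#' A product would be restricted from marketing to children when any
#' nutrient-of-concern meets or exceeds its M2K %DV threshold (6 % sodium,
#' 5 % sugars, 10 % saturated fat by default). The M2K proposal has its own
#' scope, so FOP exemptions are not applied; %DV is computed on the same
#' greater-of-serving-and-reference-amount basis as the FOP evaluation.
#'
#' @param data A products table.
#' @param policy An [m2k_policy()].
#' @return A tibble: `product_id`, per-nutrient `*_pct_dv`, and
#'   `m2k_restricted`.
#' @export
evaluate_m2k <- function(data, policy = m2k_policy()) {
  data <- as_products(data)
  basis <- compute_basis(data$reference_amount_g, data$serving_size_g)
  res <- tibble::tibble(product_id = data$product_id)
  over <- matrix(NA, nrow = nrow(data), ncol = length(nutrients))
  for (i in seq_along(nutrients)) {
    nut <- nutrients[i]
    at_basis <- scale_to_basis(data[[nut]], data$serving_size_g, basis)
    pct <- percent_dv(at_basis, nut, data$age_group, policy)
    res[[paste0(nutrient_labels[[nut]], "_pct_dv")]] <- pct
    over[, i] <- pct >= policy$thresholds_pct[[nut]]
  }
  res$m2k_restricted <- rowSums(over, na.rm = TRUE) >= 1
  res
}
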