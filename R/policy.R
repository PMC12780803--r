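#' Front-of-package threshold policy
#'
#' Bundles everything that defines a 'high in' labelling regulation: the
#' daily values (DVs) that turn nutrient amounts into percent daily values,
#' the reference-amount cut points that pick a threshold tier, and the
#' per-tier %DV thresholds.
#'
#' Defaults encode the Canadian regulation for standard products (adults and
#' children four years and older): DVs of 20 g saturated fat, 100 g total
#' sugars and 2300 mg sodium; small-format products (reference amount or
#' serving size of 30 g or less) screened at 10 %DV; most foods at 15 %DV;
#' main dishes with a reference amount of at least 200 g (170 g for foods
#' intended for children one to under four years) at 30 %DV. No default DVs
#' ship for the `young_child` age group — supply them explicitly when a
#' supply contains toddler-intended products.
#'
#' @param daily_values Named list: one entry per age group, each a named
#'   list/vector with `saturated_fat_g`, `total_sugars_g` (grams) and
#'   `sodium_mg` (milligrams).
#' @param small_ra_cutoff_g Small-format cut point in grams (inclusive).
#' @param main_dish_cutoff_g Named vector of main-dish reference-amount cut
#'   points in grams per age group (inclusive).
#' @param tier_thresholds_pct Named vector of %DV thresholds for the
#'   `small`, `general` and `main_dish` tiers.
#' @param round_pct_dv Optional pre-comparison rounding hook: number of
#'   decimals to round %DV to before the threshold test, or `NULL` (the
#'   default) to compare unrounded values.
#' @param name Policy label used in reports.
#' @return An object of class `fop_policy`.
#' @export
fop_policy <- function(daily_values = list(standard = c(saturated_fat_g = 20,
                                                        total_sugars_g = 100,
                                                        sodium_mg = 2300)),
                       small_ra_cutoff_g = 30,
                       main_dish_cutoff_g = c(standard = 200, young_child = 170),
                       tier_thresholds_pct = c(small = 10, general = 15, main_dish = 30),
                       round_pct_dv = NULL,
                       name = "canada_fop_2022") {
  stopifnot(
    all(tier_thresholds_pct > 0),
    small_ra_cutoff_g > 0,
    all(main_dish_cutoff_g > 0),
    all(c("small", "general", "main_dish") %in% names(tier_thresholds_pct))
  )
  daily_values <- lapply(daily_values, function(dv) {
    dv <- unlist(dv)
    stopifnot(all(c("saturated_fat_g", "total_sugars_g", "sodium_mg") %in% names(dv)),
              all(dv > 0))
    dv
  })
  structure(
    list(daily_values = daily_values,
         small_ra_cutoff_g = small_ra_cutoff_g,
         main_dish_cutoff_g = main_dish_cutoff_g,
         tier_thresholds_pct = tier_thresholds_pct,
         round_pct_dv = round_pct_dv,
         name = name),
    class = "fop_policy"
  )
}

#' Marketing-to-kids (M2K) nutrient policy
#'
#' The proposed Canadian restriction on marketing to children screens
#' nutrients at fixed %DV thresholds — 6 % for sodium, 5 % for sugars and
#' 10 % for saturated fat — with no tier structure and no exemptions.
#'
#' @param thresholds_pct Named vector of %DV thresholds.
#' @param daily_values As in [fop_policy()].
#' @param name Policy label.
#' @return An object of class `m2k_policy`.
#' @export
m2k_policy <- function(thresholds_pct = c(sodium_mg = 6, total_sugars_g = 5,
                                          saturated_fat_g = 10),
                       daily_values = list(standard = c(saturated_fat_g = 20,
                                                        total_sugars_g = 100,
                                                        sodium_mg = 2300)),
                       name = "canada_m2k_proposed") {
  stopifnot(all(thresholds_pct > 0),
            all(c("saturated_fat_g", "total_sugars_g", "sodium_mg") %in%
                  names(thresholds_pct)))
  structure(
    list(thresholds_pct = thresholds_pct,
         daily_values = lapply(daily_values, unlist),
         name = name),
    class = "m2k_policy"
  )
}

#' Read a policy from a YAML file
#'
#' Policy files mirror the arguments of [fop_policy()] / [m2k_policy()];
#' the `kind` key (`"fop"` or `"m2k"`) selects the constructor.
#'
#' @param path Path to a YAML file.
#' @return An `fop_policy` or `m2k_policy` object.
#' @export
read_policy <- function(path) {
  cfg <- yaml::read_yaml(path)
  kind <- cfg$kind %||% "fop"
  cfg$kind <- NULL
  if (identical(kind, "m2k")) {
    do.call(m2k_policy, lapply(cfg, unlist_keep_names))
  } else {
    args <- cfg
    if (!is.null(args$daily_values)) args$daily_values <- lapply(args$daily_values, unlist)
    for (k in c("small_ra_cutoff_g", "main_dish_cutoff_g", "tier_thresholds_pct")) {
      if (!is.null(args[[k]])) args[[k]] <- unlist(args[[k]])
    }
    do.call(fop_policy, args)
  }
}

unlist_keep_names <- function(x) if (is.list(x) && !is.list(x[[1]])) unlist(x) else x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fop_policy <- function(x, ...) {
  cat("<fop_policy>", x$name, "\n")
  cat("  tiers (%DV): small", x$tier_thresholds_pct[["small"]],
      "| general", x$tier_thresholds_pct[["general"]],
      "| main_dish", x$tier_thresholds_pct[["main_dish"]], "\n")
  cat("  small-format cutoff:", x$small_ra_cutoff_g, "g; main-dish cutoff:",
      paste(names(x$main_dish_cutoff_g), x$main_dish_cutoff_g,
            sep = "=", collapse = ", "), "g\n")
  for (ag in names(x$daily_values)) {
    dv <- x$daily_values[[ag]]
    cat("  DV[", ag, "]: satfat ", dv[["saturated_fat_g"]], " g, sugars ",
        dv[["total_sugars_g"]], " g, sodium ", dv[["sodium_mg"]], " mg\n", sep = "")
  }
  invisible(x)
}
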