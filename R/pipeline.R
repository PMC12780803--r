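#' Run the full CAP x FOP analysis pipeline
#'
#' One call from a product file (or generator config) to the three report
#' tables: read or generate the supply, classify child-appealing packaging,
#' evaluate the FOP 'high in' regulation (and optionally the M2K criteria),
#' summarize with stratified Fisher tests, verify the conservation
#' invariants, and write the outputs to a run directory:
#' `table3.tsv` (symbol prevalence by category and arm), `table4.tsv`
#' (exempt/0/1/2/3 threshold counts), `table5.tsv` (per-nutrient 'high in'
#' tallies), `summary.json` (all counts and p-values) and `manifest.json`.
#' All table output is deterministic for a fixed input/seed; only the
#' manifest carries a timestamp.
#'
#' @param input A products tibble, or a path to a products CSV.
#' @param config A [generator_config()] used when `input` is `NULL`.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param policy An [fop_policy()].
#' @param m2k An [m2k_policy()], or `NULL` to skip the M2K evaluation.
#' @param inventory Technique inventory for [classify_cap()].
#' @param strict Passed to [read_products()] when `input` is a path.
#' @return Invisibly, a list of class `fop_run`: `products`, `cap`, `fop`,
#'   `m2k`, `summary`, and `manifest` (inputs, policy names, output files,
#'   skipped-row log).
#' @export
run_pipeline <- function(input = NULL, config = NULL, out_dir = NULL,
                         policy = fop_policy(), m2k = NULL,
                         inventory = default_technique_inventory(),
                         strict = TRUE) {
  if (is.null(input) && is.null(config)) {
    stop("provide either `input` (products) or `config` (generator)", call. = FALSE)
  }
  source_desc <- if (!is.null(input)) {
    if (is.character(input)) {
      products <- read_products(input, strict = strict)
      list(kind = "csv", path = input,
           n_skipped = attr(products, "n_skipped") %||% 0L)
    } else {
      products <- as_products(input)
      list(kind = "tibble", n_skipped = 0L)
    }
  } else {
    products <- generate_supply(config)
    list(kind = "generator", seed = config$seed,
         n_categories = nrow(config$categories), n_skipped = 0L)
  }
  if (nrow(products) == 0) stop("empty supply: nothing to analyse", call. = FALSE)

  cap <- classify_cap(products, inventory)
  fop <- evaluate_products(products, policy)
  m2k_res <- if (!is.null(m2k)) evaluate_m2k(products, m2k) else NULL
  summary <- summarize_supply(products, fop, cap)

  check_conservation(summary)

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c("table3.tsv", "table4.tsv", "table5.tsv",
                                  "summary.json"))
    readr::write_tsv(table_symbol(summary), paths[1], progress = FALSE)
    readr::write_tsv(table_threshold_counts(summary), paths[2], progress = FALSE)
    readr::write_tsv(table_nutrients(summary), paths[3], progress = FALSE)
    jsonlite::write_json(
      list(arm_counts = summary$arm_counts, tests = summary$tests,
           glance = as.list(glance(summary)),
           m2k = if (!is.null(m2k_res)) {
             list(n_restricted = sum(m2k_res$m2k_restricted),
                  restricted_pct = report_percent(sum(m2k_res$m2k_restricted),
                                                  nrow(m2k_res)))
           }),
      paths[4], auto_unbox = TRUE, digits = NA, na = "null")
    outputs <- paths
  }

  manifest <- list(
    tool = "fopcap", version = as.character(utils::packageVersion("fopcap")),
    timestamp = format(Sys.time(), tz = "UTC"),
    source = source_desc,
    policy = policy$name,
    m2k_policy = if (!is.null(m2k)) m2k$name,
    n_products = nrow(products), n_cap = summary$n_cap,
    outputs = as.character(outputs)
  )
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         na = "null")
    manifest$outputs <- c(manifest$outputs, mpath)
  }

  invisible(structure(
    list(products = products, cap = cap, fop = fop, m2k = m2k_res,
         summary = summary, manifest = manifest),
    class = "fop_run"
  ))
}

# arm totals must decompose exactly into exempt + 0 + 1 + 2 + 3, and the
# symbol count into 1 + 2 + 3, in every stratum
check_conservation <- function(summary) {
  ac <- summary$arm_counts
  bad <- (ac$n_exempt + ac$n_zero + ac$n_one + ac$n_two + ac$n_three) != ac$n |
    (ac$n_one + ac$n_two + ac$n_three) != ac$n_displays
  if (any(bad)) {
    stop("conservation invariant violated in strata: ",
         paste(unique(ac$stratum[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Published benchmark tallies for the 2017 Canadian analytic sample
#'
#' The printed count tables from the 2017 Canadian packaged-food
#' evaluation of child-appealing packaging (CAP) against the FOP 'high in'
#' regulation: per-arm exempt/0/1/2/3 threshold counts, per-nutrient
#' 'high in' counts, and the headline percentages derived from them. Note
#' the published prevalence numerator (747) differs by one from the
#' published CAP arm total (746); both are kept as printed.
#'
#' @return A list of count vectors and the printed percentages.
#' @export
reference_tallies <- function() {
  list(
    n_total = 5850L,
    n_cap_prevalence = 747L,
    cap = c(exempt = 40L, zero = 151L, one = 366L, two = 185L, three = 4L),
    noncap = c(exempt = 741L, zero = 1011L, one = 1879L, two = 1399L, three = 74L),
    cap_nutrients = c(sugars = 406L, saturated_fat = 228L, sodium = 114L),
    noncap_nutrients = c(sugars = 1931L, saturated_fat = 1763L, sodium = 1205L),
    printed = list(
      cap_displays_pct = 74.4, noncap_displays_pct = 65.7,
      overall_displays_pct = 66.8, cap_prevalence_pct = 12.8,
      cap_distribution_pct = c(exempt = 5.4, zero = 20.2, one = 49.1,
                               two = 24.8, three = 0.5),
      noncap_distribution_pct = c(exempt = 14.5, zero = 19.8, one = 36.8,
                                  two = 27.4, three = 1.4),
      cap_nutrients_pct = c(sugars = 54.4, saturated_fat = 30.6, sodium = 15.3),
      noncap_nutrients_pct = c(sugars = 37.8, saturated_fat = 34.5, sodium = 23.6),
      fisher_p_bound = 0.001
    )
  )
}

#' Recompute the published benchmark tallies
#'
#' Recomputes every headline proportion and the overall Fisher exact test
#' from the printed integer counts of [reference_tallies()] using this
#' package's [report_percent()] and [fisher_exact_2x2()], and compares each
#' against its printed value. Because every published percentage is a
#' deterministic function of published integers, this is an executable
#' cross-check of the reporting conventions (half-up rounding, the
#' exempt-inclusive "no symbol" column) rather than a re-analysis.
#'
#' @return A tibble with one row per check: `check`, `computed`,
#'   `expected`, `pass` (for the Fisher row, `expected` is the printed
#'   upper bound and `pass` means `computed < expected`).
#' @export
verify_reference_tallies <- function() {
  ref <- reference_tallies()
  pr <- ref$printed
  cap_n <- sum(ref$cap)
  non_n <- sum(ref$noncap)
  cap_disp <- sum(ref$cap[c("one", "two", "three")])
  non_disp <- sum(ref$noncap[c("one", "two", "three")])

  rows <- list()
  add <- function(check, computed, expected, pass = isTRUE(all.equal(computed, expected))) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, computed = computed, expected = expected, pass = pass)
  }

  add("cap_displays_pct", report_percent(cap_disp, cap_n), pr$cap_displays_pct)
  add("noncap_displays_pct", report_percent(non_disp, non_n), pr$noncap_displays_pct)
  add("overall_displays_pct",
      report_percent(cap_disp + non_disp, ref$n_total), pr$overall_displays_pct)
  add("cap_prevalence_pct",
      report_percent(ref$n_cap_prevalence, ref$n_total), pr$cap_prevalence_pct)
  for (k in names(ref$cap)) {
    add(paste0("cap_", k, "_pct"), report_percent(ref$cap[[k]], cap_n),
        unname(pr$cap_distribution_pct[k]))
    add(paste0("noncap_", k, "_pct"), report_percent(ref$noncap[[k]], non_n),
        unname(pr$noncap_distribution_pct[k]))
  }
  for (k in names(ref$cap_nutrients)) {
    add(paste0("cap_high_", k, "_pct"),
        report_percent(ref$cap_nutrients[[k]], cap_n),
        unname(pr$cap_nutrients_pct[k]))
    add(paste0("noncap_high_", k, "_pct"),
        report_percent(ref$noncap_nutrients[[k]], non_n),
        unname(pr$noncap_nutrients_pct[k]))
  }
  fp <- fisher_exact_2x2(cap_disp, cap_n - cap_disp,
                         non_disp, non_n - non_disp)$p_value
  add("overall_fisher_p", fp, pr$fisher_p_bound, pass = fp < pr$fisher_p_bound)

  dplyr::bind_rows(rows)
}
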