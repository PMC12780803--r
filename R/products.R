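#' @importFrom rlang .data
NULL

#' Column schema for product tables
#'
#' A products table holds one row per packaged food with the fields the
#' front-of-package (FOP) evaluation needs: identifiers, Table of Reference
#' Amounts (TRA) category labels, the two possible scaling bases (regulated
#' reference amount and stated serving size, both in grams), the per-serving
#' amounts of the three nutrients-of-concern (saturated fat and total sugars
#' in grams, sodium in milligrams), regulatory exemption flags, a main-dish
#' flag, the intended age group, and the coded child-appealing marketing
#' techniques found on the package.
#'
#' In memory, `exemptions` and `techniques` are list-columns of character
#' vectors (sets); on disk they are single semicolon-delimited CSV cells.
#' A missing nutrient value is `NA` and means "cannot evaluate that
#' nutrient" — it is never treated as zero.
#'
#' @return Character vector of the column names, in canonical order.
#' @export
product_columns <- function() {
  c(
    "product_id", "name", "tra_major", "tra_sub",
    "reference_amount_g", "serving_size_g",
    "is_main_dish", "age_group",
    "saturated_fat_g", "total_sugars_g", "sodium_mg",
    "exemptions", "techniques"
  )
}

exemption_levels <- function() c("health", "technical", "practical")
age_group_levels <- function() c("standard", "young_child")

split_set <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    sort(unique(trimws(strsplit(cell, ";", fixed = TRUE)[[1]])))
  })
}

collapse_set <- function(x) {
  vapply(x, function(s) paste(sort(unique(s)), collapse = ";"), character(1))
}

#' Construct a validated products table
#'
#' Coerces a data frame to the canonical product schema (see
#' [product_columns()]), converting semicolon-delimited `exemptions` /
#' `techniques` strings to list-columns if needed, and aborts if any record
#' violates an invariant.
#'
#' @param data A data frame with the columns of [product_columns()]
#'   (`name`, `tra_major` may be absent and default to empty strings).
#' @param provenance Optional free-text metadata (source, seed, generator
#'   version) stored as an attribute.
#' @return A tibble of class `fop_products`.
#' @export
as_products <- function(data, provenance = NULL) {
  if (inherits(data, "fop_products") && is.null(provenance)) {
    return(data)  # already validated; revalidate only after mutation via tibble
  }
  data <- tibble::as_tibble(data)
  if (!"name" %in% names(data)) data$name <- ""
  if (!"tra_major" %in% names(data)) data$tra_major <- ""
  missing_cols <- setdiff(product_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("products table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(data$exemptions)) data$exemptions <- split_set(as.character(data$exemptions))
  if (!is.list(data$techniques)) data$techniques <- split_set(as.character(data$techniques))
  for (col in c("reference_amount_g", "serving_size_g",
                "saturated_fat_g", "total_sugars_g", "sodium_mg")) {
    data[[col]] <- as.double(data[[col]])
  }
  data$is_main_dish <- as.logical(data$is_main_dish)
  data$product_id <- as.character(data$product_id)
  data$age_group <- as.character(data$age_group)
  data <- data[, product_columns()]
  viol <- validate_products(data)
  if (nrow(viol) > 0) {
    stop(format_violations(viol), call. = FALSE)
  }
  class(data) <- c("fop_products", class(data))
  attr(data, "provenance") <- provenance
  data
}

#' Validate product records
#'
#' Checks every record against the schema invariants and returns the
#' violations as data, one row per broken rule, rather than raising errors.
#' An empty result means the table is valid.
#'
#' Rules checked per record: `product_id` present and unique; `tra_sub`
#' nonempty; at least one of `reference_amount_g` / `serving_size_g` present
#' and positive; nutrient amounts finite and non-negative when present;
#' `age_group` one of `standard` / `young_child`; exemption codes drawn from
#' `health` / `technical` / `practical`.
#'
#' @param data A data frame in the product schema (list- or string-valued
#'   `exemptions` accepted).
#' @return A tibble with columns `row`, `product_id`, `field`, `rule`.
#' @export
validate_products <- function(data) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  out <- list()
  add <- function(rows, field, rule) {
    if (length(rows) == 0) return()
    out[[length(out) + 1]] <<- tibble::tibble(
      row = rows,
      product_id = as.character(data$product_id[rows]),
      field = field, rule = rule
    )
  }

  id <- as.character(data$product_id)
  add(which(is.na(id) | !nzchar(id)), "product_id", "must be nonempty")
  dup <- which(duplicated(id) & !is.na(id))
  add(dup, "product_id", "must be unique within a supply")
  add(which(is.na(data$tra_sub) | !nzchar(data$tra_sub)), "tra_sub", "must be nonempty")

  ra <- as.double(data$reference_amount_g)
  ss <- as.double(data$serving_size_g)
  add(which(is.na(ra) & is.na(ss)), "reference_amount_g/serving_size_g",
      "at least one scaling basis must be present")
  add(which(!is.na(ra) & (ra <= 0 | !is.finite(ra))), "reference_amount_g",
      "must be positive and finite")
  add(which(!is.na(ss) & (ss <= 0 | !is.finite(ss))), "serving_size_g",
      "must be positive and finite")

  for (col in c("saturated_fat_g", "total_sugars_g", "sodium_mg")) {
    v <- as.double(data[[col]])
    add(which(!is.na(v) & (v < 0 | !is.finite(v))), col,
        "must be non-negative and finite when present")
  }

  add(which(!data$age_group %in% age_group_levels()), "age_group",
      paste("must be one of:", paste(age_group_levels(), collapse = ", ")))

  ex <- data$exemptions
  if (!is.list(ex)) ex <- split_set(as.character(ex))
  bad_ex <- which(vapply(ex, function(s) any(!s %in% exemption_levels()), logical(1)))
  add(bad_ex, "exemptions", "codes must be health, technical or practical")

  if (length(out) == 0) {
    tibble::tibble(row = integer(0), product_id = character(0),
                   field = character(0), rule = character(0))
  } else {
    dplyr::arrange(dplyr::bind_rows(out), .data$row)
  }
}

format_violations <- function(viol, max_shown = 5) {
  shown <- utils::head(viol, max_shown)
  lines <- sprintf("  row %d (%s): %s %s",
                   shown$row, shown$product_id, shown$field, shown$rule)
  extra <- if (nrow(viol) > max_shown) {
    sprintf("\n  ... and %d more", nrow(viol) - max_shown)
  } else ""
  paste0("invalid product records (", nrow(viol), " violation",
         if (nrow(viol) != 1) "s" else "", "):\n",
         paste(lines, collapse = "\n"), extra)
}

#' Read a products CSV
#'
#' Reads a UTF-8, comma-delimited product file with a header row matching
#' [product_columns()]. Decimal values use a point; `exemptions` and
#' `techniques` cells are semicolon-delimited within the column.
#'
#' In strict mode (default) any malformed row — a non-numeric or negative
#' nutrient cell, a missing scaling basis, an unknown code — aborts with
#' row-numbered diagnostics. In lenient mode malformed rows are skipped,
#' the skip tally is reported on standard error, and the skipped-row count
#' and the violations table are attached as attributes `n_skipped` and
#' `skipped_violations`.
#'
#' @param path Path to the CSV file.
#' @param strict Abort on any malformed row (default `TRUE`)?
#' @return A validated `fop_products` tibble.
#' @export
read_products <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- setdiff(setdiff(product_columns(), c("name", "tra_major")), names(raw))
  if (length(needed) > 0) {
    stop("missing mandatory columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!"name" %in% names(raw)) raw$name <- ""
  if (!"tra_major" %in% names(raw)) raw$tra_major <- ""
  raw <- raw[, product_columns()]

  num_cols <- c("reference_amount_g", "serving_size_g",
                "saturated_fat_g", "total_sugars_g", "sodium_mg")
  parse_viol <- list()
  for (col in num_cols) {
    cell <- raw[[col]]
    parsed <- suppressWarnings(as.double(cell))
    bad <- which(!is.na(cell) & nzchar(cell) & is.na(parsed))
    if (length(bad) > 0) {
      parse_viol[[length(parse_viol) + 1]] <- tibble::tibble(
        row = bad, product_id = as.character(raw$product_id[bad]),
        field = col, rule = sprintf("not a number: '%s'", cell[bad])
      )
    }
    raw[[col]] <- parsed
  }
  bool <- tolower(raw$is_main_dish)
  parsed_bool <- ifelse(bool %in% c("true", "1", "yes"), TRUE,
                        ifelse(bool %in% c("false", "0", "no"), FALSE, NA))
  bad_bool <- which(is.na(parsed_bool))
  if (length(bad_bool) > 0) {
    parse_viol[[length(parse_viol) + 1]] <- tibble::tibble(
      row = bad_bool, product_id = as.character(raw$product_id[bad_bool]),
      field = "is_main_dish", rule = "must be true/false"
    )
  }
  raw$is_main_dish <- as.logical(parsed_bool)
  raw$exemptions <- split_set(raw$exemptions)
  raw$techniques <- split_set(raw$techniques)

  viol <- dplyr::bind_rows(c(parse_viol, list(validate_products(raw))))
  if (nrow(viol) > 0) viol <- dplyr::arrange(viol, .data$row)

  if (strict && nrow(viol) > 0) {
    stop(format_violations(viol), call. = FALSE)
  }
  if (nrow(viol) > 0) {
    drop <- unique(viol$row)
    message(sprintf("read_products: skipped %d malformed row(s) of %d",
                    length(drop), nrow(raw)))
    raw <- raw[-drop, ]
  }
  out <- as_products(raw, provenance = list(source = path))
  attr(out, "n_skipped") <- if (nrow(viol) > 0) length(unique(viol$row)) else 0L
  attr(out, "skipped_violations") <- viol
  out
}

#' Write a products CSV
#'
#' Inverse of [read_products()]: `exemptions` / `techniques` sets are
#' serialized as sorted semicolon-delimited cells (empty set becomes an
#' empty string), so write-then-read reproduces the table field-for-field
#' and repeated writes of the same table are byte-identical.
#'
#' @param data A products table (validated with [as_products()] first).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_products <- function(data, path) {
  data <- as_products(data)
  flat <- dplyr::mutate(
    tibble::as_tibble(data),
    exemptions = collapse_set(.data$exemptions),
    techniques = collapse_set(.data$techniques)
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
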