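#' Default inventory of child-appealing marketing technique codes
#'
#' The technique families used by package-coding instruments for
#' child-directed marketing: characters (licensed or brand mascots), games
#' and activities, and "fun" graphic design such as unusual colours and
#' shapes. The inventory is deliberately extensible — coding schemes add
#' their own codes via [read_technique_inventory()] or a character vector.
#'
#' @return Character vector of technique codes.
#' @export
default_technique_inventory <- function() {
  c("character_licensed", "character_brand", "game_activity",
    "fun_shape", "fun_colour", "child_font", "cartoon_graphics",
    "child_language", "premium_offer", "movie_tiein")
}

#' Read a technique inventory file
#'
#' Plain-text list of technique codes, one per line; blank lines and `#`
#' comments are ignored.
#'
#' @param path Path to the inventory file.
#' @return Character vector of codes.
#' @export
read_technique_inventory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Classify child-appealing packaging (CAP)
#'
#' A package displaying one or more recognized child-appealing marketing
#' techniques is classified as CAP; the marketing power score is the number
#' of distinct techniques displayed. Codes not in the inventory are ignored
#' and tallied on standard error (pre-coded data can carry codes from a
#' newer instrument revision).
#'
#' @param data A products table with a `techniques` list-column.
#' @param inventory Character vector of recognized technique codes.
#' @return A tibble: `product_id`, `is_cap`, `power_score`,
#'   `techniques_present` (list-column of the recognized codes).
#' @export
classify_cap <- function(data, inventory = default_technique_inventory()) {
  stopifnot(length(inventory) > 0)
  data <- as_products(data)
  present <- lapply(data$techniques, function(s) sort(intersect(s, inventory)))
  unknown <- unique(unlist(lapply(data$techniques, function(s) setdiff(s, inventory))))
  if (length(unknown) > 0) {
    message("classify_cap: ignored ", length(unknown),
            " unrecognized technique code(s): ",
            paste(utils::head(unknown, 10), collapse = ", "))
  }
  score <- vapply(present, length, integer(1))
  tibble::tibble(
    product_id = data$product_id,
    is_cap = score >= 1L,
    power_score = score,
    techniques_present = present
  )
}

#' CAP prevalence in a supply
#'
#' @param cap_results Output of [classify_cap()].
#' @return A one-row tibble: `n_cap`, `n_total`, `prevalence_pct` (one
#'   decimal, half-up, per the reporting convention).
#' @export
cap_prevalence <- function(cap_results) {
  if (nrow(cap_results) == 0) stop("empty supply", call. = FALSE)
  n_cap <- sum(cap_results$is_cap)
  tibble::tibble(
    n_cap = n_cap,
    n_total = nrow(cap_results),
    prevalence_pct = report_percent(n_cap, nrow(cap_results))
  )
}
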