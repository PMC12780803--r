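# In-code fixture builder: one call gives n valid products, any field
# overridable with a recycled vector.
make_products <- function(n = 1, ...) {
  defaults <- tibble::tibble(
    product_id = sprintf("p%03d", seq_len(n)),
    name = sprintf("product %d", seq_len(n)),
    tra_major = "test-major",
    tra_sub = "test-sub",
    reference_amount_g = 50,
    serving_size_g = 50,
    is_main_dish = FALSE,
    age_group = "standard",
    saturated_fat_g = 1,
    total_sugars_g = 5,
    sodium_mg = 100,
    exemptions = list(character(0)),
    techniques = list(character(0))
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# small generator config for tests: one category, overridable
test_generator <- function(seed = 1, n = 500, cap_prevalence = 0.13,
                           cap_sugar_effect = 1, ...) {
  generator_config(
    seed = seed,
    categories = category_spec(
      "cereal", "cereals", n_products = n, cap_prevalence = cap_prevalence,
      reference_amount_g = 40, satfat_meanlog = log(0.5),
      sugars_meanlog = log(7), sugars_sdlog = 0.8,
      sodium_meanlog = log(140), cap_sugar_effect = cap_sugar_effect, ...)
  )
}
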