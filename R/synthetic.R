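#' Specification of one synthetic food category
#'
#' Describes how products in one TRA subcategory are drawn: sample size,
#' CAP prevalence, per-class exemption probabilities, the regulated
#' reference amount, a truncated-normal stated serving size, and
#' per-serving lognormal nutrient amounts. Lognormal shapes are used
#' because nutrient contents are strictly positive and right-skewed, the
#' typical shape of food-composition data. `cap_sugar_effect` is a
#' multiplicative shift (>= 1 encodes enrichment) applied to the sugars
#' median of CAP products, emulating the finding that child-appealing
#' packages are higher in total sugars; independent effects on other
#' nutrients can be encoded the same way.
#'
#' @param tra_sub,tra_major Category labels.
#' @param n_products Number of products to draw (>= 0).
#' @param cap_prevalence Probability a product is child-appealing packaged.
#' @param p_exempt_health,p_exempt_technical,p_exempt_practical Independent
#'   probabilities of each exemption class.
#' @param is_main_dish Is the category a main dish (meals)?
#' @param reference_amount_g Regulated reference amount in grams.
#' @param serving_mean_g,serving_sd_g Stated-serving distribution (normal,
#'   truncated below at 1 g, rounded to 0.1 g).
#' @param satfat_meanlog,satfat_sdlog,sugars_meanlog,sugars_sdlog,sodium_meanlog,sodium_sdlog
#'   Per-serving lognormal parameters (saturated fat and sugars in grams,
#'   sodium in milligrams).
#' @param cap_sugar_effect Multiplier on the sugars median for CAP products.
#' @param cap_satfat_effect,cap_sodium_effect Optional analogous multipliers
#'   (default 1 = no shift).
#' @return A one-row tibble.
#' @export
category_spec <- function(tra_sub, tra_major = "", n_products,
                          cap_prevalence,
                          p_exempt_health = 0, p_exempt_technical = 0,
                          p_exempt_practical = 0,
                          is_main_dish = FALSE,
                          reference_amount_g,
                          serving_mean_g = reference_amount_g,
                          serving_sd_g = reference_amount_g / 10,
                          satfat_meanlog, satfat_sdlog = 0.7,
                          sugars_meanlog, sugars_sdlog = 0.7,
                          sodium_meanlog, sodium_sdlog = 0.7,
                          cap_sugar_effect = 1,
                          cap_satfat_effect = 1,
                          cap_sodium_effect = 1) {
  stopifnot(
    n_products >= 0,
    cap_prevalence >= 0, cap_prevalence <= 1,
    p_exempt_health >= 0, p_exempt_health <= 1,
    p_exempt_technical >= 0, p_exempt_technical <= 1,
    p_exempt_practical >= 0, p_exempt_practical <= 1,
    reference_amount_g > 0, serving_mean_g > 0, serving_sd_g > 0,
    satfat_sdlog > 0, sugars_sdlog > 0, sodium_sdlog > 0,
    cap_sugar_effect > 0, cap_satfat_effect > 0, cap_sodium_effect > 0
  )
  tibble::tibble(
    tra_sub = tra_sub, tra_major = tra_major, n_products = as.integer(n_products),
    cap_prevalence = cap_prevalence,
    p_exempt_health = p_exempt_health, p_exempt_technical = p_exempt_technical,
    p_exempt_practical = p_exempt_practical,
    is_main_dish = is_main_dish, reference_amount_g = reference_amount_g,
    serving_mean_g = serving_mean_g, serving_sd_g = serving_sd_g,
    satfat_meanlog = satfat_meanlog, satfat_sdlog = satfat_sdlog,
    sugars_meanlog = sugars_meanlog, sugars_sdlog = sugars_sdlog,
    sodium_meanlog = sodium_meanlog, sodium_sdlog = sodium_sdlog,
    cap_sugar_effect = cap_sugar_effect,
    cap_satfat_effect = cap_satfat_effect,
    cap_sodium_effect = cap_sodium_effect
  )
}

#' Generator configuration
#'
#' @param seed Integer seed; a fixed seed makes the generated supply fully
#'   reproducible.
#' @param categories A tibble of [category_spec()] rows.
#' @param inventory Recognized technique codes.
#' @param technique_probs Named per-technique inclusion probabilities for
#'   CAP products (names must be in `inventory`); a CAP product with no
#'   technique drawn receives one sampled in proportion to these weights,
#'   so every CAP product carries at least one technique.
#' @return An object of class `supply_generator_config`.
#' @export
generator_config <- function(seed, categories,
                             inventory = default_technique_inventory(),
                             technique_probs = NULL) {
  if (is.null(technique_probs)) {
    technique_probs <- stats::setNames(
      c(0.55, 0.50, 0.40, 0.25, 0.20, 0.20, 0.15, 0.10, 0.05, 0.05),
      default_technique_inventory())[inventory]
    technique_probs[is.na(technique_probs)] <- 0.1
    names(technique_probs) <- inventory
  }
  stopifnot(
    is.numeric(seed), length(seed) == 1, seed == round(seed),
    nrow(categories) >= 0,
    !anyDuplicated(categories$tra_sub),
    all(names(technique_probs) %in% inventory),
    all(technique_probs >= 0 & technique_probs <= 1),
    sum(technique_probs) > 0
  )
  structure(
    list(seed = as.integer(seed), categories = categories,
         inventory = inventory, technique_probs = technique_probs),
    class = "supply_generator_config"
  )
}

# deterministic substream seed per (seed, category index); keeps categories
# on isolated streams so editing one spec never perturbs another's draws
category_seed <- function(seed, index) {
  ((abs(seed) %% 65521L) * 20011L + index * 7919L) %% 2147483629L
}

draw_techniques <- function(n_cap, probs) {
  codes <- names(probs)
  lapply(seq_len(n_cap), function(i) {
    hit <- codes[stats::runif(length(probs)) < probs]
    if (length(hit) == 0) hit <- sample(codes, 1, prob = probs)
    sort(hit)
  })
}

#' Generate a seeded synthetic food supply
#'
#' Draws every category independently on its own RNG substream keyed by
#' (seed, category index): the same config and seed always reproduce the
#' same supply, and editing one category's spec leaves all other
#' categories' draws unchanged. CAP status is drawn per product at the
#' category's prevalence; CAP products receive at least one marketing
#' technique and their sugars median is shifted by `cap_sugar_effect`.
#'
#' @param cfg A [generator_config()].
#' @return A validated `fop_products` tibble (empty when all `n_products`
#'   are zero) with generator provenance attached.
#' @export
generate_supply <- function(cfg) {
  stopifnot(inherits(cfg, "supply_generator_config"))
  specs <- cfg$categories
  parts <- purrr::map(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    n <- sp$n_products
    if (n == 0) return(NULL)
    withr::with_seed(category_seed(cfg$seed, i), {
      serving <- round(pmax(stats::rnorm(n, sp$serving_mean_g, sp$serving_sd_g), 1), 1)
      is_cap <- stats::runif(n) < sp$cap_prevalence
      ex_h <- stats::runif(n) < sp$p_exempt_health
      ex_t <- stats::runif(n) < sp$p_exempt_technical
      ex_p <- stats::runif(n) < sp$p_exempt_practical
      satfat <- stats::rlnorm(n, sp$satfat_meanlog +
                                ifelse(is_cap, log(sp$cap_satfat_effect), 0),
                              sp$satfat_sdlog)
      sugars <- stats::rlnorm(n, sp$sugars_meanlog +
                                ifelse(is_cap, log(sp$cap_sugar_effect), 0),
                              sp$sugars_sdlog)
      sodium <- stats::rlnorm(n, sp$sodium_meanlog +
                                ifelse(is_cap, log(sp$cap_sodium_effect), 0),
                              sp$sodium_sdlog)
      techniques <- vector("list", n)
      techniques[!is_cap] <- list(character(0))
      techniques[is_cap] <- draw_techniques(sum(is_cap), cfg$technique_probs)
      slug <- gsub("[^a-z0-9]+", "", tolower(sp$tra_sub))
      tibble::tibble(
        product_id = sprintf("%s-%05d", slug, seq_len(n)),
        name = sprintf("%s product %d", sp$tra_sub, seq_len(n)),
        tra_major = sp$tra_major, tra_sub = sp$tra_sub,
        reference_amount_g = sp$reference_amount_g,
        serving_size_g = serving,
        is_main_dish = sp$is_main_dish,
        age_group = "standard",
        saturated_fat_g = round(satfat, 2),
        total_sugars_g = round(sugars, 2),
        sodium_mg = round(sodium, 1),
        exemptions = purrr::pmap(list(ex_h, ex_t, ex_p), function(h, t, p) {
          exemption_levels()[c(h, t, p)]
        }),
        techniques = techniques
      )
    })
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      product_id = character(0), name = character(0), tra_major = character(0),
      tra_sub = character(0), reference_amount_g = double(0),
      serving_size_g = double(0), is_main_dish = logical(0),
      age_group = character(0), saturated_fat_g = double(0),
      total_sugars_g = double(0), sodium_mg = double(0),
      exemptions = list(), techniques = list()
    )
    class(out) <- c("fop_products", class(out))
    attr(out, "provenance") <- list(source = "generate_supply", seed = cfg$seed)
    return(out)
  }
  as_products(out, provenance = list(source = "generate_supply", seed = cfg$seed,
                                     n_categories = nrow(specs)))
}

#' Preset generator emulating a large branded-food database
#'
#' A ready-made [generator_config()] with 20 TRA subcategories sized and
#' parameterised to resemble the analytic sample of a 2017 Canadian
#' packaged-food evaluation: 5850 products, overall CAP prevalence near
#' 12.8 %, high exemption rates in the calcium-source dairy categories
#' (cheese, milk, drinkable yogurt) and the practical-exemption categories
#' (syrups/spreads, nut butter), main-dish meals screened at 30 %DV, and
#' sugar-enriched CAP arms. The nutrient distributions are illustrative —
#' the real database's distributions are unpublished — and are tuned only
#' so that the marginal exempt/0/1/2/3 threshold-count mix is broadly
#' realistic, not to reproduce any category-level result.
#'
#' @param seed Integer seed (default 1).
#' @return A `supply_generator_config`.
#' @export
preset_flip_like <- function(seed = 1) {
  cs <- function(...) category_spec(...)
  categories <- dplyr::bind_rows(
    cs("toaster_pastries", "bakery", 11, 1.00, reference_amount_g = 55,
       satfat_meanlog = log(1.6), sugars_meanlog = log(15), sodium_meanlog = log(170),
       cap_sugar_effect = 1.2),
    cs("crackers", "bakery", 66, 0.424, reference_amount_g = 20,
       satfat_meanlog = log(0.9), sugars_meanlog = log(1.2), sodium_meanlog = log(150),
       sodium_sdlog = 0.5, cap_sugar_effect = 1.3),
    cs("cereal", "cereals", 88, 0.534, reference_amount_g = 40,
       satfat_meanlog = log(0.4), sugars_meanlog = log(7), sugars_sdlog = 0.8,
       sodium_meanlog = log(140), cap_sugar_effect = 1.8),
    cs("candy", "sugars", 573, 0.264, reference_amount_g = 40,
       satfat_meanlog = log(1.4), satfat_sdlog = 1.2,
       sugars_meanlog = log(26), sugars_sdlog = 0.5,
       sodium_meanlog = log(25), sodium_sdlog = 1.0, cap_sugar_effect = 1.15),
    cs("fruit_sauce", "fruit", 65, 0.262, reference_amount_g = 100,
       p_exempt_health = 0.35,
       satfat_meanlog = log(0.1), sugars_meanlog = log(14), sugars_sdlog = 0.5,
       sodium_meanlog = log(10), cap_sugar_effect = 1.3),
    cs("ice_cream", "dairy", 499, 0.198, reference_amount_g = 125,
       satfat_meanlog = log(5.5), satfat_sdlog = 0.6,
       sugars_meanlog = log(20), sugars_sdlog = 0.45,
       sodium_meanlog = log(70), cap_sugar_effect = 1.15),
    cs("cookies", "bakery", 523, 0.161, reference_amount_g = 30,
       satfat_meanlog = log(1.7), sugars_meanlog = log(8), sugars_sdlog = 0.6,
       sodium_meanlog = log(95), cap_sugar_effect = 1.1),
    cs("meals", "combination dishes", 1012, 0.065, is_main_dish = TRUE,
       reference_amount_g = 250,
       satfat_meanlog = log(4.2), sugars_meanlog = log(5), sugars_sdlog = 0.9,
       sodium_meanlog = log(780), sodium_sdlog = 0.45, cap_sodium_effect = 1.2),
    cs("juice", "beverages", 608, 0.107, reference_amount_g = 250,
       p_exempt_health = 0.06,
       satfat_meanlog = log(0.05), sugars_meanlog = log(24), sugars_sdlog = 0.45,
       sodium_meanlog = log(20), cap_sugar_effect = 1.2),
    cs("pudding", "desserts", 180, 0.06, reference_amount_g = 100,
       satfat_meanlog = log(1.6), sugars_meanlog = log(16), sugars_sdlog = 0.4,
       sodium_meanlog = log(150), cap_sugar_effect = 1.2),
    cs("cakes", "bakery", 155, 0.065, reference_amount_g = 80,
       satfat_meanlog = log(4.5), satfat_sdlog = 0.5,
       sugars_meanlog = log(24), sugars_sdlog = 0.4,
       sodium_meanlog = log(230), cap_sugar_effect = 1.2),
    cs("hot_cocoa", "beverages", 32, 0.031, reference_amount_g = 30,
       satfat_meanlog = log(1.3), sugars_meanlog = log(14), sugars_sdlog = 0.3,
       sodium_meanlog = log(130), cap_sugar_effect = 1.2),
    cs("drinkable_yogurt", "dairy", 60, 0.05, reference_amount_g = 200,
       p_exempt_health = 0.9,
       satfat_meanlog = log(1.2), sugars_meanlog = log(18), sodium_meanlog = log(95),
       cap_sugar_effect = 1.3),
    cs("cheese", "dairy", 569, 0.012, reference_amount_g = 30,
       p_exempt_health = 0.92,
       satfat_meanlog = log(4.5), satfat_sdlog = 0.4,
       sugars_meanlog = log(0.6), sodium_meanlog = log(190), sodium_sdlog = 0.5),
    cs("nut_butter", "fats", 101, 0.02, reference_amount_g = 15,
       p_exempt_health = 0.75,
       satfat_meanlog = log(1.5), sugars_meanlog = log(1.6),
       sodium_meanlog = log(55), cap_sugar_effect = 1.5),
    cs("syrups_spreads", "sugars", 92, 0.022, reference_amount_g = 30,
       p_exempt_practical = 0.7,
       satfat_meanlog = log(0.3), satfat_sdlog = 1.3,
       sugars_meanlog = log(14), sodium_meanlog = log(30), sodium_sdlog = 1.2,
       cap_sugar_effect = 1.3),
    cs("milk", "dairy", 201, 0.045, reference_amount_g = 250,
       p_exempt_health = 0.6,
       satfat_meanlog = log(2.8), satfat_sdlog = 0.6,
       sugars_meanlog = log(13), sugars_sdlog = 0.45,
       sodium_meanlog = log(115), cap_sugar_effect = 1.6),
    cs("snacks", "snacks", 900, 0.135, reference_amount_g = 50,
       satfat_meanlog = log(2.0), satfat_sdlog = 1.0,
       sugars_meanlog = log(3.5), sugars_sdlog = 1.1,
       sodium_meanlog = log(320), sodium_sdlog = 0.6, cap_sugar_effect = 1.5),
    cs("meats", "meat", 80, 0.0875, reference_amount_g = 55,
       p_exempt_technical = 0.18,
       satfat_meanlog = log(2.2), sugars_meanlog = log(0.8),
       sodium_meanlog = log(470), sodium_sdlog = 0.4, cap_sodium_effect = 1.2),
    cs("shakes", "beverages", 35, 0.20, reference_amount_g = 250,
       satfat_meanlog = log(2.6), sugars_meanlog = log(26), sugars_sdlog = 0.35,
       sodium_meanlog = log(180), cap_sugar_effect = 1.25)
  )
  generator_config(seed = seed, categories = categories)
}
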