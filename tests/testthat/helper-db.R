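# A small hand-built database exercising every classification route.
# All numbers are chosen so expectations can be recomputed by hand.

tiny_tables <- function() {
  schema <- food_group_schema()
  details <- tibble::tibble(
    food_id = c(
      "11000001", "12000001", "16000001", "14000001", "27000001",
      "30000001", "98000001", "51000001", "52000001", "53000001", "54000001"
    ),
    survey_id = paste0("S", 1:11),
    name = c(
      "Carrot, cooked", "Barley, pearl, cooked", "Macadamia, raw",
      "Butter, plain", "Gravy, instant dry mix, prepared", "Sugar, white",
      "Water, tap", "Sauce, butter and vegetable", "Dish, grain with sauce",
      "Cereal, honey & macadamia clusters", "Spread, proxied"
    ),
    description = NA_character_,
    major_group_code = substr(c(
      "11000001", "12000001", "16000001", "14000001", "27000001",
      "30000001", "98000001", "51000001", "52000001", "53000001", "54000001"
    ), 1, 2),
    discretionary_flag = c(
      "core", "core", "core", "discretionary", "discretionary",
      "discretionary", "unflagged", "discretionary", "core",
      "discretionary", "discretionary"
    )
  )
  nutrients <- tibble::tibble(
    food_id = details$food_id,
    energy_kJ_per_100g = c(150, 500, 3000, 3000, 350, 1700, 0, 900, 700, 1600, 950),
    sodium_mg_per_100g = c(40, 5, 2, 650, 295, 0, 0, 210, 120, 295, 220),
    added_sugars_g_per_100g = c(0, 0, 0, 0, 0, 99, 0, 0, 0, 12, 0),
    water_g_per_100g = c(90, 60, 2, 16, 85, 0.5, 100, 68.9, 63, 4, 60),
    alcohol_g_per_100g = 0
  )
  adg <- tibble::tibble(
    food_id = c("11000001", "12000001", "16000001"),
    vegetables = c(1.2, 0, 0),
    whole_grains = c(0, 0.8, 0),
    nuts_and_seeds = c(0, 0, 3)
  )
  for (cn in setdiff(group_keys(schema), names(adg))) adg[[cn]] <- 0
  adg <- adg[, c("food_id", group_keys(schema))]
  attr(adg, "declared_groups") <- c("vegetables", "whole_grains", "nuts_and_seeds")
  recipes <- tibble::tibble(
    product_food_id = c("51000001", "51000001", "52000001", "52000001", "52000001"),
    ingredient_food_id = c("11000001", "14000001", "51000001", "12000001", "98000001"),
    ingredient_weight_g = c(50, 20, 100, 60, 40),
    weight_change_factor = c(1, 1, 0.9, 2.5, 1)
  )
  assignments <- tibble::tibble(
    food_id = c("14000001", "27000001", "30000001"),
    group = c("animal_fats", "miscellaneous_animal", "added_sugars")
  )
  exclusions <- tibble::tibble(food_id = "98000001", category = "water_or_alcohol_only")
  tags <- subgroup_tags(patterns = tibble::tibble(
    pattern = "gravy|stock", subgroup = "stock_sauce"
  ))
  labels <- tibble::tibble(
    product_food_id = c("53000001", "53000001"),
    ingredient_food_id = c("16000001", "12000001"),
    declared_percent = c(10, 80)
  )
  proxies <- tibble::tibble(product_food_id = "54000001", proxy_food_id = "51000001")
  list(
    schema = schema, details = details, nutrients = nutrients, adg = adg,
    recipes = recipes, assignments = assignments, exclusions = exclusions,
    tags = tags, labels = labels, proxies = proxies
  )
}

tiny_db <- function() {
  tt <- tiny_tables()
  tt$db <- food_database(tt$details, tt$nutrients, tt$recipes, tt$adg, schema = tt$schema)
  tt
}

classify_tiny <- function(tt = tiny_db()) {
  suppressMessages(classify_all(
    tt$db,
    assignments = tt$assignments, labels = tt$labels, proxies = tt$proxies,
    exclusions = tt$exclusions, tags = tt$tags
  ))
}

# named base vectors (groups + water/alcohol channels) for the oracle
tiny_base_vectors <- function(tt = tiny_tables()) {
  schema <- tt$schema
  keys <- c(group_keys(schema), "water_g_per_100g", "alcohol_g_per_100g")
  zero <- stats::setNames(numeric(length(keys)), keys)
  mk <- function(values, water) {
    v <- zero
    v[names(values)] <- values
    v[["water_g_per_100g"]] <- water
    v
  }
  list(
    "11000001" = mk(c(vegetables = 1.2), 90),
    "12000001" = mk(c(whole_grains = 0.8), 60),
    "16000001" = mk(c(nuts_and_seeds = 3), 2),
    "14000001" = mk(c(animal_fats = 3000 / 600), 16),
    "27000001" = mk(c(miscellaneous_animal = 295 / 120), 85),
    "30000001" = mk(c(added_sugars = 99), 0.5),
    "98000001" = mk(numeric(0), 100)
  )
}
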