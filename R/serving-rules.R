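#' Serving-size conversion primitives
#'
#' Three linear bases convert the content of a food into food-group servings
#' per 100 g:
#'
#' * **mass**: `servings = amount_g / serving_size_g`, for the core groups
#'   whose serving is a fixed mass (e.g. 75 g of cooked vegetables);
#' * **energy**: `servings = energy_kJ / 600`, for energy-dense fat groups,
#'   following the 600 kJ discretionary-food serving convention;
#' * **sodium**: `servings = sodium_mg / 120`, for stocks, sauces and gravies
#'   that are salty rather than energy-dense, anchored to the 120 mg Na/100 g
#'   low-salt threshold.
#'
#' A fourth basis, `nutrient_direct`, passes a nutrient value (added sugars,
#' g/100 g) through unchanged.
#'
#' All bases are linear: `servings(k * x) = k * servings(x)` for `k >= 0`.
#'
#' @param amount_g Amount of the group's food present, g per 100 g of product.
#' @param serving_size_g Mass of one serving, g; must be positive.
#' @return Numeric servings per 100 g (vectorised).
#' @examples
#' servings_from_mass(37.5, 75) # 0.5
#' servings_from_energy(600) # 1
#' servings_from_sodium(295) # 2.458333
#' @export
servings_from_mass <- function(amount_g, serving_size_g) {
  if (any(!is.finite(serving_size_g)) || any(serving_size_g <= 0)) {
    rlang::abort("serving_size_g must be positive", class = "plantserve_config_error")
  }
  check_nonneg(amount_g, "amount_g")
  amount_g / serving_size_g
}

#' @rdname servings_from_mass
#' @param energy_kJ Energy content, kJ per 100 g.
#' @param serving_kJ Energy equated to one serving (default 600 kJ).
#' @export
servings_from_energy <- function(energy_kJ, serving_kJ = 600) {
  if (any(!is.finite(serving_kJ)) || any(serving_kJ <= 0)) {
    rlang::abort("serving_kJ must be positive", class = "plantserve_config_error")
  }
  check_nonneg(energy_kJ, "energy_kJ")
  energy_kJ / serving_kJ
}

#' @rdname servings_from_mass
#' @param sodium_mg Sodium content, mg per 100 g.
#' @param serving_mg Sodium equated to one serving (default 120 mg/100 g).
#' @export
servings_from_sodium <- function(sodium_mg, serving_mg = 120) {
  if (any(!is.finite(serving_mg)) || any(serving_mg <= 0)) {
    rlang::abort("serving_mg must be positive", class = "plantserve_config_error")
  }
  check_nonneg(sodium_mg, "sodium_mg")
  sodium_mg / serving_mg
}

#' @rdname servings_from_mass
#' @param added_sugars_g Added sugars, g per 100 g; `NA` is treated as 0 with
#'   a warning (the nutrient file occasionally lacks the value).
#' @export
added_sugars_servings <- function(added_sugars_g) {
  if (anyNA(added_sugars_g)) {
    rlang::warn("missing added-sugars value treated as 0")
    added_sugars_g[is.na(added_sugars_g)] <- 0
  }
  check_nonneg(added_sugars_g, "added_sugars_g")
  added_sugars_g
}

check_nonneg <- function(x, what) {
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    rlang::abort(sprintf("%s must be finite and non-negative", what),
      class = "plantserve_validation_error"
    )
  }
  invisible(x)
}

#' Default serving-rule table
#'
#' One rule per (group, subgroup) pair. `subgroup = NA` is the group's
#' default rule; named subgroups (e.g. `"stock_sauce"` within the
#' miscellaneous groups) select an alternative basis for foods carrying that
#' tag. Mass serving sizes follow the Australian Dietary Guidelines
#' conventions for each core group (e.g. 75 g cooked vegetables, 150 g fruit,
#' 250 g milk); they are a user-editable starting point, not survey-derived
#' constants, and can be replaced wholesale via [read_serving_rules()].
#'
#' @return A `serving_rules` tibble with columns `group`, `subgroup`,
#'   `basis` (`mass`, `energy`, `sodium`, `nutrient_direct`) and
#'   `denominator` (serving size in g, kJ or mg Na; `NA` for
#'   `nutrient_direct`).
#' @export
default_serving_rules <- function() {
  rules <- tibble::tribble(
    ~group,                 ~subgroup,     ~basis,            ~denominator,
    "whole_grains",         NA,            "mass",            75,
    "refined_grains",       NA,            "mass",            75,
    "vegetables",           NA,            "mass",            75,
    "potatoes",             NA,            "mass",            75,
    "legumes",              NA,            "mass",            75,
    "fruits",               NA,            "mass",            150,
    "fruit_juices",         NA,            "mass",            125,
    "nuts_and_seeds",       NA,            "mass",            30,
    "herbs_and_spices",     NA,            "mass",            5,
    "plant_oils",           NA,            "mass",            10,
    "saturated_plant_fats", NA,            "energy",          600,
    "tea_and_coffee",       NA,            "mass",            250,
    "miscellaneous_plant",  NA,            "energy",          600,
    "miscellaneous_plant",  "stock_sauce", "sodium",          120,
    "red_meat",             NA,            "mass",            65,
    "processed_meat",       NA,            "mass",            65,
    "poultry",              NA,            "mass",            80,
    "fish_and_seafood",     NA,            "mass",            100,
    "eggs",                 NA,            "mass",            60,
    "milk_and_yoghurt",     NA,            "mass",            250,
    "cheese",               NA,            "mass",            40,
    "animal_fats",          NA,            "energy",          600,
    "miscellaneous_animal", NA,            "energy",          600,
    "miscellaneous_animal", "stock_sauce", "sodium",          120,
    "added_sugars",         NA,            "nutrient_direct", NA
  )
  serving_rules(rules)
}

#' Validate a serving-rule table
#'
#' @param rules Data frame with columns `group`, `subgroup`, `basis`,
#'   `denominator`.
#' @param schema Optional [food_group_schema()]; when given, every schema
#'   group must carry a default (`subgroup = NA`) rule and no rule may name a
#'   group outside the schema.
#' @return The validated tibble with class `serving_rules`.
#' @export
serving_rules <- function(rules, schema = NULL) {
  stopifnot(is.data.frame(rules))
  need <- c("group", "subgroup", "basis", "denominator")
  miss <- setdiff(need, names(rules))
  if (length(miss)) {
    rlang::abort(sprintf("serving-rule table lacks column(s): %s", paste(miss, collapse = ", ")),
      class = "plantserve_config_error"
    )
  }
  rules <- tibble::as_tibble(rules[, need])
  rules$subgroup <- as.character(rules$subgroup)
  bad_basis <- setdiff(unique(rules$basis), c("mass", "energy", "sodium", "nutrient_direct"))
  if (length(bad_basis)) {
    rlang::abort(sprintf("unknown serving basis: %s", paste(bad_basis, collapse = ", ")),
      class = "plantserve_config_error"
    )
  }
  key <- paste(rules$group, rules$subgroup, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort("each (group, subgroup) pair may have only one serving rule",
      class = "plantserve_config_error"
    )
  }
  quant <- rules$basis %in% c("mass", "energy", "sodium")
  if (any(quant & (is.na(rules$denominator) | rules$denominator <= 0))) {
    rlang::abort("mass/energy/sodium rules need a positive denominator",
      class = "plantserve_config_error"
    )
  }
  if (!is.null(schema)) {
    assert_group_keys(unique(rules$group), schema, what = "serving-rule group")
    nodefault <- setdiff(group_keys(schema), rules$group[is.na(rules$subgroup)])
    if (length(nodefault)) {
      rlang::abort(
        sprintf("group(s) without a default serving rule: %s", paste(nodefault, collapse = ", ")),
        class = "plantserve_config_error"
      )
    }
  }
  class(rules) <- c("serving_rules", class(tibble::tibble()))
  rules
}

#' Read a serving-rule configuration file
#'
#' The file is YAML: a list of records each with `group`, `basis`,
#' `denominator` and optionally `subgroup`. Unparsable or inconsistent rules
#' produce a configuration error naming the offending entry.
#'
#' @param path Path to the YAML rule file.
#' @param schema Optional schema to validate group keys against.
#' @return A `serving_rules` tibble.
#' @export
read_serving_rules <- function(path, schema = NULL) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) {
    rlang::abort("serving-rule file is empty", class = "plantserve_config_error")
  }
  rows <- purrr::map_dfr(raw, function(r) {
    tibble::tibble(
      group = as.character(r$group %||% NA_character_),
      subgroup = as.character(r$subgroup %||% NA_character_),
      basis = as.character(r$basis %||% NA_character_),
      denominator = parse_decimal(r$denominator %||% NA)
    )
  })
  if (anyNA(rows$group) || anyNA(rows$basis)) {
    rlang::abort("every rule needs `group` and `basis`", class = "plantserve_config_error")
  }
  serving_rules(rows, schema = schema)
}

#' Subgroup-tag configuration
#'
#' Subgroup tags steer [select_rule()] to an alternative serving rule within
#' a group (e.g. the sodium-based `stock_sauce` rule inside the
#' miscellaneous groups). Tags are assigned either by explicit food id or by
#' a case-insensitive regular expression on the food name.
#'
#' @param ids Tibble with columns `food_id`, `subgroup` (explicit
#'   assignments; take precedence).
#' @param patterns Tibble with columns `pattern`, `subgroup`; the first
#'   pattern matching the food name wins.
#' @return A list of class `subgroup_tags`.
#' @export
subgroup_tags <- function(ids = NULL, patterns = NULL) {
  empty_ids <- tibble::tibble(food_id = character(), subgroup = character())
  empty_pat <- tibble::tibble(pattern = character(), subgroup = character())
  ids <- if (is.null(ids)) empty_ids else tibble::as_tibble(ids)
  patterns <- if (is.null(patterns)) empty_pat else tibble::as_tibble(patterns)
  stopifnot(
    all(c("food_id", "subgroup") %in% names(ids)),
    all(c("pattern", "subgroup") %in% names(patterns))
  )
  structure(list(ids = ids, patterns = patterns), class = "subgroup_tags")
}

# internal: the subgroup tag (or NA) for one food
subgroup_for <- function(food_id, name, tags) {
  if (is.null(tags)) {
    return(NA_character_)
  }
  hit <- match(food_id, tags$ids$food_id)
  if (!is.na(hit)) {
    return(tags$ids$subgroup[hit])
  }
  if (nrow(tags$patterns) && !is.na(name)) {
    for (i in seq_len(nrow(tags$patterns))) {
      if (grepl(tags$patterns$pattern[i], name, ignore.case = TRUE)) {
        return(tags$patterns$subgroup[i])
      }
    }
  }
  NA_character_
}

#' Select the serving rule for a food within a group
#'
#' Resolution order: a rule matching the food's subgroup tag (assigned by
#' explicit id or name pattern via [subgroup_tags()]), otherwise the group's
#' default rule. Exactly one rule is returned; a group with no applicable
#' rule is a configuration error naming the food and group.
#'
#' @param food A one-row food record (list or data frame row) with at least
#'   `food_id` and `name`.
#' @param group_key Food-group key.
#' @param rules A `serving_rules` table.
#' @param tags Optional [subgroup_tags()].
#' @return A one-row `serving_rules` tibble.
#' @examples
#' rules <- default_serving_rules()
#' tags <- subgroup_tags(patterns = tibble::tibble(
#'   pattern = "stock|sauce|gravy", subgroup = "stock_sauce"
#' ))
#' select_rule(
#'   list(food_id = "27000001", name = "Gravy, instant"),
#'   "miscellaneous_animal", rules, tags
#' )$basis # sodium
#' @export
select_rule <- function(food, group_key, rules, tags = NULL) {
  stopifnot(inherits(rules, "serving_rules"))
  cand <- rules[rules$group == group_key, , drop = FALSE]
  if (!nrow(cand)) {
    rlang::abort(
      sprintf("no serving rule configured for group '%s' (food %s)", group_key, food$food_id),
      class = "plantserve_config_error"
    )
  }
  tag <- subgroup_for(food$food_id, food$name %||% NA_character_, tags)
  if (!is.na(tag) && tag %in% cand$subgroup) {
    return(cand[which(cand$subgroup == tag)[1L], , drop = FALSE])
  }
  dflt <- which(is.na(cand$subgroup))
  if (!length(dflt)) {
    rlang::abort(
      sprintf(
        "no applicable serving rule for food %s in group '%s' (no default rule)",
        food$food_id, group_key
      ),
      class = "plantserve_config_error"
    )
  }
  cand[dflt[1L], , drop = FALSE]
}

# internal: servings per 100 g for a pure (single-group) food under one rule.
# Mass basis treats the food itself as the group content: 100 g of food per
# 100 g of food; nutrient bases read the food's nutrient record.
base_servings_value <- function(food, rule) {
  switch(rule$basis,
    mass = servings_from_mass(100, rule$denominator),
    energy = servings_from_energy(food$energy_kJ_per_100g %||% 0, rule$denominator),
    sodium = servings_from_sodium(food$sodium_mg_per_100g %||% 0, rule$denominator),
    nutrient_direct = added_sugars_servings(food$added_sugars_g_per_100g %||% 0),
    rlang::abort("unknown basis", class = "plantserve_internal_error")
  )
}
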