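#' The default 23-group plant/animal food-group schema
#'
#' Returns the default classification schema used throughout the package:
#' 23 food groups, each tagged with the kingdom it derives from (`"plant"`,
#' `"animal"` or `"neither"`). Thirteen groups are plant-derived, nine are
#' animal-derived, and `added_sugars` is tagged `"neither"` by default because
#' added sugars deliberately do not distinguish plant from animal origin
#' (honey would otherwise be double-counted against plant sugars).
#'
#' Water and alcohol are not food groups: they travel through every
#' computation as side channels (grams per 100 g) and never enter
#' plant/animal membership flags.
#'
#' @return A tibble with columns `group` (unique key) and `kingdom`.
#' @seealso [food_group_schema()]
#' @export
default_food_groups <- function() {
  tibble::tribble(
    ~group,                 ~kingdom,
    "whole_grains",         "plant",
    "refined_grains",       "plant",
    "vegetables",           "plant",
    "potatoes",             "plant",
    "legumes",              "plant",
    "fruits",               "plant",
    "fruit_juices",         "plant",
    "nuts_and_seeds",       "plant",
    "herbs_and_spices",     "plant",
    "plant_oils",           "plant",
    "saturated_plant_fats", "plant",
    "tea_and_coffee",       "plant",
    "miscellaneous_plant",  "plant",
    "red_meat",             "animal",
    "processed_meat",       "animal",
    "poultry",              "animal",
    "fish_and_seafood",     "animal",
    "eggs",                 "animal",
    "milk_and_yoghurt",     "animal",
    "cheese",               "animal",
    "animal_fats",          "animal",
    "miscellaneous_animal", "animal",
    "added_sugars",         "neither"
  )
}

#' Construct a food-group schema
#'
#' A schema fixes the set of 23 food-group keys, their kingdom tags and the
#' two side channels (water, alcohol). All servings vectors, databases and
#' summaries are expressed against one schema.
#'
#' @param groups Tibble with columns `group` and `kingdom`
#'   (one of `"plant"`, `"animal"`, `"neither"`). Must contain exactly 23
#'   unique groups.
#' @param added_sugars_kingdom Convenience re-tag for the `added_sugars`
#'   group: `"neither"` (default) keeps added sugars out of plant/animal
#'   membership; `"plant"` counts them as plant-derived.
#' @return An object of class `food_group_schema`: a list with elements
#'   `groups` (tibble) and `side_channels` (character).
#' @examples
#' sch <- food_group_schema()
#' nrow(sch$groups) # 23
#' @export
food_group_schema <- function(groups = default_food_groups(),
                              added_sugars_kingdom = c("neither", "plant")) {
  added_sugars_kingdom <- match.arg(added_sugars_kingdom)
  stopifnot(is.data.frame(groups), all(c("group", "kingdom") %in% names(groups)))
  groups <- tibble::as_tibble(groups[, c("group", "kingdom")])
  if (anyDuplicated(groups$group)) {
    rlang::abort("food-group keys must be unique", class = "plantserve_schema_error")
  }
  if (nrow(groups) != 23L) {
    rlang::abort(
      sprintf("schema must define exactly 23 food groups, got %d", nrow(groups)),
      class = "plantserve_schema_error"
    )
  }
  bad <- setdiff(unique(groups$kingdom), c("plant", "animal", "neither"))
  if (length(bad)) {
    rlang::abort(
      sprintf("unknown kingdom tag(s): %s", paste(bad, collapse = ", ")),
      class = "plantserve_schema_error"
    )
  }
  if ("added_sugars" %in% groups$group) {
    groups$kingdom[groups$group == "added_sugars"] <- added_sugars_kingdom
  }
  structure(
    list(groups = groups, side_channels = c("water", "alcohol")),
    class = "food_group_schema"
  )
}

#' @export
print.food_group_schema <- function(x, ...) {
  tab <- table(x$groups$kingdom)
  cat(sprintf(
    "<food_group_schema> %d groups (%s) + side channels: %s\n",
    nrow(x$groups),
    paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
    paste(x$side_channels, collapse = ", ")
  ))
  invisible(x)
}

#' Group keys of a schema
#' @param schema A [food_group_schema()].
#' @param kingdom Optional filter: return only groups of this kingdom.
#' @return Character vector of group keys.
#' @export
group_keys <- function(schema, kingdom = NULL) {
  stopifnot(inherits(schema, "food_group_schema"))
  g <- schema$groups
  if (!is.null(kingdom)) g <- g[g$kingdom %in% kingdom, ]
  g$group
}

# internal: assert that `keys` are all valid group keys of the schema
assert_group_keys <- function(keys, schema, what = "column") {
  unknown <- setdiff(keys, group_keys(schema))
  if (length(unknown)) {
    rlang::abort(
      sprintf(
        "%s(s) not in the %d-group schema: %s",
        what, nrow(schema$groups), paste(unknown, collapse = ", ")
      ),
      class = "plantserve_schema_error"
    )
  }
  invisible(keys)
}
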