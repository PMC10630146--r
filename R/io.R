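#' Readers for AUSNUT-style source files
#'
#' Four delimited text files feed the database expansion: a Food Details
#' file (identity, names, major group, core/discretionary flag), a Food
#' Recipe file (product -> ingredient edges with ingoing weights and
#' weight-change factors), a Food Nutrient file (per-100 g energy, sodium,
#' added sugars, water, alcohol) and an existing food-group servings file
#' (dietary-guideline servings per 100 g that remain unchanged).
#'
#' All readers take comma-delimited UTF-8 with a header row. Because survey
#' releases vary in their column headers, each reader accepts a `col_map`: a
#' named character vector mapping the canonical column names documented here
#' to the headers actually present in the file. Decimal values may use
#' either `"."` or the middle dot `"·"`; both parse identically.
#'
#' @param path Path to the file.
#' @param col_map Named character vector, `canonical = "file header"`.
#'   Defaults to the canonical names themselves.
#' @name readers
NULL

# read a CSV as character columns and rename file headers to canonical names
read_mapped_csv <- function(path, col_map, required) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = c("", "NA")
  )
  if (!is.null(col_map) && length(col_map)) {
    for (canon in names(col_map)) {
      hdr <- col_map[[canon]]
      if (hdr %in% names(df)) names(df)[names(df) == hdr] <- canon
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    rlang::abort(
      sprintf("%s: missing required column(s): %s", basename(path), paste(miss, collapse = ", ")),
      class = "plantserve_schema_error"
    )
  }
  df
}

#' @describeIn readers Food Details. Canonical columns: `food_id`,
#'   `survey_id`, `name` (required); `description`, `major_group_code`,
#'   `discretionary_flag` (optional). A missing flag column yields
#'   `"unflagged"` with a warning; a missing major-group column is derived
#'   from the first two characters of the 8-digit food id.
#' @return `read_food_details()`: a tibble of food records.
#' @export
read_food_details <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, col_map, required = c("food_id", "survey_id", "name"))
  if (anyDuplicated(df$food_id)) {
    dup <- unique(df$food_id[duplicated(df$food_id)])
    rlang::abort(
      sprintf("duplicate food_id in %s: %s", basename(path), paste(head(dup, 5L), collapse = ", ")),
      class = "plantserve_integrity_error"
    )
  }
  if (!"major_group_code" %in% names(df)) {
    df$major_group_code <- substr(df$food_id, 1L, 2L)
  } else {
    df$major_group_code[is.na(df$major_group_code)] <-
      substr(df$food_id[is.na(df$major_group_code)], 1L, 2L)
    bad <- df$major_group_code != substr(df$food_id, 1L, 2L)
    if (any(bad)) {
      rlang::abort(
        sprintf(
          "major_group_code disagrees with leading food_id digits for: %s",
          paste(head(df$food_id[bad], 5L), collapse = ", ")
        ),
        class = "plantserve_integrity_error"
      )
    }
  }
  if (!"discretionary_flag" %in% names(df)) {
    rlang::warn("no discretionary_flag column; all foods marked 'unflagged'")
    df$discretionary_flag <- "unflagged"
  } else {
    df$discretionary_flag[is.na(df$discretionary_flag)] <- "unflagged"
    bad <- setdiff(unique(df$discretionary_flag), c("core", "discretionary", "unflagged"))
    if (length(bad)) {
      rlang::abort(
        sprintf("discretionary_flag must be core/discretionary/unflagged, got: %s", paste(bad, collapse = ", ")),
        class = "plantserve_validation_error"
      )
    }
  }
  if (!"description" %in% names(df)) df$description <- NA_character_
  tibble::as_tibble(df[, c(
    "food_id", "survey_id", "name", "description",
    "major_group_code", "discretionary_flag"
  )])
}

#' @describeIn readers Food Nutrient file. Canonical columns: `food_id`,
#'   `energy_kJ_per_100g`, `sodium_mg_per_100g`, `added_sugars_g_per_100g`,
#'   `water_g_per_100g`, `alcohol_g_per_100g`. Negative values are rejected;
#'   water + alcohol must not exceed 100 g/100 g.
#' @return `read_nutrient_file()`: a tibble keyed by `food_id`.
#' @export
read_nutrient_file <- function(path, col_map = NULL) {
  nutr <- c(
    "energy_kJ_per_100g", "sodium_mg_per_100g", "added_sugars_g_per_100g",
    "water_g_per_100g", "alcohol_g_per_100g"
  )
  df <- read_mapped_csv(path, col_map, required = c("food_id", nutr))
  if (anyDuplicated(df$food_id)) {
    rlang::abort("duplicate food_id in nutrient file", class = "plantserve_integrity_error")
  }
  for (cn in nutr) {
    v <- parse_decimal(df[[cn]])
    v[is.na(df[[cn]])] <- 0
    if (anyNA(v)) {
      rlang::abort(sprintf("unparseable value in column %s", cn), class = "plantserve_validation_error")
    }
    if (any(v < 0)) {
      rlang::abort(
        sprintf(
          "negative %s for food_id %s", cn,
          paste(head(df$food_id[v < 0], 5L), collapse = ", ")
        ),
        class = "plantserve_validation_error"
      )
    }
    df[[cn]] <- v
  }
  over <- df$water_g_per_100g + df$alcohol_g_per_100g > 100 + 1e-9
  if (any(over)) {
    rlang::abort(
      sprintf(
        "water + alcohol exceed 100 g/100 g for: %s",
        paste(head(df$food_id[over], 5L), collapse = ", ")
      ),
      class = "plantserve_validation_error"
    )
  }
  tibble::as_tibble(df[, c("food_id", nutr)])
}

#' @describeIn readers Food Recipe file. Canonical columns:
#'   `product_food_id`, `ingredient_food_id`, `ingredient_weight_g`
#'   (ingoing/raw weight, must be positive) and `weight_change_factor`. A
#'   missing factor column defaults to 1 (no change) with a warning.
#'   `factor_encoding` says how the factor column is stored: as a
#'   multiplier (`0.8` = 20 % moisture loss) or as a signed percentage
#'   (`-20` means the same); percentages are normalised to multipliers.
#' @param factor_encoding `"multiplier"` (default) or `"percent"`.
#' @return `read_recipe_file()`: a tibble of recipe edges.
#' @export
read_recipe_file <- function(path, col_map = NULL,
                             factor_encoding = c("multiplier", "percent")) {
  factor_encoding <- match.arg(factor_encoding)
  df <- read_mapped_csv(path, col_map,
    required = c("product_food_id", "ingredient_food_id", "ingredient_weight_g")
  )
  w <- parse_decimal(df$ingredient_weight_g)
  bad <- is.na(w) | w <= 0
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "non-positive or unparseable ingredient weight at row(s): %s",
        paste(head(which(bad), 5L), collapse = ", ")
      ),
      class = "plantserve_validation_error"
    )
  }
  df$ingredient_weight_g <- w
  if (!"weight_change_factor" %in% names(df)) {
    rlang::warn("no weight_change_factor column; assuming factor 1 (no weight change)")
    df$weight_change_factor <- 1
  } else {
    f <- parse_decimal(df$weight_change_factor)
    f[is.na(df$weight_change_factor)] <- if (factor_encoding == "percent") 0 else 1
    if (factor_encoding == "percent") f <- 1 + f / 100
    bad <- is.na(f) | f <= 0
    if (any(bad)) {
      rlang::abort(
        sprintf(
          "non-positive or unparseable weight-change factor at row(s): %s",
          paste(head(which(bad), 5L), collapse = ", ")
        ),
        class = "plantserve_validation_error"
      )
    }
    df$weight_change_factor <- f
  }
  self <- df$product_food_id == df$ingredient_food_id
  if (any(self)) {
    rlang::abort(
      sprintf(
        "recipe lists a product as its own ingredient: %s",
        paste(head(unique(df$product_food_id[self]), 5L), collapse = ", ")
      ),
      class = "plantserve_integrity_error"
    )
  }
  tibble::as_tibble(df[, c(
    "product_food_id", "ingredient_food_id",
    "ingredient_weight_g", "weight_change_factor"
  )])
}

#' @describeIn readers Existing food-group servings per 100 g. Canonical
#'   columns: `food_id` plus any subset of the schema's 23 group keys; a
#'   column outside the schema is a schema error, a negative serving a
#'   validation error. Groups absent from the file are filled with 0; the
#'   original column set is kept in the `declared_groups` attribute so that
#'   downstream code can tell declared zeros from absent groups.
#' @param schema A [food_group_schema()].
#' @return `read_adg_servings()`: a wide tibble `food_id` x 23 groups.
#' @export
read_adg_servings <- function(path, schema = food_group_schema(), col_map = NULL) {
  df <- read_mapped_csv(path, col_map, required = "food_id")
  declared <- setdiff(names(df), "food_id")
  assert_group_keys(declared, schema)
  if (anyDuplicated(df$food_id)) {
    rlang::abort("duplicate food_id in servings file", class = "plantserve_integrity_error")
  }
  for (cn in declared) {
    v <- parse_decimal(df[[cn]])
    v[is.na(df[[cn]])] <- 0
    if (anyNA(v) || any(v < 0)) {
      rlang::abort(sprintf("negative or unparseable serving value in column %s", cn),
        class = "plantserve_validation_error"
      )
    }
    df[[cn]] <- v
  }
  for (cn in setdiff(group_keys(schema), declared)) df[[cn]] <- 0
  out <- tibble::as_tibble(df[, c("food_id", group_keys(schema))])
  attr(out, "declared_groups") <- declared
  out
}

#' Assemble a source food database
#'
#' Joins the four source tables into a single object used by the
#' classification workflow. Referential integrity is checked once here:
#' recipe-edge endpoints that resolve to no food record, and nutrient rows
#' for unknown foods, are collected into one `orphans` report (and warned
#' about) rather than dropped silently.
#'
#' @param details Tibble from [read_food_details()] (or equivalent).
#' @param nutrients Optional tibble from [read_nutrient_file()].
#' @param recipes Optional tibble from [read_recipe_file()].
#' @param adg Optional wide tibble from [read_adg_servings()].
#' @param schema A [food_group_schema()].
#' @return A `food_db` object: list with `records` (details joined to
#'   nutrients), `recipes`, `adg`, `orphans` and `schema`.
#' @export
food_database <- function(details, nutrients = NULL, recipes = NULL, adg = NULL,
                          schema = food_group_schema()) {
  stopifnot(is.data.frame(details))
  details <- tibble::as_tibble(details)
  nutr_cols <- c(
    "energy_kJ_per_100g", "sodium_mg_per_100g", "added_sugars_g_per_100g",
    "water_g_per_100g", "alcohol_g_per_100g"
  )
  orphans <- tibble::tibble(source = character(), food_id = character())
  if (is.null(nutrients)) {
    nutrients <- tibble::tibble(food_id = character())
    for (cn in nutr_cols) nutrients[[cn]] <- numeric()
  } else {
    extra <- setdiff(nutrients$food_id, details$food_id)
    if (length(extra)) {
      rlang::warn(sprintf("%d nutrient row(s) have no food record; kept in orphan report", length(extra)))
      orphans <- bind_rows(orphans, tibble::tibble(source = "nutrients", food_id = extra))
    }
  }
  records <- left_join(details, nutrients, by = "food_id")
  for (cn in nutr_cols) {
    if (!cn %in% names(records)) records[[cn]] <- 0
    records[[cn]][is.na(records[[cn]])] <- 0
  }
  if (!is.null(recipes) && nrow(recipes)) {
    ends <- unique(c(recipes$product_food_id, recipes$ingredient_food_id))
    extra <- setdiff(ends, details$food_id)
    if (length(extra)) {
      rlang::warn(sprintf("%d recipe endpoint(s) have no food record; kept in orphan report", length(extra)))
      orphans <- bind_rows(orphans, tibble::tibble(source = "recipes", food_id = extra))
    }
  } else if (is.null(recipes)) {
    recipes <- tibble::tibble(
      product_food_id = character(), ingredient_food_id = character(),
      ingredient_weight_g = numeric(), weight_change_factor = numeric()
    )
  }
  if (is.null(adg)) {
    adg <- tibble::tibble(food_id = character())
    for (cn in group_keys(schema)) adg[[cn]] <- numeric()
    attr(adg, "declared_groups") <- character()
  }
  structure(
    list(
      records = records, recipes = tibble::as_tibble(recipes),
      adg = adg, orphans = orphans, schema = schema
    ),
    class = "food_db"
  )
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf(
    "<food_db> %d foods, %d recipe edges, %d with existing servings, %d orphan ids\n",
    nrow(x$records), nrow(x$recipes), nrow(x$adg), nrow(x$orphans)
  ))
  invisible(x)
}

#' Load a source database from a YAML configuration
#'
#' The configuration names the four input paths and, optionally, per-file
#' column mappings and the recipe factor encoding:
#'
#' ```yaml
#' details: details.csv
#' nutrients: nutrients.csv
#' recipes: recipes.csv
#' adg_servings: adg.csv
#' factor_encoding: multiplier
#' column_maps:
#'   details: {food_id: "Food ID", survey_id: "Survey ID", name: "Food Name"}
#' ```
#'
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config_path Path to the YAML file.
#' @param schema A [food_group_schema()].
#' @return A `food_db` object.
#' @export
load_food_database <- function(config_path, schema = food_group_schema()) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  resolve_path <- function(p) {
    if (is.null(p)) {
      return(NULL)
    }
    if (file.exists(p)) p else file.path(base, p)
  }
  maps <- cfg$column_maps %||% list()
  as_map <- function(m) if (is.null(m)) NULL else unlist(m)
  details <- read_food_details(resolve_path(cfg$details), col_map = as_map(maps$details))
  nutrients <- if (!is.null(cfg$nutrients)) {
    read_nutrient_file(resolve_path(cfg$nutrients), col_map = as_map(maps$nutrients))
  }
  recipes <- if (!is.null(cfg$recipes)) {
    read_recipe_file(resolve_path(cfg$recipes),
      col_map = as_map(maps$recipes),
      factor_encoding = cfg$factor_encoding %||% "multiplier"
    )
  }
  adg <- if (!is.null(cfg$adg_servings)) {
    read_adg_servings(resolve_path(cfg$adg_servings), schema, col_map = as_map(maps$adg_servings))
  }
  food_database(details, nutrients, recipes, adg, schema = schema)
}

#' Write / read an expanded database
#'
#' The expanded database is serialised as one CSV row per food: `food_id`,
#' `method`, the 23 group columns, `water_g_per_100g`, `alcohol_g_per_100g`
#' and a free-text `provenance` column. Writing then reading returns the
#' identical servings to at least six decimal places (values are written at
#' full precision).
#'
#' @param db An `expanded_db` from [classify_all()] or
#'   [read_expanded_database()].
#' @param path Output file path.
#' @return `write_expanded_database()` returns `path` invisibly.
#' @export
write_expanded_database <- function(db, path) {
  stopifnot(inherits(db, "expanded_db"))
  out <- left_join(db$servings, db$provenance, by = "food_id")
  out$provenance[is.na(out$provenance)] <- ""
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_expanded_database
#' @param schema A [food_group_schema()]; columns must match it exactly.
#' @param records Optional food-record tibble to attach; defaults to minimal
#'   records reconstructed from the servings rows.
#' @return `read_expanded_database()`: an `expanded_db` object.
#' @export
read_expanded_database <- function(path, schema = food_group_schema(), records = NULL) {
  df <- read_mapped_csv(path, NULL, required = c("food_id", "method"))
  keys <- group_keys(schema)
  miss <- setdiff(c(keys, "water_g_per_100g", "alcohol_g_per_100g"), names(df))
  if (length(miss)) {
    rlang::abort(sprintf("expanded database lacks column(s): %s", paste(miss, collapse = ", ")),
      class = "plantserve_schema_error"
    )
  }
  for (cn in c(keys, "water_g_per_100g", "alcohol_g_per_100g")) {
    df[[cn]] <- parse_decimal(df[[cn]])
  }
  prov <- tibble::tibble(
    food_id = df$food_id,
    provenance = if ("provenance" %in% names(df)) {
      ifelse(is.na(df$provenance), "", df$provenance)
    } else {
      ""
    }
  )
  servings <- tibble::as_tibble(
    df[, c("food_id", "method", keys, "water_g_per_100g", "alcohol_g_per_100g")]
  )
  if (is.null(records)) {
    records <- tibble::tibble(
      food_id = df$food_id, survey_id = NA_character_, name = NA_character_,
      description = NA_character_,
      major_group_code = substr(df$food_id, 1L, 2L),
      discretionary_flag = "unflagged"
    )
  }
  expanded_database(records, servings, prov, schema = schema)
}

#' Construct an expanded database object
#'
#' @param records Food-record tibble (at least `food_id`).
#' @param servings Wide servings tibble: `food_id`, `method`, 23 group
#'   columns, `water_g_per_100g`, `alcohol_g_per_100g`.
#' @param provenance Tibble `food_id`, `provenance` (free-text audit note).
#' @param outcomes Optional per-food classification outcomes (see
#'   [classify_all()]).
#' @param schema The governing [food_group_schema()].
#' @return An `expanded_db` object.
#' @export
expanded_database <- function(records, servings, provenance = NULL,
                              outcomes = NULL, schema = food_group_schema()) {
  stopifnot(is.data.frame(records), is.data.frame(servings))
  missing_rec <- setdiff(servings$food_id, records$food_id)
  if (length(missing_rec)) {
    rlang::abort(
      sprintf(
        "servings refer to food_id(s) absent from records: %s",
        paste(head(missing_rec, 5L), collapse = ", ")
      ),
      class = "plantserve_integrity_error"
    )
  }
  if (is.null(provenance)) {
    provenance <- tibble::tibble(food_id = servings$food_id, provenance = "")
  }
  structure(
    list(
      records = tibble::as_tibble(records),
      servings = tibble::as_tibble(servings),
      provenance = tibble::as_tibble(provenance),
      outcomes = outcomes, schema = schema
    ),
    class = "expanded_db"
  )
}

#' @export
print.expanded_db <- function(x, ...) {
  tab <- table(x$servings$method)
  cat(sprintf(
    "<expanded_db> %d foods classified: %s\n",
    nrow(x$servings),
    paste(sprintf("%s %s", tab, names(tab)), collapse = ", ")
  ))
  invisible(x)
}

# internal: one servings_vector from a wide servings row
sv_from_row <- function(row, schema) {
  keys <- group_keys(schema)
  servings_vector(
    stats::setNames(as.numeric(row[1L, keys]), keys),
    schema = schema,
    water = row$water_g_per_100g[1L], alcohol = row$alcohol_g_per_100g[1L],
    method = row$method[1L]
  )
}

# internal: one wide row from a servings_vector
sv_to_row <- function(food_id, v) {
  vals <- as.list(sv_groups(v))
  tibble::as_tibble(c(
    list(food_id = food_id, method = sv_method(v)),
    vals,
    list(
      water_g_per_100g = unclass(v)[["water"]],
      alcohol_g_per_100g = unclass(v)[["alcohol"]]
    )
  ))
}
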