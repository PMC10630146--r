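#' Classify every food in a database
#'
#' Runs the systematic classification workflow over all food records. Each
#' food is routed through, in order: an exclusion check (curated categories
#' that deliberately stay unclassified), direct classification (existing
#' servings or single-group rule assignment), the recipe-based approach,
#' the label-based approach and finally a proxy product — the first route
#' that succeeds wins. Foods for which every route fails become
#' `unclassified` with the failure reason recorded; nothing is fatal at the
#' whole-database level. Water and alcohol content is recorded for every
#' food, including unclassified ones, from the nutrient file.
#'
#' @param db A `food_db` from [food_database()].
#' @param rules A `serving_rules` table.
#' @param assignments Optional tibble `food_id`, `group`: single-group
#'   direct assignments for foods without an existing servings row.
#' @param labels Optional label declarations ([read_label_file()]).
#' @param proxies Optional proxy table ([read_proxy_file()]).
#' @param exclusions Optional tibble `food_id`, `category` with category in
#'   `non_nutritive_sweetener`, `human_milk_or_infant_formula`,
#'   `protein_powder_or_supplement`, `yeast`, `cooking_additive`,
#'   `water_or_alcohol_only`.
#' @param tags Optional [subgroup_tags()].
#' @param tol Servings above `tol` count as "contains the group" when
#'   deriving plant/animal flags.
#' @return An `expanded_db` whose `outcomes` element holds one row per food:
#'   `food_id`, `method`, `excluded_category`, `reason`, `depth` and the
#'   four membership flags.
#' @export
classify_all <- function(db, rules = default_serving_rules(),
                         assignments = NULL, labels = NULL, proxies = NULL,
                         exclusions = NULL, tags = NULL, tol = 1e-9) {
  schema <- db$schema
  excl_categories <- c(
    "non_nutritive_sweetener", "human_milk_or_infant_formula",
    "protein_powder_or_supplement", "yeast", "cooking_additive",
    "water_or_alcohol_only"
  )
  if (!is.null(exclusions)) {
    exclusions <- tibble::as_tibble(exclusions)
    bad <- setdiff(unique(exclusions$category), excl_categories)
    if (length(bad)) {
      rlang::abort(sprintf("unknown exclusion category: %s", paste(bad, collapse = ", ")),
        class = "plantserve_validation_error"
      )
    }
  }
  ctx <- resolution_context(db, rules, assignments, labels, proxies, tags, exclusions)
  ids <- sort(db$records$food_id)
  rows <- vector("list", length(ids))
  outcome <- vector("list", length(ids))
  prov <- character(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    rec <- food_record(ctx, id)
    excl <- if (!is.null(exclusions)) {
      j <- match(id, exclusions$food_id)
      if (!is.na(j)) exclusions$category[j] else NA_character_
    } else {
      NA_character_
    }
    if (!is.na(excl)) {
      v <- servings_vector(NULL,
        schema = schema,
        water = rec$water_g_per_100g %||% 0,
        alcohol = rec$alcohol_g_per_100g %||% 0,
        method = "unclassified"
      )
      res <- list(servings = v, method = "unclassified", depth = NA_integer_)
      prov[k] <- sprintf("excluded: %s", excl)
      reason <- sprintf("excluded category %s", excl)
    } else {
      res <- tryCatch(
        resolve_one(id, ctx, stack = character(), allow_proxy = TRUE),
        plantserve_unresolved_error = function(e) conditionMessage(e),
        plantserve_cycle_error = function(e) conditionMessage(e),
        plantserve_validation_error = function(e) conditionMessage(e)
      )
      if (is.character(res)) {
        reason <- res
        v <- servings_vector(NULL,
          schema = schema,
          water = rec$water_g_per_100g %||% 0,
          alcohol = rec$alcohol_g_per_100g %||% 0,
          method = "unclassified"
        )
        res <- list(servings = v, method = "unclassified", depth = NA_integer_)
        prov[k] <- sprintf("unclassified: %s", reason)
      } else {
        reason <- NA_character_
        prov[k] <- switch(res$method,
          direct = "direct classification",
          recipe = sprintf("recipe-based (depth %d)", res$depth),
          label = "label-based",
          proxy = sprintf("proxy=%s", ctx$proxies$proxy_food_id[match(id, ctx$proxies$product_food_id)]),
          res$method
        )
      }
    }
    flags <- derive_flags(res$servings, schema, tol = tol)
    rows[[k]] <- sv_to_row(id, res$servings)
    outcome[[k]] <- tibble::tibble(
      food_id = id, method = res$method,
      excluded_category = excl, reason = reason,
      depth = res$depth %||% NA_integer_,
      is_plant_containing = flags$is_plant_containing,
      is_animal_containing = flags$is_animal_containing,
      is_entirely_plant = flags$is_entirely_plant,
      is_entirely_animal = flags$is_entirely_animal
    )
  }
  servings <- dplyr::bind_rows(rows)
  outcomes <- dplyr::bind_rows(outcome)
  n_methods <- table(outcomes$method)
  rlang::inform(sprintf(
    "classified %d foods: %s", nrow(outcomes),
    paste(sprintf("%s=%s", names(n_methods), n_methods), collapse = ", ")
  ))
  expanded_database(
    records = db$records, servings = servings,
    provenance = tibble::tibble(food_id = ids, provenance = prov),
    outcomes = outcomes, schema = schema
  )
}

#' Derive plant/animal membership flags from a servings vector
#'
#' A food *contains* a kingdom when any group tagged with that kingdom
#' carries more than `tol` servings per 100 g. It is *entirely* of a
#' kingdom when it contains that kingdom and no group of the opposite
#' kingdom exceeds `tol`. Groups tagged `neither` (added sugars by default)
#' and the water/alcohol side channels never influence the flags.
#'
#' @param servings A [servings_vector()], or a wide servings tibble (as in
#'   `expanded_db$servings`) for row-wise flags.
#' @param schema The governing [food_group_schema()].
#' @param tol Containment threshold in servings per 100 g.
#' @return A tibble with logical columns `is_plant_containing`,
#'   `is_animal_containing`, `is_entirely_plant`, `is_entirely_animal`
#'   (one row per input food).
#' @examples
#' derive_flags(servings_vector(c(vegetables = 1)))$is_entirely_plant
#' @export
derive_flags <- function(servings, schema = food_group_schema(), tol = 1e-9) {
  plant <- group_keys(schema, "plant")
  animal <- group_keys(schema, "animal")
  if (inherits(servings, "servings_vector")) {
    g <- sv_groups(servings)
    m <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  } else if (is.data.frame(servings)) {
    assert_group_keys(intersect(names(servings), group_keys(schema)), schema)
    m <- as.matrix(servings[, group_keys(schema), drop = FALSE])
  } else {
    rlang::abort("`servings` must be a servings_vector or a wide servings table",
      class = "plantserve_validation_error"
    )
  }
  has_plant <- rowSums(m[, plant, drop = FALSE] > tol) > 0
  has_animal <- rowSums(m[, animal, drop = FALSE] > tol) > 0
  tibble::tibble(
    is_plant_containing = has_plant,
    is_animal_containing = has_animal,
    is_entirely_plant = has_plant & !has_animal,
    is_entirely_animal = has_animal & !has_plant
  )
}

#' Draw a reproducible audit sample of foods
#'
#' To mitigate classification error, a fixed fraction of foods is drawn
#' (without replacement) for independent cross-checking by a second
#' assessor. The draw is deterministic given the seed.
#'
#' @param food_ids Character vector of candidate food ids.
#' @param fraction Sampling fraction in `(0, 1]`; default 0.20.
#' @param seed Integer RNG seed.
#' @return Character vector of `round(fraction * length(food_ids))` ids.
#' @examples
#' audit_sample(sprintf("f%02d", 1:10), 0.2, seed = 1)
#' @export
audit_sample <- function(food_ids, fraction = 0.20, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
    fraction <= 0 || fraction > 1) {
    rlang::abort("fraction must lie in (0, 1]", class = "plantserve_validation_error")
  }
  size <- round(fraction * length(food_ids))
  with_local_seed(seed, sample(food_ids, size = size, replace = FALSE))
}

#' @describeIn readers Curated exclusion list: canonical columns `food_id`,
#'   `category` (one of the six exclusion categories of [classify_all()]).
#' @return `read_exclusion_file()`: a tibble of exclusions.
#' @export
read_exclusion_file <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, col_map, required = c("food_id", "category"))
  tibble::as_tibble(df[, c("food_id", "category")])
}

#' Headline summary of an expanded database
#'
#' Computes the whole-database counts used to characterise an expansion:
#' how many foods were classified, by which method, and how plant- and
#' animal-containing products are distributed. "Entirely plant" percentages
#' are reported against two denominators — plant-containing foods and all
#' classified foods — because both readings are in use; the same applies on
#' the animal side.
#'
#' @param db An `expanded_db` with outcomes (from [classify_all()]), or one
#'   whose flags can be derived from its servings table.
#' @param tol Containment threshold, servings per 100 g.
#' @return A one-row tibble of counts and percentages.
#' @export
database_headline_summary <- function(db, tol = 1e-9) {
  stopifnot(inherits(db, "expanded_db"))
  flags <- if (!is.null(db$outcomes)) {
    db$outcomes
  } else {
    dplyr::bind_cols(
      tibble::tibble(food_id = db$servings$food_id, method = db$servings$method),
      derive_flags(db$servings, db$schema, tol = tol)
    )
  }
  n <- nrow(flags)
  classified <- flags$method != "unclassified"
  n_cls <- sum(classified)
  n_plant <- sum(flags$is_plant_containing)
  n_animal <- sum(flags$is_animal_containing)
  n_ent_plant <- sum(flags$is_entirely_plant)
  n_ent_animal <- sum(flags$is_entirely_animal)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    n_foods = n,
    n_classified = n_cls,
    n_unclassified = n - n_cls,
    n_recipe = sum(flags$method == "recipe"),
    n_direct = sum(flags$method == "direct"),
    n_label = sum(flags$method == "label"),
    n_proxy = sum(flags$method == "proxy"),
    n_plant_containing = n_plant,
    pct_plant_containing = pct(n_plant, n_cls),
    n_animal_containing = n_animal,
    pct_animal_containing = pct(n_animal, n_cls),
    pct_entirely_plant_of_plant = pct(n_ent_plant, n_plant),
    pct_entirely_plant_of_classified = pct(n_ent_plant, n_cls),
    pct_entirely_animal_of_animal = pct(n_ent_animal, n_animal),
    pct_entirely_animal_of_classified = pct(n_ent_animal, n_cls)
  )
}
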