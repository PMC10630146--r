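#' Specification for a synthetic miniature food database
#'
#' The generator emulates the four survey source files (details, nutrients,
#' recipes, existing servings) plus label, proxy and exclusion side inputs,
#' with a ground-truth servings vector for every food computed analytically
#' at construction time — independently of the resolution engine — so that
#' every classification route can be verified end to end.
#'
#' @param n_base_per_group Base (single-group) foods generated per food
#'   group; at least 1.
#' @param n_composites Multi-ingredient products to generate.
#' @param max_depth Maximum recipe nesting depth (1-3); depth 1 composites
#'   contain only base foods.
#' @param factor_range Range the per-ingredient weight-change multipliers
#'   are drawn from (default `c(0.5, 1.3)`: up to 50 % moisture loss or
#'   30 % water uptake).
#' @param label_fraction,proxy_fraction Fractions of the composites routed
#'   through the label-based and proxy methods instead of a recipe.
#' @param unclassified_fraction Exclusion-listed foods to add, as a fraction
#'   of `n_composites`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_base_per_group = 2, n_composites = 40, max_depth = 2,
                         factor_range = c(0.5, 1.3),
                         label_fraction = 0.15, proxy_fraction = 0.10,
                         unclassified_fraction = 0.05, seed = 42) {
  fr <- c(label_fraction, proxy_fraction, unclassified_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(c(label_fraction, proxy_fraction)) > 1) {
    rlang::abort("route fractions must lie in [0, 1] and label + proxy must not exceed 1",
      class = "plantserve_validation_error"
    )
  }
  if (!max_depth %in% 1:3) {
    rlang::abort("max_depth must be 1, 2 or 3", class = "plantserve_validation_error")
  }
  if (n_base_per_group < 1) {
    rlang::abort("need at least one base food per group", class = "plantserve_validation_error")
  }
  if (length(factor_range) != 2L || any(factor_range <= 0) || diff(factor_range) < 0) {
    rlang::abort("factor_range must be an increasing positive pair",
      class = "plantserve_validation_error"
    )
  }
  n_label <- floor(label_fraction * n_composites)
  n_proxy <- floor(proxy_fraction * n_composites)
  n_recipe <- n_composites - n_label - n_proxy
  if (n_composites > 0 && n_recipe < max_depth) {
    rlang::abort(
      sprintf(
        "spec leaves %d recipe-routed composites but max_depth %d needs at least that many",
        n_recipe, max_depth
      ),
      class = "plantserve_validation_error"
    )
  }
  structure(
    list(
      n_base_per_group = as.integer(n_base_per_group),
      n_composites = as.integer(n_composites),
      max_depth = as.integer(max_depth),
      factor_range = factor_range,
      label_fraction = label_fraction, proxy_fraction = proxy_fraction,
      unclassified_fraction = unclassified_fraction,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic food database with known ground truth
#'
#' Base foods are drawn across all 23 groups with nutrients made coherent
#' with their intended servings (energy-basis foods carry `600 * S` kJ so
#' that energy/600 recovers S; sodium-basis sauce foods carry `120 * S` mg
#' Na; added-sugars foods carry S grams). Composites sample ingredients and
#' weight-change factors; their ground truth is the flattened analytic
#' formula (adjusted-weight proportions times ingredient truth, summed),
#' applied at construction time, and their nutrients are the
#' proportion-weighted ingredient nutrients so that nesting stays coherent.
#' A subset of composites is rerouted through the label path (declared
#' percentages equal to the recipe proportions) or the proxy path (truth
#' copied from the target); exclusion-listed foods carry a zero truth
#' vector with only water/alcohol content.
#'
#' @param spec A [fixture_spec()].
#' @return A `plantserve_fixture`: list of tibbles `details`, `nutrients`,
#'   `recipes`, `adg`, `labels`, `proxies`, `assignments`, `exclusions`,
#'   the [subgroup_tags()] object `tags`, the wide `truth` table (same
#'   layout as `expanded_db$servings`) and the `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  schema <- food_group_schema()
  rules <- default_serving_rules()
  keys <- group_keys(schema)
  channels <- c(keys, "water", "alcohol")
  zero_truth <- stats::setNames(numeric(length(channels)), channels)

  details <- list()
  nutrients <- list()
  adg <- list()
  assignments <- list()
  tag_ids <- list()
  exclusions <- list()
  recipes <- list()
  labels <- list()
  proxies <- list()
  truth <- list() # food_id -> named numeric over channels
  truth_method <- character()
  depth_of <- integer() # recipe nesting depth per food (0 for non-recipe)

  add_detail <- function(id, name, major, flag) {
    tibble::tibble(
      food_id = id, survey_id = paste0("S", id), name = name,
      description = NA_character_, major_group_code = major,
      discretionary_flag = flag
    )
  }
  flag_pool <- c("core", "discretionary", "unflagged")

  # --- base foods: n per group, nutrients coherent with intended servings
  counter <- 0L
  for (gi in seq_along(keys)) {
    g <- keys[gi]
    major <- sprintf("%02d", 10L + gi)
    for (j in seq_len(spec$n_base_per_group)) {
      counter <- counter + 1L
      id <- sprintf("%s%06d", major, counter)
      s <- runif(1, 0.3, 3)
      water <- runif(1, 2, 70)
      alcohol <- if (runif(1) < 0.05) runif(1, 0.5, 10) else 0
      sugars <- if (g == "added_sugars") s else if (runif(1) < 0.3) runif(1, 0, 20) else 0
      is_sauce <- g %in% c("miscellaneous_plant", "miscellaneous_animal") &&
        (j == spec$n_base_per_group && spec$n_base_per_group >= 2 ||
          spec$n_base_per_group == 1 && g == "miscellaneous_animal")
      rule <- rules[rules$group == g &
        (if (is_sauce) !is.na(rules$subgroup) & rules$subgroup == "stock_sauce" else is.na(rules$subgroup)), ]
      energy <- if (rule$basis == "energy") 600 * s else runif(1, 100, 2000)
      sodium <- if (rule$basis == "sodium") 120 * s else runif(1, 0, 500)
      name <- sprintf("%s %s %d", gsub("_", " ", g), if (is_sauce) "sauce" else "base", j)
      details[[id]] <- add_detail(id, name, major, sample(flag_pool, 1, prob = c(0.5, 0.4, 0.1)))
      nutrients[[id]] <- tibble::tibble(
        food_id = id, energy_kJ_per_100g = energy, sodium_mg_per_100g = sodium,
        added_sugars_g_per_100g = sugars, water_g_per_100g = water,
        alcohol_g_per_100g = alcohol
      )
      tv <- zero_truth
      tv[[g]] <- s
      if (g != "added_sugars") tv[["added_sugars"]] <- sugars
      tv[["water"]] <- water
      tv[["alcohol"]] <- alcohol
      if (rule$basis == "mass") {
        # existing dietary-guideline servings row (direct route, file-backed)
        row <- tibble::tibble(food_id = id)
        row[[g]] <- s
        adg[[id]] <- row
      } else {
        assignments[[id]] <- tibble::tibble(food_id = id, group = g)
        if (is_sauce) tag_ids[[id]] <- tibble::tibble(food_id = id, subgroup = "stock_sauce")
      }
      truth[[id]] <- tv
      truth_method[id] <- "direct"
      depth_of[id] <- 0L
    }
  }

  classified_pool <- names(truth)

  # --- composites: routes fixed up front so pooled truths never go stale
  n_label <- floor(spec$label_fraction * spec$n_composites)
  n_proxy <- floor(spec$proxy_fraction * spec$n_composites)
  n_recipe <- spec$n_composites - n_label - n_proxy
  routes <- c(rep("recipe", n_recipe), rep("label", n_label), rep("proxy", n_proxy))
  # recipe depths cycle 1..max_depth so each level is exercised
  depth_targets <- rep_len(seq_len(spec$max_depth), max(n_recipe, 1L))

  ri <- 0L
  for (ci in seq_len(spec$n_composites)) {
    major <- sample(c("51", "52", "53"), 1)
    id <- sprintf("%s%06d", major, 900000L - ci)
    route <- routes[ci]
    if (route == "proxy") {
      target <- sample(classified_pool, 1)
      proxies[[id]] <- tibble::tibble(product_food_id = id, proxy_food_id = target)
      truth[[id]] <- truth[[target]]
      truth_method[id] <- "proxy"
      depth_of[id] <- 0L
      nutrients[[id]] <- dplyr::mutate(nutrients[[target]], food_id = id)
      details[[id]] <- add_detail(
        id, sprintf("proxied product %d", ci), major,
        sample(flag_pool, 1, prob = c(0.4, 0.5, 0.1))
      )
      next
    }
    if (route == "recipe") {
      ri <- ri + 1L
      d <- depth_targets[ri]
    } else {
      d <- 1L
    }
    k <- sample(2:4, 1)
    pool_below <- names(depth_of)[depth_of < d & names(depth_of) %in% classified_pool]
    ing <- character(0)
    if (d > 1L) {
      anchors <- names(depth_of)[depth_of == d - 1L]
      ing <- sample(anchors, 1)
    }
    remaining <- setdiff(pool_below, ing)
    ing <- c(ing, sample(remaining, min(k - length(ing), length(remaining))))
    w <- runif(length(ing), 10, 200)
    f <- runif(length(ing), spec$factor_range[1], spec$factor_range[2])
    adj <- w * f
    props <- adj / sum(adj)
    tv <- zero_truth
    for (m in seq_along(ing)) tv <- tv + props[m] * truth[[ing[m]]]
    nut <- Reduce(`+`, Map(
      function(iid, p) {
        p * as.numeric(nutrients[[iid]][1, c(
          "energy_kJ_per_100g", "sodium_mg_per_100g",
          "added_sugars_g_per_100g", "water_g_per_100g", "alcohol_g_per_100g"
        )])
      },
      ing, props
    ))
    nutrients[[id]] <- tibble::tibble(
      food_id = id, energy_kJ_per_100g = nut[1], sodium_mg_per_100g = nut[2],
      added_sugars_g_per_100g = nut[3], water_g_per_100g = nut[4],
      alcohol_g_per_100g = nut[5]
    )
    if (route == "recipe") {
      recipes[[id]] <- tibble::tibble(
        product_food_id = id, ingredient_food_id = ing,
        ingredient_weight_g = w, weight_change_factor = f
      )
      truth_method[id] <- "recipe"
      depth_of[id] <- d
    } else {
      # label route: declared percentages equal the recipe proportions
      labels[[id]] <- tibble::tibble(
        product_food_id = id, ingredient_food_id = ing,
        declared_percent = 100 * props
      )
      truth_method[id] <- "label"
      depth_of[id] <- 0L
    }
    truth[[id]] <- tv
    details[[id]] <- add_detail(
      id, sprintf("%s product %d (%d ingredients)", route, ci, length(ing)),
      major, sample(flag_pool, 1, prob = c(0.4, 0.5, 0.1))
    )
    classified_pool <- c(classified_pool, id)
  }

  # --- exclusion-listed foods: zero truth, water/alcohol still recorded
  n_excl <- round(spec$unclassified_fraction * spec$n_composites)
  excl_categories <- c(
    "non_nutritive_sweetener", "human_milk_or_infant_formula",
    "protein_powder_or_supplement", "yeast", "cooking_additive",
    "water_or_alcohol_only"
  )
  for (ei in seq_len(n_excl)) {
    id <- sprintf("98%06d", ei)
    water <- runif(1, 40, 95)
    details[[id]] <- add_detail(id, sprintf("excluded item %d", ei), "98", "unflagged")
    nutrients[[id]] <- tibble::tibble(
      food_id = id, energy_kJ_per_100g = runif(1, 0, 400),
      sodium_mg_per_100g = runif(1, 0, 100), added_sugars_g_per_100g = 0,
      water_g_per_100g = water, alcohol_g_per_100g = 0
    )
    exclusions[[id]] <- tibble::tibble(
      food_id = id,
      category = excl_categories[1L + (ei - 1L) %% length(excl_categories)]
    )
    tv <- zero_truth
    tv[["water"]] <- water
    truth[[id]] <- tv
    truth_method[id] <- "unclassified"
    depth_of[id] <- 0L
  }

  ids <- sort(names(truth))
  truth_tbl <- purrr::map_dfr(ids, function(id) {
    tv <- truth[[id]]
    row <- tibble::as_tibble(as.list(tv[keys]))
    dplyr::bind_cols(
      tibble::tibble(food_id = id, method = truth_method[[id]]),
      row,
      tibble::tibble(
        water_g_per_100g = tv[["water"]],
        alcohol_g_per_100g = tv[["alcohol"]]
      )
    )
  })

  bind_or_empty <- function(lst, proto) {
    if (length(lst)) dplyr::bind_rows(lst) else proto
  }
  adg_tbl <- bind_or_empty(adg, tibble::tibble(food_id = character()))
  for (cn in keys) {
    if (!cn %in% names(adg_tbl)) adg_tbl[[cn]] <- numeric(nrow(adg_tbl))
    adg_tbl[[cn]][is.na(adg_tbl[[cn]])] <- 0
  }
  declared <- keys[vapply(keys, function(cn) any(adg_tbl[[cn]] > 0), logical(1))]
  adg_tbl <- adg_tbl[, c("food_id", keys)]
  attr(adg_tbl, "declared_groups") <- declared

  structure(
    list(
      details = dplyr::bind_rows(details),
      nutrients = dplyr::bind_rows(nutrients),
      recipes = bind_or_empty(recipes, tibble::tibble(
        product_food_id = character(), ingredient_food_id = character(),
        ingredient_weight_g = numeric(), weight_change_factor = numeric()
      )),
      adg = adg_tbl,
      labels = bind_or_empty(labels, tibble::tibble(
        product_food_id = character(), ingredient_food_id = character(),
        declared_percent = numeric()
      )),
      proxies = bind_or_empty(proxies, tibble::tibble(
        product_food_id = character(), proxy_food_id = character()
      )),
      assignments = bind_or_empty(assignments, tibble::tibble(
        food_id = character(), group = character()
      )),
      exclusions = bind_or_empty(exclusions, tibble::tibble(
        food_id = character(), category = character()
      )),
      tags = subgroup_tags(ids = bind_or_empty(tag_ids, NULL)),
      truth = truth_tbl,
      schema = schema,
      spec = spec
    ),
    class = "plantserve_fixture"
  )
}

#' @export
print.plantserve_fixture <- function(x, ...) {
  cat(sprintf(
    "<plantserve_fixture> %d foods (%d recipe edges, %d labels, %d proxies, %d excluded), seed %d\n",
    nrow(x$details), nrow(x$recipes), nrow(x$labels), nrow(x$proxies),
    nrow(x$exclusions), x$spec$seed
  ))
  invisible(x)
}

#' Assemble and classify a generated fixture
#'
#' `fixture_database()` wraps the fixture tables into a `food_db`;
#' `classify_fixture()` additionally runs [classify_all()] with the
#' fixture's side inputs, returning the `expanded_db` to compare against
#' `fixture$truth`.
#'
#' @param fixture A `plantserve_fixture` from [generate_fixture()].
#' @return A `food_db`, or an `expanded_db` respectively.
#' @export
fixture_database <- function(fixture) {
  stopifnot(inherits(fixture, "plantserve_fixture"))
  food_database(fixture$details, fixture$nutrients, fixture$recipes,
    fixture$adg,
    schema = fixture$schema
  )
}

#' @rdname fixture_database
#' @export
classify_fixture <- function(fixture) {
  classify_all(
    fixture_database(fixture),
    assignments = fixture$assignments, labels = fixture$labels,
    proxies = fixture$proxies, exclusions = fixture$exclusions,
    tags = fixture$tags
  )
}

#' Write a fixture to disk as the four source CSVs plus side inputs
#'
#' Files written: `details.csv`, `nutrients.csv`, `recipes.csv`,
#' `adg_servings.csv`, `labels.csv`, `proxies.csv`, `assignments.csv`,
#' `exclusions.csv`, `truth.csv` and a `config.yaml` loadable by
#' [load_food_database()].
#'
#' @param fixture A `plantserve_fixture`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "plantserve_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    details = fixture$details, nutrients = fixture$nutrients,
    recipes = fixture$recipes, adg_servings = fixture$adg,
    labels = fixture$labels, proxies = fixture$proxies,
    assignments = fixture$assignments, exclusions = fixture$exclusions,
    truth = fixture$truth
  )
  for (nm in names(files)) {
    readr::write_csv(files[[nm]], file.path(dir, paste0(nm, ".csv")), progress = FALSE)
  }
  yaml::write_yaml(
    list(
      details = "details.csv", nutrients = "nutrients.csv",
      recipes = "recipes.csv", adg_servings = "adg_servings.csv",
      factor_encoding = "multiplier"
    ),
    file.path(dir, "config.yaml")
  )
  invisible(dir)
}

#' The in-package worked mini-example
#'
#' A three-food miniature database anchoring the serving bases to
#' hand-checkable numbers: a gravy-style sauce with 295 mg Na/100 g (sodium
#' basis: 295/120 = 2.458333 servings/100 g), a butter-like fat at
#' 600 kJ/100 g (energy basis: exactly 1 serving/100 g) and a
#' hollandaise-style sauce holding 1.5 servings/100 g, of which a 20 g
#' intake yields 0.3 servings.
#'
#' @return A list: `db` (a `food_db`), `assignments`, `tags`, `intakes`
#'   (one 20 g consumption event) and `expected` (named list of the three
#'   hand-computed values).
#' @export
make_worked_example <- function() {
  schema <- food_group_schema()
  details <- tibble::tibble(
    food_id = c("27000001", "14000002", "27000003"),
    survey_id = paste0("S", 1:3),
    name = c(
      "Gravy, commercial, prepared", "Butter-like spread, plain",
      "Hollandaise-style sauce"
    ),
    description = NA_character_,
    major_group_code = c("27", "14", "27"),
    discretionary_flag = c("discretionary", "discretionary", "discretionary")
  )
  nutrients <- tibble::tibble(
    food_id = details$food_id,
    energy_kJ_per_100g = c(350, 600, 1900),
    sodium_mg_per_100g = c(295, 650, 450),
    added_sugars_g_per_100g = 0,
    water_g_per_100g = c(85, 16, 40),
    alcohol_g_per_100g = 0
  )
  adg <- tibble::tibble(food_id = "27000003")
  adg[["miscellaneous_animal"]] <- 1.5
  for (cn in setdiff(group_keys(schema), "miscellaneous_animal")) adg[[cn]] <- 0
  adg <- adg[, c("food_id", group_keys(schema))]
  attr(adg, "declared_groups") <- "miscellaneous_animal"
  assignments <- tibble::tibble(
    food_id = c("27000001", "14000002"),
    group = c("miscellaneous_animal", "animal_fats")
  )
  tags <- subgroup_tags(patterns = tibble::tibble(
    pattern = "gravy|stock|sauce", subgroup = "stock_sauce"
  ))
  # the hollandaise name also matches the sauce pattern, but its existing
  # servings row wins, so the tag is never consulted for it
  list(
    db = food_database(details, nutrients, schema = schema, adg = adg),
    assignments = assignments,
    tags = tags,
    intakes = tibble::tibble(person_id = "p1", food_id = "27000003", amount_g = 20),
    expected = list(
      gravy_servings_per_100g = 295 / 120,
      fat_servings_per_100g = 1,
      hollandaise_20g_servings = 1.5 / 100 * 20
    )
  )
}
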