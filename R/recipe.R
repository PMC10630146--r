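#' Recipe-based disaggregation primitives
#'
#' A multi-ingredient product or mixed dish is resolved into food-group
#' servings per 100 g in four steps:
#'
#' 1. **Final weight**: the sum of ingoing ingredient weights times the
#'    product-level yield factor (moisture loss during cooking gives a
#'    factor below 1, water uptake above 1).
#' 2. **Ingredient proportions**: each ingredient's ingoing weight times its
#'    own weight-change factor, divided by the sum of those adjusted
#'    weights. The factor converts the raw/ingoing weight to the
#'    cooked-equivalent state in which serving sizes are defined.
#' 3. **Propagation**: the ingredient's servings per 100 g (in its
#'    cooked-equivalent state) times its proportion gives its contribution
#'    per 100 g of product.
#' 4. **Summation**: contributions are summed per food group, water and
#'    alcohol included.
#'
#' All four steps are linear, so scaling every ingredient weight by a common
#' factor leaves per-100 g servings unchanged.
#'
#' @param weights Positive ingoing ingredient weights, g.
#' @param product_factor Product-level weight-change (yield) multiplier.
#' @return `final_weight()`: the final product weight in grams.
#' @examples
#' final_weight(c(60, 40), 1.25) # boiled grain taking up water: 125 g
#' ingredient_proportions(c(50, 50), c(2, 1)) # c(2/3, 1/3)
#' @export
final_weight <- function(weights, product_factor = 1) {
  if (!length(weights)) {
    rlang::abort("a recipe needs at least one ingredient", class = "plantserve_resolution_error")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    rlang::abort("ingredient weights must be positive", class = "plantserve_validation_error")
  }
  if (!is.finite(product_factor) || product_factor <= 0) {
    rlang::abort("product-level weight factor must be positive", class = "plantserve_validation_error")
  }
  sum(weights) * product_factor
}

#' @rdname final_weight
#' @param factors Per-ingredient weight-change multipliers (same length as
#'   `weights`, recycled if length 1).
#' @return `ingredient_proportions()`: proportions summing to 1.
#' @export
ingredient_proportions <- function(weights, factors = 1) {
  if (!length(weights)) {
    rlang::abort("a recipe needs at least one ingredient", class = "plantserve_resolution_error")
  }
  factors <- rep_len(factors, length(weights))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    rlang::abort("ingredient weights must be positive", class = "plantserve_validation_error")
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    rlang::abort("weight-change factors must be positive", class = "plantserve_validation_error")
  }
  adjusted <- weights * factors
  total <- sum(adjusted)
  if (total <= 0) {
    rlang::abort("adjusted ingredient weights sum to zero", class = "plantserve_resolution_error")
  }
  adjusted / total
}

#' @rdname final_weight
#' @param servings A [servings_vector()] of the ingredient (per 100 g of the
#'   ingredient, cooked-equivalent state).
#' @param proportion The ingredient's proportion of the product, in `[0, 1]`.
#' @return `propagate_servings()`: the ingredient's contribution per 100 g
#'   of product.
#' @export
propagate_servings <- function(servings, proportion) {
  stopifnot(inherits(servings, "servings_vector"))
  if (!is.finite(proportion) || proportion < 0 || proportion > 1 + 1e-12) {
    rlang::abort("proportion must lie in [0, 1]", class = "plantserve_validation_error")
  }
  sv_rescale(servings, proportion)
}

#' @rdname final_weight
#' @param contributions List of [servings_vector()]s sharing one schema.
#' @param method Method tag for the summed vector (default `"recipe"`).
#' @return `sum_product_servings()`: the per-group sum as a
#'   [servings_vector()].
#' @export
sum_product_servings <- function(contributions, method = "recipe") {
  if (!length(contributions)) {
    rlang::abort("nothing to sum", class = "plantserve_resolution_error")
  }
  sv_sum(contributions, method = method)
}

#' Resolve one food into food-group servings per 100 g
#'
#' Depth-first resolution of the recipe graph with memoisation: base foods
#' are classified directly (existing servings, or a serving rule applied to
#' a single-group assignment); composite ingredients are resolved
#' recursively before their servings are propagated. Foods with neither a
#' direct classification nor a recipe fall back to label data, then to a
#' proxy product, when those are supplied. Resolution order is deterministic
#' (ingredients visited in sorted food-id order).
#'
#' @param food_id Food to resolve.
#' @param db A `food_db` from [food_database()].
#' @param rules A `serving_rules` table.
#' @param assignments Optional tibble `food_id`, `group` assigning
#'   single-group foods that lack an existing servings row; their servings
#'   are computed from the matching serving rule.
#' @param labels Optional label declarations (see [read_label_file()]).
#' @param proxies Optional proxy table `product_food_id`, `proxy_food_id`.
#' @param exclusions Optional exclusion list `food_id`, `category`; an
#'   excluded food (water, salt, yeast, ...) resolves to a zero-group
#'   vector carrying only its water/alcohol content, so recipes that use it
#'   as an ingredient still resolve.
#' @param tags Optional [subgroup_tags()].
#' @return A `resolved_product` list: `food_id`, `servings`
#'   ([servings_vector()]), `method`, `depth` (0 for base foods),
#'   `final_weight_g` and `proportions` (both `NULL` for non-recipe
#'   methods).
#' @examples
#' # see the package vignette for an end-to-end worked recipe
#' @export
resolve_food <- function(food_id, db, rules = default_serving_rules(),
                         assignments = NULL, labels = NULL, proxies = NULL,
                         exclusions = NULL, tags = NULL) {
  ctx <- resolution_context(db, rules, assignments, labels, proxies, tags, exclusions)
  resolve_one(food_id, ctx, stack = character(), allow_proxy = TRUE)
}

# internal: shared state for a resolution run
resolution_context <- function(db, rules, assignments, labels, proxies, tags,
                               exclusions = NULL) {
  stopifnot(inherits(db, "food_db"))
  rules <- if (inherits(rules, "serving_rules")) rules else serving_rules(rules)
  list(
    db = db, rules = rules, schema = db$schema,
    assignments = if (!is.null(assignments)) tibble::as_tibble(assignments),
    labels = if (!is.null(labels)) tibble::as_tibble(labels),
    proxies = if (!is.null(proxies)) tibble::as_tibble(proxies),
    exclusions = if (!is.null(exclusions)) tibble::as_tibble(exclusions),
    tags = tags,
    memo = new.env(parent = emptyenv())
  )
}

# internal: the record (as a list) for one food id, or NULL
food_record <- function(ctx, food_id) {
  i <- match(food_id, ctx$db$records$food_id)
  if (is.na(i)) {
    return(NULL)
  }
  as.list(ctx$db$records[i, ])
}

# internal: direct classification of a base food, or NULL if no route.
# Existing (dietary-guideline) servings win; otherwise a single-group
# assignment is converted through its serving rule. Water and alcohol come
# from the nutrient record; added sugars are filled from the nutrient file
# whenever the servings source does not itself declare them.
direct_servings <- function(ctx, food_id) {
  rec <- food_record(ctx, food_id)
  schema <- ctx$schema
  i <- match(food_id, ctx$db$adg$food_id)
  if (!is.na(i)) {
    row <- ctx$db$adg[i, ]
    keys <- group_keys(schema)
    vals <- stats::setNames(as.numeric(row[1L, keys]), keys)
    declared <- attr(ctx$db$adg, "declared_groups") %||% keys
    if (!"added_sugars" %in% declared && "added_sugars" %in% keys && !is.null(rec)) {
      vals[["added_sugars"]] <- added_sugars_servings(rec$added_sugars_g_per_100g %||% 0)
    }
    return(servings_vector(vals,
      schema = schema,
      water = rec$water_g_per_100g %||% 0,
      alcohol = rec$alcohol_g_per_100g %||% 0,
      method = "direct"
    ))
  }
  if (!is.null(ctx$assignments)) {
    j <- match(food_id, ctx$assignments$food_id)
    if (!is.na(j)) {
      if (is.null(rec)) {
        rlang::abort(sprintf("assigned food %s has no food record", food_id),
          class = "plantserve_integrity_error"
        )
      }
      grp <- ctx$assignments$group[j]
      assert_group_keys(grp, schema, what = "assigned group")
      rule <- select_rule(rec, grp, ctx$rules, ctx$tags)
      vals <- stats::setNames(base_servings_value(rec, rule), grp)
      if (grp != "added_sugars" && "added_sugars" %in% group_keys(schema)) {
        vals <- c(vals, added_sugars = added_sugars_servings(rec$added_sugars_g_per_100g %||% 0))
      }
      return(servings_vector(vals,
        schema = schema,
        water = rec$water_g_per_100g, alcohol = rec$alcohol_g_per_100g,
        method = "direct"
      ))
    }
  }
  NULL
}

# internal: recursive resolver with memoisation and cycle detection
resolve_one <- function(food_id, ctx, stack, allow_proxy = TRUE) {
  if (!is.null(ctx$memo[[food_id]])) {
    return(ctx$memo[[food_id]])
  }
  if (food_id %in% stack) {
    cyc <- c(stack[which(stack == food_id):length(stack)], food_id)
    rlang::abort(
      sprintf("recipe cycle detected: %s", paste(cyc, collapse = " -> ")),
      class = "plantserve_cycle_error"
    )
  }
  res <- NULL
  if (!is.null(ctx$exclusions) && food_id %in% ctx$exclusions$food_id) {
    rec <- food_record(ctx, food_id)
    v <- servings_vector(NULL,
      schema = ctx$schema,
      water = rec$water_g_per_100g %||% 0,
      alcohol = rec$alcohol_g_per_100g %||% 0,
      method = "unclassified"
    )
    res <- list(
      food_id = food_id, servings = v, method = "unclassified",
      depth = 0L, final_weight_g = NULL, proportions = NULL
    )
  }
  direct <- if (is.null(res)) direct_servings(ctx, food_id)
  if (!is.null(direct)) {
    res <- list(
      food_id = food_id, servings = direct, method = "direct",
      depth = 0L, final_weight_g = NULL, proportions = NULL
    )
  }
  if (is.null(res)) {
    edges <- ctx$db$recipes[ctx$db$recipes$product_food_id == food_id, , drop = FALSE]
    if (nrow(edges)) {
      edges <- edges[order(edges$ingredient_food_id), , drop = FALSE]
      children <- lapply(
        edges$ingredient_food_id, resolve_one,
        ctx = ctx, stack = c(stack, food_id), allow_proxy = allow_proxy
      )
      props <- ingredient_proportions(edges$ingredient_weight_g, edges$weight_change_factor)
      contribs <- Map(function(ch, p) propagate_servings(ch$servings, p), children, props)
      res <- list(
        food_id = food_id,
        servings = sum_product_servings(contribs, method = "recipe"),
        method = "recipe",
        depth = 1L + max(vapply(children, `[[`, integer(1), "depth")),
        final_weight_g = final_weight(edges$ingredient_weight_g * edges$weight_change_factor),
        proportions = stats::setNames(props, edges$ingredient_food_id)
      )
    }
  }
  if (is.null(res) && !is.null(ctx$labels)) {
    decl <- ctx$labels[ctx$labels$product_food_id == food_id, , drop = FALSE]
    if (nrow(decl)) {
      v <- label_servings(ctx, food_id, decl, stack)
      res <- list(
        food_id = food_id, servings = v, method = "label",
        depth = 0L, final_weight_g = NULL, proportions = NULL
      )
    }
  }
  if (is.null(res) && allow_proxy && !is.null(ctx$proxies)) {
    j <- match(food_id, ctx$proxies$product_food_id)
    if (!is.na(j)) {
      v <- proxy_servings(ctx, food_id, ctx$proxies$proxy_food_id[j], stack)
      res <- list(
        food_id = food_id, servings = v, method = "proxy",
        depth = 0L, final_weight_g = NULL, proportions = NULL
      )
    }
  }
  if (is.null(res)) {
    rlang::abort(
      sprintf("food %s cannot be resolved: no direct servings, recipe, label or proxy", food_id),
      class = "plantserve_unresolved_error"
    )
  }
  class(res) <- "resolved_product"
  ctx$memo[[food_id]] <- res
  res
}

#' @export
print.resolved_product <- function(x, ...) {
  cat(sprintf("<resolved_product %s method=%s depth=%d>\n", x$food_id, x$method, x$depth))
  print(x$servings)
  invisible(x)
}
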