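#' Label-based classification
#'
#' Commercial products without a survey recipe can often be classified from
#' their packaging: the label declares the percentage of a characterising
#' ingredient (e.g. "10 % macadamias"). Each declared, not-yet-classified
#' ingredient contributes `declared_percent / 100` times its own servings
#' per 100 g; contributions from ingredients that already carry a
#' classification are merged additively through the same formula. Declared
#' percentages are taken per 100 g of final product, exactly as printed on
#' the label, so no weight-change factor applies on this path.
#'
#' If the declared percentages sum to less than 100, the undeclared
#' remainder contributes zero servings and is reported; it is never
#' renormalised away, because scaling up would fabricate content the label
#' does not claim. Sums above 100 are a validation error.
#'
#' Water and alcohol are not label-declared, so the product's own nutrient
#' record supplies the two side channels.
#'
#' @param product_food_id The product being classified.
#' @param labels Label declarations: tibble `product_food_id`,
#'   `ingredient_food_id`, `declared_percent` (see [read_label_file()]).
#' @param db A `food_db`.
#' @param rules,assignments,tags As in [resolve_food()]; used to classify
#'   the declared ingredients.
#' @return A [servings_vector()] with method `"label"`.
#' @export
apply_label <- function(product_food_id, labels, db,
                        rules = default_serving_rules(),
                        assignments = NULL, tags = NULL) {
  ctx <- resolution_context(db, rules, assignments, labels, NULL, tags)
  decl <- ctx$labels[ctx$labels$product_food_id == product_food_id, , drop = FALSE]
  if (!nrow(decl)) {
    rlang::abort(sprintf("no label declaration for product %s", product_food_id),
      class = "plantserve_unresolved_error"
    )
  }
  label_servings(ctx, product_food_id, decl, stack = character())
}

# internal: servings of one labelled product from its declaration rows
label_servings <- function(ctx, food_id, decl, stack) {
  pct <- decl$declared_percent
  if (any(!is.finite(pct)) || any(pct <= 0) || any(pct > 100)) {
    rlang::abort(
      sprintf("declared percentages for %s must lie in (0, 100]", food_id),
      class = "plantserve_validation_error"
    )
  }
  if (sum(pct) > 100 + 1e-6) {
    rlang::abort(
      sprintf("declared percentages for %s sum to %.4f > 100", food_id, sum(pct)),
      class = "plantserve_validation_error"
    )
  }
  if (sum(pct) < 100 - 1e-6) {
    rlang::inform(
      sprintf(
        "label for %s declares only %.4g %% of the product; remainder contributes no servings",
        food_id, sum(pct)
      )
    )
  }
  ingredients <- lapply(
    decl$ingredient_food_id,
    function(id) {
      if (identical(id, food_id)) {
        rlang::abort(sprintf("label for %s declares the product as its own ingredient", food_id),
          class = "plantserve_integrity_error"
        )
      }
      tryCatch(
        resolve_one(id, ctx, stack = c(stack, food_id), allow_proxy = TRUE),
        plantserve_unresolved_error = function(e) {
          rlang::abort(
            sprintf("label ingredient %s of product %s cannot be classified", id, food_id),
            class = "plantserve_unresolved_error", parent = e
          )
        }
      )
    }
  )
  contribs <- Map(
    function(ing, p) sv_rescale(ing$servings, p / 100, method = "label"),
    ingredients, pct
  )
  v <- sv_sum(contribs, method = "label")
  rec <- food_record(ctx, food_id)
  if (!is.null(rec)) {
    vals <- sv_groups(v)
    v <- servings_vector(vals,
      schema = ctx$schema,
      water = rec$water_g_per_100g %||% 0,
      alcohol = rec$alcohol_g_per_100g %||% 0, method = "label"
    )
  }
  v
}

#' Proxy-product classification
#'
#' When neither a recipe nor usable label data exists, a comparable
#' already-classified product (or a product built from a standard published
#' recipe entered as such) stands in: its full servings vector is copied,
#' the method is tagged `"proxy"` and the provenance records the proxy id.
#' The proxy must itself be classified by a non-proxy route; chains of
#' proxies are rejected.
#'
#' @param product_food_id The product being classified.
#' @param proxy_food_id The classified stand-in product.
#' @param db A `food_db`.
#' @param rules,assignments,labels,tags As in [resolve_food()].
#' @return A [servings_vector()] with method `"proxy"`.
#' @export
apply_proxy <- function(product_food_id, proxy_food_id, db,
                        rules = default_serving_rules(),
                        assignments = NULL, labels = NULL, tags = NULL) {
  ctx <- resolution_context(db, rules, assignments, labels, NULL, tags)
  proxy_servings(ctx, product_food_id, proxy_food_id, stack = character())
}

# internal: copy the proxy target's vector (target resolved without
# permitting a further proxy hop)
proxy_servings <- function(ctx, food_id, proxy_id, stack) {
  # a product may serve as its own reference (proxy_id == food_id); it is
  # then resolved directly rather than pushed onto the stack as a child
  target <- tryCatch(
    resolve_one(proxy_id, ctx,
      stack = if (identical(proxy_id, food_id)) stack else c(stack, food_id),
      allow_proxy = FALSE
    ),
    plantserve_unresolved_error = function(e) {
      rlang::abort(
        sprintf(
          "proxy %s for product %s is not classified by a non-proxy method (proxy chains are rejected)",
          proxy_id, food_id
        ),
        class = "plantserve_unresolved_error", parent = e
      )
    }
  )
  g <- sv_groups(target$servings)
  if (all(g <= 1e-9)) {
    rlang::warn(sprintf("proxy %s carries no food-group content; product %s inherits a zero vector", proxy_id, food_id))
  }
  new_servings_vector(
    stats::setNames(as.numeric(target$servings), names(target$servings)),
    method = "proxy"
  )
}

#' Sodium-anchored estimate for salty miscellaneous products
#'
#' Label data often reports sodium per 100 g; for salty products that fit
#' the miscellaneous groups (stocks, sauces, gravies), servings are
#' estimated as sodium divided by the 120 mg Na/100 g low-salt threshold.
#' This simply delegates to [servings_from_sodium()].
#'
#' @param sodium_mg Sodium content from the label, mg per 100 g of product.
#' @return Servings per 100 g for the applicable miscellaneous group.
#' @examples
#' sodium_based_label_estimate(295) # 2.458333
#' @export
sodium_based_label_estimate <- function(sodium_mg) {
  servings_from_sodium(sodium_mg)
}

#' @describeIn readers Label declarations: canonical columns
#'   `product_food_id`, `ingredient_food_id`, `declared_percent`
#'   (in `(0, 100]`; per-product sums above 100 are rejected).
#' @return `read_label_file()`: a tibble of label declarations.
#' @export
read_label_file <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, col_map,
    required = c("product_food_id", "ingredient_food_id", "declared_percent")
  )
  df$declared_percent <- parse_decimal(df$declared_percent)
  if (anyNA(df$declared_percent) || any(df$declared_percent <= 0) || any(df$declared_percent > 100)) {
    rlang::abort("declared_percent must parse and lie in (0, 100]",
      class = "plantserve_validation_error"
    )
  }
  sums <- tapply(df$declared_percent, df$product_food_id, sum)
  over <- names(sums)[sums > 100 + 1e-6]
  if (length(over)) {
    rlang::abort(
      sprintf("label percentages exceed 100 %% for: %s", paste(head(over, 5L), collapse = ", ")),
      class = "plantserve_validation_error"
    )
  }
  tibble::as_tibble(df[, c("product_food_id", "ingredient_food_id", "declared_percent")])
}

#' @describeIn readers Proxy assignments: canonical columns
#'   `product_food_id`, `proxy_food_id`; one proxy per product.
#' @return `read_proxy_file()`: a tibble of proxy assignments.
#' @export
read_proxy_file <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, col_map, required = c("product_food_id", "proxy_food_id"))
  if (anyDuplicated(df$product_food_id)) {
    rlang::abort("each product may have only one proxy", class = "plantserve_integrity_error")
  }
  tibble::as_tibble(df[, c("product_food_id", "proxy_food_id")])
}
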