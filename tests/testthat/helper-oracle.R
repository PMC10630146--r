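# Independent brute-force oracle for recipe resolution: fully flatten the
# recipe tree to leaf foods (product of adjusted-weight proportions along
# every path), then combine the leaves' servings once. No memoisation, no
# engine code paths.

oracle_leaf_proportions <- function(food_id, recipes, scale = 1) {
  edges <- recipes[recipes$product_food_id == food_id, , drop = FALSE]
  if (!nrow(edges)) {
    return(stats::setNames(scale, food_id))
  }
  adj <- edges$ingredient_weight_g * edges$weight_change_factor
  props <- adj / sum(adj)
  leaves <- numeric(0)
  for (i in seq_len(nrow(edges))) {
    leaves <- c(
      leaves,
      oracle_leaf_proportions(edges$ingredient_food_id[i], recipes, scale * props[i])
    )
  }
  tapply(leaves, names(leaves), sum)
}

# base_vectors: named list food_id -> named numeric over groups + water/alcohol
oracle_servings <- function(food_id, recipes, base_vectors) {
  lp <- oracle_leaf_proportions(food_id, recipes)
  out <- base_vectors[[1]] * 0
  for (leaf in names(lp)) {
    out <- out + lp[[leaf]] * base_vectors[[leaf]]
  }
  out
}

# the wide truth/servings row of one food as a plain named numeric
wide_row_vector <- function(tbl, food_id, schema = food_group_schema()) {
  keys <- c(group_keys(schema), "water_g_per_100g", "alcohol_g_per_100g")
  i <- match(food_id, tbl$food_id)
  stats::setNames(as.numeric(tbl[i, keys]), keys)
}
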