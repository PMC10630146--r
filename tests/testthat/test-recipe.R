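test_that("final weight applies the product-level yield factor to summed ingredients", {
  expect_identical(final_weight(c(50, 50), 1), 100)
  expect_identical(final_weight(100, 0.8), 80) # moisture loss
  expect_identical(final_weight(c(60, 40), 1.25), 125) # water uptake on boiling
  expect_error(final_weight(numeric(0)), class = "plantserve_resolution_error")
  expect_error(final_weight(c(50, -1)), class = "plantserve_validation_error")
  expect_error(final_weight(50, 0), class = "plantserve_validation_error")
})

test_that("ingredient proportions use weight-adjusted shares summing to one", {
  expect_equal(ingredient_proportions(c(50, 50)), c(0.5, 0.5))
  expect_equal(ingredient_proportions(c(50, 50), c(2, 1)), c(2 / 3, 1 / 3))
  expect_identical(ingredient_proportions(80), 1)
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- ingredient_proportions(runif(k, 1, 300), runif(k, 0.4, 1.6))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
  expect_error(ingredient_proportions(c(1, 0)), class = "plantserve_validation_error")
})

test_that("propagation scales a vector and summation merges per group", {
  v <- servings_vector(c(whole_grains = 2), water = 50, method = "direct")
  expect_equal(as.numeric(propagate_servings(v, 1)), as.numeric(v))
  expect_true(all(as.numeric(propagate_servings(v, 0)) == 0))
  half <- propagate_servings(v, 0.5)
  expect_identical(unname(sv_groups(half)["whole_grains"]), 1)
  expect_identical(unclass(half)[["water"]], 25)
  expect_error(propagate_servings(v, 1.5), class = "plantserve_validation_error")

  a <- servings_vector(c(vegetables = 1), method = "direct")
  b <- servings_vector(c(animal_fats = 0.5), method = "direct")
  s <- sum_product_servings(list(a, b))
  expect_identical(sv_method(s), "recipe")
  expect_identical(unname(sv_groups(s)[c("vegetables", "animal_fats")]), c(1, 0.5))
  s2 <- sum_product_servings(list(
    servings_vector(c(vegetables = 0.4)), servings_vector(c(vegetables = 0.6))
  ))
  expect_identical(unname(sv_groups(s2)["vegetables"]), 1)
})

test_that("a base food resolves to its direct classification", {
  tt <- tiny_db()
  res <- resolve_food("11000001", tt$db,
    assignments = tt$assignments,
    exclusions = tt$exclusions, tags = tt$tags
  )
  expect_identical(res$method, "direct")
  expect_identical(res$depth, 0L)
  expect_identical(unname(sv_groups(res$servings)["vegetables"]), 1.2)
  expect_identical(unclass(res$servings)[["water"]], 90)
})

test_that("nested recipes equal the hand-flattened oracle", {
  tt <- tiny_db()
  base <- tiny_base_vectors()
  for (id in c("51000001", "52000001")) {
    res <- resolve_food(id, tt$db,
      assignments = tt$assignments,
      exclusions = tt$exclusions, tags = tt$tags
    )
    expect_identical(res$method, "recipe")
    want <- oracle_servings(id, tt$recipes, base)
    got <- c(sv_groups(res$servings),
      water_g_per_100g = unclass(res$servings)[["water"]],
      alcohol_g_per_100g = unclass(res$servings)[["alcohol"]]
    )
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
  # the two-level dish sits at depth 2 and its proportions sum to one
  res <- resolve_food("52000001", tt$db,
    assignments = tt$assignments,
    exclusions = tt$exclusions, tags = tt$tags
  )
  expect_identical(res$depth, 2L)
  expect_equal(sum(res$proportions), 1, tolerance = 1e-12)
  # hand check: adjusted weights 100*0.9, 60*2.5, 40*1 -> 90/280, 150/280, 40/280
  expect_equal(unname(res$proportions[c("51000001", "12000001", "98000001")]),
    c(90, 150, 40) / 280,
    tolerance = 1e-12
  )
})

test_that("recipe cycles raise a cycle error naming the loop", {
  tt <- tiny_tables()
  cyc <- dplyr::bind_rows(
    tt$recipes,
    tibble::tibble(
      product_food_id = c("55000001", "55000002"),
      ingredient_food_id = c("55000002", "55000001"),
      ingredient_weight_g = c(10, 10), weight_change_factor = c(1, 1)
    )
  )
  det <- dplyr::bind_rows(
    tt$details,
    tibble::tibble(
      food_id = c("55000001", "55000002"), survey_id = c("x", "y"),
      name = c("Loop A", "Loop B"), description = NA_character_,
      major_group_code = "55", discretionary_flag = "unflagged"
    )
  )
  db <- food_database(det, tt$nutrients, cyc, tt$adg, schema = tt$schema)
  expect_error(
    resolve_food("55000001", db, assignments = tt$assignments, exclusions = tt$exclusions),
    regexp = "55000001 -> 55000002 -> 55000001", class = "plantserve_cycle_error"
  )
})

test_that("unresolvable foods raise a typed error instead of a silent zero", {
  tt <- tiny_db()
  expect_error(
    resolve_food("53000001", tt$db, assignments = tt$assignments), # label-only food, no labels given
    class = "plantserve_unresolved_error"
  )
})

test_that("doubling every ingredient weight leaves per-100 g servings unchanged", {
  tt <- tiny_tables()
  doubled <- tt$recipes
  doubled$ingredient_weight_g <- doubled$ingredient_weight_g * 2
  db1 <- tiny_db()$db
  db2 <- food_database(tt$details, tt$nutrients, doubled, tt$adg, schema = tt$schema)
  for (id in c("51000001", "52000001")) {
    r1 <- resolve_food(id, db1,
      assignments = tt$assignments,
      exclusions = tt$exclusions, tags = tt$tags
    )
    r2 <- resolve_food(id, db2,
      assignments = tt$assignments,
      exclusions = tt$exclusions, tags = tt$tags
    )
    expect_equal(as.numeric(r1$servings), as.numeric(r2$servings), tolerance = 1e-12)
  }
})

test_that("adding water strictly dilutes every non-water group", {
  tt <- tiny_tables()
  watered <- dplyr::bind_rows(
    tt$recipes,
    tibble::tibble(
      product_food_id = "51000001", ingredient_food_id = "98000001",
      ingredient_weight_g = 30, weight_change_factor = 1
    )
  )
  db1 <- tiny_db()$db
  db2 <- food_database(tt$details, tt$nutrients, watered, tt$adg, schema = tt$schema)
  r1 <- resolve_food("51000001", db1,
    assignments = tt$assignments,
    exclusions = tt$exclusions, tags = tt$tags
  )
  r2 <- resolve_food("51000001", db2,
    assignments = tt$assignments,
    exclusions = tt$exclusions, tags = tt$tags
  )
  g1 <- sv_groups(r1$servings)
  g2 <- sv_groups(r2$servings)
  nz <- names(g1)[g1 > 0]
  expect_true(all(g2[nz] < g1[nz]))
  expect_gt(unclass(r2$servings)[["water"]], unclass(r1$servings)[["water"]])
})

test_that("raising one ingredient's weight raises its groups and renormalises the rest down", {
  tt <- tiny_tables()
  more_veg <- tt$recipes
  i <- more_veg$product_food_id == "51000001" & more_veg$ingredient_food_id == "11000001"
  more_veg$ingredient_weight_g[i] <- 80 # was 50
  db1 <- tiny_db()$db
  db2 <- food_database(tt$details, tt$nutrients, more_veg, tt$adg, schema = tt$schema)
  args <- list(assignments = tt$assignments, exclusions = tt$exclusions, tags = tt$tags)
  r1 <- do.call(resolve_food, c(list("51000001", db1), args))
  r2 <- do.call(resolve_food, c(list("51000001", db2), args))
  # the increased ingredient's group goes up per 100 g of product...
  expect_gt(sv_groups(r2$servings)["vegetables"], sv_groups(r1$servings)["vegetables"])
  # ...while the untouched ingredient's group is renormalised downwards
  expect_lt(sv_groups(r2$servings)["animal_fats"], sv_groups(r1$servings)["animal_fats"])
})
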