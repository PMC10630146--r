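test_that("a single fully declared ingredient passes through unchanged", {
  tt <- tiny_db()
  labels <- tibble::tibble(
    product_food_id = "53000001", ingredient_food_id = "16000001",
    declared_percent = 100
  )
  v <- apply_label("53000001", labels, tt$db,
    assignments = tt$assignments, tags = tt$tags
  )
  expect_identical(sv_method(v), "label")
  expect_identical(unname(sv_groups(v)["nuts_and_seeds"]), 3)
  # water comes from the product's own nutrient record, not the ingredient
  expect_identical(unclass(v)[["water"]], 4)
})

test_that("declared percentages scale ingredient vectors linearly", {
  tt <- tiny_db()
  labels <- tibble::tibble(
    product_food_id = "53000001", ingredient_food_id = "16000001",
    declared_percent = 10
  )
  v <- suppressMessages(apply_label("53000001", labels, tt$db,
    assignments = tt$assignments, tags = tt$tags
  ))
  # 10 % macadamia at 3 servings/100 g contributes 0.3
  expect_equal(unname(sv_groups(v)["nuts_and_seeds"]), 0.3, tolerance = 1e-12)
})

test_that("over-declared labels fail and under-declared ones are never renormalised", {
  tt <- tiny_db()
  over <- tibble::tibble(
    product_food_id = "53000001",
    ingredient_food_id = c("16000001", "12000001"),
    declared_percent = c(60, 60)
  )
  expect_error(
    apply_label("53000001", over, tt$db, assignments = tt$assignments),
    class = "plantserve_validation_error"
  )
  expect_error(read_label_file({
    p <- tempfile(fileext = ".csv")
    readr::write_csv(over, p)
    p
  }), class = "plantserve_validation_error")

  under <- tibble::tibble(
    product_food_id = "53000001", ingredient_food_id = "16000001",
    declared_percent = 40
  )
  expect_message(
    v <- apply_label("53000001", under, tt$db, assignments = tt$assignments),
    regexp = "remainder"
  )
  expect_equal(unname(sv_groups(v)["nuts_and_seeds"]), 0.4 * 3, tolerance = 1e-12)
  expect_true(all(sv_groups(v)[setdiff(names(sv_groups(v)), "nuts_and_seeds")] == 0))
})

test_that("splitting one declared entry into two with the same total changes nothing", {
  tt <- tiny_db()
  one <- tibble::tibble(
    product_food_id = "53000001", ingredient_food_id = "16000001",
    declared_percent = 30
  )
  two <- tibble::tibble(
    product_food_id = "53000001",
    ingredient_food_id = c("16000001", "16000001"),
    declared_percent = c(10, 20)
  )
  v1 <- suppressMessages(apply_label("53000001", one, tt$db, assignments = tt$assignments))
  v2 <- suppressMessages(apply_label("53000001", two, tt$db, assignments = tt$assignments))
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)
})

test_that("labels matching recipe proportions reproduce the recipe result", {
  tt <- tiny_db()
  res <- resolve_food("51000001", tt$db,
    assignments = tt$assignments,
    exclusions = tt$exclusions, tags = tt$tags
  )
  labels <- tibble::tibble(
    product_food_id = "53000001",
    ingredient_food_id = names(res$proportions),
    declared_percent = 100 * as.numeric(res$proportions)
  )
  v <- apply_label("53000001", labels, tt$db,
    assignments = tt$assignments, tags = tt$tags
  )
  expect_equal(sv_groups(v), sv_groups(res$servings), tolerance = 1e-9)
})

test_that("proxy classification copies the target vector and rejects chains", {
  tt <- tiny_db()
  v <- apply_proxy("54000001", "51000001", tt$db,
    assignments = tt$assignments, tags = tt$tags
  )
  res <- resolve_food("51000001", tt$db,
    assignments = tt$assignments,
    exclusions = tt$exclusions, tags = tt$tags
  )
  expect_identical(sv_method(v), "proxy")
  expect_equal(sv_groups(v), sv_groups(res$servings), tolerance = 1e-12)

  # a product may reference itself (degenerate but well defined)
  self <- apply_proxy("11000001", "11000001", tt$db, assignments = tt$assignments)
  expect_identical(unname(sv_groups(self)["vegetables"]), 1.2)

  # chains are rejected: the target below is itself only proxy-classified
  expect_error(
    apply_proxy("54000002", "54000001", tt$db, assignments = tt$assignments),
    class = "plantserve_unresolved_error"
  )

  # a zero-content proxy propagates a zero vector, with a warning
  tz <- tiny_tables()
  zero_row <- tz$adg[1, ]
  zero_row$food_id <- "11000009"
  zero_row[group_keys(tz$schema)] <- 0
  adg2 <- dplyr::bind_rows(tz$adg, zero_row)
  attr(adg2, "declared_groups") <- attr(tz$adg, "declared_groups")
  det2 <- dplyr::bind_rows(tz$details, tibble::tibble(
    food_id = "11000009", survey_id = "Sz", name = "Vegetable drink, trace",
    description = NA_character_, major_group_code = "11",
    discretionary_flag = "core"
  ))
  db2 <- food_database(det2, tz$nutrients, tz$recipes, adg2, schema = tz$schema)
  expect_warning(
    vz <- apply_proxy("54000001", "11000009", db2, assignments = tz$assignments),
    regexp = "no food-group content"
  )
  expect_true(all(sv_groups(vz) == 0))
})

test_that("sodium-anchored label estimates delegate to the sodium basis", {
  expect_equal(sodium_based_label_estimate(295), 295 / 120, tolerance = 1e-12)
  expect_identical(sodium_based_label_estimate(120), 1)
  expect_identical(sodium_based_label_estimate(0), 0)
})
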