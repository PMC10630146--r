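test_that("the workflow routes each food through the first applicable method", {
  tt <- tiny_db()
  ex <- classify_tiny(tt)
  method_of <- function(id) ex$servings$method[ex$servings$food_id == id]
  expect_identical(method_of("11000001"), "direct") # existing servings
  expect_identical(method_of("14000001"), "direct") # rule assignment
  expect_identical(method_of("51000001"), "recipe")
  expect_identical(method_of("52000001"), "recipe")
  expect_identical(method_of("53000001"), "label")
  expect_identical(method_of("54000001"), "proxy")
  expect_identical(method_of("98000001"), "unclassified")
  oc <- ex$outcomes[ex$outcomes$food_id == "98000001", ]
  expect_identical(oc$excluded_category, "water_or_alcohol_only")
  # water is still recorded for unclassified foods
  row <- ex$servings[ex$servings$food_id == "98000001", ]
  expect_identical(row$water_g_per_100g, 100)
  expect_true(all(as.matrix(row[, group_keys(ex$schema)]) == 0))
})

test_that("every food receives exactly one method and counts partition the database", {
  ex <- classify_tiny()
  expect_identical(sort(ex$outcomes$food_id), sort(ex$records$food_id))
  expect_identical(anyDuplicated(ex$outcomes$food_id), 0L)
  expect_identical(sum(table(ex$outcomes$method)), nrow(ex$records))
})

test_that("membership flags follow kingdom tags and ignore added sugars and water", {
  sch <- food_group_schema()
  f <- derive_flags(servings_vector(c(vegetables = 1)), sch)
  expect_true(f$is_plant_containing && f$is_entirely_plant)
  expect_false(f$is_animal_containing || f$is_entirely_animal)

  f <- derive_flags(servings_vector(c(vegetables = 1, animal_fats = 0.2)), sch)
  expect_true(f$is_plant_containing && f$is_animal_containing)
  expect_false(f$is_entirely_plant || f$is_entirely_animal)

  f <- derive_flags(servings_vector(NULL, water = 100), sch)
  expect_false(any(as.logical(f)))

  # added sugars alone put a food in neither kingdom under the default tag
  f <- derive_flags(servings_vector(c(added_sugars = 50)), sch)
  expect_false(any(as.logical(f)))
  # ...unless the schema re-tags them as plant
  sch_p <- food_group_schema(added_sugars_kingdom = "plant")
  f <- derive_flags(servings_vector(c(added_sugars = 50), schema = sch_p), sch_p)
  expect_true(f$is_entirely_plant)

  # below-tolerance traces do not count as containment
  f <- derive_flags(servings_vector(c(vegetables = 1e-12)), sch)
  expect_false(f$is_plant_containing)
})

test_that("flag invariants hold across a whole classified fixture", {
  fx <- generate_fixture(fixture_spec(n_base_per_group = 2, n_composites = 20, seed = 31))
  ex <- suppressMessages(classify_fixture(fx))
  oc <- ex$outcomes
  expect_true(all(!oc$is_entirely_plant | (oc$is_plant_containing & !oc$is_animal_containing)))
  expect_true(all(!oc$is_entirely_animal | (oc$is_animal_containing & !oc$is_plant_containing)))
  uncls <- oc$method == "unclassified"
  m <- as.matrix(ex$servings[match(oc$food_id, ex$servings$food_id), group_keys(ex$schema)])
  expect_true(all(m[uncls, ] == 0))
})

test_that("re-classifying a database from its own output changes nothing", {
  fx <- generate_fixture(fixture_spec(n_base_per_group = 1, n_composites = 10, seed = 13))
  ex <- suppressMessages(classify_fixture(fx))
  keys <- group_keys(ex$schema)
  adg2 <- ex$servings[, c("food_id", keys)]
  attr(adg2, "declared_groups") <- keys
  db2 <- food_database(fx$details, fx$nutrients, adg = adg2, schema = ex$schema)
  ex2 <- suppressMessages(classify_all(db2, exclusions = fx$exclusions))
  got <- as.matrix(ex2$servings[match(ex$servings$food_id, ex2$servings$food_id), keys])
  expect_equal(got, as.matrix(ex$servings[, keys]), tolerance = 1e-12)
  # water/alcohol channels also survive because fixture nutrients are coherent
  expect_equal(
    ex2$servings$water_g_per_100g[match(ex$servings$food_id, ex2$servings$food_id)],
    ex$servings$water_g_per_100g,
    tolerance = 1e-9
  )
})

test_that("audit samples are deterministic, sized by rounding and validated", {
  ids <- sprintf("f%03d", 1:10)
  s1 <- audit_sample(ids, 0.2, seed = 99)
  s2 <- audit_sample(ids, 0.2, seed = 99)
  expect_identical(s1, s2)
  expect_length(s1, 2L)
  expect_true(all(s1 %in% ids) && !anyDuplicated(s1))
  expect_setequal(audit_sample(ids, 1, seed = 1), ids)
  expect_length(audit_sample(sprintf("f%03d", 1:573), 0.2, seed = 4), round(0.2 * 573))
  expect_error(audit_sample(ids, 0, seed = 1), class = "plantserve_validation_error")
  expect_error(audit_sample(ids, 1.2, seed = 1), class = "plantserve_validation_error")
  # drawing the sample does not disturb the global RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(audit_sample(ids, 0.5, seed = 7))
  expect_identical(runif(1), before)
})

test_that("unknown exclusion categories are rejected", {
  tt <- tiny_db()
  bad <- tibble::tibble(food_id = "98000001", category = "misc")
  expect_error(
    classify_all(tt$db, exclusions = bad),
    class = "plantserve_validation_error"
  )
})

test_that("headline summaries count methods and memberships consistently", {
  ex <- classify_tiny()
  s <- database_headline_summary(ex)
  expect_identical(s$n_foods, nrow(ex$records))
  expect_identical(s$n_classified + s$n_unclassified, s$n_foods)
  expect_identical(
    s$n_recipe + s$n_direct + s$n_label + s$n_proxy,
    s$n_classified
  )
  expect_equal(s$pct_plant_containing, 100 * s$n_plant_containing / s$n_classified)
  expect_true(s$pct_entirely_plant_of_plant >= s$pct_entirely_plant_of_classified)
})
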