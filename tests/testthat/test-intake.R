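test_that("intake scaling divides by 100 and multiplies by grams eaten", {
  expect_identical(servings_for_intake(100, 1), 1)
  expect_identical(servings_for_intake(0, 1.5), 0)
  expect_equal(servings_for_intake(20, 1.5), 0.3, tolerance = 1e-12)
  v <- servings_vector(c(miscellaneous_animal = 1.5), water = 40, method = "direct")
  out <- servings_for_intake(20, v)
  expect_equal(unname(sv_groups(out)["miscellaneous_animal"]), 0.3, tolerance = 1e-12)
  expect_equal(unclass(out)[["water"]], 8, tolerance = 1e-12)
  expect_error(servings_for_intake(-1, v), class = "plantserve_validation_error")
})

test_that("person totals are additive and match a hand-summed oracle", {
  ex <- classify_tiny()
  keys <- group_keys(ex$schema)
  one <- tibble::tibble(person_id = "p1", food_id = "11000001", amount_g = 150)
  t1 <- person_totals(one, ex)
  expect_equal(t1$vegetables, 1.5 * 1.2, tolerance = 1e-12)

  dup <- dplyr::bind_rows(one, one)
  t2 <- person_totals(dup, ex)
  expect_equal(as.numeric(t2[, keys]), 2 * as.numeric(t1[, keys]), tolerance = 1e-12)

  day <- tibble::tibble(
    person_id = "p2",
    food_id = c("11000001", "12000001", "14000001", "27000001", "51000001"),
    amount_g = c(80, 120, 10, 30, 60)
  )
  t3 <- person_totals(day, ex)
  oracle <- Reduce(`+`, lapply(seq_len(nrow(day)), function(i) {
    row <- ex$servings[ex$servings$food_id == day$food_id[i], keys]
    as.numeric(row) * day$amount_g[i] / 100
  }))
  expect_equal(as.numeric(t3[, keys]), oracle, tolerance = 1e-12)

  expect_error(
    person_totals(tibble::tibble(person_id = "p", food_id = "nope", amount_g = 10), ex),
    regexp = "nope", class = "plantserve_integrity_error"
  )
})

test_that("major-group summaries count containing products against stratum sizes", {
  ex <- classify_tiny()
  tab <- summarize_by_major_group(ex)
  # major group 11 holds the carrot only: vegetables in 100 % of 1 product
  row <- tab[tab$major_group_code == "11" & tab$group == "vegetables", ]
  expect_identical(row$n_products, 1L)
  expect_identical(row$n_containing, 1L)
  expect_identical(row$percent, 100)
  # a food containing k groups appears in exactly k cells of its stratum row
  keys <- group_keys(ex$schema)
  for (mg in unique(tab$major_group_code)) {
    ids <- ex$records$food_id[ex$records$major_group_code == mg]
    m <- as.matrix(ex$servings[ex$servings$food_id %in% ids, keys]) > 1e-9
    expect_identical(
      sum(tab$n_containing[tab$major_group_code == mg]),
      as.integer(sum(m))
    )
  }
})

test_that("a constructed 3-of-8 stratum reports 37.5 percent", {
  sch <- food_group_schema()
  ids <- sprintf("61%06d", 1:8)
  records <- tibble::tibble(
    food_id = ids, survey_id = ids, name = ids, description = NA_character_,
    major_group_code = "61", discretionary_flag = "core"
  )
  servings <- tibble::tibble(food_id = ids, method = "direct")
  for (cn in group_keys(sch)) servings[[cn]] <- 0
  servings$fruits <- c(1, 1, 1, 0, 0, 0, 0, 0)
  servings$water_g_per_100g <- 10
  servings$alcohol_g_per_100g <- 0
  db <- expanded_database(records, servings, schema = sch)
  tab <- summarize_by_major_group(db)
  expect_identical(tab$percent[tab$group == "fruits"], 37.5)
})

test_that("core/discretionary summaries keep unflagged foods out of both denominators", {
  sch <- food_group_schema()
  ids <- sprintf("62%06d", 1:9)
  flags <- c(rep("core", 4), rep("discretionary", 4), "unflagged")
  records <- tibble::tibble(
    food_id = ids, survey_id = ids, name = ids, description = NA_character_,
    major_group_code = "62", discretionary_flag = flags
  )
  servings <- tibble::tibble(food_id = ids, method = "direct")
  for (cn in group_keys(sch)) servings[[cn]] <- 0
  # fruit present in 1 of 4 core, 2 of 4 discretionary, and in the unflagged food
  servings$fruits <- c(1, 0, 0, 0, 1, 1, 0, 0, 1)
  servings$water_g_per_100g <- 0
  servings$alcohol_g_per_100g <- 0
  db <- expanded_database(records, servings, schema = sch)
  tab <- summarize_core_discretionary(db)
  fr <- tab[tab$group == "fruits", ]
  expect_identical(fr$percent[fr$stratum == "core"], 25)
  expect_identical(fr$percent[fr$stratum == "discretionary"], 50)
  expect_identical(fr$n_products[fr$stratum == "core"], 4L)
  expect_identical(fr$n_products[fr$stratum == "discretionary"], 4L)
  expect_identical(fr$n_products[fr$stratum == "unflagged"], 1L)

  # an all-core database yields no discretionary stratum at all
  records2 <- dplyr::mutate(records, discretionary_flag = "core")
  tab2 <- summarize_core_discretionary(expanded_database(records2, servings, schema = sch))
  expect_identical(unique(tab2$stratum), "core")
})

test_that("comparing a database against itself gives zero differences", {
  ex <- classify_tiny()
  intakes <- tibble::tibble(
    person_id = c("p1", "p1", "p2"),
    food_id = c("11000001", "52000001", "14000001"),
    amount_g = c(100, 250, 15)
  )
  cmp <- compare_databases(ex, ex, intakes)
  wide <- tidyr::pivot_wider(cmp, names_from = "database", values_from = "servings")
  expect_equal(wide$old, wide$new, tolerance = 1e-12)
  # and reduces to person totals summed over strata
  keys <- group_keys(ex$schema)
  pt <- person_totals(intakes, ex)
  agg <- cmp |>
    dplyr::filter(.data$database == "new", .data$person_id == "p1") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(servings = sum(.data$servings))
  expect_equal(
    agg$servings[match(keys, agg$group)],
    as.numeric(pt[pt$person_id == "p1", keys]),
    tolerance = 1e-12
  )
})

test_that("a database change surfaces only in the changed group", {
  ex_old <- classify_tiny()
  ex_new <- ex_old
  i <- ex_new$servings$food_id == "12000001"
  ex_new$servings$animal_fats[i] <- ex_new$servings$animal_fats[i] + 0.7
  intakes <- tibble::tibble(person_id = "p1", food_id = "12000001", amount_g = 200)
  cmp <- compare_databases(ex_old, ex_new, intakes)
  wide <- tidyr::pivot_wider(cmp, names_from = "database", values_from = "servings")
  diff <- wide$new - wide$old
  changed <- wide$group[abs(diff) > 1e-12]
  expect_identical(changed, "animal_fats")
  expect_equal(diff[wide$group == "animal_fats"], 0.7 * 2, tolerance = 1e-12)

  expect_identical(nrow(compare_databases(ex_old, ex_new, tibble::tibble(
    person_id = character(), food_id = character(), amount_g = numeric()
  ))), 0L)
})
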