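#' Convert a consumed amount into food-group servings
#'
#' The database stores servings per 100 g, so a consumed amount converts by
#' dividing by 100 (servings per gram) and multiplying by the grams eaten:
#' `servings = amount_g * servings_per_100g / 100`. Works element-wise on a
#' full [servings_vector()] or on plain numerics.
#'
#' @param amount_g Grams consumed (non-negative).
#' @param servings_per_100g A [servings_vector()] or numeric vector of
#'   servings per 100 g.
#' @return Servings for the consumed amount, same shape as
#'   `servings_per_100g`.
#' @examples
#' servings_for_intake(20, 1.5) # 0.3 servings from 20 g of a sauce
#' @export
servings_for_intake <- function(amount_g, servings_per_100g) {
  if (!is.numeric(amount_g) || length(amount_g) != 1L || !is.finite(amount_g) || amount_g < 0) {
    rlang::abort("amount_g must be a single non-negative number",
      class = "plantserve_validation_error"
    )
  }
  if (inherits(servings_per_100g, "servings_vector")) {
    sv_rescale(servings_per_100g, amount_g / 100)
  } else {
    servings_per_100g * amount_g / 100
  }
}

#' @describeIn readers Dietary-intake records: canonical columns
#'   `person_id`, `food_id`, `amount_g` (positive grams consumed).
#' @return `read_intake_file()`: a tibble of intake records.
#' @export
read_intake_file <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, col_map, required = c("person_id", "food_id", "amount_g"))
  df$amount_g <- parse_decimal(df$amount_g)
  if (anyNA(df$amount_g) || any(df$amount_g <= 0)) {
    rlang::abort("amount_g must parse and be positive", class = "plantserve_validation_error")
  }
  tibble::as_tibble(df[, c("person_id", "food_id", "amount_g")])
}

#' Per-person food-group serving totals
#'
#' Applies the expanded database to intake records: every record is scaled
#' by [servings_for_intake()] and records are summed within person. Intake
#' of unclassified foods contributes zero group servings (their water and
#' alcohol still accumulate).
#'
#' @param intakes Tibble `person_id`, `food_id`, `amount_g`.
#' @param db An `expanded_db`.
#' @return A wide tibble: `person_id`, the 23 group columns, `water_g`,
#'   `alcohol_g` — total servings (and grams of water/alcohol) consumed.
#' @export
person_totals <- function(intakes, db) {
  stopifnot(inherits(db, "expanded_db"))
  intakes <- tibble::as_tibble(intakes)
  if (any(intakes$amount_g <= 0) || anyNA(intakes$amount_g)) {
    rlang::abort("amount_g must be positive", class = "plantserve_validation_error")
  }
  unknown <- setdiff(intakes$food_id, db$servings$food_id)
  if (length(unknown)) {
    rlang::abort(
      sprintf("intake refers to unknown food_id(s): %s", paste(head(unknown, 10L), collapse = ", ")),
      class = "plantserve_integrity_error"
    )
  }
  keys <- group_keys(db$schema)
  joined <- left_join(intakes, db$servings, by = "food_id")
  scaled <- joined |>
    mutate(across(all_of(c(keys, "water_g_per_100g", "alcohol_g_per_100g")), ~ .x * amount_g / 100)) |>
    rename(water_g = "water_g_per_100g", alcohol_g = "alcohol_g_per_100g")
  scaled |>
    group_by(.data$person_id) |>
    summarise(across(all_of(c(keys, "water_g", "alcohol_g")), sum), .groups = "drop")
}

# internal: long containment summary for one stratum column
containment_summary <- function(db, stratum, tol) {
  keys <- group_keys(db$schema)
  flags_mat <- as.matrix(db$servings[, keys, drop = FALSE]) > tol
  strata <- split(seq_len(nrow(db$servings)), stratum)
  purrr::map_dfr(names(strata), function(s) {
    idx <- strata[[s]]
    n_prod <- length(idx)
    counts <- colSums(flags_mat[idx, , drop = FALSE])
    tibble::tibble(
      stratum = s, group = keys,
      n_products = n_prod,
      n_containing = as.integer(counts),
      percent = if (n_prod > 0) unname(100 * counts / n_prod) else 0,
      empty_stratum = n_prod == 0L
    )
  })
}

#' Containment summaries across strata
#'
#' `summarize_by_major_group()` tabulates, for every two-digit major food
#' group of the source survey and every food group of the 23-group schema,
#' how many products contain that group (servings above `tol`) and the
#' percentage of the stratum they represent. A food containing k groups
#' appears in exactly k cells of its stratum row; denominators are stratum
#' sizes.
#'
#' `summarize_core_discretionary()` computes the same statistic stratified
#' by the core/discretionary flag; foods without a flag are reported in a
#' separate `unflagged` stratum and never enter the core or discretionary
#' denominators.
#'
#' @param db An `expanded_db` (records must carry `major_group_code` /
#'   `discretionary_flag`).
#' @param tol Containment threshold, servings per 100 g.
#' @return A long tibble: `stratum`, `group`, `n_products`, `n_containing`,
#'   `percent`, `empty_stratum`.
#' @export
summarize_by_major_group <- function(db, tol = 1e-9) {
  stopifnot(inherits(db, "expanded_db"))
  mg <- db$records$major_group_code[match(db$servings$food_id, db$records$food_id)]
  out <- containment_summary(db, mg, tol)
  rename(out, major_group_code = "stratum")
}

#' @rdname summarize_by_major_group
#' @export
summarize_core_discretionary <- function(db, tol = 1e-9) {
  stopifnot(inherits(db, "expanded_db"))
  fl <- db$records$discretionary_flag[match(db$servings$food_id, db$records$food_id)]
  fl[is.na(fl)] <- "unflagged"
  containment_summary(db, fl, tol)
}

#' Compare intake distributions under two databases
#'
#' Applies two versions of a servings database (e.g. the original
#' dietary-guideline database and its expansion) to the same intake
#' records, splitting foods by core/discretionary status. The result is a
#' tidy long table of per-person, per-group serving totals under each
#' database, ready for distribution plots; an aggregated per-group mean is
#' attached as attribute `"means"`.
#'
#' @param db_old,db_new Two `expanded_db` objects over the same schema.
#'   Foods unclassified in either database contribute zero servings there.
#' @param intakes Tibble `person_id`, `food_id`, `amount_g`; every food
#'   must exist in both databases.
#' @return Long tibble: `person_id`, `database` (`"old"`/`"new"`),
#'   `stratum` (core/discretionary/unflagged), `group`, `servings`.
#' @export
compare_databases <- function(db_old, db_new, intakes) {
  stopifnot(inherits(db_old, "expanded_db"), inherits(db_new, "expanded_db"))
  intakes <- tibble::as_tibble(intakes)
  keys <- group_keys(db_new$schema)
  if (!identical(keys, group_keys(db_old$schema))) {
    rlang::abort("the two databases use different schemas", class = "plantserve_schema_error")
  }
  if (!nrow(intakes)) {
    return(tibble::tibble(
      person_id = character(), database = character(),
      stratum = character(), group = character(), servings = numeric()
    ))
  }
  one <- function(db, tag) {
    unknown <- setdiff(intakes$food_id, db$servings$food_id)
    if (length(unknown)) {
      rlang::abort(
        sprintf(
          "intake food_id(s) missing from the %s database: %s", tag,
          paste(head(unknown, 10L), collapse = ", ")
        ),
        class = "plantserve_integrity_error"
      )
    }
    fl <- db$records$discretionary_flag[match(intakes$food_id, db$records$food_id)]
    fl[is.na(fl)] <- "unflagged"
    joined <- dplyr::bind_cols(intakes, stratum = fl) |>
      left_join(db$servings, by = "food_id") |>
      mutate(across(all_of(keys), ~ .x * amount_g / 100))
    joined |>
      tidyr::pivot_longer(all_of(keys), names_to = "group", values_to = "servings") |>
      group_by(.data$person_id, .data$stratum, .data$group) |>
      summarise(servings = sum(.data$servings), .groups = "drop") |>
      mutate(database = tag)
  }
  out <- dplyr::bind_rows(one(db_old, "old"), one(db_new, "new")) |>
    select("person_id", "database", "stratum", "group", "servings") |>
    arrange(.data$person_id, .data$database, .data$stratum, .data$group)
  means <- out |>
    group_by(.data$database, .data$stratum, .data$group) |>
    summarise(mean_servings = mean(.data$servings), .groups = "drop")
  attr(out, "means") <- means
  out
}

#' Plot a two-database comparison
#'
#' Thin optional layer over [compare_databases()] output: per-group boxplots
#' of per-person serving totals, facetted by stratum, coloured by database.
#' Requires ggplot2.
#'
#' @param comparison Output of [compare_databases()].
#' @return A ggplot object.
#' @export
plot_database_comparison <- function(comparison) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("ggplot2 is required for plotting", class = "plantserve_config_error")
  }
  ggplot2::ggplot(
    comparison,
    ggplot2::aes(x = .data$group, y = .data$servings, fill = .data$database)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~stratum, ncol = 1) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "servings per person") +
    ggplot2::theme_minimal()
}
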