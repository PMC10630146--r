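#' Construct a servings vector
#'
#' A servings vector holds the servings per 100 g of a food across all 23
#' food groups, plus the water and alcohol content (g/100 g) as side
#' channels, and a tag recording the classification method that produced it.
#'
#' @param values Named numeric vector of servings per 100 g; names must be
#'   group keys of `schema`. Unnamed groups default to 0.
#' @param schema A [food_group_schema()].
#' @param water,alcohol Side-channel content in g/100 g.
#' @param method Classification method tag: one of `"direct"`, `"recipe"`,
#'   `"label"`, `"proxy"`, `"unclassified"`.
#' @return A named numeric vector of class `servings_vector` whose names are
#'   the 23 group keys followed by `"water"` and `"alcohol"`, with a
#'   `method` attribute.
#' @examples
#' v <- servings_vector(c(vegetables = 1.2), water = 80)
#' sv_method(v)
#' @export
servings_vector <- function(values = NULL, schema = food_group_schema(),
                            water = 0, alcohol = 0, method = "unclassified") {
  keys <- group_keys(schema)
  out <- stats::setNames(numeric(length(keys) + 2L), c(keys, "water", "alcohol"))
  if (!is.null(values) && length(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values)))) {
      rlang::abort("`values` must be a fully named numeric vector",
        class = "plantserve_validation_error"
      )
    }
    assert_group_keys(names(values), schema, what = "servings key")
    out[names(values)] <- as.numeric(values)
  }
  out["water"] <- water
  out["alcohol"] <- alcohol
  new_servings_vector(out, method = method, schema = schema)
}

# internal constructor + validator
new_servings_vector <- function(x, method, schema = NULL) {
  method <- match.arg(method, c("direct", "recipe", "label", "proxy", "unclassified"))
  if (anyNA(x) || any(!is.finite(x))) {
    rlang::abort("servings vector must be finite", class = "plantserve_validation_error")
  }
  grp <- x[setdiff(names(x), c("water", "alcohol"))]
  if (any(grp < 0)) {
    rlang::abort("servings must be non-negative", class = "plantserve_validation_error")
  }
  structure(as.numeric(x),
    names = names(x), method = method,
    class = "servings_vector"
  )
}

#' @rdname servings_vector
#' @param x A `servings_vector`.
#' @export
sv_method <- function(x) attr(x, "method", exact = TRUE)

#' @rdname servings_vector
#' @export
sv_groups <- function(x) {
  unclass(x)[setdiff(names(x), c("water", "alcohol"))]
}

#' @export
print.servings_vector <- function(x, ...) {
  nz <- sv_groups(x)
  nz <- nz[nz > 0]
  cat(sprintf(
    "<servings_vector method=%s> water=%.3g alcohol=%.3g g/100g\n",
    sv_method(x), unclass(x)[["water"]], unclass(x)[["alcohol"]]
  ))
  if (length(nz)) {
    for (k in names(nz)) cat(sprintf("  %-22s %.6g servings/100g\n", k, nz[[k]]))
  } else {
    cat("  (no food-group content)\n")
  }
  invisible(x)
}

# internal: rescale a vector, keeping names; method supplied by caller
sv_rescale <- function(x, k, method = sv_method(x)) {
  new_servings_vector(stats::setNames(as.numeric(x) * k, names(x)), method = method)
}

# internal: elementwise sum of a list of servings vectors sharing one schema
sv_sum <- function(vectors, method) {
  nm <- names(vectors[[1L]])
  for (v in vectors[-1L]) {
    if (!identical(names(v), nm)) {
      rlang::abort("servings vectors disagree on schema keys",
        class = "plantserve_internal_error"
      )
    }
  }
  tot <- Reduce(`+`, lapply(vectors, as.numeric))
  new_servings_vector(stats::setNames(tot, nm), method = method)
}
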