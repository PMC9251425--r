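#' Default 17-group food classification
#'
#' Returns the default food-group map used for PDI/hPDI scoring: 17 food
#' groups partitioned into healthy plant foods (whole grains, fruits,
#' vegetables, nuts, legumes, tea and coffee, vegetable oils), less healthy
#' plant foods (refined grains, potatoes, sugary drinks, sweets and desserts,
#' preserved and fermented foods) and animal foods (animal fats, dairy
#' products, eggs, fish or seafood, meat).
#'
#' Chinese preserved/pickled and fermented foods are carried as a single
#' `fermented_preserved` group, categorized as less-healthy plant by default;
#' supply a modified map to `food_group_map()` to re-categorize it.
#'
#' @return A `food_group_map` data frame with columns `group_id`, `name`,
#'   `category` (one of `"healthy_plant"`, `"unhealthy_plant"`, `"animal"`).
#' @export
default_food_groups <- function() {
  groups <- rbind(
    data.frame(
      group_id = c("whole_grains", "fruits", "vegetables", "nuts", "legumes",
                   "tea_coffee", "vegetable_oils"),
      name = c("Whole grains", "Fruits", "Vegetables", "Nuts", "Legumes",
               "Tea and coffee", "Vegetable oils"),
      category = "healthy_plant"
    ),
    data.frame(
      group_id = c("refined_grains", "potatoes", "sugary_drinks",
                   "sweets_desserts", "fermented_preserved"),
      name = c("Refined grains", "Potatoes", "Sugary drinks",
               "Sweets and desserts", "Preserved and fermented foods"),
      category = "unhealthy_plant"
    ),
    data.frame(
      group_id = c("animal_fats", "dairy", "eggs", "fish_seafood", "meat"),
      name = c("Animal fats", "Dairy products", "Eggs", "Fish or seafood",
               "Meat"),
      category = "animal"
    )
  )
  food_group_map(groups)
}

#' Validate a food-group map
#'
#' @param groups data frame with columns `group_id`, `name`, `category`.
#' @param item_codes optional named character vector mapping item codes to
#'   `group_id` (for item-level recall data).
#' @param n_groups required number of groups; the default scheme uses 17.
#' @return the validated map, class `food_group_map`, with the item-code
#'   lookup attached as attribute `item_codes`.
#' @export
food_group_map <- function(groups, item_codes = NULL, n_groups = 17L) {
  stopifnot(is.data.frame(groups))
  required <- c("group_id", "name", "category")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols) > 0L) {
    stop("food-group map lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(groups$group_id)) {
    stop("duplicated group_id in food-group map")
  }
  if (nrow(groups) != n_groups) {
    stop(sprintf("food-group map must define exactly %d groups, got %d",
                 n_groups, nrow(groups)))
  }
  ok <- groups$category %in% c("healthy_plant", "unhealthy_plant", "animal")
  if (!all(ok)) {
    stop("invalid category for group(s): ",
         paste(groups$group_id[!ok], collapse = ", "))
  }
  if (!is.null(item_codes)) {
    bad <- setdiff(unique(item_codes), groups$group_id)
    if (length(bad) > 0L) {
      stop("item codes map to unknown group(s): ", paste(bad, collapse = ", "))
    }
  }
  rownames(groups) <- NULL
  structure(groups, item_codes = item_codes,
            class = c("food_group_map", "data.frame"))
}

#' Read a food-group map from YAML
#'
#' The YAML layout mirrors `inst/extdata/food_groups.yaml`: a `groups` list of
#' `{group_id, name, category}` entries and an optional `item_codes` mapping.
#'
#' @param path path to a YAML file.
#' @param n_groups required number of groups (default 17).
#' @return a `food_group_map`.
#' @export
read_food_groups <- function(path, n_groups = 17L) {
  spec <- yaml::read_yaml(path)
  groups <- do.call(rbind, lapply(spec$groups, function(g) {
    data.frame(group_id = g$group_id, name = g$name, category = g$category)
  }))
  codes <- NULL
  if (!is.null(spec$item_codes)) {
    codes <- vapply(spec$item_codes, as.character, character(1))
  }
  food_group_map(groups, item_codes = codes, n_groups = n_groups)
}

#' Classify a food item code into a food group
#'
#' Unmapped codes raise an error carrying the offending codes; they are never
#' silently dropped.
#'
#' @param item_code character vector of item codes.
#' @param map a `food_group_map` with an `item_codes` lookup attached.
#' @return character vector of `group_id`.
#' @export
classify_food_item <- function(item_code, map) {
  codes <- attr(map, "item_codes")
  if (is.null(codes)) stop("food-group map has no item-code lookup attached")
  hit <- codes[as.character(item_code)]
  if (anyNA(hit)) {
    bad <- unique(item_code[is.na(hit)])
    stop("unmapped item code(s): ", paste(bad, collapse = ", "))
  }
  unname(hit)
}
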