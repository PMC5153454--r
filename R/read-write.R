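#' Read a column-mapping dialect
#'
#' A dialect adapts a survey CSV whose columns differ from the canonical
#' layout: a rename map, an optional salt column (EU labels may declare
#' salt rather than sodium), and the decimal separator.
#'
#' @param path path to a YAML file with any of the keys `rename` (map of
#'   file column name to canonical name), `salt_column` (name of a salt
#'   g/100 g column to convert to sodium), `decimal_mark` ("." or ",").
#' @return a dialect list usable as the `dialect` argument of
#'   [read_food_table()].
#' @export
read_dialect <- function(path) {
  raw <- yaml::read_yaml(path)
  dialect(rename = unlist(raw$rename %||% list()),
          salt_column = raw$salt_column,
          decimal_mark = raw$decimal_mark %||% ".")
}

#' Construct a reader dialect in code
#'
#' @param rename named character vector: names are file column names,
#'   values canonical column names.
#' @param salt_column optional name of a salt (g/100 g) column; converted
#'   to sodium at `sodium_mg = salt_g / 2.5 * 1000` where sodium is absent.
#' @param decimal_mark decimal separator used in the file.
#' @return a list of class `nutriclaim_dialect`.
#' @export
dialect <- function(rename = character(), salt_column = NULL,
                    decimal_mark = ".") {
  stopifnot(decimal_mark %in% c(".", ","))
  structure(list(rename = rename, salt_column = salt_column,
                 decimal_mark = decimal_mark),
            class = "nutriclaim_dialect")
}

#' Check nutrient panel invariants
#'
#' Validates the per-100 g panel columns of a survey table: values are
#' non-negative, total sugars do not exceed carbohydrate and saturated fat
#' does not exceed total fat beyond a 0.5 g label-rounding tolerance,
#' fruit/vegetable/nut/legume percentage lies in \[0, 100\], and the two
#' energy declarations agree within max(2 kJ, 2%).
#'
#' @param survey a tibble with (a subset of) the canonical panel columns.
#' @return invisibly `TRUE`; otherwise an error naming the violated
#'   invariant and the offending rows.
#' @export
validate_nutrient_panel <- function(survey) {
  present <- intersect(PANEL_COLS, names(survey))
  for (col in present) {
    bad <- which(has_value(survey[[col]]) & survey[[col]] < 0)
    if (length(bad)) {
      validation_error(paste0("negative values in ", col), bad)
    }
  }
  check_pair <- function(part, whole, label) {
    if (all(c(part, whole) %in% names(survey))) {
      p <- survey[[part]]; w <- survey[[whole]]
      bad <- which(has_value(p) & has_value(w) & p > w + 0.5)
      if (length(bad)) validation_error(label, bad)
    }
  }
  check_pair("total_sugars_g", "carbohydrate_g",
             "total_sugars_g exceeds carbohydrate_g beyond the 0.5 g tolerance")
  check_pair("saturated_fat_g", "total_fat_g",
             "saturated_fat_g exceeds total_fat_g beyond the 0.5 g tolerance")
  if ("fvnl_percent" %in% names(survey)) {
    f <- survey$fvnl_percent
    bad <- which(has_value(f) & (f < 0 | f > 100))
    if (length(bad)) validation_error("fvnl_percent outside [0, 100]", bad)
  }
  if (all(c("energy_kJ", "energy_kcal") %in% names(survey))) {
    kj <- survey$energy_kJ; kcal <- survey$energy_kcal
    both <- has_value(kj) & has_value(kcal)
    tol <- pmax(2, 0.02 * kj)
    bad <- which(both & abs(kj - KJ_PER_KCAL * kcal) > tol)
    if (length(bad)) {
      validation_error("energy_kJ and energy_kcal disagree beyond max(2 kJ, 2%)",
                       bad)
    }
  }
  invisible(TRUE)
}

## internal: parse the packed claims sub-field "code|text;code|text" into a
## list-column of claim tibbles
parse_claims <- function(packed, food_id) {
  purrr::map2(packed, food_id, function(cell, id) {
    if (is.na(cell) || !nzchar(trimws(cell))) {
      return(empty_claims())
    }
    parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    split2 <- strsplit(parts, "|", fixed = TRUE)
    tibble::tibble(
      claim_id = paste0(id, "#", seq_along(parts)),
      raw_text = vapply(split2, function(p) trimws(paste(p[-1], collapse = "|")),
                        character(1)),
      taxonomy_code = vapply(split2, function(p) trimws(p[[1]]), character(1)),
      resolved_type = NA_character_
    )
  })
}

empty_claims <- function() {
  tibble::tibble(claim_id = character(), raw_text = character(),
                 taxonomy_code = character(), resolved_type = character())
}

pack_claims <- function(claims) {
  vapply(claims, function(cl) {
    if (is.null(cl) || nrow(cl) == 0) return("")
    paste(ifelse(nzchar(cl$raw_text) & !is.na(cl$raw_text),
                 paste(cl$taxonomy_code, cl$raw_text, sep = "|"),
                 cl$taxonomy_code),
          collapse = ";")
  }, character(1))
}

#' Read a food-survey table
#'
#' Reads one row per sampled pre-packaged food. Empty nutrient cells become
#' missing values (an explicit 0 is a value, not missingness); when only one
#' of the two energy declarations is present the other is filled at
#' 4.184 kJ/kcal; claims arrive as a packed sub-field of semicolon-separated
#' taxonomy codes, each optionally followed by `|` and the on-pack text.
#'
#' @param path path to a UTF-8 CSV with header
#'   `food_id,country,store_type,name,eatwell_group,npsc_category,<nutrients>,claims`.
#' @param dialect optional [dialect()] describing column renames, a salt
#'   column, and the decimal separator.
#' @return a tibble of class `food_survey`, one row per food, with numeric
#'   panel columns (NA = missing) and a `claims` list-column of claim
#'   tibbles (`claim_id`, `raw_text`, `taxonomy_code`, `resolved_type`).
#' @export
read_food_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dialect <- dialect %||% dialect()
  loc <- readr::locale(decimal_mark = dialect$decimal_mark,
                       grouping_mark = if (dialect$decimal_mark == ",") "." else ",")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (length(dialect$rename)) {
    hits <- names(dialect$rename) %in% names(raw)
    names(raw)[match(names(dialect$rename)[hits], names(raw))] <-
      unname(dialect$rename[hits])
  }

  mandatory <- c("food_id", "country", "store_type", "eatwell_group",
                 "npsc_category")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    abort(paste0("mandatory columns absent: ", comma(missing_cols)))
  }

  dup <- which(duplicated(raw$food_id))
  if (length(dup)) validation_error("duplicate food_id", dup)
  bad <- which(!raw$country %in% COUNTRIES)
  if (length(bad)) validation_error("unknown country code", bad)
  bad <- which(!raw$store_type %in% STORE_TYPES)
  if (length(bad)) validation_error("unknown store_type", bad)
  bad <- which(!raw$eatwell_group %in% EATWELL_GROUPS)
  if (length(bad)) validation_error("unknown eatwell_group", bad)
  bad <- which(!raw$npsc_category %in% c("1", "2", "3"))
  if (length(bad)) validation_error("unknown npsc_category", bad)

  num <- function(col) {
    if (col %in% names(raw)) {
      readr::parse_double(dplyr::if_else(
        is.na(raw[[col]]) | !nzchar(trimws(raw[[col]])),
        NA_character_, raw[[col]]), locale = loc)
    } else {
      rep(NA_real_, nrow(raw))
    }
  }

  survey <- tibble::tibble(
    food_id = raw$food_id,
    country = raw$country,
    store_type = raw$store_type,
    name = if ("name" %in% names(raw)) raw$name else NA_character_,
    eatwell_group = raw$eatwell_group,
    npsc_category = as.integer(raw$npsc_category)
  )
  for (col in PANEL_COLS) survey[[col]] <- num(col)

  if (!is.null(dialect$salt_column) && dialect$salt_column %in% names(raw)) {
    salt <- readr::parse_double(raw[[dialect$salt_column]], locale = loc)
    fill <- is.na(survey$sodium_mg) & !is.na(salt)
    survey$sodium_mg[fill] <- salt[fill] / 2.5 * 1000
  }

  # reconcile energies: fill the absent unit from the other
  only_kcal <- is.na(survey$energy_kJ) & !is.na(survey$energy_kcal)
  survey$energy_kJ[only_kcal] <- survey$energy_kcal[only_kcal] * KJ_PER_KCAL
  only_kj <- is.na(survey$energy_kcal) & !is.na(survey$energy_kJ)
  survey$energy_kcal[only_kj] <- survey$energy_kJ[only_kj] / KJ_PER_KCAL

  validate_nutrient_panel(survey)

  survey$claims <- parse_claims(
    if ("claims" %in% names(raw)) raw$claims else rep(NA_character_, nrow(raw)),
    survey$food_id)
  class(survey) <- c("food_survey", class(survey))
  survey
}

#' Write a food-survey table
#'
#' Inverse of [read_food_table()]: claims are packed back into the
#' semicolon-separated sub-field. Reading the written file reproduces the
#' survey's identity, grouping, nutrient and claim content.
#'
#' @param survey a `food_survey` tibble.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_food_table <- function(survey, path) {
  out <- survey[intersect(c("food_id", "country", "store_type", "name",
                            "eatwell_group", "npsc_category", PANEL_COLS),
                          names(survey))]
  out$claims <- pack_claims(survey$claims)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a report table
#'
#' Writes a pipeline result table as CSV with numeric columns rendered at a
#' fixed precision. Overwrites idempotently.
#'
#' @param table a data frame produced by a pipeline stage (may be empty).
#' @param path output CSV path.
#' @param digits decimal places kept for numeric (double) columns.
#' @return invisibly, `path`.
#' @export
write_report_table <- function(table, path, digits = 4) {
  out <- dplyr::mutate(tibble::as_tibble(table), dplyr::across(
    dplyr::where(is.double), ~ round(.x, digits)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-nutrient provenance flags
#'
#' @param survey a `food_survey`, before or after [supplement()].
#' @return a tibble `food_id` x nutrient with values `"declared"`,
#'   `"supplemented"` or `"missing"`.
#' @export
provenance <- function(survey) {
  out <- tibble::tibble(food_id = survey$food_id)
  for (nut in NUTRIENTS) {
    prov_col <- paste0("prov_", nut)
    if (prov_col %in% names(survey)) {
      out[[nut]] <- survey[[prov_col]]
    } else {
      out[[nut]] <- ifelse(has_value(survey[[nut]]), "declared", "missing")
    }
  }
  out
}
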