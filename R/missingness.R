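#' Per-country missing-data audit
#'
#' Summarises the declared nutrient panels only (never supplemented
#' values): per country and nutrient, the count and percentage of foods
#' with no declaration; per country, the count of foods carrying no
#' nutritional information at all (such foods count as missing for every
#' nutrient); and overall, the share of foods missing at least one of the
#' eight selected nutrients.
#'
#' @param survey a `food_survey` tibble (non-empty).
#' @return an object of class `missingness_summary`: a list with
#'   `by_country` (tibble country x nutrient: `n_missing`, `pct_missing`),
#'   `no_information` (tibble per country: `n_no_info`, `pct_no_info`),
#'   and `overall` (list: `n_foods`, `pct_missing_any`, `pct_no_info`,
#'   per-nutrient total counts).
#' @export
missingness_summary <- function(survey) {
  if (nrow(survey) == 0) abort("missingness_summary needs a non-empty survey")
  panel <- as.matrix(survey[NUTRIENTS])
  miss <- is.na(panel)

  by_country <- tidyr::expand_grid(country = unique(survey$country),
                                   nutrient = NUTRIENTS)
  by_country <- dplyr::group_by(
    tidyr::pivot_longer(
      dplyr::bind_cols(survey["country"],
                       tibble::as_tibble(as.data.frame(miss))),
      -"country", names_to = "nutrient", values_to = "missing"),
    .data$country, .data$nutrient)
  by_country <- dplyr::summarise(by_country,
                                 n = dplyr::n(),
                                 n_missing = sum(.data$missing),
                                 pct_missing = 100 * mean(.data$missing),
                                 .groups = "drop")
  by_country$nutrient <- factor(by_country$nutrient, levels = NUTRIENTS)
  by_country <- dplyr::arrange(by_country, .data$country, .data$nutrient)

  no_info_flag <- rowSums(!miss) == 0
  no_information <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(country = survey$country,
                                   no_info = no_info_flag), .data$country),
    n = dplyr::n(),
    n_no_info = sum(.data$no_info),
    pct_no_info = 100 * mean(.data$no_info),
    .groups = "drop")

  overall <- list(
    n_foods = nrow(survey),
    n_missing_any = sum(rowSums(miss) > 0),
    pct_missing_any = 100 * mean(rowSums(miss) > 0),
    n_no_info = sum(no_info_flag),
    pct_no_info = 100 * mean(no_info_flag),
    pct_mean_nutrient = 100 * mean(colMeans(miss)),
    n_missing_by_nutrient = colSums(miss)
  )

  structure(list(by_country = by_country, no_information = no_information,
                 overall = overall),
            class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat("Missing-data audit of", x$overall$n_foods, "foods\n")
  cat(sprintf("  no nutritional information at all: %d (%.1f%%)\n",
              x$overall$n_no_info, x$overall$pct_no_info))
  cat(sprintf("  missing >=1 selected nutrient:     %d (%.1f%%)\n",
              x$overall$n_missing_any, x$overall$pct_missing_any))
  print(tidyr::pivot_wider(x$by_country[c("country", "nutrient", "n_missing")],
                           names_from = "country", values_from = "n_missing"))
  invisible(x)
}

#' Tabular view of a missingness summary
#'
#' @param summary a `missingness_summary`.
#' @return a long tibble suitable for [write_report_table()].
#' @export
missingness_table <- function(summary) {
  dplyr::bind_rows(
    dplyr::mutate(summary$by_country, nutrient = as.character(.data$nutrient)),
    dplyr::transmute(summary$no_information,
                     country = .data$country, nutrient = "none_declared",
                     n = .data$n, n_missing = .data$n_no_info,
                     pct_missing = .data$pct_no_info),
    tibble::tibble(country = "ALL", nutrient = "any_of_eight",
                   n = summary$overall$n_foods,
                   n_missing = summary$overall$n_missing_any,
                   pct_missing = summary$overall$pct_missing_any)
  )
}
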