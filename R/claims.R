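#' Load the taxonomy-code map
#'
#' @param path YAML file mapping annotation codes to `"health"` or
#'   `"nutrition"`; defaults to the map shipped with the package.
#' @return named character vector code -> type.
#' @export
load_taxonomy_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "taxonomy_map.yaml",
                                package = "nutriclaim")
  map <- unlist(yaml::read_yaml(path))
  bad <- setdiff(unique(map), c("health", "nutrition"))
  if (length(bad)) {
    abort(paste0("taxonomy map values must be 'health' or 'nutrition', got: ",
                 comma(bad)))
  }
  map
}

#' Load the exclusion-rule list
#'
#' @param path YAML file: an ordered list of rules, each with `id` and
#'   `keywords`; defaults to the rules shipped with the package.
#' @return list of rules, order preserved.
#' @export
load_exclusion_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exclusions.yaml",
                                package = "nutriclaim")
  rules <- yaml::read_yaml(path)
  stopifnot(all(vapply(rules, function(r)
    all(c("id", "keywords") %in% names(r)), logical(1))))
  rules
}

#' Screen a statement against the exclusion rules
#'
#' Applies the exclusion families in their listed order to normalised
#' (lower-cased, whitespace-collapsed) text: statements about natural /
#' organic / Halal status, additive absence, allergy advice, special
#' diets, storage, mere food presence, sport or cause advertising, and
#' nutrition-labelling schemes are not health-related claims. The first
#' matching rule wins.
#'
#' @param raw_text on-pack statement text (vectorised).
#' @param rules rules from [load_exclusion_rules()].
#' @return character vector: the matching rule id, or `"pass"`.
#' @export
#' @examples
#' exclusion_screen("Contains nuts")           # "allergy-advice"
#' exclusion_screen("stays fresh for longer")  # "storage-advice"
#' exclusion_screen("high in fibre")           # "pass"
exclusion_screen <- function(raw_text, rules = load_exclusion_rules()) {
  norm <- gsub("\\s+", " ", tolower(trimws(raw_text)))
  vapply(norm, function(txt) {
    if (is.na(txt) || !nzchar(txt)) return("pass")
    for (rule in rules) {
      if (any(vapply(rule$keywords, function(k) grepl(k, txt, fixed = TRUE),
                     logical(1)))) {
        return(rule$id)
      }
    }
    "pass"
  }, character(1), USE.NAMES = FALSE)
}

## internal: resolve one claim tibble
resolve_claim_tbl <- function(cl, map, rules) {
  if (nrow(cl) == 0) return(cl)
  unknown <- setdiff(unique(cl$taxonomy_code), names(map))
  if (length(unknown)) {
    abort(paste0("unknown taxonomy code(s): ", comma(unknown),
                 "; valid codes: ", comma(names(map))))
  }
  excluded <- exclusion_screen(cl$raw_text, rules) != "pass"
  cl$resolved_type <- ifelse(excluded, "not_claim", unname(map[cl$taxonomy_code]))
  cl
}

#' Resolve claim annotations into claim types
#'
#' Each claim record gets a `resolved_type`: excluded statements become
#' `not_claim` (exclusion precedes the taxonomy mapping); content and
#' comparative codes become `nutrition`; function, disease-risk-reduction
#' and general-health codes become `health`. Per-food indicator columns
#' `has_health_claim`, `has_nutrition_claim` and `has_any_claim` are added
#' (a food counts once per claim type regardless of claim multiplicity).
#'
#' @param survey a `food_survey` tibble.
#' @param map taxonomy map from [load_taxonomy_map()].
#' @param rules exclusion rules from [load_exclusion_rules()].
#' @return the survey with resolved claims and indicator columns.
#' @export
resolve_claims <- function(survey, map = load_taxonomy_map(),
                           rules = load_exclusion_rules()) {
  survey$claims <- purrr::map(survey$claims, resolve_claim_tbl,
                              map = map, rules = rules)
  survey$has_health_claim <- vapply(survey$claims, function(cl)
    any(cl$resolved_type == "health"), logical(1))
  survey$has_nutrition_claim <- vapply(survey$claims, function(cl)
    any(cl$resolved_type == "nutrition"), logical(1))
  survey$has_any_claim <- survey$has_health_claim | survey$has_nutrition_claim
  survey
}

#' Claim prevalence by food group
#'
#' Counts, proportions and Wald 95% confidence intervals of health,
#' nutrition and any-claim carriage per Eatwell group and in total.
#' Display percentages round halves up to integers.
#'
#' @param survey a `food_survey` after [resolve_claims()].
#' @return a `prevalence_table` tibble: `eatwell_group`, `claim_type`
#'   (health / nutrition / any), `k`, `n`, `prop`, `ci_low`, `ci_high`,
#'   and integer display columns `pct`, `pct_low`, `pct_high`.
#' @export
prevalence_by_group <- function(survey) {
  if (!"has_any_claim" %in% names(survey)) {
    abort("resolve claims first (resolve_claims())")
  }
  flags <- tibble::tibble(
    eatwell_group = survey$eatwell_group,
    health = survey$has_health_claim,
    nutrition = survey$has_nutrition_claim,
    any = survey$has_any_claim
  )
  long <- tidyr::pivot_longer(flags, -"eatwell_group",
                              names_to = "claim_type", values_to = "flag")
  per_group <- dplyr::summarise(
    dplyr::group_by(long, .data$eatwell_group, .data$claim_type),
    k = sum(.data$flag), n = dplyr::n(), .groups = "drop")
  total <- dplyr::summarise(dplyr::group_by(long, .data$claim_type),
                            k = sum(.data$flag), n = dplyr::n(),
                            .groups = "drop")
  total$eatwell_group <- "total"
  out <- dplyr::bind_rows(per_group, total[names(per_group)])
  ci <- wald_ci(out$k, out$n)
  out$prop <- ci$prop
  out$ci_low <- ci$ci_low
  out$ci_high <- ci$ci_high
  out$pct <- round_half_up(100 * out$prop)
  out$pct_low <- round_half_up(100 * out$ci_low)
  out$pct_high <- round_half_up(100 * out$ci_high)
  out$claim_type <- factor(out$claim_type,
                           levels = c("health", "nutrition", "any"))
  out <- dplyr::arrange(out, .data$eatwell_group == "total",
                        .data$eatwell_group, .data$claim_type)
  out$claim_type <- as.character(out$claim_type)
  class(out) <- c("prevalence_table", class(out))
  out
}
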