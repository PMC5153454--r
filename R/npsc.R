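#' Load an NPSC points table
#'
#' Band thresholds, protein-cap parameters and pass thresholds for the
#' FSANZ Nutrient Profiling Scoring Criterion. Defaults to the schedule
#' shipped with the package (FSA/Ofcom-derived bands; category-3
#' saturated-fat and sodium bands extended linearly to 30 points).
#'
#' @param path optional YAML file overriding the shipped table.
#' @param orientation `"standard"` applies the strictest pass threshold to
#'   beverages (category 1 fails above 0, category 2 above 3, category 3
#'   above 27); `"literal"` swaps categories 1 and 2. Overrides the file's
#'   own setting when supplied.
#' @return an object of class `npsc_points`.
#' @export
npsc_points <- function(path = NULL, orientation = NULL) {
  path <- path %||% system.file("extdata", "npsc_points.yaml",
                                package = "nutriclaim")
  pts <- yaml::read_yaml(path)
  pts$orientation <- orientation %||% pts$orientation %||% "standard"
  stopifnot(pts$orientation %in% c("standard", "literal"))
  if (pts$orientation == "literal") {
    tmp <- pts$fail_above[["1"]]
    pts$fail_above[["1"]] <- pts$fail_above[["2"]]
    pts$fail_above[["2"]] <- tmp
  }
  for (cat in c("1", "2", "3")) {
    for (nut in names(pts$baseline[[cat]])) {
      th <- as.numeric(unlist(pts$baseline[[cat]][[nut]]))
      pts$baseline[[cat]][[nut]] <- th
      if (is.unsorted(th, strictly = TRUE)) {
        abort(paste0("baseline thresholds for ", nut, " (category ", cat,
                     ") are not strictly increasing"),
              class = "nutriclaim_config_error")
      }
    }
  }
  pts$modifying$fvnl_percent$thresholds <-
    as.numeric(unlist(pts$modifying$fvnl_percent$thresholds))
  pts$modifying$fvnl_percent$points <-
    as.numeric(unlist(pts$modifying$fvnl_percent$points))
  for (nut in c("protein_g", "fibre_g")) {
    pts$modifying[[nut]] <- as.numeric(unlist(pts$modifying[[nut]]))
    if (is.unsorted(pts$modifying[[nut]], strictly = TRUE)) {
      abort(paste0("modifying thresholds for ", nut,
                   " are not strictly increasing"),
            class = "nutriclaim_config_error")
    }
  }
  structure(pts, class = "npsc_points")
}

#' Points from an ascending threshold list
#'
#' The band-lookup primitive of the NPSC: the points awarded to a nutrient
#' level are the number of thresholds strictly exceeded, so a value exactly
#' on a threshold scores the lower band.
#'
#' @param value non-negative nutrient level (vectorised).
#' @param thresholds strictly increasing numeric vector.
#' @return integer points, one per value.
#' @export
#' @examples
#' points_from_thresholds(1342.8, c(335, 670, 1005, 1340, 1675)) # 4
#' points_from_thresholds(335, c(335, 670))                      # 0
points_from_thresholds <- function(value, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly increasing",
          class = "nutriclaim_config_error")
  }
  vapply(value, function(v) {
    if (is.na(v)) return(NA_integer_)
    sum(v > thresholds)
  }, integer(1))
}

## internal: V points use a jump table (>40% -> 1, >60% -> 2, >80% -> 5)
fvnl_points <- function(fvnl, modifying) {
  idx <- points_from_thresholds(fvnl, modifying$fvnl_percent$thresholds)
  pts <- c(0, modifying$fvnl_percent$points)
  as.integer(pts[idx + 1L])
}

#' Score one nutrient panel with the FSANZ NPSC
#'
#' Baseline points (A) accrue for energy, saturated fat, total sugars and
#' sodium; modifying points (C = V + P + F) are deducted for
#' fruit/vegetable/nut/legume content, protein and fibre. Protein points
#' are suppressed when A >= 13 unless V >= 5 (the protein cap). The food
#' passes when the final score A - C does not exceed the category
#' threshold.
#'
#' @param panel named list or one-row data frame with `energy_kJ`,
#'   `saturated_fat_g`, `total_sugars_g`, `sodium_mg`, `protein_g`,
#'   `fibre_g` (all required) and optionally `fvnl_percent` (assumed 0 when
#'   absent, flagged in the result).
#' @param category NPSC food category: 1 beverages, 2 general foods,
#'   3 fats/oils/spreads/cheese.
#' @param points an [npsc_points()] table.
#' @return an `npsc_result` list: per-nutrient baseline points,
#'   `baseline_total`, `v_points`, `p_points`, `f_points`,
#'   `modifying_total`, `final_score`, `protein_capped`, `fvnl_assumed`,
#'   `passes`.
#' @export
npsc_score <- function(panel, category, points = npsc_points()) {
  stopifnot(category %in% 1:3)
  panel <- as.list(panel)
  required <- c("energy_kJ", "saturated_fat_g", "total_sugars_g", "sodium_mg",
                "protein_g", "fibre_g")
  vals <- lapply(required, function(n) panel[[n]] %||% NA_real_)
  names(vals) <- required
  absent <- required[vapply(vals, function(v) is.na(v), logical(1))]
  if (length(absent)) {
    abort(paste0("unscoreable: missing ", comma(absent)),
          class = "nutriclaim_unscoreable")
  }
  fvnl <- panel$fvnl_percent %||% NA_real_
  fvnl_assumed <- is.na(fvnl)
  if (fvnl_assumed) fvnl <- 0

  bands <- points$baseline[[as.character(category)]]
  baseline <- c(
    energy = points_from_thresholds(vals$energy_kJ, bands$energy_kJ),
    saturated_fat = points_from_thresholds(vals$saturated_fat_g,
                                           bands$saturated_fat_g),
    total_sugars = points_from_thresholds(vals$total_sugars_g,
                                          bands$total_sugars_g),
    sodium = points_from_thresholds(vals$sodium_mg, bands$sodium_mg)
  )
  a <- sum(baseline)

  v <- fvnl_points(fvnl, points$modifying)
  p <- points_from_thresholds(vals$protein_g, points$modifying$protein_g)
  f <- points_from_thresholds(vals$fibre_g, points$modifying$fibre_g)

  capped <- a >= points$protein_cap$baseline_cap &&
    v < points$protein_cap$v_release
  if (capped) p <- 0L

  score <- as.integer(a - (v + p + f))
  structure(list(
    category = as.integer(category),
    baseline_points = baseline,
    baseline_total = as.integer(a),
    v_points = v, p_points = p, f_points = f,
    modifying_total = as.integer(v + p + f),
    final_score = score,
    protein_capped = capped,
    fvnl_assumed = fvnl_assumed,
    passes = score <= points$fail_above[[as.character(category)]]
  ), class = "npsc_result")
}

#' @export
print.npsc_result <- function(x, ...) {
  cat(sprintf("FSANZ NPSC: category %d, score %d (%s)\n", x$category,
              x$final_score, if (x$passes) "passes" else "fails"))
  cat(sprintf("  baseline A = %d (energy %d, sat fat %d, sugars %d, sodium %d)\n",
              x$baseline_total, x$baseline_points[["energy"]],
              x$baseline_points[["saturated_fat"]],
              x$baseline_points[["total_sugars"]],
              x$baseline_points[["sodium"]]))
  cat(sprintf("  modifying C = %d (V %d, P %d%s, F %d)\n", x$modifying_total,
              x$v_points, x$p_points,
              if (x$protein_capped) " [capped]" else "", x$f_points))
  invisible(x)
}

#' Score every food in a survey
#'
#' Scores each record on its scoring panel (supplemented values where
#' present, declared otherwise). Foods with a required nutrient still
#' missing are collected as unscoreable, never raised as errors.
#'
#' @param survey a `food_survey`, normally after [supplement()].
#' @param points an [npsc_points()] table.
#' @return the survey with columns `npsc_scoreable`, `npsc_score`,
#'   `npsc_pass`, `npsc_baseline`, `npsc_v`, `npsc_p`, `npsc_f`,
#'   `npsc_protein_capped`, `npsc_fvnl_assumed` and
#'   `npsc_unscoreable_reason` (NA when scored).
#' @export
score_survey <- function(survey, points = npsc_points()) {
  panel <- scoring_panel(survey)
  n <- nrow(survey)
  survey$npsc_scoreable <- rep(FALSE, n)
  survey$npsc_score <- rep(NA_integer_, n)
  survey$npsc_pass <- rep(NA, n)
  survey$npsc_baseline <- rep(NA_integer_, n)
  survey$npsc_v <- rep(NA_integer_, n)
  survey$npsc_p <- rep(NA_integer_, n)
  survey$npsc_f <- rep(NA_integer_, n)
  survey$npsc_protein_capped <- rep(NA, n)
  survey$npsc_fvnl_assumed <- rep(NA, n)
  survey$npsc_unscoreable_reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      npsc_score(panel[i, ], survey$npsc_category[i], points),
      nutriclaim_unscoreable = function(e) e)
    if (inherits(res, "npsc_result")) {
      survey$npsc_scoreable[i] <- TRUE
      survey$npsc_score[i] <- res$final_score
      survey$npsc_pass[i] <- res$passes
      survey$npsc_baseline[i] <- res$baseline_total
      survey$npsc_v[i] <- res$v_points
      survey$npsc_p[i] <- res$p_points
      survey$npsc_f[i] <- res$f_points
      survey$npsc_protein_capped[i] <- res$protein_capped
      survey$npsc_fvnl_assumed[i] <- res$fvnl_assumed
    } else {
      survey$npsc_unscoreable_reason[i] <- conditionMessage(res)
    }
  }
  survey
}

#' The panel a food is scored on
#'
#' Supplemented values where supplementation has been run, declared values
#' otherwise.
#'
#' @param survey a `food_survey`.
#' @return tibble of the ten panel columns.
#' @export
scoring_panel <- function(survey) {
  out <- survey[PANEL_COLS]
  for (nut in NUTRIENTS) {
    supp_col <- paste0("supp_", nut)
    if (supp_col %in% names(survey)) out[[nut]] <- survey[[supp_col]]
  }
  if ("supp_energy_kJ" %in% names(survey)) {
    out$energy_kcal <- out$energy_kJ / KJ_PER_KCAL
  }
  out
}

#' NPSC pass proportions by country and claim status
#'
#' For each country and overall: the share of scoreable foods passing the
#' NPSC among all foods, claim-free foods, health-claim foods and
#' nutrition-claim foods, with Wald 95% confidence intervals. Empty strata
#' yield NA proportions.
#'
#' @param survey a scored, claim-resolved `food_survey`.
#' @return a `pass_table` tibble: `country`, `claim_group`, `k`, `n`,
#'   `prop`, `ci_low`, `ci_high`, `pct`, `pct_low`, `pct_high`.
#' @export
pass_proportions <- function(survey) {
  if (!"npsc_pass" %in% names(survey)) abort("score the survey first")
  if (!"has_any_claim" %in% names(survey)) abort("resolve claims first")
  scored <- survey[survey$npsc_scoreable, ]
  strata <- list(
    all = rep(TRUE, nrow(scored)),
    no_claim = !scored$has_any_claim,
    health_claim = scored$has_health_claim,
    nutrition_claim = scored$has_nutrition_claim
  )
  one_block <- function(sub_idx, country) {
    purrr::map_dfr(names(strata), function(gname) {
      sel <- strata[[gname]] & sub_idx
      n <- sum(sel)
      k <- sum(scored$npsc_pass[sel])
      tibble::tibble(country = country, claim_group = gname, k = k, n = n)
    })
  }
  blocks <- dplyr::bind_rows(
    purrr::map_dfr(sort(unique(scored$country)), function(cc)
      one_block(scored$country == cc, cc)),
    one_block(rep(TRUE, nrow(scored)), "total")
  )
  est <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    if (blocks$n[i] == 0) {
      tibble::tibble(prop = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    } else {
      wald_ci(blocks$k[i], blocks$n[i])[c("prop", "ci_low", "ci_high")]
    }
  })
  out <- dplyr::bind_cols(blocks, est)
  out$pct <- round_half_up(100 * out$prop)
  out$pct_low <- round_half_up(100 * out$ci_low)
  out$pct_high <- round_half_up(100 * out$ci_high)
  class(out) <- c("pass_table", class(out))
  out
}

#' Counterfactual claim flags restricted by the NPSC
#'
#' Emulates regulation of health claims by the NPSC: a food that carries a
#' health claim but does not pass the model is considered as not carrying
#' a claim. Returns a copy; the original flags are untouched.
#'
#' @param survey a scored, claim-resolved `food_survey`.
#' @return the survey with an added logical column
#'   `has_health_claim_npsc_restricted`.
#' @export
restrict_claims_by_npsc <- function(survey) {
  if (!all(c("npsc_pass", "has_health_claim") %in% names(survey))) {
    abort("survey must be scored and claim-resolved")
  }
  survey$has_health_claim_npsc_restricted <-
    survey$has_health_claim & !is.na(survey$npsc_pass) & survey$npsc_pass
  survey
}
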