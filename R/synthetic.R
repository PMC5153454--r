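## Default study conditions for the synthetic five-country survey: country
## sample sizes and missingness, Eatwell-group mix and per-group claim
## prevalences, per-group mean nutrient levels, and model-2 claim effects.

default_country_table <- function() {
  # per-country sample sizes, per-nutrient missing counts and counts of
  # foods with no nutritional information at all
  tibble::tribble(
    ~country, ~n, ~no_info,
    "DE", 399L, 54L,
    "NL", 416L, 41L,
    "ES", 405L, 57L,
    "SI", 416L, 128L,
    "UK", 398L, 31L
  )
}

default_missing_counts <- function() {
  m <- rbind(
    DE = c(55, 55, 55, 109, 55, 110, 123, 111),
    NL = c(41, 44, 43, 80, 42, 79, 103, 82),
    ES = c(62, 61, 61, 125, 61, 123, 161, 126),
    SI = c(128, 129, 129, 196, 131, 193, 217, 208),
    UK = c(32, 34, 33, 43, 33, 43, 49, 42)
  )
  colnames(m) <- NUTRIENTS
  m
}

default_group_table <- function() {
  tibble::tribble(
    ~eatwell_group, ~n_foods, ~n_health, ~n_nutrition,
    "bread_cereals_potatoes", 194L, 23L, 53L,
    "milk_dairy", 162L, 34L, 64L,
    "high_fat_sugar", 740L, 66L, 152L,
    "meat_fish_eggs_beans", 300L, 24L, 46L,
    "fruit_vegetables", 159L, 16L, 46L,
    "miscellaneous", 279L, 53L, 62L,
    "composite", 200L, 6L, 28L
  )
}

default_group_means <- function() {
  m <- rbind(
    bread_cereals_potatoes = c(1418.5, 9.1, 60.4, 8.4, 5.6, 1.9, 5.2, 267.3),
    milk_dairy = c(699.7, 9.3, 7.5, 6.7, 10.7, 6.0, 0.2, 273.9),
    high_fat_sugar = c(1342.8, 3.6, 40.3, 24.1, 16.2, 6.3, 1.7, 262.5),
    meat_fish_eggs_beans = c(1022.3, 16.6, 6.9, 1.5, 16.3, 4.6, 1.9, 809.7),
    fruit_vegetables = c(330.4, 1.8, 11.3, 8.9, 2.9, 0.6, 2.3, 201.5),
    miscellaneous = c(545.1, 3.8, 19.5, 11.1, 3.5, 1.5, 2.2, 2700.7),
    composite = c(713.2, 7.7, 16.7, 4.0, 7.8, 2.8, 1.5, 1021.2)
  )
  colnames(m) <- NUTRIENTS
  m
}

default_effects <- function() {
  list(
    health = c(energy_kJ = -121.9, protein_g = -1.2, carbohydrate_g = -0.7,
               total_sugars_g = -3.1, total_fat_g = -2.1,
               saturated_fat_g = -2.4, fibre_g = 0.8, sodium_mg = -842.4),
    nutrition = c(energy_kJ = -149.9, protein_g = -0.6, carbohydrate_g = 0.9,
                  total_sugars_g = -3.0, total_fat_g = -3.8,
                  saturated_fat_g = -2.6, fibre_g = 0.9, sodium_mg = -243.3)
  )
}

default_category_probs <- function() {
  # share of NPSC categories (1 beverage, 2 other, 3 fats/oils/cheese) per
  # Eatwell group: cheese within dairy, oils and spreads within the
  # fat/sugar group, some beverages among fat/sugar, fruit and
  # miscellaneous foods
  rbind(
    bread_cereals_potatoes = c(0.00, 1.00, 0.00),
    milk_dairy = c(0.10, 0.75, 0.15),
    high_fat_sugar = c(0.12, 0.80, 0.08),
    meat_fish_eggs_beans = c(0.00, 1.00, 0.00),
    fruit_vegetables = c(0.10, 0.90, 0.00),
    miscellaneous = c(0.10, 0.88, 0.02),
    composite = c(0.00, 1.00, 0.00)
  )
}

#' Configuration of the synthetic five-country survey
#'
#' The generator's defaults are the survey's study conditions: five
#' countries of 398-416 foods (75 from a discounter and 75 from a
#' neighbourhood store each, the rest from a supermarket), the observed
#' Eatwell-group mix and per-group health/nutrition-claim prevalences,
#' per-group mean nutrient levels, per-country missingness, and claim
#' effects equal to the category-adjusted (model-2) estimates the analysis
#' is designed to recover.
#'
#' @param seed integer RNG seed; identical seed and config give identical
#'   output.
#' @param cv coefficient of variation of the log-normal nutrient
#'   distributions.
#' @param beta_concentration concentration of the Beta fractions that draw
#'   total sugars within carbohydrate and saturated within total fat.
#' @param effects named list `health` / `nutrition` of additive within-group
#'   mean contrasts per nutrient (per 100 g units).
#' @param group_table,group_means,country_table,missing_counts,category_probs
#'   optional overrides of the default condition tables (see the package
#'   vignette for their layout).
#' @param fvnl_range range of the fruit/vegetable/nut/legume percentage
#'   drawn for fruit-and-vegetable foods (all other groups declare 0).
#' @return a `generator_config` list.
#' @export
survey_config <- function(seed = 1L,
                          cv = 0.8,
                          beta_concentration = 10,
                          effects = default_effects(),
                          group_table = default_group_table(),
                          group_means = default_group_means(),
                          country_table = default_country_table(),
                          missing_counts = default_missing_counts(),
                          category_probs = default_category_probs(),
                          fvnl_range = c(60, 100)) {
  stopifnot(cv > 0, beta_concentration > 0)
  cfg <- list(seed = as.integer(seed), cv = cv,
              beta_concentration = beta_concentration,
              effects = effects, group_table = group_table,
              group_means = group_means, country_table = country_table,
              missing_counts = missing_counts,
              category_probs = category_probs, fvnl_range = fvnl_range)
  cfg$group_table$prop <- cfg$group_table$n_foods / sum(cfg$group_table$n_foods)
  cfg$group_table$p_health <- cfg$group_table$n_health / cfg$group_table$n_foods
  cfg$group_table$p_nutrition <-
    cfg$group_table$n_nutrition / cfg$group_table$n_foods
  structure(cfg, class = "generator_config")
}

#' A confounded preset: claims concentrated in one healthy food group
#'
#' All within-group claim effects are zero, but claims appear almost only
#' on fruit-and-vegetable foods, so the unadjusted (model-1) contrast is
#' displaced from zero while the category-adjusted (model-2) contrast
#' covers it. Exercises the model-1 vs model-2 comparison.
#'
#' @param seed integer RNG seed.
#' @return a `generator_config`.
#' @export
confounded_config <- function(seed = 1L) {
  gt <- default_group_table()
  gt$n_health <- ifelse(gt$eatwell_group == "fruit_vegetables",
                        as.integer(round(0.5 * gt$n_foods)), 2L)
  gt$n_nutrition <- gt$n_health
  zero <- default_effects()
  zero$health[] <- 0
  zero$nutrition[] <- 0
  survey_config(seed = seed, effects = zero, group_table = gt)
}

## internal: solve the multiplicative factor f for one claim type and
## nutrient so that the claim-variance-weighted average of within-group
## mean contrasts m_g (f - 1) / (1 - p_g + p_g f) equals the target
## additive effect. f in (0, inf); targets below the weighted
## all-the-way-to-zero contrast are infeasible.
solve_effect_factor <- function(target, m_g, p_g, w_g) {
  if (target == 0 || sum(w_g) == 0) return(1)
  estimand <- function(f) {
    sum(w_g * m_g * (f - 1) / (1 - p_g + p_g * f)) / sum(w_g) - target
  }
  lower_lim <- sum(w_g * m_g * (-1) / (1 - p_g)) / sum(w_g)
  if (target <= lower_lim) {
    abort(paste0("infeasible config: effect ", format(target),
                 " implies a negative nutrient location (floor ",
                 format(lower_lim), ")"),
          class = "nutriclaim_infeasible_config")
  }
  stats::uniroot(estimand, lower = 1e-9, upper = 1e6, tol = 1e-12)$root
}

## internal: meanlog/sdlog of a log-normal with given mean and CV
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## internal: draw from a Beta with given mean and concentration
rbeta_mean <- function(n, mean, concentration) {
  mean <- pmin(pmax(mean, 1e-4), 1 - 1e-4)
  rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Generate a synthetic food survey with ground truth
#'
#' Foods are drawn by country x store x food-group strata; nutrient levels
#' come from log-normal distributions with group-specific means, with
#' total sugars drawn as a Beta fraction of carbohydrate and saturated fat
#' as a Beta fraction of total fat so panel invariants hold by
#' construction. Claim flags are Bernoulli per group (independently for
#' the two claim types); claim-bearing foods are drawn from shifted
#' distributions calibrated so that the category-adjusted regression
#' estimand equals each configured effect exactly. Missingness is applied
#' per country after the truth is captured.
#'
#' @param config a [survey_config()].
#' @return list with `records` (a `food_survey` with claims attached and
#'   missingness applied) and `truth` (list: `foods` — per-record true
#'   group, claim flags and pre-missingness panel; `effects` — the
#'   injected model-2 contrasts; `config`).
#' @export
generate_survey <- function(config = survey_config()) {
  set.seed(config$seed)
  gt <- config$group_table
  groups <- gt$eatwell_group
  means <- config$group_means[groups, , drop = FALSE]

  # pre-solve the effect injection (also validates feasibility before
  # sampling): positive targets enter as uniform additive within-group
  # shifts (the regression is then correctly specified); negative targets
  # enter as a single multiplicative factor per claim type, root-solved so
  # the claim-variance-weighted average of within-group contrasts equals
  # the configured effect exactly (a uniform negative shift would imply
  # negative nutrient levels in low-level food groups)
  w_h <- gt$n_foods * gt$p_health * (1 - gt$p_health)
  w_n <- gt$n_foods * gt$p_nutrition * (1 - gt$p_nutrition)
  f_health <- vapply(NUTRIENTS, function(nut) {
    eff <- config$effects$health[[nut]]
    if (eff > 0) 1 else solve_effect_factor(eff, means[, nut],
                                            gt$p_health, w_h)
  }, double(1))
  f_nutrition <- vapply(NUTRIENTS, function(nut) {
    eff <- config$effects$nutrition[[nut]]
    if (eff > 0) 1 else solve_effect_factor(eff, means[, nut],
                                            gt$p_nutrition, w_n)
  }, double(1))
  add_health <- vapply(NUTRIENTS, function(nut)
    max(0, config$effects$health[[nut]]), double(1))
  add_nutrition <- vapply(NUTRIENTS, function(nut)
    max(0, config$effects$nutrition[[nut]]), double(1))

  ct <- config$country_table
  n_total <- sum(ct$n)
  country <- rep(ct$country, ct$n)
  store_type <- unlist(lapply(ct$n, function(n)
    rep(c("supermarket", "discounter", "neighbourhood"),
        c(n - 150, 75, 75))))

  grp_idx <- sample.int(nrow(gt), n_total, replace = TRUE, prob = gt$prop)
  grp <- groups[grp_idx]
  has_health <- rbinom(n_total, 1, gt$p_health[grp_idx]) == 1
  has_nutrition <- rbinom(n_total, 1, gt$p_nutrition[grp_idx]) == 1

  npsc_category <- vapply(grp_idx, function(g)
    sample.int(3, 1, prob = config$category_probs[g, ]), integer(1))

  # per-record target means: base_g * f_H^h * f_N^nu, base_g solved so the
  # group marginal mean matches the configured (observed) group mean
  target <- matrix(NA_real_, n_total, length(NUTRIENTS),
                   dimnames = list(NULL, NUTRIENTS))
  for (nut in NUTRIENTS) {
    base_g <- means[, nut] /
      ((1 - gt$p_health + gt$p_health * f_health[nut]) *
         (1 - gt$p_nutrition + gt$p_nutrition * f_nutrition[nut]))
    target[, nut] <- base_g[grp_idx] *
      ifelse(has_health, f_health[nut], 1) *
      ifelse(has_nutrition, f_nutrition[nut], 1)
  }
  panel <- target
  for (nut in setdiff(NUTRIENTS, c("total_sugars_g", "saturated_fat_g"))) {
    pars <- lnorm_pars(target[, nut], config$cv)
    panel[, nut] <- stats::rlnorm(n_total, pars$meanlog, pars$sdlog)
  }
  # sugars as a Beta fraction of carbohydrate, saturated as a fraction of
  # total fat, fraction means taken from the cell target means: the draw is
  # independent of the realised carbohydrate/fat, so the nutrient mean is
  # preserved exactly and sugars <= carbohydrate by construction
  sug_frac <- rbeta_mean(n_total,
                         target[, "total_sugars_g"] / target[, "carbohydrate_g"],
                         config$beta_concentration)
  sat_frac <- rbeta_mean(n_total,
                         target[, "saturated_fat_g"] / target[, "total_fat_g"],
                         config$beta_concentration)
  panel[, "total_sugars_g"] <- sug_frac * panel[, "carbohydrate_g"]
  panel[, "saturated_fat_g"] <- sat_frac * panel[, "total_fat_g"]
  # positive effects are uniform additive shifts applied to the drawn
  # values (claim cells keep the baseline dispersion, and the shifted
  # panels remain positive and internally consistent)
  for (nut in NUTRIENTS) {
    shift <- add_health[nut] * has_health + add_nutrition[nut] * has_nutrition
    panel[, nut] <- panel[, nut] + shift
  }
  panel[, "total_sugars_g"] <- pmin(panel[, "total_sugars_g"],
                                    panel[, "carbohydrate_g"])
  panel[, "saturated_fat_g"] <- pmin(panel[, "saturated_fat_g"],
                                     panel[, "total_fat_g"])

  fvnl <- ifelse(grp == "fruit_vegetables",
                 runif(n_total, config$fvnl_range[1], config$fvnl_range[2]), 0)

  food_id <- sprintf("%s%04d", country, unlist(lapply(ct$n, seq_len)))
  truth_foods <- tibble::as_tibble(panel)
  truth_foods <- dplyr::bind_cols(
    tibble::tibble(food_id = food_id, country = country,
                   eatwell_group = grp, npsc_category = npsc_category,
                   has_health_claim = has_health,
                   has_nutrition_claim = has_nutrition,
                   fvnl_percent = fvnl),
    truth_foods)

  # missingness per country: a no-information share loses every nutrient;
  # the rest lose each nutrient at the conditional extra rate implied by
  # the configured per-nutrient counts
  declared <- panel
  mc <- config$missing_counts
  no_info <- rep(FALSE, n_total)
  for (i in seq_len(nrow(ct))) {
    idx <- which(country == ct$country[i])
    r0 <- ct$no_info[i] / ct$n[i]
    ni <- runif(length(idx)) < r0
    no_info[idx[ni]] <- TRUE
    # one uniform per food couples the per-nutrient indicators
    # (comonotone): labels that omit one minor nutrient tend to omit the
    # others too, so incomplete panels are nested, as on real packs
    u <- runif(length(idx))
    for (nut in NUTRIENTS) {
      extra <- max(0, (mc[ct$country[i], nut] - ct$no_info[i]) /
                     (ct$n[i] - ct$no_info[i]))
      drop <- !ni & u < extra
      declared[idx[drop], nut] <- NA_real_
    }
    declared[idx[ni], ] <- NA_real_
  }

  claims <- make_claim_lists(food_id, has_health, has_nutrition)

  records <- tibble::tibble(
    food_id = food_id, country = country, store_type = store_type,
    name = paste0("synthetic food ", food_id),
    eatwell_group = grp, npsc_category = npsc_category,
    energy_kJ = declared[, "energy_kJ"],
    energy_kcal = declared[, "energy_kJ"] / KJ_PER_KCAL,
    protein_g = declared[, "protein_g"],
    carbohydrate_g = declared[, "carbohydrate_g"],
    total_sugars_g = declared[, "total_sugars_g"],
    total_fat_g = declared[, "total_fat_g"],
    saturated_fat_g = declared[, "saturated_fat_g"],
    fibre_g = declared[, "fibre_g"],
    sodium_mg = declared[, "sodium_mg"],
    fvnl_percent = fvnl,
    claims = claims
  )
  class(records) <- c("food_survey", class(records))

  list(records = records,
       truth = list(foods = truth_foods, effects = config$effects,
                    factors = list(health = f_health,
                                   nutrition = f_nutrition,
                                   add_health = add_health,
                                   add_nutrition = add_nutrition),
                    config = config))
}

## internal: synthetic claim records with taxonomy codes that resolve to
## the intended types (texts avoid the exclusion keywords)
make_claim_lists <- function(food_id, has_health, has_nutrition) {
  health_codes <- c("nutrient-function", "disease-risk-reduction",
                    "general-health")
  health_texts <- c("calcium is needed for the maintenance of normal bones",
                    "helps lower cholesterol, a risk factor in heart disease",
                    "part of a healthy lifestyle")
  nutrition_texts <- c("high in fibre", "low fat", "source of protein",
                       "reduced sugars")
  purrr::pmap(list(food_id, has_health, has_nutrition), function(id, h, nu) {
    rows <- list()
    if (h) {
      pick <- sample.int(length(health_codes), 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        claim_id = NA_character_, raw_text = health_texts[pick],
        taxonomy_code = health_codes[pick], resolved_type = NA_character_)
    }
    if (nu) {
      pick <- sample.int(length(nutrition_texts), 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        claim_id = NA_character_, raw_text = nutrition_texts[pick],
        taxonomy_code = "nutrition-content", resolved_type = NA_character_)
    }
    if (!length(rows)) return(empty_claims())
    out <- dplyr::bind_rows(rows)
    out$claim_id <- paste0(id, "#", seq_len(nrow(out)))
    out
  })
}

#' Generate a matched reference databank
#'
#' One generic reference food per survey record: the pre-missingness truth
#' panel plus Gaussian noise with standard deviation equal to a fraction
#' of the per-nutrient standard deviation, floored at zero and capped so
#' reference panels satisfy the panel invariants. With noise fraction f the
#' expected declared-vs-reference Pearson correlation is
#' `1 / sqrt(1 + f^2)`; use `noise_for_target_r()` to aim at a target r.
#'
#' @param truth the `truth` element returned by [generate_survey()].
#' @param noise_sd_fraction scalar or named per-nutrient vector of noise
#'   fractions.
#' @param seed integer RNG seed.
#' @param target_r optional scalar or named per-nutrient vector of target
#'   declared-vs-reference Pearson correlations. When supplied, the noise
#'   fraction for each nutrient is root-solved so the realised correlation
#'   (after the zero floor and the consistency caps) hits the target; the
#'   closed-form `noise_for_target_r()` value is only the starting point,
#'   since flooring skewed nutrients at zero damps the attenuation.
#' @param declared optional survey records (with missingness applied).
#'   When supplied together with `target_r`, the calibration is computed
#'   on the declared pairs — the pairs [validate_matches()] measures —
#'   rather than the full truth panel; for heavy-tailed nutrients the two
#'   correlations can differ by a few hundredths.
#' @return list with `refs` (reference table) and `matches` (food_id,
#'   ref_id).
#' @export
generate_reference_databank <- function(truth, noise_sd_fraction = 0.3,
                                        seed = 1L, target_r = NULL,
                                        declared = NULL) {
  set.seed(seed)
  foods <- truth$foods
  n <- nrow(foods)
  frac <- if (length(noise_sd_fraction) == 1) {
    setNames(rep(noise_sd_fraction, length(NUTRIENTS)), NUTRIENTS)
  } else {
    stopifnot(all(NUTRIENTS %in% names(noise_sd_fraction)))
    noise_sd_fraction[NUTRIENTS]
  }
  if (!is.null(target_r)) {
    tr <- if (length(target_r) == 1) {
      setNames(rep(target_r, length(NUTRIENTS)), NUTRIENTS)
    } else {
      stopifnot(all(NUTRIENTS %in% names(target_r)))
      target_r[NUTRIENTS]
    }
  }
  refs <- tibble::tibble(ref_id = paste0("ref_", foods$food_id),
                         name = paste0("generic ", foods$food_id))
  # one fixed standard-normal draw per nutrient; the noise scale is then a
  # deterministic function of it, so target_r calibration stays reproducible
  partner <- c(total_sugars_g = "carbohydrate_g",
               saturated_fat_g = "total_fat_g")
  for (nut in NUTRIENTS) {
    x <- foods[[nut]]
    z <- rnorm(n)
    s <- sd(x)
    cap <- if (nut %in% names(partner)) refs[[partner[[nut]]]] else Inf
    make_col <- function(f) pmin(pmax(0, x + f * s * z), cap)
    keep <- if (is.null(declared)) rep(TRUE, n) else !is.na(declared[[nut]])
    if (is.null(target_r)) {
      refs[[nut]] <- make_col(frac[[nut]])
    } else if (tr[[nut]] >= 1) {
      refs[[nut]] <- x
    } else {
      f0 <- noise_for_target_r(tr[[nut]])
      f_hat <- stats::uniroot(
        function(f) cor(x[keep], make_col(f)[keep]) - tr[[nut]],
        lower = f0 / 10, upper = f0 * 20,
        extendInt = "downX", tol = 1e-6)$root
      refs[[nut]] <- make_col(f_hat)
    }
  }
  refs$total_sugars_g <- pmin(refs$total_sugars_g, refs$carbohydrate_g)
  refs$saturated_fat_g <- pmin(refs$saturated_fat_g, refs$total_fat_g)
  refs$energy_kcal <- refs$energy_kJ / KJ_PER_KCAL
  refs$fvnl_percent <- foods$fvnl_percent
  list(refs = refs,
       matches = tibble::tibble(food_id = foods$food_id,
                                ref_id = refs$ref_id))
}

#' Noise fraction that attenuates Pearson r to a target
#'
#' Inverts the attenuation relation `r = 1 / sqrt(1 + f^2)`.
#'
#' @param r target correlation in (0, 1).
#' @return noise fraction f.
#' @export
noise_for_target_r <- function(r) {
  stopifnot(all(r > 0), all(r < 1))
  sqrt(1 / r^2 - 1)
}
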