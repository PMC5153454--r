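pts <- npsc_points()

test_that("band lookup counts thresholds strictly exceeded", {
  bands <- c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350)
  expect_equal(points_from_thresholds(0, bands), 0L)
  expect_equal(points_from_thresholds(1342.8, bands), 4L)
  expect_equal(points_from_thresholds(335, bands), 0L)   # boundary: lower band
  expect_equal(points_from_thresholds(335.01, bands), 1L)
  expect_error(points_from_thresholds(1, c(3, 2, 1)), "strictly increasing")
})

test_that("hand-worked category-2 scores reproduce", {
  # mean panel of the fat/sugar food group: A = 4+6+5+2 = 17, P capped, F = 1
  high <- npsc_score(list(energy_kJ = 1342.8, saturated_fat_g = 6.3,
                          total_sugars_g = 24.1, sodium_mg = 262.5,
                          protein_g = 3.6, fibre_g = 1.7, fvnl_percent = 0),
                     category = 2, pts)
  expect_equal(high$baseline_total, 17L)
  expect_true(high$protein_capped)
  expect_equal(high$p_points, 0L)
  expect_equal(high$f_points, 1L)
  expect_equal(high$final_score, 16L)
  expect_false(high$passes)

  # mean fruit-and-vegetable panel: A = 3, V = 5, P = 1, F = 2, score -5
  fv <- npsc_score(list(energy_kJ = 330.4, saturated_fat_g = 0.6,
                        total_sugars_g = 8.9, sodium_mg = 201.5,
                        protein_g = 1.8, fibre_g = 2.3, fvnl_percent = 90),
                   category = 2, pts)
  expect_equal(fv$baseline_total, 3L)
  expect_equal(c(fv$v_points, fv$p_points, fv$f_points), c(5L, 1L, 2L))
  expect_equal(fv$final_score, -5L)
  expect_true(fv$passes)

  zero <- npsc_score(list(energy_kJ = 0, saturated_fat_g = 0,
                          total_sugars_g = 0, sodium_mg = 0, protein_g = 0,
                          fibre_g = 0), category = 2, pts)
  expect_equal(zero$final_score, 0L)
  expect_true(zero$passes)
  expect_true(zero$fvnl_assumed)
})

test_that("scores match an independent brute-force band counter", {
  withr::local_seed(2024)
  for (i in 1:1000) {
    p <- random_panel()
    category <- sample(1:3, 1)
    mine <- npsc_score(p, category, pts)
    ref <- brute_npsc(p$energy_kJ, p$saturated_fat_g, p$total_sugars_g,
                      p$sodium_mg, p$protein_g, p$fibre_g, p$fvnl_percent,
                      category)
    expect_identical(mine$final_score, as.integer(ref$score))
    expect_identical(mine$passes, ref$passes)
  }
})

test_that("scores are monotone in the expected directions", {
  withr::local_seed(99)
  for (i in 1:50) {
    p <- random_panel()
    s0 <- npsc_score(p, 2, pts)$final_score
    for (worse in c("energy_kJ", "saturated_fat_g", "total_sugars_g",
                    "sodium_mg")) {
      p2 <- p; p2[[worse]] <- p2[[worse]] * 1.5 + 10
      expect_gte(npsc_score(p2, 2, pts)$final_score, s0)
    }
    for (better in c("fibre_g", "fvnl_percent")) {
      p2 <- p; p2[[better]] <- min(if (better == "fvnl_percent") 100 else Inf,
                                   p2[[better]] * 1.5 + 1)
      expect_lte(npsc_score(p2, 2, pts)$final_score, s0)
    }
  }
})

test_that("protein contributes at most one point per band when uncapped", {
  base <- list(energy_kJ = 400, saturated_fat_g = 1, total_sugars_g = 5,
               sodium_mg = 100, protein_g = 0, fibre_g = 0, fvnl_percent = 0)
  prev <- npsc_score(base, 2, pts)$final_score
  for (prot in c(1.7, 3.3, 4.9, 6.5, 8.1)) {
    base$protein_g <- prot
    s <- npsc_score(base, 2, pts)$final_score
    expect_true((s - prev) %in% c(-1L, 0L))
    prev <- s
  }
})

test_that("passing flips exactly at the category threshold", {
  panel <- list(energy_kJ = 0, saturated_fat_g = 0, total_sugars_g = 0,
                sodium_mg = 0, protein_g = 0, fibre_g = 0, fvnl_percent = 0)
  for (category in c(1, 2, 3)) {
    limit <- c(0, 3, 27)[category]
    scores <- vapply(seq(0, 30), function(na_bands) {
      panel$sodium_mg <- 90 * na_bands + 1
      r <- npsc_score(panel, category, pts)
      as.integer(r$passes)
    }, integer(1))
    # sodium bands top out below some category-3 thresholds; check the flip
    observed_scores <- vapply(seq(0, 30), function(na_bands) {
      panel$sodium_mg <- 90 * na_bands + 1
      npsc_score(panel, category, pts)$final_score
    }, integer(1))
    expect_equal(scores, as.integer(observed_scores <= limit))
  }
})

test_that("category 3 admits foods that category 2 fails", {
  # spreadable cheese-like panel: category 2 scores 4+10+0+7 = 21 and
  # fails; category 3 scores 4+15+0+7 = 26 and passes (26 <= 27)
  butterish <- list(energy_kJ = 1500, saturated_fat_g = 15, total_sugars_g = 1,
                    sodium_mg = 700, protein_g = 0.5, fibre_g = 0,
                    fvnl_percent = 0)
  expect_false(npsc_score(butterish, 2, pts)$passes)
  expect_true(npsc_score(butterish, 3, pts)$passes)
})

test_that("the literal orientation swaps the beverage and food thresholds", {
  literal <- npsc_points(orientation = "literal")
  drinkish <- list(energy_kJ = 700, saturated_fat_g = 0, total_sugars_g = 0,
                   sodium_mg = 0, protein_g = 0, fibre_g = 0,
                   fvnl_percent = 0)  # two energy bands exceeded: score 2
  s_std <- npsc_score(drinkish, 1, pts)
  s_lit <- npsc_score(drinkish, 1, literal)
  expect_equal(s_std$final_score, 2L)
  expect_equal(s_lit$final_score, 2L)
  expect_false(s_std$passes)   # standard: beverages fail above 0
  expect_true(s_lit$passes)    # literal reading: drinks fail above 3
  # and the general-food threshold swaps the other way
  foodish <- npsc_score(drinkish, 2, literal)
  expect_false(foodish$passes)
  expect_true(npsc_score(drinkish, 2, pts)$passes)
})

test_that("batch scoring partitions into scored and unscoreable", {
  sv <- make_survey(3)
  sv$fibre_g[2] <- NA
  sv$protein_g[2] <- NA
  scored <- score_survey(sv)
  expect_equal(scored$npsc_scoreable, c(TRUE, FALSE, TRUE))
  expect_match(scored$npsc_unscoreable_reason[2], "protein_g, fibre_g")
  # order independence
  scored_rev <- score_survey(sv[3:1, ])
  expect_equal(scored_rev$npsc_score[3:1], scored$npsc_score)
})

test_that("missing required nutrients raise a named unscoreable error", {
  expect_error(npsc_score(list(energy_kJ = 100), 2, pts),
               "unscoreable: missing.*sodium_mg")
})

test_that("healthy-template foods all pass", {
  sv <- make_survey(20, group = "fruit_vegetables")
  sv$energy_kJ <- 300; sv$energy_kcal <- 300 / 4.184
  sv$saturated_fat_g <- 0.5; sv$total_sugars_g <- 4; sv$sodium_mg <- 50
  sv$total_fat_g <- 1; sv$carbohydrate_g <- 10
  sv$protein_g <- 1; sv$fibre_g <- 2; sv$fvnl_percent <- 90
  scored <- score_survey(sv)
  expect_true(all(scored$npsc_pass))
})

test_that("pass proportions reproduce printed-count arithmetic", {
  # 222 health-claim foods of which 156 pass, among 398 UK foods of which
  # 190 pass in total
  n <- 398
  sv <- make_survey(n, country = "UK")
  healthify <- function(sv, idx) {
    sv$energy_kJ[idx] <- 300; sv$saturated_fat_g[idx] <- 0.5
    sv$total_sugars_g[idx] <- 4; sv$sodium_mg[idx] <- 50
    sv$total_fat_g[idx] <- 1; sv$carbohydrate_g[idx] <- 10
    sv$protein_g[idx] <- 1; sv$fibre_g[idx] <- 2
    sv
  }
  unhealthify <- function(sv, idx) {
    sv$energy_kJ[idx] <- 2500; sv$saturated_fat_g[idx] <- 9
    sv$total_sugars_g[idx] <- 40; sv$sodium_mg[idx] <- 850
    sv$total_fat_g[idx] <- 20; sv$carbohydrate_g[idx] <- 45
    sv$protein_g[idx] <- 1; sv$fibre_g[idx] <- 0
    sv
  }
  sv <- healthify(sv, 1:190)
  sv <- unhealthify(sv, 191:n)
  for (i in 1:222) sv <- add_claim(sv, i, "general-health", "healthy inside")
  # 156 of the 222 health-claim foods pass (1:156 healthy, 157:222 not)
  sv <- unhealthify(sv, 157:190)
  sv <- healthify(sv, 223:(223 + (190 - 156) - 1))
  sv <- resolve_claims(sv)
  scored <- score_survey(sv)
  tab <- pass_proportions(scored)
  uk_all <- tab[tab$country == "UK" & tab$claim_group == "all", ]
  expect_equal(c(uk_all$k, uk_all$n), c(190, 398))
  expect_equal(c(uk_all$pct, uk_all$pct_low, uk_all$pct_high), c(48, 43, 53))
  health <- tab[tab$country == "total" & tab$claim_group == "health_claim", ]
  expect_equal(c(health$k, health$n), c(156, 222))
  expect_equal(c(health$pct, health$pct_low, health$pct_high), c(70, 64, 76))
})

test_that("degenerate pass tables keep their confidence intervals in range", {
  sv <- resolve_claims(make_survey(10, group = "fruit_vegetables"))
  sv$energy_kJ <- 100; sv$saturated_fat_g <- 0; sv$total_sugars_g <- 1
  sv$sodium_mg <- 10; sv$total_fat_g <- 0.2; sv$carbohydrate_g <- 5
  sv$protein_g <- 0.5; sv$fibre_g <- 2
  tab <- pass_proportions(score_survey(sv))
  all_row <- tab[tab$claim_group == "all" & tab$country == "total", ]
  expect_equal(c(all_row$pct, all_row$pct_low, all_row$pct_high),
               c(100, 100, 100))
  empty <- tab[tab$claim_group == "health_claim" & tab$country == "total", ]
  expect_true(is.na(empty$prop))
})

test_that("the NPSC counterfactual retains claims only for passers", {
  sv <- resolve_claims(add_claim(add_claim(make_survey(6), 1,
                                           "general-health", "good for you"),
                                 2, "general-health", "good for you"))
  scored <- score_survey(sv)
  scored$npsc_pass <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  out <- restrict_claims_by_npsc(scored)
  expect_equal(out$has_health_claim_npsc_restricted[1:2], c(TRUE, FALSE))
  expect_false(any(out$has_health_claim_npsc_restricted[3:6]))
  # original flags untouched
  expect_equal(out$has_health_claim, scored$has_health_claim)
})
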