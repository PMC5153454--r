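make_refs <- function(sv) {
  refs <- tibble::tibble(ref_id = paste0("r_", sv$food_id),
                         name = paste("generic", sv$food_id))
  for (nut in c("energy_kJ", "protein_g", "carbohydrate_g", "total_sugars_g",
                "total_fat_g", "saturated_fat_g", "fibre_g", "sodium_mg")) {
    refs[[nut]] <- sv[[nut]] + 1  # deliberately offset from declared
  }
  refs$energy_kcal <- refs$energy_kJ / 4.184
  list(refs = refs,
       matches = tibble::tibble(food_id = sv$food_id, ref_id = refs$ref_id))
}

test_that("supplement fills missing nutrients and never overwrites declared", {
  sv <- make_survey(4)
  declared_before <- sv[c("fibre_g", "sodium_mg")]
  sv$fibre_g[1] <- NA
  rm_ <- make_refs(make_survey(4))  # refs carry complete panels
  out <- supplement(sv, rm_$refs, rm_$matches)
  expect_equal(out$prov_fibre_g, c("supplemented", rep("declared", 3)))
  expect_equal(out$supp_fibre_g[1], rm_$refs$fibre_g[1])
  # declared sodium 50 stays even though the reference disagrees
  expect_equal(out$supp_sodium_mg, sv$sodium_mg)
  expect_equal(out$sodium_mg, declared_before$sodium_mg)
  # fully declared records pass through unchanged
  expect_equal(out$supp_energy_kJ, sv$energy_kJ)
  expect_true(all(out$prov_energy_kJ == "declared"))
})

test_that("unmatched records surface downstream as unscoreable", {
  sv <- make_survey(3)
  sv$fibre_g[2] <- NA
  rm_ <- make_refs(sv)
  rm_$matches <- rm_$matches[-2, ]
  out <- score_survey(supplement(sv, rm_$refs, rm_$matches))
  expect_equal(out$npsc_scoreable, c(TRUE, FALSE, TRUE))
  expect_equal(out$prov_fibre_g[2], "missing")
})

test_that("match validation recovers exact correlations", {
  sv <- make_survey(6)
  rm_ <- make_refs(sv)
  val <- validate_matches(sv, rm_$refs, rm_$matches)
  pooled <- val$correlations[val$correlations$country == "pooled", ]
  expect_true(all(abs(pooled$r - 1) < 1e-12))  # ref = declared + constant

  # exact linearity: declared (1,2,3) vs reference (2,4,6)
  sv3 <- make_survey(3)
  sv3$fibre_g <- c(1, 2, 3)
  rm3 <- make_refs(sv3)
  rm3$refs$fibre_g <- c(2, 4, 6)
  val3 <- validate_matches(sv3, rm3$refs, rm3$matches)
  fib <- val3$correlations
  expect_equal(fib$r[fib$nutrient == "fibre_g" & fib$country == "pooled"], 1)
})

test_that("correlations are undefined below 3 pairs or at zero variance", {
  sv <- make_survey(4)
  sv$fibre_g <- 2  # constant declared vector
  rm_ <- make_refs(sv)
  val <- validate_matches(sv, rm_$refs, rm_$matches)
  cors <- val$correlations
  expect_true(is.na(cors$r[cors$nutrient == "fibre_g" &
                             cors$country == "pooled"]))
  sv2 <- make_survey(2)
  rm2 <- make_refs(sv2)
  val2 <- validate_matches(sv2, rm2$refs, rm2$matches)
  expect_true(all(is.na(val2$correlations$r)))
  expect_true(all(val2$correlations$n == 2))
})

test_that("pooled pair counts equal the sum over countries", {
  g <- generate_survey(survey_config(seed = 5))
  db <- generate_reference_databank(g$truth, 0.3, seed = 6)
  val <- validate_matches(g$records, db$refs, db$matches)
  cors <- val$correlations
  for (nut in unique(cors$nutrient)) {
    sub <- cors[cors$nutrient == nut, ]
    expect_equal(sub$n[sub$country == "pooled"],
                 sum(sub$n[sub$country != "pooled"]))
  }
})

test_that("databank noise attenuates pooled r as 1/sqrt(1+f^2)", {
  g <- generate_survey(survey_config(seed = 31))
  db <- generate_reference_databank(g$truth, 0.3, seed = 32)
  val <- validate_matches(g$records, db$refs, db$matches)
  cors <- val$correlations
  r_energy <- cors$r[cors$nutrient == "energy_kJ" & cors$country == "pooled"]
  expect_gt(r_energy, 0.93)
  expect_lt(r_energy, 0.97)
})

test_that("outlier flagging reports discordant pairs without amending", {
  sv <- make_survey(30)
  rm_ <- make_refs(sv)
  withr::local_seed(1)
  rm_$refs$sodium_mg <- sv$sodium_mg + rnorm(30, sd = 5)
  rm_$refs$sodium_mg[5] <- sv$sodium_mg[5] + 1e5
  val <- validate_matches(sv, rm_$refs, rm_$matches)
  expect_true(sv$food_id[5] %in%
                val$outliers$food_id[val$outliers$nutrient == "sodium_mg"])
  expect_equal(sv$sodium_mg[5], make_survey(30)$sodium_mg[5])
})

test_that("amendments patch declared values from a reviewed file", {
  sv <- make_survey(3)
  patched <- apply_amendments(sv, tibble::tibble(
    food_id = "F002", nutrient = "sodium_mg", amended_value = 123,
    reason = "unit error on pack"))
  expect_equal(patched$sodium_mg[2], 123)
  expect_equal(patched$sodium_mg[-2], sv$sodium_mg[-2])
})

test_that("kappa agreement matches hand-computed values", {
  a <- rep(c(TRUE, FALSE), c(50, 50))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
  k <- kappa_agreement(a, b)
  expect_equal(k$agreement, 0.8)
  expect_equal(k$kappa, 0.6)  # (0.8 - 0.5) / (1 - 0.5)

  ident <- kappa_agreement(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(ident$kappa, 1)
  expect_equal(ident$agreement, 1)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::local_seed(7)
  a <- runif(500) < 0.4
  b <- ifelse(runif(500) < 0.8, a, runif(500) < 0.5)
  mine <- kappa_agreement(a, b)
  ref <- e1071::classAgreement(table(a, b))
  expect_equal(mine$kappa, ref$kappa, tolerance = 1e-12)
  expect_equal(mine$agreement, ref$diag, tolerance = 1e-12)
})

test_that("kappa is near zero for independent raters and bounded by agreement", {
  withr::local_seed(123)
  a <- runif(10000) < 0.5
  b <- runif(10000) < 0.5
  k <- kappa_agreement(a, b)
  expect_lt(abs(k$kappa), 0.03)
  expect_lte(k$kappa, k$agreement)
  # invariant under swapping the label symbols
  k_swap <- kappa_agreement(!a, !b)
  expect_equal(k_swap$kappa, k$kappa, tolerance = 1e-12)
})

test_that("constant equal raters give undefined kappa at full agreement", {
  k <- kappa_agreement(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(is.na(k$kappa))
  expect_equal(k$agreement, 1)
})
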