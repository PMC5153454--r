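# In-code fixtures shared across the suite.

survey_header <- paste(
  "food_id,country,store_type,name,eatwell_group,npsc_category,energy_kJ",
  "energy_kcal,protein_g,carbohydrate_g,total_sugars_g,total_fat_g",
  "saturated_fat_g,fibre_g,sodium_mg,fvnl_percent,claims", sep = ",")

write_survey_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                                .local_envir = parent.frame())) {
  writeLines(c(survey_header, rows), path)
  path
}

# A small complete in-code survey: every nutrient declared.
make_survey <- function(n = 6, country = "UK", group = "high_fat_sugar",
                        category = 2) {
  tibble::tibble(
    food_id = sprintf("F%03d", seq_len(n)),
    country = rep_len(country, n),
    store_type = "supermarket",
    name = paste("food", seq_len(n)),
    eatwell_group = rep_len(group, n),
    npsc_category = rep_len(as.integer(category), n),
    energy_kJ = seq(300, 1500, length.out = n),
    energy_kcal = seq(300, 1500, length.out = n) / 4.184,
    protein_g = seq(1, 10, length.out = n),
    carbohydrate_g = seq(10, 50, length.out = n),
    total_sugars_g = seq(2, 20, length.out = n),
    total_fat_g = seq(1, 20, length.out = n),
    saturated_fat_g = seq(0.5, 8, length.out = n),
    fibre_g = seq(0.5, 5, length.out = n),
    sodium_mg = seq(50, 900, length.out = n),
    fvnl_percent = 0,
    claims = replicate(n, tibble::tibble(
      claim_id = character(), raw_text = character(),
      taxonomy_code = character(), resolved_type = character()),
      simplify = FALSE)
  )
}

add_claim <- function(survey, i, code, text = "") {
  survey$claims[[i]] <- dplyr::bind_rows(
    survey$claims[[i]],
    tibble::tibble(claim_id = paste0(survey$food_id[i], "#x"),
                   raw_text = text, taxonomy_code = code,
                   resolved_type = NA_character_))
  survey
}

# Independent brute-force FSANZ NPSC scorer: literal band counting with the
# published FSA/Ofcom schedule written out long-hand. Shares no code with
# the package implementation.
brute_npsc <- function(energy, satfat, sugars, sodium, protein, fibre, fvnl,
                       category) {
  count_over <- function(v, cuts) {
    k <- 0
    for (c in cuts) if (v > c) k <- k + 1
    k
  }
  e_cuts <- c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350)
  s_cuts <- c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45)
  if (category == 3) {
    sf_cuts <- 1:30
    na_cuts <- 90 * (1:30)
  } else {
    sf_cuts <- 1:10
    na_cuts <- 90 * (1:10)
  }
  a <- count_over(energy, e_cuts) + count_over(satfat, sf_cuts) +
    count_over(sugars, s_cuts) + count_over(sodium, na_cuts)
  v <- 0
  if (fvnl > 80) v <- 5 else if (fvnl > 60) v <- 2 else if (fvnl > 40) v <- 1
  p <- count_over(protein, c(1.6, 3.2, 4.8, 6.4, 8.0))
  f <- count_over(fibre, c(0.9, 1.9, 2.8, 3.7, 4.7))
  if (a >= 13 && v < 5) p <- 0
  score <- a - (v + p + f)
  limit <- if (category == 1) 0 else if (category == 2) 3 else 27
  list(score = score, passes = score <= limit)
}

random_panel <- function() {
  list(energy_kJ = runif(1, 0, 4000),
       saturated_fat_g = runif(1, 0, 35),
       total_sugars_g = runif(1, 0, 50),
       sodium_mg = runif(1, 0, 3000),
       protein_g = runif(1, 0, 12),
       fibre_g = runif(1, 0, 8),
       fvnl_percent = sample(c(0, runif(1, 0, 100)), 1))
}
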