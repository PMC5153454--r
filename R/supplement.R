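#' Read a reference food-composition table
#'
#' @param path CSV with columns `ref_id`, `name` (optional) and the
#'   canonical nutrient columns; every entry must carry all eight selected
#'   nutrients (generic databank foods are complete by construction).
#' @return tibble of reference foods.
#' @export
read_reference_table <- function(path) {
  refs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"ref_id" %in% names(refs)) abort("reference table needs a ref_id column")
  missing_cols <- setdiff(NUTRIENTS, names(refs))
  if (length(missing_cols)) {
    abort(paste0("reference table lacks nutrient columns: ",
                 comma(missing_cols)))
  }
  incomplete <- which(!complete.cases(refs[NUTRIENTS]))
  if (length(incomplete)) {
    validation_error("reference foods with missing nutrients", incomplete)
  }
  if (!"energy_kcal" %in% names(refs)) {
    refs$energy_kcal <- refs$energy_kJ / KJ_PER_KCAL
  }
  refs
}

#' Read a survey-to-databank match table
#'
#' @param path CSV with columns `food_id`, `ref_id` (expert manual matches;
#'   this package validates matches, it does not create them).
#' @return tibble with one row per matched food.
#' @export
read_match_table <- function(path) {
  matches <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("food_id", "ref_id") %in% names(matches))) {
    abort("match table needs food_id and ref_id columns")
  }
  dup <- which(duplicated(matches$food_id))
  if (length(dup)) validation_error("food_id matched more than once", dup)
  matches
}

#' Fill missing nutrients from the matched databank entries
#'
#' Each nutrient missing from the declared panel is filled from the
#' matched reference food and flagged `"supplemented"`; declared values are
#' never overwritten. Supplemented panels feed NPSC scoring only — the
#' nutrient-level comparisons read declared panels throughout. Foods that
#' still miss a required nutrient (for example, unmatched foods) surface
#' downstream as unscoreable.
#'
#' @param survey a `food_survey`.
#' @param refs reference table from [read_reference_table()] or
#'   [generate_reference_databank()].
#' @param matches match table (`food_id`, `ref_id`).
#' @return the survey with added columns `supp_<nutrient>` (scoring values)
#'   and `prov_<nutrient>` (`"declared"`, `"supplemented"` or `"missing"`).
#' @export
supplement <- function(survey, refs, matches) {
  ref_rows <- match(matches$ref_id[match(survey$food_id, matches$food_id)],
                    refs$ref_id)
  for (nut in c(NUTRIENTS, "fvnl_percent")) {
    declared <- survey[[nut]]
    ref_vals <- if (nut %in% names(refs)) refs[[nut]][ref_rows] else NA_real_
    filled <- ifelse(is.na(declared), ref_vals, declared)
    survey[[paste0("supp_", nut)]] <- filled
    survey[[paste0("prov_", nut)]] <- dplyr::case_when(
      !is.na(declared) ~ "declared",
      !is.na(ref_vals) ~ "supplemented",
      TRUE ~ "missing"
    )
  }
  survey
}

#' Validate databank matches by per-nutrient correlation
#'
#' Pearson correlation between declared and matched reference values,
#' computed only on foods where both exist, per nutrient within each
#' country and pooled. Pairs whose absolute difference exceeds
#' `k_outlier` times the IQR of the paired differences are flagged for
#' human review (flagging never amends values; amendments are a
#' user-supplied patch file, see [apply_amendments()]).
#'
#' @param survey a `food_survey`.
#' @param refs reference table.
#' @param matches match table.
#' @param k_outlier IQR multiplier for outlier flagging.
#' @return a `match_validation` list: `correlations` (tibble nutrient x
#'   country plus `"pooled"` rows: `r`, `n`; `r` is NA when fewer than 3
#'   pairs or a vector is constant) and `outliers` (tibble `food_id`,
#'   `nutrient`, `declared`, `reference`).
#' @export
validate_matches <- function(survey, refs, matches, k_outlier = 3) {
  ref_rows <- match(matches$ref_id[match(survey$food_id, matches$food_id)],
                    refs$ref_id)
  cor_cell <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(r = NA_real_, n = n))
    }
    tibble::tibble(r = cor(x[ok], y[ok]), n = n)
  }
  out <- list(); outliers <- list()
  for (nut in NUTRIENTS) {
    declared <- survey[[nut]]
    reference <- refs[[nut]][ref_rows]
    for (cc in c(sort(unique(survey$country)), "pooled")) {
      idx <- if (cc == "pooled") rep(TRUE, nrow(survey)) else survey$country == cc
      cell <- cor_cell(declared[idx], reference[idx])
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(nutrient = nut, country = cc), cell)
    }
    ok <- !is.na(declared) & !is.na(reference)
    d <- declared[ok] - reference[ok]
    spread <- IQR(d)
    if (spread > 0) {
      flag <- abs(d) > k_outlier * spread
      if (any(flag)) {
        outliers[[length(outliers) + 1L]] <- tibble::tibble(
          food_id = survey$food_id[ok][flag], nutrient = nut,
          declared = declared[ok][flag], reference = reference[ok][flag])
      }
    }
  }
  structure(list(correlations = dplyr::bind_rows(out),
                 outliers = if (length(outliers)) dplyr::bind_rows(outliers)
                            else tibble::tibble(food_id = character(),
                                                nutrient = character(),
                                                declared = double(),
                                                reference = double())),
            class = "match_validation")
}

#' @export
print.match_validation <- function(x, ...) {
  pooled <- x$correlations[x$correlations$country == "pooled", ]
  cat("Databank match validation (pooled Pearson r):\n")
  for (i in seq_len(nrow(pooled))) {
    cat(sprintf("  %-16s r = %s (n = %d)\n", pooled$nutrient[i],
                formatC(pooled$r[i], digits = 3, format = "f"), pooled$n[i]))
  }
  cat(nrow(x$outliers), "flagged outlier pair(s)\n")
  invisible(x)
}

#' Apply human-reviewed amendments to declared values
#'
#' @param survey a `food_survey`.
#' @param patches tibble or CSV path with columns `food_id`, `nutrient`,
#'   `amended_value`, `reason`.
#' @return the survey with amended declared values.
#' @export
apply_amendments <- function(survey, patches) {
  if (is.character(patches)) {
    patches <- readr::read_csv(patches, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(all(c("food_id", "nutrient", "amended_value") %in% names(patches)))
  for (i in seq_len(nrow(patches))) {
    row <- match(patches$food_id[i], survey$food_id)
    nut <- patches$nutrient[i]
    if (is.na(row) || !nut %in% names(survey)) {
      warn(paste0("amendment skipped: ", patches$food_id[i], " / ", nut))
      next
    }
    survey[[nut]][row] <- patches$amended_value[i]
  }
  validate_nutrient_panel(survey)
  survey
}

#' Agreement between two pass/fail classifications
#'
#' Observed agreement and Cohen's kappa, `(p_o - p_e) / (1 - p_e)`, with
#' chance agreement `p_e` from the marginal products. Used to compare NPSC
#' classifications produced under alternative reference databanks.
#'
#' @param flags_a,flags_b logical (or two-level) vectors of equal length.
#' @param se `"large-sample"` for the asymptotic standard error, or
#'   `"bootstrap"` (`boot_reps` resamples).
#' @param boot_reps bootstrap replicates when `se = "bootstrap"`.
#' @return list with `agreement` (proportion observed, `p_o`), `kappa`
#'   (NA with 100% agreement when both raters are constant and equal),
#'   `se`, `n`.
#' @export
#' @examples
#' kappa_agreement(rep(c(TRUE, FALSE), c(50, 50)),
#'                 rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40)))
kappa_agreement <- function(flags_a, flags_b,
                            se = c("large-sample", "bootstrap"),
                            boot_reps = 1000) {
  se <- match.arg(se)
  stopifnot(length(flags_a) == length(flags_b), length(flags_a) >= 1)
  a <- as.logical(flags_a); b <- as.logical(flags_b)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (p_e >= 1) {
    return(list(agreement = p_o, kappa = NA_real_, se = NA_real_, n = n))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se_val <- if (se == "large-sample") {
    sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  } else {
    reps <- vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      po <- mean(a[idx] == b[idx])
      pe <- mean(a[idx]) * mean(b[idx]) + mean(!a[idx]) * mean(!b[idx])
      if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
    }, double(1))
    sd(reps, na.rm = TRUE)
  }
  list(agreement = p_o, kappa = kappa, se = se_val, n = n)
}
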