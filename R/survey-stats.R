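#' Mann-Whitney rank test
#'
#' U statistic from midrank sums. For small samples (n1 + n2 <= 12) the
#' p-value is computed by exact enumeration of all group assignments of
#' the pooled midranks (ties permitted); otherwise by the normal
#' approximation with tie-corrected variance. Two-sided throughout.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit total sample size at or below which enumeration is
#'   used.
#' @return a `rank_test` list: `statistic` (U for `x`), `z` (NA in exact
#'   mode), `p_value`, `n` (group sizes), `ties_corrected`,
#'   `method` ("exact" or "normal").
#' @export
mann_whitney <- function(x, y, exact_limit = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (length(unique(pooled)) == 1) {
    res <- list(statistic = u, z = 0, p_value = 1, n = c(n1, n2),
                ties_corrected = TRUE, method = "degenerate")
    class(res) <- "rank_test"
    return(res)
  }

  if (n <= exact_limit) {
    # enumerate which pooled positions go to sample 1; U distribution over
    # all C(n, n1) equally likely assignments, midranks kept fixed
    assignments <- combn(n, n1)
    u_all <- apply(assignments, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    ge <- mean(u_all >= u); le <- mean(u_all <= u)
    p <- min(1, 2 * min(ge, le))
    res <- list(statistic = u, z = NA_real_, p_value = p, n = c(n1, n2),
                ties_corrected = has_ties, method = "exact")
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    # continuity-corrected z (the statistic takes integer/half-integer steps)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    res <- list(statistic = u, z = z, p_value = p, n = c(n1, n2),
                ties_corrected = has_ties, method = "normal")
  }
  class(res) <- "rank_test"
  res
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference distribution on
#' (number of groups - 1) degrees of freedom, via [stats::kruskal.test()].
#'
#' @param groups list of two or more non-empty numeric samples.
#' @return a `rank_test` list: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) abort("kruskal_wallis needs at least 2 groups")
  if (any(lengths(groups) == 0)) abort("all groups must be non-empty")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    res <- list(statistic = 0, df = length(groups) - 1, p_value = 1,
                n = lengths(groups), ties_corrected = TRUE)
  } else {
    kt <- kruskal.test(values, g)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value, n = lengths(groups),
                ties_corrected = TRUE)
  }
  class(res) <- "rank_test"
  res
}

#' @export
print.rank_test <- function(x, ...) {
  stat_name <- if (!is.null(x$df)) "H" else "U"
  cat(sprintf("%s = %.4g, p = %.4g (n = %s)\n", stat_name, x$statistic,
              x$p_value, comma(x$n)))
  invisible(x)
}

#' Claim-effect estimate, optionally adjusted for food category
#'
#' Least-squares regression of a per-100 g nutrient level on a claim
#' indicator; model 2 additionally adjusts for the seven Eatwell food
#' groups via indicator terms with the largest group as the reference
#' level (the reference choice does not affect the claim coefficient).
#' Complete-case per nutrient.
#'
#' @param outcome numeric nutrient vector (declared values).
#' @param claim_flag logical claim indicator.
#' @param food_group factor or character of Eatwell groups (required for
#'   model 2).
#' @param model 1 (unadjusted) or 2 (category-adjusted).
#' @param conf_level confidence level for the interval.
#' @return an `adjusted_difference` tibble: `model`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `n`.
#' @export
adjusted_difference <- function(outcome, claim_flag, food_group = NULL,
                                model = 2, conf_level = 0.95) {
  stopifnot(model %in% c(1, 2))
  keep <- !is.na(outcome) & !is.na(claim_flag)
  if (model == 2) {
    if (is.null(food_group)) abort("model 2 needs food_group")
    keep <- keep & !is.na(food_group)
  }
  outcome <- outcome[keep]; claim <- as.logical(claim_flag)[keep]
  if (model == 2) {
    fg <- factor(food_group[keep])
    if (nlevels(droplevels(fg)) > 1) {
      fg <- stats::relevel(droplevels(fg),
                           ref = names(which.max(table(droplevels(fg)))))
      fit <- lm(outcome ~ claim + fg)
    } else {
      fit <- lm(outcome ~ claim)
    }
  } else {
    fit <- lm(outcome ~ claim)
  }
  if (any(is.na(coef(fit)))) {
    abort("rank-deficient design: claim status is collinear with food group",
          class = "nutriclaim_rank_deficiency")
  }
  est <- coef(fit)[["claimTRUE"]]
  smry <- summary(fit)$coefficients
  ci <- confint(fit, "claimTRUE", level = conf_level)
  out <- tibble::tibble(
    model = model,
    estimate = est,
    ci_low = ci[1], ci_high = ci[2],
    p_value = smry["claimTRUE", "Pr(>|t|)"],
    n = length(outcome)
  )
  class(out) <- c("adjusted_difference", class(out))
  out
}

#' Wald binomial confidence interval
#'
#' `p_hat +/- 1.96 * sqrt(p_hat (1 - p_hat) / n)`, clipped to \[0, 1\].
#' Display percentages round halves up to integers, reproducing printed
#' survey tables.
#'
#' @param k successes (vectorised).
#' @param n trials (>= 1).
#' @param conf_level confidence level.
#' @return tibble: `k`, `n`, `prop`, `ci_low`, `ci_high`, `pct`,
#'   `pct_low`, `pct_high`.
#' @export
#' @examples
#' wald_ci(222, 2034) # 11% (10%, 12%)
wald_ci <- function(k, n, conf_level = 0.95) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  tibble::tibble(
    k = k, n = n, prop = p,
    ci_low = pmax(0, p - half), ci_high = pmin(1, p + half),
    pct = round_half_up(100 * p),
    pct_low = round_half_up(100 * pmax(0, p - half)),
    pct_high = round_half_up(100 * pmin(1, p + half))
  )
}

#' Two-proportion z test
#'
#' Pooled-variance normal test of H0: p1 = p2 (two-sided), the standard
#' binomial test for comparing pass proportions between claim groups.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z`, `p_value`, `estimate` (p1 - p2).
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  p1 <- k1 / n1; p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  v <- pooled * (1 - pooled) * (1 / n1 + 1 / n2)
  if (v == 0) {
    return(list(z = 0, p_value = 1, estimate = p1 - p2))
  }
  z <- (p1 - p2) / sqrt(v)
  list(z = z, p_value = 2 * pnorm(-abs(z)), estimate = p1 - p2)
}

#' Design precision: half-width of a prevalence confidence interval
#'
#' The survey's sample-size rationale: with n foods per country and an
#' assumed prevalence p, a 95% interval extends
#' `100 * 1.96 * sqrt(p (1 - p) / n)` percentage points either side
#' (worst case at p = 0.5; n = 400 gives about +/-5 points).
#'
#' @param n per-country sample size.
#' @param p assumed prevalence in \[0, 1\].
#' @return half-width in percentage points.
#' @export
#' @examples
#' precision_half_width(400, 0.5) # 4.9
precision_half_width <- function(n, p = 0.5) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  100 * qnorm(0.975) * sqrt(p * (1 - p) / n)
}
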