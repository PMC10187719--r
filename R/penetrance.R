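#' Define a penetrance stratum
#'
#' @param label row label.
#' @param bin_col binning column (\code{"QUINTILE"} or \code{"DECILE"}), or
#'   \code{NULL} for APOE-only strata.
#' @param bin bin value selecting the stratum (e.g. 5 = top quintile).
#' @param apoe \code{"carrier"}, \code{"noncarrier"} or \code{"any"}.
#' @return list of class \code{stratum_rule}.
#' @export
stratum_rule <- function(label, bin_col = NULL, bin = NULL,
                         apoe = c("any", "carrier", "noncarrier")) {
  apoe <- match.arg(apoe)
  structure(list(label = label, bin_col = bin_col, bin = bin, apoe = apoe),
            class = "stratum_rule")
}

match_stratum <- function(cohort, rule) {
  sel <- rep(TRUE, nrow(cohort))
  if (!is.null(rule$bin_col)) sel <- sel & cohort[[rule$bin_col]] == rule$bin
  if (rule$apoe == "carrier") sel <- sel & cohort$apoe_e4
  if (rule$apoe == "noncarrier") sel <- sel & !cohort$apoe_e4
  sel & !is.na(sel)
}

#' Stratum penetrance table
#'
#' For each stratum rule, the proportion affected among cohort members
#' matching the rule (the crude, age-unadjusted penetrance), with counts.
#'
#' @param cohort cohort with bins and APOE carrier status assigned.
#' @param rules list of [stratum_rule()]s.
#' @param scope \code{"everyone"} or \code{"sibships"} (restricts to siblings).
#' @return data.frame: label, n, n_affected, penetrance (NA when n = 0).
#' @export
stratum_penetrance <- function(cohort, rules, scope = c("everyone", "sibships")) {
  scope <- match.arg(scope)
  if (scope == "sibships") cohort <- cohort[cohort$role == "sibling", , drop = FALSE]
  rows <- lapply(rules, function(r) {
    sel <- match_stratum(cohort, r)
    n <- sum(sel); k <- sum(cohort$affected[sel])
    data.frame(label = r$label, n = n, n_affected = k,
               penetrance = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Discordant sibling-pair statistic
#'
#' Among affection-discordant pairs, the fraction in which the affected
#' sibling has the strictly higher PRS. Optional stratum restriction: a pair
#' qualifies when its higher-PRS member lies in the stated quantile bin, and
#' (for APOE strata) both siblings share the stated carrier status. Exact PRS
#' ties are dropped from numerator and denominator.
#'
#' @param pairs pair table from [sample_one_pair()] or [sample_max_pairs()].
#' @param bin_col \code{"quintile"} or \code{"decile"} (pair-table bin of the
#'   higher-PRS member), or \code{NULL} for no bin restriction.
#' @param bin bin value (e.g. 5 with \code{"quintile"} = highest quintile).
#' @param apoe \code{"any"}, \code{"both_carriers"} or \code{"both_noncarriers"}.
#' @return proportion in [0, 1], or \code{NA} if no pair qualifies.
#' @export
discordant_pair_stat <- function(pairs, bin_col = NULL, bin = NULL,
                                 apoe = c("any", "both_carriers", "both_noncarriers")) {
  apoe <- match.arg(apoe)
  sel <- pairs$discordant & !pairs$prs_tie
  if (!is.null(bin_col)) {
    col <- paste0(tolower(bin_col), "_higher")
    sel <- sel & pairs[[col]] == bin
  }
  if (apoe == "both_carriers") sel <- sel & pairs$both_e4
  if (apoe == "both_noncarriers") sel <- sel & pairs$neither_e4
  sel <- sel & !is.na(sel)
  if (!any(sel)) return(NA_real_)
  mean(pairs$affected_higher[sel])
}

#' Pearson correlation of PRS between siblings
#'
#' Within-pair ordering is randomized (fixed by \code{seed}) so the estimate
#' is not biased by the pair-construction order; the two-sided p-value comes
#' from the usual t reference.
#'
#' @param pairs pair table.
#' @param seed seed for the within-pair coin flips.
#' @return list with \code{r}, \code{p}, \code{n}; \code{r = NA} (flagged via
#'   \code{degenerate = TRUE}) under zero variance or n < 3.
#' @export
sibling_prs_correlation <- function(pairs, seed = 1L) {
  set.seed(seed)
  x <- pairs$prs_a; y <- pairs$prs_b
  swap <- stats::runif(length(x)) < 0.5
  tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), degenerate = TRUE))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), degenerate = FALSE)
}

#' Sibling concordance of extreme percentile ranks
#'
#' For each threshold \code{p}, among ordered pairs whose index sibling has a
#' percentile rank in the top \code{p} fraction of the cohort, the fraction of
#' co-siblings also in the top \code{p}. Each qualifying sibling of a pair
#' serves once as index.
#'
#' @param pairs pair table (percentile ranks computed on the full cohort).
#' @param thresholds top fractions, default 1%, 5%, 10%, 20%.
#' @return data.frame: threshold, n_index, concordance (NA when no index
#'   sibling qualifies).
#' @export
percentile_concordance <- function(pairs, thresholds = c(0.01, 0.05, 0.10, 0.20)) {
  idx <- c(pairs$pctile_a, pairs$pctile_b)
  cos <- c(pairs$pctile_b, pairs$pctile_a)
  rows <- lapply(thresholds, function(p) {
    qual <- !is.na(idx) & idx > 1 - p
    data.frame(threshold = p, n_index = sum(qual),
               concordance = if (any(qual)) mean(cos[qual] > 1 - p) else NA_real_)
  })
  do.call(rbind, rows)
}

nagelkerke_r2 <- function(fit_full, fit_null) {
  n <- stats::nobs(fit_full)
  ll1 <- as.numeric(stats::logLik(fit_full))
  ll0 <- as.numeric(stats::logLik(fit_null))
  cs <- 1 - exp(-2 * (ll1 - ll0) / n)
  cs / (1 - exp(2 * ll0 / n))
}

#' Logistic association of affection with a polygenic score
#'
#' Fits \code{affected ~ score + age + sex + PCs} by logistic regression,
#' optionally within an APOE-e4 carrier stratum. The score is standardized
#' within the analysis sample so the odds ratio is per SD. Variance explained
#' is the Nagelkerke pseudo-R2 of the score model against the covariate-only
#' model. Complete-quasi separation is flagged and refit with a small ridge
#' penalty (no Wald interval in that case).
#'
#' @param cohort scored cohort.
#' @param score_col score column, \code{"PRS_STD"} or \code{"PRS_AD_STD"}.
#' @param apoe_filter \code{"any"}, \code{"carrier"} or \code{"noncarrier"}.
#' @param k_pcs number of PC covariates.
#' @return list of class \code{assoc_result}: or, ci (length 2), p, r2, n,
#'   separated, model label.
#' @export
fit_ad_association <- function(cohort, score_col = "PRS_STD",
                               apoe_filter = c("any", "carrier", "noncarrier"),
                               k_pcs = 3) {
  apoe_filter <- match.arg(apoe_filter)
  d <- cohort
  if (apoe_filter == "carrier") d <- d[d$apoe_e4, , drop = FALSE]
  if (apoe_filter == "noncarrier") d <- d[!d$apoe_e4, , drop = FALSE]
  pcn <- paste0("PC", seq_len(k_pcs))
  d <- d[stats::complete.cases(d[, c(score_col, "affected", "age", "sex", pcn)]), ]
  score <- d[[score_col]]
  score <- (score - mean(score)) / stats::sd(score)
  X <- data.frame(y = d$affected, score = score, age = d$age, sex = d$sex,
                  d[, pcn, drop = FALSE])
  fit <- stats::glm(y ~ ., data = X, family = stats::binomial())
  fit0 <- stats::glm(y ~ . - score, data = X, family = stats::binomial())
  co <- summary(fit)$coefficients["score", ]
  separated <- !fit$converged || abs(co["Estimate"]) > 10 ||
    any(fit$fitted.values > 1 - 1e-10) && any(fit$fitted.values < 1e-10)
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    Xm <- as.matrix(X[, -1])
    pen <- glmnet::glmnet(Xm, X$y, family = "binomial", alpha = 0, lambda = 1e-3)
    b <- as.numeric(stats::coef(pen))[2]
    res <- list(or = exp(b), ci = c(NA_real_, NA_real_), p = NA_real_,
                r2 = nagelkerke_r2(fit, fit0), n = nrow(X),
                separated = TRUE, model = score_col, apoe_filter = apoe_filter)
    class(res) <- "assoc_result"
    return(res)
  }
  ci <- exp(co["Estimate"] + c(-1, 1) * 1.96 * co["Std. Error"])
  res <- list(or = exp(unname(co["Estimate"])), ci = unname(ci),
              p = unname(co["Pr(>|z|)"]),
              r2 = nagelkerke_r2(fit, fit0), n = nrow(X),
              separated = separated, model = score_col, apoe_filter = apoe_filter)
  class(res) <- "assoc_result"
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s (%s): OR per SD %.3f (%.3f-%.3f), p = %.3g, Nagelkerke R2 = %.4f, n = %d%s\n",
              x$model, x$apoe_filter, x$or, x$ci[1], x$ci[2], x$p, x$r2, x$n,
              if (isTRUE(x$separated)) " [separation: penalized fit]" else ""))
  invisible(x)
}

#' Linear model of age at onset on a polygenic score
#'
#' Among affected individuals, regresses onset age on the standardized score
#' plus principal components, and reports the per-SD effect in years, its
#' p-value, and the mean onset age in the highest and lowest score quintiles.
#'
#' @param cohort scored cohort (uses its \code{QUINTILE} column for the group
#'   means).
#' @param score_col score column.
#' @param k_pcs number of PC covariates.
#' @return list: effect_per_sd (years), p, n, mean_aao_top_quintile,
#'   mean_aao_bottom_quintile.
#' @export
fit_aao_model <- function(cohort, score_col = "PRS_STD", k_pcs = 3) {
  cases <- cohort[cohort$affected, , drop = FALSE]
  if (nrow(cases) < 10) stop("fewer than 10 affected individuals: refusing to fit onset model")
  pcn <- paste0("PC", seq_len(k_pcs))
  score <- cases[[score_col]]
  score <- (score - mean(score)) / stats::sd(score)
  X <- data.frame(aao = cases$age, score = score, cases[, pcn, drop = FALSE])
  fit <- stats::lm(aao ~ ., data = X)
  co <- summary(fit)$coefficients["score", ]
  list(effect_per_sd = unname(co["Estimate"]), p = unname(co["Pr(>|t|)"]),
       n = nrow(cases),
       mean_aao_top_quintile = mean(cases$age[cases$QUINTILE == 5]),
       mean_aao_bottom_quintile = mean(cases$age[cases$QUINTILE == 1]))
}
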