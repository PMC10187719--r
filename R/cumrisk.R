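km_risk <- function(age, affected, times, weights = NULL) {
  if (length(age) == 0 || sum(affected) == 0) return(rep(0, length(times)))
  df <- data.frame(age = age, affected = as.integer(affected))
  if (is.null(weights)) weights <- rep(1, nrow(df))
  fit <- survival::survfit(survival::Surv(age, affected) ~ 1, data = df,
                           weights = weights)
  s <- summary(fit, times = times, extend = TRUE)$surv
  1 - s
}

stabilized_ipw <- function(cohort, member, covariates) {
  X <- data.frame(g = member, cohort[, covariates, drop = FALSE])
  fit <- stats::glm(g ~ ., data = X, family = stats::binomial())
  phat <- pmin(pmax(stats::fitted(fit), 1e-6), 1 - 1e-6)
  mean(member) / phat
}

#' Age-specific cumulative penetrance curve for a carrier group
#'
#' Product-limit (Kaplan-Meier-type) cumulative incidence \code{1 - S(age)}
#' within a group (e.g. the highest PRS quintile as "carriers"), with
#' unaffected individuals right-censored at their last examination age.
#' Covariate adjustment uses stabilized inverse-probability weights from a
#' logistic model of group membership on the covariates. The pointwise
#' confidence band comes from a nonparametric bootstrap resampling whole
#' families (unrelated individuals are their own resampling units).
#'
#' @param cohort cohort with \code{affected}, \code{age}, \code{fid} columns.
#' @param group logical vector over cohort rows, or a [stratum_rule()].
#' @param covariates character vector of covariate column names (e.g.
#'   \code{c("sex", "PC1", "PC2", "PC3")}), or \code{NULL} for unweighted.
#' @param ages evaluation grid (years).
#' @param n_boot bootstrap resamples for the band (0 disables the band).
#' @param conf band level.
#' @param seed bootstrap seed.
#' @param label group label carried on the result.
#' @return list of class \code{risk_curve}: age, risk, lower, upper, n_group,
#'   n_events, label.
#' @export
cumulative_penetrance_curve <- function(cohort, group, covariates = NULL,
                                        ages = 60:95, n_boot = 200,
                                        conf = 0.95, seed = 1L, label = "group") {
  if (inherits(group, "stratum_rule")) group <- match_stratum(cohort, group)
  stopifnot(length(group) == nrow(cohort))
  curve_of <- function(d, g) {
    w <- if (is.null(covariates)) NULL else stabilized_ipw(d, g, covariates)[g]
    km_risk(d$age[g], d$affected[g], ages, weights = w)
  }
  risk <- curve_of(cohort, group)
  lower <- upper <- rep(NA_real_, length(ages))
  if (n_boot > 0) {
    set.seed(seed)
    units <- split(seq_len(nrow(cohort)), cohort$fid)
    boot <- matrix(NA_real_, n_boot, length(ages))
    for (b in seq_len(n_boot)) {
      take <- unlist(units[sample(length(units), replace = TRUE)], use.names = FALSE)
      boot[b, ] <- curve_of(cohort[take, , drop = FALSE], group[take])
    }
    a <- (1 - conf) / 2
    lower <- apply(boot, 2, stats::quantile, probs = a, na.rm = TRUE)
    upper <- apply(boot, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  }
  structure(list(age = ages, risk = risk, lower = lower, upper = upper,
                 n_group = sum(group), n_events = sum(cohort$affected[group]),
                 label = label, n_boot = n_boot),
            class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("risk_curve '%s': n = %d, events = %d, ages %d-%d\n",
              x$label, x$n_group, x$n_events, min(x$age), max(x$age)))
  show <- x$age %% 5 == 0
  print(data.frame(age = x$age[show], risk = round(x$risk[show], 4),
                   lower = round(x$lower[show], 4), upper = round(x$upper[show], 4)))
  invisible(x)
}

#' Permutation test for cumulative-risk differences between two groups
#'
#' Compares product-limit cumulative-incidence estimates of two groups at the
#' requested ages. Under the null, the affection label is permuted jointly with
#' its event/censoring age (each individual's \code{(affected, age)} record
#' stays intact) across the pooled two-group sample, preserving the pooled age
#' distribution. Two-sided p-values use the absolute risk difference with the
#' add-one correction \code{p = (1 + #\{|null| >= |obs|\}) / (1 + n_perm)}.
#'
#' @param cohort cohort data.frame.
#' @param group_a,group_b logical vectors (disjoint) or [stratum_rule()]s.
#' @param ages ages at which the difference is tested.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed permutation seed.
#' @return list of class \code{group_comparison}: ages, risk_a, risk_b,
#'   observed (difference), p (per age), null (n_perm x ages matrix), n_perm.
#' @export
permutation_test <- function(cohort, group_a, group_b, ages = c(65, 70, 75, 80, 85),
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (inherits(group_a, "stratum_rule")) group_a <- match_stratum(cohort, group_a)
  if (inherits(group_b, "stratum_rule")) group_b <- match_stratum(cohort, group_b)
  if (any(group_a & group_b)) stop("groups must be disjoint")
  da <- cohort[group_a, c("affected", "age")]
  db <- cohort[group_b, c("affected", "age")]
  if (sum(da$affected) < 2 || sum(db$affected) < 2)
    stop("fewer than 2 events in a group: refusing to test")
  risk_a <- km_risk(da$age, da$affected, ages)
  risk_b <- km_risk(db$age, db$affected, ages)
  observed <- risk_a - risk_b
  pool <- rbind(da, db)
  na <- nrow(da)
  set.seed(seed)
  null <- matrix(NA_real_, n_perm, length(ages))
  for (i in seq_len(n_perm)) {
    pa <- sample(nrow(pool), na)
    null[i, ] <- km_risk(pool$age[pa], pool$affected[pa], ages) -
      km_risk(pool$age[-pa], pool$affected[-pa], ages)
  }
  p <- vapply(seq_along(ages), function(k)
    (1 + sum(abs(null[, k]) >= abs(observed[k]))) / (1 + n_perm), numeric(1))
  structure(list(ages = ages, risk_a = risk_a, risk_b = risk_b,
                 observed = observed, p = p, null = null, n_perm = n_perm),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(data.frame(age = x$ages, risk_a = round(x$risk_a, 4),
                   risk_b = round(x$risk_b, 4),
                   difference = round(x$observed, 4), p = signif(x$p, 3)))
  invisible(x)
}
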