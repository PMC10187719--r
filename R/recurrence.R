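#' Liability-threshold sibling recurrence risk
#'
#' Computes the probability that a relative of a proband is affected, given
#' that the proband's standardized polygenic score lies above a percentile of
#' the population score distribution, under the classical liability-threshold
#' model: disease occurs when a unit-variance latent liability exceeds the
#' threshold \eqn{T = \Phi^{-1}(1 - K)} set by the population prevalence
#' \eqn{K}. The score explains a fraction \code{r2} of liability variance and
#' is correlated \code{rho} between the proband and the relative (0.5 for full
#' siblings under additive inheritance).
#'
#' The proband's score component \eqn{x} is Normal(0, \code{r2}) truncated to
#' \eqn{x > \Phi^{-1}(q)\sqrt{r2}}. Conditional on \eqn{x}, the relative's
#' liability is Normal(\eqn{\rho x}, \eqn{1 - \rho^2 r2}), so the recurrence
#' risk is the expectation over the truncated proband distribution of
#' \deqn{\Phi\!\left(\frac{\rho x - T}{\sqrt{1 - \rho^2 r2}}\right),}
#' evaluated by adaptive quadrature.
#'
#' @param K population (or age-band) prevalence, in (0, 1).
#' @param r2 fraction of liability variance explained by the score, in [0, 1).
#' @param q proband percentile threshold in (0, 1); e.g. 0.80 conditions on a
#'   proband in the top quintile of the score distribution.
#' @param rho score correlation between proband and relative; default 0.5
#'   (full siblings).
#' @param rel_tol relative tolerance of the quadrature.
#' @return recurrence risk, a single probability.
#' @examples
#' # top-quintile proband, 13% prevalence, score explaining 6.8% of liability
#' liability_recurrence(K = 0.13, r2 = 0.068, q = 0.80)
#' # uninformative score: risk equals prevalence
#' liability_recurrence(K = 0.13, r2 = 0, q = 0.80)
#' @export
liability_recurrence <- function(K, r2, q, rho = 0.5, rel_tol = 1e-10) {
  stopifnot(length(K) == 1L, length(r2) == 1L, length(q) == 1L, length(rho) == 1L)
  if (!is.finite(K) || K <= 0 || K >= 1) stop("K must be in (0, 1)")
  if (!is.finite(r2) || r2 < 0 || r2 >= 1) stop("r2 must be in [0, 1)")
  if (!is.finite(q) || q <= 0 || q >= 1) stop("q must be in (0, 1), exclusive")
  if (rho^2 * r2 >= 1) stop("rho^2 * r2 must be < 1")
  T_liab <- stats::qnorm(1 - K)
  if (r2 == 0 || rho == 0) {
    # score carries no information about the relative's liability
    return(K)
  }
  s <- sqrt(r2)
  lo <- stats::qnorm(q) * s
  denom <- sqrt(1 - rho^2 * r2)
  f <- function(x) stats::dnorm(x, mean = 0, sd = s) * stats::pnorm((rho * x - T_liab) / denom)
  num <- stats::integrate(f, lower = lo, upper = Inf,
                          rel.tol = rel_tol, abs.tol = 1e-12)$value
  num / (1 - q)
}

#' Recurrence-risk table over prevalences, score r2 values and percentiles
#'
#' Evaluates [liability_recurrence()] on the full grid of prevalence values
#' (e.g. age-band prevalences), score variance fractions (e.g. the PRS and the
#' APOE-inclusive PRS), and proband percentile thresholds.
#'
#' @param prevalence named numeric vector of prevalences K; names label the
#'   rows (e.g. age bands).
#' @param r2 named numeric vector of liability variance fractions; names label
#'   the score variants (e.g. \code{c(PRS = 0.068, PRS.AD = 0.12)}).
#' @param percentiles proband percentile thresholds, defaults to the
#'   99th/95th/90th/80th percentiles.
#' @param rho sibling score correlation.
#' @param digits optional rounding of the risk columns; \code{NULL} leaves the
#'   quadrature values unrounded.
#' @return data.frame with one row per (prevalence, score) combination and one
#'   risk column per percentile.
#' @export
recurrence_table <- function(prevalence, r2,
                             percentiles = c(0.99, 0.95, 0.90, 0.80),
                             rho = 0.5, digits = NULL) {
  if (is.null(names(prevalence))) names(prevalence) <- paste0("K=", prevalence)
  if (is.null(names(r2))) names(r2) <- paste0("r2=", r2)
  grid <- expand.grid(score = names(r2), band = names(prevalence),
                      stringsAsFactors = FALSE)
  # order: band-major to mirror the usual presentation (band rows, score sub-rows)
  grid <- grid[order(match(grid$band, names(prevalence)),
                     match(grid$score, names(r2))), , drop = FALSE]
  risks <- vapply(seq_len(nrow(grid)), function(i) {
    vapply(percentiles, function(p)
      liability_recurrence(K = prevalence[[grid$band[i]]],
                           r2 = r2[[grid$score[i]]], q = p, rho = rho),
      numeric(1))
  }, numeric(length(percentiles)))
  risks <- t(matrix(risks, nrow = length(percentiles)))
  if (!is.null(digits)) risks <- round(risks, digits)
  colnames(risks) <- paste0("pct_", format(100 * percentiles, trim = TRUE))
  out <- cbind(data.frame(band = grid$band,
                          prevalence = unname(prevalence[grid$band]),
                          score = grid$score,
                          r2 = unname(r2[grid$score])),
               as.data.frame(risks))
  rownames(out) <- NULL
  out
}

#' Empirical sibling recurrence among pairs with an affected high-risk older sibling
#'
#' Within replicate sibling-pair sets, computes the proportion of younger
#' siblings affected when the older sibling is affected and carries the stated
#' risk class (top score quintile, APOE-e4 carrier, or non-carrier). Replicates
#' are drawn with [replicate_estimate()] under either pairing strategy.
#'
#' @param cohort a scored cohort (see [score_cohort()]); needs \code{QUINTILE},
#'   \code{apoe_e4}, \code{affected}, \code{age} columns.
#' @param rule one of \code{"prs_top_quintile"}, \code{"apoe_e4_carrier"},
#'   \code{"apoe_e4_noncarrier"}.
#' @param strategy pairing strategy, \code{"one_per_family"} or \code{"max_pairs"}.
#' @param n_rep number of replicate pair sets.
#' @param seed integer seed.
#' @return a \code{replicate_summary} (see [replicate_estimate()]).
#' @export
empirical_recurrence <- function(cohort, rule = c("prs_top_quintile",
                                                  "apoe_e4_carrier",
                                                  "apoe_e4_noncarrier"),
                                 strategy = c("one_per_family", "max_pairs"),
                                 n_rep = 100, seed = 1L) {
  rule <- match.arg(rule)
  strategy <- match.arg(strategy)
  stat <- function(pairs) {
    if (nrow(pairs) == 0) return(NA_real_)
    older_aff <- pairs$affected_older
    qual <- switch(rule,
      prs_top_quintile  = older_aff & pairs$quintile_older == 5L,
      apoe_e4_carrier   = older_aff & pairs$e4_older,
      apoe_e4_noncarrier = older_aff & !pairs$e4_older)
    if (!any(qual)) return(NA_real_)
    mean(pairs$affected_younger[qual])
  }
  replicate_estimate(stat, cohort, strategy = strategy, n_rep = n_rep, seed = seed,
                     name = paste0("recurrence_", rule))
}
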