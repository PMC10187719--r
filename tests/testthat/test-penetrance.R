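test_that("stratum penetrance is the affected proportion and conserves totals", {
  co <- toy_cohort(4, 2, affected = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
                   prs = 1:8 / 8)
  r <- stratum_penetrance(co, list(stratum_rule("all", NULL, NULL, "any")))
  expect_equal(r$penetrance, 5 / 8)
  expect_identical(r$n, 8L)

  fx <- get_scored_fixture()
  sc <- fx$scored
  rules <- lapply(1:5, function(b) stratum_rule(paste0("Q", b), "QUINTILE", b))
  tab <- stratum_penetrance(sc, rules)
  expect_equal(sum(tab$n_affected), sum(sc$affected))
  expect_equal(sum(tab$penetrance * tab$n) / sum(tab$n), mean(sc$affected))
  # empty stratum: proportion missing with n = 0
  none <- stratum_penetrance(co, list(stratum_rule("none", "QUINTILE", 99)))
  expect_identical(none$n, 0L)
  expect_true(is.na(none$penetrance))
})

test_that("unascertained top-quintile penetrance matches the probit-model closed form", {
  cfg <- sim_config(n_families = 2500, sibship_probs = c(1, 0, 0, 0, 0),
                    n_snps = 500, n_unrelated = 0, r2_apoe = 0, seed = 111)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  b <- bin_quantiles(co$g_prs, 5, ids = co$iid)
  top <- b$bin == 5
  emp <- mean(co$affected[top])
  # oracle: numerically integrate P(affected at exam | g) over the top-quintile
  # truncated distribution of g, averaging the three equal-width exam bands
  v <- cfg$r2_prs
  thr <- qnorm(1 - cfg$prevalence_schedule)
  qcut <- qnorm(0.8, sd = sqrt(v))
  oracle <- mean(vapply(thr, function(Tb) {
    integrate(function(g) dnorm(g, sd = sqrt(v)) * pnorm((g - Tb) / sqrt(1 - v)),
              qcut, Inf, rel.tol = 1e-9)$value / 0.2
  }, numeric(1)))
  n_top <- sum(top)
  se <- sqrt(oracle * (1 - oracle) / n_top)
  expect_lt(abs(emp - oracle), 3 * se)
})

test_that("discordant-pair statistic: arithmetic, exchangeability and enumeration oracle", {
  # 3 discordant pairs, 2 with the affected member holding the higher PRS
  pairs <- data.frame(discordant = c(TRUE, TRUE, TRUE, FALSE),
                      prs_tie = FALSE,
                      affected_higher = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(discordant_pair_stat(pairs), 2 / 3)
  expect_true(is.na(discordant_pair_stat(pairs[4, ])))

  # PRS independent of affection: statistic -> 0.5
  set.seed(121)
  nf <- 1500
  co <- toy_cohort(nf, 2, affected = rbinom(2 * nf, 1, 0.4) == 1,
                   prs = rnorm(2 * nf))
  pm <- sample_max_pairs(co, seed = 122)
  n_disc <- sum(pm$discordant)
  expect_lt(abs(discordant_pair_stat(pm) - 0.5), 3 * sqrt(0.25 / n_disc))

  # replicate mean matches brute-force enumeration over all discordant pairs
  fx <- get_scored_fixture()
  sc <- fx$ascertained
  rs <- replicate_estimate(function(p) discordant_pair_stat(p),
                           sc, "max_pairs", n_rep = 100, seed = 123)
  sibs <- sc[sc$role == "sibling", ]
  fams <- split(seq_len(nrow(sibs)), sibs$fid)
  vals <- unlist(lapply(fams, function(rows) {
    if (length(rows) < 2) return(NULL)
    cmb <- utils::combn(rows, 2)
    apply(cmb, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      if (sibs$affected[i] == sibs$affected[j]) return(NA_real_)
      hi <- if (sibs$PRS_STD[i] > sibs$PRS_STD[j]) i else j
      as.numeric(sibs$affected[hi])
    })
  }))
  enum <- mean(vals, na.rm = TRUE)
  expect_lt(abs(rs$mean - enum), 3 * max(rs$sd, 0.01))
  # antisymmetry: negating the PRS flips the statistic
  neg <- sc; neg$PRS_STD <- -neg$PRS_STD
  pm2 <- sample_max_pairs(sc, seed = 9)
  pmn <- sample_max_pairs(neg, seed = 9)
  expect_equal(discordant_pair_stat(pmn), 1 - discordant_pair_stat(pm2))
})

test_that("sibling PRS correlation behaves at its limits and recovers 0.5", {
  dup <- data.frame(prs_a = rnorm(50))
  dup$prs_b <- dup$prs_a
  expect_equal(sibling_prs_correlation(dup)$r, 1)

  set.seed(131)
  indep <- data.frame(prs_a = rnorm(800), prs_b = rnorm(800))
  expect_lt(abs(sibling_prs_correlation(indep)$r), 0.1)

  n <- 4000
  shared <- rnorm(n)
  half <- data.frame(prs_a = (shared + rnorm(n)) / sqrt(2),
                     prs_b = (shared + rnorm(n)) / sqrt(2))
  r <- sibling_prs_correlation(half, seed = 132)$r
  expect_lt(abs(r - 0.5), 3 * (1 - 0.25) / sqrt(n - 3))

  degen <- data.frame(prs_a = rep(1, 10), prs_b = rep(1, 10))
  expect_true(sibling_prs_correlation(degen)$degenerate)
})

test_that("percentile concordance: limits, independence and the orthant oracle", {
  both <- data.frame(pctile_a = c(0.99, 0.995, 0.85), pctile_b = c(0.985, 0.99, 0.87))
  expect_equal(percentile_concordance(both, 0.05)$concordance, 1)

  set.seed(141)
  n <- 50000
  indep <- data.frame(pctile_a = runif(n), pctile_b = runif(n))
  pc <- percentile_concordance(indep, 0.20)
  expect_lt(abs(pc$concordance - 0.2), 3 * sqrt(0.2 * 0.8 / pc$n_index))

  # bivariate normal, rho = 0.5: P(Y in top 20% | X in top 20%) by quadrature
  rho <- 0.5
  q <- qnorm(0.8)
  orthant <- integrate(function(x) dnorm(x) * pnorm((rho * x - q) / sqrt(1 - rho^2)),
                       q, Inf, rel.tol = 1e-10)$value / 0.2
  expect_equal(round(orthant, 2), 0.44)  # sanity anchor for the oracle itself
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  bvn <- data.frame(pctile_a = pnorm(z1), pctile_b = pnorm(z2))
  pb <- percentile_concordance(bvn, 0.20)
  expect_lt(abs(pb$concordance - orthant), 3 * sqrt(orthant * (1 - orthant) / pb$n_index))
  # concordance(p) >= p under positive correlation
  pall <- percentile_concordance(bvn)
  expect_true(all(pall$concordance >= pall$threshold))
})

test_that("logistic association is calibrated under the null and ordered by information", {
  set.seed(151)
  cover <- 0L
  for (i in 1:100) {
    n <- 400
    co <- data.frame(affected = rbinom(n, 1, 0.35) == 1, age = rnorm(n, 75, 5),
                     sex = sample(1:2, n, TRUE), PC1 = rnorm(n), PC2 = rnorm(n),
                     PC3 = rnorm(n), PRS_STD = rnorm(n), apoe_e4 = FALSE)
    f <- fit_ad_association(co)
    if (f$ci[1] <= 1 && f$ci[2] >= 1) cover <- cover + 1L
  }
  expect_gte(cover, 93L)

  fx <- get_scored_fixture()
  f_prs <- fit_ad_association(fx$scored, "PRS_STD")
  f_ad <- fit_ad_association(fx$scored, "PRS_AD_STD")
  expect_gt(f_ad$or, f_prs$or)
  expect_gt(f_ad$r2, f_prs$r2)
  expect_gt(f_prs$or, 1)
  expect_true(f_prs$ci[1] < f_prs$or && f_prs$or < f_prs$ci[2])
  expect_true(f_prs$r2 >= 0 && f_prs$r2 <= 1)
})

test_that("age-at-onset regression recovers a constructed effect", {
  set.seed(161)
  n <- 500
  score <- rnorm(n)
  co <- data.frame(affected = TRUE, age = 80 - 2 * score + rnorm(n, sd = 3),
                   PRS_STD = score, PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
                   QUINTILE = bin_quantiles(score, 5)$bin)
  fit <- fit_aao_model(co)
  se <- 3 / sqrt(n)  # approximate SE of the slope with unit-variance score
  expect_lt(abs(fit$effect_per_sd - (-2)), 3 * se)
  expect_lt(fit$p, 1e-10)
  expect_lt(fit$mean_aao_top_quintile, fit$mean_aao_bottom_quintile)
  expect_error(fit_aao_model(co[1:5, ]), "fewer than 10")
})
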