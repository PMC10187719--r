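test_that("simulation is deterministic given the seed and rejects bad configs", {
  cfg <- sim_config(n_families = 40, n_snps = 100, n_unrelated = 20, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$panel$snps, b$panel$snps)

  expect_error(sim_config(r2_prs = 0.5, r2_apoe = 0.2, r2_polygenic = 0.4),
               "variance budget")
  expect_error(sim_config(prevalence_schedule = c(`65` = 0.2, `75` = 0.1)),
               "increasing")
  expect_error(sim_config(apoe_e4_freq = 0.6, apoe_e2_freq = 0.5), "APOE")
})

test_that("liability decomposes into the configured variance components", {
  fx <- get_scored_fixture()
  co <- fx$sim$cohort
  cfg <- fx$cfg
  # component scales are calibrated in-sample, so these are near-exact
  expect_equal(var(co$g_prs), cfg$r2_prs, tolerance = 1e-6)
  expect_equal(var(co$g_apoe), cfg$r2_apoe, tolerance = 1e-6)
  n <- nrow(co)
  expect_lt(abs(var(co$g_poly) - cfg$r2_polygenic), 3 * cfg$r2_polygenic * sqrt(2 / n))
  # total liability variance ~ 1 (components are uncorrelated by construction)
  expect_lt(abs(var(co$liability) - 1), 0.06)
})

test_that("zero PRS effect yields a score uncorrelated with affection", {
  cfg <- sim_config(n_families = 1500, n_snps = 200, n_unrelated = 200,
                    r2_prs = 0, r2_apoe = 0, seed = 11)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$cohort$g_prs == 0))
  stats <- generate_summary_stats(sim$panel, seed = 12)
  sc <- score_cohort(sim$cohort, sim$panel, stats,
                     params = clump_params(p_threshold = 1))
  n <- nrow(sc)
  expect_lt(abs(cor(sc$PRS_STD, sc$affected)), 3.5 / sqrt(n))
})

test_that("Mendelian transmission gives sibling PRS-component correlation 0.5", {
  cfg <- sim_config(n_families = 3000, sibship_probs = c(1, 0, 0, 0, 0),
                    n_snps = 300, n_unrelated = 0, seed = 21)
  sim <- simulate_cohort(cfg)
  sibs <- sim$cohort[sim$cohort$role == "sibling", ]
  g1 <- sibs$g_prs[seq(1, nrow(sibs), 2)]
  g2 <- sibs$g_prs[seq(2, nrow(sibs), 2)]
  r <- cor(g1, g2)
  se <- (1 - r^2) / sqrt(length(g1) - 3)
  expect_lt(abs(r - 0.5), 3 * se)
  # per-SNP sibling dosage correlation also ~0.5 on average
  d <- sim$panel$dosage
  d1 <- d[sibs$iid[seq(1, nrow(sibs), 2)], 1:100]
  d2 <- d[sibs$iid[seq(2, nrow(sibs), 2)], 1:100]
  per_snp <- vapply(1:100, function(j) suppressWarnings(cor(d1[, j], d2[, j])),
                    numeric(1))
  expect_lt(abs(mean(per_snp, na.rm = TRUE) - 0.5), 0.02)
})

test_that("onset assignment respects liability limits and calibrates prevalence", {
  sched <- c(`65` = 0.03, `75` = 0.17, `85` = 0.32)
  hi <- assign_onset(rep(Inf, 50), sched, exam_age = runif(50, 65, 95))
  expect_true(all(hi$affected))
  expect_true(all(hi$age >= 65 & hi$age < 75))   # onset in the first band
  lo <- assign_onset(rep(-Inf, 50), sched, exam_age = runif(50, 65, 95))
  expect_true(all(!lo$affected))

  set.seed(31)
  n <- 4e5
  res <- assign_onset(rnorm(n), sched, exam_age = rep(90, n))
  se <- sqrt(0.32 * 0.68 / n)
  expect_lt(abs(mean(res$affected) - 0.32), 3 * se)
  res2 <- assign_onset(rnorm(n), sched, exam_age = rep(70, n))
  expect_lt(abs(mean(res2$affected) - 0.03), 3 * sqrt(0.03 * 0.97 / n))
})

test_that("ascertainment keeps only multiplex families and flags singleton cases", {
  co <- toy_cohort(3, 2, affected = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                   age = c(70, 72, 70, 75, 59, 58))
  asc <- ascertain_families(co)
  # F0001: no affected; F0003: both onsets <= 60 -> only F0002 kept
  expect_identical(unique(asc$fid), "F0002")

  fx <- get_scored_fixture()
  asc2 <- ascertain_families(fx$sim$cohort)
  expect_gt(mean(asc2$g_prs[asc2$role == "sibling"]),
            mean(fx$sim$cohort$g_prs))
  expect_true(all(asc2$affected[asc2$unrelated_case]))
})

test_that("summary statistics are calibrated under the null and recover signs", {
  cfg <- sim_config(n_families = 50, n_snps = 1000, n_unrelated = 0,
                    r2_prs = 0, r2_apoe = 0, seed = 41)
  simn <- simulate_cohort(cfg)
  st <- generate_summary_stats(simn$panel, seed = 42)
  null_p <- st$P[st$SNP %in% simn$panel$snps$id[simn$panel$snps$beta_true == 0]]
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)

  fx <- get_scored_fixture()
  st0 <- generate_summary_stats(fx$sim$panel, noise = FALSE, flip_frac = 0, seed = 43)
  expect_equal(st0$BETA, fx$sim$panel$snps$beta_true)
  # strong observed effects agree in sign with the true effects
  stn <- fx$stats
  truth <- fx$sim$panel$snps$beta_true[match(stn$SNP, fx$sim$panel$snps$id)]
  # orient reported betas back to the alt allele before comparing signs
  alt <- fx$sim$panel$snps$alt[match(stn$SNP, fx$sim$panel$snps$id)]
  b <- ifelse(stn$A1 == alt, stn$BETA, -stn$BETA)
  strong <- abs(stn$BETA / stn$SE) > 3 & truth != 0
  expect_gt(mean(sign(b[strong]) == sign(truth[strong])), 0.9)
})

test_that("summary stats of a mismatched panel fail clumping loudly", {
  fx <- get_scored_fixture()
  st <- fx$stats
  st$SNP <- paste0("zz", st$SNP)
  expect_error(clump_snps(st, fx$sim$panel), "overlap")
})
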