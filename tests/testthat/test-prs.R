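test_that("greedy clumping follows the p-value ordering and r2 bound", {
  # r2(1,2) = 0.5 removes SNP2; r2(1,3) = 0.1 keeps SNP3
  panel <- panel_with_correlations(r12 = sqrt(0.5), r13 = sqrt(0.1))
  st <- data.frame(SNP = c("SNP1", "SNP2", "SNP3"), CHR = "1",
                   BP = panel$snps$pos, A1 = "G", A2 = "A",
                   BETA = 0.1, SE = 0.02, P = c(0.001, 0.01, 0.05), MAF = 0.3,
                   stringsAsFactors = FALSE)
  res <- clump_snps(st, panel, clump_params(p_threshold = 0.1, r2_max = 0.2,
                                            window_bp = 10000))
  expect_setequal(res$retained, c("SNP1", "SNP3"))
  expect_identical(res$report$status[res$report$SNP == "SNP2"], "removed_ld")
  expect_identical(res$report$removed_by[res$report$SNP == "SNP2"], "SNP1")

  # mutually uncorrelated SNPs below threshold are all retained
  panel2 <- panel_with_correlations(r12 = 0, r13 = 0)
  res2 <- clump_snps(st, panel2, clump_params(window_bp = 10000))
  expect_setequal(res2$retained, c("SNP1", "SNP2", "SNP3"))
})

test_that("clumping matches an independent brute-force greedy reference", {
  cfg <- sim_config(n_families = 60, n_snps = 200, n_unrelated = 40, seed = 61)
  sim <- simulate_cohort(cfg)
  for (s in c(62, 63, 64)) {
    st <- generate_summary_stats(sim$panel, seed = s)
    st$P <- sample(st$P)  # scramble so the greedy order is nontrivial
    params <- clump_params(p_threshold = 0.5, r2_max = 0.2, window_bp = 250000)
    got <- sort(clump_snps(st, sim$panel, params)$retained)
    expect_identical(got, brute_force_clump(st, sim$panel, params))
  }
})

test_that("PRS arithmetic, allele flips and the APOE exclusion behave exactly", {
  dos <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("I", 1:3), "s1"))
  panel <- structure(list(
    snps = data.frame(id = "s1", chr = "1", pos = 100L, ref = "A", alt = "G",
                      maf = 0.3, block = 1L, beta_true = 0),
    dosage = dos), class = "genotype_panel")
  w <- data.frame(SNP = "s1", A1 = "G", A2 = "A", BETA = log(1.5))
  expect_equal(unname(compute_prs(panel, w, exclusion = NULL)),
               log(1.5) * c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(round(unname(compute_prs(panel, w, exclusion = NULL)), 3),
               c(0, 0.405, 0.811), ignore_attr = TRUE)
  # reported on the other allele: same scores up to the constant 2*beta
  wf <- data.frame(SNP = "s1", A1 = "A", A2 = "G", BETA = -log(1.5))
  expect_equal(unname(compute_prs(panel, wf, exclusion = NULL)),
               log(1.5) * c(0, 1, 2) - 2 * log(1.5), ignore_attr = TRUE)
  # unresolvable alleles are dropped with a warning
  wb <- rbind(w, data.frame(SNP = "s1", A1 = "T", A2 = "C", BETA = 1))
  wb$SNP <- c("s1", "s1")
  expect_warning(compute_prs(panel, wb, exclusion = NULL), "unresolvable")

  # a SNP inside the APOE window contributes nothing
  panel2 <- structure(list(
    snps = rbind(panel$snps,
                 data.frame(id = "s2", chr = "19", pos = 43000000L, ref = "A",
                            alt = "G", maf = 0.3, block = 2L, beta_true = 0)),
    dosage = cbind(dos, s2 = c(2, 2, 2))), class = "genotype_panel")
  w2 <- rbind(w, data.frame(SNP = "s2", A1 = "G", A2 = "A", BETA = 5))
  expect_equal(compute_prs(panel2, w2), compute_prs(panel, w))
})

test_that("scores match a naive double-loop reference on a random instance", {
  cfg <- sim_config(n_families = 30, n_snps = 50, n_unrelated = 10, seed = 71)
  sim <- simulate_cohort(cfg)
  st <- generate_summary_stats(sim$panel, seed = 72)
  w <- st[1:50, ]
  # naive reference with explicit allele orientation and mean imputation
  D <- sim$panel$dosage[, match(w$SNP, sim$panel$snps$id)]
  alt <- sim$panel$snps$alt[match(w$SNP, sim$panel$snps$id)]
  expected <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) {
    s <- 0
    for (j in seq_len(nrow(w))) {
      d_eff <- if (w$A1[j] == alt[j]) D[i, j] else 2 - D[i, j]
      s <- s + w$BETA[j] * d_eff
    }
    expected[i] <- s
  }
  got <- compute_prs(sim$panel, w, exclusion = NULL)
  expect_equal(unname(got), expected, tolerance = 1e-12, ignore_attr = TRUE)
  # permuting the weight rows changes nothing
  got2 <- compute_prs(sim$panel, w[sample(nrow(w)), ], exclusion = NULL)
  expect_equal(got, got2)
})

test_that("covariate adjustment residualizes exactly", {
  set.seed(81)
  pcs <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  s <- rnorm(100)
  expect_equal(adjust_covariates(s, NULL), s - mean(s))
  expect_equal(adjust_covariates(s, pcs * 0), s - mean(s))
  expect_lt(max(abs(adjust_covariates(3 + 2 * pcs[, 1], pcs[, 1, drop = FALSE]))),
            1e-10)
  adj <- adjust_covariates(s + pcs %*% c(1, -2, 0.5), pcs)
  expect_lt(max(abs(cor(adj, pcs))), 1e-8)
  expect_warning(adjust_covariates(s, cbind(pcs, PC4 = pcs[, 1])), "collinear")
})

test_that("PRS.AD adds the two APOE-tag SNP effects", {
  prs <- c(a = 1, b = 2, c = 3)
  d <- cbind(e4 = c(2, 0, 1), e2 = c(0, 0, 1))
  expect_equal(make_prs_ad(prs, d, c(0, 0)), prs)
  withad <- make_prs_ad(prs, d, c(0.5, -0.2))
  expect_equal(unname(withad[1] - withad[2]), (1 - 2) + 2 * 0.5)
  dm <- d; dm[2, 1] <- NA
  expect_true(is.na(make_prs_ad(prs, dm, c(0.5, -0.2))[2]))
})

test_that("quantile bins are balanced, deterministic under ties, and sort-consistent", {
  set.seed(91)
  s <- sample(rnorm(100))
  b <- bin_quantiles(s, 5)
  expect_identical(as.integer(table(b$bin)), rep(20L, 5))
  # all-equal scores: the stable id order forces the assignment
  ids <- sprintf("I%03d", 1:100)
  b_tie1 <- bin_quantiles(rep(1, 100), 5, ids = ids)
  b_tie2 <- bin_quantiles(rep(1, 100), 5, ids = ids)
  expect_identical(b_tie1, b_tie2)
  expect_identical(as.integer(table(b_tie1$bin)), rep(20L, 5))
  expect_identical(b_tie1$bin[order(ids)], rep(1:5, each = 20))
  # sort-based oracle for deciles
  s2 <- rnorm(237)
  b10 <- bin_quantiles(s2, 10)
  oracle <- ceiling(rank(s2, ties.method = "first") * 10 / 237)
  expect_identical(b10$bin, as.integer(oracle))
  expect_equal(b10$pctile, rank(s2, ties.method = "first") / 237)
  expect_error(bin_quantiles(s, 1), "at least 2")
})

test_that("computed PRS tracks the true polygenic component as noise vanishes", {
  fx <- get_scored_fixture()
  st0 <- generate_summary_stats(fx$sim$panel, noise = FALSE, seed = 93)
  sc0 <- score_cohort(fx$sim$cohort, fx$sim$panel, st0,
                      params = clump_params(p_threshold = 1, r2_max = 0.99))
  expect_gt(cor(sc0$PRS_STD, sc0$g_prs), 0.95)
  expect_gt(cor(sc0$PRS_STD, sc0$g_prs), cor(fx$scored$PRS_STD, fx$scored$g_prs))
})
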