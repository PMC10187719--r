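# Shared fixtures, built once per test run. Seeds are fixed up front.

fixture_env <- new.env(parent = emptyenv())

# moderate multiplex cohort with genotypes, sumstats and scores
get_scored_fixture <- function() {
  if (is.null(fixture_env$scored)) {
    cfg <- sim_config(n_families = 400, n_snps = 400, n_unrelated = 150, seed = 101)
    sim <- simulate_cohort(cfg)
    stats <- generate_summary_stats(sim$panel, seed = 102)
    fixture_env$cfg <- cfg
    fixture_env$sim <- sim
    fixture_env$stats <- stats
    fixture_env$scored <- score_cohort(sim$cohort, sim$panel, stats)
    fixture_env$ascertained <- score_cohort(ascertain_families(sim$cohort),
                                            sim$panel, stats)
  }
  fixture_env
}

# hand-built cohort: nf families of constant sibship size with supplied columns
toy_cohort <- function(nf, sibs_per_fam, affected, prs = NULL, age = NULL,
                       quintile = NULL, e4 = NULL) {
  n <- nf * sibs_per_fam
  fid <- rep(sprintf("F%04d", seq_len(nf)), each = sibs_per_fam)
  iid <- paste0(fid, "_S", rep(seq_len(sibs_per_fam), nf))
  d <- data.frame(fid = fid, iid = iid, father = paste0(fid, "_P1"),
                  mother = paste0(fid, "_P2"), role = "sibling",
                  sex = rep(1:2, length.out = n),
                  affected = affected,
                  age = if (is.null(age)) rep(seq(70, 80, length.out = sibs_per_fam), nf) else age,
                  apoe_e4 = if (is.null(e4)) rep(FALSE, n) else e4,
                  stringsAsFactors = FALSE)
  if (!is.null(prs)) {
    d$PRS_STD <- prs
    b5 <- bin_quantiles(prs, 5, ids = iid)
    d$QUINTILE <- if (is.null(quintile)) b5$bin else quintile
    d$DECILE <- if (n >= 10) bin_quantiles(prs, 10, ids = iid)$bin else NA_integer_
    d$PCTILE <- b5$pctile
  }
  class(d) <- c("fam_cohort", "data.frame")
  d
}

# independent brute-force greedy clumping reference (kept deliberately naive)
brute_force_clump <- function(stats, panel, params) {
  st <- stats[stats$SNP %in% panel$snps$id, , drop = FALSE]
  st <- st[st$MAF >= params$maf_min & st$P <= params$p_threshold, , drop = FALSE]
  remaining <- st[order(st$P, st$SNP), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    kept <- c(kept, top$SNP)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      if (remaining$CHR[i] == top$CHR &&
          abs(remaining$BP[i] - top$BP) <= params$window_bp) {
        x <- panel$dosage[, match(top$SNP, panel$snps$id)]
        y <- panel$dosage[, match(remaining$SNP[i], panel$snps$id)]
        r2 <- suppressWarnings(stats::cor(x, y)^2)
        if (!is.na(r2) && r2 >= params$r2_max) drop[i] <- TRUE
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}

# panel with prescribed sample correlations between continuous dosage columns
panel_with_correlations <- function(r12, r13, n = 200, window_ok = TRUE) {
  set.seed(99)
  z <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  z <- sweep(z, 2, colMeans(z))
  z <- sweep(z, 2, apply(z, 2, sd), "/")
  x1 <- z[, 1]
  x2 <- r12 * z[, 1] + sqrt(1 - r12^2) * z[, 2]
  x3 <- r13 * z[, 1] + sqrt(1 - r13^2) * z[, 3]
  # shift/scale into [0, 2]; correlations are unaffected
  resc <- function(x) (x - min(x)) / (max(x) - min(x)) * 2
  dos <- cbind(SNP1 = resc(x1), SNP2 = resc(x2), SNP3 = resc(x3))
  rownames(dos) <- paste0("I", seq_len(n))
  pos <- if (window_ok) c(1000L, 2000L, 3000L) else c(1000L, 2000000L, 4000000L)
  structure(list(
    snps = data.frame(id = colnames(dos), chr = "1", pos = pos,
                      ref = "A", alt = "G", maf = 0.3, block = 1L,
                      beta_true = 0, stringsAsFactors = FALSE),
    dosage = dos), class = "genotype_panel")
}
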