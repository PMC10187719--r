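#' Association + recurrence summary table (four score/stratum models)
#'
#' One row per model (PRS, PRS.AD, PRS within APOE-e4 carriers, PRS within
#' non-carriers): odds ratio per SD with Wald CI, Nagelkerke R2, and the
#' liability-threshold sibling recurrence risk implied by that R2 at the
#' 99th/95th/90th/80th proband percentiles.
#'
#' @param cohort scored cohort.
#' @param K prevalence used for the recurrence columns.
#' @param percentiles proband percentile thresholds.
#' @return data.frame, one row per model.
#' @export
association_recurrence_table <- function(cohort, K = 0.13,
                                         percentiles = c(0.99, 0.95, 0.90, 0.80)) {
  specs <- list(
    list(label = "AD ~ PRS + AGE + SEX + PCs", score = "PRS_STD", apoe = "any"),
    list(label = "AD ~ PRS.AD + AGE + SEX + PCs", score = "PRS_AD_STD", apoe = "any"),
    list(label = "AD ~ PRS + AGE + SEX + PCs within APOE e4 carriers",
         score = "PRS_STD", apoe = "carrier"),
    list(label = "AD ~ PRS + AGE + SEX + PCs within APOE e4 non-carriers",
         score = "PRS_STD", apoe = "noncarrier"))
  rows <- lapply(specs, function(sp) {
    fit <- fit_ad_association(cohort, score_col = sp$score, apoe_filter = sp$apoe)
    rec <- vapply(percentiles, function(q)
      liability_recurrence(K = K, r2 = min(fit$r2, 0.99), q = q), numeric(1))
    out <- data.frame(model = sp$label, or = fit$or, ci_low = fit$ci[1],
                      ci_high = fit$ci[2], r2 = fit$r2, n = fit$n)
    out[paste0("rec_pct_", 100 * percentiles)] <- as.list(rec)
    out
  })
  do.call(rbind, rows)
}

default_penetrance_rules <- function() {
  list(
    stratum_rule("APOE e4 allele", apoe = "carrier"),
    stratum_rule("Non-APOE e4 allele", apoe = "noncarrier"),
    stratum_rule("PRS in highest quintile", "QUINTILE", 5),
    stratum_rule("PRS in lowest quintile", "QUINTILE", 1),
    stratum_rule("APOE e4 carriers and PRS in the highest quintile", "QUINTILE", 5, "carrier"),
    stratum_rule("APOE e4 carriers and PRS in the lowest quintile", "QUINTILE", 1, "carrier"),
    stratum_rule("APOE e4 non-carriers and PRS in the highest quintile", "QUINTILE", 5, "noncarrier"),
    stratum_rule("APOE e4 non-carriers and PRS in the lowest quintile", "QUINTILE", 1, "noncarrier"),
    stratum_rule("PRS in highest decile", "DECILE", 10),
    stratum_rule("PRS in lowest decile", "DECILE", 1),
    stratum_rule("APOE e4 carriers and PRS in the highest decile", "DECILE", 10, "carrier"),
    stratum_rule("APOE e4 carriers and PRS in the lowest decile", "DECILE", 1, "carrier"),
    stratum_rule("APOE e4 non-carriers and PRS in the highest decile", "DECILE", 10, "noncarrier"),
    stratum_rule("APOE e4 non-carriers and PRS in the lowest decile", "DECILE", 1, "noncarrier"))
}

#' Penetrance table by score quantile and APOE stratum
#'
#' Crude penetrance for the standard strata (APOE carrier status alone, top and
#' bottom PRS quintiles/deciles, and their APOE-stratified combinations),
#' evaluated in everyone and restricted to sibships.
#'
#' @param cohort scored cohort.
#' @return data.frame: label, counts and penetrance under both scopes.
#' @export
penetrance_table <- function(cohort) {
  rules <- default_penetrance_rules()
  ev <- stratum_penetrance(cohort, rules, scope = "everyone")
  sb <- stratum_penetrance(cohort, rules, scope = "sibships")
  data.frame(label = ev$label,
             n_everyone = ev$n, penetrance_everyone = ev$penetrance,
             n_sibships = sb$n, penetrance_sibships = sb$penetrance,
             stringsAsFactors = FALSE)
}

#' Discordant sibling-pair table across replicate pairings
#'
#' Mean (SD) over replicate pair sets of the proportion of discordant pairs in
#' which the higher-PRS sibling is affected, overall and within the standard
#' quantile/APOE strata, under both pairing strategies.
#'
#' @param cohort scored cohort.
#' @param n_rep replicates per strategy.
#' @param seed master seed.
#' @return data.frame with mean/sd columns per strategy.
#' @export
discordant_pair_table <- function(cohort, n_rep = 100, seed = 1L) {
  rows <- list(
    list("Overall", NULL, NULL, "any"),
    list("PRS in highest quintile", "quintile", 5, "any"),
    list("PRS in lowest quintile", "quintile", 1, "any"),
    list("APOE e4 carriers and highest quintile", "quintile", 5, "both_carriers"),
    list("APOE e4 carriers and lowest quintile", "quintile", 1, "both_carriers"),
    list("APOE e4 non-carriers and highest quintile", "quintile", 5, "both_noncarriers"),
    list("APOE e4 non-carriers and lowest quintile", "quintile", 1, "both_noncarriers"),
    list("PRS in highest decile", "decile", 10, "any"),
    list("PRS in lowest decile", "decile", 1, "any"),
    list("APOE e4 carriers and highest decile", "decile", 10, "both_carriers"),
    list("APOE e4 carriers and lowest decile", "decile", 1, "both_carriers"),
    list("APOE e4 non-carriers and highest decile", "decile", 10, "both_noncarriers"),
    list("APOE e4 non-carriers and lowest decile", "decile", 1, "both_noncarriers"))
  out <- lapply(rows, function(r) {
    stat <- function(pairs) discordant_pair_stat(pairs, bin_col = r[[2]],
                                                 bin = r[[3]], apoe = r[[4]])
    one <- replicate_estimate(stat, cohort, "one_per_family", n_rep, seed, r[[1]])
    mx <- replicate_estimate(stat, cohort, "max_pairs", n_rep, seed + n_rep, r[[1]])
    data.frame(label = r[[1]],
               one_pair_mean = one$mean, one_pair_sd = one$sd,
               max_pairs_mean = mx$mean, max_pairs_sd = mx$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Empirical sibling recurrence table
#'
#' Mean (SD) across replicate pairings of the proportion of younger siblings
#' affected when the older sibling is affected and carries each risk class,
#' under both pairing strategies.
#'
#' @inheritParams discordant_pair_table
#' @return data.frame, one row per risk class.
#' @export
empirical_recurrence_table <- function(cohort, n_rep = 100, seed = 1L) {
  rules <- c(apoe_e4_carrier = "Older sibling affected, APOE e4 carrier",
             apoe_e4_noncarrier = "Older sibling affected, APOE e4 non-carrier",
             prs_top_quintile = "Older sibling affected, PRS in highest quintile")
  out <- lapply(names(rules), function(r) {
    mx <- empirical_recurrence(cohort, r, "max_pairs", n_rep, seed)
    one <- empirical_recurrence(cohort, r, "one_per_family", n_rep, seed + n_rep)
    data.frame(label = rules[[r]],
               max_pairs_mean = mx$mean, max_pairs_sd = mx$sd,
               one_pair_mean = one$mean, one_pair_sd = one$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, ascertain, score, pair, analyze and report as one
#' reproducible run: simulates a family cohort (or reloads one from
#' \code{data_dir}), emulates base-GWAS summary statistics, computes the
#' APOE-excluded PRS and PRS.AD, and writes the standard report tables
#' (association + model-based recurrence; penetrance by stratum; discordant
#' sibling pairs; analytic recurrence grid over the age-band prevalences;
#' empirical sibling recurrence) plus cumulative-risk comparisons and a
#' manifest with per-file checksums. All randomness derives from
#' \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory for tables and the manifest.
#' @param params [clump_params()] for scoring.
#' @param n_rep replicate pairings for pair-based tables.
#' @param n_perm permutations for the cumulative-risk comparison.
#' @param perm_ages ages at which group differences are tested.
#' @param K_overall overall prevalence used for the association-table
#'   recurrence columns.
#' @param write_data also write the simulated VCF/summary-stats/phenotypes
#'   under \code{out_dir/data}.
#' @param data_dir reload previously written inputs from this directory
#'   instead of simulating (analysis-only mode).
#' @param recurrence_only skip simulation entirely and emit only the analytic
#'   recurrence grid for \code{r2_values}.
#' @param r2_values named r2 vector for the recurrence grid.
#' @return invisible list of all computed objects and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         params = clump_params(),
                         n_rep = 100, n_perm = 1000,
                         perm_ages = c(65, 70, 75, 80, 85),
                         K_overall = 0.13,
                         write_data = FALSE, data_dir = NULL,
                         recurrence_only = FALSE,
                         r2_values = c(PRS = 0.068, PRS.AD = 0.12)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  rec_grid <- recurrence_table(config$prevalence_schedule, r2_values)
  files <- c(files, write_tsv(rec_grid, file.path(out_dir, "recurrence_by_age_band.tsv")))
  if (recurrence_only) {
    manifest <- write_manifest(out_dir, files, config)
    return(invisible(list(recurrence_by_age_band = rec_grid, manifest = manifest)))
  }

  if (is.null(data_dir)) {
    sim <- simulate_cohort(config)
    stats <- generate_summary_stats(sim$panel, n_gwas = config$n_gwas,
                                    seed = config$seed + 1L)
    if (write_data) {
      ddir <- file.path(out_dir, "data")
      write_cohort(sim$cohort, sim$panel, stats, ddir)
      files <- c(files, file.path(ddir, c("genotypes.vcf", "sumstats.tsv",
                                          "phenotypes.tsv", "covariates.tsv")))
    }
    cohort <- ascertain_families(sim$cohort)
    panel <- sim$panel
  } else {
    loaded <- read_cohort_dir(data_dir)
    cohort <- ascertain_families(loaded$cohort)
    panel <- loaded$panel
    stats <- loaded$stats
  }

  scored <- score_cohort(cohort, panel, stats, params = params)

  assoc <- association_recurrence_table(scored, K = K_overall)
  files <- c(files, write_tsv(assoc, file.path(out_dir, "association_recurrence.tsv")))

  pen <- penetrance_table(scored)
  files <- c(files, write_tsv(pen, file.path(out_dir, "penetrance_by_stratum.tsv")))

  disc <- discordant_pair_table(scored, n_rep = n_rep, seed = config$seed + 100L)
  files <- c(files, write_tsv(disc, file.path(out_dir, "discordant_pairs.tsv")))

  emp <- empirical_recurrence_table(scored, n_rep = n_rep, seed = config$seed + 300L)
  files <- c(files, write_tsv(emp, file.path(out_dir, "empirical_recurrence.tsv")))

  # model-based recurrence grid using the fitted r2 values from this cohort
  fitted_r2 <- c(PRS = assoc$r2[1], PRS.AD = assoc$r2[2])
  rec_fit <- recurrence_table(config$prevalence_schedule, pmin(fitted_r2, 0.99))
  files <- c(files, write_tsv(rec_fit, file.path(out_dir, "recurrence_by_age_band_fitted.tsv")))

  top <- stratum_rule("PRS highest quintile", "QUINTILE", 5)
  bot <- stratum_rule("PRS lowest quintile", "QUINTILE", 1)
  cmp <- permutation_test(scored, top, bot, ages = perm_ages,
                          n_perm = n_perm, seed = config$seed + 500L)
  cmp_df <- data.frame(age = cmp$ages, risk_top = cmp$risk_a, risk_bottom = cmp$risk_b,
                       difference = cmp$observed, p = cmp$p)
  files <- c(files, write_tsv(cmp_df, file.path(out_dir, "cumulative_risk_comparison.tsv")))

  curves <- lapply(list(top = top, bot = bot), function(g)
    cumulative_penetrance_curve(scored, g, covariates = c("sex", "PC1", "PC2", "PC3"),
                                n_boot = 100, seed = config$seed + 700L,
                                label = g$label))
  curve_df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(group = cv$label, age = cv$age, risk = cv$risk,
               lower = cv$lower, upper = cv$upper)))
  files <- c(files, write_tsv(curve_df, file.path(out_dir, "cumulative_risk_curves.tsv")))

  manifest <- write_manifest(out_dir, files, config)
  invisible(list(cohort = scored, association = assoc, penetrance = pen,
                 discordant = disc, empirical_recurrence = emp,
                 recurrence_by_age_band = rec_grid,
                 recurrence_fitted = rec_fit, comparison = cmp,
                 curves = curves, files = files, manifest = manifest))
}

write_manifest <- function(out_dir, files, config) {
  sums <- tools::md5sum(files)
  manifest <- list(package_version = as.character(utils::packageVersion("famprs")),
                   seed = config$seed,
                   n_files = length(files),
                   files = data.frame(path = basename(names(sums)),
                                      md5 = unname(sums)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Reload a written cohort directory
#'
#' Reassembles the cohort/panel/summary-stats triple from the files written by
#' [write_cohort()] so the pipeline can run in analysis-only mode.
#'
#' @param dir directory holding genotypes.vcf, sumstats.tsv, phenotypes.tsv,
#'   covariates.tsv.
#' @return list with cohort, panel, stats.
#' @export
read_cohort_dir <- function(dir) {
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  gt <- read_dosage_vcf(file.path(dir, "genotypes.vcf"))
  st <- read_sumstats(file.path(dir, "sumstats.tsv"))
  cv <- utils::read.table(file.path(dir, "covariates.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  n_e4 <- vapply(strsplit(ph$APOE, ""), function(a) sum(a == "4"), integer(1))
  n_e2 <- vapply(strsplit(ph$APOE, ""), function(a) sum(a == "2"), integer(1))
  is_parent <- ph$IID %in% c(ph$FATHER, ph$MOTHER)
  role <- ifelse(is_parent, "parent",
                 ifelse(ph$FATHER == "0" & ph$MOTHER == "0", "unrelated", "sibling"))
  cohort <- data.frame(fid = ph$FID, iid = ph$IID, father = ph$FATHER,
                       mother = ph$MOTHER, role = role, sex = ph$SEX,
                       apoe = ph$APOE, n_e4 = n_e4, n_e2 = n_e2,
                       apoe_e4 = n_e4 > 0,
                       affected = ph$STATUS == 2L, age = ph$AGE,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, cv[match(ph$IID, cv$IID), -1, drop = FALSE])
  class(cohort) <- c("fam_cohort", "data.frame")
  dose <- gt$dosage[match(ph$IID, rownames(gt$dosage)), , drop = FALSE]
  snps <- gt$snps
  snps$maf <- st$MAF[match(snps$id, st$SNP)]
  panel <- structure(list(snps = snps, dosage = dose), class = "genotype_panel")
  list(cohort = cohort, panel = panel, stats = st)
}
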